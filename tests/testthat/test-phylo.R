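ref_rows <- function() {
  c(A = "ACGTACGTAC", B = "ACGTACGTTT", C = "AAAAACGTAC")
}

test_that("template threading reproduces reference rows and projects indels", {
  master <- c(r1 = "AC-GTACGT", r2 = "ACCGTACGA")   # 9 columns
  # query identical to r1's ungapped sequence -> r1's gapped row exactly
  out <- template_align(c(q1 = "ACGTACGT"), master)
  expect_equal(unname(out$rows["q1"]), master[["r1"]])
  expect_equal(out$dropped[["q1"]], 0L)
  # query = r1 with one deletion -> same row with one extra gap
  out2 <- template_align(c(q2 = "ACTACGT"), master)
  expect_equal(unname(nchar(out2$rows)), unname(nchar(master[1])))
  expect_equal(sum(strsplit(out2$rows[["q2"]], "")[[1]] == "-"), 2)
  # query insertions are dropped and counted
  out3 <- template_align(c(q3 = "ACGGGTACGT"), master)
  expect_equal(nchar(out3$rows[["q3"]]), 9)
  expect_equal(out3$dropped[["q3"]], 2L)
  expect_error(template_align(c(q = "ACGT"), character()), "empty")
})

test_that("alignment distances match hand-computed p and JC values", {
  rows <- c(a = "ACGTACGTAC", b = "ACGTACGTAC")
  rows3 <- c(rows, c = "ACGTACGTTT")  # c differs from a at 2/10
  d <- distance_from_alignment(rows3, model = "raw")
  m <- as.matrix(d)
  expect_equal(m["a", "b"], 0)
  expect_equal(m["a", "c"], 0.2)
  dj <- as.matrix(distance_from_alignment(rows3, model = "JC69"))
  expect_equal(dj["a", "c"], -3 / 4 * log(1 - 4 / 3 * 0.2))
  # JC(p) >= p on (0, 0.74)
  p <- seq(0.01, 0.7, by = 0.07)
  expect_true(all(-3 / 4 * log(1 - 4 / 3 * p) >= p))
  # a pair with no shared ungapped columns errors naming the pair
  bad <- c(x = "AC--", y = "--GT", z = "ACGT")
  expect_error(distance_from_alignment(bad), "no shared ungapped columns")
})

test_that("neighbor joining recovers additive four-taxon structure", {
  # additive matrix with split AB|CD
  dm <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dm["A", "B"] <- dm["B", "A"] <- 3
  dm["A", "C"] <- dm["C", "A"] <- 5
  dm["A", "D"] <- dm["D", "A"] <- 6
  dm["B", "C"] <- dm["C", "B"] <- 6
  dm["B", "D"] <- dm["D", "B"] <- 7
  dm["C", "D"] <- dm["D", "C"] <- 7
  tr <- nj_tree(dm)
  expect_s3_class(tr, "phylo")
  expect_true(all(tr$edge.length >= 0))
  # AB|CD is the realised split
  expect_true(ape::is.monophyletic(tr, c("A", "B")))
  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers the generating topology of random additive matrices", {
  set.seed(91)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    phy <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.5))
    dm <- cophenetic(phy)
    rec <- nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(phy), ape::unroot(rec))[1], 0,
                 info = i)
  }
})

test_that("rooting places the root on the outgroup edge and detects misuse", {
  set.seed(92)
  phy <- ape::unroot(ape::rtree(6))
  rooted <- root_tree(phy, phy$tip.label[1])
  expect_true(ape::is.rooted(rooted))
  expect_error(root_tree(phy, "not_a_leaf"), "not in tree")
  # a two-leaf monophyletic outgroup roots on the stem
  cherry <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1,(E:1,F:1):1);")
  r2 <- root_tree(cherry, c("A", "B"))
  expect_true(ape::is.monophyletic(r2, c("C", "D", "E", "F")))
  # non-monophyletic outgroup is an error, not silently resolved
  expect_error(root_tree(cherry, c("A", "C")), "monophyletic")
  # rooting then unrooting preserves the topology
  expect_equal(ape::dist.topo(ape::unroot(r2), cherry)[1], 0)
})

test_that("family clade finds the MRCA leaf set and interlopers", {
  tre <- ape::read.tree(text = "(((f1:1,(f2:1,x:1):1):1,f3:1):1,(o1:1,o2:1):1);")
  fc <- family_clade(tre, c("f1", "f2", "f3"))
  expect_setequal(fc$leaves, c("f1", "f2", "f3", "x"))
  expect_equal(fc$inside_non_ref, "x")
  fc1 <- family_clade(tre, "f1")
  expect_equal(fc1$leaves, "f1")
  expect_error(family_clade(tre, c("f1", "zz")), "zz")
})

test_that("clade-based species assignment distinguishes placed/unplaced/outside", {
  # otuA sister to f1 (species S1); otuB sister to the (f1,f2) pair ->
  # family-unplaced; otuC outside the family clade
  txt <- paste0("(((((f1:1,otuA:1):1,(f2:1,f2b:1):1):1,otuB:2):1,f3:1):1,",
                "((o1:1,otuC:1):1,root2:3):1);")
  tre <- ape::root(ape::read.tree(text = txt), "root2", resolve.root = TRUE)
  map <- assign_species_by_clade(
    tre, c("otuA", "otuB", "otuC"),
    species_ref_map = list(S1 = "f1", S2 = c("f2", "f2b"), S3 = "f3"))
  expect_equal(unname(map["otuA"]), "S1")
  expect_equal(unname(map["otuB"]), "family-unplaced")
  expect_equal(unname(map["otuC"]), "outside")
  expect_error(assign_species_by_clade(tre, "ghost", list(S1 = "f1")), "ghost")
})

test_that("bootstrap support is reproducible and rewards clean splits", {
  set.seed(93)
  base <- rand_dna(200)
  groupB <- mutate_sequence(base, 40, 0, seed = 4)
  rows <- c(a1 = base, a2 = mutate_sequence(base, 2, 0, seed = 5),
            b1 = groupB, b2 = mutate_sequence(groupB, 2, 0, seed = 6),
            c1 = mutate_sequence(base, 20, 0, seed = 7))
  bs1 <- bootstrap_support(rows, n_replicates = 50, seed = 1)
  bs2 <- bootstrap_support(rows, n_replicates = 50, seed = 1)
  expect_identical(bs1$support, bs2$support)
  expect_true(all(bs1$support >= 0 & bs1$support <= 1, na.rm = TRUE))
  # the a1+a2 cherry is overwhelmingly supported
  node <- ape::getMRCA(bs1$tree, c("a1", "a2"))
  ntip <- length(bs1$tree$tip.label)
  expect_gte(bs1$support[node - ntip], 0.9)
})

test_that("Fitch length matches hand counts and the brute-force oracle", {
  rows <- c(t1 = "A", t2 = "A", t3 = "C", t4 = "C")
  tr_abcd <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  tr_acbd <- ape::read.tree(text = "((t1,t3),(t2,t4));")
  expect_equal(fitch_length(tr_abcd, rows), 1)
  expect_equal(fitch_length(tr_acbd, rows), 2)
  same <- c(t1 = "ACG", t2 = "ACG", t3 = "ACG", t4 = "ACG")
  expect_equal(fitch_length(tr_abcd, same), 0)
  # random 5-leaf alignments against exhaustive internal labelings
  set.seed(94)
  for (i in 1:6) {
    rows5 <- setNames(vapply(1:5, function(k) rand_dna(4), ""),
                      paste0("t", 1:5))
    tre <- ape::rtopology(5, rooted = FALSE, tip.label = names(rows5))
    expect_equal(fitch_length(tre, rows5),
                 brute_force_parsimony(tre, rows5), info = i)
  }
})

test_that("g1 skewness flags tree-like signal and degenerate input", {
  # direct moment computation on a hand-listed multiset
  x <- c(3, 3, 4, 10)
  mu <- mean(x); s <- sqrt(mean((x - mu)^2))
  expect_equal(taxascreen:::.g1_stat(x), mean((x - mu)^3) / s^3)
  skip_if_not_installed("e1071")
  expect_equal(taxascreen:::.g1_stat(x), e1071::skewness(x, type = 1))

  # identical rows: undefined flag set
  rows <- setNames(rep(paste(rep("A", 20), collapse = ""), 5), paste0("t", 1:5))
  g0 <- random_tree_g1(rows, n_trees = 100, seed = 2)
  expect_true(g0$undefined)

  # strongly tree-like alignment: left-skewed lengths (g1 < 0)
  set.seed(95)
  a <- rand_dna(150)
  b <- mutate_sequence(a, 30, 0, seed = 11)
  rows2 <- c(a1 = a, a2 = mutate_sequence(a, 2, 0, seed = 12),
             a3 = mutate_sequence(a, 3, 0, seed = 13),
             b1 = b, b2 = mutate_sequence(b, 2, 0, seed = 14),
             b3 = mutate_sequence(b, 3, 0, seed = 15))
  g <- random_tree_g1(rows2, n_trees = 300, seed = 3)
  expect_false(g$undefined)
  expect_lt(g$g1, 0)
  expect_error(random_tree_g1(rows2, n_trees = 50, seed = 1), ">= 100")
})
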