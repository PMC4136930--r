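md3 <- function() {
  as_sample_metadata(data.frame(
    sample_id = c("S1", "S2", "S3"), site = c("Naples", "Oslo", "Oslo"),
    date = "2010-06-15", layer = "surface", fraction = c("3-20", "3-20", "0.8-3"),
    template = "cDNA", total_reads = c(1000L, 500L, 2000L)))
}

test_that("normalisation divides by library size and group shares sum to 1", {
  counts <- matrix(c(10, 0, 5, 20, 2, 0), nrow = 3,
                   dimnames = list(c("spA", "spB", "spC"), c("S1", "S2")))
  md <- md3()[1:2, ]
  ab <- normalize_abundance(counts, md, groups = list(all = c("S1", "S2")))
  expect_equal(ab$proportions["spA", "S1"], 0.01)
  expect_equal(ab$proportions["spC", "S1"], 0.005)
  expect_equal(ab$proportions["spA", "S2"], 0.04)
  # hand-computed shares: proportions summed then renormalised
  p <- rowSums(ab$proportions)
  expect_equal(ab$group_shares[, "all"], p / sum(p))
  expect_equal(sum(ab$group_shares[, "all"]), 1)
  # zero-count species kept as explicit zeros
  expect_equal(ab$proportions["spB", "S1"], 0)
  md0 <- md; md0$total_reads <- c(0L, 500L)
  expect_error(normalize_abundance(counts, md0), "total_reads is 0")
})

test_that("the conditional tag-count pmf matches its closed form and sums to 1", {
  expect_equal(ac_pmf(0, 0, 100, 100), 0.5)
  expect_equal(ac_pmf(3, 3, 1000, 1000), choose(6, 3) / 2^7)
  for (r in c(0.5, 1, 2)) {
    expect_lt(abs(sum(ac_pmf(0:2000, 5, 1000, 1000 * r)) - 1), 1e-9)
  }
  # negative binomial identity: p(y|x) = dnbinom(y, x+1, N1/(N1+N2))
  y <- 0:60
  expect_equal(ac_pmf(y, 4, 300, 700), dnbinom(y, size = 5, prob = 0.3))
  expect_error(ac_pmf(-1, 0, 10, 10), "non-negative")
})

test_that("the tag-count test reproduces geometric-tail bounds and symmetry", {
  # x = 0, equal libraries: P(Y > y) = 2^-(y+1); upper bound is 5 at alpha 0.05
  t0 <- ac_test(0, 0, 1e5, 1e5)
  expect_equal(unname(t0$expected_range), c(0, 5))
  expect_false(t0$significant)
  expect_true(ac_test(0, 6, 1e5, 1e5)$significant)
  expect_false(ac_test(0, 5, 1e5, 1e5)$significant)
  # x = y with equal libraries: two-sided p capped at 1
  expect_equal(ac_test(7, 7, 500, 500)$p_two_sided, 1)
  # swapping the two libraries leaves significance unchanged
  set.seed(62)
  for (i in 1:20) {
    x <- rpois(1, 20); y <- rpois(1, 10)
    N1 <- 5000; N2 <- 2000
    expect_equal(ac_test(x, y, N1, N2)$significant,
                 ac_test(y, x, N2, N1)$significant, info = i)
  }
  # significance equals falling outside the expected range
  for (y in 0:12) {
    t <- ac_test(3, y, 1000, 1000)
    expect_equal(t$significant,
                 y < t$expected_range[1] || y > t$expected_range[2])
  }
})

test_that("rarefaction matches hand hypergeometric arithmetic and its bounds", {
  expect_equal(rarefaction(c(4, 1), 2)$expected_otus, 1.4)
  sizes <- c(50, 30, 20, 5, 1)
  r <- rarefaction(sizes, c(1, 10, 50, sum(sizes)))
  expect_equal(r$expected_otus[1], 1)
  expect_equal(r$expected_otus[4], length(sizes))
  expect_true(all(diff(r$expected_otus) >= 0))
  expect_error(rarefaction(sizes, sum(sizes) + 1), "exceeds")
})

test_that("rarefaction closed form agrees with Monte-Carlo subsampling", {
  sizes <- c(50, 30, 20, 5, 1)
  pool <- rep(seq_along(sizes), sizes)
  set.seed(63)
  n <- 40
  reps <- 4000
  sims <- vapply(seq_len(reps),
                 function(i) length(unique(sample(pool, n))), numeric(1))
  closed <- rarefaction(sizes, n)$expected_otus
  se <- sd(sims) / sqrt(reps)
  expect_lt(abs(mean(sims) - closed), 3 * se + 1e-8)
})

test_that("venn regions are exhaustive, exclusive, and hand-checked", {
  sets <- list(A = c(1, 2, 3), B = c(2, 3, 4), C = 3)
  v <- venn_sharing(sets)
  expect_equal(unname(v["A"]), 1)
  expect_equal(unname(v["B"]), 1)
  expect_equal(unname(v["A&B"]), 1)
  expect_equal(unname(v["A&B&C"]), 1)
  expect_equal(unname(v[c("C", "A&C", "B&C")]), c(0, 0, 0))
  expect_equal(sum(v), length(unique(unlist(sets))))
  # disjoint sets: only single-site regions populated
  vd <- venn_sharing(list(A = 1:3, B = 4:6))
  expect_equal(unname(vd[c("A", "B", "A&B")]), c(3, 3, 0))
  # identical sets: only the full intersection
  vi <- venn_sharing(list(A = 1:3, B = 1:3))
  expect_equal(unname(vi[c("A", "B", "A&B")]), c(0, 0, 3))
  expect_error(venn_sharing(list(A = 1, B = 2, C = 3, D = 4, E = 5)),
               "pairwise_sharing")
  expect_equal(pairwise_sharing(sets)["A", "B"], 2L)
})

test_that("species-site tables average fraction samples and flag presence", {
  md <- md3()
  rs <- data.frame(
    read_id = sprintf("r%02d", 1:7),
    sample_id = c("S1", "S1", "S2", "S2", "S3", "S3", "S3"),
    species = c("spA", "spA", "spA", "spB", "spA", "spB", "spB"),
    stringsAsFactors = FALSE)
  st <- species_site_table(rs, md, layer = "surface", template = "cDNA")
  # single-sample site: the share is that sample's proportion
  expect_equal(st$shares["spA", "Naples"], 2 / 1000)
  # Oslo: mean of the two fraction samples' proportions
  expect_equal(st$shares["spA", "Oslo"], mean(c(1 / 500, 1 / 2000)))
  expect_equal(st$shares["spB", "Naples"], 0)
  expect_equal(st$presence["spB", "Naples"], FALSE)
  expect_equal(st$presence["spB", "Oslo"], TRUE)
  # a species seen only at other sites keeps an explicit all-zero row
  rs3 <- rs[rs$sample_id == "S1", ]          # spA only, Naples only
  st3 <- species_site_table(rs3, md)
  expect_true("Oslo" %in% colnames(st3$shares))
  expect_equal(unname(st3$shares["spA", "Oslo"]), 0)
  expect_false(st3$presence["spA", "Oslo"])
})

test_that("tag-count comparison flags planted enrichment between datasets", {
  set.seed(64)
  species <- paste0("sp", 1:4)
  NA_ <- c(S1 = 50000, S2 = 50000)
  ca <- matrix(rpois(8, 50), 4, 2, dimnames = list(species, names(NA_)))
  cb <- ca
  cb["sp3", "S1"] <- ca["sp3", "S1"] * 10   # planted 10x enrichment
  res <- compare_datasets(ca, cb, lib_a = NA_, lib_b = NA_)
  expect_equal(nrow(res), length(species) * 2)
  expect_true(res$significant[res$species == "sp3" & res$sample_id == "S1"])
  # identical datasets: nothing significant
  res0 <- compare_datasets(ca, ca, lib_a = NA_, lib_b = NA_)
  expect_false(any(res0$significant))
})
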