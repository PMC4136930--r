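test_that("greedy capture thresholds and ties behave as specified", {
  panel <- tiny_panel()
  L <- nchar(panel$sequence[1])
  reads <- make_reads_df(c(
    panel$sequence[1],                               # exact copy of ref_A
    mutate_sequence(panel$sequence[1], 1, 0, seed = 1), # 0.95 to ref_A
    rand_dna(20)))                                   # far from everything
  set.seed(99)
  cap <- greedy_capture(reads, panel, cutoff = 0.90,
                        target_taxon = "Leptocylindraceae")
  expect_equal(cap$membership$ref_id[cap$membership$read_id == "r001"], "ref_A")
  expect_equal(cap$membership$ref_id[cap$membership$read_id == "r002"], "ref_A")
  expect_true(cap$clusters$target[cap$clusters$ref_id == "ref_A"])
  expect_false(cap$clusters$target[cap$clusters$ref_id == "ref_C"])
  expect_error(greedy_capture(reads, panel, cutoff = 1.5), "cutoff")
  # a read below the cutoff for every reference is unmatched
  low <- make_reads_df(mutate_sequence(panel$sequence[1], 5, 0, seed = 2)) # 0.75
  expect_equal(greedy_capture(low, panel, 0.90)$unmatched, "r001")
})

test_that("capture membership equals the thresholded argmax oracle", {
  cfg <- sim_config(region = "V9", seed = 13, novel_clade = c(10L, 2L))
  panel <- make_reference_panel(cfg)$panel
  set.seed(31)
  # planted identities straddling the 0.90 boundary
  seqs <- vapply(1:30, function(i) {
    k <- sample(c(5, 9, 12, 13, 14, 20), 1)
    mutate_sequence(panel$sequence[sample(6, 1)], k, 0, seed = 400 + i)
  }, "")
  reads <- make_reads_df(seqs)
  cap <- greedy_capture(reads, panel, cutoff = 0.90)
  for (k in seq_len(nrow(reads))) {
    ids <- vapply(panel$sequence, function(r) seq_identity(seqs[k], r), numeric(1))
    names(ids) <- panel$id
    best <- max(ids)
    if (best >= 0.90) {
      tied <- sort(names(ids)[round(ids, 4) == round(best, 4)])
      expect_equal(cap$membership$ref_id[cap$membership$read_id == reads$id[k]],
                   tied[1], info = k)
    } else {
      expect_true(reads$id[k] %in% cap$unmatched, info = k)
    }
  }
})

test_that("OTU reclustering partitions reads and is order-invariant", {
  base <- rand_dna(100)
  group2 <- mutate_sequence(base, 7, 0, seed = 5)   # 0.93 to base
  reads <- make_reads_df(c(rep(base, 3), rep(group2, 2),
                           mutate_sequence(base, 1, 0, seed = 6)))
  otus <- recluster_otus(reads, cutoff = 0.97)
  expect_equal(nrow(otus$otus), 2)
  # partition property
  expect_setequal(otus$membership$read_id, reads$id)
  expect_equal(anyDuplicated(otus$membership$read_id), 0)
  expect_equal(sum(otus$otus$size), nrow(reads))
  # identical reads in one OTU
  m <- otus$membership
  expect_length(unique(m$otu_id[reads$sequence[match(m$read_id, reads$id)] == base]), 1)
  # order invariance after canonical sorting
  perm <- reads[c(4, 1, 6, 2, 5, 3), ]
  otus2 <- recluster_otus(perm, cutoff = 0.97)
  expect_equal(otus$membership[order(otus$membership$read_id), ],
               otus2$membership[order(otus2$membership$read_id), ],
               ignore_attr = TRUE)
  # all-identical input collapses to a single OTU
  one <- recluster_otus(make_reads_df(rep(base, 5)), 0.97)
  expect_equal(nrow(one$otus), 1)
  expect_equal(one$otus$size, 5L)
})

test_that("greedy reclustering joins the best-matching qualifying seed", {
  # two seeds 6 apart (below a 0.95-cutoff join); the probe differs from
  # seed1 at 4 positions and from seed2 at 2, so both seeds qualify at 0.95
  # and the probe must join the better (seed2)
  set.seed(71)
  v <- strsplit(rand_dna(100), "")[[1]]
  pos <- sample(100, 6)
  flip <- function(x) chartr("ACGT", "GTAC", x)
  v2 <- v; v2[pos] <- flip(v2[pos])             # seed2: 6 diffs from seed1
  vp <- v2; vp[pos[1:2]] <- v[pos[1:2]]         # probe: revert 2 of the 6
  s1 <- paste(v, collapse = ""); s2 <- paste(v2, collapse = "")
  probe <- paste(vp, collapse = "")
  expect_equal(drop(adist(s1, probe)), 4)
  expect_equal(drop(adist(s2, probe)), 2)
  reads <- taxascreen:::.new_reads(c("a1", "a2", "a3"), "S1", c(s1, s2, probe))
  otus <- recluster_otus(reads, cutoff = 0.95)
  m <- otus$membership
  expect_equal(nrow(otus$otus), 2)
  expect_equal(m$otu_id[m$read_id == "a3"], m$otu_id[m$read_id == "a2"])
})

test_that("rare-OTU removal conserves reads and removes planted error OTUs", {
  base <- rand_dna(80)
  v1 <- mutate_sequence(base, 5, 0, seed = 1)
  v2 <- mutate_sequence(base, 5, 0, seed = 2)
  reads <- make_reads_df(c(rep(base, 4), rep(v1, 2), v2))
  otus <- recluster_otus(reads, cutoff = 0.97)
  expect_equal(sort(otus$otus$size), c(1L, 2L, 4L))
  rr <- remove_rare_otus(otus, min_size = 3)
  expect_equal(rr$kept$otus$size, 4L)
  expect_setequal(rr$removed$otus$size, c(1L, 2L))
  expect_equal(nrow(rr$kept$membership) + nrow(rr$removed$membership),
               nrow(reads))
  # min_size = 1 is the identity
  rr1 <- remove_rare_otus(otus, min_size = 1)
  expect_equal(nrow(rr1$removed$otus), 0)
  expect_equal(rr1$kept$otus, otus$otus)
})

test_that("rare-OTU removal eliminates exactly the planted rare variants", {
  cfg <- sim_config(region = "V9", reads_per_sample = 250L, seed = 23,
                    novel_clade = c(10L, 2L), chimera_rate = 0,
                    offtarget_fraction = 0, substitution_error_rate = 0,
                    plant_rare = TRUE)
  sim <- simulate_study(cfg, default_design()[1:2, ])
  otus <- recluster_otus(sim$reads, cutoff = 0.97)
  rr <- remove_rare_otus(otus, 3)
  planted <- sim$truth$reads$read_id[sim$truth$reads$type == "planted_rare"]
  expect_setequal(rr$removed$membership$read_id, planted)
})

test_that("furthest-neighbor partitions follow the hand-computed agglomeration", {
  idm <- matrix(1, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  idm["A", "B"] <- idm["B", "A"] <- 0.99   # d = 0.01
  idm["A", "C"] <- idm["C", "A"] <- 0.95   # d = 0.05
  idm["B", "C"] <- idm["C", "B"] <- 0.95
  parts <- furthest_neighbor_cluster(idm, cutoffs = c(0.95, 0.97, 1.0))
  p97 <- parts[[2]]
  expect_equal(p97[["A"]], p97[["B"]])
  expect_false(p97[["A"]] == p97[["C"]])
  p95 <- parts[[1]]                   # max within-distance 0.05 <= 0.05
  expect_length(unique(p95), 1)
  expect_length(unique(parts[[3]]), 3)
  expect_error(furthest_neighbor_cluster(idm[, 1:2, drop = FALSE], 0.97),
               "symmetric")
})

test_that("furthest-neighbor partitions are nested across cutoffs", {
  set.seed(41)
  base <- rand_dna(60)
  seqs <- vapply(c(0, 1, 2, 5, 6, 12, 13, 30), function(k)
    mutate_sequence(base, k, 0, seed = k + 50), "")
  idm <- identity_matrix(seqs)
  parts <- furthest_neighbor_cluster(idm, cutoffs = c(0.80, 0.90, 0.97))
  coarse <- parts[[1]]; mid <- parts[[2]]; fine <- parts[[3]]
  # refinement: members of one fine cluster share their mid/coarse cluster
  for (cl in unique(fine)) {
    expect_length(unique(mid[fine == cl]), 1)
    expect_length(unique(coarse[fine == cl]), 1)
  }
})

test_that("chimera screen flags midpoint chimeras of divergent parents", {
  set.seed(61)
  pa <- rand_dna(200)
  pb <- mutate_sequence(pa, 20, 0, seed = 3)   # 10% divergent parents
  panel <- taxascreen:::.new_ref_panel(
    c("ref_pa", "ref_pb"), c("Euk;Phy;Fam;G;pa", "Euk;Phy;Fam;G;pb"),
    "V4", c(pa, pb))
  chim <- paste0(substr(pa, 1, 100), substr(pb, 101, 200))
  reads <- make_reads_df(c(pa, pb, chim))
  res <- chimera_screen(reads, panel, margin = 0.02)
  expect_equal(res$detail$flagged, c(FALSE, FALSE, TRUE))
  expect_setequal(res$clean$id, c("r001", "r002"))
})

test_that("chimera flagging is precise on a simulated study", {
  cfg <- sim_config(region = "V4", reads_per_sample = 400L, seed = 303,
                    chimera_rate = 0.08, offtarget_fraction = 0,
                    novel_clade_share = 0, plant_rare = FALSE)
  sim <- simulate_study(cfg, default_design()[1:2, ])
  fam <- sim$panel[seq_along(sim$family_ids), ]
  res <- chimera_screen(sim$reads, fam, margin = 0.02)
  tr <- sim$truth$reads
  flagged <- res$detail$read_id[res$detail$flagged]
  truechim <- tr$read_id[tr$type == "chimera"]
  expect_gt(length(flagged), 0)
  precision <- mean(flagged %in% truechim)
  expect_gte(precision, 0.9)
})

test_that("clustering stages conserve per-sample counts", {
  cfg <- sim_config(region = "V9", reads_per_sample = 120L, seed = 17,
                    novel_clade = c(10L, 2L))
  sim <- simulate_study(cfg, default_design()[1:3, ])
  otus <- recluster_otus(sim$reads, cutoff = 0.97)
  per_sample_in <- table(sim$reads$sample_id)
  per_sample_out <- table(otus$membership$sample_id)
  expect_equal(as.vector(per_sample_out[names(per_sample_in)]),
               as.vector(per_sample_in))
  rr <- remove_rare_otus(otus, 3)
  tot <- table(c(rr$kept$membership$sample_id, rr$removed$membership$sample_id))
  expect_equal(as.vector(tot[names(per_sample_in)]), as.vector(per_sample_in))
})
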