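cfg_small <- function(...) {
  sim_config(region = "V9", reads_per_sample = 150L, seed = 42,
             novel_clade = c(10L, 2L), ...)
}

test_that("reference panels are deterministic and respect divergence bands", {
  cfg <- cfg_small()
  p1 <- make_reference_panel(cfg)
  p2 <- make_reference_panel(cfg)
  expect_identical(p1, p2)

  fam <- p1$panel$sequence[match(p1$family_ids, p1$panel$id)]
  im <- identity_matrix(fam)
  off <- im[upper.tri(im)]
  expect_true(all(off >= 0.93 & off <= 0.99))

  far <- p1$panel$sequence[match(p1$far_outgroup_ids, p1$panel$id)]
  for (fs in far)
    for (f in fam) expect_lt(seq_identity(fs, f), 0.80)
  og <- p1$panel$sequence[match(p1$outgroup_ids, p1$panel$id)]
  for (o in og)
    for (f in fam) {
      v <- seq_identity(o, f)
      expect_gt(v, 0.78); expect_lt(v, 0.90)
    }
})

test_that("panel generation fails for regions too short for the divergences", {
  expect_error(make_reference_panel(
    sim_config(region_length = 20L, seed = 1)), "too short")
})

test_that("mutate_sequence performs exact edit counts (Levenshtein oracle)", {
  set.seed(5)
  s <- rand_dna(390)
  expect_identical(mutate_sequence(s, 0, 0, seed = 9), s)
  m1 <- mutate_sequence(s, 29, 7, seed = 9)
  expect_equal(drop(adist(s, m1)), 36)
  m2 <- mutate_sequence(s, 29, 0, seed = 9)
  v1 <- strsplit(s, "")[[1]]; v2 <- strsplit(m2, "")[[1]]
  expect_equal(sum(v1 != v2), 29)    # Hamming when indel-free
  expect_error(mutate_sequence("ACGT", 3, 2, seed = 1), "exceeds")
  expect_identical(mutate_sequence(s, 5, 2, seed = 3),
                   mutate_sequence(s, 5, 2, seed = 3))
})

test_that("simulated studies are pure functions of (config, design, seed)", {
  cfg <- cfg_small()
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$metadata$total_reads, s2$metadata$total_reads)
})

test_that("error-free generation copies references exactly", {
  cfg <- sim_config(region = "V9", reads_per_sample = 60L, seed = 8,
                    substitution_error_rate = 0, chimera_rate = 0,
                    offtarget_fraction = 0, novel_clade = c(10L, 2L),
                    novel_clade_share = 0, plant_rare = FALSE)
  sim <- simulate_study(cfg)
  ref_seq <- setNames(sim$panel$sequence, sim$panel$id)
  fam_species <- vapply(split_path(sim$panel$taxonomy), function(p) p[length(p)], "")
  names(ref_seq) <- fam_species
  ok <- sim$reads$sequence == unname(ref_seq[sim$truth$reads$origin])
  expect_true(all(ok))
})

test_that("ground truth covers every read once and presence is by construction", {
  cfg <- cfg_small()
  sim <- simulate_study(cfg)
  expect_setequal(sim$truth$reads$read_id, sim$reads$id)
  expect_equal(anyDuplicated(sim$truth$reads$read_id), 0)
  expect_setequal(sim$truth$otu_membership$read_id, sim$reads$id)
  # novel clade restricted to one site in the default design
  expect_equal(sum(sim$truth$presence["NovelClade", ]), 1)
  # a species absent from a site contributes no reads there
  absent <- which(!sim$truth$presence, arr.ind = TRUE)
  tr <- sim$truth$reads
  for (k in seq_len(nrow(absent))) {
    sp <- rownames(sim$truth$presence)[absent[k, 1]]
    sm <- colnames(sim$truth$presence)[absent[k, 2]]
    expect_equal(sum(tr$origin == sp & tr$sample_id == sm), 0)
  }
  # metadata totals equal observed read counts
  expect_silent(validate_study(sim$reads, sim$metadata, check_totals = TRUE))
})

test_that("custom community controls which sites carry which species", {
  cfg <- cfg_small()
  design <- default_design()[1:3, ]
  comm <- matrix(0, nrow = 3, ncol = 3,
                 dimnames = list(c("Leptocylindrus danicus",
                                   "Leptocylindrus aporus",
                                   "Leptocylindrus convexus"),
                                 design$sample_id))
  comm[1, ] <- c(0.5, 1, 0.6)
  comm[2, ] <- c(0.5, 0, 0.4)
  comm[3, ] <- 0            # present nowhere
  cfg$community <- comm
  cfg$chimera_rate <- 0; cfg$offtarget_fraction <- 0; cfg$plant_rare <- FALSE
  sim <- simulate_study(cfg, design)
  expect_equal(unname(sim$truth$presence[1:3, ] * 1),
               unname((comm > 0) * 1))
  expect_equal(sum(sim$truth$reads$origin == "Leptocylindrus convexus"), 0)
  # unknown species in the community is rejected
  rownames(comm)[3] <- "Unknownia specium"
  cfg$community <- comm
  expect_error(simulate_study(cfg, design), "Unknownia")
})

test_that("measured read-to-reference identity matches the error rate", {
  cfg <- sim_config(region = "V9", reads_per_sample = 500L, seed = 77,
                    substitution_error_rate = 0.01, chimera_rate = 0,
                    offtarget_fraction = 0, novel_clade_share = 0,
                    plant_rare = FALSE, community = NULL)
  sim <- simulate_study(cfg, default_design()[1:2, ])
  tr <- sim$truth$reads
  fam_species <- vapply(split_path(sim$panel$taxonomy), function(p) p[length(p)], "")
  ref_by_sp <- setNames(sim$panel$sequence, fam_species)
  idx <- sample(nrow(tr), 1000)
  ids <- vapply(idx, function(i) {
    seq_identity(sim$reads$sequence[match(tr$read_id[i], sim$reads$id)],
                 ref_by_sp[[tr$origin[i]]])
  }, numeric(1))
  # mean identity = 1 - error_rate * 3/4... no: substitutions always change
  # the base, so expected per-base identity is 1 - rate
  p <- 1 - cfg$substitution_error_rate
  se <- sd(ids) / sqrt(length(ids))
  expect_lt(abs(mean(ids) - p), 3 * se + 1e-4)
})
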