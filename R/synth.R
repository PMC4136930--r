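#' Configuration for the synthetic amplicon study generator
#'
#' The generator emulates the structure of a two-region (V4/V9 SSU rDNA)
#' coastal metabarcoding survey of a small diatom family: a reference panel of
#' family species, related outgroup diatoms and two distant flagellate
#' outgroups; per-sample communities with species absent from some sites;
#' per-base substitution sequencing error; two-parent chimeras; off-target
#' reads from outgroup taxa; and a planted novel clade, present at a minority
#' of sites, that diverges from its nearest family reference by a fixed number
#' of substitutions and indels (default 29 + 7, just above the 0.90 capture
#' boundary for a 390 bp amplicon).
#'
#' @param n_family_species number of in-family species (>= 2).
#' @param n_outgroup_diatoms number of outgroup diatom references (>= 2).
#' @param region `"V4"` or `"V9"`; sets the default `region_length`
#'   (390 or 130 bp).
#' @param region_length amplicon length in bp; overrides the region default.
#' @param substitution_error_rate per-base substitution error probability.
#' @param chimera_rate per-read probability of being a two-parent chimera.
#' @param offtarget_fraction per-read probability of originating from an
#'   outgroup diatom.
#' @param novel_clade integer pair `c(substitutions, indels)` separating the
#'   planted novel clade from its nearest family reference.
#' @param novel_clade_share relative abundance of the novel clade at the sites
#'   where it is planted.
#' @param novel_clade_sites number of sites carrying the novel clade
#'   (default 1 of the design's sites).
#' @param novel_clade_from base sequence for the novel clade: `"nearest"`
#'   (default) mutates the common stem of the close species pair, so the
#'   novel lineage resolves below the pair's cherry, nearest to both of its
#'   members -- the geometry of a divergent sister lineage; `"ancestor"`
#'   mutates the family's ancestral sequence, placing the novelty on the
#'   family backbone (note that such basal material can legitimately look
#'   chimeric to a reference-based screen).
#' @param plant_rare also plant, per sample and present species, one singleton
#'   and one doubleton error-variant OTU, giving the rare-OTU filter known
#'   true positives.
#' @param reads_per_sample integer (scalar or per-sample vector), or `NULL` to
#'   draw each sample's depth log-uniformly from `[1e3, 1e5]`, emulating the
#'   depth disparity between sequencing runs.
#' @param community optional species x sample matrix of relative abundances
#'   (columns must sum to 1); `NULL` builds the default design
#'   (see [default_community()]).
#' @param seed integer seed; mandatory, all generation is a pure function of
#'   (config, design, seed).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_family_species = 6, n_outgroup_diatoms = 4,
                       region = c("V4", "V9"), region_length = NULL,
                       substitution_error_rate = 0.01, chimera_rate = 0.01,
                       offtarget_fraction = 0.05, novel_clade = c(29L, 7L),
                       novel_clade_share = 0.02, novel_clade_sites = 1L,
                       novel_clade_from = c("nearest", "ancestor"),
                       plant_rare = TRUE, reads_per_sample = 10000L,
                       community = NULL, seed) {
  novel_clade_from <- match.arg(novel_clade_from)
  region <- match.arg(region)
  if (missing(seed) || !is.numeric(seed))
    stop("an integer 'seed' is mandatory")
  if (is.null(region_length))
    region_length <- if (region == "V4") 390L else 130L
  probs <- c(substitution_error_rate, chimera_rate, offtarget_fraction)
  if (any(probs < 0 | probs > 1))
    stop("rates must be probabilities in [0, 1]")
  if (n_family_species < 2) stop("n_family_species must be >= 2")
  if (n_outgroup_diatoms < 2) stop("n_outgroup_diatoms must be >= 2")
  if (length(novel_clade) != 2 || any(novel_clade < 0))
    stop("novel_clade must be c(n_substitutions, n_indels)")
  cfg <- list(n_family_species = as.integer(n_family_species),
              n_outgroup_diatoms = as.integer(n_outgroup_diatoms),
              region = region, region_length = as.integer(region_length),
              substitution_error_rate = substitution_error_rate,
              chimera_rate = chimera_rate,
              offtarget_fraction = offtarget_fraction,
              novel_clade = as.integer(novel_clade),
              novel_clade_share = novel_clade_share,
              novel_clade_sites = as.integer(novel_clade_sites),
              novel_clade_from = novel_clade_from,
              plant_rare = isTRUE(plant_rare),
              reads_per_sample = reads_per_sample,
              community = community,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

.BASES <- c("A", "C", "G", "T")

.random_seq <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

# substitute k distinct positions of a character vector to a different base
.substitute_at <- function(v, pos) {
  for (p in pos) v[p] <- sample(setdiff(.BASES, v[p]), 1L)
  v
}

#' Introduce an exact number of substitutions and indels into a sequence
#'
#' Applies exactly `n_subs` substitutions (each to a different base) and
#' `n_indels` single-base insertions/deletions at distinct positions, so the
#' edit distance to the input is `n_subs + n_indels` by construction.
#' Deterministic under `seed`.
#'
#' @param seq DNA string.
#' @param n_subs,n_indels non-negative counts; their sum must not exceed
#'   `nchar(seq)`.
#' @param seed integer seed.
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(seq, n_subs, n_indels, seed) {
  seq <- .check_seq_arg(seq, "seq")
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(v)
  if (n_subs + n_indels > L)
    stop("n_subs + n_indels exceeds sequence length")
  if (n_subs == 0 && n_indels == 0) return(seq)
  set.seed(seed)
  pos <- sample.int(L, n_subs + n_indels)
  sub_pos <- pos[seq_len(n_subs)]
  indel_pos <- sort(pos[n_subs + seq_len(n_indels)], decreasing = TRUE)
  v <- .substitute_at(v, sub_pos)
  for (p in indel_pos) {
    if (stats::runif(1) < 0.5) {
      v <- v[-p]                                   # deletion
    } else {
      v <- append(v, sample(.BASES, 1L), after = p) # insertion
    }
  }
  paste(v, collapse = "")
}

.FAMILY_SPECIES <- c("Leptocylindrus danicus", "Leptocylindrus aporus",
                     "Leptocylindrus convexus", "Leptocylindrus minimus",
                     "Leptocylindrus hargravesii", "Tenuicylindrus belgicus")
.OUTGROUP_GENERA <- c("Chaetoceros", "Thalassiosira", "Skeletonema",
                      "Rhizosolenia", "Coscinodiscus", "Ditylum",
                      "Cyclotella", "Melosira")

.species_names <- function(n) {
  if (n <= length(.FAMILY_SPECIES)) return(.FAMILY_SPECIES[seq_len(n)])
  c(.FAMILY_SPECIES, paste0("Leptocylindrus sp", seq_len(n - length(.FAMILY_SPECIES))))
}

#' Generate an annotated reference panel with a master alignment
#'
#' Builds `n_family_species` mutually similar family references (pairwise
#' identity within 0.93-0.99), `n_outgroup_diatoms` outgroup diatoms at
#' 0.80-0.90 identity to the family, and two distant flagellate outgroups
#' below 0.80, all of the configured amplicon length. Family references are
#' mutated at mutually disjoint positions so their pairwise divergences are
#' exact by construction. No indels are introduced at panel level, so the
#' master alignment is the ungapped panel itself.
#'
#' @param config a [sim_config()].
#' @return A list with elements `panel` (a `ref_panel` with the two distant
#'   outgroups last), `alignment` (named character vector of master-alignment
#'   rows) and `family_ids` / `outgroup_ids` / `far_outgroup_ids`.
#' @export
make_reference_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$region_length
  nf <- config$n_family_species
  no <- config$n_outgroup_diatoms
  f <- seq(0.012, 0.030, length.out = nf)
  k <- pmax(1L, round(f * L))
  # below ~60 bp the 0.93-0.99 family band cannot be realised with whole
  # substitutions (the closest admissible pair already exceeds 7% divergence)
  if (L < 60L || sum(k) + 2L > L)
    stop("region_length too short to realise the requested divergences")
  set.seed(config$seed)
  ancestor <- strsplit(.random_seq(L), "")[[1]]

  # family: disjoint substitution blocks => exact pairwise divergences.
  # With >= 5 species, the fifth (L. hargravesii) is built as a close sister
  # of the first (L. danicus), mirroring the real family's one nearly
  # indistinguishable species pair; the planted novel clade (derived from the
  # first species) then resolves outside that cherry but inside its stem.
  k_sister <- max(4L, round(0.015 * L))
  if (sum(k) + k_sister + 2L > L)
    stop("region_length too short to realise the requested divergences")
  pool <- sample.int(L)
  offsets <- c(0L, cumsum(k))
  fam_seq <- character(nf)
  for (i in seq_len(nf)) {
    pos <- pool[(offsets[i] + 1L):offsets[i + 1L]]
    fam_seq[i] <- paste(.substitute_at(ancestor, pos), collapse = "")
  }
  pair_stem <- fam_seq[1]
  if (nf >= 5) {
    # explicit stem: both species of the close pair descend from it by
    # k_sister/2 private substitutions each, so a novel lineage derived from
    # the stem resolves below their cherry, not inside either species
    half <- max(2L, k_sister %/% 2L)
    pos <- pool[sum(k) + seq_len(2L * half)]
    stem_chars <- strsplit(fam_seq[1], "")[[1]]
    fam_seq[1] <- paste(.substitute_at(stem_chars, pos[seq_len(half)]),
                        collapse = "")
    fam_seq[5] <- paste(.substitute_at(stem_chars, pos[half + seq_len(half)]),
                        collapse = "")
  }
  fam_species <- .species_names(nf)
  fam_genus <- vapply(strsplit(fam_species, " "), `[[`, "", 1L)
  fam_id <- paste0("ref_", gsub(" ", "_", fam_species))
  fam_tax <- paste("Eukaryota", "Stramenopiles", "Bacillariophyta",
                   "Leptocylindraceae", fam_genus, fam_species, sep = ";")

  # outgroup diatoms: 0.80-0.90 identity to family members
  og_seq <- character(no)
  og_genus <- rep_len(.OUTGROUP_GENERA, no)
  for (i in seq_len(no)) {
    d <- round(stats::runif(1, 0.11, 0.16) * L)
    og_seq[i] <- paste(.substitute_at(ancestor, sample.int(L, d)), collapse = "")
  }
  og_species <- paste0(og_genus, " sim", seq_len(no))
  og_id <- paste0("ref_", gsub(" ", "_", og_species))
  og_tax <- paste("Eukaryota", "Stramenopiles", "Bacillariophyta",
                  paste0(og_genus, "aceae"), og_genus, og_species, sep = ";")

  # two distant outgroups (< 0.80 to the family): the rooting taxa; built as
  # sisters (shared deep stem, short terminal branches) so they are
  # monophyletic in any reasonable tree
  far_species <- c("Bolidomonas pacifica", "Bolidomonas mediterranea")
  far_stem <- .substitute_at(ancestor,
                             sample.int(L, round(stats::runif(1, 0.26, 0.30) * L)))
  far_seq <- character(2)
  for (i in 1:2) {
    d <- max(1L, round(stats::runif(1, 0.015, 0.03) * L))
    far_seq[i] <- paste(.substitute_at(far_stem, sample.int(L, d)), collapse = "")
  }
  far_id <- paste0("ref_", gsub(" ", "_", far_species))
  far_tax <- paste("Eukaryota", "Stramenopiles", "Bolidophyceae",
                   "Bolidomonadaceae", "Bolidomonas", far_species, sep = ";")

  panel <- .new_ref_panel(c(fam_id, og_id, far_id),
                          c(fam_tax, og_tax, far_tax),
                          config$region,
                          c(fam_seq, og_seq, far_seq))
  alignment <- stats::setNames(panel$sequence, panel$id)
  list(panel = panel, alignment = alignment,
       ancestor = paste(ancestor, collapse = ""), pair_stem = pair_stem,
       family_ids = fam_id, outgroup_ids = og_id, far_outgroup_ids = far_id)
}

#' Default 6-site sampling design
#'
#' Six coastal sites, one surface cDNA 3-20 micrometre plankton sample each.
#' `total_reads` is filled in by [simulate_study()].
#'
#' @param sites character vector of site names.
#' @return A `sample_metadata` data frame.
#' @export
default_design <- function(sites = c("Naples", "Blanes", "Oslo",
                                     "Roscoff", "Gijon", "Varna")) {
  as_sample_metadata(data.frame(
    sample_id = paste0("S_", sites), site = sites, date = "2010-06-15",
    layer = "surface", fraction = "3-20", template = "cDNA",
    total_reads = 0L, stringsAsFactors = FALSE))
}

#' Default per-sample community matrix
#'
#' One dominant species, log-spread abundances for the rest, and fixed
#' absences: the fourth species is absent from the first two (Mediterranean-
#' style) sites and the fifth from the last site, mirroring a survey in which
#' individual species are widespread but not ubiquitous. The planted novel
#' clade occupies `novel_clade_sites` sites (from the third site on) at share
#' `novel_clade_share`.
#'
#' @param species family species names (novel clade is added internally).
#' @param sample_ids design sample ids (columns).
#' @param config a [sim_config()].
#' @return A species x sample matrix whose columns sum to 1; the novel clade
#'   row is named `"NovelClade"`.
#' @export
default_community <- function(species, sample_ids, config) {
  n <- length(species)
  base <- c(0.50, 0.14, 0.12, 0.09, 0.09, 0.06)
  shares <- if (n <= 6) base[seq_len(n)] else c(base, rep(0.02, n - 6))
  m <- matrix(rep(shares, length(sample_ids)), nrow = n,
              dimnames = list(species, sample_ids))
  ns <- length(sample_ids)
  if (n >= 4 && ns >= 2) m[4, 1:2] <- 0
  if (n >= 5 && ns >= 3) m[5, ns] <- 0
  novel <- numeric(ns)
  k <- min(config$novel_clade_sites, ns)
  idx <- utils::head(seq(min(3, ns), ns), k)
  novel[idx] <- config$novel_clade_share
  m <- rbind(m, NovelClade = novel)
  sweep(m, 2, colSums(m), "/")
}

# sample() on a length-1 character vector would sample from 1:n instead
.sample_vec <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

.add_substitution_errors <- function(tmpl_chars, n_reads, rate) {
  L <- length(tmpl_chars)
  out <- character(n_reads)
  ks <- stats::rbinom(n_reads, L, rate)
  base_str <- paste(tmpl_chars, collapse = "")
  for (i in seq_len(n_reads)) {
    if (ks[i] == 0L) { out[i] <- base_str; next }
    v <- tmpl_chars
    out[i] <- paste(.substitute_at(v, sample.int(L, ks[i])), collapse = "")
  }
  out
}

#' Simulate a full amplicon study with ground truth
#'
#' Draws, per sample, reads from the configured community with per-base
#' substitution errors; a configured fraction are two-parent chimeras (5' of
#' one family parent joined to the 3' of another at a uniform breakpoint) and
#' a configured fraction are off-target reads copied from outgroup diatom
#' references. A novel clade sequence (built from the first family reference
#' with the configured substitutions + indels) is planted at a minority of
#' sites. Optionally plants, per sample and present species, one singleton and
#' one doubleton divergent error-variant so the rare-OTU filter has known true
#' positives. Everything is a pure function of `(config, design, seed)`.
#'
#' @param config a [sim_config()].
#' @param design a `sample_metadata` data frame (defaults to
#'   [default_design()]); `total_reads` is overwritten with the realised
#'   depths.
#' @return A list with `reads` (`amplicon_reads`), `metadata`
#'   (`sample_metadata`), `panel`, `alignment`, `community`, `novel_sequence`
#'   and `truth`. `truth` holds `reads` (per-read `origin`, its type and
#'   chimera parents), `presence` (species x sample logical matrix including
#'   the novel clade) and `otu_membership` (read id -> true group, where
#'   chimeras, off-target reads and each planted rare variant form their own
#'   groups).
#' @export
simulate_study <- function(config, design = default_design()) {
  stopifnot(inherits(config, "sim_config"))
  design <- as_sample_metadata(as.data.frame(design))
  if (nrow(design) == 0) stop("design must be non-empty")
  ref <- make_reference_panel(config)
  panel <- ref$panel
  fam_ids <- ref$family_ids
  fam_species <- vapply(split_path(panel$taxonomy[match(fam_ids, panel$id)]),
                        function(p) p[[length(p)]], "")
  set.seed(config$seed)

  community <- config$community
  if (is.null(community))
    community <- default_community(fam_species, design$sample_id, config)
  if (is.null(rownames(community)) || is.null(colnames(community)))
    stop("community must have species rownames and sample colnames")
  if (!all(colnames(community) == design$sample_id))
    stop("community columns must match the design sample ids")
  if (any(abs(colSums(community) - 1) > 1e-9))
    stop("community columns must each sum to 1")
  sp_names <- rownames(community)
  known <- setdiff(sp_names, "NovelClade")
  missing_sp <- setdiff(known, fam_species)
  if (length(missing_sp))
    stop("community names species absent from the panel: ",
         paste(missing_sp, collapse = ", "))

  # template sequences per community row
  L <- config$region_length
  novel_seq <- NULL
  tmpl <- list()
  for (sp in sp_names) {
    if (sp == "NovelClade") {
      if (sum(config$novel_clade) > L)
        stop("novel_clade edits exceed region_length")
      novel_base <- if (identical(config$novel_clade_from, "ancestor"))
        ref$ancestor else ref$pair_stem
      novel_seq <- mutate_sequence(novel_base,
                                   config$novel_clade[1], config$novel_clade[2],
                                   seed = config$seed + 1L)
      tmpl[[sp]] <- strsplit(novel_seq, "")[[1]]
    } else {
      tmpl[[sp]] <- strsplit(panel$sequence[match(fam_ids[match(sp, fam_species)],
                                                  panel$id)], "")[[1]]
    }
  }
  # off-target pool: outgroup diatoms plus the two distant flagellates, so
  # both the taxon filter and the capture stage see true negatives
  offtarget_ids <- c(ref$outgroup_ids, ref$far_outgroup_ids)
  og_chars <- lapply(offtarget_ids,
                     function(i) strsplit(panel$sequence[match(i, panel$id)], "")[[1]])
  set.seed(config$seed + 2L)

  depths <- config$reads_per_sample
  if (is.null(depths)) {
    depths <- round(10^stats::runif(nrow(design), 3, 5))
  } else {
    depths <- rep_len(as.integer(depths), nrow(design))
  }

  ids <- sids <- seqs <- origin <- type <- pa <- pb <- character(0)
  grp <- character(0)
  out_n <- integer(nrow(design))

  for (si in seq_len(nrow(design))) {
    sample_id <- design$sample_id[si]
    n <- depths[si]
    comm <- community[, si]
    present <- sp_names[comm > 0]
    kinds <- sample(c("chimera", "offtarget", "target"), n, replace = TRUE,
                    prob = c(config$chimera_rate, config$offtarget_fraction,
                             1 - config$chimera_rate - config$offtarget_fraction))
    r_seq <- character(n); r_org <- character(n); r_type <- kinds
    r_pa <- rep(NA_character_, n); r_pb <- rep(NA_character_, n)
    r_grp <- character(n)

    i_t <- which(kinds == "target")
    if (length(i_t)) {
      sp_draw <- .sample_vec(present, length(i_t), replace = TRUE,
                             prob = comm[present])
      for (sp in unique(sp_draw)) {
        w <- i_t[sp_draw == sp]
        r_seq[w] <- .add_substitution_errors(tmpl[[sp]], length(w),
                                             config$substitution_error_rate)
        r_org[w] <- sp; r_grp[w] <- sp
      }
    }
    i_c <- which(kinds == "chimera")
    fam_present <- intersect(present, fam_species)
    if (length(i_c)) {
      if (length(fam_present) < 2) {
        # degenerate community: fall back to plain target reads
        r_type[i_c] <- "target"
        sp_draw <- .sample_vec(present, length(i_c), replace = TRUE, prob = comm[present])
        for (sp in unique(sp_draw)) {
          w <- i_c[sp_draw == sp]
          r_seq[w] <- .add_substitution_errors(tmpl[[sp]], length(w),
                                               config$substitution_error_rate)
          r_org[w] <- sp; r_grp[w] <- sp
        }
      } else {
        for (w in i_c) {
          ps <- .sample_vec(fam_present, 2L, prob = comm[fam_present])
          bp <- sample.int(L - 1L, 1L)
          chim <- c(tmpl[[ps[1]]][1:bp], tmpl[[ps[2]]][(bp + 1):L])
          r_seq[w] <- .add_substitution_errors(chim, 1L,
                                               config$substitution_error_rate)
          r_org[w] <- sprintf("chimera(%s,%s)", ps[1], ps[2])
          r_pa[w] <- ps[1]; r_pb[w] <- ps[2]
          r_grp[w] <- "chimera"
        }
      }
    }
    i_o <- which(kinds == "offtarget")
    if (length(i_o)) {
      og_draw <- sample.int(length(og_chars), length(i_o), replace = TRUE)
      for (g in unique(og_draw)) {
        w <- i_o[og_draw == g]
        r_seq[w] <- .add_substitution_errors(og_chars[[g]], length(w),
                                             config$substitution_error_rate)
        r_org[w] <- paste0("offtarget:", offtarget_ids[g])
        r_grp[w] <- paste0("offtarget:", offtarget_ids[g])
      }
    }

    # planted rare error-variant OTUs: one singleton + one doubleton per
    # present family species (exact copies, >=3% divergent from the species)
    if (config$plant_rare && length(fam_present)) {
      ex_seq <- ex_org <- ex_grp <- character(0)
      kdiv <- max(ceiling(0.035 * L), 4L)
      for (sp in fam_present) {
        v1 <- paste(.substitute_at(tmpl[[sp]], sample.int(L, kdiv)), collapse = "")
        v2 <- paste(.substitute_at(tmpl[[sp]], sample.int(L, kdiv)), collapse = "")
        ex_seq <- c(ex_seq, v1, v2, v2)
        ex_org <- c(ex_org, rep(sp, 3L))
        ex_grp <- c(ex_grp, paste0(sp, "|rare_singleton"),
                    rep(paste0(sp, "|rare_doubleton"), 2L))
      }
      r_seq <- c(r_seq, ex_seq)
      r_org <- c(r_org, ex_org)
      r_type <- c(r_type, rep("planted_rare", length(ex_seq)))
      r_pa <- c(r_pa, rep(NA_character_, length(ex_seq)))
      r_pb <- c(r_pb, rep(NA_character_, length(ex_seq)))
      r_grp <- c(r_grp, ex_grp)
      n <- n + length(ex_seq)
    }

    r_ids <- sprintf("r%s_%06d", sample_id, seq_len(n))
    ids <- c(ids, r_ids); sids <- c(sids, rep(sample_id, n))
    seqs <- c(seqs, r_seq); origin <- c(origin, r_org); type <- c(type, r_type)
    pa <- c(pa, r_pa); pb <- c(pb, r_pb); grp <- c(grp, r_grp)
    out_n[si] <- n
  }

  reads <- .new_reads(ids, sids, seqs)
  metadata <- design
  metadata$total_reads <- out_n

  presence <- community > 0
  truth_reads <- data.frame(read_id = ids, sample_id = sids, origin = origin,
                            type = type, parent_a = pa, parent_b = pb,
                            stringsAsFactors = FALSE)
  truth <- list(reads = truth_reads, presence = presence,
                otu_membership = data.frame(read_id = ids, true_group = grp,
                                            stringsAsFactors = FALSE))
  list(reads = reads, metadata = metadata, panel = panel,
       alignment = ref$alignment, community = community,
       novel_sequence = novel_seq, truth = truth,
       family_ids = fam_ids, outgroup_ids = ref$outgroup_ids,
       far_outgroup_ids = ref$far_outgroup_ids, config = config)
}
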