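#' Run the full taxon-targeted screening funnel
#'
#' Executes, in order: best-hit/LCA taxonomic assignment against the panel;
#' the taxon filter (default: keep diatoms, `"Bacillariophyta"`); greedy
#' capture at `capture_cutoff` (0.90) with elimination of clusters keyed by
#' non-family references; the two-parent chimera screen; OTU formation at
#' `otu_cutoff` (0.97) within each family capture cluster; singleton/doubleton
#' removal; template threading of OTU representatives into the master
#' alignment; neighbor-joining tree building, rooting on the distant
#' outgroups and clade-based species assignment; removal of OTUs resolving
#' outside the family clade (false positives); and the per-sample species
#' tables. Every stage's record counts form the funnel report.
#'
#' @param reads an `amplicon_reads` data frame.
#' @param panel a `ref_panel` containing family references, outgroup taxa and
#'   the rooting outgroups.
#' @param metadata a `sample_metadata` covering all read samples.
#' @param master_alignment named character vector of equal-width gapped rows,
#'   one per panel reference (for an indel-free panel the unaligned panel
#'   works as-is; defaults to the panel sequences when their lengths are
#'   equal).
#' @param target_family family taxon defining the screen (default
#'   `"Leptocylindraceae"`).
#' @param filter_taxon taxon defining the initial dataset (default
#'   `"Bacillariophyta"`).
#' @param capture_cutoff,otu_cutoff identity thresholds of the two clustering
#'   stages.
#' @param min_otu_size rare-OTU threshold (3 removes singletons/doubletons).
#' @param chimera_margin identity-gain margin of the chimera screen.
#' @param outgroup_ids rooting outgroup leaf ids; default: panel references
#'   whose taxonomy lacks `filter_taxon` (the non-diatom outgroups).
#' @param species_merge optional named list merging indistinguishable species
#'   into one label (e.g.
#'   `list("L. danicus/hargravesii" = c("Leptocylindrus danicus",
#'   "Leptocylindrus hargravesii"))`).
#' @param collapse_tol internal edges of the validation tree shorter than
#'   this are collapsed into polytomies before clades are read (species
#'   assignment should not hinge on noise-resolved splits); default: half a
#'   substitution's worth of distance, `0.5 / alignment width`. Set 0 to
#'   disable.
#' @param min_novel_divergence a `"family-unplaced"` (candidate new taxon)
#'   verdict requires at least this divergence (`1 - identity`) from the
#'   nearest reference; less divergent material in topologically ambiguous
#'   positions is assigned its nearest reference's species. The default 0.06
#'   sits between the sequencing-error scale and the family's interspecies
#'   distances.
#' @param layer,template sample selection for the site tables.
#' @param scoring alignment scoring.
#' @param output_dir optional directory; when given, all tables and the tree
#'   are written there with a checksum manifest.
#' @param verbose log stage banners and record counts to standard error.
#' @return An object of class `screen_result`: list with `funnel` (a
#'   `funnel_report`), `assignments`, `capture`, `chimera`, `otus_all`,
#'   `otus_kept`, `otus_removed`, `tree`, `species_map`,
#'   `false_positive_otus`, `read_species`, `site_table`, `abundance`,
#'   `params` and (when written) `manifest`.
#' @export
run_screen <- function(reads, panel, metadata,
                       master_alignment = NULL,
                       target_family = "Leptocylindraceae",
                       filter_taxon = "Bacillariophyta",
                       capture_cutoff = 0.90, otu_cutoff = 0.97,
                       min_otu_size = 3, chimera_margin = 0.02,
                       outgroup_ids = NULL, species_merge = NULL,
                       collapse_tol = NULL, min_novel_divergence = 0.06,
                       layer = "surface", template = "cDNA",
                       scoring = align_scoring(),
                       output_dir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "),
                                            sprintf(...))
  stopifnot(inherits(panel, "ref_panel"))
  validate_study(reads, metadata)
  if (is.null(master_alignment)) {
    if (length(unique(nchar(panel$sequence))) != 1)
      stop("panel sequences differ in length; provide master_alignment")
    master_alignment <- stats::setNames(panel$sequence, panel$id)
  }
  fam_sel <- vapply(split_path(panel$taxonomy),
                    function(p) target_family %in% p, logical(1))
  if (!any(fam_sel)) stop("panel contains no ", target_family, " reference")
  fam_ids <- panel$id[fam_sel]
  if (is.null(outgroup_ids)) {
    out_sel <- !vapply(split_path(panel$taxonomy),
                       function(p) filter_taxon %in% p, logical(1))
    outgroup_ids <- panel$id[out_sel]
  }

  n_all <- nrow(reads)
  say("stage 1/7 assignment: %d reads vs %d references", n_all, nrow(panel))
  assignments <- assign_reads(reads, panel, method = "best_hit_lca",
                              scoring = scoring)
  keep_ids <- filter_by_taxon(assignments, filter_taxon)
  reads_f <- reads[reads$id %in% keep_ids, , drop = FALSE]
  say("stage 2/7 taxon filter (%s): %d reads retained", filter_taxon,
      nrow(reads_f))

  capture <- greedy_capture(reads_f, panel, cutoff = capture_cutoff,
                            target_taxon = target_family, scoring = scoring)
  memb <- capture$membership
  fam_memb <- memb[memb$target, , drop = FALSE]
  say("stage 3/7 capture at >= %.2f: %d putative family reads (%d eliminated, %d unmatched)",
      capture_cutoff, nrow(fam_memb), sum(!memb$target),
      length(capture$unmatched))

  fam_reads <- reads_f[match(fam_memb$read_id, reads_f$id), , drop = FALSE]
  chim <- chimera_screen(fam_reads, panel[fam_sel, , drop = FALSE],
                         margin = chimera_margin, scoring = scoring)
  say("stage 4/7 chimera screen: %d flagged, %d clean",
      nrow(chim$flagged), nrow(chim$clean))

  # OTU formation within each family capture cluster
  clean <- chim$clean
  otus_all <- NULL
  if (nrow(clean)) {
    by_ref <- split(clean$id,
                    fam_memb$ref_id[match(clean$id, fam_memb$read_id)])
    pieces <- list()
    for (ref in sort(names(by_ref))) {
      sub <- clean[clean$id %in% by_ref[[ref]], , drop = FALSE]
      pieces[[ref]] <- recluster_otus(sub, cutoff = otu_cutoff,
                                      scoring = scoring)
    }
    # renumber OTUs globally, keeping per-reference blocks
    otu_df <- NULL; memb_df <- NULL; counter <- 0L
    for (ref in names(pieces)) {
      p <- pieces[[ref]]
      new_ids <- sprintf("otu_%04d", counter + seq_len(nrow(p$otus)))
      map <- stats::setNames(new_ids, p$otus$otu_id)
      p$otus$otu_id <- new_ids
      p$membership$otu_id <- as.character(map[p$membership$otu_id])
      counter <- counter + nrow(p$otus)
      otu_df <- rbind(otu_df, p$otus)
      memb_df <- rbind(memb_df, p$membership)
    }
    otus_all <- structure(list(otus = otu_df, membership = memb_df,
                               level = otu_cutoff), class = "otu_set")
  } else {
    otus_all <- structure(list(otus = data.frame(otu_id = character(),
                                                 seed_id = character(),
                                                 size = integer(),
                                                 stringsAsFactors = FALSE),
                               membership = data.frame(read_id = character(),
                                                       sample_id = character(),
                                                       otu_id = character(),
                                                       stringsAsFactors = FALSE),
                               level = otu_cutoff), class = "otu_set")
  }
  say("stage 5/7 OTUs at >= %.2f: %d OTUs over %d reads", otu_cutoff,
      nrow(otus_all$otus), nrow(otus_all$membership))

  rare <- remove_rare_otus(otus_all, min_size = min_otu_size)
  kept <- rare$kept
  say("stage 5/7 rare-OTU removal (< %d reads): %d OTUs / %d reads kept",
      min_otu_size, nrow(kept$otus), nrow(kept$membership))

  # phylogenetic validation on one representative (the seed) per OTU
  species_map <- character(0)
  tree <- NULL
  fp_otus <- character(0)
  if (nrow(kept$otus) > 0) {
    rep_seq <- stats::setNames(
      reads$sequence[match(kept$otus$seed_id, reads$id)], kept$otus$otu_id)
    thr <- template_align(rep_seq, master_alignment, scoring = scoring)
    rows <- c(master_alignment, thr$rows)
    tree0 <- nj_tree(distance_from_alignment(rows, model = "JC69"))
    tree <- root_tree(tree0, outgroup_ids)
    # read clades off polytomies, not noise-resolved binary splits: collapse
    # internal edges shorter than half a substitution's worth of distance
    if (is.null(collapse_tol)) collapse_tol <- 0.5 / nchar(master_alignment[[1]])
    if (collapse_tol > 0) tree <- ape::di2multi(tree, tol = collapse_tol)
    species_ref_map <- split(fam_ids,
                             vapply(split_path(panel$taxonomy[fam_sel]),
                                    function(p) p[[length(p)]], ""))
    if (!is.null(species_merge)) {
      for (lab in names(species_merge)) {
        merged <- unlist(species_ref_map[species_merge[[lab]]])
        species_ref_map <- species_ref_map[
          !(names(species_ref_map) %in% species_merge[[lab]])]
        species_ref_map[[lab]] <- unname(merged)
      }
    }
    # divergence gate: reps of error-scale divergence in topologically
    # ambiguous positions fall back to their nearest reference's species;
    # only genuinely divergent material is called a candidate new taxon
    ref_label <- stats::setNames(rep(names(species_ref_map),
                                     lengths(species_ref_map)),
                                 unlist(species_ref_map))
    rep_capture <- fam_memb[match(kept$otus$seed_id, fam_memb$read_id), ]
    divergence <- stats::setNames(1 - rep_capture$identity, kept$otus$otu_id)
    nearest_label <- stats::setNames(unname(ref_label[rep_capture$ref_id]),
                                     kept$otus$otu_id)
    species_map <- assign_species_by_clade(tree, kept$otus$otu_id,
                                           species_ref_map,
                                           min_divergence = min_novel_divergence,
                                           divergence = divergence,
                                           nearest_label = nearest_label)
    outside <- names(species_map)[species_map == "outside"]
    if (length(outside)) {
      conf <- confirm_false_positives(rep_seq[outside], panel,
                                      family_taxon = target_family,
                                      scoring = scoring)
      fp_otus <- conf$id[conf$false_positive]
      # tags outside the family clade whose nearest reference is still a
      # family member stay in the dataset: divergent ones as unplaced family
      # material, error-scale ones under their nearest reference's species
      rescue <- setdiff(outside, fp_otus)
      low <- rescue[divergence[rescue] < min_novel_divergence]
      species_map[low] <- nearest_label[low]
      species_map[setdiff(rescue, low)] <- "family-unplaced"
    }
  }
  say("stage 6/7 validation: %d OTUs placed, %d false positive(s)",
      sum(!(names(species_map) %in% fp_otus)), length(fp_otus))

  final_memb <- kept$membership[!(kept$membership$otu_id %in% fp_otus), ,
                                drop = FALSE]
  read_species <- data.frame(
    read_id = final_memb$read_id, sample_id = final_memb$sample_id,
    species = unname(species_map[final_memb$otu_id]),
    otu_id = final_memb$otu_id, stringsAsFactors = FALSE)

  site_table <- species_site_table(read_species, metadata,
                                   layer = layer, template = template)
  abundance <- normalize_abundance(site_table$counts, metadata)
  say("stage 7/7 tables: %d species across %d sites",
      nrow(site_table$shares), ncol(site_table$shares))

  # the funnel: stage-by-stage read and OTU counts
  species_counts <- if (nrow(read_species)) {
    stats::aggregate(
      list(reads = read_species$read_id, otus = read_species$otu_id),
      by = list(species = read_species$species),
      FUN = function(v) length(unique(v)))
  } else {
    data.frame(species = character(), reads = integer(), otus = integer(),
               stringsAsFactors = FALSE)
  }
  funnel <- structure(list(
    stages = data.frame(
      stage = c("all reads", paste0("assigned ", filter_taxon),
                sprintf("putative %s (>= %.2f)", target_family, capture_cutoff),
                "after chimera removal",
                sprintf("after rare-OTU removal (< %d)", min_otu_size),
                "after false-positive removal"),
      reads = c(n_all, nrow(reads_f), nrow(fam_memb), nrow(chim$clean),
                nrow(kept$membership), nrow(final_memb)),
      otus = c(NA, NA, NA, nrow(otus_all$otus), nrow(kept$otus),
               nrow(kept$otus) - length(fp_otus)),
      stringsAsFactors = FALSE),
    species = species_counts,
    otu_level = otu_cutoff), class = "funnel_report")

  out <- list(funnel = funnel, assignments = assignments, capture = capture,
              chimera = chim, otus_all = otus_all, otus_kept = kept,
              otus_removed = rare$removed, tree = tree,
              species_map = species_map, false_positive_otus = fp_otus,
              read_species = read_species, site_table = site_table,
              abundance = abundance, metadata = metadata,
              params = list(target_family = target_family,
                            filter_taxon = filter_taxon,
                            capture_cutoff = capture_cutoff,
                            otu_cutoff = otu_cutoff,
                            min_otu_size = min_otu_size,
                            chimera_margin = chimera_margin,
                            layer = layer, template = template,
                            scoring = scoring))
  class(out) <- "screen_result"

  if (!is.null(output_dir)) {
    tables <- list(funnel = funnel$stages,
                   species_counts = funnel$species,
                   read_species = read_species,
                   site_shares = site_table$shares,
                   otus = kept$otus)
    trees <- if (!is.null(tree)) list(validation_tree = tree) else list()
    out$manifest <- write_outputs(tables, trees, output_dir)
    cfg <- vapply(out$params[1:8], function(p) paste(deparse(p), collapse = ""), "")
    writeLines(paste(names(cfg), cfg, sep = " = "),
               file.path(output_dir, "params.txt"))
  }
  out
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Screening funnel:\n")
  print(x$stages, row.names = FALSE)
  if (nrow(x$species)) {
    cat(sprintf("\nPer-species counts (reads and OTUs at %.2f):\n", x$otu_level))
    print(x$species, row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.screen_result <- function(x, ...) {
  print(x$funnel)
  invisible(x)
}

#' Compare species counts between two datasets sample by sample
#'
#' For every species and every sample present in both datasets, runs the
#' exact conditional tag-count test ([ac_test()]) of the species' count in
#' dataset A (library size = A's total reads for that sample) against its
#' count in dataset B. Unmatched samples are skipped with a warning.
#'
#' @param result_a,result_b `screen_result` objects, or species x sample
#'   count matrices.
#' @param lib_a,lib_b named per-sample library sizes (required for matrix
#'   input; taken from the result metadata otherwise).
#' @param alpha significance level.
#' @return A data frame with one row per species x matched sample: counts,
#'   library sizes, `p_two_sided`, `y_lo`, `y_hi`, `significant`.
#' @export
compare_datasets <- function(result_a, result_b, lib_a = NULL, lib_b = NULL,
                             alpha = 0.05) {
  get_counts <- function(r, lib) {
    if (inherits(r, "screen_result")) {
      list(counts = r$site_table$counts,
           lib = stats::setNames(r$metadata$total_reads, r$metadata$sample_id))
    } else {
      if (is.null(lib)) stop("matrix input needs named library sizes")
      list(counts = as.matrix(r), lib = lib)
    }
  }
  A <- get_counts(result_a, lib_a); B <- get_counts(result_b, lib_b)
  common <- intersect(colnames(A$counts), colnames(B$counts))
  skipped <- setdiff(union(colnames(A$counts), colnames(B$counts)), common)
  if (length(skipped))
    warning("unmatched sample(s) skipped: ", paste(skipped, collapse = ", "))
  species <- union(rownames(A$counts), rownames(B$counts))
  rows <- list()
  for (sp in species) {
    for (sm in common) {
      x <- if (sp %in% rownames(A$counts)) A$counts[sp, sm] else 0L
      y <- if (sp %in% rownames(B$counts)) B$counts[sp, sm] else 0L
      t <- ac_test(x, y, A$lib[[sm]], B$lib[[sm]], alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, sample_id = sm, x = x, y = y,
        N1 = A$lib[[sm]], N2 = B$lib[[sm]], p_two_sided = t$p_two_sided,
        y_lo = t$expected_range[1], y_hi = t$expected_range[2],
        significant = t$significant, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Consistency ratios of a published screening funnel
#'
#' Given the canonical two-region funnel count table (rows = stages, columns
#' = `stage`, `v4_reads`, `v9_reads`, `v4_otus`, `v9_otus`), recomputes the
#' headline arithmetic of such a screen: the family's share of the diatom
#' reads per region, the V9/V4 depth ratios, and the fraction of putative
#' family V9 reads discarded as false positives. Stage names must include
#' `all`, `diatoms`, `putative`, `after_rare`, `final`.
#'
#' @param funnel_counts data frame as described (see
#'   `system.file("extdata", "survey_funnel_counts.tsv", package =
#'   "taxascreen")` for the worked example).
#' @return A named list of ratios.
#' @export
funnel_ratios <- function(funnel_counts) {
  need <- c("all", "diatoms", "putative", "after_rare", "final")
  miss <- setdiff(need, funnel_counts$stage)
  if (length(miss)) stop("missing stage row(s): ", paste(miss, collapse = ", "))
  g <- function(stage, col) funnel_counts[[col]][funnel_counts$stage == stage]
  for (col in c("v4_reads", "v9_reads")) {
    v <- funnel_counts[[col]][match(need, funnel_counts$stage)]
    if (any(diff(v[-1]) > 0) || v[1] < v[2])
      stop("funnel counts must be non-increasing down the stages (", col, ")")
  }
  list(
    family_v4_pct_of_diatoms = 100 * g("final", "v4_reads") / g("diatoms", "v4_reads"),
    family_v9_pct_of_diatoms = 100 * g("final", "v9_reads") / g("diatoms", "v9_reads"),
    total_v9_v4_ratio = g("all", "v9_reads") / g("all", "v4_reads"),
    diatom_v9_v4_ratio = g("diatoms", "v9_reads") / g("diatoms", "v4_reads"),
    putative_family_v9_v4_ratio = g("putative", "v9_reads") / g("putative", "v4_reads"),
    v9_false_positive_removed_fraction =
      (g("after_rare", "v9_reads") - g("final", "v9_reads")) / g("after_rare", "v9_reads"))
}
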