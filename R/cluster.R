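#' Greedy capture clustering of reads against a reference panel
#'
#' Each read joins the reference of maximal global identity provided that
#' identity meets the cutoff (default 0.90); ties (identities equal after
#' rounding to `tie_tol`) resolve to the lexicographically smallest reference
#' id. Reads below the cutoff for every reference are returned as unmatched.
#' When `target_taxon` is given, clusters keyed by references whose taxonomy
#' does not contain it are flagged for elimination (reads grouping closer to
#' non-target references).
#'
#' @param reads an `amplicon_reads` data frame.
#' @param panel a `ref_panel`.
#' @param cutoff identity threshold in (0, 1].
#' @param target_taxon optional taxon name marking the target clusters (e.g.
#'   the family being screened for).
#' @param scoring alignment scoring.
#' @param denom identity denominator convention (see [seq_identity()]).
#' @param tie_tol identity rounding for tie detection.
#' @return An object of class `capture_clusters`: list with `membership`
#'   (data frame `read_id`, `sample_id`, `ref_id`, `identity`, `target`),
#'   `unmatched` (read ids), `clusters` (per-reference sizes and target flag)
#'   and `level`.
#' @export
greedy_capture <- function(reads, panel, cutoff = 0.90, target_taxon = NULL,
                           scoring = align_scoring(),
                           denom = c("alignment", "shorter"), tie_tol = 1e-4) {
  denom <- match.arg(denom)
  if (!inherits(panel, "ref_panel") || nrow(panel) == 0)
    stop("panel must be a non-empty ref_panel")
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must lie in (0, 1]")
  is_target <- if (is.null(target_taxon)) rep(TRUE, nrow(panel)) else
    vapply(split_path(panel$taxonomy), function(p) target_taxon %in% p, logical(1))
  if (nrow(reads) == 0) {
    out <- list(membership = data.frame(read_id = character(),
                                        sample_id = character(),
                                        ref_id = character(),
                                        identity = numeric(),
                                        target = logical(),
                                        stringsAsFactors = FALSE),
                unmatched = character(),
                clusters = data.frame(ref_id = panel$id, size = 0L,
                                      target = is_target,
                                      stringsAsFactors = FALSE),
                level = cutoff)
    class(out) <- "capture_clusters"
    return(out)
  }
  useq <- unique(reads$sequence)
  idm <- .identity_many(useq, panel$sequence, scoring, denom)
  # per unique sequence: best reference, lexicographically smallest on ties
  ord <- order(panel$id)
  best_ref <- integer(length(useq)); best_id <- numeric(length(useq))
  for (u in seq_along(useq)) {
    ids <- idm[u, ]
    b <- max(ids)
    tied <- which(round(ids, 4) == round(b, 4))
    best_ref[u] <- tied[which.min(match(tied, ord))]
    best_id[u] <- ids[best_ref[u]]
  }
  ridx <- match(reads$sequence, useq)
  hit <- best_id[ridx] >= cutoff - 1e-12
  membership <- data.frame(read_id = reads$id[hit],
                           sample_id = reads$sample_id[hit],
                           ref_id = panel$id[best_ref[ridx[hit]]],
                           identity = best_id[ridx[hit]],
                           target = is_target[best_ref[ridx[hit]]],
                           stringsAsFactors = FALSE)
  sizes <- table(factor(membership$ref_id, levels = panel$id))
  out <- list(membership = membership,
              unmatched = reads$id[!hit],
              clusters = data.frame(ref_id = panel$id,
                                    size = as.integer(sizes),
                                    target = is_target,
                                    stringsAsFactors = FALSE),
              level = cutoff)
  class(out) <- "capture_clusters"
  out
}

#' @export
print.capture_clusters <- function(x, ...) {
  cat(sprintf("Capture clustering at >= %.2f identity: %d reads in %d non-empty clusters, %d unmatched\n",
              x$level, nrow(x$membership), sum(x$clusters$size > 0),
              length(x$unmatched)))
  print(x$clusters[x$clusters$size > 0, ], row.names = FALSE)
  invisible(x)
}

#' Greedy incremental OTU clustering
#'
#' Reads are processed longest-first (ties broken by lexicographic id); a read
#' founds a new OTU unless its identity to an existing OTU seed meets the
#' cutoff, in which case it joins the best-matching seed. The OTU seed (first,
#' longest member) is the cluster representative. The result is invariant to
#' the input order of the reads.
#'
#' @param reads an `amplicon_reads` data frame (at least one read).
#' @param cutoff identity threshold (default 0.97).
#' @inheritParams greedy_capture
#' @return An object of class `otu_set`: list with `otus` (data frame
#'   `otu_id`, `seed_id`, `size`), `membership` (`read_id`, `sample_id`,
#'   `otu_id`) and `level`.
#' @export
recluster_otus <- function(reads, cutoff = 0.97, scoring = align_scoring(),
                           denom = c("alignment", "shorter"), tie_tol = 1e-4) {
  denom <- match.arg(denom)
  if (nrow(reads) < 1) stop("recluster_otus needs at least one read")
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must lie in (0, 1]")
  ord <- order(-nchar(reads$sequence), reads$id)
  seqs <- reads$sequence[ord]
  useq <- unique(seqs)
  uidx <- match(seqs, useq) - 1L
  res <- cpp_greedy_cluster(seqs, uidx, length(useq), cutoff,
                            scoring$match, scoring$mismatch,
                            scoring$gap_open, scoring$gap_extend,
                            denom == "shorter", tie_tol)
  k <- length(res$seed_index)
  otu_id <- sprintf("otu_%04d", seq_len(k))
  seed_id <- reads$id[ord][res$seed_index + 1L]
  membership <- data.frame(read_id = reads$id[ord],
                           sample_id = reads$sample_id[ord],
                           otu_id = otu_id[res$assign + 1L],
                           stringsAsFactors = FALSE)
  sizes <- table(factor(membership$otu_id, levels = otu_id))
  out <- list(otus = data.frame(otu_id = otu_id, seed_id = seed_id,
                                size = as.integer(sizes),
                                stringsAsFactors = FALSE),
              membership = membership, level = cutoff)
  class(out) <- "otu_set"
  out
}

#' @export
print.otu_set <- function(x, ...) {
  cat(sprintf("%d OTU(s) at >= %.2f identity over %d reads\n",
              nrow(x$otus), x$level, nrow(x$membership)))
  print(utils::head(x$otus, 10), row.names = FALSE)
  if (nrow(x$otus) > 10) cat("...\n")
  invisible(x)
}

#' Remove rare (singleton/doubleton) OTUs
#'
#' OTUs with fewer than `min_size` members (default 3: removes singletons and
#' doubletons, which most likely represent sequencing errors) are split off.
#' Read counts are conserved between the kept and removed sets.
#'
#' @param otus an `otu_set`.
#' @param min_size minimal OTU size to keep.
#' @return A list with `kept` and `removed`, both `otu_set`s.
#' @export
remove_rare_otus <- function(otus, min_size = 3) {
  stopifnot(inherits(otus, "otu_set"), min_size >= 1)
  keep <- otus$otus$size >= min_size
  subset_set <- function(sel) {
    ids <- otus$otus$otu_id[sel]
    out <- list(otus = otus$otus[sel, , drop = FALSE],
                membership = otus$membership[otus$membership$otu_id %in% ids, ,
                                             drop = FALSE],
                level = otus$level)
    rownames(out$otus) <- NULL; rownames(out$membership) <- NULL
    class(out) <- "otu_set"
    out
  }
  list(kept = subset_set(keep), removed = subset_set(!keep))
}

#' Furthest-neighbor (complete-linkage) clustering at several cutoffs
#'
#' Distances `1 - identity` are rounded to the nearest `1/precision` and
#' clusters agglomerated under the furthest-neighbor rule: a merge happens
#' only when every pairwise distance inside the merged cluster is at most
#' `1 - cutoff`. Partitions at higher cutoffs refine those at lower ones.
#'
#' @param idmat symmetric identity matrix (e.g. from [identity_matrix()]).
#' @param cutoffs identity cutoffs (e.g. `c(0.95, 0.97, 1.00)`).
#' @param precision distance rounding precision (1000 = highest).
#' @return A named list (one element per cutoff, names like `"0.97"`) of
#'   integer membership vectors named by sequence.
#' @export
furthest_neighbor_cluster <- function(idmat, cutoffs, precision = 1000) {
  if (!is.matrix(idmat) || nrow(idmat) != ncol(idmat) ||
      !isTRUE(all.equal(idmat, t(idmat), tolerance = 1e-8)))
    stop("idmat must be a square symmetric matrix")
  d <- round((1 - idmat) * precision) / precision
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  out <- lapply(cutoffs, function(cc) {
    stats::cutree(hc, h = (1 - cc) + 1e-9)
  })
  names(out) <- format(cutoffs)
  out
}

#' Reference-based two-parent chimera screen
#'
#' A read is flagged as chimeric when, over breakpoints scanned at every 10%
#' of its length, the best 5' segment identity and the best 3' segment
#' identity against two different references combine (length-weighted) to
#' exceed its best full-length identity by at least `margin`. Segment
#' identities are taken from the per-position match profile of the read's
#' global alignments to the references.
#'
#' @param reads an `amplicon_reads` data frame.
#' @param panel a `ref_panel` with at least 2 references.
#' @param margin required identity gain (default 0.02).
#' @param breakpoints breakpoint positions as fractions of read length.
#' @param protect_multiplicity sequences observed identically at least this
#'   many times are never flagged: replicated observation is evidence of a
#'   biological template rather than a chimeric artefact, and divergent
#'   genuine lineages otherwise risk looking chimeric against a reference
#'   panel that brackets them. `Inf` disables the rescue.
#' @inheritParams greedy_capture
#' @return A list with `clean` and `flagged` (`amplicon_reads` subsets) and
#'   `detail` (per-read `gain` and `best_full_identity`).
#' @export
chimera_screen <- function(reads, panel, margin = 0.02,
                           breakpoints = seq(0.1, 0.9, by = 0.1),
                           protect_multiplicity = 3,
                           scoring = align_scoring(),
                           denom = c("alignment", "shorter")) {
  denom <- match.arg(denom)
  if (!inherits(panel, "ref_panel") || nrow(panel) < 2)
    stop("chimera_screen needs a panel of at least 2 references")
  if (nrow(reads) == 0) {
    return(list(clean = reads, flagged = reads[0, ],
                detail = data.frame(read_id = character(), gain = numeric(),
                                    best_full_identity = numeric(),
                                    flagged = logical(),
                                    stringsAsFactors = FALSE)))
  }
  useq <- unique(reads$sequence)
  res <- cpp_chimera_screen(useq, panel$sequence,
                            scoring$match, scoring$mismatch,
                            scoring$gap_open, scoring$gap_extend,
                            denom == "shorter", breakpoints, margin)
  ridx <- match(reads$sequence, useq)
  flagged <- res$flagged[ridx]
  if (is.finite(protect_multiplicity)) {
    mult <- table(ridx)
    protected <- as.integer(names(mult)[mult >= protect_multiplicity])
    flagged[ridx %in% protected] <- FALSE
  }
  detail <- data.frame(read_id = reads$id, gain = res$gain[ridx],
                       best_full_identity = res$full_best[ridx],
                       flagged = flagged, stringsAsFactors = FALSE)
  list(clean = reads[!flagged, , drop = FALSE],
       flagged = reads[flagged, , drop = FALSE],
       detail = detail)
}
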