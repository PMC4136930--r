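#' Last (lowest) common ancestor of taxonomy paths
#'
#' The longest common prefix of the ranked paths. A single path is its own
#' LCA; paths sharing no rank give the explicit root label
#' `"unassigned-root"`.
#'
#' @param paths list of character vectors (ranked paths, broadest first), or a
#'   character vector of `;`-joined paths.
#' @return A character vector: the shared prefix.
#' @export
lca <- function(paths) {
  if (is.character(paths)) paths <- split_path(paths)
  if (length(paths) < 1) stop("lca needs at least one path")
  if (length(paths) == 1) return(paths[[1]])
  prefix <- paths[[1]]
  for (p in paths[-1]) {
    n <- min(length(prefix), length(p))
    eq <- which(prefix[seq_len(n)] != p[seq_len(n)])
    keep <- if (length(eq)) eq[1] - 1L else n
    prefix <- prefix[seq_len(keep)]
    if (!length(prefix)) break
  }
  if (!length(prefix)) "unassigned-root" else prefix
}

#' Assign reads taxonomically against an annotated reference panel
#'
#' For every read, all references are scored by global alignment identity.
#' With `method = "best_hit_lca"` the read receives the full path of the
#' unique best hit, or, when several references tie (identities equal after
#' rounding to 4 decimal places), the last common ancestor of the tied
#' references' paths. With `method = "consensus"` all hits within `top_window`
#' of the best identity are considered and the path is truncated to the
#' deepest rank at which at least `confidence` of the considered hits agree
#' (threshold inclusive).
#'
#' @param reads an `amplicon_reads` data frame (or named character vector of
#'   sequences).
#' @param panel a `ref_panel` data frame.
#' @param method assignment rule.
#' @param top_window identity margin defining the considered hits for the
#'   consensus rule (0 = exact ties only).
#' @param confidence consensus agreement threshold in (0.5, 1].
#' @param scoring alignment scoring, see [align_scoring()].
#' @param tie_tol identity rounding used for tie detection.
#' @return An `assignment_table` data frame: `read_id`, `path` (semicolon
#'   joined, possibly truncated; `"unassigned-root"` when nothing is shared),
#'   `best_identity`, `method`, `n_hits_considered`.
#' @export
assign_reads <- function(reads, panel,
                         method = c("best_hit_lca", "consensus"),
                         top_window = 0, confidence = 0.80,
                         scoring = align_scoring(), tie_tol = 1e-4) {
  method <- match.arg(method)
  if (!inherits(panel, "ref_panel") || nrow(panel) == 0)
    stop("panel must be a non-empty ref_panel")
  if (method == "consensus" && (confidence <= 0.5 || confidence > 1))
    stop("confidence must lie in (0.5, 1]")
  if (is.character(reads))
    reads <- .new_reads(names(reads), NA_character_, unname(reads))
  if (nrow(reads) == 0)
    return(structure(data.frame(read_id = character(), path = character(),
                                best_identity = numeric(), method = character(),
                                n_hits_considered = integer(),
                                stringsAsFactors = FALSE),
                     class = c("assignment_table", "data.frame")))
  useq <- unique(reads$sequence)
  idm <- .identity_many(useq, panel$sequence, scoring)
  ridx <- match(reads$sequence, useq)
  paths <- split_path(panel$taxonomy)

  upath <- character(length(useq))
  ubest <- numeric(length(useq))
  uhits <- integer(length(useq))
  for (u in seq_along(useq)) {
    ids <- idm[u, ]
    best <- max(ids)
    if (method == "best_hit_lca") {
      tied <- which(round(ids, 4) == round(best, 4))
      upath[u] <- join_path(lca(paths[tied]))
      uhits[u] <- length(tied)
    } else {
      consider <- which(ids >= best - top_window - 1e-12)
      n <- length(consider)
      cp <- paths[consider]
      depth <- 0L
      repeat {
        d <- depth + 1L
        cand <- vapply(cp, function(p) if (length(p) >= d) p[d] else NA_character_, "")
        tab <- table(cand[!is.na(cand)])
        if (!length(tab)) break
        modal <- names(tab)[which.max(tab)]
        agree <- sum(vapply(cp, function(p)
          length(p) >= d && all(p[seq_len(d)] == c(if (d > 1) pref else character(), modal)),
          logical(1)))
        if (agree / n >= confidence - 1e-12) {
          pref <- c(if (depth > 0) pref else character(), modal)
          depth <- d
        } else break
      }
      upath[u] <- if (depth == 0) "unassigned-root" else join_path(pref)
      uhits[u] <- n
    }
    ubest[u] <- best
  }
  out <- data.frame(read_id = reads$id, path = upath[ridx],
                    best_identity = ubest[ridx], method = method,
                    n_hits_considered = uhits[ridx],
                    stringsAsFactors = FALSE)
  class(out) <- c("assignment_table", "data.frame")
  out
}

#' Best-hit / LCA assignment of a single read
#'
#' Convenience wrapper around [assign_reads()] for one sequence.
#'
#' @param read a single DNA sequence.
#' @param panel a `ref_panel`.
#' @inheritParams assign_reads
#' @return A one-row `assignment_table`.
#' @export
best_hit_assign <- function(read, panel, scoring = align_scoring(),
                            tie_tol = 1e-4) {
  assign_reads(stats::setNames(read, "query"), panel,
               method = "best_hit_lca", scoring = scoring, tie_tol = tie_tol)
}

#' Consensus assignment of a single read
#'
#' @inheritParams assign_reads
#' @param read a single DNA sequence.
#' @return A one-row `assignment_table`.
#' @export
consensus_assign <- function(read, panel, top_window = 0, confidence = 0.80,
                             scoring = align_scoring()) {
  assign_reads(stats::setNames(read, "query"), panel, method = "consensus",
               top_window = top_window, confidence = confidence,
               scoring = scoring)
}

#' Keep reads whose assigned path contains a taxon
#'
#' Order-preserving and idempotent; reads assigned `"unassigned-root"` never
#' match.
#'
#' @param assignments an `assignment_table`.
#' @param taxon a taxon name (e.g. `"Bacillariophyta"`).
#' @return The read ids whose path contains `taxon`.
#' @export
filter_by_taxon <- function(assignments, taxon) {
  stopifnot(length(taxon) == 1L, nzchar(taxon))
  hit <- vapply(split_path(assignments$path), function(p) taxon %in% p,
                logical(1))
  assignments$read_id[hit]
}
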