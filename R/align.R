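#' Default alignment scoring
#'
#' Standard DNA scoring used throughout the pipeline: match +5, mismatch -4,
#' gap open -10, gap extend -1 (a gap run of length k costs
#' `gap_open + k * gap_extend`). `N` (or any non-ACGT letter) mismatches
#' everything, including itself.
#'
#' @param match,mismatch,gap_open,gap_extend numeric scores/penalties.
#' @return A named list of the four scoring parameters.
#' @export
align_scoring <- function(match = 5, mismatch = -4, gap_open = -10,
                          gap_extend = -1) {
  stopifnot(is.numeric(match), is.numeric(mismatch),
            is.numeric(gap_open), is.numeric(gap_extend))
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend)
}

.check_seq_arg <- function(x, what) {
  if (!is.character(x) || any(is.na(x)) || any(!nzchar(x)))
    stop(what, " must be non-empty character sequences", call. = FALSE)
  toupper(x)
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties (Gotoh
#' three-state recursion) and deterministic tie-breaking during traceback
#' (prefer diagonal, then up, then left). Identity is
#' `matches / columns`, where columns exclude the terminal-gap run at each end
#' of the alignment, so a short tag aligned inside a longer reference is not
#' penalised for its length.
#'
#' @param a,b DNA sequences (non-empty strings).
#' @param scoring scoring list from [align_scoring()].
#' @return An object of class `alignment_result`: list with `aligned_a`,
#'   `aligned_b` (gapped strings of equal length), `matches`, `columns`
#'   (terminal-gap-trimmed), `identity`, and `score`.
#' @examples
#' global_align("ACGT", "ACGA")$identity  # 0.75
#' @export
global_align <- function(a, b, scoring = align_scoring()) {
  a <- .check_seq_arg(a, "a"); b <- .check_seq_arg(b, "b")
  stopifnot(length(a) == 1L, length(b) == 1L)
  r <- cpp_align_pair(a, b, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
  out <- list(aligned_a = r$aligned_a, aligned_b = r$aligned_b,
              matches = r$matches, columns = r$columns,
              identity = if (r$columns > 0) r$matches / r$columns else 0,
              score = r$score)
  class(out) <- "alignment_result"
  out
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("Global alignment: score", x$score,
      sprintf("| identity %.4f (%d/%d columns)\n", x$identity, x$matches, x$columns))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' Global sequence identity between two sequences
#'
#' The identity of the optimal global alignment under `scoring`. Symmetric in
#' its arguments. With `denom = "alignment"` (default) the denominator is the
#' number of alignment columns after terminal-gap trimming; with
#' `denom = "shorter"` it is the length of the shorter sequence (the
#' convention of greedy clustering tools such as CD-HIT).
#'
#' @inheritParams global_align
#' @param denom identity denominator convention.
#' @return A fraction in `[0, 1]`.
#' @export
seq_identity <- function(a, b, scoring = align_scoring(),
                         denom = c("alignment", "shorter")) {
  denom <- match.arg(denom)
  a <- .check_seq_arg(a, "a"); b <- .check_seq_arg(b, "b")
  drop(cpp_identity_many(a, b, scoring$match, scoring$mismatch,
                         scoring$gap_open, scoring$gap_extend,
                         denom == "shorter"))
}

#' All-pairs global identity matrix
#'
#' @param seqs character vector of two or more sequences (names are kept as
#'   dimnames).
#' @inheritParams seq_identity
#' @return A symmetric matrix of pairwise identities with unit diagonal.
#' @export
identity_matrix <- function(seqs, scoring = align_scoring(),
                            denom = c("alignment", "shorter")) {
  denom <- match.arg(denom)
  if (length(seqs) < 2) stop("identity_matrix needs at least 2 sequences")
  seqs <- .check_seq_arg(seqs, "seqs")
  m <- cpp_identity_matrix(seqs, scoring$match, scoring$mismatch,
                           scoring$gap_open, scoring$gap_extend,
                           denom == "shorter")
  dimnames(m) <- list(names(seqs), names(seqs))
  m
}

# identities of many queries against many references; rows = queries
.identity_many <- function(queries, refs, scoring, denom = "alignment") {
  cpp_identity_many(toupper(queries), toupper(refs),
                    scoring$match, scoring$mismatch,
                    scoring$gap_open, scoring$gap_extend,
                    denom == "shorter")
}
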