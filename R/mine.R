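#' Iterative reference-guided mining of an annotated sequence collection
#'
#' Emulates an iterative similarity search of a local annotated database with
#' the family references as starting queries. For a query `q` the retention
#' floor is `t(q) = min` over the other family references `r` of
#' `identity(r, q)`: a database hit is retained when its identity to the
#' query is at least as high as the most dissimilar family reference is to
#' that query. Newly retained sequences become the queries of the next
#' generation, until no new sequence is added or `max_generations` is
#' reached. The retained set is a fixed point and is independent of database
#' record order.
#'
#' @param database a `ref_panel`-style annotated data frame (the collection
#'   to mine).
#' @param family_refs a `ref_panel` of family references.
#' @param max_generations iteration cap (>= 1).
#' @param scoring alignment scoring.
#' @return An object of class `mine_result`: list with `retained` (data frame
#'   `id`, `best_query`, `identity`, `generation`) and `excluded` (`id`,
#'   `reason`, `best_identity`, `best_query`, `floor`).
#' @export
mine <- function(database, family_refs, max_generations = 5,
                 scoring = align_scoring()) {
  if (max_generations < 1) stop("max_generations must be >= 1")
  if (nrow(database) == 0 || nrow(family_refs) == 0)
    stop("database and family_refs must be non-empty")
  db_ids <- database$id
  # canonical order so results cannot depend on database record order
  ord <- order(db_ids)
  database <- database[ord, , drop = FALSE]
  db_ids <- database$id

  ref_floor <- function(qid, qseq) {
    others <- family_refs$id != qid
    if (!any(others)) return(0)
    min(.identity_many(qseq, family_refs$sequence[others], scoring))
  }

  retained <- data.frame(id = character(), best_query = character(),
                         identity = numeric(), generation = integer(),
                         stringsAsFactors = FALSE)
  excl_best <- stats::setNames(rep(-Inf, nrow(database)), db_ids)
  excl_query <- stats::setNames(rep(NA_character_, nrow(database)), db_ids)
  excl_floor <- stats::setNames(rep(NA_real_, nrow(database)), db_ids)

  queries <- data.frame(id = family_refs$id, sequence = family_refs$sequence,
                        stringsAsFactors = FALSE)
  gen <- 0L
  while (nrow(queries) > 0 && gen < max_generations) {
    gen <- gen + 1L
    open <- !(db_ids %in% retained$id)
    if (!any(open)) break
    idm <- .identity_many(database$sequence[open], queries$sequence, scoring)
    open_ids <- db_ids[open]
    newly <- character()
    for (k in seq_along(open_ids)) {
      hit <- FALSE
      for (q in seq_len(nrow(queries))) {
        flo <- ref_floor(queries$id[q], queries$sequence[q])
        v <- idm[k, q]
        if (v >= flo - 1e-12) {
          retained <- rbind(retained, data.frame(
            id = open_ids[k], best_query = queries$id[q], identity = v,
            generation = gen, stringsAsFactors = FALSE))
          hit <- TRUE
          break
        }
        if (v > excl_best[open_ids[k]]) {
          excl_best[open_ids[k]] <- v
          excl_query[open_ids[k]] <- queries$id[q]
          excl_floor[open_ids[k]] <- flo
        }
      }
      if (hit) newly <- c(newly, open_ids[k])
    }
    queries <- data.frame(id = newly,
                          sequence = database$sequence[match(newly, db_ids)],
                          stringsAsFactors = FALSE)
  }
  left <- setdiff(db_ids, retained$id)
  excluded <- data.frame(id = left,
                         reason = rep("below family floor", length(left)),
                         best_identity = as.numeric(excl_best[left]),
                         best_query = as.character(excl_query[left]),
                         floor = as.numeric(excl_floor[left]),
                         stringsAsFactors = FALSE)
  out <- list(retained = retained, excluded = excluded,
              generations = gen)
  class(out) <- "mine_result"
  out
}

#' @export
print.mine_result <- function(x, ...) {
  cat(sprintf("Mining: %d retained (%d generation(s)), %d excluded\n",
              nrow(x$retained), x$generations, nrow(x$excluded)))
  invisible(x)
}

#' Doubt check: discard a candidate whose nearest neighbours are non-family
#'
#' Ranks the database (candidate excluded) by identity to the candidate and
#' keeps the candidate only when the top hit belongs to the family. An exact
#' tie between the best family and best non-family hit (identities equal
#' after rounding to 4 decimals) resolves conservatively to discard.
#'
#' @param candidate_id id of the candidate record within `database`.
#' @param database a `ref_panel`-style annotated data frame containing the
#'   candidate.
#' @param family_refs a `ref_panel` of family references (used to derive the
#'   family taxon: the deepest rank shared by all of them).
#' @param scoring alignment scoring.
#' @return `"keep"` or `"discard"`.
#' @export
doubt_check <- function(candidate_id, database, family_refs,
                        scoring = align_scoring()) {
  k <- match(candidate_id, database$id)
  if (is.na(k)) stop("candidate not found in database: ", candidate_id)
  family_taxon <- utils::tail(lca(family_refs$taxonomy), 1)
  others <- database[-k, , drop = FALSE]
  if (nrow(others) == 0) return("keep")
  ids <- drop(.identity_many(database$sequence[k], others$sequence, scoring))
  in_family <- vapply(split_path(others$taxonomy),
                      function(p) family_taxon %in% p, logical(1))
  if (!any(in_family)) return("discard")
  if (all(in_family)) return("keep")
  best_fam <- max(ids[in_family])
  best_out <- max(ids[!in_family])
  if (round(best_fam, 4) > round(best_out, 4)) "keep" else "discard"
}
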