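# Shared fixtures and independent oracles used across the suite.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Tiny annotated reference panel: two family species (one genus), one
# congeneric pair in a second genus, one distant outgroup.
tiny_panel <- function() {
  taxascreen:::.new_ref_panel(
    id = c("ref_A", "ref_B", "ref_C", "ref_D", "ref_O"),
    taxonomy = c(
      "Eukaryota;Bacillariophyta;Leptocylindraceae;Leptocylindrus;Leptocylindrus danicus",
      "Eukaryota;Bacillariophyta;Leptocylindraceae;Leptocylindrus;Leptocylindrus aporus",
      "Eukaryota;Bacillariophyta;Chaetocerotaceae;Chaetoceros;Chaetoceros one",
      "Eukaryota;Bacillariophyta;Chaetocerotaceae;Chaetoceros;Chaetoceros two",
      "Eukaryota;Bolidophyceae;Bolidomonadaceae;Bolidomonas;Bolidomonas pacifica"),
    region = "V4",
    sequence = c("ACGTACGTACGTACGTACGT",
                 "ACGTACGTACGTACGTAAAT",
                 "ACGTACGTTTTTACGTACGT",
                 "ACGTACGTTTTTACGTAAAT",
                 "TTTTTTTTCCCCACCCGGGG"))
}

make_reads_df <- function(seqs, sample_id = "S1", prefix = "r") {
  taxascreen:::.new_reads(sprintf("%s%03d", prefix, seq_along(seqs)),
                          rep_len(sample_id, length(seqs)), seqs)
}

# Exhaustive global-alignment score oracle: plain recursion over all
# alignment paths with affine gap costs (state = none/gap-in-b/gap-in-a).
brute_force_score <- function(a, b, scoring = align_scoring()) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  ma <- scoring$match; mi <- scoring$mismatch
  go <- scoring$gap_open; ge <- scoring$gap_extend
  n <- length(av); m <- length(bv)
  # plain recursion from the full lengths, state "none"
  f <- function(i, j, state) {
    if (i == n && j == m) return(0)
    best <- -Inf
    if (i < n && j < m) {
      s <- if (av[i + 1] == bv[j + 1] && av[i + 1] != "N") ma else mi
      best <- max(best, s + f(i + 1, j + 1, 0L))
    }
    if (i < n) {
      pen <- if (state == 1L) ge else go + ge
      best <- max(best, pen + f(i + 1, j, 1L))
    }
    if (j < m) {
      pen <- if (state == 2L) ge else go + ge
      best <- max(best, pen + f(i, j + 1, 2L))
    }
    best
  }
  f(0L, 0L, 0L)
}

# Brute-force Fitch oracle: enumerate all internal-node labelings.
brute_force_parsimony <- function(tree, rows) {
  m <- do.call(rbind, strsplit(toupper(rows), ""))
  rownames(m) <- names(rows)
  states <- c("A", "C", "G", "T")
  n_int <- tree$Nnode
  ntip <- length(tree$tip.label)
  edges <- tree$edge
  total <- 0L
  for (col in seq_len(ncol(m))) {
    tipstate <- m[tree$tip.label, col]
    best <- Inf
    grid <- do.call(expand.grid,
                    c(rep(list(states), n_int), stringsAsFactors = FALSE))
    for (g in seq_len(nrow(grid))) {
      lab <- c(tipstate, unlist(grid[g, ], use.names = FALSE))
      changes <- sum(lab[edges[, 1]] != lab[edges[, 2]])
      best <- min(best, changes)
    }
    total <- total + best
  }
  total
}

# Transitive-closure oracle for the mining retention rule.
mine_closure_oracle <- function(database, family_refs, max_generations = 10) {
  floor_of <- function(qid, qseq) {
    others <- family_refs$id != qid
    if (!any(others)) return(0)
    min(vapply(family_refs$sequence[others],
               function(r) seq_identity(r, qseq), numeric(1)))
  }
  retained <- character()
  queries <- data.frame(id = family_refs$id, sequence = family_refs$sequence)
  for (gen in seq_len(max_generations)) {
    new <- character()
    for (q in seq_len(nrow(queries))) {
      flo <- floor_of(queries$id[q], queries$sequence[q])
      for (k in seq_len(nrow(database))) {
        if (database$id[k] %in% c(retained, new)) next
        if (seq_identity(database$sequence[k], queries$sequence[q]) >= flo - 1e-12)
          new <- c(new, database$id[k])
      }
    }
    if (!length(new)) break
    retained <- c(retained, new)
    queries <- data.frame(id = new,
                          sequence = database$sequence[match(new, database$id)])
  }
  sort(retained)
}

# Exhaustive enumeration of unrooted binary topologies over n labelled tips
# (each topology arises exactly once by successive leaf insertion into every
# edge). Tips are nodes 1..n; internal nodes follow.
all_unrooted_topologies <- function(n) {
  trees <- list(list(edges = rbind(c(n + 1, 1), c(n + 1, 2), c(n + 1, 3)),
                     next_node = n + 2L))
  for (tip in seq_len(n)[-(1:3)]) {
    out <- vector("list", 0)
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edges))) {
        ed <- tr$edges
        w <- tr$next_node
        uv <- ed[e, ]
        ed2 <- rbind(ed[-e, , drop = FALSE],
                     c(uv[1], w), c(w, uv[2]), c(w, tip))
        out[[length(out) + 1]] <- list(edges = ed2, next_node = w + 1L)
      }
    }
    trees <- out
  }
  trees
}

# Tip-to-tip path lengths of an edge-listed topology with edge lengths.
edgelist_tip_distances <- function(edges, lengths, tip_labels) {
  n <- length(tip_labels)
  nn <- max(edges)
  adj <- vector("list", nn)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, lengths[e]))
    adj[[b]] <- rbind(adj[[b]], c(a, lengths[e]))
  }
  d <- matrix(0, n, n, dimnames = list(tip_labels, tip_labels))
  for (s in seq_len(n)) {
    dist <- rep(NA_real_, nn); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][k, 1]
        if (is.na(dist[u])) { dist[u] <- dist[v] + adj[[v]][k, 2]; queue <- c(queue, u) }
      }
    }
    d[s, ] <- dist[seq_len(n)]
  }
  d
}

# Canonical non-trivial bipartitions of an edge-listed topology.
edgelist_splits <- function(edges, tip_labels) {
  n <- length(tip_labels)
  canon <- function(side) {
    side <- sort(side); other <- sort(setdiff(tip_labels, side))
    if (length(side) < 2 || length(other) < 2) return(NULL)
    if (length(side) < length(other) ||
        (length(side) == length(other) && side[1] < other[1]))
      paste(side, collapse = "|") else paste(other, collapse = "|")
  }
  out <- character()
  for (e in seq_len(nrow(edges))) {
    rest <- edges[-e, , drop = FALSE]
    # flood fill from one endpoint without crossing the removed edge
    reach <- edges[e, 1]; grow <- TRUE
    while (grow) {
      hit <- rest[, 1] %in% reach | rest[, 2] %in% reach
      nxt <- unique(c(rest[hit, 1], rest[hit, 2]))
      grow <- length(setdiff(nxt, reach)) > 0
      reach <- union(reach, nxt)
    }
    key <- canon(tip_labels[reach[reach <= n]])
    if (!is.null(key)) out <- c(out, key)
  }
  sort(unique(out))
}

# Splits of a phylo object (via the package's postorder tip sets).
phylo_splits <- function(tre) {
  ntip <- length(tre$tip.label)
  tips <- sort(tre$tip.label)
  sets <- taxascreen:::.node_tip_sets(tre)
  out <- character()
  for (node in (ntip + 1):(ntip + tre$Nnode)) {
    side <- sort(sets[[node]])
    other <- sort(setdiff(tips, side))
    if (length(side) < 2 || length(other) < 2) next
    key <- if (length(side) < length(other) ||
               (length(side) == length(other) && side[1] < other[1]))
      paste(side, collapse = "|") else paste(other, collapse = "|")
    out <- c(out, key)
  }
  sort(unique(out))
}
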