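#' Thread query sequences into a master reference alignment
#'
#' Each query is globally aligned to its nearest (highest-identity) reference
#' and its bases are projected into that reference's columns of the master
#' alignment. Query insertions relative to the template have no column to
#' live in and are dropped (their counts are reported); query deletions
#' become gaps. Every output row has exactly the master's column count, so
#' tags can be combined with the references for distance and tree building.
#'
#' @param queries named character vector of query sequences.
#' @param master named character vector of equal-width gapped reference rows.
#' @param scoring alignment scoring.
#' @return A list with `rows` (named character vector of gapped query rows),
#'   `template` (chosen reference per query) and `dropped` (inserted bases
#'   discarded per query).
#' @export
template_align <- function(queries, master, scoring = align_scoring()) {
  if (!length(master)) stop("master alignment is empty")
  widths <- nchar(master)
  if (length(unique(widths)) != 1) stop("master alignment rows differ in width")
  width <- widths[1]
  if (!length(queries))
    return(list(rows = character(), template = character(), dropped = integer()))
  if (is.null(names(queries)) || is.null(names(master)))
    stop("queries and master must be named")
  degap <- gsub("-", "", master, fixed = TRUE)
  idm <- .identity_many(queries, degap, scoring)
  rows <- character(length(queries))
  tmpl <- character(length(queries))
  dropped <- integer(length(queries))
  for (q in seq_along(queries)) {
    r <- which.max(idm[q, ])
    tmpl[q] <- names(master)[r]
    ref_cols <- which(strsplit(master[[r]], "")[[1]] != "-")
    aln <- global_align(queries[[q]], degap[[r]], scoring)
    qa <- strsplit(aln$aligned_a, "")[[1]]
    ra <- strsplit(aln$aligned_b, "")[[1]]
    out <- rep("-", width)
    ri <- 0L; ndrop <- 0L
    for (k in seq_along(qa)) {
      if (ra[k] != "-") {
        ri <- ri + 1L
        if (qa[k] != "-") out[ref_cols[ri]] <- qa[k]
      } else {
        ndrop <- ndrop + 1L  # query insertion relative to the template
      }
    }
    rows[q] <- paste(out, collapse = "")
    dropped[q] <- ndrop
  }
  names(rows) <- names(queries)
  names(dropped) <- names(queries)
  list(rows = rows, template = tmpl, dropped = dropped)
}

.rows_to_matrix <- function(rows) {
  if (is.matrix(rows)) return(rows)
  m <- do.call(rbind, strsplit(tolower(rows), ""))
  rownames(m) <- names(rows)
  m
}

#' Pairwise distances from aligned rows
#'
#' p-distance over the columns where both rows are ungapped and unambiguous
#' (pairwise deletion), optionally with the Jukes-Cantor correction
#' `d = -(3/4) log(1 - (4/3) p)`.
#'
#' @param rows named character vector of equal-width gapped rows, or a
#'   character matrix.
#' @param model `"raw"` (p-distance) or `"JC69"`.
#' @return A `dist` object.
#' @export
distance_from_alignment <- function(rows, model = c("raw", "JC69")) {
  model <- match.arg(model)
  m <- .rows_to_matrix(rows)
  if (nrow(m) < 3) stop("need at least 3 rows")
  d <- ape::dist.dna(ape::as.DNAbin(m), model = model,
                     pairwise.deletion = TRUE)
  bad <- !is.finite(as.matrix(d))
  diag(bad) <- FALSE
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("no shared ungapped columns (or saturated distance) between '%s' and '%s'",
                 rownames(m)[ij[1]], rownames(m)[ij[2]]))
  }
  d
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Standard neighbor joining; any negative branch length is clamped to zero
#' with the deficit shifted to the adjacent edge so that path lengths are
#' preserved.
#'
#' @param d a `dist` object or symmetric distance matrix (>= 3 taxa).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (is.matrix(d)) d <- stats::as.dist(d)
  if (attr(d, "Size") < 3) stop("need at least 3 taxa")
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries")
  phy <- ape::nj(d)
  neg <- which(phy$edge.length < 0)
  for (e in neg) {
    child <- phy$edge[e, 2]
    # shift the deficit to the edges below the child (sister of the
    # subtraction in the NJ formulas), preserving leaf-to-leaf path lengths
    below <- which(phy$edge[, 1] == child)
    phy$edge.length[below] <- phy$edge.length[below] + phy$edge.length[e]
    phy$edge.length[e] <- 0
  }
  phy$edge.length[phy$edge.length < 0] <- 0
  phy
}

#' Root a tree on a designated outgroup
#'
#' The root is placed on the edge separating the outgroup from the rest. A
#' multi-leaf outgroup must be monophyletic in the unrooted tree; if it is
#' not, an error is raised rather than silently resolving it.
#'
#' @param tree an unrooted `phylo`.
#' @param outgroup_ids leaf labels of the outgroup.
#' @return A rooted `phylo`.
#' @export
root_tree <- function(tree, outgroup_ids) {
  missing <- setdiff(outgroup_ids, tree$tip.label)
  if (length(missing))
    stop("outgroup leaves not in tree: ", paste(missing, collapse = ", "))
  if (length(outgroup_ids) > 1 &&
      !ape::is.monophyletic(tree, outgroup_ids))
    stop("outgroup is not monophyletic in the unrooted tree")
  ape::root(tree, outgroup = outgroup_ids, resolve.root = TRUE)
}

#' Smallest clade containing all family reference leaves
#'
#' The most recent common ancestor of the reference set in a rooted tree,
#' with its full leaf set; non-reference leaves inside the clade are the
#' captured tags (or interlopers) resolving within the family.
#'
#' @param tree a rooted `phylo`.
#' @param family_ref_ids reference leaf labels.
#' @return A list with `node` (MRCA node id), `leaves` (all leaf labels in the
#'   clade) and `inside_non_ref` (clade leaves that are not references).
#' @export
family_clade <- function(tree, family_ref_ids) {
  missing <- setdiff(family_ref_ids, tree$tip.label)
  if (length(missing))
    stop("family reference leaves not in tree: ", paste(missing, collapse = ", "))
  if (length(family_ref_ids) == 1) {
    node <- match(family_ref_ids, tree$tip.label)
    return(list(node = node, leaves = family_ref_ids,
                inside_non_ref = character()))
  }
  node <- ape::getMRCA(tree, family_ref_ids)
  leaves <- ape::extract.clade(tree, node)$tip.label
  list(node = node, leaves = leaves,
       inside_non_ref = setdiff(leaves, family_ref_ids))
}

#' Assign OTU representatives to species by clade membership
#'
#' An OTU leaf inside the family clade is assigned to species S exactly when
#' its smallest enclosing clade that contains any reference contains only
#' references of S (species indistinguishable in the region under study
#' should be merged into one label in `species_ref_map` upstream). An OTU
#' inside the family clade but whose nearest enclosing reference clade mixes
#' species is `"family-unplaced"` (a candidate new taxon); an OTU outside the
#' family clade is `"outside"` (a putative false positive, to be confirmed by
#' a nearest-reference identity check, see [confirm_false_positives()]).
#'
#' @param tree a rooted `phylo`.
#' @param otu_ids OTU leaf labels to classify.
#' @param species_ref_map named list mapping each species label to its
#'   reference leaf label(s).
#' @param min_divergence optional gate on `"family-unplaced"` verdicts: a
#'   candidate new taxon must be at least this divergent (`1 - identity`)
#'   from its nearest reference; topologically unplaced OTUs below the gate
#'   (sequencing-error-scale material in ambiguous positions) are assigned
#'   their nearest reference's label instead. Requires `divergence` and
#'   `nearest_label`; 0 (default) disables the gate.
#' @param divergence named numeric: `1 - best reference identity` per OTU id.
#' @param nearest_label named character: nearest reference's species label
#'   per OTU id.
#' @return A named character vector: species label, `"family-unplaced"` or
#'   `"outside"` per OTU id.
#' @export
assign_species_by_clade <- function(tree, otu_ids, species_ref_map,
                                    min_divergence = 0, divergence = NULL,
                                    nearest_label = NULL) {
  fam_refs <- unlist(species_ref_map, use.names = FALSE)
  missing <- setdiff(otu_ids, tree$tip.label)
  if (length(missing))
    stop("otu id(s) not a leaf of the tree: ", paste(missing, collapse = ", "))
  clade <- family_clade(tree, fam_refs)
  ref_species <- rep(names(species_ref_map), lengths(species_ref_map))
  names(ref_species) <- fam_refs
  # one postorder sweep collecting, per internal node, its descendant tips
  tipsets <- .node_tip_sets(tree)
  # pre-compute, per multi-reference label, the leaf set of its references'
  # own MRCA: such a label delimits its species clade itself, and material
  # attaching outside it (sister to the whole species group) is not assigned
  mrca_leaves <- lapply(species_ref_map, function(refs) {
    if (length(refs) < 2) return(NULL)
    tipsets[[ape::getMRCA(tree, refs)]]
  })
  parent_of <- integer(length(tree$tip.label) + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  out <- stats::setNames(character(length(otu_ids)), otu_ids)
  for (o in otu_ids) {
    if (!(o %in% clade$leaves)) { out[o] <- "outside"; next }
    node <- match(o, tree$tip.label)
    repeat {
      parent <- parent_of[node]
      if (parent == 0L) { out[o] <- "family-unplaced"; break }
      tips <- tipsets[[parent]]
      refs_under <- intersect(tips, fam_refs)
      if (length(refs_under)) {
        sp <- unique(ref_species[refs_under])
        if (length(sp) != 1) {
          out[o] <- "family-unplaced"
        } else if (!is.null(mrca_leaves[[sp]]) &&
                   all(species_ref_map[[sp]] %in% refs_under) &&
                   !(o %in% mrca_leaves[[sp]])) {
          # sees the whole multi-reference species group from outside its
          # references' own clade: a candidate new taxon, not a member
          out[o] <- "family-unplaced"
        } else {
          out[o] <- sp
        }
        break
      }
      node <- parent
    }
  }
  if (min_divergence > 0) {
    if (is.null(divergence) || is.null(nearest_label))
      stop("min_divergence > 0 requires 'divergence' and 'nearest_label'")
    # topology proposes, divergence decides: a new-taxon call needs real
    # divergence from every reference; conversely, material that divergent
    # is never absorbed into a species by a noise-resolved topology
    low <- names(out)[out == "family-unplaced" &
                        divergence[names(out)] < min_divergence]
    out[low] <- nearest_label[low]
    high <- names(out)[!(out %in% c("family-unplaced", "outside")) &
                         divergence[names(out)] >= min_divergence]
    out[high] <- "family-unplaced"
  }
  out
}

#' Confirm putative false positives by nearest-reference identity
#'
#' For tags resolving outside the family clade, ranks the panel by global
#' identity; a tag is a confirmed false positive when its nearest reference
#' lies outside the family.
#'
#' @param seqs named character vector of tag sequences.
#' @param panel a `ref_panel`.
#' @param family_taxon family name (e.g. `"Leptocylindraceae"`).
#' @param scoring alignment scoring.
#' @return A data frame: `id`, `nearest_ref`, `identity`,
#'   `false_positive` (logical).
#' @export
confirm_false_positives <- function(seqs, panel,
                                    family_taxon = "Leptocylindraceae",
                                    scoring = align_scoring()) {
  if (!length(seqs))
    return(data.frame(id = character(), nearest_ref = character(),
                      identity = numeric(), false_positive = logical(),
                      stringsAsFactors = FALSE))
  idm <- .identity_many(seqs, panel$sequence, scoring)
  in_family <- vapply(split_path(panel$taxonomy),
                      function(p) family_taxon %in% p, logical(1))
  nearest <- apply(idm, 1, which.max)
  data.frame(id = names(seqs), nearest_ref = panel$id[nearest],
             identity = idm[cbind(seq_along(nearest), nearest)],
             false_positive = !in_family[nearest],
             stringsAsFactors = FALSE)
}

#' Bootstrap support by column resampling
#'
#' Alignment columns are resampled with replacement; a neighbor-joining tree
#' is built per replicate and the support of each bipartition of the original
#' tree is the fraction of replicates containing it. Deterministic under
#' `seed`.
#'
#' @param rows named character vector of gapped rows (or character matrix).
#' @param n_replicates number of bootstrap replicates.
#' @param seed integer seed.
#' @param model distance model passed to [distance_from_alignment()].
#' @return A list with `tree` (the NJ tree from the full alignment) and
#'   `support` (fraction in `[0, 1]` per internal node, in
#'   `ape::boot.phylo` node order).
#' @export
bootstrap_support <- function(rows, n_replicates = 100, seed = 1,
                              model = "raw") {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  m <- .rows_to_matrix(rows)
  # trees are rooted consistently on the first row so that bipartition
  # counting reduces to clade counting
  build <- function(x) {
    phy <- nj_tree(distance_from_alignment(x, model))
    ape::root(phy, outgroup = rownames(m)[1], resolve.root = TRUE)
  }
  tree <- build(m)
  set.seed(seed)
  counts <- ape::boot.phylo(tree, m, build, B = n_replicates,
                            quiet = TRUE, rooted = TRUE)
  list(tree = tree, support = counts / n_replicates)
}

#' Parsimony length of a tree (Fitch counting)
#'
#' Minimal number of state changes over the tree summed across alignment
#' columns, by the classical Fitch set-intersection algorithm.
#'
#' @param tree a `phylo` whose tip labels match the row names.
#' @param rows named character vector of aligned rows (or character matrix).
#' @return Integer parsimony score.
#' @export
fitch_length <- function(tree, rows) {
  m <- .rows_to_matrix(rows)
  if (!setequal(tree$tip.label, rownames(m)))
    stop("tree leaves and alignment rows disagree")
  dat <- phangorn::phyDat(m[tree$tip.label, , drop = FALSE], type = "DNA")
  as.integer(phangorn::fitch(tree, dat))
}

# descendant tip labels per node (tips included), by one postorder sweep
.node_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  sets <- vector("list", nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  # process edges so that children are complete before their parent:
  # sort internal nodes by decreasing height via repeated passes
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  pending <- as.integer(names(kids))
  done <- c(rep(TRUE, ntip), rep(FALSE, nnode - ntip))
  while (length(pending)) {
    progressed <- FALSE
    keep <- logical(length(pending))
    for (k in seq_along(pending)) {
      node <- pending[k]
      ch <- kids[[as.character(node)]]
      if (all(done[ch])) {
        sets[[node]] <- unlist(sets[ch], use.names = FALSE)
        done[node] <- TRUE
        progressed <- TRUE
      } else keep[k] <- TRUE
    }
    pending <- pending[keep]
    if (!progressed && length(pending)) stop("malformed tree edges")
  }
  sets
}

.g1_stat <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) return(NA_real_)
  mean((x - mu)^3) / s^3
}

#' Tree-length skewness (g1) over random topologies
#'
#' Samples uniform random leaf-labelled binary topologies (random sequential
#' leaf addition), computes each tree's parsimony length for the alignment,
#' and returns the g1 statistic (standardised third central moment) of the
#' length distribution. A strongly left-skewed distribution (g1 well below
#' zero, compared against published critical values for 4-state data) signals
#' phylogenetic structure in the alignment.
#'
#' @param rows named character vector of aligned rows (>= 4).
#' @param n_trees number of random topologies (>= 100).
#' @param seed integer seed.
#' @return An object of class `g1_result`: list with `n_trees`, `mean`, `sd`,
#'   `min`, `max`, `g1` and `undefined` (`TRUE` when the length distribution
#'   has zero variance, e.g. identical rows).
#' @export
random_tree_g1 <- function(rows, n_trees = 1000, seed = 1) {
  if (n_trees < 100) stop("n_trees must be >= 100")
  m <- .rows_to_matrix(rows)
  if (nrow(m) < 4) stop("need at least 4 rows")
  dat <- phangorn::phyDat(m, type = "DNA")
  labels <- rownames(m)
  set.seed(seed)
  lengths <- vapply(seq_len(n_trees), function(i) {
    phy <- ape::rtopology(length(labels), rooted = FALSE, tip.label = labels)
    as.numeric(phangorn::fitch(phy, dat))
  }, numeric(1))
  g1 <- .g1_stat(lengths)
  out <- list(n_trees = n_trees, mean = mean(lengths), sd = stats::sd(lengths),
              min = min(lengths), max = max(lengths), g1 = g1,
              undefined = is.na(g1), lengths = lengths)
  class(out) <- "g1_result"
  out
}

#' @export
print.g1_result <- function(x, ...) {
  cat(sprintf("Tree-length distribution over %d random topologies:\n", x$n_trees))
  cat(sprintf("  mean %.2f, sd %.2f, range [%g, %g]\n", x$mean, x$sd, x$min, x$max))
  if (x$undefined) cat("  g1 undefined (zero variance)\n")
  else cat(sprintf("  g1 skewness = %.4f\n", x$g1))
  invisible(x)
}
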