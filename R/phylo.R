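# 16S phylogenetic clustering: Kimura 2-parameter distances on aligned
# nucleotide sequences, classical Saitou-Nei neighbor-joining, and
# nonparametric bootstrap supports. Trees are returned as ape "phylo"
# objects; Newick export goes through ape::write.tree.

VALID_BASES <- c("A", "C", "G", "T")
TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

as_char_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L)
    pks_abort("sequences must be aligned (equal lengths)", "pks_value_error")
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  m
}

#' Transition/transversion counts for one aligned pair
#'
#' Only gap-free columns (both residues in A/C/G/T) are compared
#' (pairwise deletion).
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length.
#' @return List with `L` (compared sites), `P` (transition proportion),
#'   `Q` (transversion proportion).
#' @export
k2p_pair_counts <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b))
    pks_abort("sequences must have equal aligned length", "pks_value_error")
  keep <- a %in% VALID_BASES & b %in% VALID_BASES
  L <- sum(keep)
  if (L < 1L)
    pks_abort("no gap-free shared columns between the pair", "pks_value_error")
  a <- a[keep]; b <- b[keep]
  diff <- a != b
  ts <- sum(diff & TRANSITION_PARTNER[a] == b)
  tv <- sum(diff) - ts
  list(L = L, P = ts / L, Q = tv / L)
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))` over gap-free columns, with
#' `P` the transition and `Q` the transversion proportion. Saturated pairs
#' (non-positive log arguments) raise a `pks_saturation_error`.
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length.
#' @return Distance in substitutions/site.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  cnt <- k2p_pair_counts(seq_a, seq_b)
  w1 <- 1 - 2 * cnt$P - cnt$Q
  w2 <- 1 - 2 * cnt$Q
  if (w1 <= 0 || w2 <= 0)
    pks_abort(sprintf("K2P distance undefined (saturation): P=%.4g Q=%.4g",
                      cnt$P, cnt$Q), "pks_saturation_error")
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise K2P distance matrix of an alignment
#'
#' @param alignment Named character vector of aligned sequences (or a
#'   character matrix, taxa in rows).
#' @param deletion `"pairwise"` (default; gap-free columns per pair) or
#'   `"complete"` (columns gap-free in all taxa are used for every pair).
#' @return Symmetric numeric matrix with taxa dimnames.
#' @export
k2p_matrix <- function(alignment, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- as_char_matrix(alignment)
  if (is.null(rownames(m))) rownames(m) <- paste0("t", seq_len(nrow(m)))
  if (deletion == "complete") {
    keep <- apply(m, 2L, function(col) all(col %in% VALID_BASES))
    if (!any(keep))
      pks_abort("no gap-free columns under complete deletion", "pks_value_error")
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dij <- k2p_distance(paste(m[i, ], collapse = ""), paste(m[j, ], collapse = ""))
    d[i, j] <- dij; d[j, i] <- dij
  }
  d
}

# ---------------------------------------------------------------------------
# Neighbor-joining

validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    pks_abort("distance matrix must be square", "pks_validation_error")
  if (any(!is.finite(d)) || any(d < 0))
    pks_abort("distances must be finite and >= 0", "pks_validation_error")
  if (max(abs(d - t(d))) > 1e-8)
    pks_abort("distance matrix must be symmetric", "pks_validation_error")
  if (any(abs(diag(d)) > 1e-12))
    pks_abort("distance matrix must have a zero diagonal", "pks_validation_error")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  d
}

fmt_bl <- function(x) sprintf("%.10g", max(x, 0))

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei neighbor-joining (Q-criterion, standard
#' branch-length formulas). Ties in the Q matrix are broken by the lowest
#' (row, column) index pair, so the result is deterministic. Negative branch
#' lengths are clamped to zero with the deficit moved to the sibling edge
#' (MEGA-compatible); the raw values are kept in the `raw_lengths` attribute.
#'
#' @param d Symmetric distance matrix with taxa dimnames (>= 2 taxa).
#' @return An unrooted `phylo` object (ape).
#' @export
nj_tree <- function(d) {
  d <- validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 2L) pks_abort("need at least 2 taxa", "pks_validation_error")
  raw <- list()
  labels <- rownames(d)
  quote_lab <- function(x) gsub("[(),:;]", "_", x)
  nodes <- as.list(quote_lab(labels))  # newick fragments for active nodes

  join2 <- function(a, b, la, lb) sprintf("(%s:%s,%s:%s)", a, fmt_bl(la), b, fmt_bl(lb))

  while (nrow(d) > 3L) {
    r <- nrow(d)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, `+`)
    diag(Q) <- Inf
    # lowest (row, col) pair among minima, scanning upper triangle row-major
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    dij <- d[i, j]
    bi <- dij / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- dij - bi
    raw[[length(raw) + 1L]] <- c(bi, bj)
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    new_frag <- join2(nodes[[i]], nodes[[j]], bi, bj)
    dk <- (d[i, -c(i, j)] + d[j, -c(i, j)] - dij) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk), c(dk, 0))
    rn <- c(rownames(d)[keep], sprintf("node%d", length(raw)))
    dimnames(d2) <- list(rn, rn)
    d <- d2
    nodes <- c(nodes[keep], list(new_frag))
  }

  if (nrow(d) == 2L) {
    nwk <- sprintf("(%s:%s,%s:%s);", nodes[[1]], fmt_bl(d[1, 2]), nodes[[2]], fmt_bl(0))
  } else {
    # three-point formulas
    ba <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    bb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    bc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    raw[[length(raw) + 1L]] <- c(ba, bb, bc)
    bl <- clamp_triple(c(ba, bb, bc))
    nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                   nodes[[1]], fmt_bl(bl[1]), nodes[[2]], fmt_bl(bl[2]),
                   nodes[[3]], fmt_bl(bl[3]))
  }
  tree <- ape::read.tree(text = nwk)
  attr(tree, "raw_lengths") <- raw
  tree
}

# Clamp negative entries of the final three-edge star, redistributing the
# deficit over the positive siblings.
clamp_triple <- function(b) {
  neg <- sum(b[b < 0])
  b[b < 0] <- 0
  if (neg < 0) {
    pos <- b > 0
    if (any(pos)) b[pos] <- pmax(b[pos] + neg / sum(pos), 0)
  }
  b
}

# ---------------------------------------------------------------------------
# Bipartitions and bootstrap

#' Internal bipartitions of an unrooted tree
#'
#' Each internal edge splits the taxa into two sets; the canonical signature
#' is the sorted side not containing the reference taxon (first taxon,
#' alphabetically), pasted with "|".
#'
#' @param tree A `phylo` object.
#' @return Character vector of bipartition signatures (may be empty).
#' @export
tree_bipartitions <- function(tree) {
  taxa <- sort(tree$tip.label)
  ref <- taxa[1]
  n_tip <- length(taxa)
  out <- character()
  node_ids <- unique(tree$edge[, 2][tree$edge[, 2] > n_tip])
  for (node in node_ids) {
    tips <- tree$tip.label[tips_below(tree, node)]
    side <- if (ref %in% tips) setdiff(taxa, tips) else tips
    if (length(side) >= 2L && length(side) <= n_tip - 2L)
      out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

tips_below <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  acc <- integer()
  stack <- node
  while (length(stack)) {
    cur <- stack[[1]]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == cur, 2]
    tips <- kids[kids <= n_tip]
    acc <- c(acc, tips)
    stack <- c(stack, kids[kids > n_tip])
  }
  acc
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the full-data K2P + NJ tree, then resamples alignment columns with
#' replacement `n_replicates` times, rebuilding the tree each time; the
#' support of each internal bipartition of the full-data tree is the
#' percentage of (valid) replicates containing it. Replicates in which any
#' pair saturates are skipped with a warning and removed from the
#' denominator.
#'
#' @param alignment Named character vector of aligned nucleotide sequences.
#' @param n_replicates Number of bootstrap resamplings (default 1000).
#' @param seed Integer seed; the same seed gives identical supports.
#' @param deletion Gap handling passed to [k2p_matrix()].
#' @return A `phylo` tree whose `node.label` holds integer percent supports
#'   (empty for the root), with attributes `supports` (named vector) and
#'   `n_valid_replicates`.
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000L, seed = NULL,
                              deletion = "pairwise") {
  if (n_replicates < 0L) pks_abort("n_replicates must be >= 0", "pks_value_error")
  m <- as_char_matrix(alignment)
  full <- nj_tree(k2p_matrix(m, deletion))
  bips <- tree_bipartitions(full)
  counts <- setNames(numeric(length(bips)), bips)
  run <- function() {
    skipped <- 0L
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rep_tree <- tryCatch(nj_tree(k2p_matrix(m[, cols, drop = FALSE], deletion)),
                           pks_saturation_error = function(e) NULL,
                           pks_value_error = function(e) NULL)
      if (is.null(rep_tree)) { skipped <- skipped + 1L; next }
      rb <- tree_bipartitions(rep_tree)
      hit <- bips %in% rb
      counts[hit] <<- counts[hit] + 1
    }
    skipped
  }
  skipped <- if (is.null(seed)) run() else with_rng_seed(seed, run())
  valid <- n_replicates - skipped
  if (skipped > 0L)
    warning(sprintf("%d of %d bootstrap replicates skipped (saturated distances)",
                    skipped, n_replicates))
  supports <- if (valid > 0L) 100 * counts / valid else counts * NA_real_
  full <- annotate_supports(full, supports)
  attr(full, "supports") <- supports
  attr(full, "n_valid_replicates") <- valid
  full
}

# Write integer supports into node.label, matching nodes to bipartitions.
annotate_supports <- function(tree, supports) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  taxa <- sort(tree$tip.label)
  ref <- taxa[1]
  labels <- rep("", n_node)
  for (node in (n_tip + 1L):(n_tip + n_node)) {
    tips <- tree$tip.label[tips_below(tree, node)]
    side <- if (ref %in% tips) setdiff(taxa, tips) else tips
    if (length(side) < 2L || length(side) > n_tip - 2L) next
    sig <- paste(sort(side), collapse = "|")
    if (sig %in% names(supports))
      labels[node - n_tip] <- as.character(round(supports[[sig]]))
  }
  tree$node.label <- labels
  tree
}

#' Write a tree with supports as Newick
#'
#' @param tree A `phylo` object (e.g. from [bootstrap_support()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
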