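#' Transition and transversion proportions of an aligned sequence pair
#'
#' Alignment columns containing a gap or a non-ACGT symbol in either
#' sequence are excluded (pairwise deletion, applied independently for
#' each sequence pair).
#'
#' @param a,b aligned sequences of equal length (alphabet ACGTN plus "-").
#' @return list with `P` (transition proportion), `Q` (transversion
#'   proportion) and `n` (compared sites after pairwise deletion).
#' @export
count_substitutions <- function(a, b) {
  x <- seq_chars(toupper(a))
  y <- seq_chars(toupper(b))
  if (length(x) != length(y)) stop("aligned sequences must have equal length")
  ok <- x %in% DNA_BASES & y %in% DNA_BASES
  n <- sum(ok)
  if (n == 0) stop("no comparable sites after pairwise deletion")
  x <- x[ok]; y <- y[ok]
  diff <- x != y
  ts <- diff & TRANSITION[x] == y
  list(P = sum(ts) / n, Q = sum(diff & !ts) / n, n = n)
}

#' Kimura 2-parameter distance
#'
#' d = -(1/2) ln(1 - 2P - Q) - (1/4) ln(1 - 2Q), the substitution-per-site
#' estimate correcting separately for transitions and transversions.
#'
#' @param counts a list with `P` and `Q` (e.g. from
#'   [count_substitutions()]), or a transition proportion if `Q` is given.
#' @param Q transversion proportion when `counts` is numeric.
#' @return distance in substitutions per site.
#' @export
k2p_distance <- function(counts, Q = NULL) {
  if (is.list(counts)) {
    P <- counts$P; Q <- counts$Q
  } else {
    P <- counts
  }
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) {
    stop("saturation: substitution proportions too large for the K2P correction")
  }
  -0.5 * log(a1) - 0.25 * log(a2)
}

#' K2P distance matrix of a multiple alignment
#'
#' @param alignment named character vector of aligned sequences (equal
#'   length); ambiguous positions are removed for each sequence pair.
#' @return symmetric distance matrix with zero diagonal.
#' @export
k2p_matrix <- function(alignment) {
  n <- length(alignment)
  if (is.null(names(alignment))) names(alignment) <- paste0("t", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- k2p_distance(count_substitutions(alignment[[i]], alignment[[j]]))
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree construction
#'
#' Standard agglomerative neighbor joining: at each step the pair
#' minimizing the Q criterion (n-2)d(i,j) - R(i) - R(j) is joined (ties
#' broken by lowest index pair, making the output deterministic), branch
#' lengths assigned by the rate-corrected formulas, and the matrix
#' reduced. Negative branch lengths are clamped to zero with the deficit
#' moved to the sister edge so path lengths are preserved. The result is
#' an unrooted tree with a trifurcating root node.
#'
#' @param D symmetric distance matrix with labelled rows (>= 3 taxa).
#' @return an object of class `phylo`.
#' @export
nj_build <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  active <- seq_len(n)          # current node ids, tips are 1..n
  d <- D
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  nextid <- n + 1L
  while (length(active) > 3) {
    m <- length(active)
    R <- rowSums(d)
    Qc <- (m - 2) * d - outer(R, R, "+")
    diag(Qc) <- Inf
    idx <- which(Qc == min(Qc), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- 0.5 * d[i, j] + (R[i] - R[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    parent <- c(parent, nextid, nextid)
    child <- c(child, active[i], active[j])
    elen <- c(elen, li, lj)
    dn <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]),
               c(dn[keep], 0))
    active <- c(active[keep], nextid)
    nextid <- nextid + 1L
  }
  # final three-way join solves the three-point equations exactly
  la <- 0.5 * (d[1, 2] + d[1, 3] - d[2, 3])
  lb <- 0.5 * (d[1, 2] + d[2, 3] - d[1, 3])
  lc <- 0.5 * (d[1, 3] + d[2, 3] - d[1, 2])
  parent <- c(parent, rep(nextid, 3L))
  child <- c(child, active[1:3])
  elen <- c(elen, pmax(c(la, lb, lc), 0))
  # renumber internal nodes so the root (created last) becomes n+1
  remap <- function(v) ifelse(v <= n, v, n + 1L + (nextid - v))
  phy <- structure(list(
    edge = cbind(remap(parent), remap(child)),
    edge.length = unname(elen),
    tip.label = labels,
    Nnode = nextid - n
  ), class = "phylo")
  storage.mode(phy$edge) <- "integer"
  ape::reorder.phylo(phy, "cladewise")
}

# canonical keys for the non-trivial bipartitions induced by internal
# edges; each key is the sorted tip set on the side not containing the
# first tip label (alphabetically), so keys are complement-invariant
tree_bipartitions <- function(phy) {
  n <- length(phy$tip.label)
  anchor <- sort(phy$tip.label)[1]
  parts <- ape::prop.part(phy)
  labs <- attr(parts, "labels")
  keys <- character(0)
  for (p in parts) {
    side <- labs[p]
    if (length(side) %in% c(0, 1, n, n - 1)) next
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) < 2) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

# bipartition key of the clade under each internal edge, in edge order
edge_bipartition_keys <- function(phy) {
  n <- length(phy$tip.label)
  anchor <- sort(phy$tip.label)[1]
  keys <- rep(NA_character_, nrow(phy$edge))
  for (e in seq_len(nrow(phy$edge))) {
    ch <- phy$edge[e, 2]
    if (ch <= n) next
    tips <- phy$tip.label[clade_tips(phy, ch)]
    if (anchor %in% tips) tips <- setdiff(phy$tip.label, tips)
    if (length(tips) < 2 || length(tips) > n - 2) next
    keys[e] <- paste(sort(tips), collapse = "|")
  }
  keys
}

clade_tips <- function(phy, node) {
  n <- length(phy$tip.label)
  todo <- node
  tips <- integer(0)
  while (length(todo)) {
    v <- todo[1]; todo <- todo[-1]
    ch <- phy$edge[phy$edge[, 1] == v, 2]
    tips <- c(tips, ch[ch <= n])
    todo <- c(todo, ch[ch > n])
  }
  tips
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the K2P
#' neighbor-joining tree for each replicate, and reports for every
#' internal bipartition of the original tree the percentage of replicate
#' trees containing it. Supports are attached as internal node labels
#' (the convention of printed trees).
#'
#' @param alignment named character vector of aligned sequences.
#' @param n_replicates bootstrap replicates (default 100).
#' @param seed integer seed or `NULL`.
#' @param dist_fun function mapping an alignment to a distance matrix
#'   (default [k2p_matrix()]).
#' @return the neighbor-joining `phylo` tree of the full alignment with a
#'   `node.label` vector of integer supports (NA for the root). With
#'   fewer than 4 taxa supports are undefined and the labels are all NA.
#' @export
bootstrap_support <- function(alignment, n_replicates = 100, seed = NULL,
                              dist_fun = k2p_matrix) {
  stopifnot(n_replicates >= 1)
  phy <- nj_build(dist_fun(alignment))
  n <- length(alignment)
  phy$node.label <- rep(NA_integer_, phy$Nnode)
  if (n < 4) {
    warning("supports undefined with fewer than 4 taxa")
    return(phy)
  }
  mat <- do.call(rbind, strsplit(toupper(unlist(alignment)), "", fixed = TRUE))
  rownames(mat) <- names(alignment)
  L <- ncol(mat)
  counts <- stats::setNames(integer(0), character(0))
  orig_keys <- tree_bipartitions(phy)
  counts <- stats::setNames(integer(length(orig_keys)), orig_keys)
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_aln <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
      rep_keys <- tree_bipartitions(nj_build(dist_fun(rep_aln)))
      hit <- orig_keys %in% rep_keys
      counts[hit] <- counts[hit] + 1L
    }
  })
  support <- round(100 * counts / n_replicates)
  ekeys <- edge_bipartition_keys(phy)
  ntip <- length(phy$tip.label)
  for (e in seq_len(nrow(phy$edge))) {
    if (is.na(ekeys[e])) next
    node <- phy$edge[e, 2]
    phy$node.label[node - ntip] <- unname(support[ekeys[e]])
  }
  phy
}

#' Total branch length of a tree
#'
#' @param phy a `phylo` tree with branch lengths.
#' @return arithmetic sum of all branch lengths.
#' @export
tree_total_length <- function(phy) {
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  sum(phy$edge.length)
}
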