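#' Restore diploidy by random allele discard
#'
#' Aneuploid strains can carry three or four alleles at a locus; to make
#' strains comparable, supernumerary alleles are discarded uniformly at
#' random until two remain. Loci with at most two alleles are unchanged,
#' so the operation is idempotent.
#'
#' @param profiles long data.frame with columns `strain`, `locus`,
#'   `allele` (one row per allele copy).
#' @param seed integer seed or `NULL`.
#' @return profiles with at most two allele rows per strain-locus.
#' @export
diploidize <- function(profiles, seed = NULL) {
  with_seed(seed, {
    key <- paste(profiles$strain, profiles$locus, sep = "\r")
    keep <- unlist(lapply(split(seq_len(nrow(profiles)), key), function(idx) {
      if (length(idx) <= 2) idx else sort(sample(idx, 2))
    }), use.names = FALSE)
    out <- profiles[sort(keep), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Per-locus allele frequency profile of one strain
#'
#' Within-strain frequencies: a homozygote carries its allele at
#' frequency 1, a heterozygote 0.5/0.5.
#'
#' @param profiles long allele data.frame.
#' @param strain strain id.
#' @return named list locus -> named numeric vector of allele frequencies.
#' @export
strain_profile <- function(profiles, strain) {
  rows <- profiles[profiles$strain == strain, , drop = FALSE]
  if (!nrow(rows)) stop(sprintf("strain '%s' not found", strain))
  lapply(split(as.character(rows$allele), rows$locus), function(a) {
    tab <- table(a)
    stats::setNames(as.numeric(tab) / length(a), names(tab))
  })
}

#' Chord distance between two multilocus allele-frequency profiles
#'
#' Cavalli-Sforza--Edwards form: per shared locus l,
#' d_l^2 = 2 (1 - sum_a sqrt(x_la * y_la)); the distance is
#' sqrt(mean over shared loci of d_l^2). Averaging over the loci scored in
#' both strains makes strains with different locus coverage comparable
#' (loci missing in either strain are excluded), and bounds the distance
#' by sqrt(2), attained for disjoint allele sets at every shared locus.
#'
#' @param x,y strain profiles from [strain_profile()] (named lists of
#'   allele frequency vectors).
#' @return chord distance in `[0, sqrt(2)]`.
#' @export
chord_distance <- function(x, y) {
  shared <- intersect(names(x), names(y))
  if (!length(shared)) stop("no loci scored in both strains")
  d2 <- vapply(shared, function(l) {
    fx <- x[[l]]; fy <- y[[l]]
    alle <- union(names(fx), names(fy))
    s <- sum(sqrt(ifelse(alle %in% names(fx), fx[alle], 0) *
                    ifelse(alle %in% names(fy), fy[alle], 0)))
    max(0, 2 * (1 - s))
  }, numeric(1))
  sqrt(mean(d2))
}

#' Pairwise chord distance matrix of a strain set
#'
#' @param profiles long allele data.frame (diploidize first if aneuploid).
#' @return symmetric distance matrix over strains.
#' @export
chord_distance_matrix <- function(profiles) {
  strains <- unique(profiles$strain)
  sp <- lapply(strains, function(s) strain_profile(profiles, s))
  names(sp) <- strains
  n <- length(strains)
  D <- matrix(0, n, n, dimnames = list(strains, strains))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- chord_distance(sp[[i]], sp[[j]])
    }
  }
  D
}

#' Midpoint rooting
#'
#' Places the root halfway along the longest leaf-to-leaf path of an
#' unrooted weighted tree.
#'
#' @param phy a `phylo` tree with finite branch lengths (>= 2 leaves).
#' @return rooted `phylo` tree.
#' @export
midpoint_root <- function(phy) {
  if (is.null(phy$edge.length) || any(!is.finite(phy$edge.length))) {
    stop("finite branch lengths required")
  }
  n <- length(phy$tip.label)
  if (n < 2) stop("midpoint rooting needs at least 2 leaves")
  if (all(phy$edge.length == 0)) {
    warning("all branch lengths zero; returning the tree rooted as stored")
    return(phy)
  }
  if (n == 2) {
    half <- sum(phy$edge.length) / 2
    phy$edge.length <- rep(half, length(phy$edge.length))
    return(phy)
  }
  phangorn::midpoint(phy)
}

#' Fraction of strains grouping with their own population
#'
#' Tree-based label recovery: for each strain, the label of its nearest
#' neighbour by tree (cophenetic) distance is compared with its own; the
#' returned value is the fraction of strains whose nearest neighbour
#' shares their population label.
#'
#' @param phy a `phylo` tree whose tips are strains.
#' @param truth data.frame with columns `strain`, `population`.
#' @return fraction in `[0, 1]`.
#' @export
population_label_recovery <- function(phy, truth) {
  D <- ape::cophenetic.phylo(phy)
  labels <- stats::setNames(truth$population, truth$strain)
  hits <- vapply(rownames(D), function(s) {
    d <- D[s, setdiff(colnames(D), s)]
    nn <- names(d)[which.min(d)]
    labels[[nn]] == labels[[s]]
  }, logical(1))
  mean(hits)
}
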