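# fixtures built in code: random sequences, controlled mutants, chimeras,
# additive trees

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# substitute exactly round(rate * n) distinct sites, each to a different base
mutate_seq <- function(seq, rate, at = NULL) {
  x <- strsplit(seq, "")[[1]]
  sites <- if (is.null(at)) sample(length(x), round(rate * length(x))) else at
  for (i in sites) {
    x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
  }
  paste(x, collapse = "")
}

# two references diverged at `rate`, guaranteed to disagree at the two
# positions flanking `cut`, plus the chimera A[1..cut] + B[(cut+1)..n]
make_chimera <- function(n, cut, rate = 0.07) {
  refA <- rand_dna(n)
  refB <- mutate_seq(refA, rate)
  refB <- mutate_seq(refB, 0, at = c(cut, cut + 1))  # diagnostic sites at the junction
  ba <- strsplit(refA, "")[[1]]
  bb <- strsplit(refB, "")[[1]]
  # ensure the forced sites really differ from refA
  for (i in c(cut, cut + 1)) {
    if (bb[i] == ba[i]) bb[i] <- sample(setdiff(c("A", "C", "G", "T"), ba[i]), 1)
  }
  refB <- paste(bb, collapse = "")
  query <- paste0(substr(refA, 1, cut), substr(refB, cut + 1, n))
  list(refA = refA, refB = refB, query = query, cut = cut)
}

# random unrooted tree with strictly positive branch lengths and its
# additive (path-length) distance matrix
random_additive <- function(n_taxa) {
  phy <- ape::unroot(ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.05, 1)))
  D <- ape::cophenetic.phylo(phy)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = phy, D = D)
}

# an ORF of `n_codons` amino-acid codons plus a terminal stop, with no
# internal stop in frame, engineered so inserting T at `insert_at` creates
# an immediate in-frame stop (the two bases at insert_at are "AA")
make_orf <- function(n_codons, insert_at = NULL) {
  aa_codons <- setdiff(names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"],
                       character(0))
  codons <- c("ATG", sample(aa_codons, n_codons - 1, replace = TRUE), "TAA")
  orf <- paste(codons, collapse = "")
  if (!is.null(insert_at)) {
    # put "AA" at insert_at..insert_at+1 without creating an in-frame stop:
    # insert_at is the first base of a codon, "AAA" codes for Lys
    stopifnot((insert_at - 1) %% 3 == 0)
    substr(orf, insert_at, insert_at + 2) <- "AAA"
  }
  orf
}

insert_base <- function(seq, pos, base = "T") {
  paste0(substr(seq, 1, pos - 1), base, substr(seq, pos, nchar(seq)))
}

# spore columns of tetrad t in a simulated meiosis table
spore_cols <- function(t) paste(sprintf("T%03d", t), letters[1:4], sep = ".")
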