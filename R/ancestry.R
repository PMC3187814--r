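#' Identity thresholds for lineage classification of sequenced markers
#'
#' Defaults encode the field's working rules: markers with more than 99%
#' identity to the *S. cerevisiae* reference are called cerevisiae; over
#' 98% identity to the *S. uvarum* reference, uvarum; below that, the
#' lager-type band of identity to uvarum diagnostic of the third parental
#' lineage. Lager-type alleles are reported at 2--6% divergence from
#' uvarum, with printed identity tables calling 93--94%-identical
#' sequences "Lg", so the band floor defaults to 92%.
#'
#' @param cerevisiae_min minimum percent identity to the cerevisiae
#'   reference for a cerevisiae call.
#' @param uvarum_min minimum percent identity to the uvarum reference for
#'   a uvarum call.
#' @param lager_min lower bound of the lager band of identity to uvarum;
#'   the band is `[lager_min, uvarum_min)`.
#' @return a `classification_thresholds` list.
#' @export
classification_thresholds <- function(cerevisiae_min = 99, uvarum_min = 98,
                                      lager_min = 92) {
  stopifnot(cerevisiae_min > 0, cerevisiae_min <= 100,
            uvarum_min > 0, uvarum_min <= 100,
            lager_min < uvarum_min)
  structure(list(cerevisiae_min = cerevisiae_min, uvarum_min = uvarum_min,
                 lager_min = lager_min),
            class = "classification_thresholds")
}

ALIGN_MATCH <- 1
ALIGN_MISMATCH <- -1
ALIGN_GAP_OPEN <- 5
ALIGN_GAP_EXT <- 1

align_pair <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = ALIGN_MATCH,
                                                  mismatch = ALIGN_MISMATCH)
  Biostrings::pairwiseAlignment(Biostrings::DNAString(a), Biostrings::DNAString(b),
                                type = "global", substitutionMatrix = mat,
                                gapOpening = ALIGN_GAP_OPEN,
                                gapExtension = ALIGN_GAP_EXT)
}

#' Global-alignment percent nucleotide identity
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap open -5,
#' gap extend -1); identity = matching columns / all aligned columns, with
#' gap columns counted in the denominator as non-matches (a conservative,
#' reproducible convention).
#'
#' @param a,b non-empty nucleotide sequences (character strings).
#' @return list with `identity` (percent, full precision) and
#'   `aligned_length` (columns).
#' @export
percent_identity <- function(a, b) {
  if (!nchar(a) || !nchar(b)) stop("sequences must be non-empty")
  aln <- align_pair(a, b)
  p <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
  s <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
  matches <- sum(p == s & p != "-")
  list(identity = 100 * matches / length(p), aligned_length = length(p))
}

#' Classify a sequenced marker into a parental lineage
#'
#' Applies the identity thresholds in order (cerevisiae, uvarum, lager
#' band); markers fitting none are screened for a chimeric structure with
#' [detect_breakpoint()] and called chimeric when splitting the query
#' between the two references improves the summed identity by at least
#' `chimera_margin` percentage points over the best single assignment;
#' otherwise ambiguous. An empty query is reported absent.
#'
#' @param query marker sequence (possibly empty for an absent marker).
#' @param cerevisiae_ref,uvarum_ref non-empty reference sequences.
#' @param thresholds a [classification_thresholds()].
#' @param chimera_margin improvement (identity points) required to call a
#'   chimera.
#' @return a `marker_call` list: `lineage`, `identity_to_cerevisiae`,
#'   `identity_to_uvarum`, `aligned_length`, and the `breakpoint` call when
#'   chimeric.
#' @export
classify_marker <- function(query, cerevisiae_ref, uvarum_ref,
                            thresholds = classification_thresholds(),
                            chimera_margin = 2) {
  if (!nchar(cerevisiae_ref) || !nchar(uvarum_ref)) stop("references must be non-empty")
  if (is.null(query) || !nchar(query)) {
    return(structure(list(lineage = "absent",
                          identity_to_cerevisiae = NA_real_,
                          identity_to_uvarum = NA_real_,
                          aligned_length = NA_integer_, breakpoint = NULL),
                     class = "marker_call"))
  }
  idc <- percent_identity(query, cerevisiae_ref)
  idu <- percent_identity(query, uvarum_ref)
  call <- function(lineage, breakpoint = NULL) {
    structure(list(lineage = lineage,
                   identity_to_cerevisiae = idc$identity,
                   identity_to_uvarum = idu$identity,
                   aligned_length = max(idc$aligned_length, idu$aligned_length),
                   breakpoint = breakpoint),
              class = "marker_call")
  }
  if (idc$identity >= thresholds$cerevisiae_min) return(call("cerevisiae"))
  if (idu$identity >= thresholds$uvarum_min) return(call("uvarum"))
  if (idu$identity >= thresholds$lager_min && idu$identity < thresholds$uvarum_min) {
    return(call("lager"))
  }
  bp <- tryCatch(detect_breakpoint(query, cerevisiae_ref, uvarum_ref),
                 error = function(e) NULL)
  best_single <- max(idc$identity, idu$identity)
  if (!is.null(bp) && bp$combined_identity >= best_single + chimera_margin) {
    return(call("chimeric", breakpoint = bp))
  }
  call("ambiguous")
}

#' @export
print.marker_call <- function(x, ...) {
  cat(sprintf("marker call: %s (identity to cerevisiae %.1f%%, to uvarum %.1f%%)\n",
              x$lineage,
              x$identity_to_cerevisiae, x$identity_to_uvarum))
  if (!is.null(x$breakpoint)) {
    cat(sprintf("  breakpoint at query position %d (5' %d nt, 3' %d nt)\n",
                x$breakpoint$breakpoint, x$breakpoint$seg5_length,
                x$breakpoint$seg3_length))
  }
  invisible(x)
}

# per-query-position match indicator against a reference, from a global
# alignment; query positions deleted in the reference count as mismatches
query_match_profile <- function(query, ref) {
  aln <- align_pair(query, ref)
  p <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
  s <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
  m <- logical(nchar(query))
  qpos <- 0L
  for (i in seq_along(p)) {
    if (p[i] != "-") {
      qpos <- qpos + 1L
      m[qpos] <- p[i] == s[i]
    }
  }
  m
}

#' Locate the breakpoint of a chimeric gene
#'
#' Chooses the query position p maximizing matches of the 5' segment
#' `query[1..p]` to one reference plus matches of the 3' segment
#' `query[(p+1)..end]` to the other, evaluated over both reference
#' orderings; reports the better ordering with per-segment identities.
#' This is the operation that localizes junctions such as a gene whose 5'
#' part tracks one parental genome and whose 3' part is identical to the
#' other.
#'
#' @param query query sequence (>= 50 nt).
#' @param refA,refB the two candidate parental references.
#' @return a `chimera_call` list: `breakpoint` (= 5' segment length),
#'   `seg5_length`, `seg3_length`, `seg5_ref`/`seg3_ref` ("A"/"B"),
#'   per-segment identities to both references, and `combined_identity`
#'   (percent of query positions matching their assigned reference).
#' @export
detect_breakpoint <- function(query, refA, refB) {
  L <- nchar(query)
  if (L < 50) stop("query shorter than 50 nt: insufficient signal for breakpoint detection")
  mA <- query_match_profile(query, refA)
  mB <- query_match_profile(query, refB)
  cA <- c(0, cumsum(mA))
  cB <- c(0, cumsum(mB))
  # ordering 1: refA 5', refB 3'; ordering 2: the reverse. The junction is
  # identifiable only up to the diagnostic sites flanking it (positions
  # where the two references disagree), so the midpoint of the maximal
  # score plateau is reported.
  s1 <- cA + (cB[L + 1] - cB)
  s2 <- cB + (cA[L + 1] - cA)
  plateau_mid <- function(s) {
    at <- which(s == max(s)) - 1L
    at[ceiling(length(at) / 2)]
  }
  if (max(s1) >= max(s2)) {
    p <- plateau_mid(s1)
    ord <- c("A", "B")
    total <- max(s1)
  } else {
    p <- plateau_mid(s2)
    ord <- c("B", "A")
    total <- max(s2)
  }
  seg_id <- function(m, from, to) {
    if (to < from) return(NA_real_)
    100 * sum(m[from:to]) / (to - from + 1)
  }
  structure(list(
    breakpoint = p,
    seg5_length = p,
    seg3_length = L - p,
    seg5_ref = ord[1], seg3_ref = ord[2],
    seg5_identity_to_A = seg_id(mA, 1L, p),
    seg5_identity_to_B = seg_id(mB, 1L, p),
    seg3_identity_to_A = seg_id(mA, p + 1L, L),
    seg3_identity_to_B = seg_id(mB, p + 1L, L),
    combined_identity = 100 * total / L
  ), class = "chimera_call")
}

translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Fraction of substitutions that are synonymous between two coding sequences
#'
#' Compares two equal-length in-frame coding sequences site by site; a
#' differing site counts as synonymous when the two codons containing it
#' encode the same amino acid (standard code). The result is the
#' "neutral" substitution fraction used to argue common ancestry of
#' closely related alleles.
#'
#' @param coding_a,coding_b in-frame gapless sequences of equal length
#'   divisible by 3.
#' @return fraction in `[0, 1]`, or `NA` when the sequences are identical
#'   (no substitutions to classify).
#' @export
neutral_fraction <- function(coding_a, coding_b) {
  if (nchar(coding_a) != nchar(coding_b)) stop("sequences must have equal length")
  if (nchar(coding_a) %% 3 != 0) stop("length must be divisible by 3")
  if (grepl("-", coding_a, fixed = TRUE) || grepl("-", coding_b, fixed = TRUE)) {
    stop("gapless sequences required")
  }
  a <- seq_chars(toupper(coding_a))
  b <- seq_chars(toupper(coding_b))
  diff <- which(a != b)
  if (!length(diff)) return(NA_real_)
  codon_idx <- (diff - 1L) %/% 3L
  codA <- vapply(codon_idx, function(k) chars_seq(a[(3 * k + 1):(3 * k + 3)]), character(1))
  codB <- vapply(codon_idx, function(k) chars_seq(b[(3 * k + 1):(3 * k + 3)]), character(1))
  syn <- translate_codons(codA) == translate_codons(codB)
  sum(syn) / length(diff)
}

#' Predict frameshift truncation of an open reading frame
#'
#' Translates frame 1 under the standard code until the first stop codon.
#' The canonical use is deciding whether a single-base insertion (such as
#' a T inserted mid-gene) has created a premature stop and a truncated
#' protein.
#'
#' @param orf nucleotide sequence starting with ATG, length >= 6; a
#'   trailing partial codon is ignored.
#' @return list with `protein_length_aa` (codons before the first stop),
#'   `premature` (stop before the final codon) and `no_stop` (no stop
#'   found; full-length translation reported).
#' @export
predict_truncation <- function(orf) {
  orf <- toupper(orf)
  if (nchar(orf) < 6) stop("ORF must be at least 6 nt")
  if (substr(orf, 1, 3) != "ATG") stop("ORF must start with ATG")
  n_codons <- nchar(orf) %/% 3
  codons <- substring(orf, 3 * seq_len(n_codons) - 2, 3 * seq_len(n_codons))
  aa <- translate_codons(codons)
  stop_at <- which(aa == "*")
  if (!length(stop_at)) {
    return(list(protein_length_aa = n_codons, premature = FALSE, no_stop = TRUE))
  }
  first <- stop_at[1]
  list(protein_length_aa = first - 1L,
       premature = first < n_codons,
       no_stop = FALSE)
}
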