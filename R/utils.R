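#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state, so seeded simulators never perturb the caller's
#' random stream. With `seed = NULL` the expression runs on the current
#' stream unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer")
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

# split a sequence string into a character vector of bases
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

chars_seq <- function(x) paste(x, collapse = "")

DNA_BASES <- c("A", "C", "G", "T")

# transition partner of each base (A<->G, C<->T)
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

#' Draw substituted bases with a transition:transversion bias
#'
#' @param bases character vector of current bases (ACGT).
#' @param ts_tv transition:transversion ratio; a substitution is a
#'   transition with probability `ts_tv / (ts_tv + 1)`.
#' @return character vector of new bases, each differing from the input.
#' @keywords internal
mutate_bases <- function(bases, ts_tv = 2) {
  n <- length(bases)
  if (n == 0L) return(character(0))
  is_ts <- stats::runif(n) < ts_tv / (ts_tv + 1)
  out <- character(n)
  out[is_ts] <- TRANSITION[bases[is_ts]]
  if (any(!is_ts)) {
    tv <- which(!is_ts)
    # two transversion partners per base, chosen uniformly
    for (i in tv) {
      alt <- setdiff(DNA_BASES, c(bases[i], TRANSITION[[bases[i]]]))
      out[i] <- alt[sample.int(2L, 1L)]
    }
  }
  out
}

round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}
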