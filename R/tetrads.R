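#' Spore viability of dissected asci
#'
#' @param n_asci number of dissected asci (> 0).
#' @param n_germinated number of spores that germinated.
#' @param spores_per_ascus spores per ascus (default 4).
#' @return percent viability, rounded half-up to an integer (so 36
#'   germinated spores from 13 four-spore asci give 69).
#' @export
viability <- function(n_asci, n_germinated, spores_per_ascus = 4) {
  if (n_asci == 0) stop("n_asci must be > 0")
  total <- n_asci * spores_per_ascus
  if (n_germinated < 0 || n_germinated > total) {
    stop("n_germinated must lie in [0, n_asci * spores_per_ascus]")
  }
  as.integer(round_half_up(100 * n_germinated / total))
}

#' Cell-value vocabulary of printed tetrad tables
#'
#' Printed marker tables mix "+"/"-" presence calls, allele labels
#' (contig names, allele types such as UVA/LG/CARB/UVAR, locus genotypes),
#' "ND" for not determined, and phenotype qualifiers such as "delay".
#' This dictionary normalizes a raw cell to `present`, `absent` or
#' `missing`; any unmapped non-empty value is treated as an allele label,
#' i.e. `present`.
#'
#' @return named character vector mapping raw cell values to classes.
#' @export
cell_vocabulary <- function() {
  stats::setNames(
    c("present", "absent", "absent", "missing", "missing", "missing"),
    c("+", "-", "−", "ND", "", "NA"))
}

normalize_cells <- function(values, vocabulary = cell_vocabulary(), positive = NULL) {
  values <- trimws(as.character(values))
  out <- ifelse(values %in% names(vocabulary), vocabulary[values], "present")
  if (!is.null(positive)) {
    out <- ifelse(out == "missing", "missing",
                  ifelse(values == positive, "present", "absent"))
  }
  unname(out)
}

#' Segregation ratio class of one marker in one tetrad
#'
#' @param marker_values the four spore values (raw cells or
#'   present/absent/missing).
#' @param positive optional allele label to score as "present" for
#'   allele-typed rows (e.g. score the lager allele of a two-allele
#'   marker).
#' @return one of "4:0", "3:1", "2:2", "1:3", "0:4", or "incomplete" when
#'   any spore is missing.
#' @export
segregation_ratio <- function(marker_values, positive = NULL) {
  v <- normalize_cells(marker_values, positive = positive)
  if (all(v == "missing")) stop("all spore values missing")
  if (any(v == "missing")) return("incomplete")
  if (length(v) != 4) stop("a tetrad has 4 spores")
  paste0(sum(v == "present"), ":", sum(v == "absent"))
}

#' Ditype class of a marker pair in one tetrad
#'
#' Defined only when both markers segregate 2:2: parental ditype (PD) when
#' the two spore partitions coincide, nonparental ditype (NPD) when they
#' are exactly complementary, tetratype (TT) otherwise.
#'
#' @param x,y four spore values per marker.
#' @param positive_x,positive_y optional allele labels scored as present.
#' @return "PD", "NPD", "TT" or "unscorable".
#' @export
classify_ditype <- function(x, y, positive_x = NULL, positive_y = NULL) {
  vx <- normalize_cells(x, positive = positive_x)
  vy <- normalize_cells(y, positive = positive_y)
  if (any(vx == "missing") || any(vy == "missing")) return("unscorable")
  px <- vx == "present"
  py <- vy == "present"
  if (sum(px) != 2 || sum(py) != 2) return("unscorable")
  if (all(px == py)) return("PD")
  if (all(px == !py)) return("NPD")
  "TT"
}

#' Test independent assortment from ditype classes
#'
#' Under independence, parental and nonparental ditypes are equally
#' frequent among PD+NPD tetrads; linkage inflates PD. The test is the
#' two-sided exact binomial on the PD count among PD+NPD.
#'
#' @param classes character vector of ditype classes across tetrads
#'   ("PD"/"NPD"/"TT"; other values ignored).
#' @return list with `PD`, `NPD`, `TT` counts and `p_value` (NA when
#'   PD+NPD = 0).
#' @export
assortment_test <- function(classes) {
  pd <- sum(classes == "PD")
  npd <- sum(classes == "NPD")
  tt <- sum(classes == "TT")
  p <- if (pd + npd > 0) stats::binom.test(pd, pd + npd, 0.5)$p.value else NA_real_
  list(PD = pd, NPD = npd, TT = tt, p_value = p)
}

#' Parse a printed-style tetrad marker table (TSV)
#'
#' Layout: first column marker name, second the scoring methodology, then
#' one column per strain or spore; `#`-prefixed lines are comments.
#'
#' @param path TSV file path.
#' @return a `tetrad_table` list: `values` (marker x strain character
#'   matrix), `methodology` (per-marker), `strains`.
#' @export
parse_marker_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- length(fields[[1]])
  if (n_col < 3) stop("marker table needs marker, methodology and at least one strain column")
  bad <- which(vapply(fields, length, integer(1)) != n_col)
  if (length(bad)) {
    stop(sprintf("ragged row at line %d: expected %d fields, found %d",
                 bad[1], n_col, length(fields[[bad[1]]])))
  }
  header <- fields[[1]]
  body <- fields[-1]
  markers <- vapply(body, `[[`, character(1), 1)
  if (anyDuplicated(markers)) stop("duplicate marker names")
  methodology <- vapply(body, `[[`, character(1), 2)
  values <- t(vapply(body, function(f) f[-(1:2)], character(n_col - 2)))
  dimnames(values) <- list(markers, header[-(1:2)])
  structure(list(values = values, methodology = stats::setNames(methodology, markers),
                 strains = header[-(1:2)]),
            class = "tetrad_table")
}

#' @export
print.tetrad_table <- function(x, ...) {
  cat(sprintf("tetrad marker table: %d markers x %d strains\n",
              nrow(x$values), length(x$strains)))
  print(utils::head(x$values, 8))
  invisible(x)
}

#' Columns of one tetrad's four spores
#'
#' @param table a `tetrad_table`.
#' @param tetrad tetrad name prefix; spore columns are `<tetrad><a-d>` or
#'   `<tetrad>.<a-d>`.
#' @return the four matching column names, ordered a--d.
#' @export
tetrad_spores <- function(table, tetrad) {
  cand <- c(paste0(tetrad, letters[1:4]), paste0(tetrad, ".", letters[1:4]))
  hit <- cand[cand %in% table$strains]
  if (length(hit) != 4) stop(sprintf("tetrad '%s' does not have 4 spore columns", tetrad))
  hit
}

#' Infer per-spore contig content from mapped marker rows
#'
#' A contig is called present in a spore iff all of its mapped marker rows
#' are positive for that spore; rows disagreeing within one contig are
#' flagged as conflicts.
#'
#' @param table a `tetrad_table`.
#' @param contig_map named list mapping contig name -> marker row names.
#' @param strains columns to evaluate (default all).
#' @return named list strain -> character vector of contigs present, with
#'   a `conflicts` attribute (data.frame strain/contig) for disagreeing
#'   rows.
#' @export
infer_contig_content <- function(table,
                                 contig_map = list(cA = "Contig cA",
                                                   cB = "Contig cB",
                                                   cC = "Contig cC"),
                                 strains = NULL) {
  if (is.null(strains)) strains <- table$strains
  conflicts <- data.frame(strain = character(0), contig = character(0))
  out <- lapply(strains, function(s) {
    present <- character(0)
    for (contig in names(contig_map)) {
      rows <- contig_map[[contig]]
      if (!all(rows %in% rownames(table$values))) {
        stop(sprintf("contig '%s' maps to unknown marker rows", contig))
      }
      v <- normalize_cells(table$values[rows, s])
      if (all(v == "present")) {
        present <- c(present, contig)
      } else if (any(v == "present")) {
        conflicts <<- rbind(conflicts, data.frame(strain = s, contig = contig))
      }
    }
    present
  })
  names(out) <- strains
  attr(out, "conflicts") <- conflicts
  out
}
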