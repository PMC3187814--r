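#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of sequences; duplicate ids are an
#'   error.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate FASTA id '%s'", ids[duplicated(ids)][1]))
  }
  stats::setNames(as.character(set), ids)
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector or named list of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a probe intensity/design table (TSV)
#'
#' Expected columns: `probe_id`, `chrom`, `start`, `end`, and optionally
#' `intensity`; coordinates 1-based inclusive.
#'
#' @param path TSV file.
#' @return validated probe data.frame sorted by (chrom, start).
#' @export
read_probe_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stop("probe table must have columns probe_id, chrom, start, end")
  }
  if (anyDuplicated(df$probe_id)) stop("duplicate probe_id")
  bad <- which(df$start > df$end)
  if (length(bad)) stop(sprintf("start > end at row %d", bad[1]))
  if (!is.null(df$intensity)) {
    bad <- which(df$intensity < 0)
    if (length(bad)) stop(sprintf("negative intensity at row %d", bad[1]))
  }
  sort_track(df)
}

#' Write a probe table to TSV
#' @param df probe data.frame.
#' @param path output file.
#' @export
write_probe_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write detected regions as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open,
#' so starts are decremented by one and ends kept. This is the single
#' conversion site in the package.
#'
#' @param regions region data.frame (`chrom`, `start`, `end`, optionally
#'   `mean_log_ratio`).
#' @param path output BED file.
#' @export
write_bed <- function(regions, path) {
  bed <- data.frame(
    chrom = regions$chrom,
    start = regions$start - 1L,
    end = regions$end,
    name = sprintf("region_%d", seq_len(max(1, nrow(regions)))[seq_len(nrow(regions))]),
    score = if (!is.null(regions$mean_log_ratio)) {
      round(regions$mean_log_ratio, 4)
    } else 0,
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a tree to Newick (supports as internal node labels)
#' @param phy a `phylo` tree.
#' @param path output file.
#' @export
write_newick <- function(phy, path) {
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Newick file.
#' @return a `phylo` tree.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Write a ground-truth record as JSON
#' @param truth list or data.frame.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
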