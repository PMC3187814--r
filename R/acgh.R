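#' Scan configuration for comparative-hybridization introgression detection
#'
#' @param window_probes odd sliding-window width in probes (default 11,
#'   roughly one gene at typical probe density).
#' @param gap_merge_bp regions on one chromosome separated by less than
#'   this genomic gap are considered contiguous (default 1000 bp; sub-kb
#'   gaps are read as false-negative hybridization).
#' @param min_region_bp size cutoff used when summarizing ("regions larger
#'   than" this, default 1000 bp).
#' @param threshold_k a probe is elevated when its smoothed log-ratio
#'   exceeds the track median by `threshold_k` robust standard deviations.
#' @param zones number of genomic zones for background estimation.
#' @param log_base base of the hybridization log-ratio.
#' @return a `scan_config` list.
#' @export
scan_config <- function(window_probes = 11, gap_merge_bp = 1000,
                        min_region_bp = 1000, threshold_k = 3,
                        zones = 16, log_base = 2) {
  if (window_probes < 1 || window_probes %% 2 == 0) {
    stop("window_probes must be odd and >= 1")
  }
  if (gap_merge_bp < 0 || min_region_bp < 0) stop("gap and size cutoffs must be >= 0")
  structure(list(window_probes = as.integer(window_probes),
                 gap_merge_bp = gap_merge_bp, min_region_bp = min_region_bp,
                 threshold_k = threshold_k, zones = as.integer(zones),
                 log_base = log_base),
            class = "scan_config")
}

# order a probe/track data.frame by (chrom, start)
sort_track <- function(track) track[order(track$chrom, track$start), , drop = FALSE]

track_values <- function(track) {
  if (!is.null(track$value)) track$value else track$intensity
}

#' Zoned background subtraction
#'
#' The ordered probe track is divided into `zones` contiguous genomic
#' zones; each zone's background is the mean of its lowest 2% of
#' intensities, and every probe subtracts a distance-weighted combination
#' of the zone backgrounds (weights 1/(d^2+1) in zone units), floored at a
#' small positive value. This is a deliberately simple stand-in for
#' chip-style zoned background correction: it removes additive offsets and
#' slow background gradients provided each zone contains some
#' background-level probes.
#'
#' @param track probe data.frame with an `intensity` column, sorted by
#'   (chrom, start).
#' @param config a [scan_config()].
#' @return the track with background-corrected intensities.
#' @export
subtract_background <- function(track, config = scan_config()) {
  track <- sort_track(track)
  x <- track$intensity
  n <- length(x)
  zones <- config$zones
  if (n < zones) {
    warning("fewer probes than zones; using a single background zone")
    zones <- 1L
  }
  zone_of <- ceiling(seq_len(n) / n * zones)
  zone_bg <- vapply(seq_len(zones), function(z) {
    v <- sort(x[zone_of == z])
    mean(v[seq_len(max(1L, ceiling(0.02 * length(v))))])
  }, numeric(1))
  zone_center <- vapply(seq_len(zones), function(z) mean(which(zone_of == z)), numeric(1))
  zone_width <- n / zones
  bg <- vapply(seq_len(n), function(i) {
    d <- (i - zone_center) / zone_width
    w <- 1 / (d^2 + 1)
    w[abs(d) > 2.5] <- 0  # local weighting: only nearby zones inform a probe
    sum(w * zone_bg) / sum(w)
  }, numeric(1))
  # floor at a few percent of the typical intensity: keeps downstream
  # ratios finite and stops background-level probes from exploding the
  # log-ratio spread
  floor_val <- max(0.05 * stats::median(x), .Machine$double.eps)
  track$intensity <- pmax(x - bg, floor_val)
  track
}

#' Normalize a replicate pair by fitted slope
#'
#' The slope between the two hybridization signals is a least-squares
#' regression through the origin of the second replicate on the first; the
#' second replicate is divided by it so the pair can be averaged.
#'
#' @param rep1,rep2 probe data.frames over the same probes in the same
#'   order.
#' @return list with `track` (rescaled rep2) and `slope`.
#' @export
normalize_pair <- function(rep1, rep2) {
  check_matched_probes(rep1, rep2)
  v1 <- rep1$intensity
  v2 <- rep2$intensity
  if (all(v1 == 0)) stop("slope undefined: first replicate is all zeros")
  slope <- sum(v1 * v2) / sum(v1^2)
  rep2$intensity <- v2 / slope
  list(track = rep2, slope = slope)
}

check_matched_probes <- function(a, b) {
  if (nrow(a) != nrow(b) || any(a$probe_id != b$probe_id)) {
    bad <- if (nrow(a) != nrow(b)) "(different probe counts)" else {
      i <- which(a$probe_id != b$probe_id)[1]
      sprintf("(first mismatch at row %d: %s vs %s)", i, a$probe_id[i], b$probe_id[i])
    }
    stop("probe sets do not match ", bad)
  }
  invisible(TRUE)
}

#' Per-probe hybridization log-ratios
#'
#' @param test,reference matched probe data.frames with strictly positive
#'   intensities (after background flooring).
#' @param config a [scan_config()]; sets the log base (default 2).
#' @return the probe table with a `value` column of log-ratios.
#' @export
compute_log_ratios <- function(test, reference, config = scan_config()) {
  check_matched_probes(test, reference)
  if (any(test$intensity <= 0) || any(reference$intensity <= 0)) {
    stop("intensities must be strictly positive to form log-ratios")
  }
  out <- test[, c("probe_id", "chrom", "start", "end")]
  if (!is.null(test$repeat_group)) out$repeat_group <- test$repeat_group
  out$value <- log(test$intensity / reference$intensity, base = config$log_base)
  out
}

#' Sliding-window smoothing of a log-ratio track
#'
#' Centered moving average over `w` probes applied per chromosome, with
#' the window truncated at chromosome ends; output length equals input
#' length.
#'
#' @param track log-ratio track (with a `value` column).
#' @param w odd window width in probes.
#' @return smoothed track.
#' @export
smooth_track <- function(track, w = 11) {
  if (w %% 2 == 0) stop("window width must be odd")
  if (w == 1) return(track)
  track <- sort_track(track)
  half <- (w - 1) / 2
  for (chrom in unique(track$chrom)) {
    idx <- which(track$chrom == chrom)
    x <- track$value[idx]
    n <- length(x)
    cs <- c(0, cumsum(x))
    i <- seq_len(n)
    lo <- pmax(1, i - half)
    hi <- pmin(n, i + half)
    track$value[idx] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  track
}

#' Detect regions with hybridization signal stronger than the background
#'
#' The track background is its median and the spread its median absolute
#' deviation (scaled to a standard deviation); probes whose value exceeds
#' median + `threshold_k` * spread are elevated, and maximal runs of at
#' least two consecutive elevated probes become candidate regions spanning
#' the first to the last probe. Candidates on the same chromosome separated
#' by less than `gap_merge_bp` of genomic gap are merged. If the probe
#' table carries a `repeat_group` column (telomeric repeats present at many
#' chromosome ends), regions made of one repeat group inherit the label so
#' that downstream summaries count each repeated element once.
#'
#' @param track log-ratio track (typically smoothed).
#' @param config a [scan_config()].
#' @return data.frame of disjoint sorted regions: `chrom`, `start`, `end`,
#'   `n_probes`, `mean_log_ratio`, `length`, `repeat_group`.
#' @export
detect_regions <- function(track, config = scan_config()) {
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      n_probes = integer(0), mean_log_ratio = numeric(0),
                      length = integer(0), repeat_group = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(track)) return(empty)
  track <- sort_track(track)
  v <- track$value
  bg <- stats::median(v)
  spread <- stats::mad(v)
  elevated <- v > bg + config$threshold_k * spread
  out <- list()
  for (chrom in unique(track$chrom)) {
    idx <- which(track$chrom == chrom)
    e <- elevated[idx]
    r <- rle(e)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values & r$lengths >= 2)
    for (k in keep) {
      rows <- idx[starts[k]:ends[k]]
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom,
        start = track$start[rows[1]],
        end = track$end[rows[length(rows)]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  regions <- do.call(rbind, out)
  regions <- merge_regions(regions, config$gap_merge_bp)
  annotate_regions(regions, track)
}

#' Merge regions separated by sub-threshold genomic gaps
#'
#' Gap is measured between genomic coordinates: the number of bases between
#' the end of one region and the start of the next on the same chromosome.
#' Merging is idempotent.
#'
#' @param regions region data.frame (`chrom`, `start`, `end`).
#' @param gap_merge_bp merge when the gap is strictly less than this.
#' @return merged, sorted region data.frame.
#' @export
merge_regions <- function(regions, gap_merge_bp = 1000) {
  if (nrow(regions) < 2) return(regions)
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  keep <- regions[1, c("chrom", "start", "end"), drop = FALSE]
  for (i in 2:nrow(regions)) {
    last <- nrow(keep)
    gap <- regions$start[i] - keep$end[last] - 1
    if (regions$chrom[i] == keep$chrom[last] && gap < gap_merge_bp) {
      keep$end[last] <- max(keep$end[last], regions$end[i])
    } else {
      keep <- rbind(keep, regions[i, c("chrom", "start", "end")])
    }
  }
  rownames(keep) <- NULL
  keep
}

annotate_regions <- function(regions, track) {
  regions$n_probes <- NA_integer_
  regions$mean_log_ratio <- NA_real_
  regions$repeat_group <- NA_character_
  for (i in seq_len(nrow(regions))) {
    inside <- track$chrom == regions$chrom[i] &
      track$start >= regions$start[i] & track$end <= regions$end[i]
    regions$n_probes[i] <- sum(inside)
    regions$mean_log_ratio[i] <- mean(track$value[inside])
    if (!is.null(track$repeat_group)) {
      g <- unique(track$repeat_group[inside])
      g <- g[!is.na(g)]
      if (length(g) == 1 && all(!is.na(track$repeat_group[inside]))) {
        regions$repeat_group[i] <- as.character(g)
      }
    }
  }
  regions$length <- regions$end - regions$start + 1L
  regions
}

#' Count and total length of regions above a size cutoff
#'
#' Regions sharing a `repeat_group` label (telomeric repeats detected at
#' several chromosome ends) are counted once: only the first occurrence
#' contributes to the count and the total.
#'
#' @param regions region data.frame from [detect_regions()].
#' @param min_region_bp regions strictly larger than this are counted.
#' @return list with `n` (count) and `total_kb` (summed length in kb,
#'   one decimal).
#' @export
summarize_regions <- function(regions, min_region_bp = 1000) {
  if (!nrow(regions)) return(list(n = 0L, total_kb = 0))
  if (!is.null(regions$repeat_group)) {
    dup <- !is.na(regions$repeat_group) & duplicated(regions$repeat_group)
    regions <- regions[!dup, , drop = FALSE]
  }
  if (is.null(regions$length)) regions$length <- regions$end - regions$start + 1L
  big <- regions[regions$length > min_region_bp, , drop = FALSE]
  list(n = nrow(big), total_kb = round(sum(big$length) / 1000, 1))
}

#' Full comparative-hybridization scan from replicate intensities
#'
#' Convenience wrapper running the stage chain: zoned background
#' subtraction on every replicate, slope normalization and averaging
#' within each condition, per-probe log-ratios, sliding-window smoothing,
#' and region detection.
#'
#' @param test_reps,ref_reps lists of replicate probe data.frames for the
#'   test and reference hybridizations.
#' Segmentation runs on the raw per-probe log-ratios so that region
#' boundaries stay probe-accurate; the smoothed track (for plots, where
#' the window corresponds approximately to one gene) is returned
#' alongside.
#'
#' @param config a [scan_config()].
#' @return list with `regions`, `track` (raw log-ratios), `smoothed`
#'   (window-averaged log-ratios) and `summary` from
#'   [summarize_regions()].
#' @export
acgh_scan <- function(test_reps, ref_reps, config = scan_config()) {
  prep <- function(reps) {
    reps <- lapply(reps, subtract_background, config = config)
    if (length(reps) == 1) return(reps[[1]])
    base <- reps[[1]]
    acc <- base$intensity
    for (i in 2:length(reps)) {
      acc <- acc + normalize_pair(base, reps[[i]])$track$intensity
    }
    base$intensity <- acc / length(reps)
    base
  }
  test <- prep(test_reps)
  ref <- prep(ref_reps)
  lr <- compute_log_ratios(test, ref, config)
  sm <- smooth_track(lr, config$window_probes)
  regions <- detect_regions(lr, config)
  list(regions = regions, track = lr, smoothed = sm,
       summary = summarize_regions(regions, config$min_region_bp))
}
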