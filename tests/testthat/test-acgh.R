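flat_track <- function(n = 320, level = 100, chrom = "chrA", spacing = 250) {
  data.frame(probe_id = sprintf("p%04d", 1:n), chrom = chrom,
             start = seq(1L, by = spacing, length.out = n),
             end = seq(1L, by = spacing, length.out = n) + 59L,
             intensity = level, stringsAsFactors = FALSE)
}

test_that("an additive offset is removed when background-only probes are present", {
  set.seed(1)
  tr <- flat_track(level = 100)
  bg_probes <- seq(1, 320, by = 10)          # 10% background-only probes
  tr$intensity[bg_probes] <- 0
  offset <- 50
  tr$intensity <- tr$intensity + offset
  out <- subtract_background(tr)
  # oracle: signal probes recover their pre-offset level within 1%
  sig <- setdiff(seq_len(320), bg_probes)
  expect_true(all(abs(out$intensity[sig] - 100) / 100 < 0.01))
})

test_that("with no background component the track passes through (floor aside)", {
  tr <- flat_track(level = 100)
  tr$intensity[seq(1, 320, by = 10)] <- 0    # zero background anchors
  out <- subtract_background(tr)
  sig <- tr$intensity > 0
  expect_true(all(abs(out$intensity[sig] - tr$intensity[sig]) / 100 < 0.01))
})

test_that("a linear background gradient is mostly removed", {
  tr <- flat_track(n = 400)
  amplitude <- 60
  tr$intensity <- seq(20, 20 + amplitude, length.out = 400)  # background only
  out <- subtract_background(tr)
  floor_val <- 0.05 * median(tr$intensity)
  residual <- out$intensity - floor_val
  expect_lt(max(residual), 0.1 * amplitude)
})

test_that("fewer probes than zones falls back to a single zone with a warning", {
  tr <- flat_track(n = 8)
  expect_warning(subtract_background(tr), "single")
})

test_that("slope normalization recovers pure scaling exactly", {
  tr <- flat_track()
  tr$intensity <- runif(320, 50, 150)
  r2 <- tr
  r2$intensity <- 2 * tr$intensity
  res <- normalize_pair(tr, r2)
  expect_equal(res$slope, 2)
  expect_equal(res$track$intensity, tr$intensity)
  # identity pair
  res1 <- normalize_pair(tr, tr)
  expect_equal(res1$slope, 1)
})

test_that("slope normalization recovers a known factor under noise", {
  set.seed(42)
  tr <- flat_track()
  tr$intensity <- runif(320, 50, 150)
  r2 <- tr
  r2$intensity <- 1.7 * tr$intensity + rnorm(320, 0, 0.05 * mean(tr$intensity))
  res <- normalize_pair(tr, r2)
  expect_gt(res$slope, 1.65)
  expect_lt(res$slope, 1.75)
})

test_that("all-zero first replicate makes the slope undefined", {
  tr <- flat_track(level = 0)
  expect_error(normalize_pair(tr, tr), "undefined")
})

test_that("log-ratios are zero for self and one for doubling", {
  tr <- flat_track()
  tr$intensity <- runif(320, 50, 150)
  expect_true(all(compute_log_ratios(tr, tr)$value == 0))
  dbl <- tr; dbl$intensity <- 2 * tr$intensity
  expect_true(all(compute_log_ratios(dbl, tr)$value == 1))
})

test_that("mismatched probe sets are reported with the first offender", {
  a <- flat_track(n = 10)
  b <- a; b$probe_id[4] <- "odd"
  expect_error(compute_log_ratios(a, b), "odd")
})

test_that("smoothing preserves constants, w=1 is the identity, impulse response is 1/w", {
  tr <- flat_track(n = 41)
  tr$value <- 5
  expect_equal(smooth_track(tr, 11)$value, rep(5, 41))
  tr$value <- rnorm(41)
  expect_equal(smooth_track(tr, 1)$value, tr$value)
  tr$value <- 0
  tr$value[21] <- 1                       # interior unit spike
  sm <- smooth_track(tr, 11)
  expect_equal(max(sm$value), 1 / 11)
  expect_error(smooth_track(tr, 4), "odd")
})

test_that("a flat noiseless track yields no regions", {
  tr <- flat_track()
  tr$value <- 0
  expect_equal(nrow(detect_regions(tr)), 0)
})

test_that("sub-kilobase gaps merge regions and kilobase-plus gaps do not", {
  base <- function(gap_bp) {
    n <- 120
    starts <- seq(1L, by = 100L, length.out = n)
    tr <- data.frame(probe_id = sprintf("p%03d", 1:n), chrom = "chrA",
                     start = starts, end = starts + 59L,
                     value = rnorm(n, 0, 0.05), stringsAsFactors = FALSE)
    run1 <- 41:48
    tr$value[run1] <- 3
    # place the second run so that the genomic gap is exactly gap_bp
    gap_start_probe <- 48 + ceiling((gap_bp + 60) / 100)
    run2 <- gap_start_probe:(gap_start_probe + 7)
    tr$value[run2] <- 3
    tr
  }
  set.seed(7)
  merged <- detect_regions(base(800))
  expect_equal(nrow(merged), 1)
  set.seed(7)
  split <- detect_regions(base(1200))
  expect_equal(nrow(split), 2)
})

test_that("a simulated block is recovered with probe-level boundary accuracy", {
  p <- simulate_parents(20, chrom_lengths = c(chrA = 50000))
  iv <- data.frame(chrom = "chrA", start = 22000L, end = 26999L)
  mo <- implant_introgressions(p$uvarum, p$cerevisiae, iv)
  probes <- make_probe_design(p$cerevisiae)
  tr <- simulate_array(probes, mo$genome, p$cerevisiae, noise_sd = 0.1,
                       n_replicates = 2, seed = 31)
  rr <- simulate_array(probes, p$uvarum, p$cerevisiae, noise_sd = 0.1,
                       n_replicates = 2, seed = 32)
  sc <- acgh_scan(tr, rr)
  big <- sc$regions[sc$regions$length > 1000, ]
  expect_equal(nrow(big), 1)
  spacing <- 250
  expect_lte(abs(big$start - iv$start), spacing)
  expect_lte(abs(big$end - iv$end), spacing)
})

test_that("gap merging is idempotent", {
  set.seed(5)
  regions <- data.frame(
    chrom = sample(c("c1", "c2"), 12, replace = TRUE),
    start = sample.int(100000, 12))
  regions$end <- regions$start + sample.int(3000, 12)
  m1 <- merge_regions(regions, 1000)
  m2 <- merge_regions(m1, 1000)
  expect_equal(m1, m2)
})

test_that("regions are disjoint, sorted, and contain at least two probes", {
  set.seed(9)
  n <- 300
  starts <- seq(1L, by = 200L, length.out = n)
  tr <- data.frame(probe_id = sprintf("p%03d", 1:n), chrom = "chrA",
                   start = starts, end = starts + 59L,
                   value = rnorm(n, 0, 0.1), stringsAsFactors = FALSE)
  tr$value[c(50:55, 120:121, 200:210)] <- 4
  regs <- detect_regions(tr)
  expect_true(all(regs$n_probes >= 2))
  expect_true(all(diff(regs$start) > 0))
  if (nrow(regs) > 1) {
    expect_true(all(regs$start[-1] > regs$end[-nrow(regs)]))
  }
})

test_that("rescaling both channels leaves log-ratios and regions unchanged", {
  p <- simulate_parents(22, chrom_lengths = c(chrA = 40000))
  iv <- data.frame(chrom = "chrA", start = 15001L, end = 20000L)
  mo <- implant_introgressions(p$uvarum, p$cerevisiae, iv)
  probes <- make_probe_design(p$cerevisiae)
  tr <- simulate_array(probes, mo$genome, p$cerevisiae, noise_sd = 0.1,
                       n_replicates = 2, seed = 41)
  rr <- simulate_array(probes, p$uvarum, p$cerevisiae, noise_sd = 0.1,
                       n_replicates = 2, seed = 42)
  sc1 <- acgh_scan(tr, rr)
  scale_by <- function(reps, k) lapply(reps, function(x) { x$intensity <- k * x$intensity; x })
  sc2 <- acgh_scan(scale_by(tr, 3.7), scale_by(rr, 3.7))
  expect_equal(sc1$track$value, sc2$track$value)
  expect_equal(sc1$regions, sc2$regions)
})

test_that("telomeric repeat regions are counted once in summaries", {
  regions <- data.frame(chrom = c("c1", "c2", "c3"),
                        start = c(1000L, 2000L, 5000L),
                        end = c(4000L, 5000L, 7000L),
                        length = c(3001L, 3001L, 2001L),
                        repeat_group = c("Yprime", "Yprime", NA))
  s <- summarize_regions(regions, 1000)
  expect_equal(s$n, 2)
  expect_equal(s$total_kb, 5.0)
})

test_that("region summaries count and total lengths above the cutoff", {
  expect_equal(summarize_regions(data.frame(chrom = character(0),
                                            start = integer(0), end = integer(0))),
               list(n = 0L, total_kb = 0))
  regions <- data.frame(chrom = "c1", start = c(1L, 10001L),
                        end = c(2000L, 13500L))
  s <- summarize_regions(regions, 1000)
  expect_equal(s$n, 2)
  expect_equal(s$total_kb, 5.5)
})
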