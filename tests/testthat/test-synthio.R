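test_that("zero divergence yields byte-identical uvarum and lager genomes", {
  p <- simulate_parents(1, chrom_lengths = c(chrA = 2000), divergence_uv_lg = 0)
  expect_identical(p$uvarum, p$lager)
})

test_that("realized uvarum/lager identity tracks the requested divergence", {
  p <- simulate_parents(11, chrom_lengths = c(chrA = 50000), divergence_uv_lg = 0.07)
  # oracle: direct mismatch count
  id <- 100 * mean(strsplit(p$uvarum[[1]], "")[[1]] == strsplit(p$lager[[1]], "")[[1]])
  expect_gte(id, 92.5)
  expect_lte(id, 93.5)
  # default divergences reproduce the lager regime at gene level (~93% "Lg")
  g <- p$genes
  gene_ids <- vapply(seq_len(nrow(g)), function(i) {
    u <- substr(p$uvarum[[1]], g$start[i], g$end[i])
    l <- substr(p$lager[[1]], g$start[i], g$end[i])
    100 * mean(strsplit(u, "")[[1]] == strsplit(l, "")[[1]])
  }, numeric(1))
  expect_gt(mean(gene_ids), 91)
  expect_lt(mean(gene_ids), 95)
})

test_that("parent simulation is seed-deterministic", {
  a <- simulate_parents(5, chrom_lengths = c(chrA = 5000))
  b <- simulate_parents(5, chrom_lengths = c(chrA = 5000))
  expect_identical(a, b)
  c <- simulate_parents(6, chrom_lengths = c(chrA = 5000))
  expect_false(identical(a$uvarum, c$uvarum))
})

test_that("implanting with an empty interval list is a no-op", {
  p <- simulate_parents(2, chrom_lengths = c(chrA = 3000))
  res <- implant_introgressions(p$uvarum, p$cerevisiae,
                                data.frame(chrom = character(0),
                                           start = integer(0), end = integer(0)))
  expect_identical(res$genome, p$uvarum)
  expect_equal(nrow(res$truth), 0)
})

test_that("implanted blocks match the donor, flanks match the recipient, length conserved", {
  p <- simulate_parents(3, chrom_lengths = c(chrA = 40000))
  iv <- data.frame(chrom = "chrA", start = 15001L, end = 35000L)
  res <- implant_introgressions(p$uvarum, p$cerevisiae, iv)
  # oracle: slicing
  expect_identical(substr(res$genome[[1]], 15001, 35000),
                   substr(p$cerevisiae[[1]], 15001, 35000))
  expect_identical(substr(res$genome[[1]], 1, 15000),
                   substr(p$uvarum[[1]], 1, 15000))
  expect_identical(substr(res$genome[[1]], 35001, 40000),
                   substr(p$uvarum[[1]], 35001, 40000))
  expect_equal(nchar(res$genome[[1]]), nchar(p$uvarum[[1]]))
})

test_that("invalid intervals are rejected with the offending interval named", {
  p <- simulate_parents(4, chrom_lengths = c(chrA = 5000))
  expect_error(implant_introgressions(p$uvarum, p$cerevisiae,
                                      data.frame(chrom = "chrA", start = 10L, end = 9000L)),
               "out of bounds")
  iv2 <- data.frame(chrom = "chrA", start = c(10L, 400L), end = c(500L, 900L))
  expect_error(implant_introgressions(p$uvarum, p$cerevisiae, iv2), "overlap")
})

test_that("preset mirroring the three contigs implants a 30803 bp block", {
  p <- simulate_parents(5)
  iv <- preset_cabc(p$uvarum)
  expect_equal(nrow(iv), 3)
  expect_true(30803 %in% (iv$end - iv$start + 1))
})

test_that("noiseless self-comparison gives equal intensities and zero log-ratios", {
  p <- simulate_parents(6, chrom_lengths = c(chrA = 10000))
  probes <- make_probe_design(p$uvarum)
  a <- simulate_array(probes, p$uvarum, p$uvarum, noise_sd = 0, n_replicates = 1)
  b <- simulate_array(probes, p$uvarum, p$uvarum, noise_sd = 0, n_replicates = 1)
  expect_equal(a[[1]]$intensity, b[[1]]$intensity)
  lr <- compute_log_ratios(a[[1]], b[[1]])
  expect_true(all(lr$value == 0))
})

test_that("a noiseless implanted donor block separates cleanly from background", {
  p <- simulate_parents(7, chrom_lengths = c(chrA = 30000))
  iv <- data.frame(chrom = "chrA", start = 10001L, end = 20000L)
  mo <- implant_introgressions(p$uvarum, p$cerevisiae, iv)
  probes <- make_probe_design(p$cerevisiae)
  arr <- simulate_array(probes, mo$genome, p$cerevisiae, noise_sd = 0, n_replicates = 1)
  inside <- probes$start >= 10001 & probes$end <= 20000
  expect_gt(min(arr[[1]]$intensity[inside]), max(arr[[1]]$intensity[!inside]))
})

test_that("with noise, in-block log-ratios clear background mean + 3 sd", {
  p <- simulate_parents(8, chrom_lengths = c(chrA = 40000))
  iv <- data.frame(chrom = "chrA", start = 15001L, end = 25000L)
  mo <- implant_introgressions(p$uvarum, p$cerevisiae, iv)
  probes <- make_probe_design(p$cerevisiae)
  t1 <- simulate_array(probes, mo$genome, p$cerevisiae, noise_sd = 0.1,
                       n_replicates = 1, seed = 21)[[1]]
  r1 <- simulate_array(probes, p$uvarum, p$cerevisiae, noise_sd = 0.1,
                       n_replicates = 1, seed = 22)[[1]]
  lr <- compute_log_ratios(t1, r1)
  # oracle: direct computation on the truth partition
  inside <- probes$start >= 15001 & probes$end <= 25000
  expect_gt(mean(lr$value[inside]),
            mean(lr$value[!inside]) + 3 * sd(lr$value[!inside]))
})

test_that("probes outside the genome are rejected by name", {
  p <- simulate_parents(9, chrom_lengths = c(chrA = 2000))
  probes <- data.frame(probe_id = "bad1", chrom = "chrA", start = 1990L, end = 2100L)
  expect_error(simulate_array(probes, p$uvarum, p$uvarum), "bad1")
})

test_that("homozygous markers segregate 4:0 and heterozygous exactly 2:2 in all tetrads", {
  mei <- simulate_meiosis(list(c(both = TRUE, het = TRUE, neither = FALSE),
                               c(both = TRUE, het = FALSE, neither = FALSE)),
                          n_tetrads = 40, seed = 10)
  tab <- as.matrix(mei$table)
  for (t in 1:40) {
    cols <- spore_cols(t)
    expect_equal(sum(tab["both", cols] == "+"), 4)
    expect_equal(sum(tab["het", cols] == "+"), 2)
    expect_equal(sum(tab["neither", cols] == "+"), 0)
  }
})

test_that("unlinked marker pairs give PD close to NPD over many tetrads", {
  n <- 4000
  mei <- simulate_meiosis(list(c(m1 = TRUE, m2 = TRUE), c(m1 = FALSE, m2 = FALSE)),
                          n_tetrads = n, seed = 11)
  tab <- as.matrix(mei$table)
  cls <- vapply(seq_len(n), function(t) {
    cols <- spore_cols(t)
    classify_ditype(tab["m1", cols], tab["m2", cols])
  }, character(1))
  pd <- sum(cls == "PD"); npd <- sum(cls == "NPD")
  # oracle: binomial expectation, PD = NPD for independent assortment
  expect_lt(abs(pd - npd) / (pd + npd), 0.05)
  # and tetratypes dominate 4:1:1
  expect_gt(sum(cls == "TT") / n, 0.55)
})

test_that("tightly linked markers give parental ditypes almost exclusively", {
  mei <- simulate_meiosis(list(c(a = TRUE, b = TRUE), c(a = FALSE, b = FALSE)),
                          n_tetrads = 300,
                          linkage = data.frame(m1 = "a", m2 = "b", cM = 1),
                          seed = 12)
  tab <- as.matrix(mei$table)
  cls <- vapply(1:300, function(t) {
    cols <- spore_cols(t)
    classify_ditype(tab["a", cols], tab["b", cols])
  }, character(1))
  expect_gt(sum(cls == "PD"), 250)
  expect_gt(sum(cls == "PD"), 50 * max(1, sum(cls == "NPD")))
})

test_that("degenerate microsatellite populations collapse to zero chord distance", {
  ms <- simulate_microsat_profiles(n_populations = 2, n_strains_per_pop = 3,
                                   n_loci = 4, allele_pool_overlap = 1,
                                   pool_size = 1, aneuploidy_rate = 0,
                                   missing_rate = 0, seed = 13)
  D <- chord_distance_matrix(ms$profiles)
  expect_true(all(D == 0))
})

test_that("disjoint allele pools share no alleles at any locus", {
  ms <- simulate_microsat_profiles(n_populations = 2, n_strains_per_pop = 5,
                                   n_loci = 6, allele_pool_overlap = 0,
                                   missing_rate = 0, seed = 14)
  pops <- split(ms$truth$strain, ms$truth$population)
  for (l in unique(ms$profiles$locus)) {
    a1 <- ms$profiles$allele[ms$profiles$locus == l & ms$profiles$strain %in% pops[[1]]]
    a2 <- ms$profiles$allele[ms$profiles$locus == l & ms$profiles$strain %in% pops[[2]]]
    expect_length(intersect(a1, a2), 0)
  }
  # hence the shared-allele term of the chord distance is zero: distance is
  # sqrt(2) between populations
  dip <- diploidize(ms$profiles, seed = 1)
  x <- strain_profile(dip, pops[[1]][1])
  y <- strain_profile(dip, pops[[2]][1])
  expect_equal(chord_distance(x, y), sqrt(2))
})

test_that("simulators are deterministic under a fixed seed", {
  a <- simulate_meiosis(list(c(m = TRUE), c(m = FALSE)), 5, seed = 3)
  b <- simulate_meiosis(list(c(m = TRUE), c(m = FALSE)), 5, seed = 3)
  expect_identical(a, b)
  c1 <- simulate_microsat_profiles(seed = 3, n_strains_per_pop = 3)
  c2 <- simulate_microsat_profiles(seed = 3, n_strains_per_pop = 3)
  expect_identical(c1, c2)
})
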