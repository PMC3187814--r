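#' Assemble a validated pipeline run configuration
#'
#' All stage parameters of the end-to-end analysis in one serializable
#' object. Unknown arguments are rejected before any computation.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param out_dir output directory.
#' @param chrom_lengths simulated chromosome lengths (bp). Defaults keep
#'   the implanted donor blocks a small fraction (~14%) of the genome, as
#'   introgressions are in real hybrid genomes; the median/MAD background
#'   model of the scanner assumes elevated probes are a minority.
#' @param divergence_uv_lg,divergence_ce,neutral_target parent-genome
#'   simulation parameters (see [simulate_parents()]).
#' @param noise_sd,n_replicates array simulation parameters.
#' @param scan a [scan_config()]. The default uses 4 background zones:
#'   zones must stay wide relative to the largest introgressed block so
#'   that every zone contains recipient-background probes, and the
#'   simulated genome is compact.
#' @param thresholds a [classification_thresholds()].
#' @param n_tetrads tetrads to simulate.
#' @param bootstrap bootstrap replicates for the phylogeny stage.
#' @param microsat list of [simulate_microsat_profiles()] parameters.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("mosaicseq_run_"),
                       chrom_lengths = c(chrI = 200000, chrII = 150000, chrIII = 120000),
                       divergence_uv_lg = 0.07, divergence_ce = 0.20,
                       neutral_target = 0.97,
                       noise_sd = 0.1, n_replicates = 2,
                       scan = scan_config(zones = 4),
                       thresholds = classification_thresholds(),
                       n_tetrads = 50, bootstrap = 100,
                       microsat = list(n_populations = 3, n_strains_per_pop = 20,
                                       n_loci = 12, allele_pool_overlap = 0.3)) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              chrom_lengths = chrom_lengths,
              divergence_uv_lg = divergence_uv_lg,
              divergence_ce = divergence_ce,
              neutral_target = neutral_target,
              noise_sd = noise_sd, n_replicates = n_replicates,
              scan = scan, thresholds = thresholds,
              n_tetrads = n_tetrads, bootstrap = bootstrap,
              microsat = microsat)
  validate_run_config(cfg)
}

RUN_CONFIG_KEYS <- c("seed", "out_dir", "chrom_lengths", "divergence_uv_lg",
                     "divergence_ce", "neutral_target", "noise_sd",
                     "n_replicates", "scan", "thresholds", "n_tetrads",
                     "bootstrap", "microsat")

validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(RUN_CONFIG_KEYS, names(cfg))
  if (length(missing)) {
    stop(sprintf("missing config key(s): %s", paste(missing, collapse = ", ")))
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$scan)) raw$scan <- do.call(scan_config, raw$scan)
  if (!is.null(raw$thresholds)) raw$thresholds <- do.call(classification_thresholds, raw$thresholds)
  if (!is.null(raw$chrom_lengths)) raw$chrom_lengths <- unlist(raw$chrom_lengths)
  defaults <- run_config()
  for (k in setdiff(RUN_CONFIG_KEYS, names(raw))) raw[[k]] <- defaults[[k]]
  validate_run_config(raw)
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  plain <- unclass(config)
  plain$scan <- unclass(plain$scan)
  plain$thresholds <- unclass(plain$thresholds)
  plain$chrom_lengths <- as.list(plain$chrom_lengths)
  yaml::write_yaml(plain, path)
  invisible(path)
}

stage_seed <- function(config, k) (config$seed * 101L + k) %% .Machine$integer.max

#' Run the end-to-end synthetic analysis
#'
#' Executes the stage chain on simulated data: parent-genome and mosaic
#' simulation (subtelomeric donor blocks, preset mirroring the three
#' contigs with the 30803-bp block), replicate array simulation and
#' comparative-hybridization scan, marker lineage classification
#' (including a constructed chimera), tetrad simulation with segregation
#' and independence analysis, K2P neighbor-joining phylogeny with
#' bootstrap supports, and microsatellite chord-distance clustering with
#' midpoint rooting. Every output under `out_dir` is reproducible from
#' the configuration and seed alone.
#'
#' @param config a [run_config()].
#' @return (invisibly) the summary report list, also written as
#'   `summary.json` together with per-stage FASTA/TSV/BED/Newick/JSON
#'   outputs.
#' @export
run_pipeline <- function(config = run_config()) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed)

  # -- simulate ------------------------------------------------------------
  parents <- simulate_parents(stage_seed(config, 1),
                              chrom_lengths = config$chrom_lengths,
                              divergence_uv_lg = config$divergence_uv_lg,
                              divergence_ce = config$divergence_ce,
                              neutral_target = config$neutral_target)
  intervals <- preset_cabc(parents$uvarum)
  mosaic <- implant_introgressions(parents$uvarum, parents$cerevisiae, intervals)
  write_fasta(mosaic$genome, file.path(config$out_dir, "mosaic_genome.fa"))
  write_truth_json(mosaic$truth, file.path(config$out_dir, "introgression_truth.json"))
  report$simulate <- list(
    n_chromosomes = length(parents$uvarum),
    implanted_blocks = nrow(mosaic$truth),
    largest_block_bp = max(mosaic$truth$end - mosaic$truth$start + 1),
    lager_uvarum_identity_pct = round(100 * (1 - mean(parents$realized_divergence_uv_lg)), 2)
  )

  # -- comparative hybridization scan -------------------------------------
  probes <- make_probe_design(parents$cerevisiae)
  test_reps <- simulate_array(probes, mosaic$genome, parents$cerevisiae,
                              noise_sd = config$noise_sd,
                              n_replicates = config$n_replicates,
                              seed = stage_seed(config, 2))
  ref_reps <- simulate_array(probes, parents$uvarum, parents$cerevisiae,
                             noise_sd = config$noise_sd,
                             n_replicates = config$n_replicates,
                             seed = stage_seed(config, 3))
  scan <- acgh_scan(test_reps, ref_reps, config$scan)
  write_bed(scan$regions, file.path(config$out_dir, "regions.bed"))
  write_probe_tsv(scan$track, file.path(config$out_dir, "log_ratios.tsv"))
  report$acgh <- list(n_regions_gt_min = scan$summary$n,
                      total_kb = scan$summary$total_kb)

  # -- marker lineage classification --------------------------------------
  genes <- parents$genes
  gene_seq <- function(genome, g) {
    substr(genome[[genes$chrom[g]]], genes$start[g], genes$end[g])
  }
  pick <- seq_len(min(6, nrow(genes)))
  calls <- lapply(pick, function(g) {
    queries <- list(uvarum_allele = gene_seq(parents$uvarum, g),
                    lager_allele = gene_seq(parents$lager, g),
                    cerevisiae_allele = gene_seq(parents$cerevisiae, g))
    lapply(queries, classify_marker,
           cerevisiae_ref = gene_seq(parents$cerevisiae, g),
           uvarum_ref = gene_seq(parents$uvarum, g),
           thresholds = config$thresholds)
  })
  lineages <- unlist(lapply(calls, function(x) vapply(x, `[[`, character(1), "lineage")))
  # a constructed chimera: 5' third from the uvarum allele, rest donor
  g1 <- pick[1]
  u <- gene_seq(parents$uvarum, g1); ce <- gene_seq(parents$cerevisiae, g1)
  cut <- nchar(u) %/% 3
  chim <- paste0(substr(u, 1, cut), substr(ce, cut + 1, nchar(ce)))
  bp <- detect_breakpoint(chim, ce, u)
  report$ancestry <- list(
    calls = as.list(table(lineages)),
    chimera_breakpoint = bp$breakpoint,
    chimera_true_breakpoint = cut
  )
  call_df <- data.frame(
    marker = names(lineages), lineage = unname(lineages))
  utils::write.table(call_df, file.path(config$out_dir, "marker_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # -- tetrads -------------------------------------------------------------
  p1 <- c(cA = TRUE, cB = TRUE, cC = TRUE, SuMEL = FALSE)
  p2 <- c(cA = FALSE, cB = FALSE, cC = FALSE, SuMEL = TRUE)
  mei <- simulate_meiosis(list(p1, p2), config$n_tetrads,
                          seed = stage_seed(config, 4))
  tets <- sprintf("T%03d", seq_len(config$n_tetrads))
  classes <- vapply(tets, function(t) {
    cols <- paste(t, letters[1:4], sep = ".")
    classify_ditype(unlist(mei$table["cA", cols]), unlist(mei$table["cB", cols]))
  }, character(1))
  at <- assortment_test(classes)
  report$tetrads <- list(PD = at$PD, NPD = at$NPD, TT = at$TT,
                         p_value = at$p_value,
                         viability_demo_pct = viability(13, 36))
  utils::write.table(mei$table, file.path(config$out_dir, "tetrad_table.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)

  # -- phylogeny ------------------------------------------------------------
  g2 <- pick[min(2, length(pick))]
  aln <- c(uvarum = gene_seq(parents$uvarum, g2),
           lager = gene_seq(parents$lager, g2),
           cerevisiae = gene_seq(parents$cerevisiae, g2),
           mosaic_strain = gene_seq(mosaic$genome, g2))
  tree <- bootstrap_support(aln, n_replicates = config$bootstrap,
                            seed = stage_seed(config, 5))
  write_newick(tree, file.path(config$out_dir, "marker_tree.nwk"))
  report$phylo <- list(total_branch_length = round(tree_total_length(tree), 6),
                       min_support = min(tree$node.label, na.rm = TRUE))

  # -- microsatellites ------------------------------------------------------
  ms <- do.call(simulate_microsat_profiles,
                c(config$microsat, list(seed = stage_seed(config, 6))))
  dip <- diploidize(ms$profiles, seed = stage_seed(config, 7))
  D <- chord_distance_matrix(dip)
  mtree <- midpoint_root(nj_build(D))
  write_newick(mtree, file.path(config$out_dir, "microsat_tree.nwk"))
  report$microsat <- list(
    n_strains = length(unique(dip$strain)),
    max_chord_distance = round(max(D), 4),
    label_recovery = round(population_label_recovery(mtree, ms$truth), 3)
  )

  jsonlite::write_json(report, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 6, pretty = TRUE)
  invisible(report)
}
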