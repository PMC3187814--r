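#' Simulate three parental yeast genomes with controlled divergence
#'
#' Generates the study system of a mosaic hybrid genome: a *S. uvarum*-like
#' recipient, a lager-like sister lineage derived from it at a requested
#' substitution divergence (defaults emulate the ~93% nucleotide identity of
#' lager-type alleles to their *S. uvarum* counterparts, i.e. 2--6%
#' divergence), and an independently diverged *S. cerevisiae*-like donor.
#'
#' Each chromosome carries a toy gene annotation (300-codon open reading
#' frames tiled with intergenic spacers). Lager substitution sites are
#' drawn uniformly, so per-gene divergence tracks the genome-wide target;
#' a site landing in coding sequence is realized as a synonymous change
#' at the third position of its codon with probability `neutral_target`,
#' so that translated lager proteins stay nearly identical to their
#' recipient orthologues -- the "SNPs are almost all neutral" regime.
#' Substituted bases are drawn with a 2:1 transition:transversion bias,
#' matching the two-parameter substitution model used downstream.
#'
#' @param seed integer; fully determines the output.
#' @param chrom_lengths named or unnamed vector of chromosome lengths in bp
#'   (each >= 1000).
#' @param divergence_uv_lg fraction of sites substituted between the
#'   recipient and the lager lineage (0--0.25). Default 0.07 (~93% identity).
#' @param divergence_ce fraction substituted between recipient and the
#'   cerevisiae-like donor. Default 0.20.
#' @param neutral_target fraction of coding lager substitutions placed
#'   synonymously. Default 0.97: nearly all coding SNPs neutral, keeping
#'   translated proteins over 99% identical while nucleotide identity
#'   sits near 93%.
#' @param ts_tv transition:transversion ratio for substituted bases.
#' @return A `parent_set` list: `uvarum`, `lager`, `cerevisiae` (named lists
#'   of chromosome sequences), `genes` (toy gene table with 1-based
#'   inclusive coordinates), realized divergences, and the call parameters.
#' @export
simulate_parents <- function(seed, chrom_lengths = c(chrI = 200000, chrII = 150000, chrIII = 120000),
                             divergence_uv_lg = 0.07, divergence_ce = 0.20,
                             neutral_target = 0.97, ts_tv = 2) {
  if (any(chrom_lengths < 1000)) stop("all chromosome lengths must be >= 1 kb")
  if (divergence_uv_lg < 0 || divergence_uv_lg > 0.25 ||
      divergence_ce < 0 || divergence_ce > 0.25) {
    stop("divergences must lie in [0, 0.25]")
  }
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", utils::as.roman(seq_along(chrom_lengths)))
  }
  with_seed(seed, {
    uvarum <- lapply(chrom_lengths, function(L) {
      chars_seq(sample(DNA_BASES, L, replace = TRUE))
    })
    genes <- toy_gene_annotation(chrom_lengths)
    lager <- uvarum
    neutral_shortfall <- FALSE
    realized_uv_lg <- numeric(0)
    for (chrom in names(uvarum)) {
      res <- derive_lager_chromosome(uvarum[[chrom]],
                                     genes[genes$chrom == chrom, , drop = FALSE],
                                     divergence_uv_lg, neutral_target, ts_tv)
      lager[[chrom]] <- res$seq
      neutral_shortfall <- neutral_shortfall || res$shortfall
      realized_uv_lg[chrom] <- res$n_sub / chrom_lengths[[chrom]]
    }
    cerevisiae <- lapply(uvarum, function(s) {
      x <- seq_chars(s)
      n_sub <- round(divergence_ce * length(x))
      if (n_sub > 0) {
        sites <- sample.int(length(x), n_sub)
        x[sites] <- mutate_bases(x[sites], ts_tv)
      }
      chars_seq(x)
    })
    if (neutral_shortfall) {
      warning("neutral_target unattainable at the requested divergence; best effort recorded")
    }
    structure(list(
      uvarum = uvarum, lager = lager, cerevisiae = cerevisiae,
      genes = genes,
      divergence_uv_lg = divergence_uv_lg, divergence_ce = divergence_ce,
      neutral_target = neutral_target, neutral_shortfall = neutral_shortfall,
      realized_divergence_uv_lg = realized_uv_lg,
      seed = seed
    ), class = "parent_set")
  })
}

# Toy gene models: 300-codon ORFs (900 bp) every 1500 bp, frame known.
# Coverage ~60% of each chromosome, leaving intergenic capacity for the
# non-synonymous remainder of the lager substitutions.
toy_gene_annotation <- function(chrom_lengths) {
  out <- lapply(names(chrom_lengths), function(chrom) {
    L <- chrom_lengths[[chrom]]
    starts <- seq(101L, by = 1500L, length.out = max(0L, (L - 1100L) %/% 1500L + 1L))
    starts <- starts[starts + 899L <= L]
    if (!length(starts)) return(NULL)
    data.frame(chrom = chrom, gene = paste0(chrom, "_g", seq_along(starts)),
               start = starts, end = starts + 899L, stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

# Lager derivation: substitution sites are drawn uniformly over the
# chromosome so that per-gene divergence matches the genome-wide target;
# a site landing in coding sequence is realized synonymously (relocated
# to the third position of its codon) with probability neutral_target,
# non-synonymously otherwise. A shortfall is recorded when a requested
# synonymous change has no synonymous alternative at its codon.
derive_lager_chromosome <- function(seq, genes, divergence, neutral_target, ts_tv) {
  x <- seq_chars(seq)
  L <- length(x)
  n_sub <- round(divergence * L)
  if (n_sub == 0) return(list(seq = seq, n_sub = 0L, shortfall = FALSE))
  in_gene <- integer(L)  # 0 = intergenic, else gene row index
  for (i in seq_len(nrow(genes))) in_gene[genes$start[i]:genes$end[i]] <- i
  sites <- sample.int(L, n_sub)
  touched <- logical(L)
  syn_requested <- 0L
  syn_placed <- 0L
  for (site in sites) {
    g <- in_gene[site]
    placed_syn <- FALSE
    if (g > 0 && stats::runif(1) < neutral_target) {
      syn_requested <- syn_requested + 1L
      # synonymous change at the third position of this site's codon;
      # when that position is taken or the codon admits none (Met, Trp),
      # relocate to another free third position of the same gene
      codon_start <- genes$start[g] + ((site - genes$start[g]) %/% 3L) * 3L
      n_codons <- (genes$end[g] - genes$start[g] + 1L) %/% 3L
      extra <- genes$start[g] + 3L * (sample.int(n_codons, min(10L, n_codons)) - 1L)
      cand <- c(codon_start, extra[extra + 2L <= genes$end[g]])
      for (cs in cand) {
        pos3 <- cs + 2L
        if (touched[pos3]) next
        codon <- x[cs:(cs + 2L)]
        alt <- synonymous_alternatives(codon)
        if (!length(alt)) next
        tsb <- TRANSITION[[codon[3L]]]
        x[pos3] <- if (tsb %in% alt && stats::runif(1) < ts_tv / (ts_tv + 1)) {
          tsb
        } else {
          alt[sample.int(length(alt), 1L)]
        }
        touched[pos3] <- TRUE
        syn_placed <- syn_placed + 1L
        placed_syn <- TRUE
        break
      }
    }
    if (!placed_syn && !touched[site]) {
      # best effort: an undeliverable synonymous change (e.g. a Met or
      # Trp codon) falls back to an ordinary substitution at the site
      x[site] <- mutate_bases(x[site], ts_tv)
      touched[site] <- TRUE
    }
  }
  shortfall <- syn_requested > 0 && syn_placed / syn_requested < 0.9
  list(seq = chars_seq(x), n_sub = sum(touched), shortfall = shortfall)
}

synonymous_alternatives <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  aa <- code[[paste(codon, collapse = "")]]
  alt <- setdiff(DNA_BASES, codon[3L])
  alt[vapply(alt, function(b) code[[paste(c(codon[1:2], b), collapse = "")]] == aa, logical(1))]
}

#' Implant donor segments into a recipient genome
#'
#' Replaces the recipient sequence by the donor sequence on each interval
#' (1-based inclusive coordinates), modelling subtelomeric introgressed
#' blocks. Total genome length is conserved.
#'
#' @param recipient,donor named lists of chromosome sequences sharing names
#'   and lengths.
#' @param intervals data.frame with columns `chrom`, `start`, `end` and
#'   optionally `donor` (lineage label, default "cerevisiae").
#' @return list with `genome` (the mosaic) and `truth` (a truth record
#'   data.frame of implanted intervals with their donor lineage).
#' @export
implant_introgressions <- function(recipient, donor, intervals) {
  if (!nrow(intervals)) {
    return(list(genome = recipient,
                truth = data.frame(chrom = character(0), start = integer(0),
                                   end = integer(0), donor = character(0))))
  }
  if (is.null(intervals$donor)) intervals$donor <- "cerevisiae"
  for (i in seq_len(nrow(intervals))) {
    iv <- intervals[i, ]
    if (!iv$chrom %in% names(recipient)) {
      stop(sprintf("interval %d: unknown chromosome '%s'", i, iv$chrom))
    }
    L <- nchar(recipient[[iv$chrom]])
    if (iv$start > iv$end || iv$start < 1 || iv$end > L) {
      stop(sprintf("interval %d (%s:%d-%d) is out of bounds or inverted",
                   i, iv$chrom, iv$start, iv$end))
    }
  }
  o <- order(intervals$chrom, intervals$start)
  iv <- intervals[o, , drop = FALSE]
  if (nrow(iv) > 1) {
    same <- iv$chrom[-1] == iv$chrom[-nrow(iv)]
    overlap <- same & iv$start[-1] <= iv$end[-nrow(iv)]
    if (any(overlap)) {
      k <- which(overlap)[1] + 1
      stop(sprintf("overlapping intervals on %s (the one starting at %d)",
                   iv$chrom[k], iv$start[k]))
    }
  }
  mosaic <- recipient
  for (i in seq_len(nrow(iv))) {
    chrom <- iv$chrom[i]
    substr(mosaic[[chrom]], iv$start[i], iv$end[i]) <-
      substr(donor[[chrom]], iv$start[i], iv$end[i])
  }
  list(genome = mosaic,
       truth = iv[, c("chrom", "start", "end", "donor")])
}

#' Subtelomeric introgression preset mirroring contigs cA, cB and cC
#'
#' Three donor blocks placed near chromosome ends, one of exactly 30803 bp
#' (the assembled length of the largest contig, cB), the other two of
#' contig-scale sizes.
#'
#' @param genome a genome (named list of chromosome sequences) giving
#'   chromosome names and lengths; needs at least 3 chromosomes of
#'   sufficient length.
#' @return interval data.frame suitable for [implant_introgressions()].
#' @export
preset_cabc <- function(genome) {
  if (length(genome) < 3) stop("preset cABC needs at least 3 chromosomes")
  lens <- vapply(genome, nchar, integer(1))
  sizes <- c(cB = 30803L, cA = 19000L, cC = 16000L)
  if (any(lens[1:3] < sizes + 3000L)) stop("chromosomes too short for preset cABC")
  data.frame(
    chrom = names(genome)[1:3],
    start = lens[1:3] - 2000L - sizes + 1L,
    end = lens[1:3] - 2000L,
    donor = "cerevisiae",
    contig = names(sizes),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Tile a genome with array probes
#'
#' @param genome named list of chromosome sequences (the probe-design
#'   genome, i.e. the species the array targets).
#' @param spacing probe start-to-start spacing in bp.
#' @param probe_len effective probe footprint in bp. The default (150)
#'   emulates a per-gene probe-set summary rather than a single short
#'   oligo: short footprints on a ~20%-diverged background occasionally
#'   land on conserved stretches and cross-hybridize, which a probe-set
#'   average smooths out.
#' @return data.frame of probes (`probe_id`, `chrom`, `start`, `end`),
#'   sorted by (chrom, start), 1-based inclusive.
#' @export
make_probe_design <- function(genome, spacing = 250, probe_len = 150) {
  out <- lapply(names(genome), function(chrom) {
    L <- nchar(genome[[chrom]])
    starts <- seq(1L, L - probe_len + 1L, by = spacing)
    data.frame(chrom = chrom, start = starts, end = starts + probe_len - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$probe_id <- sprintf("p%05d", seq_len(nrow(out)))
  out[, c("probe_id", "chrom", "start", "end")]
}

# Three-plateau response of probe intensity to probe/target identity:
# near-perfect targets hybridize at a high plateau, ~93%-identical
# lager-type targets at an intermediate level, and <=80%-diverged targets
# fall to the array background. Plateau parameters are calibration knobs,
# not measured values.
plateau_intensity <- function(identity, background = 60, mid = 400, high = 1200) {
  background +
    (mid - background) * stats::plogis((identity - 0.885) / 0.008) +
    (high - mid) * stats::plogis((identity - 0.965) / 0.008)
}

#' Simulate replicate array hybridization intensities
#'
#' Each probe's noiseless intensity is a decreasing function of the
#' divergence between the hybridized genome and the probe-design genome
#' over the probe footprint (three-plateau response), with per-replicate
#' log-normal multiplicative noise.
#'
#' @param probe_design probe table from [make_probe_design()] (sorted by
#'   chrom, start).
#' @param genome the hybridized (sample) genome.
#' @param reference_genome the probe-design genome the identities are
#'   measured against.
#' @param noise_sd standard deviation of log-normal multiplicative noise
#'   (natural-log scale); 0 gives noiseless intensities.
#' @param n_replicates number of replicate arrays (>= 1).
#' @param seed integer seed or `NULL`.
#' @return list of `n_replicates` probe data.frames with an `intensity`
#'   column added.
#' @export
simulate_array <- function(probe_design, genome, reference_genome,
                           noise_sd = 0.1, n_replicates = 2, seed = NULL) {
  stopifnot(n_replicates >= 1, noise_sd >= 0)
  for (i in seq_len(nrow(probe_design))) {
    chrom <- probe_design$chrom[i]
    if (!chrom %in% names(genome) || probe_design$end[i] > nchar(genome[[chrom]])) {
      stop(sprintf("probe %s lies outside the genome", probe_design$probe_id[i]))
    }
  }
  ident <- vapply(seq_len(nrow(probe_design)), function(i) {
    chrom <- probe_design$chrom[i]
    a <- substr(genome[[chrom]], probe_design$start[i], probe_design$end[i])
    b <- substr(reference_genome[[chrom]], probe_design$start[i], probe_design$end[i])
    mean(seq_chars(a) == seq_chars(b))
  }, numeric(1))
  mu <- plateau_intensity(ident)
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      df <- probe_design
      noise <- if (noise_sd > 0) exp(stats::rnorm(length(mu), 0, noise_sd)) else 1
      df$intensity <- mu * noise
      df
    })
  })
}

#' Simulate hybrid meioses producing four-spore tetrads
#'
#' Markers heterozygous between the two parents segregate exactly 2:2 in
#' every tetrad; markers shared by (or absent from) both parents segregate
#' 4:0 (0:4). Unlinked markers assort independently, giving
#' parental:nonparental ditype:tetratype ratios of 1:1:4 in expectation;
#' linked pairs are modelled with a four-chromatid crossover process
#' (crossover count Poisson with mean = cM/50, no chromatid interference).
#'
#' @param parent_marker_sets list of two named logical vectors
#'   (marker -> presence), one per parent.
#' @param n_tetrads number of tetrads (>= 1).
#' @param linkage optional data.frame with columns `m1`, `m2`, `cM` chaining
#'   linked marker pairs; markers not mentioned are unlinked.
#' @param seed integer seed or `NULL`.
#' @return list with `table` (marker x column data.frame shaped like a
#'   printed tetrad table: parent columns P1/P2 then `<tetrad>.<a-d>`, cells
#'   "+"/"-") and `truth` (list of per-tetrad logical matrices of the
#'   parent-1 allele).
#' @export
simulate_meiosis <- function(parent_marker_sets, n_tetrads, linkage = NULL, seed = NULL) {
  stopifnot(length(parent_marker_sets) == 2, n_tetrads >= 1)
  markers <- union(names(parent_marker_sets[[1]]), names(parent_marker_sets[[2]]))
  p1 <- vapply(markers, function(m) isTRUE(parent_marker_sets[[1]][[m]]), logical(1))
  p2 <- vapply(markers, function(m) isTRUE(parent_marker_sets[[2]][[m]]), logical(1))
  het <- xor(p1, p2)

  # linkage groups as chains: each linked marker hangs off a previously
  # simulated partner
  link_to <- stats::setNames(rep(NA_character_, length(markers)), markers)
  link_cm <- stats::setNames(rep(NA_real_, length(markers)), markers)
  if (!is.null(linkage) && nrow(linkage)) {
    for (i in seq_len(nrow(linkage))) {
      if (identical(linkage$cM[i], "unlinked")) next
      link_to[[linkage$m2[i]]] <- linkage$m1[i]
      link_cm[[linkage$m2[i]]] <- as.numeric(linkage$cM[i])
    }
  }

  with_seed(seed, {
    tetrad_ids <- sprintf("T%03d", seq_len(n_tetrads))
    spores <- c("a", "b", "c", "d")
    tab <- matrix("-", nrow = length(markers),
                  ncol = 2 + 4 * n_tetrads,
                  dimnames = list(markers,
                                  c("P1", "P2",
                                    paste(rep(tetrad_ids, each = 4), spores, sep = "."))))
    tab[p1, "P1"] <- "+"
    tab[p2, "P2"] <- "+"
    truth <- vector("list", n_tetrads)
    names(truth) <- tetrad_ids
    for (t in seq_len(n_tetrads)) {
      # chromatids 1,2 carry the parent-1 allele, 3,4 parent-2; each
      # linkage group gets its own random chromatid-to-spore permutation
      from_p1 <- matrix(NA, nrow = length(markers), ncol = 4,
                        dimnames = list(markers, spores))
      chrom_alleles <- list()  # marker -> chromatid allele vector (TRUE = P1)
      for (m in markers) {
        anchor <- link_to[[m]]
        if (is.na(anchor) || is.null(chrom_alleles[[anchor]])) {
          alle <- c(TRUE, TRUE, FALSE, FALSE)
          perm <- sample.int(4L)
        } else {
          prev <- chrom_alleles[[anchor]]
          alle <- prev$alleles
          nx <- stats::rpois(1, link_cm[[m]] / 50)
          for (k in seq_len(nx)) {
            i1 <- sample(1:2, 1)  # one chromatid from each homolog
            i2 <- sample(3:4, 1)
            tmp <- alle[i1]; alle[i1] <- alle[i2]; alle[i2] <- tmp
          }
          perm <- prev$perm
        }
        chrom_alleles[[m]] <- list(alleles = alle, perm = perm)
        from_p1[m, ] <- alle[perm]
      }
      present <- from_p1
      for (m in markers) {
        present[m, ] <- ifelse(from_p1[m, ], p1[[m]], p2[[m]])
      }
      cols <- 2 + seq(4 * (t - 1) + 1, 4 * t)
      tab[, cols] <- ifelse(present, "+", "-")
      truth[[t]] <- from_p1
    }
    list(table = as.data.frame(tab, stringsAsFactors = FALSE), truth = truth)
  })
}

#' Simulate population-structured microsatellite profiles
#'
#' Strains carry 1--4 alleles per locus (aneuploids allowed), loci may be
#' missing, and each population draws from its own allele pool whose
#' overlap with other populations is controlled. The default 12 loci match
#' the multilocus panel used for strain clustering.
#'
#' @param n_populations,n_strains_per_pop population structure.
#' @param n_loci number of loci (default 12).
#' @param allele_pool_overlap fraction of each locus's allele pool shared
#'   across populations (0 = fully disjoint, 1 = one common pool).
#' @param pool_size alleles per population pool per locus.
#' @param aneuploidy_rate probability a strain carries a third allele at a
#'   locus.
#' @param missing_rate probability a strain-locus is unscored.
#' @param seed integer seed or `NULL`.
#' @return list with `profiles` (long data.frame strain/locus/allele, one
#'   row per allele copy) and `truth` (data.frame strain -> population).
#' @export
simulate_microsat_profiles <- function(n_populations = 3, n_strains_per_pop = 20,
                                       n_loci = 12, allele_pool_overlap = 0.3,
                                       pool_size = 6, aneuploidy_rate = 0.1,
                                       missing_rate = 0.05, seed = NULL) {
  stopifnot(n_loci >= 1, n_populations >= 1, pool_size >= 1,
            allele_pool_overlap >= 0, allele_pool_overlap <= 1)
  with_seed(seed, {
    loci <- sprintf("L%02d", seq_len(n_loci))
    n_shared <- round(allele_pool_overlap * pool_size)
    pools <- list()
    freqs <- list()
    for (l in seq_len(n_loci)) {
      shared <- if (n_shared > 0) 1000L * l + seq_len(n_shared) else integer(0)
      for (k in seq_len(n_populations)) {
        private <- if (pool_size - n_shared > 0) {
          1000L * l + 100L * k + seq_len(pool_size - n_shared)
        } else integer(0)
        pool <- c(shared, private)
        w <- stats::rgamma(length(pool), shape = 1)
        key <- paste(l, k)
        pools[[key]] <- pool
        freqs[[key]] <- if (length(pool) == 1) 1 else w / sum(w)
      }
    }
    rows <- list()
    strains <- character(0)
    pops <- character(0)
    for (k in seq_len(n_populations)) {
      for (s in seq_len(n_strains_per_pop)) {
        strain <- sprintf("pop%d_s%02d", k, s)
        strains <- c(strains, strain)
        pops <- c(pops, paste0("pop", k))
        for (l in seq_len(n_loci)) {
          if (stats::runif(1) < missing_rate) next
          key <- paste(l, k)
          n_alleles <- 2L + (stats::runif(1) < aneuploidy_rate)
          pool <- pools[[key]]
          al <- pool[sample.int(length(pool), n_alleles, replace = TRUE,
                                prob = freqs[[key]])]
          rows[[length(rows) + 1]] <- data.frame(
            strain = strain, locus = loci[l], allele = al,
            stringsAsFactors = FALSE)
        }
      }
    }
    list(profiles = do.call(rbind, rows),
         truth = data.frame(strain = strains, population = pops,
                            stringsAsFactors = FALSE))
  })
}
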