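#' Configure a pooled-accession simulation
#'
#' Builds the parameter set for simulating deep pooled amplicon sequencing of
#' heterogeneous, outcrossing accessions. Each accession is represented by a
#' DNA pool of `n_plants` diploid individuals, so the smallest segregating
#' allele (one heterozygous plant) has pool frequency `1 / (2 * n_plants)`.
#' Defaults emulate the study conditions the package targets: 95 accessions,
#' pools of 96 plants, six amplicon targets, mean coverage near 14,000x
#' ranging roughly 3,000--30,000x, and wild accessions carrying many more
#' private alleles than modern cultivars.
#'
#' @param n_accessions Number of accessions (pools).
#' @param n_plants Diploid plants per pool.
#' @param n_amplicons Number of amplicon targets.
#' @param amplicon_length Length of each amplicon in base pairs.
#' @param group_props Named proportions of accessions per germplasm group
#'   (`wild`, `landrace`, `historic`, `modern`); normalised internally.
#' @param variant_density Shared (common) variant sites per base pair of
#'   amplicon sequence.
#' @param carrier_af_shape Beta shape parameters for the fraction of
#'   accessions carrying each common variant.
#' @param common_vaf_shape Beta shape parameters for within-accession
#'   frequency of a carried common variant (mass concentrated at low VAF).
#' @param private_allele_rate Named per-accession expected counts of private
#'   high-frequency alleles by germplasm group.
#' @param private_vaf_shape Named list of Beta shape pairs for private-allele
#'   within-accession frequency by group.
#' @param hidden_allele_rate Expected number, per accession, of alleles
#'   carried by exactly one heterozygous plant (pool frequency
#'   `1/(2*n_plants)`).
#' @param n_diverged Number of maximally diverged accessions (first wild
#'   accessions), homozygous for the alternate allele at a large fraction of
#'   common sites.
#' @param diverged_site_frac Fraction of common sites fixed alternate in
#'   diverged accessions.
#' @param indel_frac Fraction of simulated variant sites that are 1-bp
#'   indels rather than SNVs.
#' @param coverage_mean,coverage_min,coverage_max Per-pool, per-site read
#'   depth: mean and truncation bounds of the log-normal depth distribution.
#' @param error_rate Per-base substitution error probability.
#' @param seed Master seed; per-stage substreams are derived from it.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_accessions = 6, n_amplicons = 2, seed = 1)
#' truth <- simulate_truth(cfg)
sim_config <- function(n_accessions = 95,
                       n_plants = 96,
                       n_amplicons = 6,
                       amplicon_length = 600,
                       group_props = c(wild = 0.11, landrace = 0.37,
                                       historic = 0.36, modern = 0.16),
                       variant_density = 1 / 12,
                       carrier_af_shape = c(0.3, 1.0),
                       common_vaf_shape = c(0.25, 4.75),
                       private_allele_rate = c(wild = 6, landrace = 2,
                                               historic = 0.8, modern = 0.5),
                       private_vaf_shape = list(wild = c(1.2, 1.8),
                                                landrace = c(0.35, 2.5),
                                                historic = c(0.35, 2.5),
                                                modern = c(0.35, 2.5)),
                       hidden_allele_rate = 2,
                       n_diverged = 1,
                       diverged_site_frac = 0.8,
                       indel_frac = 0.05,
                       coverage_mean = 13948,
                       coverage_min = 2924,
                       coverage_max = 30275,
                       error_rate = 0.001,
                       seed = 1L) {
  cfg <- list(
    n_accessions = as.integer(n_accessions),
    n_plants = as.integer(n_plants),
    n_amplicons = as.integer(n_amplicons),
    amplicon_length = as.integer(amplicon_length),
    group_props = group_props / sum(group_props),
    variant_density = variant_density,
    carrier_af_shape = carrier_af_shape,
    common_vaf_shape = common_vaf_shape,
    private_allele_rate = private_allele_rate,
    private_vaf_shape = private_vaf_shape,
    hidden_allele_rate = hidden_allele_rate,
    n_diverged = as.integer(n_diverged),
    diverged_site_frac = diverged_site_frac,
    indel_frac = indel_frac,
    coverage_mean = coverage_mean,
    coverage_min = coverage_min,
    coverage_max = coverage_max,
    error_rate = error_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot_msg <- function(ok, msg) if (!ok) abort(paste0("invalid sim_config: ", msg))
  counts <- c("n_accessions", "n_plants", "n_amplicons", "amplicon_length")
  for (f in counts) {
    stopifnot_msg(length(cfg[[f]]) == 1 && !is.na(cfg[[f]]) && cfg[[f]] >= 1,
                  paste(f, "must be a positive count"))
  }
  stopifnot_msg(cfg$error_rate >= 0 && cfg$error_rate < 0.5,
                "error_rate must be in [0, 0.5)")
  stopifnot_msg(cfg$coverage_min <= cfg$coverage_mean &&
                  cfg$coverage_mean <= cfg$coverage_max,
                "need coverage_min <= coverage_mean <= coverage_max")
  stopifnot_msg(cfg$coverage_min > 0, "coverage_min must be positive")
  stopifnot_msg(all(cfg$group_props >= 0) && abs(sum(cfg$group_props) - 1) < 1e-8,
                "group_props must be nonnegative proportions")
  stopifnot_msg(setequal(names(cfg$group_props),
                         c("wild", "landrace", "historic", "modern")),
                "group_props must name wild/landrace/historic/modern")
  stopifnot_msg(cfg$hidden_allele_rate >= 0, "hidden_allele_rate must be >= 0")
  stopifnot_msg(cfg$n_diverged >= 0 && cfg$n_diverged <= cfg$n_accessions,
                "n_diverged out of range")
  stopifnot_msg(cfg$diverged_site_frac >= 0 && cfg$diverged_site_frac <= 1,
                "diverged_site_frac must be in [0, 1]")
  stopifnot_msg(!is.na(cfg$seed), "seed must be an integer")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_accessions, " accessions x ", x$n_plants,
      " plants, ", x$n_amplicons, " amplicons of ", x$amplicon_length,
      " bp\n  coverage ", x$coverage_min, "-", x$coverage_max,
      " (mean ", x$coverage_mean, "), error rate ", x$error_rate,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# 96-well-plate-style accession codes (A1..H12, then plate 2 prefix).
plate_codes <- function(n) {
  base <- as.vector(outer(LETTERS[1:8], 1:12, paste0))
  if (n <= 96) return(base[seq_len(n)])
  reps <- ceiling(n / 96)
  codes <- unlist(lapply(seq_len(reps), function(p) {
    if (p == 1) base else paste0("P", p, "_", base)
  }))
  codes[seq_len(n)]
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Hardy-Weinberg genotype counts for one pool at allele frequency f. A
# carrier pool contains the allele by definition, so the draw is
# conditioned on at least one alternate allele being sampled (rejection,
# falling back to a single heterozygote for vanishing frequencies).
hw_counts <- function(n_plants, f) {
  probs <- c((1 - f)^2, 2 * f * (1 - f), f^2)
  for (try in 1:50) {
    g <- drop(rmultinom(1, n_plants, probs))
    if (g[2] + g[3] > 0) return(g)
  }
  c(n_plants - 1L, 1L, 0L)
}

#' Simulate ground-truth allele frequencies and pool genotypes
#'
#' Draws the "truth" a pooled amplicon experiment tries to recover: shared
#' common variants segregating at mostly low frequency across accessions,
#' private high-frequency alleles confined to single accessions (most
#' numerous in wild material), hidden alleles carried by exactly one
#' heterozygous plant in one pool, and optionally one maximally diverged
#' accession fixed for the alternate allele at most common sites. Within
#' each accession, plant genotypes follow Hardy-Weinberg proportions
#' (random-mating, outcrossing model) independently per site; the true pool
#' frequency is the realised allele frequency of the sampled plants, so
#' `true_freq == (n_het + 2 * n_alt_hom) / (2 * n_plants)` exactly.
#'
#' @param config A [sim_config()].
#' @return An object of class `pool_truth`: a list with `accessions`
#'   (accession codes and germplasm groups), `sites` (variant keys with
#'   origin `common`/`private`/`hidden` and owner), `freq` (carrier rows:
#'   accession, site, genotype counts and exact pool frequency), `ref_seqs`
#'   (named amplicon sequences) and `models` (simple one-exon gene models).
#' @export
simulate_truth <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  validate_sim_config(config)
  with_seed(stage_seed(config$seed, "truth"), simulate_truth_impl(config))
}

simulate_truth_impl <- function(cfg) {
  acc <- plate_codes(cfg$n_accessions)
  groups <- rep(names(cfg$group_props),
                times = diff(round(cumsum(c(0, cfg$group_props)) * cfg$n_accessions)))
  # rounding can drop/add one; pad with the modal group
  if (length(groups) < cfg$n_accessions) {
    groups <- c(groups, rep("landrace", cfg$n_accessions - length(groups)))
  }
  groups <- groups[seq_len(cfg$n_accessions)]
  # keep group order stable but assign codes in order: wild first so the
  # diverged accession is wild when any wild slots exist
  accessions <- tibble(accession = acc, group = groups)
  amplicons <- paste0("AMP", seq_len(cfg$n_amplicons))
  ref_seqs <- setNames(
    vapply(amplicons, function(a) random_dna(cfg$amplicon_length), character(1)),
    amplicons
  )

  n_common <- max(1L, round(cfg$variant_density * cfg$n_amplicons *
                              cfg$amplicon_length))
  wild_idx <- which(groups == "wild")
  diverged <- if (cfg$n_diverged > 0) {
    idx <- c(wild_idx, setdiff(seq_along(acc), wild_idx))[seq_len(cfg$n_diverged)]
    acc[idx]
  } else {
    character(0)
  }

  # private alleles are planted, not drawn: each accession receives the
  # integer part of its group rate plus a Bernoulli remainder (a rate of
  # 0.5 gives 0 or 1 per accession)
  rate <- cfg$private_allele_rate[groups]
  n_private <- as.integer(floor(rate) + rbinom(cfg$n_accessions, 1,
                                               rate - floor(rate)))
  n_hidden <- rpois(cfg$n_accessions, cfg$hidden_allele_rate)
  n_sites <- n_common + sum(n_private) + sum(n_hidden)

  sites <- draw_site_keys(n_sites, amplicons, ref_seqs, cfg$indel_frac)
  sites$origin <- c(rep("common", n_common),
                    rep("private", sum(n_private)),
                    rep("hidden", sum(n_hidden)))
  sites$owner <- NA_character_
  sites$owner[sites$origin == "private"] <- rep(acc, times = n_private)
  sites$owner[sites$origin == "hidden"] <- rep(acc, times = n_hidden)
  sites$site_id <- sprintf("S%04d", seq_len(n_sites))
  sites <- sites[, c("site_id", "amplicon", "pos", "ref", "alt",
                     "origin", "owner")]

  freq_rows <- vector("list", 3)

  # common sites: carrier accessions drawn at a site-specific accession
  # frequency; carried alleles segregate at (mostly low) Beta frequencies
  common_ids <- sites$site_id[sites$origin == "common"]
  if (length(common_ids) > 0) {
    carrier_af <- rbeta(length(common_ids), cfg$carrier_af_shape[1],
                        cfg$carrier_af_shape[2])
    rows <- map2(common_ids, carrier_af, function(sid, af) {
      is_carrier <- runif(cfg$n_accessions) < af
      # shared variants are carried by at least two accessions; variants
      # confined to a single accession are planted via the private class
      while (sum(is_carrier) < min(2L, cfg$n_accessions)) {
        is_carrier[sample.int(cfg$n_accessions, 1)] <- TRUE
      }
      carriers <- acc[is_carrier]
      f <- rbeta(length(carriers), cfg$common_vaf_shape[1],
                 cfg$common_vaf_shape[2])
      # diverged accessions are fixed alternate at most common sites
      for (d in diverged) {
        if (runif(1) < cfg$diverged_site_frac) {
          if (!d %in% carriers) {
            carriers <- c(carriers, d)
            f <- c(f, 1)
          } else {
            f[carriers == d] <- 1
          }
        }
      }
      tibble(accession = carriers, site_id = sid, target_freq = f)
    })
    freq_rows[[1]] <- list_rbind(rows)
  }

  private_sites <- sites[sites$origin == "private", ]
  if (nrow(private_sites) > 0) {
    grp <- accessions$group[match(private_sites$owner, accessions$accession)]
    shapes <- cfg$private_vaf_shape[grp]
    freq_rows[[2]] <- tibble(
      accession = private_sites$owner,
      site_id = private_sites$site_id,
      target_freq = map_dbl(shapes, ~ rbeta(1, .x[1], .x[2]))
    )
  }

  hidden_sites <- sites[sites$origin == "hidden", ]
  if (nrow(hidden_sites) > 0) {
    freq_rows[[3]] <- tibble(
      accession = hidden_sites$owner,
      site_id = hidden_sites$site_id,
      target_freq = NA_real_  # forced single heterozygote below
    )
  }

  freq <- list_rbind(freq_rows[!vapply(freq_rows, is.null, logical(1))])

  gt <- t(vapply(seq_len(nrow(freq)), function(i) {
    if (is.na(freq$target_freq[i])) {
      c(cfg$n_plants - 1L, 1L, 0L)  # exactly one heterozygous plant
    } else if (freq$target_freq[i] >= 1) {
      c(0L, 0L, cfg$n_plants)
    } else {
      hw_counts(cfg$n_plants, freq$target_freq[i])
    }
  }, integer(3)))
  freq$n_ref_hom <- gt[, 1]
  freq$n_het <- gt[, 2]
  freq$n_alt_hom <- gt[, 3]
  freq$true_freq <- (freq$n_het + 2 * freq$n_alt_hom) / (2 * cfg$n_plants)
  freq$target_freq <- NULL
  # alleles lost in the sampled plants are not segregating in the pool
  freq <- freq[freq$true_freq > 0, ]
  # drop sites lost from every pool
  sites <- sites[sites$site_id %in% freq$site_id, ]

  structure(
    list(
      config = cfg,
      accessions = accessions,
      diverged = diverged,
      sites = as_tibble(sites),
      freq = as_tibble(freq),
      ref_seqs = ref_seqs,
      models = default_gene_models(ref_seqs)
    ),
    class = "pool_truth"
  )
}

# Distinct, non-overlapping variant keys over the amplicon panel.
draw_site_keys <- function(n_sites, amplicons, ref_seqs, indel_frac) {
  len <- nchar(ref_seqs[[1]])
  # leave 2 bp at each end so indel keys stay inside the amplicon
  slots <- expand.grid(amplicon = amplicons, pos = 3:(len - 2),
                       stringsAsFactors = FALSE)
  if (n_sites > nrow(slots)) {
    abort("simulation requests more variant sites than available positions")
  }
  pick <- slots[sample.int(nrow(slots), n_sites), ]
  is_indel <- runif(n_sites) < indel_frac
  ref <- character(n_sites)
  alt <- character(n_sites)
  for (i in seq_len(n_sites)) {
    seq_i <- ref_seqs[[pick$amplicon[i]]]
    base <- substr(seq_i, pick$pos[i], pick$pos[i])
    if (!is_indel[i]) {
      ref[i] <- base
      alt[i] <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
    } else if (runif(1) < 0.5) {  # insertion after pos
      ref[i] <- base
      alt[i] <- paste0(base, sample(c("A", "C", "G", "T"), 1))
    } else {  # 1-bp deletion of pos+1
      ref[i] <- substr(seq_i, pick$pos[i], pick$pos[i] + 1)
      alt[i] <- base
    }
  }
  tibble(amplicon = pick$amplicon, pos = as.integer(pick$pos),
         ref = ref, alt = alt)
}

# One plus-strand coding exon per amplicon, covering the central two thirds,
# trimmed to whole codons.
default_gene_models <- function(ref_seqs) {
  map(names(ref_seqs), function(a) {
    len <- nchar(ref_seqs[[a]])
    start <- max(1L, floor(len / 6))
    width <- len - 2 * start + 1
    width <- width - width %% 3
    gene_model(amplicon = a, strand = "+",
               exons = tibble(start = start, end = start + width - 1L),
               ref_seq = ref_seqs[[a]])
  }) |>
    setNames(names(ref_seqs))
}

#' @export
print.pool_truth <- function(x, ...) {
  cat("<pool_truth> ", nrow(x$accessions), " accessions, ",
      nrow(x$sites), " segregating sites (",
      sum(x$sites$origin == "common"), " common, ",
      sum(x$sites$origin == "private"), " private, ",
      sum(x$sites$origin == "hidden"), " hidden)\n", sep = "")
  invisible(x)
}

#' Expand pool genotype counts to per-plant genotypes
#'
#' Plants within a pool are exchangeable, so the simulator stores genotype
#' counts per accession and site; this helper materialises one row per plant
#' with alternate-allele dosage 0/1/2 when an individual-plant table is
#' needed (e.g. to emulate CAPS genotyping of single plants).
#'
#' @param truth A [simulate_truth()] result.
#' @param site_ids Optional subset of site ids.
#' @return A tibble with columns `accession`, `site_id`, `plant`, `dosage`.
#' @export
expand_genotypes <- function(truth, site_ids = NULL) {
  stopifnot(inherits(truth, "pool_truth"))
  fr <- truth$freq
  if (!is.null(site_ids)) fr <- fr[fr$site_id %in% site_ids, ]
  n <- truth$config$n_plants
  list_rbind(pmap(fr[, c("accession", "site_id", "n_ref_hom", "n_het",
                         "n_alt_hom")],
                  function(accession, site_id, n_ref_hom, n_het, n_alt_hom) {
                    tibble(accession = accession, site_id = site_id,
                           plant = seq_len(n),
                           dosage = rep(c(0L, 1L, 2L),
                                        c(n_ref_hom, n_het, n_alt_hom)))
                  }))
}

#' Sample pooled read counts from a truth set
#'
#' Per accession and segregating site, draws a sequencing depth from a
#' log-normal distribution truncated to `[coverage_min, coverage_max]` and
#' alternate-read counts from `Binomial(depth, f (1 - e) + (1 - f) e)`,
#' where `f` is the true pool frequency and `e` the per-base error rate.
#' Accessions that do not carry an allele (`f = 0`) still accumulate
#' alternate reads at the error rate, which is what downstream calling has
#' to reject.
#'
#' @param truth A [simulate_truth()] result.
#' @param config Simulation configuration; defaults to the one stored in
#'   `truth`.
#' @return A tibble (one row per accession x site) with the variant key,
#'   `true_freq`, `depth_ref`, `depth_alt` and `depth`.
#' @export
sample_read_counts <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "pool_truth"))
  validate_sim_config(config)
  with_seed(stage_seed(config$seed, "counts"), {
    grid <- tidyr::expand_grid(accession = truth$accessions$accession,
                               site_id = truth$sites$site_id)
    grid <- left_join(grid,
                      truth$freq[, c("accession", "site_id", "true_freq")],
                      by = c("accession", "site_id"))
    grid$true_freq[is.na(grid$true_freq)] <- 0
    grid <- left_join(grid, truth$sites[, c("site_id", "amplicon", "pos",
                                            "ref", "alt")],
                      by = "site_id")
    n <- nrow(grid)
    depth <- rtrunc_lnorm(n, config$coverage_mean, config$coverage_min,
                          config$coverage_max)
    p_alt <- grid$true_freq * (1 - config$error_rate) +
      (1 - grid$true_freq) * config$error_rate
    alt <- rbinom(n, depth, p_alt)
    grid$depth_alt <- alt
    grid$depth_ref <- depth - alt
    grid$depth <- depth
    grid[, c("accession", "site_id", "amplicon", "pos", "ref", "alt",
             "true_freq", "depth_ref", "depth_alt", "depth")]
  })
}

# Log-normal depths with the requested mean, truncated by rejection.
rtrunc_lnorm <- function(n, mean, lo, hi) {
  sdlog <- 0.45
  meanlog <- log(mean) - sdlog^2 / 2
  out <- round(rlnorm(n, meanlog, sdlog))
  bad <- which(out < lo | out > hi)
  guard <- 0
  while (length(bad) > 0 && guard < 100) {
    out[bad] <- round(rlnorm(length(bad), meanlog, sdlog))
    bad <- bad[out[bad] < lo | out[bad] > hi]
    guard <- guard + 1
  }
  if (length(bad) > 0) out[bad] <- pmin(pmax(out[bad], lo), hi)
  as.integer(out)
}

#' Describe an emulated variant caller
#'
#' A caller profile is a minimal stand-in for the behavioural differences
#' between pooled variant callers: each applies its own minimum
#' alternate-read and minimum-frequency thresholds to the same read counts,
#' so emitted call sets overlap but differ.
#'
#' @param name Caller label (e.g. `"gatk_like"`).
#' @param min_alt_reads Minimum alternate reads to report a sample call.
#' @param min_vaf Minimum alternate-read fraction to report a sample call.
#' @return A `caller_profile` object.
#' @export
caller_profile <- function(name, min_alt_reads = 20, min_vaf = 0.0026) {
  stopifnot(is.character(name), length(name) == 1,
            min_alt_reads >= 0, min_vaf >= 0, min_vaf <= 1)
  structure(list(name = name, min_alt_reads = min_alt_reads,
                 min_vaf = min_vaf),
            class = "caller_profile")
}

#' Three default caller profiles
#'
#' Thresholds chosen so the three call sets overlap strongly but differ at
#' low-frequency sites, emulating a permissive haplotype-based caller, a
#' conservative frequentist caller, and an intermediate pooled caller.
#'
#' @return A named list of three [caller_profile()] objects.
#' @export
default_caller_profiles <- function() {
  list(
    gatk_like  = caller_profile("gatk_like",  min_alt_reads = 5,
                                min_vaf = 1 / 384),
    snver_like = caller_profile("snver_like", min_alt_reads = 25,
                                min_vaf = 1 / 128),
    crisp_like = caller_profile("crisp_like", min_alt_reads = 10,
                                min_vaf = 1 / 256)
  )
}

#' Write an emulated caller VCF from pooled read counts
#'
#' Applies a caller profile to a read-count table and writes a multi-sample
#' VCF 4.2 file with per-accession `AD` (ref,alt allelic depths) and `DP`
#' fields. Accessions failing the profile at a site are reported with zero
#' alternate depth (uncalled); sites failing in every accession are omitted.
#'
#' @param counts A [sample_read_counts()] table.
#' @param profile A [caller_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
emit_caller_vcf <- function(counts, profile, path) {
  stopifnot(inherits(profile, "caller_profile"))
  vaf <- ifelse(counts$depth > 0, counts$depth_alt / counts$depth, 0)
  called <- counts$depth_alt >= profile$min_alt_reads & vaf >= profile$min_vaf
  counts$ad_alt <- ifelse(called, counts$depth_alt, 0L)
  keep_sites <- unique(counts$site_id[called])

  samples <- sort(unique(counts$accession))
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##source=poolvaf_", profile$name),
    "##INFO=<ID=NS,Number=1,Type=Integer,Description=\"Number of called pools\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  if (length(keep_sites) > 0) {
    sub <- counts[counts$site_id %in% keep_sites, ]
    sub <- arrange(sub, .data$amplicon, .data$pos, .data$alt)
    per_site <- split(sub, factor(sub$site_id, levels = unique(sub$site_id)))
    lines <- vapply(per_site, function(d) {
      d <- d[match(samples, d$accession), ]
      ns <- sum(d$ad_alt > 0)
      fmt <- paste0(d$depth - d$ad_alt, ",", d$ad_alt, ":", d$depth)
      paste(c(d$amplicon[1], d$pos[1], ".", d$ref[1], d$alt[1], ".", "PASS",
              paste0("NS=", ns), "AD:DP", fmt), collapse = "\t")
    }, character(1))
    writeLines(lines, con)
  }
  invisible(path)
}
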