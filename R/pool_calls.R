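#' Variant allele frequency from allelic depths
#'
#' The within-pool variant allele frequency (VAF) is the fraction of reads
#' supporting the alternate allele: `depth_alt / (depth_ref + depth_alt)`.
#' Zero total depth yields `NA` — a site with no data, which is distinct
#' from an observed VAF of 0.
#'
#' @param depth_ref,depth_alt Nonnegative read counts (vectorised).
#' @return A numeric vector of VAFs in `[0, 1]`, `NA` where depth is zero.
#' @export
#' @examples
#' compute_vaf(50, 50)       # 0.5
#' compute_vaf(191, 1)       # 1/192, one heterozygote in a pool of 96
compute_vaf <- function(depth_ref, depth_alt) {
  if (any(depth_ref < 0 | depth_alt < 0, na.rm = TRUE)) {
    abort("depths must be nonnegative")
  }
  total <- depth_ref + depth_alt
  out <- ifelse(total > 0, depth_alt / total, NA_real_)
  if (anyNA(out)) {
    warn("zero total depth at some sites: VAF set to NA (missing, not 0)")
  }
  out
}

#' Fraction of positions with enough depth to support a rare variant
#'
#' A position can support a variant present at frequency `target_freq` with
#' at least `min_supporting_reads` reads when its depth is at least
#' `min_supporting_reads / target_freq` (e.g. 400x for 20 reads at 5%).
#'
#' @param depths Per-position read depths.
#' @param min_supporting_reads Required reads on the variant allele.
#' @param target_freq Variant frequency to be supported.
#' @return Fraction of positions passing, in `[0, 1]`.
#' @export
coverage_qc <- function(depths, min_supporting_reads = 20, target_freq = 0.05) {
  if (length(depths) == 0) abort("`depths` must be nonempty")
  if (target_freq <= 0 || target_freq > 1) abort("target_freq must be in (0, 1]")
  mean(depths >= min_supporting_reads / target_freq)
}

#' Call pooled variants from read counts
#'
#' A stand-in pooled caller: a site is called in an accession when the
#' alternate-read count reaches `min_alt_reads` and an exact one-sided
#' binomial test rejects the hypothesis that alternate reads arise from
#' sequencing error alone (`depth_alt ~ Binomial(depth, error_rate)`) at
#' level `alpha`. The exact tail is used rather than a normal approximation
#' so small counts are handled correctly. The default `alpha` is small
#' because every accession x position pair in a deep amplicon experiment is
#' implicitly tested.
#'
#' @param counts A read-count table ([sample_read_counts()] or compatible:
#'   columns `accession`, `amplicon`, `pos`, `ref`, `alt`, `depth_ref`,
#'   `depth_alt`).
#' @param min_alt_reads Minimum alternate reads.
#' @param error_rate Assumed per-base error probability.
#' @param alpha Significance level of the binomial error test.
#' @return A tibble of called accession x site records with `vaf` and the
#'   binomial `p_error` tail probability.
#' @export
call_pooled_variants <- function(counts, min_alt_reads = 20,
                                 error_rate = 0.001, alpha = 1e-6) {
  depth <- counts$depth_ref + counts$depth_alt
  p_tail <- pbinom(counts$depth_alt - 1, depth, error_rate,
                   lower.tail = FALSE)
  called <- counts$depth_alt >= min_alt_reads & p_tail < alpha & depth > 0
  out <- counts[called, ]
  out$vaf <- compute_vaf(out$depth_ref, out$depth_alt)
  out$p_error <- p_tail[called]
  as_tibble(out)
}

#' Normalize variant keys
#'
#' Trims the shared suffix, then the shared prefix, of ref/alt allele pairs
#' (keeping at least one base of each) and shifts the position by the
#' trimmed prefix, so equivalent records from different callers share one
#' key. Normalisation is idempotent.
#'
#' @param calls A tibble with `pos`, `ref`, `alt` columns.
#' @return The tibble with normalised `pos`, `ref`, `alt`.
#' @export
normalize_keys <- function(calls) {
  pos <- calls$pos
  ref <- calls$ref
  alt <- calls$alt
  if (any(ref == alt)) abort("ref and alt alleles must differ")
  for (i in which(nchar(ref) > 1 | nchar(alt) > 1)) {
    r <- strsplit(ref[i], "")[[1]]
    a <- strsplit(alt[i], "")[[1]]
    # shared suffix
    while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    # shared prefix
    off <- 0
    while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]
      a <- a[-1]
      off <- off + 1
    }
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
    pos[i] <- pos[i] + off
  }
  calls$pos <- pos
  calls$ref <- ref
  calls$alt <- alt
  calls
}

#' Intersect call sets from multiple callers
#'
#' Returns the variants whose normalised key (`amplicon`, `pos`, `ref`,
#' `alt`) appears in every input call set. Per-accession VAFs from each
#' caller are retained side by side (long format, `caller` column), since
#' callers agree on variant identity more than on frequency.
#'
#' @param call_sets A named list of call-set tibbles (each with the key
#'   columns plus `accession` and `vaf`).
#' @return A tibble of common variants, one row per caller x accession x
#'   variant, with a `caller` column.
#' @export
consensus_calls <- function(call_sets) {
  stopifnot(is.list(call_sets), length(call_sets) >= 2)
  if (is.null(names(call_sets)) || any(names(call_sets) == "")) {
    names(call_sets) <- paste0("caller", seq_along(call_sets))
  }
  key_cols <- c("amplicon", "pos", "ref", "alt")
  call_sets <- map(call_sets, normalize_keys)
  amps <- map(call_sets, ~ unique(.x$amplicon))
  if (length(Reduce(intersect, amps)) == 0 &&
      any(vapply(call_sets, nrow, integer(1)) > 0)) {
    abort("call sets share no amplicon names: mismatched namespaces?")
  }
  keys <- map(call_sets, ~ distinct(.x[, key_cols]))
  common <- Reduce(function(x, y) inner_join(x, y, by = key_cols), keys)
  out <- imap(call_sets, function(cs, nm) {
    cs <- semi_join(cs, common, by = key_cols)
    cs$caller <- nm
    cs
  })
  arrange(list_rbind(out), .data$amplicon, .data$pos, .data$alt,
          .data$caller, .data$accession)
}

#' Build an accessions-by-variants VAF table
#'
#' Pivots a (single-caller) call set into the central VariantTable: one row
#' per variant, one VAF column per accession, 0 where not called.
#'
#' @param calls A call-set tibble (`amplicon`, `pos`, `ref`, `alt`,
#'   `accession`, `vaf`).
#' @return A tibble with key columns followed by one numeric column per
#'   accession.
#' @export
variant_table <- function(calls) {
  stopifnot(all(c("amplicon", "pos", "ref", "alt", "accession", "vaf")
                %in% names(calls)))
  pivot_wider(calls[, c("amplicon", "pos", "ref", "alt", "accession", "vaf")],
              names_from = "accession", values_from = "vaf",
              values_fill = 0, values_fn = max) |>
    arrange(.data$amplicon, .data$pos, .data$alt)
}

#' Per-variant summaries of a VAF table
#'
#' For each variant: mean VAF over carrying accessions (VAF > 0), maximum
#' VAF, number of carrying accessions, and whether the variant is private
#' (carried by exactly one accession).
#'
#' @param vtab A [variant_table()] (key columns + per-accession VAFs).
#' @return A tibble with `mean_vaf`, `max_vaf`, `n_accessions`, `private`
#'   per variant.
#' @export
summarize_variants <- function(vtab) {
  key_cols <- c("amplicon", "pos", "ref", "alt")
  m <- as.matrix(vtab[, setdiff(names(vtab), key_cols)])
  carriers <- m > 0
  n_acc <- rowSums(carriers)
  mean_vaf <- ifelse(n_acc > 0, rowSums(m) / pmax(n_acc, 1), NA_real_)
  out <- vtab[, key_cols]
  out$mean_vaf <- mean_vaf
  out$max_vaf <- apply(m, 1, max)
  out$n_accessions <- as.integer(n_acc)
  out$private <- n_acc == 1
  out
}

#' Cumulative percentage of variants by VAF
#'
#' The overlay curve of a VAF scatter: the percentage of variants whose
#' summary VAF is at or below each value, evaluated at the observed VAFs
#' (so e.g. "75% of variants have a VAF of 0.05 or lower" can be read off).
#'
#' @param summary A [summarize_variants()] table.
#' @param stat Which per-variant statistic to accumulate (`"mean_vaf"` or
#'   `"max_vaf"`).
#' @return A tibble with `vaf` and `cum_pct` (0-100), sorted by `vaf`.
#' @export
vaf_cumulative_curve <- function(summary, stat = "mean_vaf") {
  v <- sort(summary[[stat]])
  tibble(vaf = v, cum_pct = 100 * seq_along(v) / length(v))
}

#' Read a pooled multi-sample VCF into a call set
#'
#' Reads a VCF 4.2 file, decomposes multi-allelic records into biallelic
#' keys, normalises keys, and computes per-accession VAFs from the `AD`
#' field (alternate depth over total); when `AD` is absent, falls back to
#' the alternate-allele count in `GT` divided by the ploidy. Samples with
#' zero alternate depth are omitted (uncalled).
#'
#' @param path VCF file path.
#' @return A call-set tibble: `amplicon`, `pos`, `ref`, `alt`, `accession`,
#'   `depth_ref`, `depth_alt`, `vaf`.
#' @export
read_pool_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (!is.null(fix) && is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  if (is.null(fix) || nrow(fix) == 0) {
    return(tibble(amplicon = character(), pos = integer(),
                  ref = character(), alt = character(),
                  accession = character(), depth_ref = integer(),
                  depth_alt = integer(), vaf = double()))
  }
  gt <- v@gt
  samples <- colnames(gt)[-1]
  fmt_keys <- strsplit(gt[, 1], ":")
  has_ad <- vapply(fmt_keys, function(k) "AD" %in% k, logical(1))

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    fields <- strsplit(gt[i, -1], ":")
    keys <- fmt_keys[[i]]
    for (k in seq_along(alts)) {
      if (has_ad[i]) {
        ad <- map(fields, ~ suppressWarnings(
          as.integer(strsplit(.x[match("AD", keys)], ",")[[1]])))
        dref <- map_int(ad, ~ .x[1] %||% NA_integer_)
        dalt <- map_int(ad, function(x) {
          if (length(x) >= k + 1) x[k + 1] else NA_integer_
        })
      } else if ("GT" %in% keys) {
        gts <- map_chr(fields, ~ .x[match("GT", keys)])
        alleles <- strsplit(gts, "[/|]")
        dalt <- map_int(alleles, ~ sum(.x == as.character(k)))
        dref <- map_int(alleles, ~ sum(.x != "." )) - dalt
      } else {
        abort(paste0("record ", i, " in ", path, " has neither AD nor GT"))
      }
      total <- dref + dalt
      keep <- which(!is.na(dalt) & dalt > 0 & total > 0)
      if (length(keep) == 0) next
      rows[[length(rows) + 1]] <- tibble(
        amplicon = unname(fix[i, "CHROM"]),
        pos = as.integer(fix[i, "POS"]),
        ref = unname(fix[i, "REF"]),
        alt = alts[k],
        accession = unname(samples[keep]),
        depth_ref = unname(dref[keep]),
        depth_alt = unname(dalt[keep]),
        vaf = unname(dalt[keep] / total[keep])
      )
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(tibble(amplicon = character(), pos = integer(),
                  ref = character(), alt = character(),
                  accession = character(), depth_ref = integer(),
                  depth_alt = integer(), vaf = double()))
  }
  normalize_keys(arrange(list_rbind(rows), .data$amplicon, .data$pos,
                         .data$alt, .data$accession))
}
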