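#' Two-part Wilcoxon test for zero-inflated samples
#'
#' Compares two zero-inflated samples (here, per-accession VAF vectors over
#' a common variant set) by combining a binomial part and a rank part, after
#' Lachenbruch's two-part construction:
#' `B` is the pooled-variance two-proportion z-statistic comparing the
#' fractions of zeros, `W` is the tie-corrected normal-standardised
#' Wilcoxon rank-sum statistic on the nonzero values, and `X2 = B^2 + W^2`
#' is referred to a chi-square distribution with 2 degrees of freedom. When
#' exactly one part is computable (no zeros in either sample, or no nonzero
#' values in one of them), `X2` is that part's square on 1 df. When both
#' parts are degenerate the test is flagged and `p = 1`.
#'
#' @param x,y Numeric vectors of VAFs (zeros included).
#' @param alpha Significance level for the rejection flag.
#' @return A `two_part_wilcoxon` object (see [tidy()] for a one-row tibble
#'   with `statistic`, `df`, `p_value`, `z_zero`, `z_nonzero`, `reject`).
#' @export
#' @examples
#' set.seed(1)
#' x <- c(rep(0, 40), rbeta(60, 1, 4))
#' y <- c(rep(0, 60), rbeta(40, 1, 4))
#' tidy(two_part_wilcoxon(x, y))
two_part_wilcoxon <- function(x, y, alpha = 0.05) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be nonempty")
  n1 <- length(x)
  n2 <- length(y)
  z1 <- sum(x == 0)
  z2 <- sum(y == 0)

  # binomial part: pooled two-proportion z on the zero fractions
  p_pool <- (z1 + z2) / (n1 + n2)
  b_ok <- p_pool > 0 && p_pool < 1
  z_zero <- if (b_ok) {
    (z1 / n1 - z2 / n2) / sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  } else {
    NA_real_
  }

  # rank part: tie-corrected normal approximation on the nonzero values
  xx <- x[x != 0]
  yy <- y[y != 0]
  m <- length(xx)
  n <- length(yy)
  w_ok <- m > 0 && n > 0
  z_nonzero <- NA_real_
  if (w_ok) {
    r <- rank(c(xx, yy))
    ties <- table(c(xx, yy))
    N <- m + n
    var_w <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (var_w <= 0) {
      w_ok <- FALSE  # all nonzero values identical
    } else {
      w_stat <- sum(r[seq_len(m)])
      z_nonzero <- (w_stat - m * (N + 1) / 2) / sqrt(var_w)
    }
  }

  if (!b_ok && !w_ok) {
    res <- list(statistic = 0, df = NA_integer_, p_value = 1,
                z_zero = z_zero, z_nonzero = z_nonzero,
                degenerate = TRUE, reject = FALSE, alpha = alpha)
    return(structure(res, class = "two_part_wilcoxon"))
  }
  stat <- sum(c(if (b_ok) z_zero^2, if (w_ok) z_nonzero^2))
  df <- b_ok + w_ok
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(statistic = stat, df = as.integer(df), p_value = p,
                 z_zero = z_zero, z_nonzero = z_nonzero,
                 degenerate = FALSE, reject = p < alpha, alpha = alpha),
            class = "two_part_wilcoxon")
}

#' @export
print.two_part_wilcoxon <- function(x, ...) {
  cat("Two-part Wilcoxon test\n",
      "  X2 = ", signif(x$statistic, 4), " on ", x$df, " df, p = ",
      signif(x$p_value, 4), if (x$degenerate) "  (degenerate)" else "",
      "\n", sep = "")
  invisible(x)
}

#' @rdname two_part_wilcoxon
#' @param x A `two_part_wilcoxon` object.
#' @param ... Unused.
#' @method tidy two_part_wilcoxon
#' @export
tidy.two_part_wilcoxon <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         z_zero = x$z_zero, z_nonzero = x$z_nonzero,
         degenerate = x$degenerate, reject = x$reject)
}

#' Pairwise two-part Wilcoxon significance matrix
#'
#' Applies [two_part_wilcoxon()] to every unordered pair of accessions and
#' records a 1 where the VAF distributions differ at level `alpha`. No
#' multiplicity correction is applied by default (raw per-pair decisions);
#' `correct = "bonferroni"` divides `alpha` by the number of pairs.
#'
#' @param vafs A named list of equal-length VAF vectors, or a matrix with
#'   accessions in rows.
#' @param alpha Significance level.
#' @param correct `"none"` (default) or `"bonferroni"`.
#' @return A binary symmetric `signif_matrix` matrix with zero diagonal and
#'   attributes `alpha` and `p_values` (the symmetric p-value matrix).
#' @export
pairwise_significance <- function(vafs, alpha = 0.05, correct = c("none", "bonferroni")) {
  correct <- match.arg(correct)
  if (is.matrix(vafs)) {
    vafs <- setNames(lapply(seq_len(nrow(vafs)), function(i) vafs[i, ]),
                     rownames(vafs) %||% paste0("acc", seq_len(nrow(vafs))))
  }
  k <- length(vafs)
  if (k < 2) abort("need at least two accessions")
  labs <- names(vafs)
  m <- matrix(0L, k, k, dimnames = list(labs, labs))
  pm <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  diag(pm) <- 1
  n_pairs <- k * (k - 1) / 2
  a <- if (correct == "bonferroni") alpha / n_pairs else alpha
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      res <- two_part_wilcoxon(vafs[[i]], vafs[[j]], alpha = a)
      m[i, j] <- m[j, i] <- as.integer(res$reject)
      pm[i, j] <- pm[j, i] <- res$p_value
    }
  }
  structure(m, alpha = alpha, correct = correct, p_values = pm,
            class = c("signif_matrix", class(m)))
}

#' Cluster accessions on a binary significance matrix
#'
#' Treats the 0/1 matrix as a dissimilarity matrix and clusters it
#' agglomeratively with complete linkage. Flat clusters are cut just below
#' height 1, so accessions whose distributions were never called different
#' from one another share a cluster.
#'
#' @param m A [pairwise_significance()] matrix.
#' @param cut_height Cut height for flat clusters (default 0.5).
#' @return A list with `dendrogram` (an `hclust`) and `clusters` (a tibble
#'   of accession and cluster id).
#' @export
cluster_significance_matrix <- function(m, cut_height = 0.5) {
  hc <- hclust(as.dist(m), method = "complete")
  cl <- cutree(hc, h = cut_height)
  list(dendrogram = hc,
       clusters = tibble(accession = names(cl), cluster = unname(cl)))
}

#' Per-accession VAF distribution summaries
#'
#' The numbers behind a strip/violin display of per-accession VAF
#' distributions: median and mean VAF, fraction of zeros, fraction of
#' values in `[0.3, 0.5]` (hybrid-like heterozygosity band) and at or above
#' 0.7 (near-fixed alternate alleles), plus a kernel-density grid over the
#' nonzero values for violin rendering.
#'
#' @param vafs A named list of VAF vectors or an accessions-by-variants
#'   matrix.
#' @param density_n Number of kernel-density grid points.
#' @return A tibble, one row per accession, with a nested `density`
#'   list-column of `(vaf, dens)` tibbles.
#' @export
vaf_distribution_summary <- function(vafs, density_n = 128) {
  if (is.matrix(vafs)) {
    vafs <- setNames(lapply(seq_len(nrow(vafs)), function(i) vafs[i, ]),
                     rownames(vafs) %||% paste0("acc", seq_len(nrow(vafs))))
  }
  list_rbind(imap(vafs, function(v, nm) {
    nz <- v[v != 0]
    dens <- if (length(nz) >= 2 && stats::sd(nz) > 0) {
      d <- density(nz, n = density_n, from = 0, to = 1)
      tibble(vaf = d$x, dens = d$y)
    } else {
      tibble(vaf = numeric(), dens = numeric())
    }
    tibble(accession = nm,
           median_vaf = median(v),
           mean_vaf = mean(v),
           frac_zero = mean(v == 0),
           frac_het_band = mean(v >= 0.3 & v <= 0.5),
           frac_high = mean(v >= 0.7),
           density = list(dens))
  }))
}
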