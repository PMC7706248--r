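#' Threshold settings for VAF-to-genotype conversion
#'
#' A threshold setting maps a pool VAF to a genotype-like score as if the
#' pool were a single diploid individual: `VAF < lower` scores 0 (reference
#' homozygote), `VAF >= upper` scores 1 (variant homozygote), and values in
#' `[lower, upper)` score 2 (heterozygote). The three named presets are
#' `(0.3, 0.7)`, `(0.4, 0.6)` and `(0.2, 0.8)`. A VAF exactly equal to
#' `lower` falls in the heterozygote band so the mapping is total on
#' `[0, 1]`.
#'
#' @param lower,upper Band bounds, `0 < lower < upper <= 1`.
#' @return A `threshold_setting` object.
#' @export
threshold_setting <- function(lower, upper) {
  if (!(lower > 0 && lower < upper && upper <= 1)) {
    abort("need 0 < lower < upper <= 1")
  }
  structure(list(lower = lower, upper = upper),
            class = "threshold_setting")
}

#' @rdname threshold_setting
#' @return `preset_thresholds()`: a named list of the three presets.
#' @export
preset_thresholds <- function() {
  list(t30_70 = threshold_setting(0.3, 0.7),
       t40_60 = threshold_setting(0.4, 0.6),
       t20_80 = threshold_setting(0.2, 0.8))
}

#' Convert VAF values to genotype scores
#'
#' @param vaf Numeric VAFs in `[0, 1]` (vector or matrix).
#' @param setting A [threshold_setting()].
#' @return Integer scores 0/1/2, same shape as `vaf`.
#' @export
#' @examples
#' vaf_to_genotype(c(0, 0.5, 0.7), threshold_setting(0.3, 0.7))  # 0 2 1
vaf_to_genotype <- function(vaf, setting) {
  stopifnot(inherits(setting, "threshold_setting"))
  if (any(vaf < 0 | vaf > 1, na.rm = TRUE)) abort("VAF out of [0, 1]")
  out <- ifelse(vaf < setting$lower, 0L,
                ifelse(vaf >= setting$upper, 1L, 2L))
  if (is.matrix(vaf)) {
    out <- matrix(out, nrow(vaf), ncol(vaf), dimnames = dimnames(vaf))
  }
  out
}

#' Euclidean distance between genotype-score rows
#'
#' @param genos An accessions-by-variants matrix of 0/1/2 scores.
#' @return A symmetric distance matrix.
#' @export
genotype_euclidean <- function(genos) {
  if (anyNA(genos)) abort("genotype matrix must be complete")
  as.matrix(dist(genos, method = "euclidean"))
}

#' Sensitivity of tree topology to the VAF genotype thresholds
#'
#' Converts a VAF matrix to genotype scores under each threshold setting,
#' computes Euclidean distances and a neighbor-joining tree per setting,
#' and reports pairwise Robinson-Foulds distances between the trees as the
#' topology-difference metric.
#'
#' @param freqs An accessions-by-variants VAF matrix
#'   ([frequency_matrix()]).
#' @param settings A named list of [threshold_setting()]s (default: the
#'   three presets).
#' @return A list with `trees` (named `phylo` list) and `rf` (a tibble of
#'   setting pairs and their Robinson-Foulds distance).
#' @export
threshold_sensitivity <- function(freqs, settings = preset_thresholds()) {
  stopifnot(length(settings) >= 2)
  trees <- map(settings, function(s) {
    neighbor_joining(genotype_euclidean(vaf_to_genotype(freqs, s)))
  })
  pairs <- utils::combn(names(settings), 2)
  rf <- tibble(
    setting1 = pairs[1, ],
    setting2 = pairs[2, ],
    rf_distance = map2_dbl_(pairs[1, ], pairs[2, ], function(a, b) {
      phangorn::RF.dist(trees[[a]], trees[[b]])
    })
  )
  list(trees = trees, rf = rf)
}

map2_dbl_ <- function(x, y, f) {
  vapply(seq_along(x), function(i) f(x[[i]], y[[i]]), numeric(1))
}
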