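#' Published CAPS/Sanger validation assays
#'
#' The bundled validation table of 16 variant x accession assays from the
#' rye deep-sampling study that motivated this package: per-caller
#' predicted VAFs (GATK / SNVer / CRISP), the observed allele frequency
#' from genotyping 6--27 individual plants, the number of plants and the
#' number of heterozygous individuals. Thirteen assays recovered the
#' variant (`vaf_obs > 0`).
#'
#' @return A tibble suitable for [caps_validation_report()].
#' @export
caps_validation_data <- function() {
  path <- system.file("extdata", "caps_validation.tsv", package = "poolvaf")
  as_tibble(read.delim(path, na.strings = "NA"))
}
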