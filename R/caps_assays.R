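#' Restriction enzymes
#'
#' `restriction_enzyme()` validates a name and IUPAC recognition sequence;
#' `default_enzymes()` returns the enzymes used in typical CAPS validation
#' panels (NotI, TaqI, MboI, MnlI, FokI).
#'
#' @param name Enzyme name.
#' @param site Recognition sequence (IUPAC codes allowed, length >= 4).
#' @return A `restriction_enzyme` object / a named list of them.
#' @export
restriction_enzyme <- function(name, site) {
  site <- toupper(site)
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  if (nchar(site) < 4) abort("recognition sequence must be >= 4 bp")
  if (!all(strsplit(site, "")[[1]] %in% iupac)) {
    abort("recognition sequence must use the IUPAC alphabet")
  }
  structure(list(name = name, site = site), class = "restriction_enzyme")
}

#' @rdname restriction_enzyme
#' @export
default_enzymes <- function() {
  list(
    NotI = restriction_enzyme("NotI", "GCGGCCGC"),
    TaqI = restriction_enzyme("TaqI", "TCGA"),
    MboI = restriction_enzyme("MboI", "GATC"),
    MnlI = restriction_enzyme("MnlI", "CCTC"),
    FokI = restriction_enzyme("FokI", "GGATG")
  )
}

#' Find restriction-enzyme recognition sites
#'
#' Matches the IUPAC-expanded recognition pattern on the forward strand and
#' the pattern's reverse complement (a site on the bottom strand reads as
#' the reverse complement on the top strand), deduplicating palindromic
#' matches. Positions are 1-based starts of the match on the forward
#' strand.
#'
#' @param sequence A DNA string over A/C/G/T.
#' @param enzyme A [restriction_enzyme()].
#' @return Sorted integer vector of 1-based match start positions.
#' @export
#' @examples
#' find_sites("AAGCGGCCGCTT", default_enzymes()$NotI)  # 3
find_sites <- function(sequence, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence)) {
    abort("sequence must contain only A/C/G/T")
  }
  subject <- Biostrings::DNAString(sequence)
  pat <- Biostrings::DNAString(enzyme$site)
  fwd <- Biostrings::start(Biostrings::matchPattern(pat, subject,
                                                    fixed = FALSE))
  rev <- Biostrings::start(
    Biostrings::matchPattern(Biostrings::reverseComplement(pat), subject,
                             fixed = FALSE))
  sort(unique(c(fwd, rev)))
}

# Fragment lengths when cutting at the first base of each site match.
digest_fragments <- function(sequence, enzyme) {
  sites <- find_sites(sequence, enzyme)
  len <- nchar(sequence)
  cuts <- setdiff(sites - 1L, 0L)
  as.integer(diff(c(0L, sort(cuts), len)))
}

apply_variant <- function(sequence, pos, ref, alt) {
  if (substr(sequence, pos, pos + nchar(ref) - 1) != ref) {
    abort(paste0("ref allele '", ref, "' does not match the amplicon at ",
                 pos))
  }
  paste0(substr(sequence, 1, pos - 1), alt,
         substr(sequence, pos + nchar(ref), nchar(sequence)))
}

#' Restriction-site gain/loss for a variant
#'
#' Applies the alternate allele to the amplicon (indels shift downstream
#' coordinates), re-scans both full allele sequences for the enzyme's
#' sites, and classifies the change as a site `gain`, `loss`, or `none`.
#' Returns predicted digestion fragment lengths for both alleles; fragment
#' boundaries fall at the first base of each site match, so lengths are
#' approximate to within the site length but distinguish alleles, which is
#' all a CAPS gel needs.
#'
#' @param amplicon Amplicon reference sequence.
#' @param pos,ref,alt The variant (1-based, `ref` must match the amplicon).
#' @param enzyme A [restriction_enzyme()].
#' @return A list with `change` (`"gain"`/`"loss"`/`"none"`), `ref_sites`,
#'   `alt_sites` (positions) and `ref_fragments`, `alt_fragments`
#'   (ordered lengths summing to each allele's length).
#' @export
site_change <- function(amplicon, pos, ref, alt, enzyme) {
  amplicon <- toupper(amplicon)
  alt_seq <- apply_variant(amplicon, pos, ref, alt)
  ref_sites <- find_sites(amplicon, enzyme)
  alt_sites <- find_sites(alt_seq, enzyme)
  change <- if (length(alt_sites) > length(ref_sites)) {
    "gain"
  } else if (length(alt_sites) < length(ref_sites)) {
    "loss"
  } else {
    "none"
  }
  list(change = change,
       ref_sites = ref_sites, alt_sites = alt_sites,
       ref_fragments = digest_fragments(amplicon, enzyme),
       alt_fragments = digest_fragments(alt_seq, enzyme))
}

#' Screen a variant against a panel of enzymes
#'
#' @param amplicon Amplicon reference sequence.
#' @param pos,ref,alt The variant.
#' @param enzymes A named list of [restriction_enzyme()]s.
#' @return A tibble with one row per enzyme whose site count changes
#'   (`change` of `gain` or `loss`), with fragment patterns nested.
#' @export
design_caps <- function(amplicon, pos, ref, alt,
                        enzymes = default_enzymes()) {
  rows <- imap(enzymes, function(e, nm) {
    sc <- site_change(amplicon, pos, ref, alt, e)
    tibble(enzyme = nm, change = sc$change,
           n_ref_sites = length(sc$ref_sites),
           n_alt_sites = length(sc$alt_sites),
           ref_fragments = list(sc$ref_fragments),
           alt_fragments = list(sc$alt_fragments))
  })
  filter(list_rbind(rows), .data$change != "none")
}

#' Observed allele frequency from per-plant genotype counts
#'
#' The frequency of the variant allele among `n` individually genotyped
#' plants, each classified homozygous reference (RefRef), heterozygous
#' (RefAlt) or homozygous variant (AltAlt):
#' `(RefAlt + 2 AltAlt) / (2 n)`. Reported to two decimals by convention in
#' validation tables; the full-precision value is returned.
#'
#' @param ref_ref,ref_alt,alt_alt Nonnegative genotype counts (vectorised).
#' @return Numeric observed frequency in `[0, 1]`.
#' @export
#' @examples
#' observed_frequency(20, 5, 0)   # 0.10
#' observed_frequency(11, 5, 0)   # 0.15625, i.e. 0.16 at two decimals
observed_frequency <- function(ref_ref, ref_alt, alt_alt) {
  if (any(c(ref_ref, ref_alt, alt_alt) < 0)) abort("counts must be nonnegative")
  n <- ref_ref + ref_alt + alt_alt
  if (any(n == 0)) abort("no plants genotyped (n = 0)")
  (ref_alt + 2 * alt_alt) / (2 * n)
}

#' Compare caller-predicted VAFs with an observed frequency
#'
#' @param predicted Named numeric vector of per-caller predicted VAFs.
#' @param observed Observed allele frequency ([observed_frequency()]).
#' @return A tibble with `caller`, `predicted`, `abs_dev` and a logical
#'   `closest` (ties are all flagged), sorted by deviation.
#' @export
#' @examples
#' compare_predicted_observed(
#'   c(gatk = 0.880, snver = 0.587, crisp = 0.819), 0.79)
compare_predicted_observed <- function(predicted, observed) {
  if (length(predicted) < 1) abort("need at least one caller prediction")
  if (is.null(names(predicted))) {
    names(predicted) <- paste0("caller", seq_along(predicted))
  }
  dev <- abs(predicted - observed)
  tibble(caller = names(predicted), predicted = unname(predicted),
         observed = observed, abs_dev = unname(dev),
         closest = dev == min(dev)) |>
    arrange(.data$abs_dev)
}

#' CAPS/Sanger validation report over many assays
#'
#' For a table of validation assays (one row per variant x accession with
#' per-caller predicted VAFs and the observed frequency), computes the
#' per-caller absolute deviation and the closest caller per recovered
#' assay (observed > 0), plus the tally of closest-caller wins.
#'
#' @param assays A tibble with columns `vaf_obs` and one `vaf_<caller>`
#'   column per caller.
#' @return A list with `per_assay` (input plus `closest_caller`) and
#'   `tally` (closest-caller counts over recovered assays; ties contribute
#'   to every tied caller).
#' @export
caps_validation_report <- function(assays) {
  pred_cols <- grep("^vaf_(?!obs)", names(assays), value = TRUE, perl = TRUE)
  if (length(pred_cols) == 0) abort("no vaf_<caller> prediction columns")
  callers <- sub("^vaf_", "", pred_cols)
  closest <- map(seq_len(nrow(assays)), function(i) {
    preds <- setNames(as.numeric(assays[i, pred_cols]), callers)
    cmp <- compare_predicted_observed(preds, assays$vaf_obs[i])
    cmp$caller[cmp$closest]
  })
  assays$closest_caller <- map_chr(closest, paste, collapse = ",")
  recovered <- assays$vaf_obs > 0
  tally <- table(factor(unlist(closest[recovered]), levels = callers))
  list(per_assay = assays,
       tally = tibble(caller = names(tally), n_closest = as.integer(tally)))
}
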