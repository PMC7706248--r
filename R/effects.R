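#' Define a simple amplicon gene model
#'
#' A minimal gene model sufficient for coding-effect classification: the
#' amplicon reference sequence, the strand of the coding sequence, ordered
#' non-overlapping exon (coding) intervals in 1-based amplicon coordinates,
#' and the phase of the first coding base (0/1/2, for amplicons that
#' truncate a gene mid-codon).
#'
#' @param amplicon Amplicon identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons A data frame with `start`, `end` (1-based, inclusive).
#' @param ref_seq Reference sequence of the amplicon (A/C/G/T).
#' @param cds_phase Number of bases of the first exon completing an
#'   upstream codon (0, 1 or 2), counted along the coding strand.
#' @return A `gene_model` object.
#' @export
gene_model <- function(amplicon, strand, exons, ref_seq, cds_phase = 0L) {
  exons <- as_tibble(exons)
  stopifnot(strand %in% c("+", "-"),
            all(c("start", "end") %in% names(exons)),
            cds_phase %in% 0:2)
  exons <- arrange(exons, .data$start)
  if (any(exons$start > exons$end)) abort("exon start > end")
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    abort("exons must be non-overlapping")
  }
  if (max(exons$end) > nchar(ref_seq)) abort("exon beyond amplicon end")
  if (!grepl("^[ACGT]+$", toupper(ref_seq))) {
    abort("ref_seq must contain only A/C/G/T")
  }
  structure(list(amplicon = amplicon, strand = strand, exons = exons,
                 ref_seq = toupper(ref_seq),
                 cds_phase = as.integer(cds_phase)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$amplicon, " (", x$strand, " strand), ",
      nrow(x$exons), " exon(s), ", nchar(x$ref_seq), " bp\n", sep = "")
  invisible(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# genomic positions of the coding sequence in translation order
cds_positions <- function(model) {
  pos <- unlist(map2(model$exons$start, model$exons$end, seq))
  if (model$strand == "-") pos <- rev(pos)
  pos
}

#' Classify coding effects of variants
#'
#' Classifies each variant against a gene model into one of `silent`,
#' `missense`, `nonsense`, `intronic`, `frameshift_indel`, `inframe_indel`.
#' SNVs inside coding exons are translated with the standard genetic code
#' on the coding strand; indels inside exons are classified by the length
#' difference modulo 3; positions outside exons are `intronic`. Variants
#' whose reference allele spans an exon-intron boundary are classified
#' `intronic` with a warning. Errors if a ref allele disagrees with the
#' model's reference sequence.
#'
#' @param keys A tibble of variant keys (`amplicon`, `pos`, `ref`, `alt`);
#'   extra columns are carried through.
#' @param models A single [gene_model()] or a named list of them (one per
#'   amplicon).
#' @return `keys` with an `effect` character column appended.
#' @export
annotate_variants <- function(keys, models) {
  if (inherits(models, "gene_model")) {
    models <- setNames(list(models), models$amplicon)
  }
  keys$effect <- vapply(seq_len(nrow(keys)), function(i) {
    m <- models[[keys$amplicon[i]]]
    if (is.null(m)) abort(paste0("no gene model for amplicon ",
                                 keys$amplicon[i]))
    annotate_one(keys$pos[i], keys$ref[i], keys$alt[i], m)
  }, character(1))
  keys
}

annotate_one <- function(pos, ref, alt, model) {
  seq_chars <- strsplit(model$ref_seq, "")[[1]]
  span <- pos:(pos + nchar(ref) - 1)
  if (max(span) > length(seq_chars)) abort("variant beyond amplicon end")
  if (paste(seq_chars[span], collapse = "") != ref) {
    abort(paste0("ref allele '", ref, "' at ", model$amplicon, ":", pos,
                 " disagrees with the reference sequence"))
  }
  in_exon <- vapply(span, function(p) {
    any(p >= model$exons$start & p <= model$exons$end)
  }, logical(1))
  if (!any(in_exon)) return("intronic")
  if (!all(in_exon)) {
    warn(paste0("variant at ", model$amplicon, ":", pos,
                " spans an exon boundary; classified intronic"))
    return("intronic")
  }
  if (nchar(ref) != nchar(alt)) {
    shift <- abs(nchar(ref) - nchar(alt))
    return(if (shift %% 3 == 0) "inframe_indel" else "frameshift_indel")
  }
  # SNV (nchar == 1 by key normalization)
  cpos <- cds_positions(model)
  i <- match(pos, cpos)
  if (is.na(i)) return("intronic")
  i <- i - model$cds_phase
  if (i < 1) return("intronic")  # partial upstream codon
  codon_idx <- (i - 1) %/% 3
  codon_pos <- (i - 1) %% 3 + 1
  codon_sites <- cpos[model$cds_phase + codon_idx * 3 + 1:3]
  if (anyNA(codon_sites)) return("intronic")  # partial trailing codon
  # codon_sites are already in coding order (descending genomic positions on
  # the minus strand), so only a per-base complement is needed there
  ref_codon <- paste(seq_chars[codon_sites], collapse = "")
  alt_chars <- seq_chars
  alt_chars[pos] <- alt
  alt_codon <- paste(alt_chars[codon_sites], collapse = "")
  if (model$strand == "-") {
    ref_codon <- chartr("ACGT", "TGCA", ref_codon)
    alt_codon <- chartr("ACGT", "TGCA", alt_codon)
  }
  code <- Biostrings::GENETIC_CODE
  aa_ref <- code[[ref_codon]]
  aa_alt <- code[[alt_codon]]
  if (aa_ref == aa_alt) return("silent")
  if (aa_alt == "*") return("nonsense")
  "missense"
}

#' All recognised effect classes
#' @return Character vector of the effect enumeration.
#' @export
effect_classes <- function() {
  c("silent", "missense", "nonsense", "intronic",
    "frameshift_indel", "inframe_indel")
}

#' Tabulate effect classes, optionally with a deleterious flag
#'
#' Counts variants per effect class. Deleteriousness prediction requires an
#' external protein-level tool; when a logical `deleterious` column is
#' present (externally supplied), counts are also split by it.
#'
#' @param annotated An [annotate_variants()] result.
#' @return A tibble of counts per effect (and per deleterious flag when
#'   available).
#' @export
effect_summary <- function(annotated) {
  stopifnot("effect" %in% names(annotated))
  grp <- if ("deleterious" %in% names(annotated)) {
    c("effect", "deleterious")
  } else {
    "effect"
  }
  count(annotated, across(dplyr::all_of(grp)), name = "n_variants")
}
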