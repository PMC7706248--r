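#' Run the pooled-VAF pipeline end to end on simulated data
#'
#' Orchestrates the full analysis on a seeded synthetic experiment:
#' simulate truth and read counts, emit three emulated caller VCFs, ingest
#' them, intersect the call sets, classify coding effects, summarise
#' variants, compute Nei's distance with a neighbor-joining tree and PCoA,
#' tabulate private alleles by germplasm group, build the pairwise two-part
#' Wilcoxon significance matrix with its clustering, and run the
#' genotype-score threshold sensitivity analysis. All tabular outputs are
#' written as TSV (trees as Newick) under `out_dir` with fixed column
#' orders, together with a JSON-free plain-text run manifest of per-stage
#' record counts. Deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing). `NULL` skips all
#'   file output and returns results only.
#' @param profiles Caller profiles ([default_caller_profiles()]).
#' @param alpha Significance level of the pairwise two-part test.
#' @param consensus_caller Which caller's VAFs feed the population-genetic
#'   stages (first profile by default, the permissive one).
#' @return A list with every intermediate and final result (`truth`,
#'   `counts`, `call_sets`, `consensus`, `vtab`, `summary`, `effects`,
#'   `nei`, `tree`, `pcoa`, `private`, `signif`, `clusters`,
#'   `distributions`, `sensitivity`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         profiles = default_caller_profiles(),
                         alpha = 0.05,
                         consensus_caller = names(profiles)[1]) {
  t0 <- Sys.time()
  truth <- simulate_truth(config)
  counts <- sample_read_counts(truth)

  tmp <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    vcf_dir <- out_dir
  } else {
    tmp <- tempfile("poolvaf_vcf_")
    dir.create(tmp)
    vcf_dir <- tmp
  }
  on.exit(if (!is.null(tmp)) unlink(tmp, recursive = TRUE), add = TRUE)

  call_sets <- imap(profiles, function(p, nm) {
    path <- file.path(vcf_dir, paste0("calls_", nm, ".vcf"))
    emit_caller_vcf(counts, p, path)
    read_pool_vcf(path)
  })

  consensus <- consensus_calls(call_sets)
  focal <- filter(consensus, .data$caller == consensus_caller)
  vtab <- variant_table(focal)
  vsum <- summarize_variants(vtab)
  effects <- annotate_variants(vsum, truth$models)

  freqs <- frequency_matrix(vtab)
  nei <- nei_distance(freqs)
  nei_capped <- cap_infinite(nei)
  tree <- neighbor_joining(nei_capped)
  ord <- pcoa_ordination(nei_capped)
  private <- private_allele_stats(vtab, truth$accessions)

  signif <- pairwise_significance(freqs, alpha = alpha)
  clusters <- cluster_significance_matrix(signif)
  distributions <- vaf_distribution_summary(freqs)
  sensitivity <- threshold_sensitivity(freqs)

  manifest <- tibble(
    stage = c("simulate", "counts", names(call_sets), "consensus",
              "variants", "accessions"),
    n_records = c(nrow(truth$sites), nrow(counts),
                  vapply(call_sets, nrow, integer(1)),
                  nrow(vtab) * length(call_sets), nrow(vtab),
                  nrow(truth$accessions))
  )

  res <- list(truth = truth, counts = counts, call_sets = call_sets,
              consensus = consensus, vtab = vtab, summary = vsum,
              effects = effects, nei = nei, tree = tree, pcoa = ord,
              private = private, signif = signif, clusters = clusters,
              distributions = distributions, sensitivity = sensitivity,
              manifest = manifest)

  if (!is.null(out_dir)) {
    write_tsv_table(truth$accessions, file.path(out_dir, "accessions.tsv"))
    write_tsv_table(truth$sites, file.path(out_dir, "truth_sites.tsv"))
    write_tsv_table(truth$freq, file.path(out_dir, "truth_freq.tsv"))
    write_tsv_table(vtab, file.path(out_dir, "variant_table.tsv"))
    write_tsv_table(effects, file.path(out_dir, "variant_summary.tsv"))
    write_distance_matrix(nei, file.path(out_dir, "nei_distance.tsv"))
    write_distance_matrix(nei_capped, file.path(out_dir, "nei_distance.phy"),
                          format = "phylip")
    write_newick(tree, file.path(out_dir, "nj_tree.nwk"))
    write_tsv_table(tidy(ord), file.path(out_dir, "pcoa_coordinates.tsv"))
    write_tsv_table(tibble(axis = seq_along(ord$eigenvalues),
                           eigenvalue = ord$eigenvalues),
                    file.path(out_dir, "pcoa_eigenvalues.tsv"))
    write_tsv_table(private$per_accession,
                    file.path(out_dir, "private_per_accession.tsv"))
    write_tsv_table(private$per_group,
                    file.path(out_dir, "private_per_group.tsv"))
    write_tsv_table(as.data.frame(unclass(signif)) |>
                      (\(d) cbind(accession = rownames(signif), d))(),
                    file.path(out_dir, "significance_matrix.tsv"))
    write_tsv_table(clusters$clusters, file.path(out_dir, "vaf_clusters.tsv"))
    write_tsv_table(distributions,
                    file.path(out_dir, "vaf_distributions.tsv"))
    for (nm in names(sensitivity$trees)) {
      write_newick(sensitivity$trees[[nm]],
                   file.path(out_dir, paste0("nj_genoscore_", nm, ".nwk")))
    }
    write_tsv_table(sensitivity$rf, file.path(out_dir, "threshold_rf.tsv"))
    manifest$wall_seconds <- as.numeric(difftime(Sys.time(), t0,
                                                 units = "secs"))
    write_tsv_table(manifest, file.path(out_dir, "run_manifest.tsv"))
  }
  res
}
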