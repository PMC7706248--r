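test_that("compute_vaf handles depths, symmetry and missingness", {
  expect_equal(compute_vaf(50, 50), 0.5)
  expect_equal(compute_vaf(191, 1), 1 / 192)
  expect_warning(v <- compute_vaf(0, 0), "missing")
  expect_true(is.na(v))
  expect_error(compute_vaf(-1, 5), "nonnegative")
  # monotone in depth_alt at fixed total depth
  alt <- 0:400
  v <- compute_vaf(400 - alt, alt)
  expect_true(all(diff(v) > 0))
})

test_that("the stand-in caller applies count and binomial-tail thresholds", {
  counts <- tibble::tibble(
    accession = "X", amplicon = "AMP1", pos = c(10L, 20L, 30L),
    ref = "A", alt = "G",
    depth_ref = c(10000L, 380L, 390L), depth_alt = c(0L, 20L, 10L))
  counts$depth <- counts$depth_ref + counts$depth_alt

  # zero alt reads: never called
  none <- call_pooled_variants(counts, min_alt_reads = 1, alpha = 0.05)
  expect_false(10L %in% none$pos)

  # depth 400, alt 20, error 0.001: the classic 5% depth-rule boundary case
  called <- call_pooled_variants(counts, min_alt_reads = 20,
                                 error_rate = 0.001, alpha = 0.05)
  expect_true(20L %in% called$pos)
  expect_equal(called$vaf[called$pos == 20L], 0.05)
  # exact binomial tail oracle by direct summation of the tail
  oracle <- sum(dbinom(20:400, 400, 0.001))
  expect_equal(called$p_error[called$pos == 20L], oracle, tolerance = 1e-12)
  expect_lt(oracle, 1e-20)

  # min_alt_reads excludes the 10-read site even though its tail is small
  expect_false(30L %in% called$pos)
})

test_that("coverage QC returns the fraction of positions passing", {
  expect_equal(coverage_qc(c(400, 399, 1000), 20, 0.05), 2 / 3)
  expect_equal(coverage_qc(c(0, 0, 0), 20, 0.05), 0)
  expect_equal(coverage_qc(rep(14000, 50), 20, 0.05), 1)
  expect_error(coverage_qc(numeric(0)), "nonempty")
})

test_that("key normalization trims affixes, shifts positions, idempotent", {
  raw <- tibble::tibble(amplicon = "A", pos = c(10L, 5L, 7L),
                        ref = c("CTT", "TAC", "G"),
                        alt = c("CT", "TGC", "GA"))
  norm <- normalize_keys(raw)
  expect_equal(norm$ref, c("CT", "A", "G"))
  expect_equal(norm$alt, c("C", "G", "GA"))
  expect_equal(norm$pos, c(10L, 6L, 7L))
  expect_identical(normalize_keys(norm), norm)
  expect_error(normalize_keys(tibble::tibble(pos = 1L, ref = "A", alt = "A")),
               "differ")
})

test_that("consensus keeps keys present in every call set", {
  mk <- function(pos, vaf = 0.1) {
    tibble::tibble(amplicon = "AMP1", pos = as.integer(pos), ref = "A",
                   alt = "G", accession = "X", vaf = vaf)
  }
  s1 <- dplyr::bind_rows(mk(1), mk(2))
  s2 <- dplyr::bind_rows(mk(2), mk(3))
  s3 <- mk(2)
  out <- consensus_calls(list(a = s1, b = s2, c = s3))
  expect_setequal(unique(out$pos), 2L)
  expect_setequal(unique(out$caller), c("a", "b", "c"))

  # identical sets: identity on keys; order of inputs irrelevant
  same <- consensus_calls(list(s1, s1, s1))
  expect_setequal(unique(same$pos), c(1L, 2L))
  flip <- consensus_calls(list(c = s3, a = s1, b = s2))
  expect_setequal(unique(flip$pos), unique(out$pos))

  expect_error(
    consensus_calls(list(mk(1),
                         dplyr::mutate(mk(1), amplicon = "OTHER"))),
    "namespace")
})

test_that("nested caller thresholds produce nested call sets", {
  truth <- simulate_truth(small_config(seed = 31))
  counts <- sample_read_counts(truth)
  sets <- lapply(c(5, 120, 40), function(m) {
    call_pooled_variants(counts, min_alt_reads = m)
  })
  sizes <- vapply(sets, nrow, integer(1))
  expect_true(sizes[2] < sizes[3] & sizes[3] < sizes[1])
  common <- consensus_calls(setNames(sets, c("loose", "tight", "mid")))
  keys <- dplyr::distinct(common[, c("amplicon", "pos", "ref", "alt")])
  tight_keys <- dplyr::distinct(sets[[2]][, c("amplicon", "pos", "ref", "alt")])
  expect_equal(nrow(keys), nrow(tight_keys))
})

test_that("variant summaries report carrier means, max, private flags", {
  calls <- tibble::tibble(
    amplicon = "AMP1", pos = c(1L, 1L, 2L), ref = "A", alt = "G",
    accession = c("X", "Y", "X"), vaf = c(0.2, 0.4, 0.3))
  vtab <- variant_table(calls)
  s <- summarize_variants(vtab)
  expect_equal(s$mean_vaf, c(0.3, 0.3))
  expect_equal(s$max_vaf, c(0.4, 0.3))
  expect_equal(s$n_accessions, c(2L, 1L))
  expect_equal(s$private, c(FALSE, TRUE))
  expect_true(all(s$max_vaf >= s$mean_vaf))
})

test_that("cumulative VAF curve reaches planted quantiles", {
  # 75 variants at VAF <= 0.05, 25 above
  s <- tibble::tibble(amplicon = "A", pos = 1:100, ref = "A", alt = "G",
                      mean_vaf = c(runif(75, 0.001, 0.05),
                                   runif(25, 0.2, 0.9)),
                      max_vaf = 1, n_accessions = 1L, private = TRUE)
  curve <- vaf_cumulative_curve(s)
  expect_equal(max(curve$cum_pct[curve$vaf <= 0.05]), 75)
})

test_that("multi-allelic VCF records decompose into normalized keys", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "AMP1\t10\t.\tA\tG,C\t.\tPASS\t.\tAD:DP\t90,10,0:100\t80,0,20:100",
    "AMP1\t20\t.\tCT\tC\t.\tPASS\t.\tAD:DP\t50,50:100\t100,0:100")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  calls <- read_pool_vcf(path)
  expect_equal(nrow(calls), 3)
  expect_setequal(paste(calls$pos, calls$ref, calls$alt),
                  c("10 A G", "10 A C", "20 CT C"))
  expect_equal(calls$vaf[calls$alt == "G"], 0.1)
  expect_equal(calls$vaf[calls$accession == "S1" & calls$pos == 20], 0.5)
})

test_that("GT genotype counts back VAF when AD is absent", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    paste0("AMP1\t5\t.\tA\tT\t.\tPASS\t.\tGT\t",
           paste(c(rep("0", 3), "1"), collapse = "/")))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  calls <- read_pool_vcf(path)
  expect_equal(calls$vaf, 0.25)  # 1 alt allele / ploidy 4
})
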