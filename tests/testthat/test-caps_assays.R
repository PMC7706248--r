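test_that("site scanning matches a sliding-window oracle on both strands", {
  enz <- default_enzymes()
  expect_equal(find_sites("AAGCGGCCGCTT", enz$NotI), 3L)
  expect_equal(find_sites("AAAAAA", enz$NotI), integer(0))
  # palindromic NotI site found once despite matching both strands
  expect_equal(length(find_sites("AAGCGGCCGCTT", enz$NotI)), 1L)
  # non-palindromic FokI: bottom-strand occurrence reported too
  expect_equal(find_sites("AAGGATGAA", enz$FokI), 3L)       # forward
  expect_equal(find_sites("AACATCCAA", enz$FokI), 3L)       # reverse strand
  # random sequences against the brute-force oracle for every enzyme
  set.seed(20)
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    for (e in enz) {
      expect_equal(find_sites(s, e), find_sites_oracle(s, e$site))
    }
  }
  # IUPAC-ambiguous recognition sequences expand correctly
  hinfi <- restriction_enzyme("HinfI", "GANTC")
  expect_equal(find_sites("AAGACTCAA", hinfi), 3L)
  expect_equal(find_sites("AAGACTCAA", hinfi),
               find_sites_oracle("AAGACTCAA", "GANTC"))
  expect_error(find_sites("ACGTN", enz$NotI), "A/C/G/T")
  expect_error(restriction_enzyme("bad", "GCGX"), "IUPAC")
  expect_error(restriction_enzyme("short", "GC"), ">= 4")
})

test_that("variant-induced site gain and loss classify correctly", {
  enz <- default_enzymes()
  amp <- paste0("AA", "GCGGCCGA", paste(rep("T", 12), collapse = ""))
  # SNV restoring the NotI site: gain
  sc <- site_change(amp, 10, "A", "C", enz$NotI)
  expect_equal(sc$change, "gain")
  expect_equal(length(sc$alt_sites), length(sc$ref_sites) + 1)
  expect_gt(length(sc$alt_fragments), length(sc$ref_fragments))
  # variant far from any site: no change, identical patterns
  sc2 <- site_change(amp, 15, "T", "A", enz$NotI)
  expect_equal(sc2$change, "none")
  expect_identical(sc2$ref_fragments, sc2$alt_fragments)
  # destroying a site: loss
  amp2 <- paste0("AA", "GCGGCCGC", paste(rep("T", 10), collapse = ""))
  sc3 <- site_change(amp2, 10, "C", "A", enz$NotI)
  expect_equal(sc3$change, "loss")
  # ref mismatch is an error
  expect_error(site_change(amp, 10, "G", "C", enz$NotI), "does not match")
})

test_that("fragment lengths always sum to the allele sequence length", {
  enz <- default_enzymes()
  # a 600 bp amplicon with one created MboI cut near position 200
  set.seed(22)
  body <- sample(c("A", "C", "T"), 600, replace = TRUE)  # no G: no GATC
  body[200:203] <- c("G", "A", "T", "G")                  # one SNV from a site
  body[204:206] <- c("T", "T", "A")                       # no accidental site
  amp <- paste(body, collapse = "")
  sc <- site_change(amp, 203, "G", "C", enz$MboI)
  expect_equal(sc$change, "gain")
  expect_equal(length(sc$alt_fragments), 2)
  expect_equal(sum(sc$alt_fragments), 600)
  expect_equal(sort(sc$alt_fragments), c(199, 401))
  # property: for random sequences, variants and enzymes, lengths conserve
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 250, replace = TRUE),
               collapse = "")
    pos <- sample(5:240, 1)
    ref <- substr(s, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    for (e in default_enzymes()) {
      sc <- site_change(s, pos, ref, alt, e)
      expect_equal(sum(sc$ref_fragments), 250)
      expect_equal(sum(sc$alt_fragments), 250)
    }
  }
})

test_that("indel variants shift coordinates before re-scanning", {
  enz <- default_enzymes()
  amp <- paste0("AAAA", "TTTT", "GCGGCCGC", "TTTT")  # NotI at 9
  expect_equal(find_sites(amp, enz$NotI), 9L)
  # 2 bp deletion upstream shifts the site to 7 in the alt allele
  sc <- site_change(amp, 2, "AAA", "A", enz$NotI)
  expect_equal(sc$change, "none")
  expect_equal(sc$alt_sites, 7L)
  expect_equal(sum(sc$alt_fragments), nchar(amp) - 2)
  # insertion creating a site across the edit: AAGCGGCGC -> AAGCGGCCGC
  amp3 <- paste0("AAGCGGCGC", paste(rep("T", 8), collapse = ""))
  sc2 <- site_change(amp3, 6, "G", "GC", enz$NotI)
  expect_equal(sc2$change, "gain")
  expect_equal(sum(sc2$alt_fragments), nchar(amp3) + 1)
})

test_that("design_caps reports only discriminating enzymes", {
  amp <- paste0("AA", "GCGGCCGA", paste(rep("T", 12), collapse = ""))
  out <- design_caps(amp, 10, "A", "C")
  expect_true("NotI" %in% out$enzyme)
  expect_true(all(out$change != "none"))
})

test_that("observed frequency follows the genotype-count formula", {
  expect_equal(observed_frequency(20, 5, 0), 0.10)
  expect_equal(observed_frequency(0, 0, 10), 1)
  expect_equal(observed_frequency(11, 5, 0), 0.15625)
  expect_equal(round(observed_frequency(11, 5, 0), 2), 0.16)
  expect_error(observed_frequency(0, 0, 0), "n = 0")
  expect_error(observed_frequency(-1, 2, 0), "nonnegative")
  # bounds and boundary cases on a grid
  grid <- expand.grid(rr = 0:4, ra = 0:4, aa = 0:4)
  grid <- grid[rowSums(grid) > 0, ]
  f <- observed_frequency(grid$rr, grid$ra, grid$aa)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all((f == 0) == (grid$ra == 0 & grid$aa == 0)))
  expect_true(all((f == 1) == (grid$rr == 0 & grid$ra == 0)))
  # adding a heterozygote moves the frequency toward 1/2
  for (i in sample(nrow(grid), 50)) {
    f0 <- observed_frequency(grid$rr[i], grid$ra[i], grid$aa[i])
    f1 <- observed_frequency(grid$rr[i], grid$ra[i] + 1, grid$aa[i])
    if (f0 < 0.5) expect_gt(f1, f0) else expect_lte(f1, f0)
  }
})

test_that("predicted-vs-observed comparison finds the closest caller", {
  cmp <- compare_predicted_observed(
    c(gatk = 0.880, snver = 0.587, crisp = 0.819), 0.79)
  expect_equal(cmp$caller[cmp$closest], "crisp")
  expect_equal(min(cmp$abs_dev), 0.029, tolerance = 1e-12)
  # ties are all reported
  tie <- compare_predicted_observed(c(a = 0.5, b = 0.5), 0.4)
  expect_true(all(tie$closest))
  # single caller wins trivially
  one <- compare_predicted_observed(c(only = 0.3), 0.1)
  expect_true(one$closest)
})

test_that("the bundled validation table reproduces published tallies", {
  assays <- caps_validation_data()
  expect_equal(nrow(assays), 16)
  rep <- caps_validation_report(assays)
  tally <- setNames(rep$tally$n_closest, rep$tally$caller)
  expect_equal(tally[["gatk"]], 7L)
  expect_equal(tally[["snver"]], 2L)
  expect_equal(tally[["crisp"]], 4L)
  expect_equal(sum(assays$vaf_obs > 0), 13)
})
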