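# Shared fixtures built in code.

# A small, fast simulation: 12 accessions (4 wild / 4 landrace / 4 modern),
# 3 amplicons, one maximally diverged wild accession.
small_config <- function(seed = 101, n_amplicons = 3, ...) {
  sim_config(
    n_accessions = 12,
    n_amplicons = n_amplicons,
    group_props = c(wild = 4, landrace = 4, historic = 0, modern = 4) / 12,
    seed = seed,
    ...
  )
}

# Hand-built truth object for controlled read-count sampling: one accession,
# `n_sites` sites all at pool frequency `freq`.
fixed_truth <- function(freq, n_sites, config) {
  n <- config$n_plants
  n_alt <- round(freq * 2 * n)
  sites <- tibble::tibble(
    site_id = sprintf("S%04d", seq_len(n_sites)),
    amplicon = "AMP1",
    pos = seq_len(n_sites) + 2L,
    ref = "A", alt = "G",
    origin = "common", owner = NA_character_
  )
  freq_tab <- tibble::tibble(
    accession = "A1",
    site_id = sites$site_id,
    n_ref_hom = n - n_alt, n_het = 0L, n_alt_hom = 0L,
    true_freq = freq
  )
  # represent the frequency through heterozygotes when below 0.5
  if (n_alt <= n) {
    freq_tab$n_het <- n_alt
    freq_tab$n_ref_hom <- n - n_alt
  } else {
    freq_tab$n_alt_hom <- n_alt - n
    freq_tab$n_het <- 2L * n - n_alt
    freq_tab$n_ref_hom <- 0L
  }
  if (freq == 0) freq_tab <- freq_tab[0, ]
  structure(
    list(config = config,
         accessions = tibble::tibble(accession = "A1", group = "landrace"),
         diverged = character(0),
         sites = sites, freq = freq_tab,
         ref_seqs = NULL, models = NULL),
    class = "pool_truth"
  )
}

# Brute-force Nei distance: explicit per-locus summation over both alleles.
nei_oracle <- function(p_x, p_y) {
  jx <- 0; jy <- 0; jxy <- 0
  for (l in seq_along(p_x)) {
    fx <- c(p_x[l], 1 - p_x[l])
    fy <- c(p_y[l], 1 - p_y[l])
    jx <- jx + sum(fx^2)
    jy <- jy + sum(fy^2)
    jxy <- jxy + sum(fx * fy)
  }
  L <- length(p_x)
  -log((jxy / L) / sqrt((jx / L) * (jy / L)))
}

# Brute-force sliding-window site scan with manual IUPAC expansion.
iupac_match <- function(base, code) {
  expand <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
              S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT",
              H = "ACT", V = "ACG", N = "ACGT")
  grepl(base, expand[[code]], fixed = TRUE)
}

revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

find_sites_oracle <- function(sequence, site) {
  hits <- integer(0)
  for (pat in unique(c(site, revcomp_chr(site)))) {
    pchars <- strsplit(pat, "")[[1]]
    k <- length(pchars)
    for (i in seq_len(nchar(sequence) - k + 1)) {
      window <- strsplit(substr(sequence, i, i + k - 1), "")[[1]]
      if (all(mapply(iupac_match, window, pchars))) hits <- c(hits, i)
    }
  }
  sort(unique(hits))
}
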