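test_that("Nei distance matches the brute-force two-allele oracle", {
  # worked example: X = (1, 0), Y = (0.5, 0.5)
  f <- rbind(X = c(1, 0), Y = c(0.5, 0.5))
  d <- nei_distance(f)
  expect_equal(d["X", "Y"], -log(0.5 / sqrt(0.5)))
  expect_equal(d["X", "Y"], 0.34657359, tolerance = 1e-7)
  expect_equal(d["X", "Y"], nei_oracle(f[1, ], f[2, ]))

  # identical rows at distance zero
  f2 <- rbind(A = c(0.2, 0.7, 0.1), B = c(0.2, 0.7, 0.1))
  expect_equal(nei_distance(f2)["A", "B"], 0)

  # random matrices against the oracle, symmetry, zero diagonal
  set.seed(1)
  for (rep in 1:5) {
    f <- matrix(runif(4 * 7), 4, 7,
                dimnames = list(paste0("a", 1:4), NULL))
    d <- nei_distance(f)
    expect_equal(unclass(d), t(unclass(d)), ignore_attr = TRUE)
    expect_equal(unname(diag(d)), rep(0, 4))
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(d[i, j], nei_oracle(f[i, ], f[j, ]), tolerance = 1e-12)
    }
    # invariance under locus permutation
    d2 <- nei_distance(f[, sample(ncol(f))])
    expect_equal(unclass(d2), unclass(d), tolerance = 1e-12)
  }
})

test_that("disjoint alleles give a flagged infinite distance, cappable", {
  f <- rbind(X = 1, Y = 0)
  expect_warning(d <- nei_distance(f), "infinite")
  expect_true(is.infinite(d["X", "Y"]))
  f3 <- rbind(X = c(1, 1), Y = c(0, 0), Z = c(0.4, 0.4))
  expect_warning(d3 <- nei_distance(f3), "infinite")
  expect_warning(capped <- cap_infinite(d3), "capping")
  expect_equal(capped["X", "Y"], 10 * max(d3[is.finite(d3)]))
  expect_error(neighbor_joining(d3), "cap_infinite")
})

test_that("monomorphic loci shared by both accessions dilute the distance", {
  x <- c(0.9, 0.1)
  y <- c(0.2, 0.6)
  d_prev <- nei_distance(rbind(X = x, Y = y))["X", "Y"]
  for (k in 1:5) {
    x <- c(x, 0)
    y <- c(y, 0)
    d_new <- nei_distance(rbind(X = x, Y = y))["X", "Y"]
    expect_lt(d_new, d_prev)
    d_prev <- d_new
  }
})

test_that("neighbor joining recovers additive trees exactly", {
  # two taxa: one edge of the full distance
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- neighbor_joining(d2)
  expect_setequal(t2$tip.label, c("A", "B"))
  expect_equal(sum(t2$edge.length), 3)

  # additive 4-taxon matrix from tree ((A:1,B:2):1,(C:3,D:4):0)
  d4 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d4["A", "B"] <- d4["B", "A"] <- 3
  d4["A", "C"] <- d4["C", "A"] <- 5
  d4["A", "D"] <- d4["D", "A"] <- 6
  d4["B", "C"] <- d4["C", "B"] <- 6
  d4["B", "D"] <- d4["D", "B"] <- 7
  d4["C", "D"] <- d4["D", "C"] <- 7
  # four-point oracle: the true split pairs the two smallest of the three sums
  sums <- c(AB_CD = d4["A", "B"] + d4["C", "D"],
            AC_BD = d4["A", "C"] + d4["B", "D"],
            AD_BC = d4["A", "D"] + d4["B", "C"])
  expect_equal(names(which.min(sums)), "AB_CD")
  t4 <- neighbor_joining(d4)
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_equal(phangorn::RF.dist(t4, ref), 0)
  # exact branch lengths: path distances reproduce the input matrix
  coph <- cophenetic(t4)[rownames(d4), colnames(d4)]
  expect_equal(coph, d4, tolerance = 1e-10)

  # ultrametric 3 taxa: closed-form pendant lengths (dij + dik - djk) / 2
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- neighbor_joining(d3)
  bl <- tip_branch_lengths(t3)
  expect_equal(bl$branch_length[bl$accession == "A"], (2 + 4 - 4) / 2)
  expect_equal(bl$branch_length[bl$accession == "C"], (4 + 4 - 2) / 2)

  # random additive 5-taxon trees are reconstructed exactly
  set.seed(7)
  for (rep in 1:5) {
    tr <- ape::rtree(5, br = function(n) runif(n, 0.5, 2))
    tr$edge.length <- round(tr$edge.length, 3)
    dm <- cophenetic(tr)
    rec <- neighbor_joining(dm)
    expect_equal(phangorn::RF.dist(rec, ape::unroot(tr)), 0)
    expect_equal(cophenetic(rec)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-8)
  }
})

test_that("PCoA reconstructs Euclidean configurations", {
  # all distances zero: all coordinates zero
  d0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  p0 <- pcoa_ordination(d0)
  expect_true(all(p0$coordinates == 0))

  # collinear points: one positive eigenvalue, distances reproduced
  x <- c(0, 1, 2)
  dl <- as.matrix(dist(x))
  pl <- pcoa_ordination(dl)
  expect_equal(pl$n_positive, 1)
  expect_equal(as.matrix(dist(pl$coordinates)), dl, ignore_attr = TRUE,
               tolerance = 1e-10)

  # unit square: two equal positive eigenvalues
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  ps <- pcoa_ordination(as.matrix(dist(sq)))
  expect_equal(ps$n_positive, 2)
  expect_equal(ps$eigenvalues[1], ps$eigenvalues[2], tolerance = 1e-10)

  # random 6-point 3-D configurations to 1e-8
  set.seed(9)
  for (rep in 1:5) {
    pts <- matrix(rnorm(18), 6, 3)
    dm <- as.matrix(dist(pts))
    rownames(dm) <- colnames(dm) <- paste0("p", 1:6)
    rec <- pcoa_ordination(dm)
    expect_equal(as.matrix(dist(rec$coordinates)), dm, ignore_attr = TRUE,
                 tolerance = 1e-8)
  }
  g <- glance(pcoa_ordination(as.matrix(dist(sq))))
  expect_equal(g$n_axes, 2)
  expect_equal(g$var_axis1, 0.5)
})

test_that("private allele statistics recover planted group structure", {
  md <- tibble::tibble(accession = c("W1", "W2", "L1", "M1"),
                       group = c("wild", "wild", "landrace", "modern"))
  vtab <- tibble::tibble(
    amplicon = "AMP1", pos = 1:6, ref = "A", alt = "G",
    W1 = c(0.5, 0.4, 0, 0, 0.2, 0),
    W2 = c(0, 0, 0.6, 0, 0.2, 0),
    L1 = c(0, 0, 0, 0.1, 0, 0),
    M1 = c(0, 0, 0, 0, 0, 0))
  ps <- private_allele_stats(vtab, md)
  pa <- ps$per_accession
  expect_equal(pa$n_private[pa$accession == "W1"], 2L)
  expect_equal(pa$n_private[pa$accession == "M1"], 0L)
  pg <- ps$per_group
  expect_equal(pg$mean_private_per_accession[pg$group == "wild"], 1.5)
  expect_equal(pg$mean_private_per_accession[pg$group == "modern"], 0)
  expect_equal(pg$mean_vaf[pg$group == "wild"], mean(c(0.5, 0.4, 0.6)))
  # unknown accessions are rejected
  expect_error(private_allele_stats(vtab, md[-1, ]), "missing")
  # no private variants at all
  vt0 <- vtab
  vt0$M1 <- vt0$L1 <- vt0$W2 <- vt0$W1
  ps0 <- private_allele_stats(vt0, md)
  expect_true(all(ps0$per_accession$n_private == 0))
})
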