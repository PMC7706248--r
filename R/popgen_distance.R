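#' Frequency matrix from a variant table
#'
#' Converts a [variant_table()] into an accessions-by-loci matrix of allele
#' frequencies, treating each variant as a biallelic locus with alternate
#' frequency `p` (the pool VAF) and reference frequency `1 - p`. Uncalled
#' cells are 0 (monomorphic reference), the imputation used for distance
#' computation.
#'
#' @param vtab A [variant_table()].
#' @return A numeric matrix, accessions in rows, loci in columns.
#' @export
frequency_matrix <- function(vtab) {
  key_cols <- c("amplicon", "pos", "ref", "alt")
  m <- t(as.matrix(vtab[, setdiff(names(vtab), key_cols)]))
  colnames(m) <- paste0(vtab$amplicon, ":", vtab$pos, "_", vtab$ref, ">",
                        vtab$alt)
  if (any(m < 0 | m > 1, na.rm = TRUE)) abort("frequencies must lie in [0, 1]")
  if (anyNA(m)) {
    warn("missing frequencies imputed as 0 for distance computation")
    m[is.na(m)] <- 0
  }
  m
}

#' Nei's (1972) genetic distance from allele frequencies
#'
#' For each pair of accessions X, Y over biallelic loci with alternate
#' frequency `p` and reference frequency `q = 1 - p`:
#' `Jx = mean(p_x^2 + q_x^2)`, `Jy` likewise,
#' `Jxy = mean(p_x p_y + q_x q_y)`, and `D = -ln(Jxy / sqrt(Jx Jy))`.
#' `Jxy = 0` (completely disjoint alleles at every locus) gives an infinite
#' distance, flagged with a warning; see [cap_infinite()] before tree
#' building.
#'
#' @param freqs A [frequency_matrix()] (accessions x loci, values in
#'   `[0, 1]`).
#' @return A symmetric `nei_dist` matrix with zero diagonal.
#' @export
#' @examples
#' f <- rbind(X = c(1, 0), Y = c(0.5, 0.5))
#' nei_distance(f)  # -log(0.5 / sqrt(0.5)) = 0.3466
nei_distance <- function(freqs) {
  freqs <- as.matrix(freqs)
  if (nrow(freqs) < 2) abort("need at least two accessions")
  if (ncol(freqs) < 1) abort("need at least one locus")
  if (any(freqs < 0 | freqs > 1)) abort("frequencies must lie in [0, 1]")
  p <- freqs
  q <- 1 - freqs
  L <- ncol(p)
  j_self <- rowMeans(p^2 + q^2)
  j_cross <- (p %*% t(p) + q %*% t(q)) / L
  denom <- sqrt(outer(j_self, j_self))
  d <- -log(j_cross / denom)
  d[j_cross == 0] <- Inf
  diag(d) <- 0
  d <- (d + t(d)) / 2  # enforce exact symmetry against rounding
  diag(d) <- 0
  if (any(is.infinite(d))) {
    warn("some pairs share no alleles at any locus: infinite Nei distance")
  }
  structure(d, class = c("nei_dist", class(d)))
}

#' Cap infinite distances before tree building
#'
#' Replaces infinite entries by `factor` times the largest finite distance
#' (the exact infinities should be preserved in any exported table).
#'
#' @param dist A distance matrix.
#' @param factor Multiplier of the largest finite entry.
#' @return The matrix with infinities capped.
#' @export
cap_infinite <- function(dist, factor = 10) {
  if (!any(is.infinite(dist))) return(dist)
  mx <- max(dist[is.finite(dist)])
  warn(paste0("capping infinite distances at ", factor, " x max finite (",
              signif(mx * factor, 4), ")"))
  dist[is.infinite(dist)] <- mx * factor
  dist
}

#' Tidy a distance matrix into pair rows
#'
#' @param x A symmetric distance matrix (e.g. [nei_distance()]).
#' @param ... Unused.
#' @return A tibble with `item1`, `item2`, `distance` for each unordered
#'   pair.
#' @method tidy nei_dist
#' @export
tidy.nei_dist <- function(x, ...) {
  labs <- rownames(x) %||% as.character(seq_len(nrow(x)))
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(item1 = labs[idx[, 1]], item2 = labs[idx[, 2]],
         distance = x[idx])
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (Studier-Keppler Q criterion, as
#' implemented in \pkg{ape}); the two-taxon case (a single edge) is handled
#' directly. Negative branch lengths are retained by default; set
#' `clamp_negative = TRUE` to clamp them to zero. Infinite entries are an
#' error: apply [cap_infinite()] first.
#'
#' @param dist A symmetric finite distance matrix with labels.
#' @param clamp_negative Clamp negative branch lengths to zero?
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dist, clamp_negative = FALSE) {
  dist <- as.matrix(dist)
  if (any(is.infinite(dist))) {
    abort("distance matrix has infinite entries; apply cap_infinite() first")
  }
  if (nrow(dist) < 2) abort("need at least two taxa")
  if (is.null(rownames(dist))) {
    rownames(dist) <- colnames(dist) <- paste0("t", seq_len(nrow(dist)))
  }
  if (nrow(dist) == 2) {
    tree <- ape::read.tree(
      text = paste0("(", rownames(dist)[1], ":", dist[1, 2] / 2, ",",
                    rownames(dist)[2], ":", dist[1, 2] / 2, ");"))
  } else {
    tree <- ape::nj(as.dist(dist))
  }
  if (clamp_negative) tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Terminal branch lengths of a tree
#'
#' @param tree A `phylo` object.
#' @return A tibble with `accession` (tip label) and `branch_length` of the
#'   pendant edge, longest first.
#' @export
tip_branch_lengths <- function(tree) {
  tip_edges <- match(seq_along(tree$tip.label), tree$edge[, 2])
  tibble(accession = tree$tip.label,
         branch_length = tree$edge.length[tip_edges]) |>
    arrange(dplyr::desc(.data$branch_length))
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: Gower double-centering of the squared distance
#' matrix followed by eigendecomposition (via [stats::cmdscale()]).
#' Coordinates are returned only for positive eigenvalues (eigenvectors
#' scaled by the square root of the eigenvalue); negative eigenvalues are
#' reported but carry no coordinates.
#'
#' @param dist A symmetric finite distance matrix.
#' @return A `pool_pcoa` object: list with `eigenvalues` (all, descending)
#'   and `coordinates` (accessions x positive axes).
#' @export
pcoa_ordination <- function(dist) {
  dist <- as.matrix(dist)
  if (any(is.infinite(dist))) abort("infinite distances: cap them first")
  n <- nrow(dist)
  sc <- suppressWarnings(cmdscale(as.dist(dist), k = max(1, n - 1),
                                  eig = TRUE))
  eig <- sc$eig
  tol <- max(abs(eig)) * 1e-9
  pos <- which(eig > tol)
  coords <- sc$points[, seq_along(pos), drop = FALSE]
  if (length(pos) == 0) {
    coords <- matrix(0, n, 1, dimnames = list(rownames(dist), "Axis1"))
  } else {
    colnames(coords) <- paste0("Axis", seq_along(pos))
  }
  structure(list(eigenvalues = eig, coordinates = coords,
                 n_positive = length(pos)),
            class = "pool_pcoa")
}

#' @export
print.pool_pcoa <- function(x, ...) {
  cat("<pool_pcoa> ", nrow(x$coordinates), " accessions, ", x$n_positive,
      " positive axes\n  relative eigenvalues: ",
      paste(signif(head(x$eigenvalues, 3) / sum(pmax(x$eigenvalues, 0)), 3),
            collapse = ", "), " ...\n", sep = "")
  invisible(x)
}

#' @rdname pcoa_ordination
#' @param x A `pool_pcoa` object.
#' @param ... Unused.
#' @method tidy pool_pcoa
#' @export
tidy.pool_pcoa <- function(x, ...) {
  as_tibble(x$coordinates, rownames = "accession")
}

#' @rdname pcoa_ordination
#' @method glance pool_pcoa
#' @export
glance.pool_pcoa <- function(x, ...) {
  pos <- pmax(x$eigenvalues, 0)
  tibble(n_axes = x$n_positive,
         var_axis1 = pos[1] / sum(pos),
         var_axis2 = if (length(pos) > 1) pos[2] / sum(pos) else NA_real_,
         n_negative_eig = sum(x$eigenvalues < 0))
}

#' Private-allele counts by accession and germplasm group
#'
#' A private allele is a variant carried (VAF > 0) by exactly one accession
#' of the analysed set. Returns per-accession counts and per-group
#' summaries (mean count per accession, mean and median VAF of private
#' alleles).
#'
#' @param vtab A [variant_table()].
#' @param metadata A tibble with `accession` and `group` columns covering
#'   every accession column of `vtab`.
#' @return A list of two tibbles: `per_accession` and `per_group`.
#' @export
private_allele_stats <- function(vtab, metadata) {
  key_cols <- c("amplicon", "pos", "ref", "alt")
  acc <- setdiff(names(vtab), key_cols)
  missing_md <- setdiff(acc, metadata$accession)
  if (length(missing_md) > 0) {
    abort(paste0("accessions missing from metadata: ",
                 paste(missing_md, collapse = ", ")))
  }
  m <- as.matrix(vtab[, acc])
  carriers <- m > 0
  is_private <- rowSums(carriers) == 1
  owner <- ifelse(is_private, acc[max.col(carriers, ties.method = "first")],
                  NA_character_)
  priv <- tibble(accession = owner[is_private],
                 vaf = m[cbind(which(is_private),
                               max.col(carriers, ties.method = "first")[is_private])])
  per_acc <- left_join(metadata[metadata$accession %in% acc, ],
                       count(priv, .data$accession, name = "n_private"),
                       by = "accession")
  per_acc$n_private[is.na(per_acc$n_private)] <- 0L
  per_group <- priv |>
    left_join(metadata, by = "accession") |>
    group_by(.data$group) |>
    summarise(n_private = n(), mean_vaf = mean(.data$vaf),
              median_vaf = median(.data$vaf), .groups = "drop") |>
    left_join(count(per_acc, .data$group, name = "n_accessions"),
              by = "group") |>
    mutate(mean_private_per_accession = .data$n_private / .data$n_accessions)
  groups_no_priv <- setdiff(unique(per_acc$group), per_group$group)
  if (length(groups_no_priv) > 0) {
    per_group <- bind_rows(
      per_group,
      tibble(group = groups_no_priv, n_private = 0L, mean_vaf = NA_real_,
             median_vaf = NA_real_,
             n_accessions = map_int(groups_no_priv,
                                    ~ sum(per_acc$group == .x)),
             mean_private_per_accession = 0))
  }
  list(per_accession = arrange(per_acc, dplyr::desc(.data$n_private)),
       per_group = arrange(per_group,
                           dplyr::desc(.data$mean_private_per_accession)))
}
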