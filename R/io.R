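#' Read a multi-record FASTA file
#'
#' @param path FASTA file path.
#' @return A named character vector of uppercased sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA not found: ", path))
  s <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(s)), names(s))
}

#' Write amplicon sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write / read a Newick tree
#'
#' Thin wrappers over \pkg{ape}'s Newick serialisation, kept as the
#' package's fixed tree exchange format.
#'
#' @param tree A `phylo` object.
#' @param path File path.
#' @return `write_newick()`: `path` invisibly; `read_newick()`: a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Write a square distance matrix as TSV or PHYLIP
#'
#' @param dist A symmetric labelled matrix.
#' @param path Output path.
#' @param format `"tsv"` (labelled square TSV) or `"phylip"` (square
#'   PHYLIP).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dist, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  dist <- as.matrix(dist)
  if (format == "tsv") {
    df <- data.frame(accession = rownames(dist), dist, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "wt")
    on.exit(close(con), add = TRUE)
    writeLines(sprintf("%5d", nrow(dist)), con)
    labs <- formatC(substr(rownames(dist), 1, 10), width = 10, flag = "-")
    for (i in seq_len(nrow(dist))) {
      writeLines(paste0(labs[i],
                        paste(sprintf("%.6f", dist[i, ]), collapse = "  ")),
                 con)
    }
  }
  invisible(path)
}

#' Read a square distance matrix written by [write_distance_matrix()]
#'
#' @param path File path (TSV format).
#' @return A symmetric labelled matrix.
#' @export
read_distance_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}

#' Read accession metadata
#'
#' A tab-separated table with at least `accession` and `group` columns
#' (germplasm group: wild / landrace / historic / modern).
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_metadata <- function(path) {
  md <- as_tibble(read.delim(path))
  if (!all(c("accession", "group") %in% names(md))) {
    abort("metadata must have 'accession' and 'group' columns")
  }
  md
}

#' Read a restriction-enzyme table
#'
#' A TSV with columns `name` and `site` (IUPAC recognition sequence).
#'
#' @param path TSV file path.
#' @return A named list of [restriction_enzyme()]s.
#' @export
read_enzymes <- function(path) {
  df <- read.delim(path)
  if (!all(c("name", "site") %in% names(df))) {
    abort("enzyme table must have 'name' and 'site' columns")
  }
  setNames(map2(df$name, df$site, restriction_enzyme), df$name)
}

#' Write a tibble as TSV with fixed column order
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  x <- as.data.frame(x)
  list_cols <- vapply(x, is.list, logical(1))
  x <- x[, !list_cols, drop = FALSE]
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
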