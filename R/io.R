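#' Read a gene x sample count table from TSV
#'
#' Expects a header row of sample identifiers with gene identifiers in the
#' first column.  Entries must be non-negative integers; duplicated gene
#' or sample identifiers are rejected, and offending cells are named in
#' the error.
#'
#' @param path TSV file path.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("read_counts: file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("read_counts: need gene column plus >= 1 sample")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop("read_counts: duplicated gene identifiers: ",
         paste(utils::head(unique(genes[duplicated(genes)]), 5),
               collapse = ", "))
  if (anyDuplicated(names(df)[-1]))
    stop("read_counts: duplicated sample identifiers")
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(as.numeric(m))
  bad <- which(is.na(num) | num < 0 | num != round(num))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(m))
    stop(sprintf(
      "read_counts: non-count entry '%s' at gene %s, sample %s (line %d)",
      m[bad[1]], genes[rc[1]], colnames(m)[rc[2]], rc[1] + 1))
  }
  m <- matrix(as.integer(num), nrow = nrow(m),
              dimnames = list(genes, colnames(m)))
  m
}

#' Write a count table as TSV
#'
#' @param counts gene x sample matrix.
#' @param path output path.
#' @param gene_column name of the identifier column (default `gene`).
#' @export
write_counts <- function(counts, path, gene_column = "gene") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE)
  names(df)[1] <- gene_column
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pair two species' count tables through a 1:1 orthology map
#'
#' Keeps genes that are present in both count tables and uniquely mapped
#' (any identifier appearing more than once in either orthology column is
#' rejected), aligns the rows, and canonicalizes their order by the
#' species-A identifier.  Dropped counts are reported with a message.
#'
#' @param counts_a,counts_b gene x sample count matrices of the two
#'   species.
#' @param orthology data.frame whose first two columns are the gene
#'   identifiers in species A and B.
#' @return list with aligned `counts_a`, `counts_b` (equal row counts,
#'   rows correspond), and the retained `map`.
#' @export
pair_orthologues <- function(counts_a, counts_b, orthology) {
  stopifnot(is.data.frame(orthology), ncol(orthology) >= 2)
  map <- orthology[, 1:2]
  names(map) <- c("gene_a", "gene_b")
  dup <- duplicated(map$gene_a) | duplicated(map$gene_b) |
    duplicated(map$gene_a, fromLast = TRUE) |
    duplicated(map$gene_b, fromLast = TRUE)
  if (any(dup)) {
    stop(sprintf(
      "pair_orthologues: %d non-unique (many-to-many) orthology rows, e.g. %s - %s",
      sum(dup), map$gene_a[dup][1], map$gene_b[dup][1]))
  }
  present <- map$gene_a %in% rownames(counts_a) &
    map$gene_b %in% rownames(counts_b)
  if (sum(present) == 0) stop("pair_orthologues: no pair present in both tables")
  if (any(!present))
    message(sprintf("pair_orthologues: dropped %d pair(s) missing from a table",
                    sum(!present)))
  map <- map[present, , drop = FALSE]
  map <- map[order(map$gene_a), , drop = FALSE]
  list(counts_a = counts_a[map$gene_a, , drop = FALSE],
       counts_b = counts_b[map$gene_b, , drop = FALSE],
       map = map)
}
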