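#' Distance matrix under the three dendrogram metrics
#'
#' Distances between the rows of `data`: `1 - r` for the Pearson and
#' Spearman correlation metrics, or the standard Euclidean distance.
#' Correlation metrics require every row to be non-constant.
#'
#' @param data Numeric matrix or data frame, items in rows, features in
#'   columns; at least 2 rows.
#' @param metric `"pearson"`, `"euclidean"` or `"spearman"`.
#' @return A [stats::dist] object.
#' @export
distance_matrix <- function(data, metric = c("pearson", "euclidean", "spearman")) {
  metric <- match.arg(metric)
  m <- as.matrix(data)
  if (nrow(m) < 2) abort("Need at least 2 items (rows).")
  if (metric == "euclidean") return(dist(m, method = "euclidean"))
  const <- apply(m, 1, function(r) all(r == r[1]))
  if (any(const)) {
    lab <- rownames(m)[const]
    if (is.null(lab)) lab <- which(const)
    abort(paste0("Constant row(s) with a correlation metric: ",
                 paste(head(lab, 5), collapse = ", ")))
  }
  r <- cor(t(m), method = metric)
  as.dist(1 - r)
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering where the distance between clusters is the mean
#' of all pairwise item distances. Ties are broken deterministically by the
#' smallest original index pair (the behaviour of [stats::hclust()]).
#'
#' @param d A [stats::dist] object or a symmetric numeric matrix with zero
#'   diagonal.
#' @return An [stats::hclust] tree (`method = "average"`).
#' @export
hclust_average <- function(d) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d))) abort("Distance matrix must be symmetric.")
    d <- as.dist(d)
  }
  if (!inherits(d, "dist")) abort("`d` must be a dist object or symmetric matrix.")
  hclust(d, method = "average")
}

#' log2 RPKM expression matrix of a count table
#'
#' Per-gene, per-sample `log2(RPKM + pseudocount)` values, the input of the
#' expression-pattern dendrograms. The pseudocount keeps zero-RPKM genes
#' finite.
#'
#' @param table A [count_table()].
#' @param pseudo_rpkm Pseudocount added before the log, default 0.001.
#' @return Numeric matrix, genes in rows (named), the four samples in
#'   columns.
#' @export
expression_matrix <- function(table, pseudo_rpkm = 0.001) {
  stopifnot(inherits(table, "count_table"))
  lt <- library_totals(table)
  m <- vapply(sample_labels(), function(s) {
    log2(rpkm(table[[s]], lt[[s]], table$length) + pseudo_rpkm)
  }, numeric(nrow(table)))
  rownames(m) <- table$gene_id
  m
}

#' Chromosome-by-position incidence matrix of a gene set
#'
#' Counts genes per chromosome and per position-code bin, the input
#' reconstruction for chromosome-location dendrograms. Bin width is in
#' position-code units (the five-character locus field), default 1000.
#'
#' @param gene_id Character vector of gene identifiers.
#' @param bin_width Positive bin width, default 1000.
#' @return Integer matrix, chromosomes (all 22 labels incl. unknown) in
#'   rows, position bins in columns.
#' @export
chromosome_position_matrix <- function(gene_id, bin_width = 1000) {
  if (bin_width <= 0) abort("`bin_width` must be positive.")
  loc <- parse_gene_id(gene_id)
  bins <- floor(loc$position / bin_width)
  levels_bin <- seq(0, max(bins))
  tab <- table(factor(loc$chromosome, levels = bna_chromosomes()),
               factor(bins, levels = levels_bin))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab),
                              sprintf("bin%05d", as.integer(colnames(tab)))))
  m
}
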