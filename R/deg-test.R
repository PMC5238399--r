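#' RPKM expression value
#'
#' Reads per kilobase of gene per million mapped reads:
#' `1e9 * C / (N * L)` for `C` reads on a gene of length `L` bases in a
#' library of `N` uniquely mapped reads. Linear in `C`, inverse in `N` and
#' `L`, so values are comparable across genes and libraries.
#'
#' @param reads_on_gene Non-negative read counts `C` (vectorised).
#' @param total_mapped_reads Positive library total `N`.
#' @param gene_length_bases Positive gene length `L` in bases.
#' @return Numeric vector of RPKM values.
#' @examples
#' rpkm(10, 1e6, 1000) # 10
#' @export
rpkm <- function(reads_on_gene, total_mapped_reads, gene_length_bases) {
  if (any(reads_on_gene < 0)) abort("`reads_on_gene` must be non-negative.")
  if (any(total_mapped_reads <= 0)) abort("`total_mapped_reads` must be positive.")
  if (any(gene_length_bases <= 0)) abort("`gene_length_bases` must be positive.")
  1e9 * reads_on_gene / (total_mapped_reads * gene_length_bases)
}

#' Conditional term probability of the tag-count exact test
#'
#' Under the Poisson model for unambiguous clean-tag counts, the probability
#' of observing `y` tags of a gene in a library of total `N2` given `x` tags
#' in a library of total `N1`, with the gene expressed at the same
#' (unknown) rate in both, is
#' \deqn{p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
#'   \frac{(x+y)!}{x!\,y!\,(1 + N_2/N_1)^{x+y+1}}.}
#' Evaluated in log space via `lgamma` so counts of 1e4 and beyond do not
#' overflow. Equivalently, `y | x` is negative binomial with size `x + 1`
#' and success probability `N1 / (N1 + N2)`.
#'
#' @param y,x Non-negative tag counts (vectorised, recycled).
#' @param N1,N2 Positive library totals.
#' @param log Return the log probability? Default `FALSE`.
#' @return Probabilities in (0, 1].
#' @examples
#' ac_term_probability(0, 0, 1e6, 1e6) # 0.5
#' @export
ac_term_probability <- function(y, x, N1, N2, log = FALSE) {
  if (any(x < 0) || any(y < 0)) abort("Counts must be non-negative.")
  if (any(N1 <= 0) || any(N2 <= 0)) abort("Library totals must be positive.")
  r <- N2 / N1
  lp <- y * base::log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(r)
  if (log) lp else exp(lp)
}

# Lower equal-expression tail P(Y <= y | x) of the exact test, by stable
# log-space summation of the y + 1 conditional terms. Scalar helper.
ac_lower_tail <- function(x, y, N1, N2) {
  r <- N2 / N1
  lq <- base::log(r) - log1p(r) # log p2
  lt0 <- -(x + 1) * log1p(r)    # log p(0 | x)
  if (y == 0) return(exp(lt0))
  j <- seq_len(y)
  # log increments of p(j)/p(j-1) = (x + j)/j * p2
  lt <- lt0 + cumsum(base::log((x + j) / j) + lq)
  lt <- c(lt0, lt)
  m <- max(lt)
  exp(m) * sum(exp(lt - m))
}

#' Two-sided p-value of the tag-count exact test
#'
#' Doubles the smaller of the two one-sided equal-expression tails obtained
#' by conditioning on either library:
#' \deqn{p = 2 \min\{ P(Y \le y \mid x; N_1, N_2),\;
#'                    P(X \le x \mid y; N_2, N_1) \}, }
#' capped at 1. The two tails sum to exactly 1 (a binomial-tail identity of
#' the conditional negative-binomial law), so the p-value is exactly
#' exchangeable under swapping `(x, N1)` with `(y, N2)`, and both tails are
#' finite sums -- no infinite-tail truncation is needed.
#'
#' @param x,y Non-negative tag counts in the two libraries (vectorised).
#' @param N1,N2 Positive library totals of the `x` and `y` libraries.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' deg_pvalue(50, 0, 1e6, 1e6)
#' @export
deg_pvalue <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) abort("Counts must be non-negative.")
  if (any(N1 <= 0) || any(N2 <= 0)) abort("Library totals must be positive.")
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  vapply(seq_len(n), function(i) {
    lo <- ac_lower_tail(x[i], y[i], N1[i], N2[i])
    hi <- ac_lower_tail(y[i], x[i], N2[i], N1[i])
    min(1, 2 * min(lo, hi))
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, monotone-enforced, order-aligned with the input.
#' Thin validated wrapper over [stats::p.adjust()].
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("`p_values` must all lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' The four comparison groups of the drought design
#'
#' Each group is an ordered pair of samples whose per-gene counts are tested
#' against each other. The ratio orientation follows the reporting
#' convention of the two-round filter rules: `RT-R` is reported as
#' `log2(R/RT)`, `S-R` as `log2(R/S)`, `ST-S` as `log2(S/ST)` and `ST-RT`
#' as `log2(RT/ST)`.
#'
#' @return A tibble with columns `comparison`, `numerator`, `denominator`.
#' @export
comparison_groups <- function() {
  tibble(
    comparison = c("RT-R", "S-R", "ST-RT", "ST-S"),
    numerator = c("R", "R", "RT", "S"),
    denominator = c("RT", "S", "ST", "ST")
  )
}

#' Test all genes of one comparison group for differential expression
#'
#' Computes per-gene RPKM in the two libraries of the group, the log2
#' expression ratio (numerator over denominator, with a pseudocount so
#' zero-count genes yield finite extreme ratios), the exact-test p-value,
#' and the BH-adjusted FDR over all genes of the table (the multiplicity
#' family is the full gene list of the comparison). A gene is called a DEG
#' when `fdr <= fdr_max` and `|log2_ratio| >= min_abs_log2`.
#'
#' @param table A [count_table()].
#' @param comparison One of `"RT-R"`, `"S-R"`, `"ST-RT"`, `"ST-S"`, or a
#'   one-row data frame like a row of [comparison_groups()].
#' @param fdr_max FDR threshold, default 0.001.
#' @param min_abs_log2 Minimum absolute log2 ratio, default 1.
#' @param pseudo_rpkm Pseudocount added to both RPKM values before the
#'   ratio, default 0.001 RPKM.
#' @return A tibble of class `deg_result` with columns `gene_id`,
#'   `comparison`, `x`, `y` (counts in the numerator and denominator
#'   libraries), `rpkm_x`, `rpkm_y`, `log2_ratio`, `p_value`, `fdr`,
#'   `is_deg` and `direction` (`"up"`/`"down"` for DEGs by the sign of the
#'   ratio, `"none"` otherwise).
#' @export
call_degs <- function(table, comparison, fdr_max = 0.001, min_abs_log2 = 1,
                      pseudo_rpkm = 0.001) {
  stopifnot(inherits(table, "count_table"))
  groups <- comparison_groups()
  if (is.character(comparison)) {
    if (!comparison %in% groups$comparison) {
      abort(paste0("Unknown comparison group '", comparison, "'."))
    }
    grp <- groups[groups$comparison == comparison, ]
  } else {
    grp <- as_tibble(comparison)
    if (!all(c("comparison", "numerator", "denominator") %in% names(grp)) ||
        nrow(grp) != 1) {
      abort("`comparison` must be a group name or a one-row group definition.")
    }
  }
  if (!all(c(grp$numerator, grp$denominator) %in% names(table))) {
    abort(paste0("Unknown sample label in group '", grp$comparison, "'."))
  }
  lt <- library_totals(table)
  x <- table[[grp$numerator]]
  y <- table[[grp$denominator]]
  n1 <- lt[[grp$numerator]]
  n2 <- lt[[grp$denominator]]
  rx <- rpkm(x, n1, table$length)
  ry <- rpkm(y, n2, table$length)
  lr <- log2((rx + pseudo_rpkm) / (ry + pseudo_rpkm))
  p <- deg_pvalue(x, y, n1, n2)
  fdr <- bh_fdr(p)
  deg <- fdr <= fdr_max & abs(lr) >= min_abs_log2
  out <- tibble(
    gene_id = table$gene_id,
    comparison = grp$comparison,
    x = x, y = y,
    rpkm_x = rx, rpkm_y = ry,
    log2_ratio = lr,
    p_value = p,
    fdr = fdr,
    is_deg = deg,
    direction = dplyr::case_when(deg & lr > 0 ~ "up",
                                 deg & lr < 0 ~ "down",
                                 .default = "none")
  )
  class(out) <- c("deg_result", class(out))
  out
}

#' Run all four comparison groups of a count table
#'
#' @inheritParams call_degs
#' @return A `deg_result` tibble stacking the four comparisons.
#' @export
call_all_degs <- function(table, fdr_max = 0.001, min_abs_log2 = 1,
                          pseudo_rpkm = 0.001) {
  groups <- comparison_groups()
  out <- purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    call_degs(table, groups[i, ], fdr_max = fdr_max,
              min_abs_log2 = min_abs_log2, pseudo_rpkm = pseudo_rpkm)
  })
  class(out) <- c("deg_result", class(out))
  out
}

#' @export
glance.deg_result <- function(x, ...) {
  as_tibble(x) %>%
    group_by(.data$comparison) %>%
    summarise(
      n_genes = dplyr::n(),
      n_deg = sum(.data$is_deg),
      n_up = sum(.data$direction == "up"),
      n_down = sum(.data$direction == "down"),
      .groups = "drop"
    )
}

#' Per-group DEG identifier sets
#'
#' @param results A `deg_result` (one or several comparisons).
#' @return Named list of character vectors, one per comparison present.
#' @export
deg_sets <- function(results) {
  res <- as_tibble(results) %>% filter(.data$is_deg)
  split(res$gene_id, res$comparison)
}
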