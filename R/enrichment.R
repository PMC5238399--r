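#' Upper-tail hypergeometric p-value
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' sampled without replacement from a background of `N_bg` genes of which
#' `K` carry the term: `P(X >= k)` for
#' `X ~ Hypergeometric(N_bg, K, n)`. Computed through the log-space tail of
#' [stats::phyper()].
#'
#' @param k Annotated genes observed in the query set (vectorised).
#' @param n Query-set size.
#' @param K Annotated genes in the background.
#' @param N_bg Background size.
#' @return Upper-tail probabilities.
#' @examples
#' hypergeom_upper_pvalue(2, 2, 2, 4) # 1/6
#' @export
hypergeom_upper_pvalue <- function(k, n, K, N_bg) {
  m <- max(length(k), length(n), length(K), length(N_bg))
  k <- rep_len(k, m); n <- rep_len(n, m)
  K <- rep_len(K, m); N_bg <- rep_len(N_bg, m)
  if (any(k < 0) || any(k > pmin(n, K)) || any(n > N_bg) || any(K > N_bg)) {
    abort("Counts must satisfy 0 <= k <= min(n, K), n <= N_bg, K <= N_bg.")
  }
  exp(phyper(k - 1, K, N_bg - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Term over-representation in a gene set
#'
#' One-sided hypergeometric test of every annotation term carried by at
#' least one query gene, against the whole-transcriptome background of the
#' annotation map. The correction family is the set of tested terms (terms
#' with >= 1 query gene), following the node-wise correction of classic GO
#' term-finding tools. The corrected value is Bonferroni
#' (`min(1, m * p_raw)`); the term is reported enriched when it is at or
#' below `alpha`.
#'
#' @param query_genes Character vector of gene identifiers; must be a
#'   subset of the background (i.e. `length(unique(query_genes)) <=`
#'   background size).
#' @param annotations An [annotation_map()].
#' @param term_kind `"pathway"` (KEGG) or `"process"` (GO biological
#'   process).
#' @param alpha Corrected-significance threshold, default 0.05.
#' @param correction Only `"bonferroni"` is implemented.
#' @return A tibble of class `enrich_result` with columns `term_id`,
#'   `term_kind`, `k`, `n`, `K`, `N_bg`, `p_raw`, `p_corrected`,
#'   `enriched`, sorted by `p_corrected`. Empty query gives zero rows.
#' @export
enrich <- function(query_genes, annotations,
                   term_kind = c("pathway", "process"),
                   alpha = 0.05, correction = "bonferroni") {
  stopifnot(inherits(annotations, "annotation_map"))
  term_kind <- match.arg(term_kind)
  correction <- match.arg(correction)
  query_genes <- unique(query_genes)
  N_bg <- annotations$background_size
  if (length(query_genes) > N_bg) {
    abort("Query has more genes than the annotation background.")
  }
  ann <- if (term_kind == "pathway") annotations$pathways else annotations$processes
  n <- length(query_genes)
  empty <- tibble(term_id = character(), term_kind = character(),
                  k = integer(), n = integer(), K = integer(),
                  N_bg = integer(), p_raw = double(),
                  p_corrected = double(), enriched = logical())
  if (n == 0 || nrow(ann) == 0) {
    class(empty) <- c("enrich_result", class(empty))
    return(empty)
  }
  hit <- ann %>% filter(.data$gene_id %in% query_genes) %>%
    count(.data$term_id, name = "k")
  if (nrow(hit) == 0) {
    class(empty) <- c("enrich_result", class(empty))
    return(empty)
  }
  bg <- ann %>% count(.data$term_id, name = "K")
  m <- nrow(hit)
  out <- left_join(hit, bg, by = "term_id") %>%
    mutate(
      term_kind = term_kind,
      n = n,
      N_bg = N_bg,
      p_raw = hypergeom_upper_pvalue(.data$k, n, .data$K, N_bg),
      p_corrected = pmin(1, m * .data$p_raw),
      enriched = .data$p_corrected <= alpha
    ) %>%
    select("term_id", "term_kind", "k", "n", "K", "N_bg",
           "p_raw", "p_corrected", "enriched") %>%
    arrange(.data$p_corrected, .data$term_id)
  class(out) <- c("enrich_result", class(out))
  out
}

#' @export
glance.enrich_result <- function(x, ...) {
  tibble(
    n_terms = nrow(x),
    n_enriched = sum(x$enriched),
    term_kind = if (nrow(x) > 0) x$term_kind[1] else NA_character_,
    query_size = if (nrow(x) > 0) x$n[1] else 0L
  )
}

#' Pathway involvement of a gene set
#'
#' Plain membership tallies, no test: which pathways the genes of a set are
#' annotated to and by how many member genes.
#'
#' @param gene_set Character vector of gene identifiers.
#' @param annotations An [annotation_map()].
#' @return A tibble `term_id`, `n_genes`, `genes` (list column of member
#'   identifiers), sorted by decreasing `n_genes`. Genes without pathway
#'   annotation contribute no rows.
#' @export
pathway_involvement <- function(gene_set, annotations) {
  stopifnot(inherits(annotations, "annotation_map"))
  annotations$pathways %>%
    filter(.data$gene_id %in% unique(gene_set)) %>%
    group_by(term_id = .data$term_id) %>%
    summarise(n_genes = dplyr::n(),
              genes = list(sort(.data$gene_id)),
              .groups = "drop") %>%
    arrange(desc(.data$n_genes), .data$term_id)
}
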