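# Small in-code fixtures shared across tests.

tiny_count_table <- function() {
  count_table(
    tibble::tibble(
      gene_id = c("BnaA01g00010D", "BnaC05g12340D", "BnaCnng00001D"),
      length = c(1000L, 2000L, 500L),
      R = c(10L, 0L, 100L),
      RT = c(12L, 40L, 95L),
      S = c(9L, 1L, 120L),
      ST = c(11L, 38L, 110L)
    ),
    library_total = c(R = 1e6, RT = 1.2e6, S = 9e5, ST = 1.1e6)
  )
}

tiny_annotation_map <- function() {
  annotation_map(
    pathways = tibble::tibble(
      gene_id = c("BnaA01g00010D", "BnaA01g00010D", "BnaC05g12340D"),
      term_id = c("ko01100", "ko01110", "ko01100")
    ),
    processes = tibble::tibble(
      gene_id = c("BnaA01g00010D", "BnaC05g12340D", "BnaCnng00001D"),
      term_id = c("GO:0006950", "GO:0006950", "GO:0009414")
    ),
    background_size = 100
  )
}

# Annotation map over arbitrary gene/term universes, drawn with a fixed
# local seed so helpers never disturb the global RNG stream.
random_annotation_map <- function(genes, n_pathways = 6, n_processes = 8,
                                  p_edge = 0.3, seed = 42,
                                  background_size = length(genes) + 10) {
  withr::with_seed(seed, {
    pw_terms <- sprintf("ko%05d", seq_len(n_pathways))
    bp_terms <- sprintf("GO:%07d", seq_len(n_processes))
    pw <- expand.grid(gene_id = genes, term_id = pw_terms,
                      stringsAsFactors = FALSE)
    pw <- pw[stats::runif(nrow(pw)) < p_edge, ]
    bp <- expand.grid(gene_id = genes, term_id = bp_terms,
                      stringsAsFactors = FALSE)
    bp <- bp[stats::runif(nrow(bp)) < p_edge, ]
    annotation_map(pw, bp, background_size = background_size)
  })
}

# Brute-force projection weights: pairwise shared-term counts from a long
# annotation table, independent of any graph machinery.
brute_projection_weights <- function(ann_tab, nodes) {
  sets <- lapply(stats::setNames(nodes, nodes), function(g) {
    ann_tab$term_id[ann_tab$gene_id == g]
  })
  out <- list()
  if (length(nodes) >= 2) {
    for (i in seq_len(length(nodes) - 1)) {
      for (j in seq(i + 1, length(nodes))) {
        w <- length(intersect(sets[[i]], sets[[j]]))
        if (w > 0) {
          out[[length(out) + 1]] <- tibble::tibble(
            node_a = nodes[i], node_b = nodes[j], weight = w)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(node_a = character(), node_b = character(),
                          weight = numeric()))
  }
  dplyr::bind_rows(out)
}

# Canonical edge key for order-insensitive comparison of edge tables.
edge_key <- function(tab) {
  k <- paste(pmin(tab$node_a, tab$node_b), pmax(tab$node_a, tab$node_b),
             tab$weight, sep = "|")
  sort(k)
}
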