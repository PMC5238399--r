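#' Build the gene-process-pathway tripartite graph
#'
#' Three node layers -- genes, GO biological-process terms and KEGG pathway
#' terms -- with inter-layer edges only: a gene is connected to each of its
#' annotated processes and pathways, and a process is connected to a
#' pathway exactly when at least one gene carries both. Genes without any
#' annotation are retained as degree-0 nodes.
#'
#' @param genes Character vector of gene identifiers (the gene layer).
#' @param annotations An [annotation_map()]; only annotations of `genes`
#'   are used.
#' @return An [igraph][igraph::igraph-package] graph of class
#'   `tripartite_graph` with vertex attribute `layer` in
#'   `c("gene", "process", "pathway")`.
#' @export
build_tripartite <- function(genes, annotations) {
  stopifnot(inherits(annotations, "annotation_map"))
  genes <- unique(genes)
  gp <- annotations$pathways %>% filter(.data$gene_id %in% genes)
  gb <- annotations$processes %>% filter(.data$gene_id %in% genes)
  pathways <- sort(unique(gp$term_id))
  processes <- sort(unique(gb$term_id))
  if (length(intersect(pathways, processes)) > 0) {
    abort("Process and pathway term identifiers must not collide.")
  }
  # process-pathway edges: term pairs co-annotated on >= 1 gene
  pp <- dplyr::inner_join(gb, gp, by = "gene_id",
                          suffix = c("_process", "_pathway"),
                          relationship = "many-to-many") %>%
    distinct(.data$term_id_process, .data$term_id_pathway)
  edges <- rbind(
    cbind(gb$gene_id, gb$term_id),
    cbind(gp$gene_id, gp$term_id),
    cbind(pp$term_id_process, pp$term_id_pathway)
  )
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(genes), name = genes, layer = "gene")
  g <- igraph::add_vertices(g, length(processes), name = processes,
                            layer = "process")
  g <- igraph::add_vertices(g, length(pathways), name = pathways,
                            layer = "pathway")
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  class(g) <- c("tripartite_graph", class(g))
  g
}

#' Layer sizes of a tripartite graph
#'
#' @param graph A `tripartite_graph`.
#' @return Named integer vector over gene, process, pathway.
#' @export
layer_sizes <- function(graph) {
  tab <- table(factor(igraph::V(graph)$layer,
                      levels = c("gene", "process", "pathway")))
  setNames(as.integer(tab), names(tab))
}

#' One-mode weighted projection of the tripartite graph
#'
#' Projects onto `node_layer`: two nodes are joined when they share at
#' least one neighbour in `linking_layer`, with edge weight equal to the
#' number of shared linking entities. Following the field convention the
#' projection is named `"<linking_layer>-<node_layer>"` (so the
#' `pathway-gene` network has gene nodes linked by shared pathways).
#' Projections are simple weighted graphs (no self-loops or multi-edges);
#' nodes sharing no linking entity with any other node are retained as
#' isolated nodes.
#'
#' @param graph A `tripartite_graph`.
#' @param node_layer,linking_layer Distinct layer names among
#'   `"gene"`, `"process"`, `"pathway"`.
#' @return An igraph graph of class `projection_network` with edge
#'   attribute `weight` and graph attributes `name`, `node_layer`,
#'   `linking_layer`.
#' @export
project <- function(graph, node_layer, linking_layer) {
  layers <- c("gene", "process", "pathway")
  if (!node_layer %in% layers || !linking_layer %in% layers) {
    abort("Layers must be 'gene', 'process' or 'pathway'.")
  }
  if (node_layer == linking_layer) {
    abort("`node_layer` and `linking_layer` must differ.")
  }
  nodes <- igraph::V(graph)$name[igraph::V(graph)$layer == node_layer]
  links <- igraph::V(graph)$name[igraph::V(graph)$layer == linking_layer]
  el <- igraph::as_edgelist(graph)
  vl <- setNames(igraph::V(graph)$layer, igraph::V(graph)$name)
  sel <- (vl[el[, 1]] == node_layer & vl[el[, 2]] == linking_layer) |
    (vl[el[, 1]] == linking_layer & vl[el[, 2]] == node_layer)
  el <- el[sel, , drop = FALSE]
  A <- matrix(0L, nrow = length(nodes), ncol = length(links),
              dimnames = list(nodes, links))
  if (nrow(el) > 0) {
    swap <- vl[el[, 1]] == linking_layer
    nd <- ifelse(swap, el[, 2], el[, 1])
    lk <- ifelse(swap, el[, 1], el[, 2])
    A[cbind(nd, lk)] <- 1L
  }
  W <- tcrossprod(A)
  diag(W) <- 0
  net <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
  net <- igraph::set_graph_attr(net, "name",
                                paste(linking_layer, node_layer, sep = "-"))
  net <- igraph::set_graph_attr(net, "node_layer", node_layer)
  net <- igraph::set_graph_attr(net, "linking_layer", linking_layer)
  class(net) <- c("projection_network", class(net))
  net
}

#' @export
tidy.projection_network <- function(x, ...) {
  el <- igraph::as_edgelist(x)
  tibble(
    node_a = as.character(el[, 1]),
    node_b = as.character(el[, 2]),
    weight = if (igraph::ecount(x) > 0) igraph::E(x)$weight else numeric()
  )
}

#' Summary statistics of a projection network
#'
#' Reports node and edge counts, the unweighted degree sequence, the mean
#' degree under both conventions in circulation -- sum of degrees over
#' nodes (`2E/N`) and edges over nodes (`E/N`) -- the isolated nodes, the
#' maximum-weight edge, and the integer-degree histogram.
#'
#' @param net A `projection_network`.
#' @return A list of class `network_stats` with elements `name`,
#'   `n_nodes`, `n_edges`, `degrees` (tibble `node`, `degree`),
#'   `mean_degree_2e_n`, `mean_degree_e_n`, `isolated` (character vector),
#'   `max_weight_edge` (one-row tibble or NULL), `degree_histogram`
#'   (tibble `degree`, `n_nodes`).
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "projection_network"))
  deg <- igraph::degree(net)
  nn <- igraph::vcount(net)
  ne <- igraph::ecount(net)
  hist <- count(tibble(degree = as.integer(deg)), .data$degree,
                name = "n_nodes")
  max_edge <- NULL
  if (ne > 0) {
    w <- igraph::E(net)$weight
    i <- which.max(w)
    ends <- igraph::ends(net, igraph::E(net)[i])
    max_edge <- tibble(node_a = ends[1], node_b = ends[2], weight = w[i])
  }
  structure(list(
    name = igraph::graph_attr(net, "name"),
    n_nodes = nn,
    n_edges = ne,
    degrees = tibble(node = names(deg), degree = as.integer(deg)),
    mean_degree_2e_n = if (nn > 0) 2 * ne / nn else 0,
    mean_degree_e_n = if (nn > 0) ne / nn else 0,
    isolated = names(deg)[deg == 0],
    max_weight_edge = max_edge,
    degree_histogram = hist
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("<network_stats> %s: %d nodes, %d edges, mean degree %.2f (2E/N) / %.2f (E/N), %d isolated\n",
              x$name, x$n_nodes, x$n_edges, x$mean_degree_2e_n,
              x$mean_degree_e_n, length(x$isolated)))
  invisible(x)
}

#' @export
glance.projection_network <- function(x, ...) {
  s <- network_stats(x)
  tibble(
    name = s$name, n_nodes = s$n_nodes, n_edges = s$n_edges,
    mean_degree_2e_n = s$mean_degree_2e_n,
    mean_degree_e_n = s$mean_degree_e_n,
    n_isolated = length(s$isolated),
    max_weight = if (is.null(s$max_weight_edge)) NA_real_
                 else s$max_weight_edge$weight
  )
}

#' All six one-mode projections
#'
#' @param graph A `tripartite_graph`.
#' @return Named list of the six `projection_network`s, named
#'   `"<linking>-<node>"`.
#' @export
project_all <- function(graph) {
  layers <- c("gene", "process", "pathway")
  pairs <- expand.grid(node = layers, linking = layers,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$node != pairs$linking, ]
  nets <- purrr::map(seq_len(nrow(pairs)), function(i) {
    project(graph, pairs$node[i], pairs$linking[i])
  })
  setNames(nets, paste(pairs$linking, pairs$node, sep = "-"))
}

#' Log-log least-squares slope of a degree histogram
#'
#' Fits `log10(frequency) ~ log10(degree)` over the non-empty
#' positive-degree bins, the usual reading of a binned degree distribution
#' on doubly logarithmic axes. Zero-degree nodes are excluded. With fewer
#' than 3 usable bins the slope is undefined and returned as `NA` (no
#' error is thrown).
#'
#' @param degree_histogram A tibble/data frame with columns `degree` and
#'   `n_nodes` (as in [network_stats()]).
#' @return A list with `slope`, `intercept` (both `NA` when undefined) and
#'   `n_bins`, the number of bins used.
#' @export
powerlaw_slope <- function(degree_histogram) {
  h <- as_tibble(degree_histogram) %>%
    filter(.data$degree > 0, .data$n_nodes > 0)
  if (nrow(h) < 3) {
    return(list(slope = NA_real_, intercept = NA_real_, n_bins = nrow(h)))
  }
  fit <- lm(log10(n_nodes) ~ log10(degree), data = h)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n_bins = nrow(h))
}

#' Write a projection network to disk
#'
#' `"tsv"` writes the weighted edge list (`node_a`, `node_b`, `weight`;
#' header always present, so an empty network gives a header-only file).
#' `"graphml"` writes GraphML through igraph, preserving isolated nodes and
#' attributes, and is the round-trip-safe format.
#'
#' @param net A `projection_network`.
#' @param path Output path.
#' @param format `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(tidy(net), path)
  } else {
    igraph::write_graph(net, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network written by [export_network()]
#'
#' @param path Input path.
#' @param format `"tsv"` or `"graphml"`. TSV reconstructs from edges only
#'   (isolated nodes are not represented in an edge list).
#' @return A `projection_network`.
#' @export
import_network <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    ed <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = "ccd")
    g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
  }
  class(g) <- c("projection_network", class(g))
  g
}
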