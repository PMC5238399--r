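one_triangle_map <- function() {
  annotation_map(
    pathways = tibble::tibble(gene_id = "g1", term_id = "ko00001"),
    processes = tibble::tibble(gene_id = "g1", term_id = "GO:0000001"),
    background_size = 10
  )
}

test_that("one fully annotated gene yields a triangle", {
  tri <- build_tripartite("g1", one_triangle_map())
  expect_equal(unname(layer_sizes(tri)), c(1L, 1L, 1L))
  expect_equal(igraph::ecount(tri), 3)
})

test_that("genes with disjoint annotations give disjoint triangles", {
  map <- annotation_map(
    pathways = tibble::tibble(gene_id = c("g1", "g2"),
                              term_id = c("ko00001", "ko00002")),
    processes = tibble::tibble(gene_id = c("g1", "g2"),
                               term_id = c("GO:0000001", "GO:0000002")),
    background_size = 10
  )
  tri <- build_tripartite(c("g1", "g2"), map)
  expect_equal(igraph::ecount(tri), 6)
  comp <- igraph::components(tri)
  expect_equal(comp$no, 2)
  # an unannotated gene joins as a degree-0 node
  tri3 <- build_tripartite(c("g1", "g2", "g3"), map)
  expect_equal(sum(igraph::degree(tri3) == 0), 1)
})

test_that("process-pathway edges exist exactly for co-annotated term pairs", {
  map <- annotation_map(
    pathways = tibble::tibble(gene_id = c("g1", "g2"),
                              term_id = c("ko00001", "ko00002")),
    processes = tibble::tibble(gene_id = c("g1", "g1", "g2"),
                               term_id = c("GO:0000001", "GO:0000002",
                                           "GO:0000001")),
    background_size = 10
  )
  tri <- build_tripartite(c("g1", "g2"), map)
  # GO:1-ko1 (via g1), GO:2-ko1 (via g1), GO:1-ko2 (via g2); never GO:2-ko2
  expect_true(igraph::are_adjacent(tri, "GO:0000001", "ko00001"))
  expect_true(igraph::are_adjacent(tri, "GO:0000002", "ko00001"))
  expect_true(igraph::are_adjacent(tri, "GO:0000001", "ko00002"))
  expect_false(igraph::are_adjacent(tri, "GO:0000002", "ko00002"))
})

test_that("the toy projection matches the hand enumeration", {
  map <- annotation_map(
    pathways = tibble::tibble(
      gene_id = c("a", "a", "b", "b", "c"),
      term_id = c("ko00001", "ko00002", "ko00001", "ko00002", "ko00003")
    ),
    processes = tibble::tibble(gene_id = character(), term_id = character()),
    background_size = 10
  )
  net <- project(build_tripartite(c("a", "b", "c"), map), "gene", "pathway")
  ed <- tidy(net)
  expect_equal(nrow(ed), 1)
  expect_setequal(c(ed$node_a, ed$node_b), c("a", "b"))
  expect_equal(ed$weight, 2)
  st <- network_stats(net)
  expect_equal(st$isolated, "c")
  expect_equal(st$n_nodes, 3)
})

test_that("projection weights equal brute-force intersection counts", {
  for (seed in 1:6) {
    genes <- sprintf("g%02d", 1:25)
    map <- random_annotation_map(genes, n_pathways = 8, n_processes = 10,
                                 p_edge = 0.25, seed = seed)
    tri <- build_tripartite(genes, map)
    # gene layer via pathways
    got <- tidy(project(tri, "gene", "pathway"))
    want <- brute_projection_weights(map$pathways, genes)
    expect_equal(edge_key(got), edge_key(want))
    # pathway layer via genes (transpose roles of the annotation table)
    pw <- unique(map$pathways$term_id)
    got2 <- tidy(project(tri, "pathway", "gene"))
    want2 <- brute_projection_weights(
      tibble::tibble(gene_id = map$pathways$term_id,
                     term_id = map$pathways$gene_id), pw)
    expect_equal(edge_key(got2), edge_key(want2))
  }
})

test_that("total projection weight satisfies the pairs-per-linker identity", {
  genes <- sprintf("g%02d", 1:20)
  map <- random_annotation_map(genes, n_pathways = 6, p_edge = 0.4, seed = 9)
  net <- project(build_tripartite(genes, map), "gene", "pathway")
  total_w <- sum(tidy(net)$weight)
  # each linking pathway with d annotated genes contributes C(d, 2)
  d <- table(map$pathways$term_id)
  expect_equal(total_w, sum(choose(d, 2)))
})

test_that("all six projections exist and keep every node-layer vertex", {
  genes <- sprintf("g%02d", 1:15)
  map <- random_annotation_map(genes, seed = 4)
  tri <- build_tripartite(genes, map)
  nets <- project_all(tri)
  expect_setequal(names(nets),
                  c("pathway-gene", "process-gene", "gene-pathway",
                    "process-pathway", "gene-process", "pathway-process"))
  sizes <- layer_sizes(tri)
  for (nm in names(nets)) {
    node_layer <- igraph::graph_attr(nets[[nm]], "node_layer")
    expect_equal(igraph::vcount(nets[[nm]]), unname(sizes[node_layer]))
    w <- igraph::E(nets[[nm]])$weight
    if (length(w) > 0) expect_true(all(w >= 1))
  }
  expect_error(project(tri, "gene", "gene"), "differ")
})

test_that("network statistics report both mean-degree conventions", {
  map <- annotation_map(
    pathways = tibble::tibble(gene_id = c("a", "b", "c"), term_id = "ko00001"),
    processes = tibble::tibble(gene_id = character(), term_id = character()),
    background_size = 5
  )
  net <- project(build_tripartite(c("a", "b", "c"), map), "gene", "pathway")
  st <- network_stats(net) # triangle
  expect_equal(st$n_edges, 3)
  expect_equal(st$mean_degree_2e_n, 2)
  expect_equal(st$mean_degree_e_n, 1)
  expect_length(st$isolated, 0)
  # empty network: all nodes isolated, zero mean degree
  empty_map <- annotation_map(
    pathways = tibble::tibble(gene_id = character(), term_id = character()),
    processes = tibble::tibble(gene_id = character(), term_id = character()),
    background_size = 5
  )
  st0 <- network_stats(project(build_tripartite(c("a", "b"), empty_map),
                               "gene", "pathway"))
  expect_equal(st0$n_edges, 0)
  expect_equal(st0$mean_degree_2e_n, 0)
  expect_length(st0$isolated, 2)
})

test_that("a constructed exact power law is recovered to high precision", {
  h <- tibble::tibble(degree = 1:50, n_nodes = 1000 * (1:50)^-2)
  fit <- powerlaw_slope(h)
  expect_equal(fit$slope, -2, tolerance = 0.01)
  # uniform histogram: slope zero
  flat <- tibble::tibble(degree = 1:30, n_nodes = 7)
  expect_equal(powerlaw_slope(flat)$slope, 0, tolerance = 1e-10)
  # too few bins: NA signal, no exception
  two <- tibble::tibble(degree = c(1, 2), n_nodes = c(5, 3))
  expect_true(is.na(powerlaw_slope(two)$slope))
  expect_equal(powerlaw_slope(two)$n_bins, 2)
})

test_that("networks round-trip through GraphML and edge-list TSV", {
  genes <- sprintf("g%02d", 1:12)
  map <- random_annotation_map(genes, seed = 21)
  net <- project(build_tripartite(genes, map), "gene", "pathway")
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back <- import_network(gml, "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(net))
  expect_equal(edge_key(tidy(back)), edge_key(tidy(net)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "tsv")
  back2 <- import_network(tsv, "tsv")
  expect_equal(edge_key(tidy(back2)), edge_key(tidy(net)))
  # empty network: header-only TSV
  e <- igraph::delete_edges(net, igraph::E(net))
  class(e) <- class(net)
  export_network(e, tsv, "tsv")
  expect_equal(readLines(tsv), "node_a\tnode_b\tweight")
})
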