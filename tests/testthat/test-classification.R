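test_that("the annotation filter keeps only pathway-annotated genes", {
  map <- tiny_annotation_map()
  sets <- list("RT-R" = c("BnaA01g00010D", "BnaCnng00001D"),
               "ST-S" = c("BnaC05g12340D", "BnaA01g00010D"),
               "S-R" = character())
  out <- filter_pathway_annotated(sets, map)
  expect_equal(out[["RT-R"]], "BnaA01g00010D")
  expect_setequal(out[["ST-S"]], c("BnaC05g12340D", "BnaA01g00010D"))
  expect_length(out[["S-R"]], 0)
  # all-annotated is the identity; none-annotated empties every set
  all_ann <- list("RT-R" = c("BnaA01g00010D", "BnaC05g12340D"))
  expect_equal(filter_pathway_annotated(all_ann, map), all_ann)
  none <- list("RT-R" = "BnaUnng99999D", "ST-S" = "BnaUnng99998D")
  emptied <- filter_pathway_annotated(none, map)
  expect_true(all(lengths(emptied) == 0))
  # downstream stages accept the empty result without error
  expect_equal(nrow(venn_partition(emptied)), 0)
})

test_that("disjoint and identical sets produce the expected regions", {
  disjoint <- list("RT-R" = c("a", "b"), "S-R" = "c", "ST-RT" = "d",
                   "ST-S" = "e")
  part <- venn_partition(disjoint)
  expect_setequal(unique(part$mask), c("RT-R", "S-R", "ST-RT", "ST-S"))
  same <- list("RT-R" = c("a", "b"), "S-R" = c("a", "b"),
               "ST-RT" = c("a", "b"), "ST-S" = c("a", "b"))
  part2 <- venn_partition(same)
  expect_equal(unique(part2$mask), "RT-R+S-R+ST-RT+ST-S")
})

test_that("venn regions match a per-gene membership-bitmask oracle", {
  groups <- comparison_groups()$comparison
  for (seed in 1:5) {
    sets <- withr::with_seed(seed, {
      universe <- sprintf("g%03d", 1:80)
      lapply(stats::setNames(groups, groups), function(g) {
        sample(universe, sample(0:50, 1))
      })
    })
    part <- venn_partition(sets)
    # oracle: per-gene bitmask over the four sets
    genes <- unique(unlist(sets))
    oracle_mask <- vapply(genes, function(g) {
      paste(groups[vapply(groups, function(s) g %in% sets[[s]], logical(1))],
            collapse = "+")
    }, character(1))
    expect_equal(nrow(part), length(genes))
    expect_equal(part$mask[match(genes, part$gene_id)],
                 unname(oracle_mask))
    # disjointness/union: each gene appears exactly once
    expect_false(anyDuplicated(part$gene_id) > 0)
  }
})

test_that("category assignment follows the seven-subgroup rules", {
  part <- tibble::tibble(
    gene_id = sprintf("g%d", 1:8),
    mask = c("RT-R", "RT-R+S-R", "ST-S", "S-R+ST-S", "S-R", "RT-R+ST-S",
             "RT-R+S-R+ST-S", "ST-RT")
  )
  asg <- assign_categories(part)
  expect_equal(asg$category,
               c("RDR", "RDR", "SDR", "SDR", "CDR", "CDR", "CDR", "EXCLUDED"))
  # any mask containing the control-control comparison is excluded
  mixed <- assign_categories(tibble::tibble(
    gene_id = c("h1", "h2"), mask = c("RT-R+ST-RT", "RT-R+S-R+ST-RT+ST-S")))
  expect_equal(unique(mixed$category), "EXCLUDED")
})

test_that("second-round rules match the published worked ratios", {
  asg <- assign_categories(tibble::tibble(
    gene_id = c("deep", "shallow", "edge"),
    mask = "RT-R"
  ))
  ratios <- tibble::tibble(
    gene_id = c("deep", "shallow", "edge"),
    log2_R_RT = c(-10.2858, 1.2528, 5.0)
  )
  out <- filter_crucial(asg, ratios)
  expect_equal(out$crucial, c(TRUE, FALSE, TRUE))
})

test_that("crucial selection equals a brute-force rule-table oracle", {
  masks <- c("RT-R", "RT-R+S-R", "ST-S", "S-R+ST-S", "S-R", "RT-R+ST-S",
             "RT-R+S-R+ST-S")
  dat <- withr::with_seed(7, tibble::tibble(
    gene_id = sprintf("g%04d", 1:1000),
    mask = sample(masks, 1000, replace = TRUE),
    log2_R_RT = stats::runif(1000, -8, 8),
    log2_R_S = stats::runif(1000, -8, 8),
    log2_S_ST = stats::runif(1000, -8, 8)
  ))
  asg <- assign_categories(dat[, c("gene_id", "mask")])
  got <- filter_crucial(asg, dat[, -2])$crucial
  oracle <- vapply(seq_len(nrow(dat)), function(i) {
    d1 <- dat$log2_R_RT[i]; d2 <- dat$log2_R_S[i]; d3 <- dat$log2_S_ST[i]
    switch(dat$mask[i],
      "RT-R" = abs(d1) >= 5,
      "RT-R+S-R" = abs(d1 - d2) >= 2 || abs(d1) >= 5 || abs(d2) >= 5,
      "ST-S" = abs(d3) >= 5,
      "S-R+ST-S" = abs(d2 - d3) >= 5 || abs(d2) >= 5 || abs(d3) >= 5,
      "S-R" = abs(d2) >= 5,
      "RT-R+ST-S" = abs(d1 - d3) >= 1 || abs(d1) >= 3 || abs(d3) >= 3,
      "RT-R+S-R+ST-S" = abs(d1) >= 2 || abs(d2) >= 2 || abs(d3) >= 2)
  }, logical(1))
  expect_equal(got, oracle)
})

test_that("raising any cutoff never adds a crucial gene", {
  masks <- c("RT-R", "RT-R+S-R", "S-R+ST-S", "RT-R+ST-S", "RT-R+S-R+ST-S")
  dat <- withr::with_seed(3, tibble::tibble(
    gene_id = sprintf("g%04d", 1:400),
    mask = sample(masks, 400, replace = TRUE),
    log2_R_RT = stats::runif(400, -8, 8),
    log2_R_S = stats::runif(400, -8, 8),
    log2_S_ST = stats::runif(400, -8, 8)
  ))
  asg <- assign_categories(dat[, c("gene_id", "mask")])
  base <- filter_crucial(asg, dat[, -2])$crucial
  raised <- crucial_cutoffs()
  for (m in names(raised)) {
    raised[[m]] <- lapply(raised[[m]], function(v) v + 1)
  }
  up <- filter_crucial(asg, dat[, -2], cutoffs = raised)$crucial
  expect_true(all(base | !up))
})

test_that("a mask lacking its required ratio raises a named error", {
  asg <- assign_categories(tibble::tibble(gene_id = "gX", mask = "RT-R+S-R"))
  ratios <- tibble::tibble(gene_id = "gX", log2_R_RT = 3)
  expect_error(filter_crucial(asg, ratios), "gX.*RT-R\\+S-R|RT-R\\+S-R.*gX")
})

test_that("excluded genes are never crucial", {
  asg <- assign_categories(tibble::tibble(gene_id = "gZ", mask = "ST-RT"))
  out <- filter_crucial(asg, tibble::tibble(gene_id = "gZ"))
  expect_false(out$crucial)
})

test_that("regulation tallies count directions and close over genes", {
  tab <- count_table(
    tibble::tibble(
      gene_id = sprintf("BnaA01g%05dD", 1:3),
      length = 1000L,
      R = c(900L, 10L, 600L), RT = c(100L, 500L, 600L),
      S = c(880L, 12L, 600L), ST = c(110L, 480L, 600L)
    ),
    c(R = 1e6, RT = 1e6, S = 1e6, ST = 1e6)
  )
  res <- call_all_degs(tab)
  asg <- assign_categories(venn_partition(deg_sets(res)))
  summ <- regulation_summary(asg, res)
  expect_true(all(summ$n_up + summ$n_down == summ$n))
  rtr <- summ[summ$comparison == "RT-R", ]
  expect_equal(sum(rtr$n_up), 1) # the 9-fold-up gene
  expect_equal(sum(rtr$n_down), 1) # the 50-fold-down gene
  # all-up degenerate case
  one <- assign_categories(venn_partition(
    deg_sets(dplyr::filter(res, gene_id == "BnaA01g00001D"))))
  s1 <- regulation_summary(one, res)
  expect_true(all(s1$n_down == 0))
  # the published percentage arithmetic: 29 of 37 is 78.38%
  expect_equal(round(100 * 29 / 37, 2), 78.38)
})
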