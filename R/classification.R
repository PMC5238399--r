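#' Canonical comparison-group order and mask strings
#'
#' A Venn mask names the subset of comparison groups in which a gene is a
#' DEG; masks are written as group names joined by `+` in the fixed order
#' `RT-R`, `S-R`, `ST-RT`, `ST-S` (e.g. `"RT-R+S-R"`). Fifteen non-empty
#' masks exist over the four groups.
#'
#' @param groups Character vector of group names (any order, no
#'   duplicates).
#' @return The canonical mask string.
#' @export
venn_mask <- function(groups) {
  ord <- comparison_groups()$comparison
  bad <- setdiff(groups, ord)
  if (length(bad) > 0) {
    abort(paste0("Unknown comparison group(s): ", paste(bad, collapse = ", ")))
  }
  paste(ord[ord %in% groups], collapse = "+")
}

mask_groups <- function(mask) strsplit(mask, "+", fixed = TRUE)

#' All fifteen non-empty Venn masks
#'
#' @return Character vector of the 15 canonical mask strings.
#' @export
all_venn_masks <- function() {
  ord <- comparison_groups()$comparison
  masks <- character()
  for (k in 1:4) {
    cmb <- utils::combn(ord, k)
    masks <- c(masks, apply(cmb, 2, venn_mask))
  }
  masks
}

#' Restrict DEG sets to pathway-annotated genes
#'
#' Genes without any KEGG pathway annotation are removed from every
#' comparison group's DEG set before Venn partitioning; only annotated DEGs
#' enter the classification.
#'
#' @param deg_sets Named list of gene-identifier vectors, one per
#'   comparison group (see [deg_sets()]).
#' @param annotations An [annotation_map()].
#' @return The filtered named list, same names.
#' @export
filter_pathway_annotated <- function(deg_sets, annotations) {
  stopifnot(inherits(annotations, "annotation_map"))
  keep <- annotated_genes(annotations, "pathway")
  lapply(deg_sets, function(g) intersect(g, keep))
}

#' Venn partition of per-group DEG sets
#'
#' Assigns every gene in the union of the four per-group DEG sets to
#' exactly one of the 15 disjoint Venn regions.
#'
#' @param deg_sets Named list of gene-identifier vectors; names must be
#'   comparison-group names. Missing groups are treated as empty sets.
#' @return A tibble with columns `gene_id` and `mask`, one row per gene in
#'   the union.
#' @export
venn_partition <- function(deg_sets) {
  ord <- comparison_groups()$comparison
  bad <- setdiff(names(deg_sets), ord)
  if (length(bad) > 0) {
    abort(paste0("Unknown comparison group(s): ", paste(bad, collapse = ", ")))
  }
  sets <- lapply(setNames(ord, ord), function(g) unique(deg_sets[[g]]))
  genes <- sort(unique(unlist(sets, use.names = FALSE)))
  if (length(genes) == 0) return(tibble(gene_id = character(), mask = character()))
  member <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  member <- matrix(member, nrow = length(genes),
                   dimnames = list(NULL, ord))
  mask <- apply(member, 1, function(m) paste(ord[m], collapse = "+"))
  tibble(gene_id = genes, mask = mask)
}

#' Region sizes of a Venn partition
#'
#' @param partition Output of [venn_partition()].
#' @return A tibble `mask`, `n` covering all 15 masks (zeros included).
#' @export
venn_region_sizes <- function(partition) {
  tibble(mask = all_venn_masks()) %>%
    left_join(count(partition, .data$mask), by = "mask") %>%
    mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Assign drought-response categories from Venn masks
#'
#' The comparison between the two untreated controls (`ST-RT`) does not
#' contrast drought against control, so every mask containing `ST-RT` is
#' excluded. The remaining seven masks define three categories:
#' resistant-cultivar drought-responsive (RDR: only `RT-R`, or
#' `RT-R`+`S-R`), sensitive-cultivar drought-responsive (SDR: only `ST-S`,
#' or `S-R`+`ST-S`), and cultivar-non-specific (CDR: only `S-R`,
#' `RT-R`+`ST-S`, or `RT-R`+`S-R`+`ST-S`).
#'
#' @param partition A tibble with columns `gene_id`, `mask` (from
#'   [venn_partition()] or built directly).
#' @return A tibble of class `category_assignment` with columns `gene_id`,
#'   `mask`, `category` (`"RDR"`, `"SDR"`, `"CDR"` or `"EXCLUDED"`).
#' @export
assign_categories <- function(partition) {
  partition <- as_tibble(partition)
  stopifnot(all(c("gene_id", "mask") %in% names(partition)))
  bad <- setdiff(unique(partition$mask), all_venn_masks())
  if (length(bad) > 0) {
    abort(paste0("Unknown Venn mask(s): ", paste(bad, collapse = ", ")))
  }
  lookup <- c(
    "RT-R" = "RDR", "RT-R+S-R" = "RDR",
    "ST-S" = "SDR", "S-R+ST-S" = "SDR",
    "S-R" = "CDR", "RT-R+ST-S" = "CDR", "RT-R+S-R+ST-S" = "CDR"
  )
  has_strt <- vapply(mask_groups(partition$mask),
                     function(g) "ST-RT" %in% g, logical(1))
  category <- ifelse(has_strt, "EXCLUDED",
                     unname(lookup[partition$mask]))
  out <- mutate(partition, category = category)
  class(out) <- c("category_assignment", class(out))
  out
}

#' Category totals of an assignment
#'
#' @param assignments Output of [assign_categories()].
#' @return A tibble `category`, `n` over RDR, SDR, CDR, EXCLUDED.
#' @export
category_totals <- function(assignments) {
  count(as_tibble(assignments), .data$category)
}

#' Default second-round fold-change cutoffs
#'
#' One rule per analysed Venn mask, all inclusive (`>=`). `single` bounds an
#' individual absolute log2 ratio, `diff` bounds the absolute difference of
#' the two ratios of a two-group mask, `any` bounds each ratio of the
#' three-group mask.
#'
#' @return Named list of per-mask cutoff lists.
#' @export
crucial_cutoffs <- function() {
  list(
    "RT-R" = list(single = 5),
    "RT-R+S-R" = list(diff = 2, single = 5),
    "ST-S" = list(single = 5),
    "S-R+ST-S" = list(diff = 5, single = 5),
    "S-R" = list(single = 5),
    "RT-R+ST-S" = list(diff = 1, single = 3),
    "RT-R+S-R+ST-S" = list(any = 2)
  )
}

# Evaluate the second-round rule of one mask. d1 = log2(R/RT),
# d2 = log2(R/S), d3 = log2(S/ST); only the ratios of the mask's member
# groups may be used.
crucial_rule <- function(mask, d1, d2, d3, cutoffs) {
  cut <- cutoffs[[mask]]
  switch(mask,
    "RT-R" = abs(d1) >= cut$single,
    "S-R" = abs(d2) >= cut$single,
    "ST-S" = abs(d3) >= cut$single,
    "RT-R+S-R" = abs(d1 - d2) >= cut$diff |
      abs(d1) >= cut$single | abs(d2) >= cut$single,
    "S-R+ST-S" = abs(d2 - d3) >= cut$diff |
      abs(d2) >= cut$single | abs(d3) >= cut$single,
    "RT-R+ST-S" = abs(d1 - d3) >= cut$diff |
      abs(d1) >= cut$single | abs(d3) >= cut$single,
    "RT-R+S-R+ST-S" = abs(d1) >= cut$any | abs(d2) >= cut$any |
      abs(d3) >= cut$any,
    abort(paste0("No second-round rule for mask '", mask, "'."))
  )
}

# Ratios named by each mask's rule.
mask_required_ratios <- function(mask) {
  switch(mask,
    "RT-R" = "log2_R_RT",
    "S-R" = "log2_R_S",
    "ST-S" = "log2_S_ST",
    "RT-R+S-R" = c("log2_R_RT", "log2_R_S"),
    "S-R+ST-S" = c("log2_R_S", "log2_S_ST"),
    "RT-R+ST-S" = c("log2_R_RT", "log2_S_ST"),
    "RT-R+S-R+ST-S" = c("log2_R_RT", "log2_R_S", "log2_S_ST")
  )
}

#' Spread per-comparison log2 ratios to one row per gene
#'
#' @param results A `deg_result` covering one or more comparisons.
#' @return A tibble `gene_id`, `log2_R_RT`, `log2_R_S`, `log2_S_ST`,
#'   `log2_RT_ST` (columns present for the comparisons available; `NA`
#'   where a gene was not tested).
#' @export
ratio_table <- function(results) {
  nm <- c("RT-R" = "log2_R_RT", "S-R" = "log2_R_S",
          "ST-S" = "log2_S_ST", "ST-RT" = "log2_RT_ST")
  as_tibble(results) %>%
    mutate(ratio_name = unname(nm[.data$comparison])) %>%
    select("gene_id", "ratio_name", "log2_ratio") %>%
    tidyr::pivot_wider(names_from = "ratio_name", values_from = "log2_ratio")
}

#' Second-round selection of crucial drought-responsive genes
#'
#' Applies the per-mask fold-change rules (see [crucial_cutoffs()]) to the
#' non-excluded genes of a category assignment. Excluded genes are never
#' crucial. All comparisons are inclusive (`>=`).
#'
#' @param assignments A `category_assignment`.
#' @param ratios A tibble with `gene_id` and the log2-ratio columns of
#'   [ratio_table()]. A ratio named by a gene's mask rule must be non-`NA`
#'   for that gene, otherwise an error names the gene and mask.
#' @param cutoffs Per-mask cutoff list, default [crucial_cutoffs()].
#' @return The assignment tibble with an added logical `crucial` column.
#' @export
filter_crucial <- function(assignments, ratios, cutoffs = crucial_cutoffs()) {
  x <- as_tibble(assignments)
  ratios <- as_tibble(ratios)
  for (col in c("log2_R_RT", "log2_R_S", "log2_S_ST")) {
    if (!col %in% names(ratios)) ratios[[col]] <- NA_real_
  }
  x <- left_join(x, ratios[, c("gene_id", "log2_R_RT", "log2_R_S", "log2_S_ST")],
                 by = "gene_id")
  crucial <- logical(nrow(x))
  analysed <- x$category != "EXCLUDED"
  for (i in which(analysed)) {
    need <- mask_required_ratios(x$mask[i])
    vals <- unlist(x[i, need])
    if (any(is.na(vals))) {
      abort(sprintf("Gene %s (mask %s) is missing required ratio(s): %s.",
                    x$gene_id[i], x$mask[i],
                    paste(need[is.na(vals)], collapse = ", ")))
    }
    crucial[i] <- crucial_rule(x$mask[i], x$log2_R_RT[i], x$log2_R_S[i],
                               x$log2_S_ST[i], cutoffs)
  }
  out <- mutate(assignments,
                crucial = crucial[match(assignments$gene_id, x$gene_id)])
  class(out) <- unique(c("category_assignment", class(out)))
  out
}

#' Up/down regulation tallies per category and comparison
#'
#' For the genes of each category (optionally only the crucial ones),
#' counts how many are up- and down-regulated in each comparison group they
#' are DEGs of, with percentages.
#'
#' @param assignments A `category_assignment`, with a `crucial` column if
#'   `crucial_only = TRUE`.
#' @param results A `deg_result` carrying directions.
#' @param crucial_only Restrict to crucial genes? Default `FALSE`.
#' @return A tibble `category`, `comparison`, `n_up`, `n_down`, `n`,
#'   `pct_up`, `pct_down` (percentages to full precision).
#' @export
regulation_summary <- function(assignments, results, crucial_only = FALSE) {
  x <- as_tibble(assignments) %>% filter(.data$category != "EXCLUDED")
  if (crucial_only) {
    if (!"crucial" %in% names(x)) {
      abort("`assignments` has no `crucial` column; run filter_crucial() first.")
    }
    x <- filter(x, .data$crucial)
  }
  keep_genes <- x$gene_id
  res <- as_tibble(results) %>%
    filter(.data$is_deg, .data$gene_id %in% keep_genes) %>%
    select("gene_id", "comparison", "direction")
  left_join(res, x[, c("gene_id", "category")], by = "gene_id") %>%
    group_by(.data$category, .data$comparison) %>%
    summarise(
      n_up = sum(.data$direction == "up"),
      n_down = sum(.data$direction == "down"),
      n = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(pct_up = 100 * .data$n_up / .data$n,
           pct_down = 100 * .data$n_down / .data$n)
}
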