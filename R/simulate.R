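#' Configuration of the synthetic four-library experiment
#'
#' The generator emulates the study design this package analyses: four
#' single-library tag-count samples (R, RT, S, ST) with Poisson counts, a
#' log-normal baseline expression distribution, genes planted into the
#' seven analysed Venn masks (and an `ST-RT`-contaminated mask) with effect
#' sizes above the second-round cutoffs, B. napus-style gene identifiers,
#' and annotation maps with planted term enrichment concentrated in the
#' planted crucial genes.
#'
#' Library totals default to 1e6, a down-scaled working size of deep
#' sequencing runs, keeping simulations fast while leaving counts in the
#' regime where the exact test has high power at the planted effects.
#'
#' Genes planted into a *singleton* mask (DE in exactly one comparison)
#' cannot have high counts in all four libraries: the four log2 ratios are
#' linearly dependent, so a strong single-comparison effect would force a
#' second comparison past threshold. Such genes are therefore planted with
#' one expressed side of moderate counts and the remaining libraries at a
#' few counts, where the other exact tests are underpowered while the
#' pseudocounted expression ratio of the active comparison is still
#' extreme -- the regime that produces singleton-region genes in real
#' libraries.
#'
#' @param n_genes Number of genes, default 2000.
#' @param library_totals Named totals for R, RT, S, ST; default 1e6 each.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-gene baseline expected count (at a 1e6-read library); defaults
#'   `log(30)` and 1.
#' @param planted_fractions Named fractions of `n_genes` planted per mask;
#'   names among the seven analysed masks plus `"S-R+ST-RT"` (the
#'   contaminated mask). Must sum to at most 1.
#' @param planted_log2_effects Named list of `c(min, max)` absolute log2
#'   effect ranges for the multiplier-based masks.
#' @param pathway_count,process_count Annotation-universe sizes; defaults
#'   128 and 1200.
#' @param pathway_density,process_density Mean terms per annotated gene;
#'   defaults 2 and 5.
#' @param unannotated_fraction Fraction of genes with no pathway
#'   annotation, default 0.3.
#' @param n_planted_terms Planted-enrichment terms per annotation kind,
#'   default 2.
#' @param planted_term_rate Probability that a planted term annotates a
#'   planted crucial gene, default 0.5 (background genes get the term at
#'   the ambient density).
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              library_totals = c(R = 1e6, RT = 1e6,
                                                 S = 1e6, ST = 1e6),
                              baseline_meanlog = log(30),
                              baseline_sdlog = 1,
                              planted_fractions = c(
                                "RT-R" = 0.010,
                                "RT-R+S-R" = 0.015,
                                "ST-S" = 0.005,
                                "S-R+ST-S" = 0.015,
                                "S-R" = 0.010,
                                "RT-R+ST-S" = 0.010,
                                "RT-R+S-R+ST-S" = 0.010,
                                "S-R+ST-RT" = 0.010),
                              planted_log2_effects = list(
                                "RT-R+S-R" = c(6, 9),
                                "S-R+ST-S" = c(3.5, 5),
                                "RT-R+ST-S" = c(4, 6),
                                "RT-R+S-R+ST-S" = c(3, 5),
                                "S-R+ST-RT" = c(2, 4)),
                              pathway_count = 128,
                              process_count = 1200,
                              pathway_density = 2,
                              process_density = 5,
                              unannotated_fraction = 0.3,
                              n_planted_terms = 2,
                              planted_term_rate = 0.5,
                              seed = 1L) {
  known_masks <- c("RT-R", "RT-R+S-R", "ST-S", "S-R+ST-S", "S-R",
                   "RT-R+ST-S", "RT-R+S-R+ST-S", "S-R+ST-RT")
  bad <- setdiff(names(planted_fractions), known_masks)
  if (length(bad) > 0) {
    abort(paste0("Unknown planted mask(s): ", paste(bad, collapse = ", ")))
  }
  if (any(planted_fractions < 0) || sum(planted_fractions) > 1) {
    abort("`planted_fractions` must be non-negative and sum to at most 1.")
  }
  for (rng in planted_log2_effects) {
    if (length(rng) != 2 || any(!is.finite(rng)) || rng[1] > rng[2]) {
      abort("Each planted effect range must be a finite c(min, max).")
    }
  }
  structure(list(
    n_genes = as.integer(n_genes),
    library_totals = library_totals[sample_labels()],
    baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog,
    planted_fractions = planted_fractions,
    planted_log2_effects = planted_log2_effects,
    pathway_count = as.integer(pathway_count),
    process_count = as.integer(process_count),
    pathway_density = pathway_density,
    process_density = process_density,
    unannotated_fraction = unannotated_fraction,
    n_planted_terms = as.integer(n_planted_terms),
    planted_term_rate = planted_term_rate,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# Random well-formed gene identifiers over the 19 chromosomes plus the
# unknown-position labels. Unique by construction.
random_gene_ids <- function(n) {
  chr <- sample(bna_chromosomes(), n, replace = TRUE)
  repeat {
    pos <- sprintf("%05d", sample(0:99999, n, replace = TRUE))
    ids <- paste0("Bna", chr, "g", pos, "D")
    if (!anyDuplicated(ids)) return(ids)
  }
}

# Expected per-library rates (at 1e6 total) of one planted gene.
# Returns c(R, RT, S, ST) and the designed crucial flag.
plant_rates <- function(mask, effect, sign, baseline) {
  b <- baseline
  switch(mask,
    # Singleton masks: expressed side at moderate counts, off-samples low
    # so the remaining tests are underpowered. The active comparison's
    # pseudocounted ratio is extreme (the planted direction is "down" in
    # the treated numerator, the dominant direction in this design).
    "RT-R" = c(R = 0, RT = b, S = 5, ST = 12),
    "ST-S" = c(R = 5, RT = 12, S = 0, ST = b),
    "S-R" = c(R = b, RT = b, S = 0, ST = 9),
    "RT-R+S-R" = c(R = b * 2^(sign * effect), RT = b, S = b, ST = b),
    "S-R+ST-S" = c(R = b, RT = b, S = b * 2^(sign * effect), ST = b),
    "RT-R+ST-S" = c(R = b * 2^(sign * effect), RT = b,
                    S = b * 2^(sign * effect), ST = b),
    "RT-R+S-R+ST-S" = c(R = b * 2^(sign * effect), RT = b,
                        S = b * 2^(-sign * 0.6 * effect), ST = b),
    "S-R+ST-RT" = c(R = b, RT = b, S = b * 2^(sign * effect),
                    ST = b * 2^(sign * effect)),
    abort(paste0("No planting template for mask '", mask, "'."))
  )
}

#' Simulate a four-library tag-count experiment with planted structure
#'
#' Draws per-gene Poisson counts for R, RT, S, ST with rates
#' `baseline x mask template x library-total scaling`, generates gene
#' identifiers in the BnaXNNgNNNNND convention, and builds pathway/process
#' annotation maps in which a few planted terms are concentrated in the
#' planted crucial genes. The same seed yields identical output; the
#' caller's RNG state is left untouched.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `counts` (a [count_table()]),
#'   `annotations` (an [annotation_map()]), `truth` (tibble: `gene_id`,
#'   `planted_mask` (`NA` for null genes), `category`, `crucial`,
#'   `planted_effect`), `term_truth` (tibble: `term_id`, `term_kind`,
#'   `planted`) and `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_genes
  ids <- random_gene_ids(n)
  len <- round(runif(n, 500, 3000))
  baseline <- rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)

  n_planted <- round(config$planted_fractions * n)
  masks <- rep(names(n_planted), n_planted)
  planted_idx <- seq_along(masks) # deterministic: first genes are planted
  truth_mask <- rep(NA_character_, n)
  truth_mask[planted_idx] <- masks
  effect <- rep(NA_real_, n)
  sign_v <- rep(NA_real_, n)

  # planted genes use power-adequate baselines; singleton templates use a
  # moderate expressed side by design
  rates <- matrix(rep(baseline, 4), ncol = 4,
                  dimnames = list(NULL, sample_labels()))
  for (i in planted_idx) {
    m <- masks[i]
    rng <- config$planted_log2_effects[[m]]
    eff <- if (is.null(rng)) NA_real_ else runif(1, rng[1], rng[2])
    sg <- sample(c(-1, 1), 1)
    b <- if (m %in% c("RT-R", "ST-S", "S-R")) runif(1, 22, 32)
         else runif(1, 50, 150)
    effect[i] <- eff
    sign_v[i] <- sg
    rates[i, ] <- plant_rates(m, eff, sg, b)[sample_labels()]
  }

  lt <- config$library_totals
  counts <- vapply(sample_labels(), function(s) {
    rpois(n, rates[, s] * lt[[s]] / 1e6)
  }, numeric(n))
  tab <- count_table(
    tibble(gene_id = ids, length = len,
           R = counts[, "R"], RT = counts[, "RT"],
           S = counts[, "S"], ST = counts[, "ST"]),
    lt
  )

  # truth categories via the assignment rules applied to the planted masks
  analysed <- !is.na(truth_mask) & truth_mask != "S-R+ST-RT"
  category <- rep(NA_character_, n)
  if (any(analysed)) {
    asg <- assign_categories(tibble(gene_id = ids[analysed],
                                    mask = truth_mask[analysed]))
    category[analysed] <- asg$category
  }
  category[!is.na(truth_mask) & truth_mask == "S-R+ST-RT"] <- "EXCLUDED"
  crucial <- !is.na(category) & category != "EXCLUDED"

  truth <- tibble(gene_id = ids, planted_mask = truth_mask,
                  category = category, crucial = crucial,
                  planted_effect = effect)

  ann <- simulate_annotations(ids, crucial, config)

  list(counts = tab, annotations = ann$map, truth = truth,
       term_truth = ann$term_truth, config = config)
}

# Annotation maps with ambient density plus planted term concentration in
# the crucial genes. Called inside simulate_experiment's seeded context.
simulate_annotations <- function(ids, crucial, config) {
  n <- length(ids)
  pw_terms <- sprintf("ko%05d", seq_len(config$pathway_count))
  bp_terms <- sprintf("GO:%07d", seq_len(config$process_count))
  annotated <- runif(n) >= config$unannotated_fraction

  draw <- function(terms, density, eligible) {
    k <- rpois(n, density) * eligible
    k <- pmin(k, length(terms))
    genes <- rep(ids, k)
    term <- unlist(lapply(k[k > 0], function(m) sample(terms, m)))
    tibble(gene_id = genes, term_id = if (length(genes)) term else character())
  }
  pw <- draw(pw_terms, config$pathway_density, annotated)
  bp <- draw(bp_terms, config$process_density, rep(TRUE, n))

  npl <- config$n_planted_terms
  planted_pw <- pw_terms[seq_len(min(npl, length(pw_terms)))]
  planted_bp <- bp_terms[seq_len(min(npl, length(bp_terms)))]
  plant <- function(tab, terms) {
    for (t in terms) {
      carriers <- ids[crucial & runif(n) < config$planted_term_rate]
      if (length(carriers) > 0) {
        tab <- bind_rows(tab, tibble(gene_id = carriers, term_id = t))
      }
    }
    distinct(tab)
  }
  pw <- plant(pw, planted_pw)
  bp <- plant(bp, planted_bp)
  # keep planted crucial genes pathway-annotated so they survive the
  # annotation filter: give each at least one ambient pathway
  bare <- setdiff(ids[crucial], unique(pw$gene_id))
  if (length(bare) > 0) {
    pw <- bind_rows(pw, tibble(gene_id = bare,
                               term_id = sample(pw_terms, length(bare),
                                                replace = TRUE)))
  }
  map <- annotation_map(pw, bp, background_size = n)
  term_truth <- bind_rows(
    tibble(term_id = pw_terms, term_kind = "pathway",
           planted = pw_terms %in% planted_pw),
    tibble(term_id = bp_terms, term_kind = "process",
           planted = bp_terms %in% planted_bp)
  )
  list(map = map, term_truth = term_truth)
}
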