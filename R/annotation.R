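#' Construct an annotation map
#'
#' Holds the two local annotation tables used throughout the pipeline: gene
#' to KEGG pathway (identifiers `koNNNNN`) and gene to GO biological-process
#' term, together with the whole-transcriptome background size used by the
#' enrichment tests. Pairs are deduplicated. No network access is ever
#' performed; annotations are plain local tables.
#'
#' @param pathways Data frame with columns `gene_id`, `term_id`
#'   (`koNNNNN`). May have zero rows.
#' @param processes Data frame with columns `gene_id`, `term_id` (GO
#'   biological-process identifiers or free-text labels). May have zero rows.
#' @param background_size Positive integer, the whole-transcriptome
#'   background gene count.
#' @return A list of class `annotation_map` with elements `pathways`,
#'   `processes` (tibbles) and `background_size`.
#' @export
annotation_map <- function(pathways, processes, background_size) {
  pathways <- as_tibble(pathways)
  processes <- as_tibble(processes)
  for (nm in list(pathways, processes)) {
    if (!all(c("gene_id", "term_id") %in% names(nm))) {
      abort("Annotation tables need columns `gene_id` and `term_id`.")
    }
  }
  bad <- which(!grepl("^ko[0-9]{5}$", pathways$term_id))
  if (length(bad) > 0) {
    abort(sprintf("Malformed pathway identifier '%s' (line %d); expected koNNNNN.",
                  pathways$term_id[bad[1]], bad[1]))
  }
  if (!is.numeric(background_size) || length(background_size) != 1 ||
      background_size < 1 || background_size != round(background_size)) {
    abort("`background_size` must be a positive integer.")
  }
  structure(
    list(
      pathways = distinct(pathways[, c("gene_id", "term_id")]),
      processes = distinct(processes[, c("gene_id", "term_id")]),
      background_size = as.integer(background_size)
    ),
    class = "annotation_map"
  )
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf(
    "<annotation_map> %d gene-pathway pairs (%d genes), %d gene-process pairs (%d genes), background %d genes\n",
    nrow(x$pathways), dplyr::n_distinct(x$pathways$gene_id),
    nrow(x$processes), dplyr::n_distinct(x$processes$gene_id),
    x$background_size
  ))
  invisible(x)
}

#' Genes carrying at least one annotation
#'
#' @param map An `annotation_map`.
#' @param kind `"pathway"` or `"process"`.
#' @return Character vector of gene identifiers.
#' @export
annotated_genes <- function(map, kind = c("pathway", "process")) {
  stopifnot(inherits(map, "annotation_map"))
  kind <- match.arg(kind)
  unique(if (kind == "pathway") map$pathways$gene_id else map$processes$gene_id)
}

#' Read annotation maps from two-column TSV files
#'
#' Each line is `gene_id <TAB> term_id`; no header. An empty file yields an
#' empty table (all genes then have empty term sets). Genes absent from the
#' pathway table are thereby unannotated, which drives the
#' pathway-annotation filter of the classification stage.
#'
#' @param pathway_path Path of the gene-to-pathway TSV.
#' @param process_path Path of the gene-to-process TSV.
#' @param background_size Whole-transcriptome background gene count.
#' @return An `annotation_map`.
#' @export
read_annotation_map <- function(pathway_path, process_path, background_size) {
  read2 <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) {
      return(tibble(gene_id = character(), term_id = character()))
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2)
    if (length(bad) > 0) {
      abort(sprintf("Malformed annotation line %d in %s.", bad[1], path))
    }
    tibble(gene_id = vapply(parts, `[`, "", 1),
           term_id = vapply(parts, `[`, "", 2))
  }
  pw <- read2(pathway_path)
  bad <- which(!grepl("^ko[0-9]{5}$", pw$term_id))
  if (length(bad) > 0) {
    abort(sprintf("Malformed pathway identifier '%s' at line %d of %s.",
                  pw$term_id[bad[1]], bad[1], pathway_path))
  }
  annotation_map(pw, read2(process_path), background_size)
}

#' Write an annotation map as two-column TSV files
#'
#' Inverse of [read_annotation_map()]; round-trip exact up to pair order.
#'
#' @param map An `annotation_map`.
#' @param pathway_path,process_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_annotation_map <- function(map, pathway_path, process_path) {
  stopifnot(inherits(map, "annotation_map"))
  write2 <- function(tab, path) {
    writeLines(if (nrow(tab) > 0) paste(tab$gene_id, tab$term_id, sep = "\t")
               else character(), path)
  }
  write2(map$pathways, pathway_path)
  write2(map$processes, process_path)
  invisible(c(pathway_path, process_path))
}
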