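#' Parse Brassica napus gene identifiers
#'
#' B. napus genes follow the convention `Bna` + chromosome label + `g` +
#' five-character locus code + `D`. Chromosome labels are `A01`--`A10` (the
#' A subgenome inherited from *B. rapa*), `C01`--`C09` (the C subgenome from
#' *B. oleracea*), or `Ann`/`Cnn`/`Unn` for genes whose chromosome position
#' is unknown. The locus code orders genes along a chromosome; no genomic
#' coordinate semantics are attached to it.
#'
#' Identifiers are case-sensitive and stored verbatim; parsing never
#' canonicalises.
#'
#' @param gene_id Character vector of gene identifiers.
#' @return A tibble with one row per identifier and columns `gene_id`,
#'   `chromosome` (the three-character label), `subgenome` (`"A"`, `"C"` or
#'   `"U"`), `position` (integer locus code) and `position_unknown` (`TRUE`
#'   for `Ann`/`Cnn`/`Unn` labels).
#' @examples
#' parse_gene_id(c("BnaA05g09600D", "BnaCnng59500D"))
#' @export
parse_gene_id <- function(gene_id) {
  if (!is.character(gene_id) || length(gene_id) == 0) {
    abort("`gene_id` must be a non-empty character vector.")
  }
  pat <- "^Bna(A(?:0[1-9]|10)|C0[1-9]|Ann|Cnn|Unn)g([0-9]{5})D$"
  ok <- grepl(pat, gene_id)
  if (!all(ok)) {
    bad <- unique(gene_id[!ok])
    abort(paste0(
      "Malformed gene identifier(s): ",
      paste0("'", head(bad, 5), "'", collapse = ", "),
      if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else ""
    ))
  }
  chrom <- sub(pat, "\\1", gene_id)
  pos <- as.integer(sub(pat, "\\2", gene_id))
  tibble(
    gene_id = gene_id,
    chromosome = chrom,
    subgenome = substr(chrom, 1, 1),
    position = pos,
    position_unknown = chrom %in% c("Ann", "Cnn", "Unn")
  )
}

#' Test whether strings are well-formed gene identifiers
#'
#' @param gene_id Character vector.
#' @return Logical vector.
#' @export
is_valid_gene_id <- function(gene_id) {
  grepl("^Bna(A(?:0[1-9]|10)|C0[1-9]|Ann|Cnn|Unn)g[0-9]{5}D$", gene_id)
}

#' Chromosome labels of the B. napus genome
#'
#' The 19 chromosomes A01--A10 and C01--C09, optionally followed by the
#' unknown-position labels Ann, Cnn and Unn.
#'
#' @param include_unknown Include `Ann`, `Cnn`, `Unn`? Default `TRUE`.
#' @return Character vector of labels.
#' @export
bna_chromosomes <- function(include_unknown = TRUE) {
  chr <- c(sprintf("A%02d", 1:10), sprintf("C%02d", 1:9))
  if (include_unknown) chr <- c(chr, "Ann", "Cnn", "Unn")
  chr
}
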