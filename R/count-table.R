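#' Sample labels of the four-library design
#'
#' R and S are the drought-resistant and drought-sensitive cultivars treated
#' with PEG-6000 osmoticum; RT and ST are their well-watered controls.
#'
#' @return Character vector `c("R", "RT", "S", "ST")`.
#' @export
sample_labels <- function() c("R", "RT", "S", "ST")

#' Construct a validated count table
#'
#' A count table holds the uniquely mapped clean-read counts of each gene in
#' the four libraries, the per-gene length in bases, and the per-library
#' total of uniquely aligned reads. Library totals are carried as metadata
#' rather than inferred from column sums because they count all uniquely
#' aligned reads genome-wide, not only reads on the analysed gene set.
#'
#' @param x Data frame with columns `gene_id`, `length`, `R`, `RT`, `S`,
#'   `ST`. Counts must be non-negative integers; lengths positive integers;
#'   gene identifiers unique.
#' @param library_total Named numeric vector with one positive entry per
#'   sample (`R`, `RT`, `S`, `ST`), each at least the corresponding column
#'   sum.
#' @return A tibble of class `count_table` with attribute `library_total`.
#' @export
count_table <- function(x, library_total) {
  x <- as_tibble(x)
  required <- c("gene_id", "length", sample_labels())
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Count table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(x), required)
  if (length(extra) > 0) {
    abort(paste0("Unknown sample label(s) in count table: ",
                 paste(extra, collapse = ", ")))
  }
  if (anyDuplicated(x$gene_id)) {
    abort(paste0("Duplicate gene_id(s): ",
                 paste(unique(x$gene_id[duplicated(x$gene_id)]), collapse = ", ")))
  }
  if (any(!is.finite(x$length)) || any(x$length <= 0) ||
      any(x$length != round(x$length))) {
    abort("`length` must be positive integers (bases).")
  }
  for (s in sample_labels()) {
    v <- x[[s]]
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad) > 0) {
      abort(sprintf("Non-integer or negative count in column %s, row %d.",
                    s, bad[1]))
    }
  }
  if (is.null(names(library_total)) ||
      !setequal(names(library_total), sample_labels())) {
    abort("`library_total` must be named with exactly R, RT, S, ST.")
  }
  library_total <- library_total[sample_labels()]
  if (any(!is.finite(library_total)) || any(library_total <= 0)) {
    abort("`library_total` entries must be positive.")
  }
  csum <- vapply(sample_labels(), function(s) sum(x[[s]]), numeric(1))
  short <- names(csum)[csum > library_total]
  if (length(short) > 0) {
    abort(paste0("library_total below column sum for sample(s): ",
                 paste(short, collapse = ", ")))
  }
  x <- x[, required]
  structure(x, library_total = library_total,
            class = c("count_table", class(x)))
}

#' Library totals of a count table
#'
#' @param x A `count_table`.
#' @return Named numeric vector of uniquely aligned read totals per sample.
#' @export
library_totals <- function(x) {
  stopifnot(inherits(x, "count_table"))
  attr(x, "library_total")
}

#' Read a count table from TSV
#'
#' Expects a metadata line `#library_total R=<int> RT=<int> S=<int> ST=<int>`
#' followed by a header `gene_id length R RT S ST` and one row per gene.
#'
#' @param path Path to the TSV file.
#' @return A `count_table`.
#' @export
read_count_table <- function(path) {
  lines <- readLines(path, n = 1L)
  if (length(lines) == 0 || !startsWith(lines[1], "#library_total")) {
    abort("First line must be '#library_total R=<int> RT=<int> S=<int> ST=<int>'.")
  }
  kv <- strsplit(trimws(sub("^#library_total\\s+", "", lines[1])), "\\s+")[[1]]
  parts <- strsplit(kv, "=", fixed = TRUE)
  if (any(lengths(parts) != 2)) abort("Malformed #library_total metadata line.")
  lt <- setNames(as.numeric(vapply(parts, `[`, "", 2)),
                 vapply(parts, `[`, "", 1))
  tab <- readr::read_tsv(path, skip = 1L, show_col_types = FALSE,
                         col_types = readr::cols(
                           gene_id = readr::col_character(),
                           .default = readr::col_double()
                         ))
  count_table(tab, lt)
}

#' Write a count table to TSV
#'
#' Inverse of [read_count_table()]; round-trip exact.
#'
#' @param x A `count_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  lt <- library_totals(x)
  meta <- paste0("#library_total ",
                 paste(sprintf("%s=%d", names(lt), as.integer(lt)), collapse = " "))
  writeLines(meta, path)
  readr::write_tsv(as_tibble(as.data.frame(x)), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}
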