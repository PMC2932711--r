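#' Construct an expression time-course dataset
#'
#' A light container for one platform's genes-by-time-points measurement
#' matrix. Rows are genes (unique canonical symbols), columns are ordered
#' time-point labels. Missing measurements are `NA` and are propagated as
#' missing, never as zero; correlations downstream use pairwise-complete
#' observations.
#'
#' @param values Numeric matrix, genes in rows, conditions in columns.
#'   Row and column names are required unless `genes`/`conditions` given.
#' @param dataset_id Short label, e.g. `"I"`.
#' @param platform `"count"` (SAGE-like discrete measurements) or
#'   `"continuous"` (array-like intensities/ratios).
#' @param genes,conditions Optional character vectors overriding the
#'   dimnames of `values`.
#' @param synonyms Synonym table passed to [canonicalize_symbols()].
#' @return An object of class `expression_dataset`: a list with elements
#'   `dataset_id`, `platform`, `genes`, `conditions`, `values`.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("Pax6", "Six3"), c("E13", "E15", "P0")))
#' expression_dataset(m, "demo", "continuous")
#' @export
expression_dataset <- function(values, dataset_id, platform = c("continuous", "count"),
                               genes = rownames(values),
                               conditions = colnames(values),
                               synonyms = default_synonyms()) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values)) {
    if (is.matrix(values) && nrow(values) == 0) {
      storage.mode(values) <- "double"
    } else {
      stop("`values` must be a numeric matrix", call. = FALSE)
    }
  }
  if (!is.character(dataset_id) || length(dataset_id) != 1 || !nzchar(dataset_id)) {
    stop("`dataset_id` must be a non-empty string", call. = FALSE)
  }
  if (is.null(conditions) || length(conditions) != ncol(values)) {
    stop("condition labels must match the number of columns", call. = FALSE)
  }
  if (ncol(values) < 2) {
    stop("an expression dataset needs at least 2 conditions", call. = FALSE)
  }
  if (nrow(values) > 0) {
    if (is.null(genes) || length(genes) != nrow(values)) {
      stop("gene symbols must match the number of rows", call. = FALSE)
    }
    genes <- canonicalize_symbols(genes, synonyms)
    if (anyDuplicated(symbol_key(genes))) {
      stop("gene symbols must be unique after canonicalization; ",
           "collapse duplicates first (see read_expression_matrix)",
           call. = FALSE)
    }
  } else {
    genes <- character(0)
  }
  dimnames(values) <- list(genes, as.character(conditions))
  structure(
    list(dataset_id = dataset_id, platform = platform,
         genes = genes, conditions = as.character(conditions),
         values = values),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset '%s'> %d genes x %d conditions [%s]\n",
              x$dataset_id, length(x$genes), length(x$conditions), x$platform))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

# Row lookup by case-insensitive canonical symbol; NA if absent.
dataset_row <- function(dataset, gene) {
  i <- match(symbol_key(gene), symbol_key(dataset$genes))
  if (is.na(i)) return(NULL)
  dataset$values[i, ]
}

dataset_has_gene <- function(dataset, gene) {
  symbol_key(gene) %in% symbol_key(dataset$genes)
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-delimited file with a header row of condition labels
#' (first cell blank or an arbitrary tag such as "gene") and one row per
#' gene: first column the gene symbol, remaining columns numeric
#' measurements with empty cells meaning missing. Duplicate gene rows
#' (e.g. multiple probes per symbol) are collapsed to one row by
#' per-condition median of the non-missing values; the collapse is
#' order-independent.
#'
#' @param path Path to the TSV file.
#' @inheritParams expression_dataset
#' @param quiet Suppress informational messages (empty file body,
#'   duplicate collapsing).
#' @return An [expression_dataset()].
#' @export
read_expression_matrix <- function(path, dataset_id, platform = c("continuous", "count"),
                                   synonyms = default_synonyms(), quiet = FALSE) {
  platform <- match.arg(platform)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    stop(sprintf("'%s': empty file, expected a header of condition labels", path),
         call. = FALSE)
  }
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  conditions <- header[-1]
  if (length(conditions) < 2) {
    stop(sprintf("'%s': need at least 2 condition columns, found %d",
                 path, length(conditions)), call. = FALSE)
  }
  body <- lines[-1]
  if (length(body) == 0) {
    if (!quiet) message(sprintf("'%s': header only, dataset has 0 genes", path))
    vals <- matrix(numeric(0), nrow = 0, ncol = length(conditions))
    return(expression_dataset(vals, dataset_id, platform,
                              genes = character(0), conditions = conditions,
                              synonyms = synonyms))
  }
  cells <- strsplit(body, "\t", fixed = TRUE)
  ncolumns <- length(conditions) + 1L
  raw_genes <- character(length(cells))
  vals <- matrix(NA_real_, nrow = length(cells), ncol = length(conditions))
  for (i in seq_along(cells)) {
    row <- cells[[i]]
    length(row) <- ncolumns  # right-pad missing trailing cells with NA
    raw_genes[[i]] <- row[[1]]
    cell <- trimws(row[-1])
    is_blank <- is.na(cell) | !nzchar(cell) | cell == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is_blank & is.na(num))
    if (length(bad)) {
      stop(sprintf("'%s': non-numeric value '%s' at gene row %d ('%s'), column '%s'",
                   path, cell[bad[1]], i, row[[1]], conditions[bad[1]]),
           call. = FALSE)
    }
    num[is_blank] <- NA_real_
    vals[i, ] <- num
  }
  genes <- canonicalize_symbols(raw_genes, synonyms)
  key <- symbol_key(genes)
  if (anyDuplicated(key)) {
    if (!quiet) {
      ndup <- sum(duplicated(key))
      message(sprintf("'%s': collapsing %d duplicate gene row(s) by per-condition median",
                      path, ndup))
    }
    first <- !duplicated(key)
    idx <- split(seq_along(key), factor(key, levels = key[first]))
    vals <- t(vapply(idx, function(rows) {
      apply(vals[rows, , drop = FALSE], 2, stats::median, na.rm = TRUE)
    }, numeric(length(conditions))))
    vals[is.nan(vals)] <- NA_real_
    genes <- genes[first]
  }
  expression_dataset(vals, dataset_id, platform,
                     genes = genes, conditions = conditions, synonyms = synonyms)
}

#' Write an expression dataset to TSV
#'
#' Inverse of [read_expression_matrix()]: full-precision (`%.17g`) values
#' so that a write/read round trip reproduces finite values bit-for-bit;
#' missing cells are written empty.
#'
#' @param dataset An [expression_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  fmt_val <- function(v) {
    ifelse(is.na(v), "", sprintf("%.17g", v))
  }
  lines <- c(
    paste(c("gene", dataset$conditions), collapse = "\t"),
    vapply(seq_along(dataset$genes), function(i) {
      paste(c(dataset$genes[[i]], fmt_val(dataset$values[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
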