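#' Average (midrank) ranks with ties
#'
#' Ranks 1..n are assigned in increasing order of value; tied values
#' receive the mean of the rank positions they span, so the rank sum is
#' always n(n+1)/2. This is the tie treatment under which
#' Pearson-on-ranks is the correct Spearman coefficient; the classical
#' 6*sum(d^2)/(n(n^2-1)) shortcut is biased under ties and is not used
#' anywhere in this package.
#'
#' @param values Numeric vector of finite values, length >= 1.
#' @return Numeric vector of ranks.
#' @examples
#' average_ranks(c(5, 5, 7))  # 1.5 1.5 3
#' @export
average_ranks <- function(values) {
  if (length(values) == 0) stop("cannot rank an empty sequence", call. = FALSE)
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("all values must be finite numbers", call. = FALSE)
  }
  n <- length(values)
  o <- order(values)
  r <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && values[o[j + 1L]] == values[o[i]]) j <- j + 1L
    r[o[i:j]] <- (i + j) / 2
    i <- j + 1L
  }
  r
}

#' Spearman rank correlation over complete pairs
#'
#' Drops pairs where either value is missing, midranks the remaining
#' values of each vector, and returns the Pearson correlation of the two
#' rank vectors. Returns `NA` (undefined, deliberately not an error and
#' never coerced to 0) when fewer than `min_pairs` complete pairs remain
#' or when either rank vector has zero variance: a constant profile must
#' neither create nor suppress an edge.
#'
#' @param x,y Numeric vectors of equal length; `NA` allowed.
#' @param min_pairs Minimum number of complete pairs required (default 4;
#'   rank correlation on fewer points is nearly uninformative).
#' @return Correlation in `[-1, 1]`, or `NA_real_` when undefined.
#' @examples
#' spearman_rho(1:4, c(2, 4, 6, 8))    # 1
#' spearman_rho(1:4, c(8, 6, 4, 2))    # -1
#' spearman_rho(rep(1, 4), 1:4)        # NA: zero rank variance
#' @export
spearman_rho <- function(x, y, min_pairs = 4L) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < max(2L, min_pairs)) return(NA_real_)
  rx <- average_ranks(x[keep])
  ry <- average_ranks(y[keep])
  rank_pearson(rx, ry)
}

# Pearson correlation of two rank vectors; NA on zero variance.
rank_pearson <- function(rx, ry) {
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sx <- sum(dx * dx)
  sy <- sum(dy * dy)
  if (sx <= 0 || sy <= 0) return(NA_real_)
  r <- sum(dx * dy) / sqrt(sx * sy)
  max(-1, min(1, r))
}

# Midrank each row of a matrix; only valid for rows without missing
# values (the complete-data fast path). Returns a matrix of ranks.
rank_rows <- function(values) {
  t(apply(values, 1, average_ranks))
}

#' Thresholded pairwise rank correlations within a dataset
#'
#' Computes Spearman correlations between all unordered pairs drawn from
#' two symbol sets (each pair once, no self-pairs) and keeps those with
#' defined rho passing the absolute threshold. Genes absent from the
#' dataset are silently skipped here; presence bookkeeping is the
#' caller's job (see [extract_esn()]).
#'
#' @param dataset An [expression_dataset()].
#' @param genes_a,genes_b Character vectors of gene symbols; `genes_b`
#'   defaults to `genes_a` (all pairs within one set).
#' @param threshold Absolute correlation threshold in (0, 1], default
#'   0.65.
#' @param min_pairs Passed to [spearman_rho()].
#' @param strict If `TRUE` use `|rho| > threshold` instead of the default
#'   inclusive `|rho| >= threshold`.
#' @return Data frame of class `correlation_edges` with columns `gene_a`,
#'   `gene_b` (unordered pair in lexicographic order), `rho`, `n_pairs`,
#'   `dataset_id`.
#' @export
pairwise_correlations <- function(dataset, genes_a, genes_b = genes_a,
                                  threshold = 0.65, min_pairs = 4L,
                                  strict = FALSE) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold <= 0 || threshold > 1) {
    stop("`threshold` must be a single number in (0, 1]", call. = FALSE)
  }
  key <- symbol_key(dataset$genes)
  ia <- match(unique(symbol_key(genes_a)), key)
  ib <- match(unique(symbol_key(genes_b)), key)
  ia <- ia[!is.na(ia)]
  ib <- ib[!is.na(ib)]
  if (length(ia) == 0 || length(ib) == 0) return(empty_edges(dataset$dataset_id))
  pairs <- unique_cross_pairs(ia, ib)
  if (nrow(pairs) == 0) return(empty_edges(dataset$dataset_id))

  vals <- dataset$values
  rows_needed <- unique(c(pairs[, 1], pairs[, 2]))
  complete <- !anyNA(vals[rows_needed, , drop = FALSE])
  if (complete) {
    ranks <- rank_rows(vals[rows_needed, , drop = FALSE])
    rownames(ranks) <- as.character(rows_needed)
    rho <- vapply(seq_len(nrow(pairs)), function(k) {
      rank_pearson(ranks[as.character(pairs[k, 1]), ],
                   ranks[as.character(pairs[k, 2]), ])
    }, numeric(1))
    npair <- rep(ncol(vals), nrow(pairs))
    if (ncol(vals) < max(2L, min_pairs)) rho[] <- NA_real_
  } else {
    res <- vapply(seq_len(nrow(pairs)), function(k) {
      x <- vals[pairs[k, 1], ]
      y <- vals[pairs[k, 2], ]
      c(spearman_rho(x, y, min_pairs), sum(is.finite(x) & is.finite(y)))
    }, numeric(2))
    rho <- res[1, ]
    npair <- res[2, ]
  }
  pass <- !is.na(rho) & (if (strict) abs(rho) > threshold else abs(rho) >= threshold)
  if (!any(pass)) return(empty_edges(dataset$dataset_id))
  ga <- dataset$genes[pairs[pass, 1]]
  gb <- dataset$genes[pairs[pass, 2]]
  swap <- tolower(ga) > tolower(gb)
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  out <- data.frame(gene_a = ga, gene_b = gb, rho = rho[pass],
                    n_pairs = as.integer(npair[pass]),
                    dataset_id = dataset$dataset_id,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("correlation_edges", "data.frame")
  out
}

empty_edges <- function(dataset_id = character(0)) {
  out <- data.frame(gene_a = character(0), gene_b = character(0),
                    rho = numeric(0), n_pairs = integer(0),
                    dataset_id = character(0), stringsAsFactors = FALSE)
  class(out) <- c("correlation_edges", "data.frame")
  out
}

# All unordered index pairs {i, j}, i != j, with i in ia and j in ib.
unique_cross_pairs <- function(ia, ib) {
  grid <- expand.grid(a = ia, b = ib, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$a != grid$b, , drop = FALSE]
  lo <- pmin(grid$a, grid$b)
  hi <- pmax(grid$a, grid$b)
  keep <- !duplicated(paste(lo, hi))
  cbind(lo[keep], hi[keep])
}
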