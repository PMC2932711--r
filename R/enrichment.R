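#' Log binomial coefficient
#'
#' `log(choose(n, k))` computed via log-gamma, numerically stable for
#' n ~ 1e4 and beyond. Out-of-range `k` (negative or greater than `n`)
#' returns `-Inf`, the log of a zero-probability contribution, so callers
#' can sum log-space terms without special-casing the support boundary.
#'
#' @param n Non-negative integer(s).
#' @param k Integer(s).
#' @return `log(choose(n, k))`, vectorized.
#' @examples
#' log_choose(5, 2)  # log(10)
#' log_choose(5, 6)  # -Inf
#' @export
log_choose <- function(n, k) {
  if (any(!is.finite(n)) || any(n < 0) || any(n != round(n))) {
    stop("`n` must be non-negative integer(s)", call. = FALSE)
  }
  if (any(!is.finite(k)) || any(k != round(k))) {
    stop("`k` must be integer(s)", call. = FALSE)
  }
  out <- lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
  out[k < 0 | k > n] <- -Inf
  out
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= x)` when `X` counts annotated genes in a size-`n` list drawn
#' without replacement from a universe of `N` genes of which `K` are
#' annotated. Terms are accumulated in log space (log-sum-exp) so the
#' result is accurate even deep in the tail. Returns exactly 1 when
#' `x <= max(0, n + K - N)` (the certain event) and 0 when
#' `x > min(n, K)` (empty support).
#'
#' This is the one-sided Fisher's exact / over-representation p-value.
#'
#' @param x Observed count (non-negative integer).
#' @param n List size.
#' @param K Annotated genes in the universe.
#' @param N Universe size.
#' @return Upper-tail probability.
#' @examples
#' hypergeom_upper_tail(7, 46, 550, 8544)  # ~0.026
#' @export
hypergeom_upper_tail <- function(x, n, K, N) {
  for (v in list(x = x, n = n, K = K, N = N)) {
    if (length(v) != 1 || !is.finite(v) || v != round(v)) {
      stop("x, n, K, N must be single finite integers", call. = FALSE)
    }
  }
  if (x < 0 || n < 0 || K < 0 || N < 0 || n > N || K > N) {
    stop("need 0 <= n <= N, 0 <= K <= N, x >= 0", call. = FALSE)
  }
  lo <- max(0, n + K - N)
  hi <- min(n, K)
  if (x <= lo) return(1)
  if (x > hi) return(0)
  i <- x:hi
  log_terms <- log_choose(K, i) + log_choose(N - K, n - i) - log_choose(N, n)
  m <- max(log_terms)
  min(1, exp(m + log(sum(exp(log_terms - m)))))
}

#' Construct an annotation set
#'
#' Either gene-level membership (`annotated_genes` plus `universe_size`)
#' or counts-only (`annotated_size` K and `universe_size` N without a
#' gene list — the form used when an annotation source declares its
#' universe by counts rather than by an enumerable gene list).
#'
#' @param term_id Annotation term identifier.
#' @param universe_size Total genes assayed, N.
#' @param annotated_genes Optional character vector of annotated symbols.
#' @param annotated_size K; required in counts-only mode, defaults to
#'   `length(annotated_genes)` otherwise.
#' @return Object of class `annotation_set`.
#' @export
annotation_set <- function(term_id, universe_size, annotated_genes = NULL,
                           annotated_size = NULL) {
  if (!is.numeric(universe_size) || length(universe_size) != 1 ||
      universe_size < 1 || universe_size != round(universe_size)) {
    stop("`universe_size` must be a positive integer", call. = FALSE)
  }
  if (!is.null(annotated_genes)) {
    annotated_genes <- canonicalize_symbols(annotated_genes)
    annotated_genes <- annotated_genes[!duplicated(symbol_key(annotated_genes))]
    if (is.null(annotated_size)) annotated_size <- length(annotated_genes)
    if (annotated_size != length(annotated_genes)) {
      stop("`annotated_size` disagrees with the supplied gene membership",
           call. = FALSE)
    }
  }
  if (is.null(annotated_size)) {
    stop("counts-only mode needs `annotated_size`", call. = FALSE)
  }
  if (annotated_size > universe_size) {
    stop("`annotated_size` cannot exceed `universe_size`", call. = FALSE)
  }
  structure(list(term_id = term_id,
                 annotated_genes = annotated_genes,
                 annotated_size = as.integer(annotated_size),
                 universe_size = as.integer(universe_size)),
            class = "annotation_set")
}

#' Read annotation sets
#'
#' Two formats: a two-column TSV of (gene, term) pairs — returning one
#' membership-mode [annotation_set()] per term, with `universe_size`
#' supplied by the caller — or a JSON file with objects
#' `{"term": ..., "K": ..., "N": ...}` (single object or array) for
#' counts-only sets.
#'
#' @param path Path to `.tsv` or `.json`.
#' @param universe_size Required for the TSV form.
#' @return Named list of [annotation_set()] objects, keyed by term.
#' @export
read_annotations <- function(path, universe_size = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    parsed <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (!is.data.frame(parsed)) parsed <- as.data.frame(parsed, stringsAsFactors = FALSE)
    if (!all(c("term", "K", "N") %in% names(parsed))) {
      stop(sprintf("'%s': counts-only JSON needs fields term, K, N", path),
           call. = FALSE)
    }
    sets <- lapply(seq_len(nrow(parsed)), function(i) {
      annotation_set(parsed$term[i], parsed$N[i], annotated_size = parsed$K[i])
    })
    names(sets) <- parsed$term
    return(sets)
  }
  if (is.null(universe_size)) {
    stop("gene-level TSV annotations need `universe_size`", call. = FALSE)
  }
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("gene", "term"), comment.char = "#")
  if (identical(tolower(tab$gene[1]), "gene")) tab <- tab[-1, , drop = FALSE]
  split_genes <- split(tab$gene, tab$term)
  sets <- lapply(names(split_genes), function(tm) {
    annotation_set(tm, universe_size, annotated_genes = split_genes[[tm]])
  })
  names(sets) <- names(split_genes)
  sets
}

#' Over-representation test for one annotation term
#'
#' One-sided (upper-tail) Fisher's exact test: is the annotation term
#' observed in the candidate list more often than expected when drawing
#' the same number of genes at random from the universe? In membership
#' mode, `x` is the size of the intersection between candidates and the
#' annotated genes; in counts-only mode the caller supplies the observed
#' count.
#'
#' @param candidates Character vector of candidate gene symbols.
#' @param annotation An [annotation_set()].
#' @param observed Observed annotated-candidate count; required in
#'   counts-only mode, ignored (with a warning) when membership is
#'   available.
#' @return Object of class `enrichment_result`: list with `term_id`,
#'   `x`, `n`, `K`, `N`, `p_value`.
#' @examples
#' ann <- annotation_set("GO:0007399", 8544, annotated_size = 550)
#' overrepresentation_test(paste0("g", 1:46), ann, observed = 7)
#' @export
overrepresentation_test <- function(candidates, annotation, observed = NULL) {
  stopifnot(inherits(annotation, "annotation_set"))
  candidates <- canonicalize_symbols(candidates)
  candidates <- candidates[!duplicated(symbol_key(candidates))]
  n <- length(candidates)
  N <- annotation$universe_size
  K <- annotation$annotated_size
  if (n > N) {
    stop("candidate list is larger than the universe", call. = FALSE)
  }
  if (!is.null(annotation$annotated_genes)) {
    if (!is.null(observed)) {
      warning("`observed` ignored: annotation supplies gene membership",
              call. = FALSE)
    }
    x <- sum(symbol_key(candidates) %in% symbol_key(annotation$annotated_genes))
  } else {
    if (is.null(observed)) {
      stop("counts-only annotation needs `observed`", call. = FALSE)
    }
    x <- as.integer(observed)
    if (x < 0 || x > min(n, K)) {
      stop("`observed` must lie in [0, min(n, K)]", call. = FALSE)
    }
  }
  structure(list(term_id = annotation$term_id, x = x, n = n, K = K, N = N,
                 p_value = hypergeom_upper_tail(x, n, K, N)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> term %s: %d/%d annotated (universe %d/%d), upper-tail p = %.4g\n",
              x$term_id, x$x, x$n, x$K, x$N, x$p_value))
  invisible(x)
}

#' Test several annotation terms against one candidate list
#'
#' Runs [overrepresentation_test()] per term; Benjamini-Hochberg
#' adjustment across terms is available but off by default (the intended
#' use is a single biologically motivated term).
#'
#' @param candidates Character vector of candidate symbols.
#' @param annotations Named list of [annotation_set()] objects.
#' @param observed Optional named numeric vector of observed counts for
#'   counts-only sets.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame: `term_id`, `x`, `n`, `K`, `N`, `p_value`, and
#'   `p_adjusted` when `adjust = "BH"`.
#' @export
enrich_terms <- function(candidates, annotations, observed = NULL,
                         adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  res <- lapply(names(annotations), function(tm) {
    obs <- if (!is.null(observed) && tm %in% names(observed)) observed[[tm]] else NULL
    r <- overrepresentation_test(candidates, annotations[[tm]], observed = obs)
    data.frame(term_id = r$term_id, x = r$x, n = r$n, K = r$K, N = r$N,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}
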