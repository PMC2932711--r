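#' Genes correlated with one seed gene in one dataset
#'
#' All genes in the dataset (other than the seed itself) whose rank
#' correlation with the seed is defined and passes the absolute
#' threshold. A seed absent from the dataset yields an empty list — a
#' logged condition, not an error, mirroring how per-platform absence is
#' reported in the extraction step.
#'
#' @param dataset An [expression_dataset()].
#' @param seed Seed gene symbol.
#' @inheritParams pairwise_correlations
#' @param quiet Suppress the absence message.
#' @return Data frame with columns `gene`, `rho`, sorted by `|rho|`
#'   descending then symbol.
#' @export
seed_correlate_list <- function(dataset, seed, threshold = 0.65, min_pairs = 4L,
                                strict = FALSE, quiet = FALSE) {
  stopifnot(inherits(dataset, "expression_dataset"))
  seed <- normalize_symbol(seed)
  i <- match(symbol_key(seed), symbol_key(dataset$genes))
  if (is.na(i)) {
    if (!quiet) {
      message(sprintf("seed '%s' not present in dataset '%s'", seed, dataset$dataset_id))
    }
    return(data.frame(gene = character(0), rho = numeric(0), stringsAsFactors = FALSE))
  }
  vals <- dataset$values
  x <- vals[i, ]
  others <- setdiff(seq_len(nrow(vals)), i)
  if (length(others) == 0) {
    return(data.frame(gene = character(0), rho = numeric(0), stringsAsFactors = FALSE))
  }
  if (!anyNA(vals)) {
    # complete-data fast path: rank once, correlate the seed's rank
    # vector against every other row's
    rx <- average_ranks(x)
    ranks <- rank_rows(vals[others, , drop = FALSE])
    if (ncol(vals) < max(2L, min_pairs)) {
      rho <- rep(NA_real_, length(others))
    } else {
      dx <- rx - mean(rx)
      sx <- sum(dx * dx)
      centered <- ranks - rowMeans(ranks)
      sy <- rowSums(centered * centered)
      rho <- as.numeric(centered %*% dx) / sqrt(sx * sy)
      rho[sx <= 0 | sy <= 0] <- NA_real_
      rho <- pmax(-1, pmin(1, rho))
    }
  } else {
    rho <- vapply(others, function(j) spearman_rho(x, vals[j, ], min_pairs),
                  numeric(1))
  }
  pass <- !is.na(rho) & (if (strict) abs(rho) > threshold else abs(rho) >= threshold)
  out <- data.frame(gene = dataset$genes[others[pass]], rho = rho[pass],
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$rho), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the per-(seed, dataset) support table
#'
#' Runs [seed_correlate_list()] for every query seed in every dataset and
#' stacks the results into one long table — the raw material for
#' [aggregate_candidates()].
#'
#' @param datasets List of [expression_dataset()] objects.
#' @param seeds Character vector of query seed symbols (typically
#'   [esn_query_seeds()] of an extracted network).
#' @inheritParams seed_correlate_list
#' @return Data frame with columns `seed`, `dataset_id`, `gene`, `rho`.
#' @export
candidate_supports <- function(datasets, seeds, threshold = 0.65, min_pairs = 4L,
                               strict = FALSE, quiet = TRUE) {
  seeds <- canonicalize_symbols(seeds)
  seeds <- seeds[!duplicated(symbol_key(seeds))]
  rows <- list()
  for (ds in datasets) {
    for (s in seeds) {
      hits <- seed_correlate_list(ds, s, threshold, min_pairs, strict, quiet = quiet)
      if (nrow(hits)) {
        rows[[length(rows) + 1L]] <- data.frame(
          seed = s, dataset_id = ds$dataset_id, gene = hits$gene, rho = hits$rho,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(seed = character(0), dataset_id = character(0),
                      gene = character(0), rho = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Aggregate per-seed lists into candidate records
#'
#' A gene becomes a candidate when it appears in the correlate lists of at
#' least `min_seeds` *distinct* seed genes, pooled over the union of all
#' datasets (a candidate need not meet all its seeds on one platform; a
#' seed supported in two datasets still counts once). Seed genes
#' themselves are never candidates. Records are sorted by `n_seeds`
#' descending, then gene symbol.
#'
#' @param supports Long support table from [candidate_supports()] —
#'   columns `seed`, `dataset_id`, `gene`, `rho` — or a named list of
#'   such pieces which will be row-bound.
#' @param seed_set Character vector of all seed symbols (used to exclude
#'   seeds from candidacy; defaults to the seeds appearing in
#'   `supports`).
#' @param min_seeds Minimum number of distinct supporting seeds
#'   (default 3, inclusive).
#' @return Object of class `candidate_records`: list with `records`
#'   (data frame `gene`, `n_seeds`, `seed_signature` — distinct sorted
#'   seeds collapsed with `"|"`) and `supports` (the per-record long
#'   table, columns `gene`, `seed`, `dataset_id`, `rho`).
#' @export
aggregate_candidates <- function(supports, seed_set = NULL, min_seeds = 3L) {
  if (is.list(supports) && !is.data.frame(supports)) {
    supports <- do.call(rbind, supports)
  }
  stopifnot(is.data.frame(supports))
  if (!all(c("seed", "dataset_id", "gene", "rho") %in% names(supports))) {
    stop("`supports` needs columns seed, dataset_id, gene, rho", call. = FALSE)
  }
  if (!is.numeric(min_seeds) || length(min_seeds) != 1 || is.na(min_seeds) ||
      min_seeds < 1) {
    stop("`min_seeds` must be a single integer >= 1", call. = FALSE)
  }
  min_seeds <- as.integer(min_seeds)
  if (is.null(seed_set)) seed_set <- unique(supports$seed)
  seed_key <- symbol_key(if (length(seed_set)) canonicalize_symbols(seed_set) else character(0))

  empty <- structure(
    list(records = data.frame(gene = character(0), n_seeds = integer(0),
                              seed_signature = character(0),
                              stringsAsFactors = FALSE),
         supports = data.frame(gene = character(0), seed = character(0),
                               dataset_id = character(0), rho = numeric(0),
                               stringsAsFactors = FALSE),
         min_seeds = min_seeds),
    class = "candidate_records")
  if (nrow(supports) == 0) return(empty)

  supports <- supports[!(symbol_key(supports$gene) %in% seed_key), , drop = FALSE]
  if (nrow(supports) == 0) return(empty)

  gkey <- symbol_key(supports$gene)
  per_gene <- split(seq_len(nrow(supports)), gkey)
  rec <- lapply(per_gene, function(ix) {
    seeds <- sort(unique(supports$seed[ix]))
    data.frame(gene = supports$gene[ix[1]],
               n_seeds = length(seeds),
               seed_signature = paste(seeds, collapse = "|"),
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, c(rec, list(make.row.names = FALSE)))
  rec <- rec[rec$n_seeds >= min_seeds, , drop = FALSE]
  if (nrow(rec) == 0) return(empty)
  rec <- rec[order(-rec$n_seeds, rec$gene), , drop = FALSE]
  rownames(rec) <- NULL

  keep <- gkey %in% symbol_key(rec$gene)
  sup <- supports[keep, c("gene", "seed", "dataset_id", "rho")]
  sup <- sup[order(match(symbol_key(sup$gene), symbol_key(rec$gene)),
                   sup$seed, sup$dataset_id), , drop = FALSE]
  rownames(sup) <- NULL
  structure(list(records = rec, supports = sup, min_seeds = min_seeds),
            class = "candidate_records")
}

#' @export
print.candidate_records <- function(x, ...) {
  cat(sprintf("<candidate_records> %d candidate(s) with >= %d distinct seed(s)\n",
              nrow(x$records), x$min_seeds))
  if (nrow(x$records)) print(utils::head(x$records, 10))
  invisible(x)
}

#' Group candidates by their seed signature
#'
#' Candidates sharing exactly the same distinct-seed set form a group;
#' groups get letter labels a, b, c, ... in order of first appearance
#' under the record sort (n_seeds descending, gene ascending), mirroring
#' how correlated-seed groups are designated in candidate tables.
#'
#' @param records A [aggregate_candidates()] result.
#' @return Data frame with columns `label`, `seed_signature`, `n_genes`,
#'   `genes` (list column).
#' @export
group_by_seed_signature <- function(records) {
  stopifnot(inherits(records, "candidate_records"))
  rec <- records$records
  if (nrow(rec) == 0) {
    return(data.frame(label = character(0), seed_signature = character(0),
                      n_genes = integer(0), genes = I(list()),
                      stringsAsFactors = FALSE))
  }
  sigs <- unique(rec$seed_signature)
  labels <- make_group_labels(length(sigs))
  out <- data.frame(label = labels, seed_signature = sigs,
                    n_genes = NA_integer_, stringsAsFactors = FALSE)
  out$genes <- I(lapply(sigs, function(s) rec$gene[rec$seed_signature == s]))
  out$n_genes <- lengths(out$genes)
  out
}

# a, b, ..., z, aa, ab, ... for however many groups appear
make_group_labels <- function(n) {
  if (n <= 26) return(letters[seq_len(n)])
  c(letters, paste0(rep(letters, each = 26), letters))[seq_len(n)]
}

#' Per-seed candidate counts and core-subset counts
#'
#' For every seed, the number of candidates whose signature contains it;
#' optionally, for each named seed subset, the number of candidates whose
#' signature contains *every* member (e.g. how many candidates correlate
#' minimally with a named seed core).
#'
#' @param records A [aggregate_candidates()] result.
#' @param core_sets Optional named list of character vectors of seeds.
#' @return List with `per_seed` (data frame `seed`, `n_candidates`,
#'   sorted by count descending then seed) and `core` (data frame
#'   `core`, `seeds`, `n_candidates`; `NULL` when no `core_sets`).
#' @export
core_seed_summary <- function(records, core_sets = NULL) {
  stopifnot(inherits(records, "candidate_records"))
  rec <- records$records
  sig_list <- strsplit(rec$seed_signature, "|", fixed = TRUE)
  seeds <- sort(unique(unlist(sig_list)))
  per_seed <- data.frame(
    seed = as.character(seeds),
    n_candidates = vapply(seeds, function(s) {
      sum(vapply(sig_list, function(sig) s %in% sig, logical(1)))
    }, integer(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE, row.names = NULL)
  per_seed <- per_seed[order(-per_seed$n_candidates, per_seed$seed), , drop = FALSE]
  rownames(per_seed) <- NULL
  core <- NULL
  if (!is.null(core_sets)) {
    core <- data.frame(
      core = names(core_sets),
      seeds = vapply(core_sets, paste, character(1), collapse = "|"),
      n_candidates = vapply(core_sets, function(cs) {
        cs <- canonicalize_symbols(cs)
        sum(vapply(sig_list, function(sig) all(symbol_key(cs) %in% symbol_key(sig)),
                   logical(1)))
      }, integer(1)),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  list(per_seed = per_seed, core = core)
}

#' Write a candidate table to TSV
#'
#' One row per candidate: gene, distinct-seed count, seed signature, and
#' one column per dataset holding that dataset's supports as
#' `seed(rho)` entries separated by `"; "`.
#'
#' @param records A [aggregate_candidates()] result.
#' @param path Output path.
#' @param dataset_ids Dataset order for the per-dataset columns; defaults
#'   to order of first appearance in the supports.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(records, path,
                                  dataset_ids = unique(records$supports$dataset_id)) {
  stopifnot(inherits(records, "candidate_records"))
  rec <- records$records
  sup <- records$supports
  header <- paste(c("gene", "n_seeds", "seed_signature",
                    paste0("supports_", dataset_ids)), collapse = "\t")
  lines <- vapply(seq_len(nrow(rec)), function(i) {
    g <- rec$gene[i]
    cells <- vapply(dataset_ids, function(d) {
      rows <- sup[symbol_key(sup$gene) == symbol_key(g) & sup$dataset_id == d, ,
                  drop = FALSE]
      if (nrow(rows) == 0) return("")
      paste(sprintf("%s(%.3f)", rows$seed, rows$rho), collapse = "; ")
    }, character(1))
    paste(c(g, rec$n_seeds[i], rec$seed_signature[i], cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}
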