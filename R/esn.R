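#' Project a fly seed network onto mouse homologs
#'
#' The mouse seed set is the union of all mapped symbols (fly genes
#' sharing a homolog are merged: `toy` and `ey` both map to `Pax6`, which
#' appears once). Each fly edge (a, b, sign) expands to the full cross
#' product map(a) x map(b); self-pairs arising when both endpoints share a
#' homolog are excluded, and each projected pair records the fly edge it
#' came from.
#'
#' @param spec A [seed_network_spec()].
#' @param map A [homolog_map()]; every fly node of `spec` must have an
#'   entry.
#' @return List with `seed_genes` (character vector of distinct canonical
#'   mouse symbols) and `edges` (data frame `fly_a`, `fly_b`, `sign`,
#'   `mouse_a`, `mouse_b`, pairs in lexicographic order).
#' @export
project_homologs <- function(spec, map) {
  stopifnot(inherits(spec, "seed_network_spec"), inherits(map, "homolog_map"))
  fly_key <- tolower(names(map$entries))
  missing <- spec$fly_nodes[!(tolower(spec$fly_nodes) %in% fly_key)]
  if (length(missing)) {
    stop(sprintf("fly gene(s) missing from the homolog map: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  lookup <- function(fly) map$entries[[match(tolower(fly), fly_key)]]
  seed_genes <- unique(unlist(lapply(spec$fly_nodes, lookup), use.names = FALSE))
  seed_genes <- seed_genes[!duplicated(symbol_key(seed_genes))]

  expansions <- lapply(seq_len(nrow(spec$fly_edges)), function(i) {
    e <- spec$fly_edges[i, ]
    grid <- expand.grid(mouse_a = lookup(e$gene_a), mouse_b = lookup(e$gene_b),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[symbol_key(grid$mouse_a) != symbol_key(grid$mouse_b), , drop = FALSE]
    if (nrow(grid) == 0) return(NULL)
    swap <- tolower(grid$mouse_a) > tolower(grid$mouse_b)
    tmp <- grid$mouse_a[swap]; grid$mouse_a[swap] <- grid$mouse_b[swap]
    grid$mouse_b[swap] <- tmp
    data.frame(fly_a = e$gene_a, fly_b = e$gene_b, sign = e$sign,
               mouse_a = grid$mouse_a, mouse_b = grid$mouse_b,
               stringsAsFactors = FALSE)
  })
  expansions <- Filter(Negate(is.null), expansions)
  edges <- if (length(expansions)) do.call(rbind, expansions) else NULL
  if (!is.null(edges)) rownames(edges) <- NULL
  if (is.null(edges)) {
    edges <- data.frame(fly_a = character(0), fly_b = character(0),
                        sign = integer(0), mouse_a = character(0),
                        mouse_b = character(0), stringsAsFactors = FALSE)
  }
  list(seed_genes = seed_genes, edges = edges)
}

#' Extract the correlation-supported seed network (ESN)
#'
#' For each dataset, screens *all* unordered pairs among the seed genes
#' present in that dataset at `|rho| >= threshold` — not only pairs that
#' realize a fly edge, so paralog pairs without a fly counterpart (e.g.
#' Eya2--Eya3) can appear. Per (gene, dataset) presence is recorded as
#' `"present_correlated"` (at least one passing edge touches the gene
#' there), `"present_uncorrelated"` (gene assayed, no passing edge), or
#' `"absent"` (gene not assayed on that platform).
#'
#' @param datasets List of [expression_dataset()] objects (non-empty).
#' @param seed_genes Character vector of mouse seed symbols.
#' @inheritParams pairwise_correlations
#' @return Object of class `extracted_seed_network`: list with
#'   `seed_genes`, `presence` (character matrix, genes x datasets),
#'   `edges` (`correlation_edges` across all datasets), `threshold`,
#'   `min_pairs`, `strict`.
#' @export
extract_esn <- function(datasets, seed_genes, threshold = 0.65, min_pairs = 4L,
                        strict = FALSE) {
  if (!is.list(datasets) || length(datasets) == 0 ||
      !all(vapply(datasets, inherits, logical(1), "expression_dataset"))) {
    stop("`datasets` must be a non-empty list of expression_dataset objects",
         call. = FALSE)
  }
  seed_genes <- canonicalize_symbols(seed_genes)
  seed_genes <- seed_genes[!duplicated(symbol_key(seed_genes))]
  ids <- vapply(datasets, `[[`, character(1), "dataset_id")
  if (anyDuplicated(ids)) stop("dataset_id labels must be unique", call. = FALSE)

  presence <- matrix("absent", nrow = length(seed_genes), ncol = length(datasets),
                     dimnames = list(seed_genes, ids))
  all_edges <- vector("list", length(datasets))
  for (d in seq_along(datasets)) {
    ds <- datasets[[d]]
    here <- symbol_key(seed_genes) %in% symbol_key(ds$genes)
    presence[here, d] <- "present_uncorrelated"
    ed <- pairwise_correlations(ds, seed_genes[here], threshold = threshold,
                                min_pairs = min_pairs, strict = strict)
    if (nrow(ed)) {
      # report edges under the seed set's canonical casing
      ed$gene_a <- seed_genes[match(symbol_key(ed$gene_a), symbol_key(seed_genes))]
      ed$gene_b <- seed_genes[match(symbol_key(ed$gene_b), symbol_key(seed_genes))]
      touched <- symbol_key(seed_genes) %in% symbol_key(c(ed$gene_a, ed$gene_b))
      presence[touched, d] <- "present_correlated"
    }
    all_edges[[d]] <- ed
  }
  edges <- do.call(rbind, all_edges)
  rownames(edges) <- NULL
  class(edges) <- c("correlation_edges", "data.frame")
  structure(
    list(seed_genes = seed_genes, presence = presence, edges = edges,
         threshold = threshold, min_pairs = min_pairs, strict = strict),
    class = "extracted_seed_network"
  )
}

#' @export
print.extracted_seed_network <- function(x, ...) {
  cat(sprintf("<extracted_seed_network> %d seed genes, %d passing edges across %d dataset(s), |rho| %s %.2f\n",
              length(x$seed_genes), nrow(x$edges), ncol(x$presence),
              if (isTRUE(x$strict)) ">" else ">=", x$threshold))
  cat(sprintf("  query seeds (>=1 edge in >=1 dataset): %d\n",
              length(esn_query_seeds(x))))
  invisible(x)
}

#' Seed genes eligible as query seeds
#'
#' The ESN node set used for downstream candidate querying: every seed
#' gene with at least one passing edge in at least one dataset. Genes
#' with no edge anywhere stay in the presence report but are not used as
#' query seeds.
#'
#' @param esn An [extract_esn()] result.
#' @return Character vector of seed symbols.
#' @export
esn_query_seeds <- function(esn) {
  stopifnot(inherits(esn, "extracted_seed_network"))
  esn$seed_genes[apply(esn$presence == "present_correlated", 1, any)]
}

#' Compare an extracted seed network to the fly seed network
#'
#' Classifies each fly edge as `supported` (at least one projected mouse
#' pair realized by a passing edge in at least one dataset), `untestable`
#' (no projected pair could ever be tested: the projection is empty, or
#' for every projected pair at least one endpoint is absent from every
#' dataset), or `unsupported` (testable but no realizing edge). For
#' supported edges, `sign_agreement` records whether any realizing mouse
#' edge's rho sign matches the fly edge sign, and `sign_conflict` whether
#' realizing edges disagree in sign among themselves (kept per-dataset,
#' flagged here).
#'
#' @param esn An [extract_esn()] result built with the same `map`.
#' @param spec A [seed_network_spec()].
#' @param map The [homolog_map()] used for the projection.
#' @return Object of class `fly_conservation_report`: list with
#'   `per_edge` (data frame: `fly_a`, `fly_b`, `fly_sign`, `status`,
#'   `n_support`, `sign_agreement`, `sign_conflict`) and `counts`
#'   (named vector over the three statuses).
#' @export
compare_to_fly <- function(esn, spec, map) {
  stopifnot(inherits(esn, "extracted_seed_network"))
  proj <- project_homologs(spec, map)
  present_anywhere <- rownames(esn$presence)[apply(esn$presence != "absent", 1, any)]
  pk <- symbol_key(present_anywhere)
  edge_key <- paste(symbol_key(esn$edges$gene_a), symbol_key(esn$edges$gene_b))

  per_edge <- lapply(seq_len(nrow(spec$fly_edges)), function(i) {
    e <- spec$fly_edges[i, ]
    pp <- proj$edges[proj$edges$fly_a == e$gene_a & proj$edges$fly_b == e$gene_b, ,
                     drop = FALSE]
    if (nrow(pp) == 0) {
      return(data.frame(fly_a = e$gene_a, fly_b = e$gene_b, fly_sign = e$sign,
                        status = "untestable", n_support = 0L,
                        sign_agreement = NA, sign_conflict = NA,
                        stringsAsFactors = FALSE))
    }
    testable <- symbol_key(pp$mouse_a) %in% pk & symbol_key(pp$mouse_b) %in% pk
    hit <- match(paste(symbol_key(pp$mouse_a), symbol_key(pp$mouse_b)), edge_key)
    realized <- which(!is.na(hit))
    if (length(realized)) {
      rhos <- esn$edges$rho[edge_key %in%
                              paste(symbol_key(pp$mouse_a), symbol_key(pp$mouse_b))[realized]]
      data.frame(fly_a = e$gene_a, fly_b = e$gene_b, fly_sign = e$sign,
                 status = "supported", n_support = length(rhos),
                 sign_agreement = any(sign(rhos) == e$sign),
                 sign_conflict = length(unique(sign(rhos))) > 1,
                 stringsAsFactors = FALSE)
    } else if (!any(testable)) {
      data.frame(fly_a = e$gene_a, fly_b = e$gene_b, fly_sign = e$sign,
                 status = "untestable", n_support = 0L,
                 sign_agreement = NA, sign_conflict = NA,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(fly_a = e$gene_a, fly_b = e$gene_b, fly_sign = e$sign,
                 status = "unsupported", n_support = 0L,
                 sign_agreement = NA, sign_conflict = NA,
                 stringsAsFactors = FALSE)
    }
  })
  per_edge <- do.call(rbind, per_edge)
  counts <- c(supported = sum(per_edge$status == "supported"),
              unsupported = sum(per_edge$status == "unsupported"),
              untestable = sum(per_edge$status == "untestable"))
  structure(list(per_edge = per_edge, counts = counts),
            class = "fly_conservation_report")
}

#' @export
print.fly_conservation_report <- function(x, ...) {
  cat("<fly_conservation_report>\n")
  print(x$counts)
  invisible(x)
}
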