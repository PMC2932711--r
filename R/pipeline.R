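#' Simulate a study and write it to disk
#'
#' Writes one TSV per dataset (`dataset_<id>.tsv`), a fly-style homolog
#' map (`homologs.tsv`, synthetic fly symbols `fly_<seed>` mapping 1:1 to
#' the mouse-style seed symbols), a signed seed-network edge list
#' (`seed_network.tsv`, the planted co-module pairs expressed over the
#' synthetic fly symbols), and the truth manifest (`truth.json`). Output
#' is deterministic given the config, byte for byte.
#'
#' @param config A [synthetic_config()], or a path to a JSON file of
#'   config fields understood by [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the [generate_study()] result.
#' @export
sn_simulate <- function(config, out_dir) {
  if (is.character(config)) {
    fields <- jsonlite::fromJSON(config, simplifyVector = TRUE)
    if (!is.null(fields$seed_genes)) {
      fields$seed_genes <- unlist(fields$seed_genes)
    }
    config <- do.call(synthetic_config, fields)
  }
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- generate_study(config)

  for (ds in study$datasets) {
    write_expression_matrix(ds, file.path(out_dir, sprintf("dataset_%s.tsv", ds$dataset_id)))
  }
  seeds <- names(config$seed_genes)
  writeLines(c("fly_gene\tmouse_homologs",
               paste(paste0("fly_", seeds), seeds, sep = "\t")),
             file.path(out_dir, "homologs.tsv"))
  # planted network over the synthetic fly symbols: distinct co-module
  # pairs with their planted sign (dataset-independent)
  pe <- study$truth$planted_seed_edges
  key <- paste(pe$gene_a, pe$gene_b)
  first <- !duplicated(key)
  writeLines(c("gene_a\tgene_b\tsign",
               if (any(first)) {
                 paste(paste0("fly_", pe$gene_a[first]),
                       paste0("fly_", pe$gene_b[first]),
                       ifelse(pe$sign[first] > 0, "+", "-"), sep = "\t")
               }),
             file.path(out_dir, "seed_network.tsv"))
  truth <- study$truth
  jsonlite::write_json(
    list(planted_seed_edges = truth$planted_seed_edges,
         planted_candidates = truth$planted_candidates,
         absences = truth$absences,
         universe = truth$universe,
         config = truth$config),
    file.path(out_dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(study)
}

#' Extract an ESN from dataset files and write reports
#'
#' Reads the expression matrices, homolog map, and fly seed network;
#' projects the network onto the mapped symbols; extracts the
#' correlation-supported seed network; and writes `presence.tsv`,
#' `edges.tsv`, `esn.sif` (+ companion `esn_edges.tsv`),
#' `conservation.tsv`, and `query_seeds.txt` under `out_dir`.
#'
#' @param dataset_paths Character vector of expression TSV paths.
#' @param homologs_path Two-column homolog TSV.
#' @param seed_network_path Three-column signed edge TSV.
#' @param out_dir Output directory.
#' @param platforms Platform tag per dataset (scalar recycled).
#' @param dataset_ids Labels per dataset; default I, II, III, ...
#' @inheritParams pairwise_correlations
#' @return Invisibly, a list with `esn`, `report`, `spec`, `map`,
#'   `datasets`.
#' @export
sn_extract <- function(dataset_paths, homologs_path, seed_network_path, out_dir,
                       platforms = "continuous",
                       dataset_ids = as.character(utils::as.roman(seq_along(dataset_paths))),
                       threshold = 0.65, min_pairs = 4L, strict = FALSE) {
  if (length(platforms) == 1) platforms <- rep(platforms, length(dataset_paths))
  datasets <- Map(function(p, id, plat) {
    read_expression_matrix(p, id, plat, quiet = TRUE)
  }, dataset_paths, dataset_ids, platforms)
  names(datasets) <- dataset_ids
  map <- read_homolog_map(homologs_path)
  spec <- read_seed_network(seed_network_path)
  proj <- project_homologs(spec, map)
  esn <- extract_esn(datasets, proj$seed_genes, threshold, min_pairs, strict)
  report <- compare_to_fly(esn, spec, map)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pres <- esn$presence
  writeLines(c(paste(c("gene", colnames(pres)), collapse = "\t"),
               vapply(seq_len(nrow(pres)), function(i) {
                 paste(c(rownames(pres)[i], pres[i, ]), collapse = "\t")
               }, character(1))),
             file.path(out_dir, "presence.tsv"))
  writeLines(c("gene_a\tgene_b\trho\tn_pairs\tdataset_id",
               if (nrow(esn$edges)) {
                 paste(esn$edges$gene_a, esn$edges$gene_b,
                       sprintf("%.17g", esn$edges$rho), esn$edges$n_pairs,
                       esn$edges$dataset_id, sep = "\t")
               }),
             file.path(out_dir, "edges.tsv"))
  write_network_sif(esn$edges, file.path(out_dir, "esn.sif"))
  pe <- report$per_edge
  writeLines(c("fly_a\tfly_b\tfly_sign\tstatus\tn_support\tsign_agreement\tsign_conflict",
               paste(pe$fly_a, pe$fly_b, pe$fly_sign, pe$status, pe$n_support,
                     pe$sign_agreement, pe$sign_conflict, sep = "\t")),
             file.path(out_dir, "conservation.tsv"))
  writeLines(esn_query_seeds(esn), file.path(out_dir, "query_seeds.txt"))
  invisible(list(esn = esn, report = report, spec = spec, map = map,
                 datasets = datasets))
}

#' Query datasets for candidates correlated with ESN seeds
#'
#' Reads query seeds (one per line, e.g. the `query_seeds.txt` written by
#' [sn_extract()]), builds per-(seed, dataset) correlate lists, aggregates
#' genes supported by at least `min_seeds` distinct seeds, and writes
#' `candidates.tsv` (one row per candidate with per-dataset supports) and
#' `per_seed_summary.tsv`.
#'
#' @param dataset_paths,platforms,dataset_ids As in [sn_extract()].
#' @param seeds_path File with one query seed symbol per line.
#' @param out_dir Output directory.
#' @inheritParams aggregate_candidates
#' @inheritParams pairwise_correlations
#' @return Invisibly, the [aggregate_candidates()] result.
#' @export
sn_query <- function(dataset_paths, seeds_path, out_dir,
                     platforms = "continuous",
                     dataset_ids = as.character(utils::as.roman(seq_along(dataset_paths))),
                     threshold = 0.65, min_pairs = 4L, min_seeds = 3L,
                     strict = FALSE) {
  if (length(platforms) == 1) platforms <- rep(platforms, length(dataset_paths))
  datasets <- Map(function(p, id, plat) {
    read_expression_matrix(p, id, plat, quiet = TRUE)
  }, dataset_paths, dataset_ids, platforms)
  seeds <- readLines(seeds_path, warn = FALSE)
  seeds <- seeds[nzchar(trimws(seeds))]
  supports <- candidate_supports(datasets, seeds, threshold, min_pairs, strict)
  records <- aggregate_candidates(supports, seed_set = seeds, min_seeds = min_seeds)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_candidate_table(records, file.path(out_dir, "candidates.tsv"),
                        dataset_ids = dataset_ids)
  summ <- core_seed_summary(records)
  writeLines(c("seed\tn_candidates",
               if (nrow(summ$per_seed)) {
                 paste(summ$per_seed$seed, summ$per_seed$n_candidates, sep = "\t")
               }),
             file.path(out_dir, "per_seed_summary.tsv"))
  invisible(records)
}

#' Run an over-representation test and write the result
#'
#' Counts-only mode (`K`, `N`, `observed` supplied directly — the form
#' needed when the annotation universe is declared by counts) or
#' membership mode (`annotations_path` + `universe_size`, observed counts
#' computed from the candidate list).
#'
#' @param candidates_path `candidates.tsv` from [sn_query()] (or any TSV
#'   whose first column is the gene symbol; a header is detected).
#' @param out_path Output TSV path.
#' @param K,N,observed Counts-only parameters.
#' @param term Term label for counts-only mode.
#' @param annotations_path,universe_size Membership-mode inputs (see
#'   [read_annotations()]).
#' @return Invisibly, a data frame of results.
#' @export
sn_enrich <- function(candidates_path, out_path,
                      K = NULL, N = NULL, observed = NULL, term = "term",
                      annotations_path = NULL, universe_size = NULL) {
  lines <- readLines(candidates_path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  genes <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1)
  if (length(genes) && tolower(genes[[1]]) %in% c("gene", "candidate", "symbol")) {
    genes <- genes[-1]
  }
  if (!is.null(annotations_path)) {
    sets <- read_annotations(annotations_path, universe_size)
    out <- enrich_terms(genes, sets)
  } else {
    if (is.null(K) || is.null(N) || is.null(observed)) {
      stop("counts-only mode needs K, N and observed", call. = FALSE)
    }
    ann <- annotation_set(term, N, annotated_size = K)
    r <- overrepresentation_test(genes, ann, observed = observed)
    out <- data.frame(term_id = r$term_id, x = r$x, n = r$n, K = r$K, N = r$N,
                      p_value = r$p_value, stringsAsFactors = FALSE)
  }
  writeLines(c("term_id\tx\tn\tK\tN\tp_value",
               paste(out$term_id, out$x, out$n, out$K, out$N,
                     sprintf("%.10g", out$p_value), sep = "\t")),
             out_path)
  invisible(out)
}
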