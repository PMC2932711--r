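#' Configuration for a synthetic multi-dataset time-course study
#'
#' Describes a study of several short developmental time courses with a
#' planted signed co-expression module structure: seed genes loaded on a
#' smooth latent trajectory (with per-gene signs, so planted pairwise
#' correlations carry signs), candidate genes loaded on the same latent
#' signal as their module's seeds, and background genes that are pure
#' independent noise. Per-(seed, dataset) dropout emulates genes not
#' assayed on a platform, and per-dataset platform tags emulate count-like
#' (SAGE) versus continuous (array) measurements.
#'
#' `loading_strength` is calibrated so that the *pairwise* planted
#' correlation magnitude equals it in expectation (each gene carries
#' latent loading `sqrt(loading_strength)`); `loading_strength = 1` is
#' the noiseless limit in which every planted pair has `|rho| = 1` on a
#' continuous platform. Count platforms add Poisson sampling noise by
#' design and are therefore exact only in rank expectation.
#'
#' @param n_datasets Number of datasets (default 4).
#' @param time_points Integer vector of time points per dataset (scalar
#'   recycled); defaults to a heterogeneous 6-20 range.
#' @param n_background Background (pure noise) genes, default 2000.
#' @param seed_genes Named numeric vector of +1/-1 signs, one per seed
#'   gene; the planted sign of pair (i, j) is `sign_i * sign_j`.
#' @param n_candidates Planted candidate genes, default 20.
#' @param candidate_min_links Minimum distinct seeds each planted
#'   candidate is linked to (>= 3); with the module construction a
#'   candidate is linked to every seed of its module, so each module must
#'   hold at least this many seeds.
#' @param loading_strength Target planted pairwise `|rho|`, in (0, 1].
#' @param dropout_rate Probability a *seed* gene is absent from a given
#'   dataset, in [0, 1).
#' @param platforms Character vector (`"count"`/`"continuous"`) per
#'   dataset; scalar recycled.
#' @param n_modules Number of independent latent modules seeds and
#'   candidates are assigned to round-robin (default 1: one coherent
#'   network, as in a single developmental program).
#' @param count_depth,count_dispersion Mean depth and log-rate scale of
#'   the exponential-rate transform used on count platforms:
#'   `counts ~ Poisson(count_depth * exp(count_dispersion * value))`.
#' @param rng_seed Integer seed; all randomness flows through one seeded
#'   generator and the global RNG state is restored on exit.
#' @return Object of class `synthetic_config` (validated list).
#' @export
synthetic_config <- function(n_datasets = 4,
                             time_points = NULL,
                             n_background = 2000,
                             seed_genes = c(Pax6 = 1, Six3 = 1, Notch1 = 1,
                                            Eya1 = -1, Bmp4 = -1, Tshz1 = 1),
                             n_candidates = 20,
                             candidate_min_links = 3,
                             loading_strength = 0.9,
                             dropout_rate = 0.25,
                             platforms = NULL,
                             n_modules = 1,
                             count_depth = 100,
                             count_dispersion = 0.7,
                             rng_seed = 1) {
  fail <- function(field, msg) {
    stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  chk_count <- function(v, field, min = 0) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < min || v != round(v)) {
      fail(field, sprintf("must be a single integer >= %d", min))
    }
    as.integer(v)
  }
  n_datasets <- chk_count(n_datasets, "n_datasets", 1)
  if (is.null(time_points)) {
    # heterogeneous short series in the 6-20 range, like the real studies
    time_points <- rep(c(16, 10, 6, 12), length.out = n_datasets)
  }
  if (length(time_points) == 1) time_points <- rep(time_points, n_datasets)
  if (length(time_points) != n_datasets ||
      any(!is.finite(time_points) | time_points < 2 | time_points != round(time_points))) {
    fail("time_points", "must be integers >= 2, one per dataset")
  }
  time_points <- as.integer(time_points)
  n_background <- chk_count(n_background, "n_background")
  n_candidates <- chk_count(n_candidates, "n_candidates")
  candidate_min_links <- chk_count(candidate_min_links, "candidate_min_links", 1)
  n_modules <- chk_count(n_modules, "n_modules", 1)
  if (is.null(names(seed_genes)) || any(!nzchar(names(seed_genes))) ||
      !all(seed_genes %in% c(-1, 1))) {
    fail("seed_genes", "must be a named vector of +1/-1 signs")
  }
  if (anyDuplicated(tolower(names(seed_genes)))) {
    fail("seed_genes", "seed names must be unique")
  }
  if (!is.numeric(loading_strength) || length(loading_strength) != 1 ||
      is.na(loading_strength) || loading_strength <= 0 || loading_strength > 1) {
    fail("loading_strength", "must lie in (0, 1]")
  }
  if (!is.numeric(dropout_rate) || length(dropout_rate) != 1 ||
      is.na(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1) {
    fail("dropout_rate", "must lie in [0, 1)")
  }
  if (is.null(platforms)) {
    # default: one SAGE-like count platform, the rest array-like
    platforms <- c("count", rep("continuous", n_datasets - 1L))
  }
  if (length(platforms) == 1) platforms <- rep(platforms, n_datasets)
  if (length(platforms) != n_datasets || !all(platforms %in% c("count", "continuous"))) {
    fail("platforms", "must be 'count'/'continuous', one per dataset")
  }
  module_of_seed <- ((seq_along(seed_genes) - 1L) %% n_modules) + 1L
  if (min(table(factor(module_of_seed, levels = seq_len(n_modules)))) <
      candidate_min_links) {
    fail("candidate_min_links", "exceeds the number of seeds in some module")
  }
  if (candidate_min_links > length(seed_genes)) {
    fail("candidate_min_links", "cannot exceed the number of seed genes")
  }
  if (!is.numeric(count_depth) || count_depth <= 0) {
    fail("count_depth", "must be positive")
  }
  if (!is.numeric(count_dispersion) || count_dispersion <= 0) {
    fail("count_dispersion", "must be positive")
  }
  rng_seed <- chk_count(rng_seed, "rng_seed")
  structure(list(
    n_datasets = n_datasets, time_points = time_points,
    n_background = n_background, seed_genes = seed_genes,
    n_candidates = n_candidates, candidate_min_links = candidate_min_links,
    loading_strength = loading_strength, dropout_rate = dropout_rate,
    platforms = platforms, n_modules = n_modules,
    count_depth = count_depth, count_dispersion = count_dispersion,
    rng_seed = rng_seed
  ), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config> %d datasets (tp: %s), %d seeds, %d candidates (>=%d links), %d background\n",
              x$n_datasets, paste(x$time_points, collapse = "/"),
              length(x$seed_genes), x$n_candidates, x$candidate_min_links,
              x$n_background))
  cat(sprintf("  loading %.2f, dropout %.2f, platforms %s, rng_seed %d\n",
              x$loading_strength, x$dropout_rate,
              paste(x$platforms, collapse = "/"), x$rng_seed))
  invisible(x)
}

#' Generate a synthetic multi-dataset study with ground truth
#'
#' Per dataset, one smooth latent trajectory is drawn per module (a
#' standardized Gaussian random walk over the time points — monotone-ish,
#' developmental-like, without assuming a parametric curve). Each seed or
#' candidate profile is `sign * (sqrt(l) * latent + sqrt(1 - l) * noise)`
#' with `l = loading_strength`, so planted pairs correlate at `±l` in
#' expectation; background genes are independent Gaussian noise. Count
#' platforms then emit `Poisson(count_depth * exp(count_dispersion *
#' value))` — an exponential-rate transform preserving rank structure in
#' expectation. Seed rows hit by dropout are omitted from the emitted
#' matrix entirely. Identical config (incl. `rng_seed`) gives
#' bit-identical output; the caller's RNG state is untouched.
#'
#' @param config A [synthetic_config()].
#' @return List with `datasets` (list of [expression_dataset()]) and
#'   `truth` (class `truth_manifest`: `planted_seed_edges` — per-dataset
#'   pairs among co-module seeds both present, with sign;
#'   `planted_candidates` — per candidate its module and intended seed
#'   links; `absences`; `universe`; `config`).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$rng_seed)

  seeds <- names(config$seed_genes)
  signs <- unname(config$seed_genes)
  n_seeds <- length(seeds)
  module_of_seed <- ((seq_len(n_seeds) - 1L) %% config$n_modules) + 1L
  cand_names <- if (config$n_candidates > 0) {
    sprintf("cand%03d", seq_len(config$n_candidates))
  } else character(0)
  module_of_cand <- if (config$n_candidates > 0) {
    ((seq_len(config$n_candidates) - 1L) %% config$n_modules) + 1L
  } else integer(0)
  cand_signs <- if (config$n_candidates > 0) {
    ifelse(stats::runif(config$n_candidates) < 0.5, 1, -1)
  } else numeric(0)
  bg_names <- if (config$n_background > 0) {
    sprintf("bg%05d", seq_len(config$n_background))
  } else character(0)

  # dropout decided up front, seeds only
  absent <- matrix(stats::runif(n_seeds * config$n_datasets) < config$dropout_rate,
                   nrow = n_seeds)
  l <- config$loading_strength
  a <- sqrt(l)
  b <- sqrt(1 - l)

  datasets <- vector("list", config$n_datasets)
  absences <- list()
  planted_edges <- list()
  for (d in seq_len(config$n_datasets)) {
    tp <- config$time_points[[d]]
    latent <- vapply(seq_len(config$n_modules), function(m) {
      z <- cumsum(stats::rnorm(tp))
      as.numeric(scale(z))
    }, numeric(tp))
    profile_for <- function(sign, module) {
      sign * (a * latent[, module] + b * stats::rnorm(tp))
    }
    seed_prof <- t(vapply(seq_len(n_seeds), function(i) {
      profile_for(signs[i], module_of_seed[i])
    }, numeric(tp)))
    cand_prof <- if (config$n_candidates > 0) {
      t(vapply(seq_len(config$n_candidates), function(i) {
        profile_for(cand_signs[i], module_of_cand[i])
      }, numeric(tp)))
    } else matrix(numeric(0), 0, tp)
    bg_prof <- if (config$n_background > 0) {
      matrix(stats::rnorm(config$n_background * tp), ncol = tp)
    } else matrix(numeric(0), 0, tp)

    keep_seed <- !absent[, d]
    vals <- rbind(seed_prof[keep_seed, , drop = FALSE], cand_prof, bg_prof)
    genes <- c(seeds[keep_seed], cand_names, bg_names)
    if (config$platforms[[d]] == "count") {
      lambda <- config$count_depth * exp(config$count_dispersion * vals)
      vals <- matrix(stats::rpois(length(lambda), lambda), nrow = nrow(vals))
    }
    id <- as.character(utils::as.roman(d))
    conditions <- sprintf("t%02d", seq_len(tp))
    datasets[[d]] <- expression_dataset(vals, id, config$platforms[[d]],
                                        genes = genes, conditions = conditions)
    if (any(absent[, d])) {
      absences[[length(absences) + 1L]] <- data.frame(
        gene = seeds[absent[, d]], dataset_id = id, stringsAsFactors = FALSE)
    }
    # planted edges: co-module seed pairs both present in this dataset
    pres <- which(keep_seed)
    if (length(pres) >= 2) {
      pr <- utils::combn(pres, 2)
      same_mod <- module_of_seed[pr[1, ]] == module_of_seed[pr[2, ]]
      if (any(same_mod)) {
        ii <- pr[1, same_mod]; jj <- pr[2, same_mod]
        ga <- seeds[ii]; gb <- seeds[jj]
        swap <- tolower(ga) > tolower(gb)
        tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
        planted_edges[[length(planted_edges) + 1L]] <- data.frame(
          dataset_id = id, gene_a = ga, gene_b = gb,
          sign = as.integer(signs[ii] * signs[jj]), stringsAsFactors = FALSE)
      }
    }
  }

  planted_candidates <- data.frame(
    gene = cand_names,
    module = module_of_cand,
    sign = as.integer(cand_signs),
    links = vapply(module_of_cand, function(m) {
      paste(sort(seeds[module_of_seed == m]), collapse = "|")
    }, character(1)),
    stringsAsFactors = FALSE)

  truth <- structure(list(
    planted_seed_edges = if (length(planted_edges)) {
      do.call(rbind, planted_edges)
    } else data.frame(dataset_id = character(0), gene_a = character(0),
                      gene_b = character(0), sign = integer(0),
                      stringsAsFactors = FALSE),
    planted_candidates = planted_candidates,
    absences = if (length(absences)) do.call(rbind, absences) else {
      data.frame(gene = character(0), dataset_id = character(0),
                 stringsAsFactors = FALSE)
    },
    universe = c(seeds, cand_names, bg_names),
    config = unclass(config)
  ), class = "truth_manifest")
  list(datasets = datasets, truth = truth)
}

#' @export
print.truth_manifest <- function(x, ...) {
  cat(sprintf("<truth_manifest> %d planted edge instance(s), %d planted candidate(s), %d absence(s)\n",
              nrow(x$planted_seed_edges), nrow(x$planted_candidates),
              nrow(x$absences)))
  invisible(x)
}

#' Score pipeline output against a truth manifest
#'
#' Compares recovered candidates to planted candidates and recovered ESN
#' edges (per dataset, unordered pair plus sign of rho) to planted seed
#' edges. Precision over an empty recovered set is undefined; it is
#' reported as 1 with `precision_degenerate = TRUE` so downstream
#' aggregation never divides by zero silently.
#'
#' @param records A [aggregate_candidates()] result from the truth's
#'   datasets.
#' @param esn An [extract_esn()] result from the truth's datasets.
#' @param truth The `truth_manifest` from [generate_study()].
#' @return List: `candidate_recall`, `candidate_precision`,
#'   `edge_recall`, `edge_precision`, degeneracy flags, and `per_dataset`
#'   edge breakdown.
#' @export
evaluate_recovery <- function(records, esn, truth) {
  stopifnot(inherits(records, "candidate_records"),
            inherits(esn, "extracted_seed_network"),
            inherits(truth, "truth_manifest"))
  uni <- symbol_key(truth$universe)
  stray <- records$records$gene[!(symbol_key(records$records$gene) %in% uni)]
  if (length(stray)) {
    stop(sprintf("candidate gene(s) not in the truth universe: %s",
                 paste(utils::head(stray, 5), collapse = ", ")), call. = FALSE)
  }

  planted <- symbol_key(truth$planted_candidates$gene)
  found <- symbol_key(records$records$gene)
  n_hit <- length(intersect(planted, found))
  cand_recall <- if (length(planted)) n_hit / length(planted) else 1
  cand_prec_degenerate <- length(found) == 0
  cand_precision <- if (cand_prec_degenerate) 1 else n_hit / length(found)

  ekey <- function(df, ga = "gene_a", gb = "gene_b", id = "dataset_id", sgn) {
    paste(df[[id]], symbol_key(df[[ga]]), symbol_key(df[[gb]]), sgn)
  }
  true_keys <- ekey(truth$planted_seed_edges, sgn = truth$planted_seed_edges$sign)
  got_keys <- ekey(esn$edges, sgn = as.integer(sign(esn$edges$rho)))
  e_hit <- length(intersect(true_keys, got_keys))
  edge_recall <- if (length(true_keys)) e_hit / length(true_keys) else 1
  edge_prec_degenerate <- length(got_keys) == 0
  edge_precision <- if (edge_prec_degenerate) 1 else e_hit / length(got_keys)

  per_dataset <- lapply(colnames(esn$presence), function(id) {
    tk <- true_keys[truth$planted_seed_edges$dataset_id == id]
    gk <- got_keys[esn$edges$dataset_id == id]
    data.frame(dataset_id = id,
               n_planted = length(tk), n_recovered = length(intersect(tk, gk)),
               n_extra = length(setdiff(gk, tk)), stringsAsFactors = FALSE)
  })
  list(candidate_recall = cand_recall,
       candidate_precision = cand_precision,
       candidate_precision_degenerate = cand_prec_degenerate,
       edge_recall = edge_recall,
       edge_precision = edge_precision,
       edge_precision_degenerate = edge_prec_degenerate,
       per_dataset = do.call(rbind, per_dataset))
}
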