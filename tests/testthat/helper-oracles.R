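# Independent oracles, deliberately coded by a different route than the
# implementation: counting-based midranks, textbook sum-formula Pearson,
# and exhaustive draw enumeration for the hypergeometric tail.

# midrank by counting: rank_i = #(x < x_i) + (#(x == x_i) + 1) / 2
oracle_ranks <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  if (den == 0) return(NA_real_)
  num / den
}

oracle_spearman <- function(x, y, min_pairs = 4) {
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < max(2, min_pairs)) return(NA_real_)
  oracle_pearson(oracle_ranks(x[keep]), oracle_ranks(y[keep]))
}

# P(X >= x) by enumerating every size-n draw from a universe 1..N whose
# annotated members are 1..K. Only viable for small N.
oracle_hyper_tail <- function(x, n, K, N) {
  if (n == 0) return(as.numeric(x <= 0))
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= x)
}

# row of an expression dataset by symbol (case-insensitive)
get_row <- function(ds, gene) {
  ds$values[match(tolower(gene), tolower(ds$genes)), ]
}

# quick dataset from a genes-by-conditions matrix
make_dataset <- function(values, id = "I", platform = "continuous",
                         genes = rownames(values)) {
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("t%02d", seq_len(ncol(values)))
  }
  expression_dataset(values, id, platform, genes = genes,
                     conditions = colnames(values))
}

# small noiseless world shared by several tests: one latent trajectory,
# seeds A..D with signs, candidates tied to all seeds, no background
tiny_noiseless_config <- function(...) {
  synthetic_config(n_datasets = 2, time_points = 10, n_background = 0,
                   seed_genes = c(SeedA = 1, SeedB = 1, SeedC = -1, SeedD = 1),
                   n_candidates = 4, candidate_min_links = 3,
                   loading_strength = 1, dropout_rate = 0,
                   platforms = "continuous", rng_seed = 11, ...)
}
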