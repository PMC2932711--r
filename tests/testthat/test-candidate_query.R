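test_that("seed_correlate_list finds planted correlates and reports seed absence", {
  set.seed(31)
  z <- cumsum(rnorm(10))
  vals <- rbind(Seed = z, hit1 = z + 1e-8, hit2 = -z + 1e-8,
                miss = rnorm(10))
  ds <- make_dataset(vals)
  out <- seed_correlate_list(ds, "Seed")
  expect_setequal(out$gene, c("hit1", "hit2"))
  expect_false("Seed" %in% out$gene)   # never the seed itself
  expect_equal(abs(out$rho), c(1, 1), tolerance = 1e-12)

  expect_message(out2 <- seed_correlate_list(ds, "NotHere"), "not present")
  expect_equal(nrow(out2), 0)
})

test_that("seed_correlate_list fast path equals per-pair spearman_rho", {
  set.seed(32)
  vals <- matrix(rnorm(200), 20, 10,
                 dimnames = list(c("Seed", paste0("g", 1:19)), sprintf("t%02d", 1:10)))
  ds <- make_dataset(vals)
  out <- seed_correlate_list(ds, "Seed", threshold = 0.01)
  for (i in seq_len(nrow(out))) {
    expect_equal(out$rho[i],
                 spearman_rho(vals["Seed", ], vals[out$gene[i], ]),
                 tolerance = 1e-12)
  }
})

test_that("background inclusions are consistent with a permutation-estimated FPR", {
  set.seed(33)
  n_bg <- 100
  z <- cumsum(rnorm(10))
  bg <- matrix(rnorm(n_bg * 10), n_bg, 10)
  vals <- rbind(Seed = z, p1 = z + 1e-8, p2 = -z + 1e-8, p3 = z + 1e-8)
  vals <- rbind(vals, bg)
  rownames(vals) <- c("Seed", "p1", "p2", "p3", sprintf("bg%03d", 1:n_bg))
  ds <- make_dataset(vals)
  out <- seed_correlate_list(ds, "Seed")
  expect_true(all(c("p1", "p2", "p3") %in% out$gene))

  # permutation oracle: shuffle background profiles, recompute hit rate
  n_perm <- 50
  perm_hits <- replicate(n_perm, {
    hits <- vapply(seq_len(n_bg), function(i) {
      r <- spearman_rho(z, sample(bg[i, ]))
      !is.na(r) && abs(r) >= 0.65
    }, logical(1))
    mean(hits)
  })
  fpr <- mean(perm_hits)
  observed_fpr <- mean(grepl("^bg", out$gene)) * nrow(out) / n_bg
  # binomial slack around the permutation estimate
  slack <- 3 * sqrt(fpr * (1 - fpr) / n_bg) + 2 / n_bg
  expect_lte(abs(observed_fpr - fpr), slack + 0.02)
})

test_that("aggregate_candidates counts DISTINCT seeds across the dataset union", {
  sup <- data.frame(
    seed = c("A", "B", "C", "A", "A", "B"),
    dataset_id = c("I", "I", "I", "I", "II", "III"),
    gene = c("g1", "g1", "g1", "g2", "g2", "g2"),
    rho = c(0.9, 0.8, -0.7, 0.9, 0.95, 0.66),
    stringsAsFactors = FALSE)
  res <- aggregate_candidates(sup, seed_set = c("A", "B", "C"), min_seeds = 3)
  # g1: three distinct seeds in one dataset -> included
  expect_true("g1" %in% res$records$gene)
  expect_equal(res$records$n_seeds[res$records$gene == "g1"], 3)
  # g2: seed A twice (two datasets) + seed B once = 2 distinct -> excluded
  expect_false("g2" %in% res$records$gene)
  # supports enumerate every (seed, dataset, rho) occurrence
  expect_equal(nrow(res$supports[res$supports$gene == "g1", ]), 3)

  expect_equal(nrow(aggregate_candidates(sup[0, ], min_seeds = 3)$records), 0)
  expect_error(aggregate_candidates(sup, min_seeds = 0), "min_seeds")
})

test_that("seed genes are never candidates and ordering is deterministic", {
  sup <- data.frame(
    seed = rep(c("A", "B", "C", "D"), times = 3),
    dataset_id = "I",
    gene = c(rep("zed", 4), rep("abc", 4), rep("B", 4)),
    rho = 0.9, stringsAsFactors = FALSE)
  res <- aggregate_candidates(sup, seed_set = c("A", "B", "C", "D"), min_seeds = 3)
  expect_false("B" %in% res$records$gene)   # seed excluded from candidacy
  expect_equal(res$records$gene, c("abc", "zed"))  # n_seeds tie -> alphabetical
})

test_that("min_seeds is monotone and adding a dataset never removes a candidate", {
  set.seed(34)
  cfg <- tiny_noiseless_config()
  st <- generate_study(cfg)
  seeds <- names(cfg$seed_genes)
  sup_all <- candidate_supports(st$datasets, seeds)
  sup_one <- candidate_supports(st$datasets[1], seeds)

  genes_at <- function(sup, k) aggregate_candidates(sup, seeds, k)$records$gene
  prev <- genes_at(sup_all, 1)
  for (k in 2:4) {
    cur <- genes_at(sup_all, k)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  expect_true(all(genes_at(sup_one, 3) %in% genes_at(sup_all, 3)))
})

test_that("signature grouping is deterministic with letter labels", {
  sup <- data.frame(
    seed = c("Six3", "Eya1", "Notch1",  "Six3", "Eya1", "Notch1",  "Six3", "Notch1", "Tshz1"),
    dataset_id = "I",
    gene = c(rep("g1", 3), rep("g2", 3), rep("g3", 3)),
    rho = 0.8, stringsAsFactors = FALSE)
  res <- aggregate_candidates(sup, seed_set = c("Six3", "Eya1", "Notch1", "Tshz1"),
                              min_seeds = 3)
  grp <- group_by_seed_signature(res)
  expect_equal(nrow(grp), 2)
  expect_equal(grp$label, c("a", "b"))
  sig1 <- grp[grp$seed_signature == "Eya1|Notch1|Six3", ]
  expect_equal(sig1$n_genes, 2L)
  expect_setequal(sig1$genes[[1]], c("g1", "g2"))

  empty <- aggregate_candidates(sup[0, ], min_seeds = 3)
  expect_equal(nrow(group_by_seed_signature(empty)), 0)
})

test_that("core_seed_summary counts per-seed and core-subset membership", {
  sup <- rbind(
    data.frame(seed = c("X", "Y", "Z"), dataset_id = "I", gene = "g1", rho = 0.7),
    data.frame(seed = c("X", "Y", "Z", "W"), dataset_id = "I", gene = "g2", rho = 0.7),
    data.frame(seed = c("X", "Y", "W"), dataset_id = "I", gene = "g3", rho = 0.7))
  res <- aggregate_candidates(sup, seed_set = c("X", "Y", "Z", "W"), min_seeds = 3)
  summ <- core_seed_summary(res, core_sets = list(core = c("X", "Y", "Z")))
  expect_equal(summ$per_seed$n_candidates[summ$per_seed$seed == "X"], 3L)
  expect_equal(summ$per_seed$n_candidates[summ$per_seed$seed == "Z"], 2L)
  # candidates containing the whole {X, Y, Z} core
  expect_equal(summ$core$n_candidates, 2L)

  empty <- aggregate_candidates(sup[0, ], min_seeds = 3)
  expect_equal(nrow(core_seed_summary(empty)$per_seed), 0)
})

test_that("candidate table export mirrors the records", {
  set.seed(35)
  cfg <- tiny_noiseless_config()
  st <- generate_study(cfg)
  seeds <- names(cfg$seed_genes)
  recs <- aggregate_candidates(candidate_supports(st$datasets, seeds), seeds)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_candidate_table(recs, path, dataset_ids = c("I", "II"))
  lines <- readLines(path)
  expect_equal(length(lines), nrow(recs$records) + 1)
  expect_match(lines[1], "^gene\tn_seeds\tseed_signature\tsupports_I\tsupports_II$")
})
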