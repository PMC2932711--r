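test_that("expression matrix round-trips bit-for-bit, preserving missing cells", {
  set.seed(1)
  vals <- matrix(rnorm(12), 3, 4,
                 dimnames = list(c("GeneA", "GeneB", "GeneC"),
                                 c("E13", "E15", "P0", "P5")))
  vals[2, 3] <- NA
  ds <- expression_dataset(vals, "I", "continuous")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(ds, path)
  back <- read_expression_matrix(path, "I", "continuous", quiet = TRUE)
  expect_identical(back$genes, ds$genes)
  expect_identical(back$conditions, ds$conditions)
  expect_identical(back$values, ds$values)
})

test_that("duplicate gene rows collapse by per-condition median, order-independently", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rows <- c("gene\tt1\tt2\tt3",
            "GeneA\t1\t2\t3",
            "GeneB\t9\t9\t9",
            "GeneA\t3\t4\t5")
  writeLines(rows, path)
  ds <- read_expression_matrix(path, "I", "continuous", quiet = TRUE)
  expect_equal(unname(ds$values["GeneA", ]), c(2, 3, 4))

  # permuting input rows yields the identical dataset (modulo row order)
  writeLines(rows[c(1, 4, 3, 2)], path)
  ds2 <- read_expression_matrix(path, "I", "continuous", quiet = TRUE)
  expect_identical(ds$values[order(ds$genes), ], ds2$values[order(ds2$genes), ])
})

test_that("malformed expression files raise informative errors; header-only is valid", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tt1\tt2", "GeneA\t1\tx"), path)
  expect_error(read_expression_matrix(path, "I", quiet = TRUE), "GeneA.*t2")
  writeLines(c("gene\tt1", "GeneA\t1"), path)
  expect_error(read_expression_matrix(path, "I", quiet = TRUE), "2 condition")
  writeLines(character(0), path)
  expect_error(read_expression_matrix(path, "I", quiet = TRUE), "empty")
  writeLines("gene\tt1\tt2", path)
  expect_message(ds <- read_expression_matrix(path, "I"), "0 genes")
  expect_equal(length(ds$genes), 0)
  expect_equal(ds$conditions, c("t1", "t2"))
})

test_that("empty cells become NA and mixed missing rows survive collapse", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tt1\tt2\tt3", "GeneA\t1\t\t3", "GeneB\t\t\t"), path)
  ds <- read_expression_matrix(path, "I", quiet = TRUE)
  expect_equal(unname(ds$values["GeneA", ]), c(1, NA, 3))
  expect_true(all(is.na(ds$values["GeneB", ])))
})

test_that("homolog map parses one-to-many and merges many-to-one", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("fly_gene\tmouse_homologs",
               "so\tSix1/Six2",
               "optix\tSix3/Six6",
               "toy\tPax6",
               "ey\tPax6",
               "tsh\tSdccag33"), path)
  map <- read_homolog_map(path)
  expect_setequal(map$entries$so, c("Six1", "Six2"))
  expect_setequal(map$entries$optix, c("Six3", "Six6"))
  # synonym table resolves the stale teashirt symbol
  expect_equal(map$entries$tsh, "Tshz1")
  # toy and ey both map to Pax6; the union has it once
  all_mouse <- unique(unlist(map$entries))
  expect_equal(sum(all_mouse == "Pax6"), 1)
})

test_that("homolog map rejects empty mouse fields and merges duplicate fly rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("so\tSix1", "eya\t"), path)
  expect_error(read_homolog_map(path), "eya")
  writeLines(c("so\tSix1", "so\tSix2"), path)
  expect_warning(map <- read_homolog_map(path), "merged")
  expect_setequal(map$entries$so, c("Six1", "Six2"))
})

test_that("symbol normalization trims, maps synonyms, is idempotent, rejects empties", {
  expect_equal(normalize_symbol("  pax6 "), "pax6")
  expect_equal(canonicalize_symbols(c("Pax6", "  pax6 ")), c("Pax6", "Pax6"))
  expect_equal(normalize_symbol("Sdccag33"), "Tshz1")
  expect_equal(normalize_symbol("sdccag33"), "Tshz1")
  once <- normalize_symbol("Sdccag33")
  expect_identical(normalize_symbol(once), once)
  expect_error(normalize_symbol(""), "empty")
  expect_error(normalize_symbol("   "), "empty")
})

test_that("SIF export writes pos/neg relations and a full-precision score table", {
  edges <- data.frame(gene_a = c("Notch1", "Atoh7"), gene_b = c("Pax6", "Shh"),
                      rho = c(0.891, -0.922), n_pairs = c(9L, 9L),
                      dataset_id = c("II", "IV"), stringsAsFactors = FALSE)
  sif <- withr::local_tempfile(fileext = ".sif")
  paths <- write_network_sif(edges, sif)
  expect_equal(readLines(sif), c("Notch1 pos Pax6", "Atoh7 neg Shh"))
  tsv <- readLines(paths$tsv)
  expect_match(tsv[1], "^gene_a\tgene_b\tdataset_id\trho$")
  expect_match(tsv[2], "0.891")
  expect_match(tsv[3], "-0.922")

  write_network_sif(edges[0, ], sif)
  expect_length(readLines(sif), 0)
})

test_that("packaged homolog table and seed network load and are consistent", {
  map <- fly_homolog_map()
  net <- fly_seed_network()
  expect_length(map$entries, 18)
  expect_length(net$fly_nodes, 18)
  expect_true(all(tolower(net$fly_nodes) %in% tolower(names(map$entries))))
  expect_true(all(net$fly_edges$sign %in% c(-1L, 1L)))
  # no duplicate unordered pairs, no self-edges
  k <- paste(pmin(net$fly_edges$gene_a, net$fly_edges$gene_b),
             pmax(net$fly_edges$gene_a, net$fly_edges$gene_b))
  expect_false(anyDuplicated(k) > 0)
  expect_false(any(net$fly_edges$gene_a == net$fly_edges$gene_b))
})
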