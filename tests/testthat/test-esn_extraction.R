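make_spec <- function(...) {
  seed_network_spec(data.frame(...))
}

test_that("homolog projection expands fly edges by cross product, excluding self-pairs", {
  map <- homolog_map(list(so = c("Six1", "Six2"), optix = c("Six3", "Six6"),
                          toy = "Pax6", ey = "Pax6"))
  spec <- make_spec(gene_a = "so", gene_b = "optix", sign = 1)
  proj <- project_homologs(spec, map)
  expect_equal(nrow(proj$edges), 4)   # 2 x 2 cross product
  expect_setequal(paste(proj$edges$mouse_a, proj$edges$mouse_b),
                  c("Six1 Six3", "Six1 Six6", "Six2 Six3", "Six2 Six6"))

  # fly genes sharing one homolog: edge projects to zero mouse pairs
  spec2 <- make_spec(gene_a = "toy", gene_b = "ey", sign = 1)
  proj2 <- project_homologs(spec2, map)
  expect_equal(nrow(proj2$edges), 0)
  expect_equal(sum(proj2$seed_genes == "Pax6"), 1)

  spec3 <- make_spec(gene_a = "so", gene_b = "dac", sign = 1)
  expect_error(project_homologs(spec3, map), "dac")
})

test_that("packaged full map projects to 21 distinct mouse query symbols", {
  # The curated table maps 18 fly genes onto overlapping mouse paralog
  # sets; after merging shared homologs (toy/ey -> Pax6) and resolving
  # the Sdccag33/Tshz1 synonymy, 21 distinct query symbols remain.
  proj <- project_homologs(fly_seed_network(), fly_homolog_map())
  expect_equal(length(proj$seed_genes), 21)
  expect_true(all(c("Pax6", "Tshz1", "Six6", "Atoh7", "Wif1") %in% proj$seed_genes))
  expect_false(any(duplicated(tolower(proj$seed_genes))))
})

test_that("extract_esn fills the three presence statuses correctly", {
  z <- cumsum(rnorm(10))
  vals1 <- rbind(Pax6 = z + rnorm(10, sd = 1e-6),
                 Notch1 = z + rnorm(10, sd = 1e-6),
                 Meis2 = rnorm(10))
  vals2 <- rbind(Pax6 = rnorm(10), Hes1 = rnorm(10))
  d1 <- make_dataset(vals1, "I")
  d2 <- make_dataset(vals2, "II")
  seeds <- c("Pax6", "Notch1", "Meis2", "Hes1", "Wif1")
  esn <- extract_esn(list(d1, d2), seeds)

  expect_equal(esn$presence["Pax6", "I"], "present_correlated")
  expect_equal(esn$presence["Notch1", "I"], "present_correlated")
  expect_equal(esn$presence["Notch1", "II"], "absent")
  expect_equal(esn$presence["Wif1", "I"], "absent")
  expect_equal(esn$presence["Wif1", "II"], "absent")
  # present, but no passing edge there
  expect_true(esn$presence["Meis2", "I"] %in% c("present_uncorrelated", "present_correlated"))

  # presence consistency: present_correlated iff an edge touches the gene
  for (d in colnames(esn$presence)) {
    touched <- unique(c(esn$edges$gene_a[esn$edges$dataset_id == d],
                        esn$edges$gene_b[esn$edges$dataset_id == d]))
    expect_setequal(rownames(esn$presence)[esn$presence[, d] == "present_correlated"],
                    touched)
  }
  # absent implies no touching edges
  expect_false("Wif1" %in% c(esn$edges$gene_a, esn$edges$gene_b))

  expect_error(extract_esn(list(), seeds), "non-empty")
})

test_that("a single present seed yields no edges but correct presence", {
  ds <- make_dataset(rbind(Pax6 = rnorm(10)), "I")
  esn <- extract_esn(list(ds), "Pax6")
  expect_equal(nrow(esn$edges), 0)
  expect_equal(esn$presence["Pax6", "I"], "present_uncorrelated")
  expect_length(esn_query_seeds(esn), 0)
})

test_that("esn screens ALL seed pairs, not only projected fly edges", {
  # Eya2--Eya3 style pair: same fly gene's paralogs, no fly edge between them
  z <- cumsum(rnorm(12))
  ds <- make_dataset(rbind(Eya2 = z, Eya3 = z + 1e-8), "IV")
  esn <- extract_esn(list(ds), c("Eya2", "Eya3"))
  expect_equal(nrow(esn$edges), 1)
  expect_equal(paste(esn$edges$gene_a, esn$edges$gene_b), "Eya2 Eya3")
})

test_that("dataset order does not change the edge set", {
  set.seed(21)
  cfg <- tiny_noiseless_config()
  st <- generate_study(cfg)
  seeds <- names(cfg$seed_genes)
  key <- function(esn) {
    e <- esn$edges
    sort(paste(e$dataset_id, e$gene_a, e$gene_b, round(e$rho, 12)))
  }
  expect_identical(key(extract_esn(st$datasets, seeds)),
                   key(extract_esn(rev(st$datasets), seeds)))
})

test_that("compare_to_fly classifies supported / unsupported / untestable edges", {
  map <- homolog_map(list(N = "Notch1", toy = "Pax6", ey = "Pax6",
                          hth = "Meis2", dac = "Dach1"))
  spec <- make_spec(gene_a = c("N", "hth", "toy"),
                    gene_b = c("toy", "dac", "ey"),
                    sign = c(1, 1, 1))
  z <- cumsum(rnorm(10))
  ds <- make_dataset(rbind(Notch1 = z, Pax6 = z + 1e-9, Dach1 = rnorm(10)), "I")
  proj <- project_homologs(spec, map)
  esn <- extract_esn(list(ds), proj$seed_genes)
  rep <- compare_to_fly(esn, spec, map)

  st <- setNames(rep$per_edge$status, paste(rep$per_edge$fly_a, rep$per_edge$fly_b))
  expect_equal(unname(st["N toy"]), "supported")
  expect_true(rep$per_edge$sign_agreement[rep$per_edge$fly_a == "N"])
  # Meis2 absent from every dataset -> hth--dac untestable
  expect_equal(unname(st["dac hth"]), "untestable")  # pairs stored lexicographically
  # toy--ey projects only to the excluded Pax6 self-pair -> untestable
  expect_equal(unname(st["ey toy"]), "untestable")
  expect_equal(unname(rep$counts), c(1L, 0L, 2L))

  # with zero esn edges nothing is supported
  ds2 <- make_dataset(rbind(Notch1 = rnorm(10), Pax6 = rnorm(10),
                            Dach1 = rnorm(10)), "I")
  esn2 <- extract_esn(list(ds2), proj$seed_genes)
  rep2 <- compare_to_fly(esn2, spec, map)
  expect_equal(sum(rep2$per_edge$status == "supported"), 0)
})

test_that("sign disagreement between fly edge and mouse correlation is flagged", {
  map <- homolog_map(list(N = "Notch1", ey = "Pax6"))
  spec <- make_spec(gene_a = "N", gene_b = "ey", sign = 1)
  z <- cumsum(rnorm(10))
  ds <- make_dataset(rbind(Notch1 = z, Pax6 = -z + 1e-9), "I")
  esn <- extract_esn(list(ds), c("Notch1", "Pax6"))
  rep <- compare_to_fly(esn, spec, map)
  expect_equal(rep$per_edge$status, "supported")
  expect_false(rep$per_edge$sign_agreement)
})
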