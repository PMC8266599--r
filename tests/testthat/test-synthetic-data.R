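test_that("generators are byte-identical under the same seed", {
  a <- gen_proteome(n_proteins = 5, seed = 99)
  b <- gen_proteome(n_proteins = 5, seed = 99)
  expect_identical(a$proteins, b$proteins)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$proteins,
                         gen_proteome(n_proteins = 5, seed = 100)$proteins))

  t1 <- gen_te_table(n_genes = 50, seed = 7)
  t2 <- gen_te_table(n_genes = 50, seed = 7)
  expect_identical(t1$table, t2$table)

  h1 <- gen_homolog_data(n_queries = 10, n_set = 3, seed = 5)
  h2 <- gen_homolog_data(n_queries = 10, n_set = 3, seed = 5)
  expect_identical(h1$hits, h2$hits)
  expect_identical(h1$meta, h2$meta)
})

test_that("planted saturated regions are recovered at the expected margin", {
  # fraction 1 regions between non-TAPSLIVR spacers: detection must
  # extend each planted region by exactly the window overhang
  # (window - ceiling(min_fraction * window) = 6 residues) on each side
  g <- gen_proteome(n_proteins = 10, n_regions = 1,
                    region_fraction = c(1, 1), seed = 3)
  res <- scan_proteome(g$proteins)
  expect_equal(res$summary$n_with_region, 10L)
  expect_equal(res$summary$n_regions, 10L)
  merged <- merge(res$regions, g$truth, by = "protein_id",
                  suffixes = c("", "_truth"))
  expect_equal(merged$start0, merged$start0_truth - 6L)
  expect_equal(merged$end0, merged$end0_truth + 6L)
})

test_that("multiple planted regions never merge across spacers", {
  g <- gen_proteome(n_proteins = 6, n_regions = 3,
                    region_fraction = c(0.9, 1), seed = 13)
  res <- scan_proteome(g$proteins)
  expect_equal(res$summary$n_regions, 18L)
  expect_equal(res$summary$n_with_region, 6L)
  # every planted region lies inside exactly one detected region
  for (i in seq_len(nrow(g$truth))) {
    tr <- g$truth[i, ]
    hit <- res$regions[res$regions$protein_id == tr$protein_id &
                         res$regions$start0 <= tr$start0 &
                         res$regions$end0 >= tr$end0, ]
    expect_equal(nrow(hit), 1L)
  }
})

test_that("background-only proteomes yield no detections", {
  for (s in 1:5) {
    g <- gen_proteome(n_proteins = 20, n_regions = 0,
                      background_rate = 0.2, seed = s)
    expect_equal(scan_proteome(g$proteins)$summary$n_regions, 0L)
  }
})

test_that("gen_cds translates back to its protein and honours bias", {
  g <- gen_proteome(n_proteins = 3, seed = 2)
  for (id in names(g$proteins)) {
    cds <- gen_cds(g$proteins[[id]], seed = 4)
    expect_equal(unname(translate_cds(cds)), g$proteins[[id]])
  }

  prot <- strrep("TA", 100)  # 200 TAPSLIVR residues, no Ile
  full <- adat_enrichment(gen_cds(prot, adat_bias = 1, seed = 6)[[1]])
  expect_equal(full$adat_percent, 100)

  half <- adat_enrichment(gen_cds(prot, adat_bias = 0.5, seed = 6)[[1]])
  expect_lt(abs(half$adat_percent / 100 - 0.5), 3 * sqrt(0.25 / 200))

  # bias restricted to a region leaves the rest at usage frequencies
  biased <- gen_cds(prot, adat_bias = 0,
                    adat_regions = data.frame(start0 = 0, end0 = 100),
                    seed = 8)
  left <- adat_enrichment(biased[[1]], region = c(0, 100))
  expect_equal(left$adat_percent, 0)

  expect_warning(gen_cds(strrep("I", 30), adat_bias = 0, seed = 1),
                 "no non-ADAT synonym")
})

test_that("homolog generator calibrates to its planted rates", {
  # equal rates across groups: ratio compatible with 1
  g <- gen_homolog_data(n_queries = 80, n_set = 20,
                        lambda_set = c(prok = 3, euk_uni = 3, euk_multi = 3),
                        lambda_bg = c(prok = 3, euk_uni = 3, euk_multi = 3),
                        fail_fraction = 0, seed = 31)
  mat <- species_hit_matrix(filter_hits(g$hits), g$meta)
  gr <- group_average_ratio(mat, g$meta, c("Archaea", "Bacteria"), "Eukarya")
  # per-genome rates are Poisson(3) means over 80 queries x 20 genomes
  se <- sqrt(2 * 3 / (80 * 20)) / 3  # rough delta-method CI on the ratio
  expect_lt(abs(gr$ratio - 1), 5 * se)

  # monotone A34 link with zero noise: Spearman rho = 1 across groups
  g2 <- gen_homolog_data(n_queries = 40, n_set = 10,
                         lambda_set = c(prok = 0.1, euk_uni = 2,
                                        euk_multi = 8),
                         seed = 32)
  mat2 <- species_hit_matrix(filter_hits(g2$hits), g2$meta)
  counts <- colSums(mat2[g2$query_set, , drop = FALSE])
  euk <- g2$meta[g2$meta$domain == "Eukarya", ]
  res <- trna_spearman(counts, euk)
  expect_equal(res$rho, 1)
})

test_that("filter-failing decoys are actually removed by the filters", {
  g <- gen_homolog_data(n_queries = 20, n_set = 5, fail_fraction = 0.3,
                        seed = 41)
  kept <- filter_hits(g$hits)
  expect_false(any(grepl("_bad", kept$subject_id)))
  expect_true(any(grepl("_bad", g$hits$subject_id)))
})

test_that("null TE tables give the analytic impaired false-positive rate", {
  g <- gen_te_table(n_genes = 4000, n_planted = 0, delta = 0, sigma = 0.5,
                    seed = 51)
  sets <- classify_te(g$table)
  # under the null, impaired = significant with fc below 1.5; with
  # sigma = 0.5 the significant positive tail lies above 1.5, so the
  # expected rate is the one-sided 0.025
  rate <- length(sets$impaired) / 4000
  expect_lt(abs(rate - 0.025), 3 * sqrt(0.025 * 0.975 / 4000))
})

test_that("planted TE effects are recovered by the enrichment tests", {
  g <- gen_te_table(n_genes = 800, n_planted = 40, delta = 2, sigma = 0.5,
                    frac_annotated = 0.05, seed = 52)
  sets <- classify_te(g$table)
  expect_gt(length(intersect(sets$impaired, g$truth$planted)), 20)
  fish <- fisher_enrichment(sets$impaired,
                            g$table$gene_id[g$table$encodes_lcr],
                            g$table$gene_id)
  expect_lt(fish$p, 1e-6)
})
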