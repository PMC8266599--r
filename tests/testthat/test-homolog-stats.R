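make_meta <- function(n_prok = 2, n_uni = 0, n_multi = 2) {
  ids <- c(sprintf("pk%02d", seq_len(n_prok)),
           sprintf("eu%02d", seq_len(n_uni)),
           sprintf("em%02d", seq_len(n_multi)))
  data.frame(
    species_id = ids,
    domain = rep(c("Bacteria", "Eukarya", "Eukarya"),
                 c(n_prok, n_uni, n_multi)),
    phylum = rep(c("Proteobacteria", "Ascomycota", "Chordata"),
                 c(n_prok, n_uni, n_multi)),
    multicellularity = rep(c(NA, "unicellular", "multicellular"),
                           c(n_prok, n_uni, n_multi)),
    n_A34_genes = 0L, a34_diversity = 0L,
    stringsAsFactors = FALSE)
}

test_that("filter_hits applies e-value, overlap, de-duplication and cap", {
  hits <- data.frame(
    query_id = c("q1", "q1", "q1", "q1"),
    subject_id = c("s1", "s2", "s3", "s1"),
    species_id = "pk01",
    evalue = c(0.05, 0.001, 0.001, 0.002),
    overlap_fraction = c(0.5, 0.10, 0.50, 0.9),
    stringsAsFactors = FALSE)
  out <- filter_hits(hits)
  # 0.05 fails e-value; s2 fails overlap; duplicate s1 keeps best e-value
  # (0.002, overlap 0.9) and passes
  expect_setequal(out$subject_id, c("s1", "s3"))
  expect_equal(out$evalue[out$subject_id == "s1"], 0.002)

  # per-query cap keeps best-by-e-value hits, applied before the filters
  many <- data.frame(
    query_id = "q1", subject_id = sprintf("s%03d", 1:50),
    species_id = "pk01", evalue = seq(1e-20, 1e-4, length.out = 50),
    overlap_fraction = 0.9, stringsAsFactors = FALSE)
  out <- filter_hits(many, max_hits_per_query = 10)
  expect_equal(nrow(out), 10L)
  expect_equal(out$subject_id, sprintf("s%03d", 1:10))
})

test_that("species_hit_matrix counts distinct subjects per cell", {
  meta <- make_meta()
  hits <- data.frame(
    query_id = c("q1", "q1", "q1", "q2"),
    subject_id = c("a", "b", "c", "a"),
    species_id = c("pk01", "pk01", "pk01", "em01"),
    evalue = 1e-5, overlap_fraction = 0.9, stringsAsFactors = FALSE)
  mat <- species_hit_matrix(hits, meta)
  expect_equal(mat["q1", "pk01"], 3L)
  expect_equal(mat["q2", "pk01"], 0L)
  expect_equal(sum(mat["q2", ]), 1L)

  hits$species_id[1] <- "nope"
  expect_error(species_hit_matrix(hits, meta), "not in metadata: nope")
})

test_that("group_average_ratio matches hand-computed per-genome rates", {
  meta <- make_meta(2, 0, 2)
  mat <- matrix(c(1, 0, 10, 10,   # q1: 1 prok hit, 10+10 euk? see below
                  0, 0, 5, 5),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("q1", "q2"),
                                c("pk01", "pk02", "em01", "em02")))
  # q1: prok rate 1/2, euk rate 20/2 = 10; q2: 0 and 5
  g <- group_average_ratio(mat, meta, c("Archaea", "Bacteria"), "Eukarya")
  expect_equal(g$avg_a, 0.25)
  expect_equal(g$avg_b, 7.5)
  expect_equal(g$ratio, 0.25 / 7.5)

  # hand-computed example: q1 = (1 prok, 10 euk), q2 = (0, 10)
  mat2 <- matrix(c(1, 0, 5, 5,
                   0, 0, 5, 5), nrow = 2, byrow = TRUE,
                 dimnames = dimnames(mat))
  g2 <- group_average_ratio(mat2, meta, c("Archaea", "Bacteria"), "Eukarya")
  expect_equal(g2$avg_a, 0.25)
  expect_equal(g2$avg_b, 5)
  expect_equal(g2$ratio, 0.05)

  # symmetry: identical counts and genome numbers -> ratio 1
  sym <- matrix(2, 2, 4, dimnames = dimnames(mat))
  expect_equal(group_average_ratio(sym, meta, "Bacteria", "Eukarya")$ratio, 1)

  # all-zero numerator group
  mat3 <- mat2; mat3[, 1:2] <- 0
  expect_equal(group_average_ratio(mat3, meta, "Bacteria", "Eukarya")$ratio, 0)

  # zero denominator flagged
  mat4 <- mat2; mat4[, 3:4] <- 0
  g4 <- group_average_ratio(mat4, meta, "Bacteria", "Eukarya")
  expect_true(g4$undefined)
  expect_true(is.na(g4$ratio))
})

test_that("group averages are invariant to duplicating a group's genomes", {
  meta <- make_meta(2, 0, 2)
  withr::with_seed(3, {
    mat <- matrix(rpois(40, 3), nrow = 10,
                  dimnames = list(sprintf("q%02d", 1:10),
                                  meta$species_id))
    g <- group_average_ratio(mat, meta, "Bacteria", "Eukarya")
    # duplicate every eukaryote genome together with its hit column
    meta2 <- rbind(meta, transform(meta[3:4, ],
                                   species_id = c("em03", "em04")))
    mat2 <- cbind(mat, em03 = mat[, "em01"], em04 = mat[, "em02"])
    g2 <- group_average_ratio(mat2, meta2, "Bacteria", "Eukarya")
    expect_equal(g2$ratio, g$ratio)
  })
})

test_that("permutation_ratio_test is degenerate-exact on the full set", {
  meta <- make_meta(2, 0, 2)
  withr::with_seed(4, {
    mat <- matrix(rpois(40, 3), nrow = 10,
                  dimnames = list(sprintf("q%02d", 1:10), meta$species_id))
    res <- permutation_ratio_test(mat, meta, rownames(mat), "Bacteria",
                                  "Eukarya", B = 50, seed = 1)
    expect_identical(res$z, 0)
    expect_true(res$degenerate)
  })
})

test_that("permutation_ratio_test recovers a planted depletion", {
  g <- gen_homolog_data(n_queries = 60, n_set = 15,
                        lambda_set = c(prok = 0.02, euk_uni = 4,
                                       euk_multi = 4),
                        lambda_bg = c(prok = 3, euk_uni = 3, euk_multi = 3),
                        seed = 21)
  mat <- species_hit_matrix(filter_hits(g$hits), g$meta)
  res <- permutation_ratio_test(mat, g$meta, g$query_set,
                                c("Archaea", "Bacteria"), "Eukarya",
                                B = 1000, seed = 5, alternative = "less")
  expect_lt(res$p, 0.001)
  expect_lt(res$observed, res$null_mean)
  # determinism under the seed
  res2 <- permutation_ratio_test(mat, g$meta, g$query_set,
                                 c("Archaea", "Bacteria"), "Eukarya",
                                 B = 1000, seed = 5, alternative = "less")
  expect_identical(res$p, res2$p)
})

test_that("presence_screen requires a detected region in the homolog", {
  homologs <- data.frame(
    query_id = c("q1", "q1", "q2"),
    species_id = c("em01", "em02", "em01"),
    subject_id = c("h1", "h2", "h3"),
    seq = c(strrep("G", 60),
            paste0(strrep("G", 10), strrep("A", 40), strrep("G", 10)),
            strrep("G", 60)),
    stringsAsFactors = FALSE)
  pres <- presence_screen(homologs)
  expect_false(pres$present[pres$species_id == "em01" &
                              pres$query_id == "q1"])
  expect_true(pres$present[pres$species_id == "em02" &
                             pres$query_id == "q1"])
  expect_false(any(pres$present[pres$query_id == "q2"]))
})

test_that("phylum_normalize divides by phylum species counts", {
  meta <- make_meta(4, 2, 2)
  presence <- data.frame(
    species_id = c("pk01", "pk02", "eu01", "em01", "em02"),
    query_id = "q1",
    present = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  out <- phylum_normalize(presence, meta)
  frac <- setNames(out$fraction, out$phylum)
  expect_equal(unname(frac["Proteobacteria"]), 0.5)  # 2 of 4
  expect_equal(unname(frac["Chordata"]), 1.0)
  expect_equal(unname(frac["Ascomycota"]), 0.0)
})

test_that("multicellular_compare reports median fold-change and MW p", {
  meta <- make_meta(0, 3, 3)
  mat <- matrix(c(10, 10, 10, 70, 70, 70), nrow = 1,
                dimnames = list("q1", meta$species_id))
  res <- multicellular_compare(mat, meta, B = 50, seed = 1)
  expect_equal(res$fc_median, 7)

  same <- matrix(5, 1, 6, dimnames = list("q1", meta$species_id))
  res2 <- multicellular_compare(same, meta, B = 50, seed = 1)
  expect_equal(res2$fc_median, 1)
  expect_equal(res2$mann_whitney_p, 1)

  mat3 <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
                 dimnames = list("q1", meta$species_id))
  res3 <- multicellular_compare(mat3, meta, B = 50, seed = 1)
  expect_equal(res3$mann_whitney_p, 0.1)  # 2 of 20 orderings, doubled
})

test_that("Mann-Whitney agrees with exact enumeration for small groups", {
  withr::with_seed(17, {
    for (i in 1:10) {
      m <- sample(3:6, 1); n <- sample(3:6, 1)
      vals <- sample(1:100, m + n)  # distinct -> exact test applies
      x <- vals[seq_len(m)]; y <- vals[-seq_len(m)]
      expect_equal(wilcox.test(x, y)$p.value, enumerate_mw_p(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("trna_spearman excludes above the gene-count bound only", {
  meta <- make_meta(0, 0, 6)
  meta$n_A34_genes <- c(10L, 20L, 50L, 100L, 400L, 401L)
  counts <- setNames(c(1, 2, 5, 10, 40, 100), meta$species_id)
  res <- trna_spearman(counts, meta)
  expect_equal(res$excluded, "em06")
  expect_equal(res$n_used, 5L)
  expect_equal(res$rho, 1)

  # perfectly decreasing
  res2 <- trna_spearman(setNames(rev(unname(counts)), meta$species_id), meta)
  expect_equal(res2$rho, -1)

  # constant vector flagged
  res3 <- trna_spearman(setNames(rep(3, 6), meta$species_id), meta)
  expect_true(res3$constant)
  expect_true(is.na(res3$rho))
})
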