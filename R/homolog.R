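# Comparative-genomics statistics: hit filtering, per-species group
# averages and average ratios, permutation z-score tests, presence
# screening and phylum normalisation, unicellular/multicellular
# comparison, and the A34-tRNA gene-content correlation.

#' Filter homology hits
#'
#' Duplicate (query, subject) pairs are collapsed to one hit keeping the
#' best e-value; per query at most `max_hits_per_query` best-by-e-value
#' hits are retained (mirroring a search tool's accepted-hit cap,
#' applied before the score filters); then hits must pass
#' `evalue <= evalue_max` and `overlap_fraction >= overlap_min`.
#'
#' @param hits Data frame with columns `query_id`, `subject_id`,
#'   `species_id`, `evalue`, `overlap_fraction`.
#' @param evalue_max E-value cut-off (default 0.01).
#' @param overlap_min Minimum aligned-query-coverage (default 0.20).
#' @param max_hits_per_query Hit cap per query (default 10000).
#' @return Filtered data frame.
#' @export
filter_hits <- function(hits, evalue_max = 0.01, overlap_min = 0.20,
                        max_hits_per_query = 10000L) {
  req <- c("query_id", "subject_id", "species_id", "evalue",
           "overlap_fraction")
  miss <- setdiff(req, names(hits))
  if (length(miss)) stop("hits table misses columns: ",
                         paste(miss, collapse = ", "))
  if (any(hits$evalue <= 0)) stop("e-values must be > 0")
  hits <- hits[order(hits$query_id, hits$evalue), , drop = FALSE]
  hits <- hits[!duplicated(hits[c("query_id", "subject_id")]), ,
               drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$query_id),
                        function(i) utils::head(i, max_hits_per_query)),
                 use.names = FALSE)
  hits <- hits[sort(keep), , drop = FALSE]
  hits <- hits[hits$evalue <= evalue_max &
                 hits$overlap_fraction >= overlap_min, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Query-by-species hit count matrix
#'
#' One hit is one distinct subject protein per query (apply
#' [filter_hits()] first to collapse duplicate HSPs).  All species in
#' `meta` appear as columns; missing combinations are 0.
#'
#' @param hits Filtered hits data frame.
#' @param meta Species metadata data frame (see [read_species_meta()]).
#' @return Integer matrix, queries x species.
#' @export
species_hit_matrix <- function(hits, meta) {
  unknown <- setdiff(unique(hits$species_id), meta$species_id)
  if (length(unknown)) {
    stop("species not in metadata: ", paste(unknown, collapse = ", "))
  }
  hits <- hits[!duplicated(hits[c("query_id", "subject_id")]), ,
               drop = FALSE]
  q <- factor(hits$query_id, levels = sort(unique(hits$query_id)))
  s <- factor(hits$species_id, levels = meta$species_id)
  m <- table(q, s)
  mat <- matrix(as.integer(m), nrow = nrow(m), dimnames = dimnames(m))
  names(dimnames(mat)) <- NULL
  mat
}

# resolve species IDs belonging to a group specification
.group_species <- function(meta, group, by) {
  if (!by %in% names(meta)) stop("no column '", by, "' in species meta")
  sp <- meta$species_id[meta[[by]] %in% group & !is.na(meta[[by]])]
  if (!length(sp)) stop("empty species group: ", paste(group, collapse = "/"))
  sp
}

#' Per-genome group averages and their ratio
#'
#' For each query, the per-genome hit rate in a group is the total
#' number of hits in the group divided by the number of genomes in the
#' group.  `avg_a` and `avg_b` are the means of these rates over
#' queries; the average ratio is `avg_a / avg_b` (a single pooled
#' number, not a mean of per-query ratios, which are undefined whenever
#' a query has no group-b hits).
#'
#' @param mat Query-by-species hit matrix.
#' @param meta Species metadata.
#' @param group_a,group_b Values of the `by` column defining the two
#'   groups (e.g. `c("Archaea", "Bacteria")` vs `"Eukarya"`).
#' @param by Metadata column holding the grouping (default `"domain"`).
#' @return List with `avg_a`, `avg_b`, `ratio` (NA and flagged
#'   `undefined` when `avg_b` is 0), and `per_query` rates.
#' @export
group_average_ratio <- function(mat, meta, group_a, group_b,
                                by = "domain") {
  sp_a <- intersect(.group_species(meta, group_a, by), colnames(mat))
  sp_b <- intersect(.group_species(meta, group_b, by), colnames(mat))
  if (!length(sp_a) || !length(sp_b)) {
    stop("group species absent from the hit matrix")
  }
  ra <- rowSums(mat[, sp_a, drop = FALSE]) / length(sp_a)
  rb <- rowSums(mat[, sp_b, drop = FALSE]) / length(sp_b)
  avg_a <- mean(ra); avg_b <- mean(rb)
  list(avg_a = avg_a, avg_b = avg_b,
       ratio = if (avg_b > 0) avg_a / avg_b else NA_real_,
       undefined = avg_b == 0,
       per_query = data.frame(query_id = rownames(mat), rate_a = ra,
                              rate_b = rb, row.names = NULL,
                              stringsAsFactors = FALSE))
}

#' Permutation test on the group average ratio
#'
#' The observed statistic is the [group_average_ratio()] of the query
#' set; the null distribution comes from `B` uniform
#' without-replacement draws of equally many queries from the whole
#' matrix.  The z-score against the null mean and SD yields the normal
#' p-value for `alternative` (default `"less"`: the query set's ratio
#' is depleted relative to random sets, the direction of interest when
#' asking whether homologs are rare in one group).  The empirical tail
#' proportion is reported alongside.
#'
#' @param mat Query-by-species hit matrix over the whole proteome.
#' @param meta Species metadata.
#' @param query_set Character vector of query IDs (subset of
#'   `rownames(mat)`).
#' @param group_a,group_b,by Grouping, as in [group_average_ratio()].
#' @param B Number of permutation draws (default 5000).
#' @param seed Optional integer seed (local to this call).
#' @param alternative `"less"`, `"greater"` or `"two.sided"`.
#' @return Object of class `permutation_result`: `observed`,
#'   `null_mean`, `null_sd`, `z`, `p` (normal), `p_empirical`, `B`,
#'   `set_size`, `seed`, `alternative`, `degenerate`.
#' @export
permutation_ratio_test <- function(mat, meta, query_set, group_a, group_b,
                                   by = "domain", B = 5000L, seed = NULL,
                                   alternative = c("less", "greater",
                                                   "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(B >= 1L)
  bad <- setdiff(query_set, rownames(mat))
  if (length(bad)) stop("query_set not in matrix: ",
                        paste(utils::head(bad, 5L), collapse = ", "))
  sp_a <- intersect(.group_species(meta, group_a, by), colnames(mat))
  sp_b <- intersect(.group_species(meta, group_b, by), colnames(mat))
  ra <- rowSums(mat[, sp_a, drop = FALSE]) / length(sp_a)
  rb <- rowSums(mat[, sp_b, drop = FALSE]) / length(sp_b)
  k <- length(query_set)
  n <- nrow(mat)
  idx_obs <- match(query_set, rownames(mat))
  observed <- mean(ra[idx_obs]) / mean(rb[idx_obs])
  draw <- function() {
    i <- sample.int(n, k)
    mean(ra[i]) / mean(rb[i])
  }
  null <- if (is.null(seed)) {
    vapply(seq_len(B), function(j) draw(), numeric(1))
  } else {
    withr::with_seed(seed,
                     vapply(seq_len(B), function(j) draw(), numeric(1)))
  }
  .permutation_result(observed, null, B = B, set_size = k, seed = seed,
                      alternative = alternative)
}

# shared assembly of a permutation test result
.permutation_result <- function(observed, null, B, set_size, seed,
                                alternative) {
  mu <- mean(null)
  s <- sd(null)
  degenerate <- !is.finite(s) || s == 0
  z <- if (degenerate) {
    if (isTRUE(all.equal(observed, mu))) 0 else sign(observed - mu) * Inf
  } else {
    (observed - mu) / s
  }
  p <- if (degenerate && z != 0) NA_real_ else switch(
    alternative,
    less = pnorm(z),
    greater = pnorm(z, lower.tail = FALSE),
    two.sided = 2 * pnorm(-abs(z))
  )
  if (degenerate) p <- NA_real_
  emp <- switch(alternative,
                less = mean(null <= observed),
                greater = mean(null >= observed),
                two.sided = mean(abs(null - mu) >= abs(observed - mu)))
  structure(list(observed = observed, null_mean = mu, null_sd = s,
                 z = z, p = p, p_empirical = emp, B = B,
                 set_size = set_size, seed = seed,
                 alternative = alternative, degenerate = degenerate),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test (B =", x$B, ", set size =", x$set_size, ")\n")
  cat(sprintf("  observed = %.6g, null mean = %.6g (sd %.3g)\n",
              x$observed, x$null_mean, x$null_sd))
  cat(sprintf("  z = %.4g, p (%s, normal) = %.4g, empirical = %.4g\n",
              x$z, x$alternative, x$p, x$p_empirical))
  if (x$degenerate) cat("  [degenerate null: sd = 0]\n")
  invisible(x)
}

#' Screen homolog sequences for TAPSLIVR-rich regions
#'
#' A (query, species) pair is marked present when the species has at
#' least one homolog of the query that itself contains at least one
#' low-complexity TAPSLIVR-rich region (detected with
#' [find_regions()]).
#'
#' @param homologs Data frame with columns `query_id`, `species_id`,
#'   `subject_id`, `seq` (subject protein sequences).
#' @param params A [scan_params()] object.
#' @return Data frame `species_id`, `query_id`, `present` (logical),
#'   one row per observed pair; pairs without homologs are absent.
#' @export
presence_screen <- function(homologs, params = scan_params()) {
  req <- c("query_id", "species_id", "subject_id", "seq")
  miss <- setdiff(req, names(homologs))
  if (length(miss)) stop("homologs table misses columns: ",
                         paste(miss, collapse = ", "))
  has_region <- vapply(homologs$seq, function(s) {
    nrow(find_regions(s, params)) > 0L
  }, logical(1), USE.NAMES = FALSE)
  agg <- stats::aggregate(has_region,
                          by = list(species_id = homologs$species_id,
                                    query_id = homologs$query_id),
                          FUN = any)
  names(agg)[3] <- "present"
  agg[order(agg$species_id, agg$query_id), , drop = FALSE]
}

#' Normalise presence counts by phylum
#'
#' For each (phylum, query): the fraction of the phylum's species with
#' at least one qualifying homolog.  Species without any screened
#' homolog count as absent; the denominator is all species of the
#' phylum in `meta`.
#'
#' @param presence Output of [presence_screen()].
#' @param meta Species metadata.
#' @return Long-format data frame `phylum`, `query_id`, `fraction`.
#' @export
phylum_normalize <- function(presence, meta) {
  unknown <- setdiff(unique(presence$species_id), meta$species_id)
  if (length(unknown)) {
    stop("species not in metadata: ", paste(unknown, collapse = ", "))
  }
  n_phy <- table(meta$phylum)
  queries <- sort(unique(presence$query_id))
  pres <- presence[presence$present, , drop = FALSE]
  pres$phylum <- meta$phylum[match(pres$species_id, meta$species_id)]
  out <- expand.grid(phylum = names(n_phy), query_id = queries,
                     stringsAsFactors = FALSE)
  key <- paste(pres$phylum, pres$query_id)
  cnt <- vapply(seq_len(nrow(out)), function(i) {
    length(unique(pres$species_id[key == paste(out$phylum[i],
                                               out$query_id[i])]))
  }, numeric(1))
  out$fraction <- cnt / as.numeric(n_phy[out$phylum])
  out
}

#' Compare homolog abundance between unicellular and multicellular
#' eukaryotes
#'
#' Per-species counts (column sums of the matrix over the given query
#' set) are split by multicellularity.  Reports the fold-change of the
#' medians (multicellular / unicellular), a two-sided Mann-Whitney U
#' test with tie correction, and a [permutation_ratio_test()] on the
#' unicellular/multicellular average ratio.
#'
#' @param mat Query-by-species hit or presence-count matrix.
#' @param meta Species metadata with `multicellularity` set for
#'   eukaryotes.
#' @param query_set Query IDs whose homolog counts are compared
#'   (default: all queries, in which case the permutation arm is
#'   degenerate by construction).
#' @param B,seed Permutation settings.
#' @return List with `fc_median`, `fc_undefined`, `mann_whitney_p`,
#'   `permutation` (a `permutation_result`), and the two count vectors.
#' @export
multicellular_compare <- function(mat, meta, query_set = rownames(mat),
                                  B = 5000L, seed = NULL) {
  sp_uni <- intersect(.group_species(meta, "unicellular",
                                     "multicellularity"), colnames(mat))
  sp_multi <- intersect(.group_species(meta, "multicellular",
                                       "multicellularity"), colnames(mat))
  sub <- mat[query_set, , drop = FALSE]
  uni <- colSums(sub[, sp_uni, drop = FALSE])
  multi <- colSums(sub[, sp_multi, drop = FALSE])
  med_u <- median(uni)
  fc <- if (med_u > 0) median(multi) / med_u else NA_real_
  mw <- suppressWarnings(wilcox.test(multi, uni, alternative = "two.sided"))
  # completely tied samples make the tie-corrected statistic 0/0; there
  # is no evidence of a shift, so report p = 1
  if (is.nan(mw$p.value)) mw$p.value <- 1
  perm <- permutation_ratio_test(mat, meta, query_set,
                                 group_a = "unicellular",
                                 group_b = "multicellular",
                                 by = "multicellularity", B = B,
                                 seed = seed, alternative = "less")
  list(fc_median = fc, fc_undefined = med_u == 0,
       mann_whitney_p = mw$p.value, permutation = perm,
       counts_unicellular = uni, counts_multicellular = multi)
}

#' Spearman correlation of homolog abundance with A34-tRNA gene content
#'
#' Species with more A34-tRNA genes than `exclude_above` are excluded
#' (and listed); the correlation is computed on (`n_A34_genes`,
#' homolog count) over the remaining species with tRNA annotations.
#'
#' @param counts Named numeric vector: qualifying-homolog count per
#'   species.
#' @param meta Species metadata with `n_A34_genes` and `a34_diversity`.
#' @param exclude_above Exclusion bound on A34-tRNA gene count (default
#'   400; strictly greater values are excluded).
#' @return List with `rho`, `p`, `n_used`, `excluded` (species IDs),
#'   `constant` flag, and the merged `data`.
#' @export
trna_spearman <- function(counts, meta, exclude_above = 400) {
  m <- meta[!is.na(meta$n_A34_genes) &
              meta$species_id %in% names(counts), , drop = FALSE]
  excluded <- m$species_id[m$n_A34_genes > exclude_above]
  m <- m[m$n_A34_genes <= exclude_above, , drop = FALSE]
  if (nrow(m) < 3L) stop("fewer than 3 species after exclusion")
  x <- m$n_A34_genes
  y <- as.numeric(counts[m$species_id])
  constant <- sd(x) == 0 || sd(y) == 0
  if (constant) {
    rho <- NA_real_; p <- NA_real_
  } else {
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = FALSE))
    rho <- unname(ct$estimate); p <- ct$p.value
  }
  list(rho = rho, p = p, n_used = nrow(m), excluded = excluded,
       constant = constant,
       data = data.frame(species_id = m$species_id, n_A34_genes = x,
                         homolog_count = y,
                         a34_diversity = m$a34_diversity,
                         stringsAsFactors = FALSE))
}
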