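# Translation-efficiency enrichment statistics: interaction-threshold
# classification, Fisher exact enrichment, permutation-proportion test.

#' Classify genes by translation-efficiency fold-changes
#'
#' In `"threshold"` mode, translationally impaired genes have an
#' interaction fold-change (KD vs CTRL of HP/Total) below `fc_cut` with
#' `p < p_cut`, on the fold-change scale as printed in such tables;
#' increased genes exceed `fc_cut` with significance.  `"relaxed"` mode
#' classifies by fold-change sign only (above/below 1, i.e. positive or
#' negative log fold-change) with no significance filter.  Highly
#' translated genes in control cells have `fc_hp_total_ctrl > fc_cut`,
#' additionally requiring `p_ctrl < p_cut` when a `p_ctrl` column is
#' present.
#'
#' @param records TE table data frame (see [read_te_table()]).
#' @param fc_cut Fold-change cut (default 1.5).
#' @param p_cut Significance cut (default 0.05).
#' @param mode `"threshold"` or `"relaxed"`.
#' @return List of gene-ID vectors: `impaired` (or `down` in relaxed
#'   mode), `increased` (`up`), `unchanged`, `highly_translated`.
#' @export
classify_te <- function(records, fc_cut = 1.5, p_cut = 0.05,
                        mode = c("threshold", "relaxed")) {
  mode <- match.arg(mode)
  g <- records$gene_id
  if (mode == "threshold") {
    impaired <- records$interaction_fc < fc_cut & records$p < p_cut
    increased <- records$interaction_fc > fc_cut & records$p < p_cut
    sets <- list(impaired = g[impaired], increased = g[increased],
                 unchanged = g[!impaired & !increased])
  } else {
    down <- records$interaction_fc < 1
    up <- records$interaction_fc > 1
    sets <- list(down = g[down], up = g[up], unchanged = g[!down & !up])
  }
  ht <- records$fc_hp_total_ctrl > fc_cut
  if ("p_ctrl" %in% names(records)) ht <- ht & records$p_ctrl < p_cut
  sets$highly_translated <- g[ht]
  sets
}

#' Fisher exact enrichment of an annotation within a gene set
#'
#' Builds the 2x2 table (rows: in/out of the set, columns:
#' annotated/not, within the universe) and computes the exact
#' hypergeometric two-sided p-value.  The odds ratio is the sample odds
#' ratio of the raw table, with a Haldane 0.5 correction applied only
#' when a zero cell makes it undefined.
#'
#' @param set Character vector of gene IDs (subset of `universe`).
#' @param annotated Character vector of annotated gene IDs.
#' @param universe Character vector of all gene IDs.
#' @return List with `table` (2x2 matrix), `odds_ratio`, `p`.
#' @export
fisher_enrichment <- function(set, annotated, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  set <- intersect(unique(set), universe)
  annotated <- intersect(unique(annotated), universe)
  a <- length(intersect(set, annotated))
  b <- length(set) - a
  c_ <- length(annotated) - a
  d <- length(universe) - a - b - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("in_set", "out_set"),
                                c("annotated", "not_annotated")))
  or <- if (any(tab == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    (a * d) / (b * c_)
  }
  list(table = tab, odds_ratio = or,
       p = fisher.test(tab, alternative = "two.sided")$p.value)
}

#' Permutation test on the annotated proportion of a gene set
#'
#' The statistic is the proportion of a random `n`-gene set (drawn
#' without replacement from the universe) carrying the annotation; the
#' p-value is the proportion of permutations with a statistic at least
#' as extreme as (i.e. `>=`, or `>` when `inclusive = FALSE`) the
#' observed proportion.  As `B` grows this converges to the
#' hypergeometric upper-tail probability.
#'
#' @param universe Character vector of all gene IDs.
#' @param annotated Character vector of annotated gene IDs, or a
#'   logical vector along `universe`.
#' @param n Set size drawn per permutation (default 31).
#' @param observed Observed proportion in `[0, 1]`; alternatively give
#'   `set`.
#' @param set Optional observed gene set from which `observed` is
#'   computed.
#' @param B Number of permutations (default 10000).
#' @param seed Optional integer seed (local to this call).
#' @param inclusive Count ties as extreme (default `TRUE`).
#' @param smooth Add-one smoothing of the proportion (default `FALSE`,
#'   matching the plain proportion-of-permutations definition).
#' @return Object of class `permutation_result` (normal-approximation
#'   fields included for completeness; `p` here is the empirical
#'   proportion).
#' @export
permutation_proportion_test <- function(universe, annotated, n = 31L,
                                        observed = NULL, set = NULL,
                                        B = 10000L, seed = NULL,
                                        inclusive = TRUE, smooth = FALSE) {
  universe <- unique(universe)
  N <- length(universe)
  if (n > N) stop("n exceeds the universe size")
  ann <- if (is.logical(annotated)) {
    if (length(annotated) != N) stop("logical annotation length mismatch")
    annotated
  } else {
    universe %in% annotated
  }
  if (!is.null(set)) {
    obs_set <- intersect(unique(set), universe)
    if (!length(obs_set)) stop("observed set has no genes in the universe")
    observed <- mean(obs_set %in% universe[ann])
  }
  if (is.null(observed) || is.na(observed) || observed < 0 || observed > 1) {
    stop("observed proportion must be in [0, 1]")
  }
  draw <- function() mean(ann[sample.int(N, n)])
  null <- if (is.null(seed)) {
    vapply(seq_len(B), function(j) draw(), numeric(1))
  } else {
    withr::with_seed(seed,
                     vapply(seq_len(B), function(j) draw(), numeric(1)))
  }
  eps <- 1e-12
  hits <- if (inclusive) sum(null >= observed - eps) else
    sum(null > observed + eps)
  p <- if (smooth) (hits + 1) / (B + 1) else hits / B
  res <- .permutation_result(observed, null, B = B, set_size = n,
                             seed = seed, alternative = "greater")
  res$p <- p
  res$p_empirical <- p
  res
}
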