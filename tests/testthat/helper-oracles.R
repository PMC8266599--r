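# Independent oracles used across tests.  These deliberately use naive
# brute-force formulations, separate from the package's implementations.

# residue coverage of the union of qualifying fixed-length windows
brute_coverage <- function(protein, window = 30L, min_fraction = 0.8) {
  mask <- strsplit(toupper(protein), "")[[1]] %in%
    c("T", "A", "P", "S", "L", "I", "V", "R")
  n <- length(mask)
  cov <- rep(FALSE, n)
  need <- ceiling(min_fraction * window)
  if (n >= window) {
    for (s in seq_len(n - window + 1L)) {
      if (sum(mask[s:(s + window - 1L)]) >= need) {
        cov[s:(s + window - 1L)] <- TRUE
      }
    }
  }
  cov
}

# coverage implied by a region table
region_coverage <- function(regions, n) {
  cov <- rep(FALSE, n)
  for (i in seq_len(nrow(regions))) {
    cov[(regions$start0[i] + 1L):regions$end0[i]] <- TRUE
  }
  cov
}

random_protein <- function(n, p_tap = 0.5) {
  tap <- c("T", "A", "P", "S", "L", "I", "V", "R")
  other <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], tap)
  paste(ifelse(runif(n) < p_tap,
               sample(tap, n, replace = TRUE),
               sample(other, n, replace = TRUE)), collapse = "")
}

split_codons <- function(cds) {
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

# a random CDS of n sense codons (uniform over the 61)
random_cds <- function(n) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n, replace = TRUE), collapse = "")
}

# exact two-sided Mann-Whitney p by full enumeration (no ties)
enumerate_mw_p <- function(x, y) {
  pool <- c(x, y)
  stopifnot(!anyDuplicated(pool))
  m <- length(x)
  r <- rank(pool)
  u_of <- function(idx) sum(r[idx]) - m * (m + 1) / 2
  u_obs <- u_of(seq_len(m))
  combos <- utils::combn(length(pool), m)
  u_all <- apply(combos, 2, u_of)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# exact two-sided Fisher p by enumerating all tables with fixed margins
enumerate_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  support <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(support, c1, N - c1, r1)
  obs <- stats::dhyper(a, c1, N - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
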