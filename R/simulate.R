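# Seeded synthetic-data generators.  Every generator returns its truth
# table alongside the data, and is fully deterministic under its seed.

.non_tapslivr_aa <- function() setdiff(.aa_alphabet(), c(tapslivr_aa(), "X"))

#' Generate a synthetic proteome with planted TAPSLIVR-rich regions
#'
#' Proteins with planted regions are built as alternating spacers and
#' regions.  Spacers contain only non-TAPSLIVR residues and are at
#' least `2 * window` long, guaranteeing that planted regions never
#' merge and that detected coordinates relate to planted ones by the
#' fixed window-overhang margin alone.  Planted regions draw each
#' residue from the TAPSLIVR set with the region's target fraction.
#' Proteins without regions are pure background: TAPSLIVR residues at
#' `background_rate`, far below any sensible detection threshold.
#'
#' @param n_proteins Number of proteins.
#' @param n_regions Planted regions per protein (0 for pure background).
#' @param region_length Range (min, max) of planted-region lengths.
#' @param region_fraction Range (min, max) of target TAPSLIVR
#'   fractions.
#' @param background_length Length of background-only proteins.
#' @param background_rate Background TAPSLIVR rate.
#' @param window Detection window the spacers are sized against
#'   (default 30).
#' @param seed Integer seed; fully determines the output.
#' @return List with `proteins` (named character vector) and `truth`
#'   (data frame `protein_id`, `start0`, `end0`, `target_fraction`),
#'   plus the `seed`.
#' @export
gen_proteome <- function(n_proteins = 20L, n_regions = 1L,
                         region_length = c(35L, 60L),
                         region_fraction = c(1, 1),
                         background_length = 200L,
                         background_rate = 0.2, window = 30L,
                         seed = 1L) {
  stopifnot(n_proteins >= 1L, n_regions >= 0L,
            region_length[1] >= window,
            region_fraction[1] > 0, region_fraction[2] <= 1)
  withr::with_seed(seed, {
    bg_aa <- .non_tapslivr_aa()
    tap_aa <- tapslivr_aa()
    spacer_len <- 2L * as.integer(window)
    truth <- list()
    proteins <- character(n_proteins)
    ids <- sprintf("sp%04d", seq_len(n_proteins))
    for (i in seq_len(n_proteins)) {
      if (n_regions == 0L) {
        is_tap <- runif(background_length) < background_rate
        res <- ifelse(is_tap,
                      sample(tap_aa, background_length, replace = TRUE),
                      sample(bg_aa, background_length, replace = TRUE))
        proteins[i] <- paste(res, collapse = "")
        next
      }
      pieces <- character(0)
      pos <- 0L
      for (r in seq_len(n_regions)) {
        spacer <- paste(sample(bg_aa, spacer_len, replace = TRUE),
                        collapse = "")
        len <- sample(seq.int(region_length[1], region_length[2]), 1L)
        frac <- runif(1, region_fraction[1], region_fraction[2])
        n_tap <- ceiling(frac * len)
        flags <- sample(c(rep(TRUE, n_tap), rep(FALSE, len - n_tap)))
        region <- ifelse(flags, sample(tap_aa, len, replace = TRUE),
                         sample(bg_aa, len, replace = TRUE))
        pieces <- c(pieces, spacer, paste(region, collapse = ""))
        pos <- pos + spacer_len
        truth[[length(truth) + 1L]] <- data.frame(
          protein_id = ids[i], start0 = pos, end0 = pos + len,
          target_fraction = n_tap / len, stringsAsFactors = FALSE)
        pos <- pos + len
      }
      tail_spacer <- paste(sample(bg_aa, spacer_len, replace = TRUE),
                           collapse = "")
      proteins[i] <- paste(c(pieces, tail_spacer), collapse = "")
    }
    names(proteins) <- ids
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(protein_id = character(0), start0 = integer(0),
                 end0 = integer(0), target_fraction = numeric(0))
    list(proteins = proteins, truth = truth, seed = seed)
  })
}

#' Generate a coding sequence for a protein by usage-weighted sampling
#'
#' Codons are sampled among each residue's synonyms proportionally to
#' `usage`.  Inside `adat_regions`, TAPSLIVR residues instead draw an
#' ADAT-sensitive synonym with probability `adat_bias` (and a non-ADAT
#' synonym otherwise), each proportionally to usage within its class.
#' Isoleucine has only ADAT-sensitive codons, so a sub-1 bias cannot be
#' honoured there (a warning is emitted once).
#'
#' @param protein A single protein sequence string (no `X`).
#' @param usage Codon usage table.
#' @param adat_bias Target ADAT fraction among TAPSLIVR codons, or
#'   `NULL` for plain usage-weighted sampling.
#' @param adat_regions Data frame with `start0`, `end0` (0-based
#'   half-open residue coordinates) delimiting where the bias applies;
#'   `NULL` with a non-`NULL` `adat_bias` applies it everywhere.
#' @param seed Integer seed.
#' @return Named character vector of length 1 (the CDS, no stop codon).
#' @export
gen_cds <- function(protein, usage = human_codon_usage(),
                    adat_bias = NULL, adat_regions = NULL, seed = 1L) {
  protein <- toupper(protein[[1]])
  aa <- strsplit(protein, "")[[1]]
  if (any(aa == "X")) stop("cannot backtranslate 'X' residues")
  gc_code <- .genetic_code()
  sense <- names(gc_code)[gc_code != "*"]
  names(usage) <- normalize_nt(names(usage))
  syn <- split(sense, gc_code[sense])
  in_bias <- rep(!is.null(adat_bias), length(aa))
  if (!is.null(adat_regions) && !is.null(adat_bias)) {
    in_bias <- rep(FALSE, length(aa))
    for (r in seq_len(nrow(adat_regions))) {
      in_bias[(adat_regions$start0[r] + 1L):adat_regions$end0[r]] <- TRUE
    }
  }
  adat <- adat_codons()
  withr::with_seed(seed, {
    warned <- FALSE
    codons <- vapply(seq_along(aa), function(i) {
      cs <- syn[[aa[i]]]
      if (in_bias[i] && aa[i] %in% tapslivr_aa()) {
        pick_adat <- runif(1) < adat_bias
        pool <- if (pick_adat) intersect(cs, adat) else setdiff(cs, adat)
        if (!length(pool)) {
          if (!warned && aa[i] == "I") {
            warning("Ile has no non-ADAT synonym; bias not achievable",
                    call. = FALSE)
            warned <<- TRUE
          }
          pool <- cs
        }
        cs <- pool
      }
      p <- usage[cs]
      if (sum(p) <= 0) p <- rep(1, length(cs))
      cs[sample.int(length(cs), 1L, prob = p)]
    }, character(1))
    setNames(paste(codons, collapse = ""), names(protein) %||% "cds")
  })
}

#' Generate synthetic homolog hits, species metadata and truth
#'
#' Species are laid out from `species_spec` (one row per group of
#' identical species).  Hit counts per (query, species) are Poisson
#' with a rate depending on whether the query belongs to the planted
#' query set and on the species' rate group; each kept hit passes the
#' default filters, and `fail_fraction` extra hits failing either the
#' e-value or overlap filter are interspersed.  Eukaryotic A34-tRNA
#' gene counts are a monotone function of the species' planted-set hit
#' rate plus optional noise.
#'
#' @param n_queries Total queries; the first `n_set` form the planted
#'   set.
#' @param n_set Size of the planted query set.
#' @param species_spec Data frame with columns `group`, `domain`,
#'   `phylum`, `multicellularity`, `n_species` (see
#'   `default_species_spec()`).
#' @param lambda_set,lambda_bg Named numeric vectors of Poisson rates
#'   per species `group`, for planted-set and background queries.
#' @param fail_fraction Fraction of additional filter-failing hits.
#' @param a34_link Monotone function mapping a eukaryotic species'
#'   realised planted-set homolog count to its expected A34-tRNA gene
#'   count; with zero noise and a strictly increasing integer-valued
#'   link, gene counts and homolog counts are perfectly rank-correlated
#'   by construction.
#' @param a34_noise_sd Gaussian noise SD on the A34 link (0 = exact).
#' @param seed Integer seed.
#' @return List with `hits` (data frame), `meta` (species metadata),
#'   `query_set` (planted query IDs) and `truth` (rates used).
#' @export
gen_homolog_data <- function(n_queries = 50L, n_set = 10L,
                             species_spec = default_species_spec(),
                             lambda_set = c(prok = 0.05, euk_uni = 2,
                                            euk_multi = 8),
                             lambda_bg = c(prok = 2, euk_uni = 2,
                                           euk_multi = 2),
                             fail_fraction = 0.1,
                             a34_link = function(n) 20 + 3 * n,
                             a34_noise_sd = 0, seed = 1L) {
  stopifnot(n_set <= n_queries)
  meta <- do.call(rbind, lapply(seq_len(nrow(species_spec)), function(i) {
    s <- species_spec[i, ]
    data.frame(
      species_id = sprintf("%s%03d", s$group, seq_len(s$n_species)),
      domain = s$domain, phylum = s$phylum,
      multicellularity = s$multicellularity, group = s$group,
      stringsAsFactors = FALSE)
  }))
  queries <- sprintf("q%04d", seq_len(n_queries))
  query_set <- queries[seq_len(n_set)]
  withr::with_seed(seed, {
    rows <- list()
    for (qi in seq_along(queries)) {
      lam <- if (qi <= n_set) lambda_set else lambda_bg
      counts <- rpois(nrow(meta), lam[meta$group])
      keep <- counts > 0
      if (any(keep)) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = rep(queries[qi], sum(counts)),
          subject_id = paste0(rep(meta$species_id[keep], counts[keep]),
                              "_h", sequence(counts[keep]), "_",
                              queries[qi]),
          species_id = rep(meta$species_id[keep], counts[keep]),
          evalue = 10^runif(sum(counts), -30, -3),
          overlap_fraction = runif(sum(counts), 0.25, 1),
          stringsAsFactors = FALSE)
      }
    }
    hits <- do.call(rbind, rows)
    n_fail <- ceiling(fail_fraction * nrow(hits))
    if (n_fail > 0) {
      pick <- sample.int(nrow(hits), n_fail, replace = TRUE)
      bad <- hits[pick, , drop = FALSE]
      bad$subject_id <- paste0(bad$subject_id, "_bad", seq_len(n_fail))
      half <- seq_len(n_fail) %% 2L == 0L
      bad$evalue[half] <- 10^runif(sum(half), -1.5, 0)
      bad$overlap_fraction[!half] <- runif(sum(!half), 0, 0.19)
      hits <- rbind(hits, bad)
    }
    hits <- hits[sample.int(nrow(hits)), , drop = FALSE]
    rownames(hits) <- NULL
    euk <- meta$domain == "Eukarya"
    set_hits <- hits[hits$query_id %in% query_set &
                       !grepl("_bad", hits$subject_id), , drop = FALSE]
    realised <- table(factor(set_hits$species_id, levels = meta$species_id))
    n_a34 <- ifelse(euk,
                    pmax(0, round(a34_link(as.numeric(realised)) +
                                    rnorm(nrow(meta), 0, a34_noise_sd))),
                    0L)
    meta$n_A34_genes <- as.integer(n_a34)
    meta$a34_diversity <- ifelse(meta$n_A34_genes > 0, 8L, 0L)
    meta$group <- NULL
    list(hits = hits, meta = meta, query_set = query_set,
         truth = list(lambda_set = lambda_set, lambda_bg = lambda_bg,
                      species_groups = species_spec, seed = seed))
  })
}

#' Default species layout for the homolog generator
#'
#' @return Data frame with columns `group`, `domain`, `phylum`,
#'   `multicellularity`, `n_species`.
#' @export
default_species_spec <- function() {
  data.frame(
    group = c("prok", "euk_uni", "euk_multi"),
    domain = c("Bacteria", "Eukarya", "Eukarya"),
    phylum = c("Proteobacteria", "Ascomycota", "Chordata"),
    multicellularity = c(NA, "unicellular", "multicellular"),
    n_species = c(20L, 10L, 10L),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic translation-efficiency table
#'
#' Background genes draw log2 interaction fold-changes from
#' `Normal(0, sigma)`; the planted impaired subset from
#' `Normal(-delta, sigma)`.  P-values are the two-sided normal
#' p-values of the corresponding z-scores, so the table behaves like
#' the output of a differential fit.  Planted genes are annotated
#' (`encodes_lcr`) with probability `planted_annotation_rate`,
#' background genes with `frac_annotated`.  Control HP/Total
#' fold-changes are lognormal around 1, shifted up for planted genes so
#' they are "highly translated in control".
#'
#' @param n_genes Number of genes.
#' @param n_planted Size of the planted impaired subset.
#' @param delta Downward shift of planted log2 fold-changes.
#' @param sigma SD of log2 fold-changes (default 0.5).
#' @param frac_annotated Background annotation rate.
#' @param planted_annotation_rate Annotation rate in the planted subset
#'   (default 1).
#' @param ctrl_shift Upward log2 shift of planted genes' control
#'   fold-change (default 1).
#' @param seed Integer seed.
#' @return List with `table` (TE data frame) and `truth` (planted gene
#'   IDs and parameters).
#' @export
gen_te_table <- function(n_genes = 1000L, n_planted = 31L, delta = 0,
                         sigma = 0.5, frac_annotated = 0.1,
                         planted_annotation_rate = 1, ctrl_shift = 1,
                         seed = 1L) {
  stopifnot(n_planted <= n_genes)
  withr::with_seed(seed, {
    ids <- sprintf("g%05d", seq_len(n_genes))
    planted <- rep(c(TRUE, FALSE), c(n_planted, n_genes - n_planted))
    mu <- ifelse(planted, -delta, 0)
    lfc <- rnorm(n_genes, mu, sigma)
    z <- lfc / sigma
    p <- 2 * pnorm(-abs(z))
    ann <- ifelse(planted,
                  runif(n_genes) < planted_annotation_rate,
                  runif(n_genes) < frac_annotated)
    ctrl <- 2^rnorm(n_genes, ifelse(planted, ctrl_shift, 0), sigma)
    tab <- data.frame(
      gene_id = ids,
      fc_hp_total_ctrl = ctrl,
      fc_hp_total_kd = ctrl * 2^lfc,
      interaction_fc = 2^lfc,
      p = p,
      encodes_lcr = ann,
      stringsAsFactors = FALSE
    )
    list(table = tab,
         truth = list(planted = ids[planted], delta = delta,
                      sigma = sigma, seed = seed))
  })
}
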