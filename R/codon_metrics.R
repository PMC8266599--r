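# ADAT-codon enrichment scoring, threshold derivation from codon usage,
# GC and CAI metrics, and synonymous recoding into ADAT-sensitive
# (C-ended) or ADAT-insensitive (G-ended) variants.

#' Default enrichment threshold (percent)
#'
#' The shipped default (65.743%) is the genome-expected ADAT fraction
#' among TAPSLIVR codons under reported human codon usage; see
#' [derive_threshold()].
#' @export
ADAT_THRESHOLD_DEFAULT <- 65.743

#' ADAT-codon enrichment of a coding region
#'
#' Among the TAPSLIVR codons of the region, the percentage that are
#' ADAT-sensitive.  A sequence is called enriched when this percentage
#' strictly exceeds `threshold`.
#'
#' @param cds A single coding sequence string.
#' @param region Optional residue interval `c(start0, end0)` (0-based
#'   half-open, as in region tables); codons are taken from the matching
#'   CDS positions.  Default: whole sequence.
#' @param threshold Enrichment threshold in percent (default
#'   [ADAT_THRESHOLD_DEFAULT]).
#' @return List with `n_tapslivr`, `n_adat`, `adat_percent` (NA when the
#'   region has no TAPSLIVR codon), `enriched`, `undefined`, `threshold`.
#' @export
#' @examples
#' adat_enrichment("ACCGCA")
adat_enrichment <- function(cds, region = NULL,
                            threshold = ADAT_THRESHOLD_DEFAULT) {
  cds <- normalize_nt(cds)
  codons <- codon_split(cds)
  if (!is.null(region)) {
    stopifnot(length(region) == 2L, region[1] >= 0,
              region[2] <= length(codons), region[1] < region[2])
    codons <- codons[(region[1] + 1L):region[2]]
  }
  cls <- codon_class(codons)
  n_tap <- sum(cls %in% c("ADAT", "TAPSLIVR_NON_ADAT"))
  n_adat <- sum(cls == "ADAT")
  pct <- if (n_tap > 0) 100 * n_adat / n_tap else NA_real_
  list(n_tapslivr = n_tap, n_adat = n_adat, adat_percent = pct,
       enriched = !is.na(pct) && pct > threshold,
       undefined = n_tap == 0L, threshold = threshold)
}

#' Derive the ADAT enrichment threshold from a codon usage table
#'
#' The genome-expected ADAT fraction among TAPSLIVR codons:
#' `100 * sum(usage over the 24 ADAT codons) / sum(usage over the 37
#' TAPSLIVR codons)`.  This is the null expectation against which
#' "enriched" is judged; it is invariant to rescaling the usage table.
#'
#' @param usage Named numeric codon usage vector (see
#'   [read_codon_usage()]).
#' @return Threshold in percent.
#' @export
#' @examples
#' u <- setNames(rep(1, 61), names(Biostrings::GENETIC_CODE)[
#'   Biostrings::GENETIC_CODE != "*"])
#' derive_threshold(u)  # 100 * 24/37
derive_threshold <- function(usage) {
  names(usage) <- normalize_nt(names(usage))
  tot <- sum(usage[tapslivr_codons()], na.rm = TRUE)
  if (!isTRUE(tot > 0)) stop("zero total TAPSLIVR usage")
  100 * sum(usage[adat_codons()], na.rm = TRUE) / tot
}

#' GC content of a nucleotide sequence, in percent
#'
#' @param seq A single non-empty nucleotide string.
#' @return Percent G+C.
#' @export
gc_percent <- function(seq) {
  seq <- normalize_nt(seq)
  if (!nchar(seq)) stop("empty sequence")
  if (grepl("[^ACGT]", seq)) stop("non-ACGT character in sequence")
  counts <- table(strsplit(seq, "")[[1]])
  100 * sum(counts[c("G", "C")], na.rm = TRUE) / nchar(seq)
}

# relative adaptiveness w(c) = usage(c) / max usage among synonyms
.relative_adaptiveness <- function(usage, floor = 0.01) {
  gc <- .genetic_code()
  sense <- names(gc)[gc != "*"]
  usage <- usage[sense]
  w <- unsplit(lapply(split(usage, gc[sense]), function(v) v / max(v)),
               gc[sense])
  names(w) <- sense
  w[!is.finite(w) | w <= 0] <- floor
  pmax(w, floor)
}

#' Codon Adaptation Index
#'
#' Geometric mean over codons of the relative adaptiveness
#' `w(c) = usage(c) / max usage among c's synonyms`.  Codons of
#' single-codon families (Met, Trp) and stop codons are excluded;
#' zero-usage codons receive a floor value.
#'
#' @param cds A single coding sequence string.
#' @param usage Named numeric codon usage vector.
#' @param floor Relative adaptiveness assigned to zero-usage codons
#'   (default 0.01).
#' @return CAI value in (0, 1].
#' @export
cai <- function(cds, usage = human_codon_usage(), floor = 0.01) {
  cds <- normalize_nt(cds)
  names(usage) <- normalize_nt(names(usage))
  w <- .relative_adaptiveness(usage, floor)
  gc <- .genetic_code()
  codons <- codon_split(cds)
  aa <- gc[codons]
  keep <- !aa %in% c("*", "M", "W")
  if (!any(keep)) stop("no codons contribute to CAI")
  exp(mean(log(w[codons[keep]])))
}

#' Canonical synonym tables for reporter recoding
#'
#' One codon per TAPSLIVR amino acid.  `C_ENDED` uses the C-ended codon
#' of each I34 box (ADAT-sensitive); `G_ENDED` uses the G-ended synonym
#' (read by C34-tRNAs, ADAT-insensitive).  Isoleucine has no G-ended
#' codon; the fallback keeps the GC-matched ATC by default (see
#' [recode_tapslivr()]).
#'
#' @param mode `"C_ENDED"` or `"G_ENDED"`.
#' @param ile_fallback For `G_ENDED`: `"ATC"` (default, GC-preserving),
#'   `"ATT"`, or `"keep"` (leave Ile codons untouched).
#' @return Named character vector, amino acid -> codon (`NA` for Ile
#'   under `"keep"`).
#' @export
recode_map <- function(mode = c("C_ENDED", "G_ENDED"),
                       ile_fallback = c("ATC", "ATT", "keep")) {
  mode <- match.arg(mode)
  ile_fallback <- match.arg(ile_fallback)
  if (mode == "C_ENDED") {
    c(T = "ACC", A = "GCC", P = "CCC", S = "TCC",
      L = "CTC", I = "ATC", V = "GTC", R = "CGC")
  } else {
    ile <- switch(ile_fallback, ATC = "ATC", ATT = "ATT", keep = NA_character_)
    c(T = "ACG", A = "GCG", P = "CCG", S = "TCG",
      L = "CTG", I = ile, V = "GTG", R = "CGG")
  }
}

#' Recode all TAPSLIVR codons of a coding sequence
#'
#' Every codon encoding a TAPSLIVR amino acid is replaced by the mode's
#' canonical synonym; all other codons are untouched and translation is
#' preserved.  In `G_ENDED` mode isoleucine positions cannot be made
#' G-ended (no such codon exists) and are handled by the fallback,
#' counted in `n_fallback`.  Because C-ended and G-ended synonyms differ
#' only in a G/C swap at the third position (and Ile positions are
#' identical under the default fallback), the two modes yield equal GC
#' content by construction.
#'
#' @param cds A single coding sequence string (terminal stop allowed).
#' @param mode `"C_ENDED"` (ADAT-sensitive) or `"G_ENDED"`
#'   (ADAT-insensitive).
#' @param usage Optional codon usage for before/after CAI bookkeeping.
#' @param ile_fallback See [recode_map()].
#' @return List with `cds` (recoded sequence) and `report`: `mode`,
#'   `substitutions` (data frame `index`, `old`, `new`), `n_changed`,
#'   `n_fallback`, `gc_before`, `gc_after`, and `cai_before`/`cai_after`
#'   when `usage` is given.
#' @export
#' @examples
#' recode_tapslivr("ACAGGG", mode = "C_ENDED")$cds
recode_tapslivr <- function(cds, mode = c("C_ENDED", "G_ENDED"),
                            usage = NULL,
                            ile_fallback = c("ATC", "ATT", "keep")) {
  mode <- match.arg(mode)
  ile_fallback <- match.arg(ile_fallback)
  cds <- normalize_nt(cds)
  codons <- codon_split(cds)
  gc_code <- .genetic_code()
  aa <- unname(gc_code[codons])
  map <- recode_map(mode, ile_fallback)
  idx <- which(aa %in% tapslivr_aa())
  new <- codons
  new[idx] <- ifelse(is.na(map[aa[idx]]), codons[idx], map[aa[idx]])
  n_fallback <- if (mode == "G_ENDED") sum(aa[idx] == "I") else 0L
  if (n_fallback > 0) {
    warning("no G-ended isoleucine codon exists; ", n_fallback,
            " Ile position(s) handled by fallback '", ile_fallback, "'")
  }
  changed <- which(new != codons)
  out <- paste(new, collapse = "")
  stopifnot(translate_cds(setNames(out, "x")) ==
              translate_cds(setNames(cds, "x")))
  report <- list(
    mode = mode,
    substitutions = data.frame(index = changed, old = codons[changed],
                               new = new[changed], stringsAsFactors = FALSE),
    n_changed = length(changed),
    n_fallback = n_fallback,
    gc_before = gc_percent(cds),
    gc_after = gc_percent(out)
  )
  if (!is.null(usage)) {
    report$cai_before <- cai(cds, usage)
    report$cai_after <- cai(out, usage)
  }
  list(cds = out, report = report)
}

#' Standard EGFP protein sequence
#'
#' The canonical 239-residue enhanced GFP protein (avGFP F64L/S65T with
#' the Val2 insertion), used as the reporter scaffold for building
#' matched ADAT-sensitive / ADAT-insensitive coding variants.  This is a
#' standard reference sequence bundled for convenience; published
#' reporter plasmid sequences can be supplied to the same functions via
#' [read_fasta()] instead.
#'
#' @return Named character vector of length 1.
#' @export
egfp_protein <- function() {
  c(eGFP = paste0(
    "MVSKGEELFTGVVPILVELDGDVNGHKFSVSGEGEGDATYGKLTLKFICTTGKLPVPWPTLVTTLTYGVQ",
    "CFSRYPDHMKQHDFFKSAMPEGYVQERTIFFKDDGNYKTRAEVKFEGDTLVNRIELKGIDFKEDGNILGH",
    "KLEYNYNSHNVYIMADKQKNGIKVNFKIRHNIEDGSVQLADHYQQNTPIGDGPVLLPDNHYLSTQSALSK",
    "DPNEKRDHMVLLEFVTAAGITLGMDELYK"))
}

#' Build a matched ADAT / non-ADAT reporter CDS pair
#'
#' Backtranslates a protein using each non-TAPSLIVR amino acid's
#' most-used codon from `usage`, then sets every TAPSLIVR codon to the
#' canonical C-ended synonym (ADAT variant) or G-ended synonym
#' (non-ADAT variant).  The two variants encode the same protein and
#' have identical GC content by construction; CAI bookkeeping is
#' reported so matched codon optimality can be verified.
#'
#' @param protein A single protein sequence string (default
#'   [egfp_protein()]).
#' @param usage Codon usage table (default [human_codon_usage()]).
#' @param ile_fallback See [recode_map()].
#' @return List with `adat`, `nonadat` (CDS strings) and `stats`:
#'   `n_codons`, `n_tapslivr`, `tapslivr_percent`, `gc_adat`,
#'   `gc_nonadat`, `cai_adat`, `cai_nonadat`.
#' @export
build_reporter_pair <- function(protein = egfp_protein(),
                                usage = human_codon_usage(),
                                ile_fallback = "ATC") {
  protein <- toupper(protein[[1]])
  gc_code <- .genetic_code()
  sense <- names(gc_code)[gc_code != "*"]
  names(usage) <- normalize_nt(names(usage))
  fam <- split(sense, gc_code[sense])
  top <- vapply(fam, function(cs) cs[which.max(usage[cs])], character(1))
  aa <- strsplit(protein, "")[[1]]
  if (any(aa == "X")) stop("cannot backtranslate 'X' residues")
  base <- paste(top[aa], collapse = "")
  adat <- recode_tapslivr(base, "C_ENDED", usage = usage)
  nonadat <- suppressWarnings(
    recode_tapslivr(base, "G_ENDED", usage = usage,
                    ile_fallback = ile_fallback))
  score <- adat_enrichment(adat$cds)
  list(
    adat = adat$cds,
    nonadat = nonadat$cds,
    stats = list(
      n_codons = nchar(base) / 3,
      n_tapslivr = score$n_tapslivr,
      tapslivr_percent = 100 * score$n_tapslivr / (nchar(base) / 3),
      gc_adat = gc_percent(adat$cds),
      gc_nonadat = gc_percent(nonadat$cds),
      cai_adat = cai(adat$cds, usage),
      cai_nonadat = cai(nonadat$cds, usage)
    )
  )
}
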