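# Running-window detection of low-complexity TAPSLIVR-rich regions.
#
# A window of `window` residues qualifies when at least
# ceiling(min_fraction * window) of its residues are TAPSLIVR; maximal
# regions are the coordinate union of qualifying windows.  Coordinates
# are 0-based half-open throughout.

#' Scan parameters for TAPSLIVR region detection
#'
#' @param window Window size in residues (default 30).
#' @param min_fraction Minimum TAPSLIVR fraction per window; the integer
#'   threshold is `ceiling(min_fraction * window)`, i.e. at least 24 of
#'   30 with the defaults.  Inclusive ("at least 80%").
#' @param step Window step (default 1).
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(window = 30L, min_fraction = 0.80, step = 1L) {
  window <- as.integer(window)
  step <- as.integer(step)
  if (is.na(window) || window < 1L) stop("window must be >= 1")
  if (is.na(step) || step < 1L) stop("step must be >= 1")
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must be in (0, 1]")
  }
  structure(list(window = window, min_fraction = min_fraction, step = step),
            class = "scan_params")
}

#' TAPSLIVR mask of a protein sequence
#'
#' @param protein A single protein sequence string.
#' @return Logical vector, one flag per residue; `TRUE` iff the residue
#'   is one of T, A, P, S, L, I, V, R.  `X` is never TAPSLIVR.
#' @export
#' @examples
#' tapslivr_mask("TGX")
tapslivr_mask <- function(protein) {
  strsplit(toupper(protein), "")[[1]] %in% tapslivr_aa()
}

.empty_regions <- function() {
  data.frame(protein_id = character(0), start0 = integer(0),
             end0 = integer(0), length = integer(0),
             tapslivr_fraction = numeric(0), n_windows = integer(0),
             stringsAsFactors = FALSE)
}

#' Detect low-complexity TAPSLIVR-rich regions in one protein
#'
#' Slides fixed-length windows, marks those meeting the TAPSLIVR
#' threshold, and merges overlapping or adjacent qualifying windows by
#' coordinate union into maximal regions.  The reported fraction is
#' recomputed over the merged region and may fall below `min_fraction`;
#' regions are defined by their qualifying windows, not re-filtered.
#'
#' @param protein A single protein sequence string.
#' @param params A [scan_params()] object.
#' @param id Protein ID for the output table.
#' @return Data frame with columns `protein_id`, `start0`, `end0`
#'   (0-based half-open), `length`, `tapslivr_fraction`, `n_windows`.
#' @export
#' @examples
#' find_regions(strrep("A", 30), id = "p1")
find_regions <- function(protein, params = scan_params(), id = "protein") {
  mask <- tapslivr_mask(protein)
  n <- length(mask)
  w <- params$window
  if (n < w) return(.empty_regions())
  need <- ceiling(params$min_fraction * w)
  cs <- c(0L, cumsum(mask))
  starts <- seq.int(1L, n - w + 1L, by = params$step)
  qual <- starts[(cs[starts + w] - cs[starts]) >= need]
  if (!length(qual)) return(.empty_regions())
  delta <- tabulate(qual, nbins = n + 1L) - tabulate(qual + w, nbins = n + 1L)
  covered <- cumsum(delta[seq_len(n)]) > 0L
  r <- rle(covered)
  ends1 <- cumsum(r$lengths)
  starts1 <- ends1 - r$lengths + 1L
  keep <- which(r$values)
  res <- lapply(keep, function(k) {
    a <- starts1[k]; b <- ends1[k]
    data.frame(
      protein_id = id, start0 = a - 1L, end0 = b, length = b - a + 1L,
      tapslivr_fraction = (cs[b + 1L] - cs[a]) / (b - a + 1L),
      n_windows = sum(qual >= a & qual + w - 1L <= b),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Scan a proteome for TAPSLIVR-rich regions
#'
#' @param proteins Named character vector of protein sequences; IDs must
#'   be unique.
#' @param params A [scan_params()] object.
#' @return List with `regions` (region table sorted by protein then
#'   start) and `summary` (`n_proteins`, `n_with_region`, `n_regions`).
#' @export
scan_proteome <- function(proteins, params = scan_params()) {
  stopifnot(is.character(proteins))
  ids <- names(proteins)
  if (is.null(ids) && length(proteins)) stop("proteins must be named")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate protein IDs: ", paste(dup, collapse = ", "))
  }
  tabs <- lapply(seq_along(proteins), function(i) {
    find_regions(proteins[[i]], params, id = ids[i])
  })
  regions <- do.call(rbind, c(tabs, list(.empty_regions())))
  list(
    regions = regions,
    summary = list(
      n_proteins = length(proteins),
      n_with_region = length(unique(regions$protein_id)),
      n_regions = nrow(regions)
    )
  )
}

#' Per-position TAPSLIVR and ADAT-codon composition profile
#'
#' Centered moving fractions along a protein: at each residue, the
#' TAPSLIVR fraction of residues in the window centered there (truncated
#' at the sequence edges) and, when a coding sequence is supplied, the
#' fraction of window codons that are ADAT-sensitive, plus the ADAT
#' fraction among the window's TAPSLIVR codons (the quantity compared
#' against the enrichment threshold).
#'
#' @param protein A single protein sequence string.
#' @param cds Optional coding sequence whose translation (minus terminal
#'   stop) equals `protein`.
#' @param window Window size (default 30).
#' @return Data frame with one row per residue: `position0`, `residue`,
#'   `tapslivr_fraction`, and with `cds` also `adat_fraction` and
#'   `adat_among_tapslivr` (NA where a window has no TAPSLIVR codon).
#' @export
composition_profile <- function(protein, cds = NULL, window = 30L) {
  mask <- tapslivr_mask(protein)
  n <- length(mask)
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  cls <- NULL
  if (!is.null(cds)) {
    cds <- normalize_nt(cds)
    tr <- translate_cds(setNames(cds, "cds"))
    if (unname(tr) != toupper(protein)) {
      stop("cds does not translate to the given protein")
    }
    cls <- codon_class(codon_split(cds))[seq_len(n)]
  }
  if (window > n) {
    warning("window larger than sequence; full-sequence value repeated")
    lo <- rep(1L, n); hi <- rep(n, n)
  } else {
    half_l <- (window - 1L) %/% 2L
    half_r <- window - 1L - half_l
    lo <- pmax(1L, seq_len(n) - half_l)
    hi <- pmin(n, seq_len(n) + half_r)
  }
  cs <- c(0, cumsum(mask))
  out <- data.frame(
    position0 = seq_len(n) - 1L,
    residue = strsplit(toupper(protein), "")[[1]],
    tapslivr_fraction = (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L),
    stringsAsFactors = FALSE
  )
  if (!is.null(cls)) {
    ca <- c(0, cumsum(cls == "ADAT"))
    ct <- c(0, cumsum(cls %in% c("ADAT", "TAPSLIVR_NON_ADAT")))
    n_adat <- ca[hi + 1L] - ca[lo]
    n_tap <- ct[hi + 1L] - ct[lo]
    out$adat_fraction <- n_adat / (hi - lo + 1L)
    out$adat_among_tapslivr <- ifelse(n_tap > 0, n_adat / n_tap, NA_real_)
  }
  out
}
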