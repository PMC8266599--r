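# Readers and writers: FASTA via Biostrings, tabular formats as TSV with
# '#'-prefixed comment lines.

.aa_alphabet <- function() c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Read a FASTA file into a named character vector
#'
#' Record IDs are the first whitespace-delimited token of each header;
#' sequences are uppercased.  For `type = "dna"`, U is mapped to T.
#' Protein records may contain the 20 canonical residues plus `X`;
#' other letters (selenocysteine, ambiguity codes) are coerced to `X`
#' with a warning when `coerce = TRUE`, and rejected otherwise.
#'
#' @param path Path to a FASTA file.
#' @param type `"protein"` or `"dna"`.
#' @param coerce For proteins, coerce non-canonical letters to `X`
#'   (default `TRUE`).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("protein", "dna"), coerce = TRUE) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(!grepl("^\\s*$", lines))
  if (!length(nonblank)) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  if (!startsWith(lines[nonblank[1]], ">")) {
    stop("malformed FASTA (", path, "): line ", nonblank[1],
         " precedes any '>' header")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA (", path, "): ",
                             conditionMessage(e), call. = FALSE)
  )
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (type == "dna") {
    seqs <- normalize_nt(seqs)
    bad <- grepl("[^ACGT]", seqs)
    if (any(bad)) {
      stop("non-ACGT characters in nucleotide record(s): ",
           paste(utils::head(names(seqs)[bad], 5L), collapse = ", "))
    }
  } else {
    pat <- paste0("[^", paste(.aa_alphabet(), collapse = ""), "]")
    bad <- grepl(pat, seqs)
    if (any(bad)) {
      if (coerce) {
        warning("non-canonical residues coerced to 'X' in ",
                sum(bad), " record(s)")
        seqs[bad] <- gsub(pat, "X", seqs[bad])
      } else {
        stop("non-canonical residues in record(s): ",
             paste(utils::head(names(seqs)[bad], 5L), collapse = ", "))
      }
    }
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Translate coding sequences under the standard genetic code
#'
#' A single terminal stop codon, if present, is dropped.  Internal stop
#' codons are an error identifying the offending codon index.
#'
#' @param cds Named character vector of coding sequences (DNA; U
#'   accepted).
#' @return Named character vector of protein sequences.
#' @export
#' @examples
#' translate_cds(c(x = "ATGGCCTAA"))
translate_cds <- function(cds) {
  cds <- normalize_nt(cds)
  gc <- .genetic_code()
  ids <- names(cds) %||% as.character(seq_along(cds))
  ids[is.na(ids) | ids == ""] <- as.character(which(is.na(ids) | ids == ""))
  out <- vapply(seq_along(cds), function(i) {
    s <- cds[[i]]
    if (nchar(s) %% 3L != 0L) {
      stop("CDS length not divisible by 3 for record ", ids[i])
    }
    aa <- unname(gc[codon_split(s)])
    if (anyNA(aa)) stop("invalid codon in record ", ids[i])
    n <- length(aa)
    stops <- which(aa == "*")
    if (length(stops) && any(stops < n)) {
      stop("internal stop codon at codon index ", stops[stops < n][1],
           " in record ", ids[i])
    }
    if (length(stops)) aa <- aa[-n]
    paste(aa, collapse = "")
  }, character(1))
  names(out) <- names(cds)
  out
}

#' Validate coding records against linked proteins
#'
#' Checks length divisibility, absence of internal stops, and (when
#' `proteins` is given) that the translation minus terminal stop equals
#' the linked protein sequence of the same ID.
#'
#' @param cds Named character vector of coding sequences.
#' @param proteins Optional named character vector of protein sequences.
#' @return `TRUE`, invisibly; errors otherwise.
#' @export
validate_cds <- function(cds, proteins = NULL) {
  tr <- translate_cds(cds)
  if (!is.null(proteins)) {
    common <- intersect(names(cds), names(proteins))
    mism <- common[tr[common] != proteins[common]]
    if (length(mism)) {
      stop("CDS translation does not match linked protein for: ",
           paste(utils::head(mism, 5L), collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Read a codon usage table
#'
#' Two-column TSV (codon, frequency), '#' comment lines allowed.  Codons
#' may be in RNA or DNA notation.  Frequencies can be fractions or
#' per-thousand values; all downstream uses are scale-invariant.
#'
#' @param path Path to the TSV file.
#' @return Named numeric vector over the 61 sense codons.
#' @export
read_codon_usage <- function(path) {
  df <- read.delim(path, comment.char = "#", header = TRUE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("codon usage table needs two columns")
  usage <- setNames(as.numeric(df[[2]]), normalize_nt(df[[1]]))
  gc <- .genetic_code()
  sense <- names(gc)[gc != "*"]
  missing <- setdiff(sense, names(usage))
  if (length(missing)) {
    stop("codon usage table misses sense codons: ",
         paste(missing, collapse = ", "))
  }
  usage <- usage[sense]
  if (any(usage < 0) || anyNA(usage)) stop("codon usage must be >= 0")
  fam <- split(usage, gc[sense])
  dead <- names(fam)[vapply(fam, function(v) all(v == 0), logical(1))]
  if (length(dead)) {
    stop("synonymous family with all-zero usage: ",
         paste(dead, collapse = ", "))
  }
  usage
}

#' Bundled human codon usage (per-thousand)
#'
#' The widely reprinted *H. sapiens* codon usage table (GenBank-derived,
#' per 1000 codons).  Used as the default reference for CAI and for
#' deriving the genome-expected ADAT fraction among TAPSLIVR codons.
#'
#' @return Named numeric vector over the 61 sense codons.
#' @export
human_codon_usage <- function() {
  read_codon_usage(system.file("extdata", "human_codon_usage.tsv",
                               package = "adatscan", mustWork = TRUE))
}

#' Read BLAST tabular hits (outfmt 6)
#'
#' Standard 12-column tabular output, optionally with `qlen` as a 13th
#' column; otherwise query lengths must be supplied.  The overlap
#' fraction is aligned query span / query length.  The species of each
#' subject is extracted from the subject ID with `species_from`.
#'
#' @param path Path to the tabular file ('#' comments allowed).
#' @param query_lengths Optional named numeric vector of query lengths.
#' @param species_from Function mapping subject IDs to species IDs
#'   (default: first 5 characters, the OMA convention).
#' @return Data frame with columns `query_id`, `subject_id`,
#'   `species_id`, `evalue`, `overlap_fraction`.
#' @export
read_blast_hits <- function(path, query_lengths = NULL,
                            species_from = function(x) substr(x, 1L, 5L)) {
  df <- read.delim(path, comment.char = "#", header = FALSE,
                   stringsAsFactors = FALSE)
  if (!ncol(df) %in% c(12L, 13L)) {
    stop("expected 12 or 13 tab-separated columns (BLAST outfmt 6)")
  }
  qlen <- if (ncol(df) == 13L) as.numeric(df[[13]]) else {
    if (is.null(query_lengths)) {
      stop("no qlen column: supply query_lengths")
    }
    unknown <- setdiff(unique(df[[1]]), names(query_lengths))
    if (length(unknown)) {
      stop("query_lengths misses: ", paste(unknown, collapse = ", "))
    }
    query_lengths[df[[1]]]
  }
  data.frame(
    query_id = df[[1]],
    subject_id = df[[2]],
    species_id = species_from(df[[2]]),
    evalue = as.numeric(df[[11]]),
    overlap_fraction = (abs(as.numeric(df[[8]]) - as.numeric(df[[7]])) + 1) /
      qlen,
    stringsAsFactors = FALSE
  )
}

#' Read a species metadata table
#'
#' TSV with columns `species_id`, `domain`, `phylum`,
#' `multicellularity`, `n_A34_genes`, `a34_diversity`.
#'
#' @param path Path to the TSV file.
#' @return Data frame.
#' @export
read_species_meta <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("species_id", "domain", "phylum", "multicellularity",
           "n_A34_genes", "a34_diversity")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("species meta misses columns: ",
                         paste(miss, collapse = ", "))
  validate_species_meta(df)
  df
}

validate_species_meta <- function(meta) {
  ok_dom <- meta$domain %in% c("Archaea", "Bacteria", "Eukarya")
  if (!all(ok_dom)) stop("unknown domain values in species meta")
  if (any(meta$a34_diversity > 8, na.rm = TRUE)) {
    stop("a34_diversity cannot exceed 8")
  }
  bad <- !is.na(meta$a34_diversity) & meta$a34_diversity == 0 &
    !is.na(meta$n_A34_genes) & meta$n_A34_genes > 0
  if (any(bad)) stop("a34_diversity 0 implies n_A34_genes 0")
  invisible(TRUE)
}

#' Read a gene translation-efficiency table
#'
#' TSV with columns `gene_id`, `fc_hp_total_ctrl`, `fc_hp_total_kd`,
#' `interaction_fc`, `p`, `encodes_lcr` (fold-changes on the linear
#' scale; the interaction fold-change is KD-vs-CTRL of HP/Total).
#'
#' @param path Path to the TSV file.
#' @return Data frame.
#' @export
read_te_table <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("gene_id", "fc_hp_total_ctrl", "fc_hp_total_kd",
           "interaction_fc", "p", "encodes_lcr")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("TE table misses columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$interaction_fc <= 0) || any(df$p < 0 | df$p > 1)) {
    stop("fold-changes must be positive and p-values in [0, 1]")
  }
  df$encodes_lcr <- as.logical(df$encodes_lcr)
  df
}

#' Write a TSV with '#'-prefixed provenance comments
#'
#' @param df Data frame.
#' @param path Output path.
#' @param comments Character vector of comment lines (without '#').
#' @return `path`, invisibly.
#' @export
write_tsv_commented <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
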