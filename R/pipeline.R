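# Orchestration: a validated run configuration, stage chaining over
# files, and a reproducibility manifest.

#' Default pipeline configuration
#'
#' All stage parameters at their standard values: window 30,
#' minimum window fraction 0.80, enrichment threshold 65.743%, e-value
#' cut-off 0.01, overlap threshold 0.20, 10000-hit cap, B = 5000 for
#' the ratio permutation and B = 10000 for the proportion permutation.
#'
#' @return Nested named list (class `run_config`).
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    scan = list(window = 30L, min_fraction = 0.80, step = 1L),
    enrichment = list(threshold = ADAT_THRESHOLD_DEFAULT),
    filter = list(evalue_max = 0.01, overlap_min = 0.20,
                  max_hits_per_query = 10000L),
    permutation = list(B_ratio = 5000L, B_proportion = 10000L),
    te = list(fc_cut = 1.5, p_cut = 0.05, n_set = 31L),
    inputs = list(proteins_fasta = NULL, cds_fasta = NULL,
                  hits_tsv = NULL, meta_tsv = NULL, te_tsv = NULL)
  ), class = "run_config")
}

# deep-validate a config against the default skeleton; unknown keys and
# degenerate values are rejected before any stage runs
validate_config <- function(config) {
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  merged <- utils::modifyList(unclass(def), config, keep.null = TRUE)
  for (sec in setdiff(names(def), c("seed", "inputs"))) {
    bad <- setdiff(names(merged[[sec]]), names(def[[sec]]))
    if (length(bad)) stop("unknown config keys in '", sec, "': ",
                          paste(bad, collapse = ", "))
  }
  scan_params(merged$scan$window, merged$scan$min_fraction,
              merged$scan$step)  # validates
  with(merged$filter, {
    if (evalue_max <= 0 || overlap_min < 0 || overlap_min > 1 ||
        max_hits_per_query < 1) {
      stop("invalid filter settings")
    }
  })
  if (merged$permutation$B_ratio < 1 || merged$permutation$B_proportion < 1) {
    stop("permutation B must be >= 1")
  }
  if (merged$enrichment$threshold < 0 || merged$enrichment$threshold > 100) {
    stop("enrichment threshold must be a percent in [0, 100]")
  }
  structure(merged, class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' CLI flags or caller overrides can be layered on top; unknown keys
#' are rejected.
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @param overrides Named list merged over the file contents.
#' @return Validated configuration (class `run_config`).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- utils::modifyList(cfg, overrides, keep.null = TRUE)
  validate_config(cfg)
}

#' Run the analysis pipeline
#'
#' Runs the stages for which inputs are configured (or, when no inputs
#' are given, over a small seeded synthetic data set) in dependency
#' order, writing each stage's TSV and a manifest recording package
#' version, parameters, seed and input/output checksums.  Reruns with
#' the same configuration are bit-identical for the deterministic
#' stages and give identical permutation p-values under the same seed.
#'
#' @param config A `run_config`, a nested list, or a YAML path.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage results and the manifest
#'   path.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- load_config(config)
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- config$inputs
  for (f in unlist(inp)) {
    if (!is.null(f) && !file.exists(f)) {
      stop("missing input before any stage runs: ", f)
    }
  }
  params <- scan_params(config$scan$window, config$scan$min_fraction,
                        config$scan$step)
  results <- list()
  comments <- function(extra = character(0)) {
    c(paste0("adatscan ", as.character(packageVersion("adatscan"))),
      paste0("seed=", config$seed), extra)
  }

  synthetic <- is.null(inp$proteins_fasta)
  proteins <- if (synthetic) {
    gen_proteome(n_proteins = 12L, seed = config$seed)$proteins
  } else {
    read_fasta(inp$proteins_fasta, type = "protein")
  }

  scan <- scan_proteome(proteins, params)
  write_tsv_commented(scan$regions, file.path(out_dir, "regions.tsv"),
                      comments(sprintf("window=%d min_fraction=%g step=%d",
                                       params$window, params$min_fraction,
                                       params$step)))
  results$scan <- scan

  cds <- if (!is.null(inp$cds_fasta)) {
    read_fasta(inp$cds_fasta, type = "dna")
  } else if (synthetic) {
    vapply(names(proteins), function(id) {
      gen_cds(proteins[[id]], seed = config$seed +
                match(id, names(proteins)))[[1]]
    }, character(1))
  }
  if (!is.null(cds)) {
    validate_cds(cds, proteins)
    reg <- scan$regions[scan$regions$protein_id %in% names(cds), ,
                        drop = FALSE]
    enr <- do.call(rbind, lapply(seq_len(nrow(reg)), function(i) {
      e <- adat_enrichment(cds[[reg$protein_id[i]]],
                           region = c(reg$start0[i], reg$end0[i]),
                           threshold = config$enrichment$threshold)
      data.frame(protein_id = reg$protein_id[i], start0 = reg$start0[i],
                 end0 = reg$end0[i], n_tapslivr = e$n_tapslivr,
                 n_adat = e$n_adat, adat_percent = e$adat_percent,
                 enriched = e$enriched, stringsAsFactors = FALSE)
    }))
    if (is.null(enr)) {
      enr <- data.frame(protein_id = character(0), start0 = integer(0),
                        end0 = integer(0), n_tapslivr = integer(0),
                        n_adat = integer(0), adat_percent = numeric(0),
                        enriched = logical(0))
    }
    write_tsv_commented(enr, file.path(out_dir, "enrichment.tsv"),
                        comments(sprintf("threshold=%g",
                                         config$enrichment$threshold)))
    results$enrichment <- enr
  }

  homolog <- if (!is.null(inp$hits_tsv)) {
    list(hits = read_blast_hits(inp$hits_tsv),
         meta = read_species_meta(inp$meta_tsv),
         query_set = NULL)
  } else if (synthetic) {
    g <- gen_homolog_data(seed = config$seed)
    list(hits = g$hits, meta = g$meta, query_set = g$query_set)
  }
  if (!is.null(homolog)) {
    fh <- filter_hits(homolog$hits, config$filter$evalue_max,
                      config$filter$overlap_min,
                      config$filter$max_hits_per_query)
    mat <- species_hit_matrix(fh, homolog$meta)
    qs <- homolog$query_set %||% rownames(mat)
    perm <- permutation_ratio_test(
      mat, homolog$meta, qs, group_a = c("Archaea", "Bacteria"),
      group_b = "Eukarya", B = config$permutation$B_ratio,
      seed = config$seed, alternative = "less")
    stats <- data.frame(
      statistic = c("avg_ratio_prok_euk", "null_mean", "null_sd", "z",
                    "p_normal", "p_empirical"),
      value = c(perm$observed, perm$null_mean, perm$null_sd, perm$z,
                perm$p, perm$p_empirical))
    write_tsv_commented(stats, file.path(out_dir, "homolog_stats.tsv"),
                        comments(sprintf("B=%d", config$permutation$B_ratio)))
    results$homolog <- perm
  }

  te <- if (!is.null(inp$te_tsv)) {
    read_te_table(inp$te_tsv)
  } else if (synthetic) {
    gen_te_table(n_genes = 400L, n_planted = config$te$n_set,
                 delta = 1, seed = config$seed)$table
  }
  if (!is.null(te)) {
    sets <- classify_te(te, config$te$fc_cut, config$te$p_cut)
    fish <- fisher_enrichment(sets$impaired,
                              te$gene_id[te$encodes_lcr], te$gene_id)
    obs_set <- utils::head(sets$highly_translated, config$te$n_set)
    perm_p <- permutation_proportion_test(
      te$gene_id, te$gene_id[te$encodes_lcr], n = config$te$n_set,
      set = if (length(obs_set)) obs_set else NULL,
      observed = if (length(obs_set)) NULL else 0,
      B = config$permutation$B_proportion, seed = config$seed)
    te_stats <- data.frame(
      statistic = c("n_impaired", "n_highly_translated", "fisher_or",
                    "fisher_p", "perm_observed", "perm_p"),
      value = c(length(sets$impaired), length(sets$highly_translated),
                fish$odds_ratio, fish$p, perm_p$observed, perm_p$p))
    write_tsv_commented(te_stats, file.path(out_dir, "te_stats.tsv"),
                        comments(sprintf("n=%d B=%d", config$te$n_set,
                                         config$permutation$B_proportion)))
    results$te <- list(sets = sets, fisher = fish, permutation = perm_p)
  }

  outputs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package = "adatscan",
    version = as.character(packageVersion("adatscan")),
    seed = config$seed,
    parameters = unclass(config)[c("scan", "enrichment", "filter",
                                   "permutation", "te")],
    inputs = lapply(Filter(Negate(is.null), inp), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }),
    outputs = lapply(setNames(outputs, basename(outputs)), function(f) {
      unname(tools::md5sum(f))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  results$manifest <- manifest_path
  invisible(results)
}
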