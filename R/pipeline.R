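## End-to-end pipeline: configuration with the analysis thresholds, staged
## execution on an on-disk study, and a checksummed, reproducible results
## directory.

#' Pipeline configuration
#'
#' Collects every analysis threshold with its default: interaction
#' significance 12 with rescue band from 11, TAD delta-Z 2.0, compartment
#' cutoff +/-10, differential expression at |log2FC| > 1.5 and padj < 0.05,
#' 100 enrichment permutations and 1000 containment permutations. The
#' configuration round-trips losslessly through JSON.
#'
#' @param input_dir directory holding a study written by [write_study()].
#' @param outdir results directory.
#' @param cell_types the two cell-type labels.
#' @param significance_threshold,rescue_low merged-score thresholds.
#' @param tad_delta_z_min minimum TAD delta-Z.
#' @param no_bias_eps directionality-bias epsilon for TAD end extension.
#' @param compartment_threshold A/B cutoff on compartment values.
#' @param de_log2fc_min,de_padj_max differential-expression thresholds.
#' @param n_perm_enrichment,n_perm_containment permutation counts.
#' @param bin_bp,compartment_bin_bp matrix resolutions (bp).
#' @param seed integer seed for all randomised stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, outdir = NULL,
                            cell_types = c("ESC", "NEC"),
                            significance_threshold = 12,
                            rescue_low = 11,
                            tad_delta_z_min = 2.0,
                            no_bias_eps = 0.25,
                            compartment_threshold = 10,
                            de_log2fc_min = 1.5,
                            de_padj_max = 0.05,
                            n_perm_enrichment = 100L,
                            n_perm_containment = 1000L,
                            bin_bp = 25000,
                            compartment_bin_bp = 250000,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Serialise / restore a pipeline configuration
#' @param config a [pipeline_config()].
#' @param path JSON path.
#' @return `read_pipeline_config()` returns the restored config.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(pipeline_config, x[setdiff(names(x), c())])
  cfg
}

#' Run the full analysis pipeline on an on-disk study
#'
#' Executes the stages in dependency order -- interaction calling,
#' fragment-state assignment, PIR feature enrichment, TAD and compartment
#' calling, CRU construction and containment, and interaction dynamics --
#' and writes tables, JSON summaries, a run log and an md5 checksum
#' manifest to `config$outdir`. Reruns with the same configuration and seed
#' are byte-identical.
#'
#' @param config a [pipeline_config()] with `input_dir` and `outdir` set.
#' @return (invisibly) a list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$input_dir) || is.null(config$outdir)) {
    stopf("config must set input_dir and outdir")
  }
  t0 <- Sys.time()
  need <- c("fragments.bed", "scores.tsv", "expression.tsv",
            paste0("segmentation_", config$cell_types, ".bed"))
  for (f in need) {
    if (!file.exists(file.path(config$input_dir, f))) {
      stopf("missing input: %s", file.path(config$input_dir, f))
    }
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$outdir, ...)
  log_lines <- c(sprintf("regwire %s", as.character(utils::packageVersion("regwire"))),
                 sprintf("seed: %d", config$seed))
  stage <- function(name) {
    log_lines <<- c(log_lines, sprintf("stage: %s", name))
  }
  ct <- config$cell_types

  ## ---- load inputs ---------------------------------------------------
  stage("load")
  fmb <- read_bed(file.path(config$input_dir, "fragments.bed"))
  fm <- fmb[, .(fragment_id, chrom, start, end, bait, gene_id, protein_coding)]
  data.table::setcolorder(fm, c("fragment_id", "chrom", "start", "end"))
  segs <- lapply(ct, function(cc) {
    read_bed(file.path(config$input_dir, sprintf("segmentation_%s.bed", cc)))
  })
  names(segs) <- ct
  expression <- data.table::fread(file.path(config$input_dir, "expression.tsv"))

  ## ---- interaction calls ---------------------------------------------
  stage("calls")
  calls <- load_scores(file.path(config$input_dir, "scores.tsv"), fm, ct)
  calls <- call_significant(calls, config$significance_threshold,
                            config$rescue_low, ct)
  for (cc in ct) {
    write_washu(calls, fm, cc, p(sprintf("interactions_%s.washu.txt", cc)))
    data.table::fwrite(pirs_per_promoter(calls, cc),
                       p(sprintf("pirs_per_promoter_%s.tsv", cc)), sep = "\t")
  }

  ## ---- chromatin states ----------------------------------------------
  stage("states")
  states <- lapply(ct, function(cc) {
    suppressWarnings(fragment_states(fm, segs[[cc]], cc))
  })
  names(states) <- ct
  for (cc in ct) {
    data.table::fwrite(states[[cc]], p(sprintf("fragment_states_%s.tsv", cc)),
                       sep = "\t")
  }

  ## ---- enrichment -----------------------------------------------------
  stage("enrichment")
  enrich <- list()
  for (i in 1:2) {
    cc <- ct[i]
    peaks_file <- file.path(config$input_dir, sprintf("peaks_%s.bed", cc))
    if (!file.exists(peaks_file)) next
    ctrl <- sample_distance_matched_controls(
      calls, fm, cc, n_perm = config$n_perm_enrichment,
      seed = sub_seed(config$seed, 20L + i))
    fe <- feature_enrichment(ctrl$pirs, ctrl, read_bed(peaks_file), fm)
    enrich[[cc]] <- list(observed = fe$observed,
                         permuted_mean = fe$permuted_mean,
                         z_score = fe$z_score, empirical_p = fe$empirical_p)
  }
  if (length(enrich)) {
    jsonlite::write_json(enrich, p("enrichment.json"), auto_unbox = TRUE,
                         digits = NA)
  }

  ## ---- topology --------------------------------------------------------
  stage("topology")
  tad_tables <- list()
  mat_files <- list.files(config$input_dir, "^contacts_.*\\.tsv$")
  for (f in mat_files) {
    parts <- sub("^contacts_(.*)\\.tsv$", "\\1", f)
    cc <- sub("_chr.*$", "", parts)
    chr <- sub("^.*_(chr.*)$", "\\1", parts)
    mat <- read_dense_matrix(file.path(config$input_dir, f))
    di <- smooth_and_standardize(directionality_index(mat, config$bin_bp))
    tads <- call_tads(di, config$tad_delta_z_min, config$no_bias_eps)
    if (nrow(tads)) {
      tads <- data.table::data.table(chrom = chr, cell_type = cc, tads)
      tad_tables[[f]] <- tads
    }
  }
  if (length(tad_tables)) {
    data.table::fwrite(data.table::rbindlist(tad_tables), p("tads.tsv"),
                       sep = "\t")
  }

  ## ---- CRUs ------------------------------------------------------------
  stage("cru")
  crus <- lapply(ct, function(cc) build_crus(calls, fm, states[[cc]], cc))
  names(crus) <- ct
  for (cc in ct) {
    out <- data.table::copy(crus[[cc]])[, pir_ids := NULL]
    data.table::fwrite(out, p(sprintf("crus_%s.tsv", cc)), sep = "\t")
  }
  trans <- transition_matrix(crus[[1]], crus[[2]], expression,
                             config$de_log2fc_min, config$de_padj_max)
  data.table::fwrite(trans$transitions, p("cru_transitions.tsv"), sep = "\t")

  ## ---- dynamics --------------------------------------------------------
  stage("dynamics")
  dyn <- filter_rewired_retained(calls, config$significance_threshold, ct,
                                 states_a = states[[1]], states_b = states[[2]])
  dyn <- classify_recolouring(dyn, states[[1]], states[[2]], ct)
  keep_cols <- intersect(
    c("bait_id", "other_end_id", "rewiring", "recoloured",
      paste0("state_", ct), paste0("quintile_", ct)), names(dyn))
  data.table::fwrite(dyn[rewiring != "unclassified", ..keep_cols],
                     p("dynamics.tsv"), sep = "\t")
  assoc <- rewiring_recolouring_association(dyn, ct)
  expr <- expression_association(dyn, expression, fm, ct)
  jsonlite::write_json(list(
    n_retained = sum(dyn$rewiring == "retained"),
    n_rewired = sum(grepl("^rewired", dyn$rewiring)),
    retained_recoloured_fraction = retained_recoloured_fraction(dyn),
    rewiring_recolouring_fisher_p = assoc$fisher_p,
    cru_transition_fisher_p = trans$fisher_p,
    expression_recolouring_p = expr$recolouring$p,
    expression_rewiring_p = expr$rewiring$p
  ), p("dynamics_summary.json"), auto_unbox = TRUE, digits = NA)

  ## ---- log + checksums -------------------------------------------------
  log_lines <- c(log_lines, sprintf("elapsed_stages: %d", length(log_lines) - 2L))
  writeLines(log_lines, p("run_log.txt"))
  outs <- setdiff(list.files(config$outdir), "checksums.txt")
  sums <- tools::md5sum(file.path(config$outdir, sort(outs)))
  writeLines(sprintf("%s  %s", unname(sums), sort(outs)), p("checksums.txt"))
  invisible(list(calls = calls, states = states, crus = crus, dynamics = dyn,
                 transitions = trans, association = assoc, expression = expr,
                 elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))))
}
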