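#' Declarative configuration for an end-to-end synthetic run
#'
#' Collects every stage parameter in one serialisable list: simulator
#' configurations, calling thresholds, expression and TE analysis options.
#' The configuration (and hence any run) is a pure function of its fields;
#' `seed` seeds every stage. Individual fields can be overridden through
#' `...` using the same names, or loaded from a YAML file with
#' [load_pipeline_config()].
#'
#' @param seed Master integer seed.
#' @param stages Stages to execute, in dependency order, a subset of
#'   `c("trac", "expression", "te")`.
#' @param trac_sim,expr_sim,te_sim Simulator configs (see
#'   [trac_sim_config()], [expr_sim_config()], [te_sim_config()]); their
#'   seeds are overridden by `seed`.
#' @param min_depth,epsilon,literal_score Calling parameters (see
#'   [cleavage_ratio()], [cleavage_score()]).
#' @param window,min_score,min_ratio Site-calling window and thresholds.
#' @param motif_flank Flank for [site_motif()].
#' @param kd_methylation_factor Factor applied to the treated-arm cleavage
#'   probability when simulating the knockdown condition's TRAC libraries.
#' @param expressed_threshold,filter_expressed Expression-stage options.
#' @param min_input_fpkm,te_threshold,te_quantile TE-stage options.
#' @param ... Reserved.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            stages = c("trac", "expression", "te"),
                            trac_sim = trac_sim_config(seed = seed),
                            expr_sim = expr_sim_config(seed = seed),
                            te_sim = te_sim_config(seed = seed),
                            min_depth = 20, epsilon = 1e-4,
                            literal_score = FALSE,
                            window = 46:48, min_score = 4, min_ratio = 0.1,
                            motif_flank = 5,
                            kd_methylation_factor = 0.5,
                            expressed_threshold = 10000,
                            filter_expressed = TRUE,
                            min_input_fpkm = 1,
                            te_threshold = log2(1.5),
                            te_quantile = 0.25, ...) {
  stages <- match.arg(stages, c("trac", "expression", "te"),
                      several.ok = TRUE)
  if (any(c("expression", "te") %in% stages) && !"trac" %in% stages) {
    stop("plan error: stages 'expression' and 'te' depend on 'trac'",
         call. = FALSE)
  }
  trac_sim$seed <- expr_sim$seed <- te_sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), stages = stages,
                 trac_sim = trac_sim, expr_sim = expr_sim, te_sim = te_sim,
                 min_depth = min_depth, epsilon = epsilon,
                 literal_score = literal_score, window = window,
                 min_score = min_score, min_ratio = min_ratio,
                 motif_flank = motif_flank,
                 kd_methylation_factor = kd_methylation_factor,
                 expressed_threshold = expressed_threshold,
                 filter_expressed = filter_expressed,
                 min_input_fpkm = min_input_fpkm,
                 te_threshold = te_threshold,
                 te_quantile = te_quantile),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields in the file override [pipeline_config()] defaults;
#' `trac_sim`/`expr_sim`/`te_sim` blocks override the corresponding
#' simulator defaults field by field.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sims <- list(trac_sim = trac_sim_config, expr_sim = expr_sim_config,
               te_sim = te_sim_config)
  args <- raw[setdiff(names(raw), names(sims))]
  for (s in names(sims)) {
    sim_args <- raw[[s]] %||% list()
    if (!is.null(raw$seed)) sim_args$seed <- raw$seed
    args[[s]] <- do.call(sims[[s]], sim_args)
  }
  do.call(pipeline_config, args)
}

#' Run the full synthetic TRAC-seq / translation pipeline
#'
#' Executes the enabled stages in dependency order: (1) simulate the mature
#' reference and paired TRAC libraries for a control and a knockdown
#' condition, compute pileups, cleavage ratios, cleavage scores, call m7G
#' sites, summarise methylation levels and the paired condition test, and
#' build the site motif; (2) simulate expression libraries and compute
#' RPKM and per-class fold changes; (3) derive the m7G codon set from the
#' calls, simulate the polysome/input experiment with that set implanted,
#' and compute TE, translation ratios, the codon-frequency correlation,
#' quantile-group and TE-class comparisons. Re-running an unchanged config
#' reproduces identical results; [write_run_outputs()] serialises them
#' with the config hash.
#'
#' @param config A [pipeline_config()].
#' @return A `tracseq_run` list with per-stage results and a `report`
#'   summary (see [run_report()]).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  run <- list(config = config, config_hash = rlang::hash(config))

  sim <- simulate_trna_reference(config$trac_sim)
  run$reference <- sim$reference
  run$truth_trnas <- sim$truth

  if ("trac" %in% config$stages) {
    run$trac <- run_trac_stage(sim, config)
  }
  if ("expression" %in% config$stages) {
    run$expression <- run_expression_stage(sim, run$trac$m7g_trnas, config)
  }
  if ("te" %in% config$stages) {
    codon_set <- build_m7g_codon_set(run$trac$calls, sim$reference)
    codon_set$codon_set <- setdiff(codon_set$codon_set,
                                   c("TAA", "TAG", "TGA"))
    run$te <- run_te_stage(codon_set, config)
  }
  run$report <- run_report(run)
  structure(run, class = "tracseq_run")
}

run_trac_stage <- function(sim, config) {
  score_tracks <- list()
  for (cond in c("control", "knockdown")) {
    p_site <- if (cond == "knockdown") {
      config$trac_sim$p_cleave_treated * config$kd_methylation_factor
    } else NULL
    off <- if (cond == "knockdown") 1L else 0L
    arms <- lapply(c(treated = "treated", non_treated = "non_treated"),
                   function(arm) {
                     aln <- simulate_trac_library(
                       sim$reference, sim$truth, config$trac_sim, arm,
                       p_site = if (arm == "treated") p_site else NULL,
                       seed_offset = off)
                     cleavage_ratio(compute_pileup(aln, sim$reference),
                                    min_depth = config$min_depth)
                   })
    score_tracks[[cond]] <- cleavage_score(arms$treated, arms$non_treated,
                                           epsilon = config$epsilon,
                                           literal = config$literal_score)
  }
  calls <- call_m7g_sites(score_tracks$control, window = config$window,
                          min_score = config$min_score,
                          min_ratio = config$min_ratio)
  levels <- lapply(names(score_tracks), function(cond) {
    methylation_levels(score_tracks[[cond]], window = config$window,
                       condition = cond)
  })
  names(levels) <- names(score_tracks)
  ids <- m7g_trnas(calls)
  methyl_test <- if (length(ids) >= 5) {
    compare_methylation_paired(
      levels$control[levels$control$trna_id %in% ids, ],
      levels$knockdown[levels$knockdown$trna_id %in% ids, ])
  } else NULL
  motif <- if (length(ids) > 0) {
    site_motif(calls, sim$reference, flank = config$motif_flank)
  } else NULL
  list(score_tracks = score_tracks, calls = calls, m7g_trnas = ids,
       methylation_levels = dplyr::bind_rows(levels),
       methylation_test = methyl_test, motif = motif)
}

run_expression_stage <- function(sim, m7g_ids, config) {
  expr <- simulate_expression_counts(sim$reference, sim$truth,
                                     config$expr_sim)
  ctrl <- rpkm(expr$control, total_reads = expr$totals[["control"]],
               expressed_threshold = config$expressed_threshold)
  kd <- rpkm(expr$knockdown, total_reads = expr$totals[["knockdown"]],
             expressed_threshold = config$expressed_threshold)
  fc <- expression_fold_change(kd, ctrl, m7g_trnas = m7g_ids,
                               filter_expressed = config$filter_expressed)
  class_medians <- fc |>
    dplyr::filter(!is.na(.data$fold_change)) |>
    dplyr::group_by(.data$m7g_class) |>
    dplyr::summarise(median_fc = stats::median(.data$fold_change),
                     n = dplyr::n(), .groups = "drop")
  list(control = ctrl, knockdown = kd, fold_changes = fc,
       class_medians = class_medians)
}

run_te_stage <- function(codon_set, config) {
  if (length(codon_set$codon_set) == 0L) {
    return(list(skipped = "empty m7G codon set: no passing calls upstream"))
  }
  te_cfg <- config$te_sim
  te_cfg$m7g_codons <- codon_set$codon_set
  exp <- simulate_te_experiment(te_cfg)
  cts <- exp$counts
  fpkms <- lapply(c(input_ctrl = "input_ctrl", poly_ctrl = "poly_ctrl",
                    input_kd = "input_kd", poly_kd = "poly_kd"),
                  function(lib) fpkm(cts[[lib]], cts$length_nt))
  te_ctrl <- translation_efficiency(fpkms$poly_ctrl, fpkms$input_ctrl,
                                    min_input_fpkm = config$min_input_fpkm)
  te_kd <- translation_efficiency(fpkms$poly_kd, fpkms$input_kd,
                                  min_input_fpkm = config$min_input_fpkm)
  tr <- translation_ratio(te_kd, te_ctrl)
  profiles <- m7g_codon_frequency(exp$cds$cds, codon_set$codon_set,
                                  gene_id = exp$cds$gene_id)
  gene_table <- tibble::tibble(
    gene_id = cts$gene_id,
    input_fpkm_ctrl = fpkms$input_ctrl, poly_fpkm_ctrl = fpkms$poly_ctrl,
    input_fpkm_kd = fpkms$input_kd, poly_fpkm_kd = fpkms$poly_kd,
    te_ctrl = te_ctrl, te_kd = te_kd,
    translation_ratio = tr$ratio, log2_translation_ratio = tr$log2_ratio,
    f = profiles$f[match(cts$gene_id, profiles$gene_id)],
    te_class = classify_te_genes(tr$log2_ratio,
                                 threshold = config$te_threshold))
  analysed <- gene_table[!is.na(gene_table$log2_translation_ratio), ]
  corr <- correlate_freq_te(
    profiles, tibble::tibble(gene_id = analysed$gene_id,
                             value = analysed$log2_translation_ratio))
  groups <- split_by_codon_frequency(
    analysed[, c("gene_id", "f")], q = config$te_quantile)
  lr <- stats::setNames(analysed$log2_translation_ratio, analysed$gene_id)
  group_test <- compare_groups(lr[groups$low], lr[groups$high],
                               labels = c("low_f", "high_f"))
  f_by_class <- split(analysed$f, analysed$te_class)
  class_test <- compare_groups(f_by_class$decreased,
                               c(f_by_class$increased, f_by_class$other),
                               labels = c("decreased", "rest"))
  codon_profile <- te_class_codon_profile(profiles, gene_table$te_class,
                                          codon_set$codon_set)
  list(experiment = exp, gene_table = gene_table, profiles = profiles,
       correlation = corr, groups = groups, group_test = group_test,
       class_mean_f = vapply(f_by_class, mean, numeric(1)),
       class_sizes = vapply(f_by_class, length, integer(1)),
       class_test = class_test, codon_profile = codon_profile,
       codon_set = codon_set)
}

#' Machine-readable summary of a pipeline run
#'
#' @param run A `tracseq_run` (or the partial list built inside
#'   [run_pipeline()]). Skipped stages are marked explicitly.
#' @return A list of headline statistics.
#' @export
run_report <- function(run) {
  rep <- list(config_hash = run$config_hash, seed = run$config$seed)
  rep$n_trnas <- nrow(run$reference)
  if (!is.null(run$trac)) {
    rep$n_m7g_trnas_called <- length(run$trac$m7g_trnas)
    rep$n_m7g_trnas_truth <- sum(run$truth_trnas$modified)
    rep$methylation_p_value <-
      if (is.null(run$trac$methylation_test)) NA_real_ else
        run$trac$methylation_test$p_value
  } else rep$trac <- "stage skipped"
  if (!is.null(run$expression)) {
    cm <- run$expression$class_medians
    rep$median_fc <- stats::setNames(as.list(cm$median_fc), cm$m7g_class)
  } else rep$expression <- "stage skipped"
  if (!is.null(run$te)) {
    if (!is.null(run$te$skipped)) {
      rep$te <- paste("stage skipped:", run$te$skipped)
      rep$codon_set_size <- 0L
    } else {
      rep$codon_set_size <- length(run$te$codon_set$codon_set)
      rep$pearson_r <- run$te$correlation$r
      rep$pearson_p <- run$te$correlation$p_value
      rep$group_test_p <- run$te$group_test$p_value
      rep$class_sizes <- as.list(run$te$class_sizes)
      rep$class_mean_f <- as.list(run$te$class_mean_f)
      rep$class_test_p <- run$te$class_test$p_value
    }
  } else rep$te <- "stage skipped"
  rep
}

#' @export
print.tracseq_run <- function(x, ...) {
  r <- x$report
  cat("tracseq synthetic run (seed ", r$seed, ", config ",
      substr(r$config_hash, 1, 8), ")\n", sep = "")
  cat("  tRNAs simulated: ", r$n_trnas, "\n", sep = "")
  if (!is.null(r$n_m7g_trnas_called)) {
    cat("  m7G tRNAs called: ", r$n_m7g_trnas_called, " (truth: ",
        r$n_m7g_trnas_truth, ")\n", sep = "")
    cat("  paired methylation test p = ",
        format(r$methylation_p_value, digits = 3), "\n", sep = "")
  }
  if (!is.null(r$median_fc)) {
    cat("  median expression FC: modified ",
        format(r$median_fc$modified, digits = 3), ", unmodified ",
        format(r$median_fc$unmodified, digits = 3), "\n", sep = "")
  }
  if (!is.null(r$pearson_r)) {
    cat("  Pearson r(f, log2 TR) = ", format(r$pearson_r, digits = 3),
        " (p = ", format(r$pearson_p, digits = 3), ")\n", sep = "")
    cat("  low-vs-high f group test p = ",
        format(r$group_test_p, digits = 3), "\n", sep = "")
    cat("  TE classes (decreased/increased/other): ",
        paste(unlist(r$class_sizes), collapse = "/"), "\n", sep = "")
  }
  invisible(x)
}

#' Write a run's tabular outputs and report to disk
#'
#' Every TSV starts with `#`-prefixed header lines carrying the config
#' hash and seed (coordinates are 1-based inclusive throughout); the
#' report is written as JSON. Outputs are deterministic, so re-running an
#' unchanged config regenerates byte-identical files.
#'
#' @param run A `tracseq_run`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_run_outputs <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(paste0("# config_hash=", run$config_hash),
            paste0("# seed=", run$config$seed))
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    con <- file(p, "w")
    writeLines(meta, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    paths <<- c(paths, p)
  }
  if (!is.null(run$trac)) {
    emit(run$trac$score_tracks$control, "score_track_control.tsv")
    emit(run$trac$calls, "m7g_calls.tsv")
    emit(run$trac$methylation_levels, "methylation_levels.tsv")
    if (!is.null(run$trac$motif)) {
      emit(as.data.frame(run$trac$motif), "site_motif.tsv")
    }
  }
  if (!is.null(run$expression)) {
    emit(run$expression$fold_changes, "trna_fold_changes.tsv")
  }
  if (!is.null(run$te) && is.null(run$te$skipped)) {
    emit(run$te$gene_table, "gene_te_table.tsv")
    emit(run$te$codon_profile, "te_decreased_codon_profile.tsv")
  }
  p <- file.path(outdir, "report.json")
  jsonlite::write_json(run$report, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, p))
}
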