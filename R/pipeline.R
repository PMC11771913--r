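# End-to-end orchestration: simulate or ingest, preprocess, cluster, fit
# both probit models, compare by DIC, write every artifact, log every stage.

#' Configure a full analysis run
#'
#' @param input Path to a crash-table file, or a [synthetic_config()] to
#'   simulate from.
#' @param age_threshold Older-driver age cutoff (inclusive), default 65.
#' @param eps_values,min_pts_values Sensitivity-sweep grids for the
#'   clustering stage.
#' @param chosen_eps,chosen_min_pts The (radius, density) pair used for the
#'   headline hotspot map.
#' @param weights Weight rule for the probit stage:
#'   `list(rule = "knn", k = 5)` or
#'   `list(rule = "distance_band", threshold = <r>)`.
#' @param predictors Candidate predictor columns; empty for intercept-only
#'   models.
#' @param encoding Design encoding, `"ordinal"` or `"dummy"`.
#' @param r_threshold Collinearity screen cutoff, default 0.7.
#' @param mcmc An [mcmc_config()].
#' @param prune Run [stepwise_prune()] instead of a single fit.
#' @param dic_threshold DIC difference treated as decisive, default 10.
#' @param output_dir Directory for artifacts (created if missing), or
#'   `NULL` to skip writing.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input,
                            age_threshold = 65,
                            eps_values = c(100, 150, 200),
                            min_pts_values = c(5, 10, 15),
                            chosen_eps = max(eps_values),
                            chosen_min_pts = max(min_pts_values),
                            weights = list(rule = "knn", k = 5),
                            predictors = NULL,
                            encoding = "ordinal",
                            r_threshold = 0.7,
                            mcmc = mcmc_config(),
                            prune = FALSE,
                            dic_threshold = 10,
                            output_dir = NULL) {
  stopifnot(length(eps_values) >= 1, length(min_pts_values) >= 1)
  structure(list(input = input, age_threshold = age_threshold,
                 eps_values = eps_values, min_pts_values = min_pts_values,
                 chosen_eps = chosen_eps, chosen_min_pts = chosen_min_pts,
                 weights = weights, predictors = predictors,
                 encoding = encoding, r_threshold = r_threshold,
                 mcmc = mcmc, prune = prune, dic_threshold = dic_threshold,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Compare two fitted models by DIC
#'
#' @param dic_a,dic_b [compute_dic()] results; `a` is conventionally the
#'   non-spatial model and `b` the spatial one, but any pair works.
#' @param labels Length-2 model labels for the verdict.
#' @param threshold DIC difference treated as decisive (default 10).
#' @return List: `preferred` (label), `delta` (`dic_a - dic_b`),
#'   `decisive` (|delta| > threshold), `verdict` (one-line text).
#' @export
compare_models <- function(dic_a, dic_b, labels = c("probit", "spatial_probit"),
                           threshold = 10) {
  stopifnot(is.finite(dic_a$dic), is.finite(dic_b$dic))
  delta <- dic_a$dic - dic_b$dic
  preferred <- if (dic_b$dic < dic_a$dic) labels[2] else labels[1]
  decisive <- abs(delta) > threshold
  verdict <- sprintf(
    "%s preferred (DIC %.3f vs %.3f); difference %.3f is %s the decisive threshold of %g",
    preferred, dic_a$dic, dic_b$dic, abs(delta),
    if (decisive) "over" else "below", threshold)
  list(preferred = preferred, delta = delta, decisive = decisive,
       verdict = verdict)
}

log_stage <- function(lines, msg, log_con = NULL) {
  message(msg)
  if (!is.null(log_con)) writeLines(msg, log_con)
  c(lines, msg)
}

#' Run the full hotspot-and-severity analysis pipeline
#'
#' Stages: ingest or simulate -> older-driver filter -> severity
#' binarisation -> sensitivity sweep -> clustering at the chosen
#' (radius, density) -> hotspot hulls -> collinearity screen -> design
#' matrix -> weight matrix -> plain probit fit -> spatial probit fit ->
#' DIC comparison. Counts are logged at every stage; artifacts (labels,
#' GeoJSON hulls, sweep table, fit reports, comparison verdict, run log,
#' run report) are written to `config$output_dir` when set.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `run_report`: stage counts, sweep table,
#'   hotspot summary, both fits and DICs, the comparison verdict, and
#'   provenance (seed, config echo, timestamp).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  log_con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    log_con <- file(file.path(out_dir, "run.log"), "w")
    on.exit(close(log_con))
  }
  lg <- character(0)

  # -- ingest / simulate ------------------------------------------------
  truth <- NULL
  if (inherits(config$input, "synthetic_config")) {
    gen <- generate_crash_table(config$input)
    tab <- gen$table
    truth <- gen$truth
    lg <- log_stage(lg, sprintf("simulate: %d records (seed %d)",
                                nrow(tab), config$input$seed), log_con)
  } else {
    tab <- read_crash_table(config$input)
    lg <- log_stage(lg, sprintf("ingest: %d records from %s", nrow(tab),
                                config$input), log_con)
  }
  n0 <- nrow(tab)

  # -- preprocess -------------------------------------------------------
  tab <- filter_older_drivers(tab, config$age_threshold)
  n_old <- nrow(tab)
  lg <- log_stage(lg, sprintf("older-driver filter (age >= %g): %d records",
                              config$age_threshold, nrow(tab)), log_con)
  tab <- binarize_severity(tab)
  lg <- log_stage(lg, sprintf("binarize severity: %d records, %d injury/fatality",
                              nrow(tab), sum(tab$severity)), log_con)
  if (nrow(tab) == 0) stop("stage 'preprocess': no records survive the filters")

  # -- clustering -------------------------------------------------------
  sweep <- sensitivity_sweep(tab, config$eps_values, config$min_pts_values)
  lg <- log_stage(lg, sprintf("sensitivity sweep: %d (eps, minPts) cells",
                              nrow(sweep)), log_con)
  clus <- dbscan(tab, config$chosen_eps, config$chosen_min_pts)
  hulls <- cluster_hulls(tab, clus)
  lg <- log_stage(lg, sprintf(
    "clustering at (eps = %g, minPts = %d): %d cluster(s), %d noise, %d border tie(s)",
    config$chosen_eps, config$chosen_min_pts, length(clus$clusters),
    sum(clus$point_class == "noise"), clus$n_border_ties), log_con)

  # -- design -----------------------------------------------------------
  predictors <- config$predictors
  screen <- NULL
  if (length(predictors) >= 2) {
    screen <- collinearity_screen(tab, predictors, config$r_threshold)
    predictors <- screen$retained
    lg <- log_stage(lg, sprintf(
      "collinearity screen (|r| >= %g): retained %d of %d predictors",
      config$r_threshold, length(predictors), length(config$predictors)),
      log_con)
  }
  if (length(predictors) == 0) {
    warning("empty predictor list; fitting intercept-only models")
    design <- build_design(tab, character(0), config$encoding)
  } else {
    design <- build_design(tab, predictors, config$encoding)
  }
  lg <- log_stage(lg, sprintf("design matrix: %d x %d (%s encoding)",
                              design$n, ncol(design$X), design$encoding),
                  log_con)

  # -- weights ----------------------------------------------------------
  Wm <- switch(config$weights$rule,
    knn = knn_weights(design$coords, config$weights$k),
    distance_band = distance_band_weights(design$coords,
                                          config$weights$threshold),
    stop("stage 'weights': unknown rule ", config$weights$rule))
  Wm <- row_standardize(Wm)
  lg <- log_stage(lg, sprintf("weights: %s, %d isolated row(s), rho support (%.3f, %.3f)",
                              Wm$rule, length(Wm$isolated),
                              Wm$rho_support[1], Wm$rho_support[2]), log_con)

  # -- fits -------------------------------------------------------------
  if (config$prune) {
    pp <- stepwise_prune(design, NULL, config$mcmc)
    fit_p <- pp$fit
    ps <- stepwise_prune(design, Wm, config$mcmc)
    fit_s <- ps$fit
    design_p <- pp$design; design_s <- ps$design
    lg <- log_stage(lg, sprintf("stepwise pruning: removed %d (probit), %d (spatial)",
                                nrow(pp$removal_log), nrow(ps$removal_log)),
                    log_con)
  } else {
    fit_p <- fit_probit(design, config$mcmc)
    fit_s <- fit_spatial_probit(design, Wm, config$mcmc)
    design_p <- design_s <- design
  }
  lg <- log_stage(lg, sprintf("probit fit: %d retained draws", nrow(fit_p$beta_draws)),
                  log_con)
  lg <- log_stage(lg, sprintf("spatial probit fit: rho mean %.3f, acceptance %.2f",
                              mean(fit_s$rho_draws), fit_s$acceptance_rate),
                  log_con)

  dic_p <- compute_dic(fit_p, design_p)
  dic_s <- compute_dic(fit_s, design_s, Wm)
  comp <- compare_models(dic_p, dic_s, threshold = config$dic_threshold)
  lg <- log_stage(lg, comp$verdict, log_con)

  report <- structure(list(
    counts = c(input = n0, older_driver = n_old, modelled = design$n),
    sweep = sweep, clustering = clus,
    hotspots = data.frame(
      cluster_id = vapply(hulls, `[[`, integer(1), "cluster_id"),
      members = vapply(hulls, function(h) length(h$members), integer(1)),
      cores = vapply(hulls, `[[`, integer(1), "n_core"),
      area = vapply(hulls, `[[`, numeric(1), "area"),
      degenerate = vapply(hulls, `[[`, logical(1), "degenerate")),
    screen = screen, fit_probit = fit_p, fit_spatial = fit_s,
    dic_probit = dic_p, dic_spatial = dic_s, comparison = comp,
    truth = truth,
    provenance = list(seed = config$mcmc$seed,
                      timestamp = format(Sys.time(), tz = "UTC"),
                      config = config),
    log = lg), class = "run_report")

  if (!is.null(out_dir)) {
    write_cluster_labels(tab, clus, file.path(out_dir, "cluster_labels.tsv"))
    write_hulls_geojson(hulls, file.path(out_dir, "hotspots.geojson"))
    utils::write.table(sweep, file.path(out_dir, "sweep.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_fit_report(fit_p, dic_p, file.path(out_dir, "fit_probit.txt"))
    write_fit_report(fit_s, dic_s, file.path(out_dir, "fit_spatial_probit.txt"))
    write_run_report(report, file.path(out_dir, "report.txt"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run:", x$counts["input"], "records in,",
      x$counts["modelled"], "modelled;",
      nrow(x$hotspots), "hotspot(s)\n")
  cat(x$comparison$verdict, "\n")
  invisible(x)
}

#' Write the run report as structured text
#'
#' The timestamp is confined to a single header line so that report bodies
#' from identically-seeded runs are byte-identical.
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @export
write_run_report <- function(report, path) {
  s_p <- report$fit_probit$summaries
  s_s <- report$fit_spatial$summaries
  fmt_sum <- function(s) sprintf(
    "  %-28s %10.3f %10.3f %8.3f  (%8.3f, %8.3f)%s",
    s$parameter, s$mean, s$sd, s$mcse, s$bci_lower, s$bci_upper,
    ifelse(s$significant, " *", ""))
  lines <- c(
    paste0("timestamp: ", report$provenance$timestamp),
    paste0("seed: ", report$provenance$seed),
    "== stage counts ==",
    sprintf("  %s: %d", names(report$counts), report$counts),
    "== sensitivity sweep ==",
    utils::capture.output(print(report$sweep, row.names = FALSE)),
    "== hotspots ==",
    utils::capture.output(print(report$hotspots, row.names = FALSE)),
    "== Bayesian binary probit ==", fmt_sum(s_p),
    sprintf("  DIC %.3f", report$dic_probit$dic),
    "== Bayesian spatial lag binary probit ==", fmt_sum(s_s),
    sprintf("  DIC %.3f", report$dic_spatial$dic),
    "== comparison ==",
    paste0("  ", report$comparison$verdict))
  writeLines(lines, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Mirrors the arguments of [pipeline_config()]; `input` may name a crash
#' table file or a synthetic-DGP YAML (nested under `synthetic`).
#'
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  input <- if (!is.null(y$synthetic)) read_synthetic_config(y$synthetic)
           else y$input
  mc <- do.call(mcmc_config, y$mcmc %||% list())
  pipeline_config(
    input = input,
    age_threshold = y$age_threshold %||% 65,
    eps_values = unlist(y$eps_values %||% c(100, 150, 200)),
    min_pts_values = unlist(y$min_pts_values %||% c(5, 10, 15)),
    chosen_eps = y$chosen_eps %||% max(unlist(y$eps_values %||% 200)),
    chosen_min_pts = y$chosen_min_pts %||% max(unlist(y$min_pts_values %||% 15)),
    weights = y$weights %||% list(rule = "knn", k = 5),
    predictors = unlist(y$predictors),
    encoding = y$encoding %||% "ordinal",
    r_threshold = y$r_threshold %||% 0.7,
    mcmc = mc, prune = isTRUE(y$prune),
    dic_threshold = y$dic_threshold %||% 10,
    output_dir = y$output_dir)
}
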