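#' Pipeline configuration
#'
#' Describes a full SCC evaluation run: data source (CSV paths or a synthetic
#' configuration -- exactly one), effective wavelength window, preprocessing
#' (a fixed [preprocess_spec()] or `NULL` to select the winner of
#' [compare_preprocessing()]), split ratio, wavelength selection method and
#' the per-stage configurations. The master `seed` deterministically derives
#' the seeds of every stochastic stage (MCUVE draws, SVR CV folds, PSO) as
#' `seed * 1000 + stage offset`; the synthetic generator keeps its own seed
#' because it defines the dataset's identity.
#'
#' @param spectra_path,reference_path CSV paths (canonical dialects of
#'   [read_spectra()] / [read_reference()]); `NULL` when simulating.
#' @param group_map Optional replicate-to-sample map for
#'   [average_replicates()] when reading replicate rows from file.
#' @param synthetic A [synthetic_config()], or a fixture name for
#'   [make_fixture()]; `NULL` when reading files.
#' @param effective_range `c(low, high)` nm window retained before modelling.
#' @param preprocessing A [preprocess_spec()] to apply unconditionally, or
#'   `NULL` to run the preprocessing comparison and use its winner.
#' @param ratio SPXY calibration:validation parts, default `c(3, 1)`.
#' @param selection `"mcuve"` or `"spa"`.
#' @param spa SPA configuration ([spa_config()]).
#' @param mcuve MCUVE configuration ([mcuve_config()]).
#' @param pso PSO configuration ([pso_config()]).
#' @param max_factors PLSR factor cap for preprocessing comparison.
#' @param seed Master seed.
#' @param out_dir Output directory for persisted stage artifacts, or `NULL`
#'   to keep everything in memory.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(spectra_path = NULL, reference_path = NULL,
                            group_map = NULL, synthetic = NULL,
                            effective_range = c(498, 1020),
                            preprocessing = NULL, ratio = c(3, 1),
                            selection = c("mcuve", "spa"),
                            spa = spa_config(), mcuve = mcuve_config(),
                            pso = pso_config(), max_factors = 10,
                            seed = 1L, out_dir = NULL) {
  selection <- match.arg(selection)
  from_file <- !is.null(spectra_path) || !is.null(reference_path)
  if (from_file == !is.null(synthetic))
    stop_scc("provide exactly one of file paths or a synthetic source",
             class = "scc_config")
  if (from_file && (is.null(spectra_path) || is.null(reference_path)))
    stop_scc("both spectra_path and reference_path are required",
             class = "scc_config")
  if (!is.null(preprocessing) && !inherits(preprocessing, "preprocess_spec"))
    stop_scc("preprocessing must be a preprocess_spec or NULL",
             class = "scc_config")
  structure(list(spectra_path = spectra_path,
                 reference_path = reference_path, group_map = group_map,
                 synthetic = synthetic, effective_range = effective_range,
                 preprocessing = preprocessing, ratio = ratio,
                 selection = selection, spa = spa, mcuve = mcuve, pso = pso,
                 max_factors = max_factors, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full SCC evaluation pipeline
#'
#' Stage order: load or simulate spectra, trim to the effective window,
#' average replicate spectra, preprocess (fixed or comparison winner), SPXY
#' partition, select characteristic wavelengths (SPA or MCUVE), tune an
#' RBF-SVR by PSO on the selected channels, and score the final model on
#' both sets. When `cfg$out_dir` is set, every stage artifact is persisted
#' (CSV/JSON) together with a manifest of MD5 content hashes; reruns with the
#' same configuration reproduce the artifacts exactly.
#'
#' @param cfg A [pipeline_config()].
#' @return An object of class `evaluation_report`: provenance (preprocessing
#'   choice and comparison table, factor caps, selected wavelengths, C, g,
#'   PSO fitness and trajectory, all seeds), per-set statistics, split audit,
#'   and the final metrics (`r_cal`, `rmse_cal`, `r_val`, `rmse_val`, max
#'   relative error per set).
#' @examples
#' \donttest{
#' cfg <- pipeline_config(synthetic = "tiny-10x8", selection = "mcuve",
#'                        effective_range = c(500, 850),
#'                        preprocessing = preprocess_spec("none"),
#'                        mcuve = mcuve_config(n_runs = 20, max_factors = 3),
#'                        pso = pso_config(swarm_size = 4, iterations = 3))
#' run_pipeline(cfg)
#' }
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  persist <- !is.null(cfg$out_dir)
  if (persist) dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  keep <- function(name, writer) {
    if (!persist) return(invisible(NULL))
    path <- file.path(cfg$out_dir, name)
    writer(path)
    artifacts[[name]] <<- path
    invisible(path)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (persist) write_manifest(cfg$out_dir, artifacts)
      stop_scc("stage '%s' failed: %s", name, conditionMessage(e),
               class = "scc_stage")
    })
  }

  # -- load or simulate -------------------------------------------------------
  group_map <- cfg$group_map
  dat <- stage("input", {
    if (!is.null(cfg$synthetic)) {
      d <- if (is.character(cfg$synthetic)) make_fixture(cfg$synthetic)
           else simulate_pear_spectra(cfg$synthetic)
      group_map <- d$group_map
      list(spectra = d$spectra, reference = d$reference)
    } else {
      list(spectra = read_spectra(cfg$spectra_path),
           reference = read_reference(cfg$reference_path))
    }
  })
  keep("raw_spectra.csv", function(p) write_spectra(dat$spectra, p))
  keep("reference.csv", function(p) write_reference(dat$reference, p))

  # -- trim + replicate averaging --------------------------------------------
  s <- stage("trim", trim_wavelengths(dat$spectra, cfg$effective_range[1],
                                      cfg$effective_range[2]))
  if (!is.null(group_map)) s <- stage("average", average_replicates(s, group_map))
  keep("averaged_spectra.csv", function(p) write_spectra(s, p))

  # -- split on preprocessed spectra, preprocessing chosen on that split ------
  # The comparison needs a split and the split runs on preprocessed spectra;
  # the split used for the comparison is built on the raw (trimmed, averaged)
  # spectra, then the winner's preprocessing is applied and the final split
  # recomputed on the preprocessed matrix.
  comparison <- NULL
  pp <- cfg$preprocessing
  if (is.null(pp)) {
    pre_split <- stage("split", spxy_split(s, dat$reference, cfg$ratio))
    comparison <- stage("preprocess_compare",
      compare_preprocessing(s, dat$reference, pre_split,
                            max_factors = cfg$max_factors))
    pp <- comparison$specs[[comparison$chosen]]
    keep("preprocess_comparison.csv", function(p)
      utils::write.csv(comparison$table, p, row.names = FALSE))
  }
  sp <- stage("preprocess", apply_preprocess(pp, s))
  keep("preprocessed_spectra.csv", function(p) write_spectra(sp, p))

  split <- stage("split", spxy_split(sp, dat$reference, cfg$ratio))
  y <- align_reference(sp, dat$reference)
  audit <- validate_split(split, y)
  keep("split.csv", function(p) {
    utils::write.csv(data.frame(
      id = sp$sample_ids,
      set = ifelse(seq_along(y) %in% split$calibration_idx,
                   "calibration", "validation")), p, row.names = FALSE)
  })

  Xc <- sp$reflectance[split$calibration_idx, , drop = FALSE]
  yc <- y[split$calibration_idx]
  Xv <- sp$reflectance[split$validation_idx, , drop = FALSE]
  yv <- y[split$validation_idx]

  # -- wavelength selection ---------------------------------------------------
  sel <- stage("selection", {
    if (cfg$selection == "mcuve") {
      mc <- cfg$mcuve
      mc$seed <- derive_seed(cfg$seed, 2L)
      mcuve_run(Xc, yc, Xv, yv, mc, wavelengths = sp$wavelengths)
    } else {
      spa_select(Xc, yc, Xv, yv, cfg$spa, wavelengths = sp$wavelengths)
    }
  })
  keep("selection.csv", function(p)
    utils::write.csv(data.frame(channel = sel$selected,
                                wavelength_nm = sel$wavelengths),
                     p, row.names = FALSE))
  keep("selection_trajectory.csv", function(p)
    utils::write.csv(sel$trajectory, p, row.names = FALSE))

  # -- PSO-tuned SVR ----------------------------------------------------------
  ps <- cfg$pso
  ps$seed <- derive_seed(cfg$seed, 3L)
  Xc_sel <- Xc[, sel$selected, drop = FALSE]
  Xv_sel <- Xv[, sel$selected, drop = FALSE]
  tuned <- stage("pso", pso_optimize(Xc_sel, yc, ps))
  model <- stage("svr", train_svr(Xc_sel, yc, tuned$params))
  X_sel <- sp$reflectance[, sel$selected, drop = FALSE]
  metrics <- stage("evaluate", evaluate_model(model, split, X_sel, y))

  report <- structure(list(
    selection_method = cfg$selection,
    preprocessing = format(pp),
    comparison = if (!is.null(comparison)) comparison$table,
    effective_range = cfg$effective_range,
    n_samples = length(y),
    split = list(n_cal = length(split$calibration_idx),
                 n_val = length(split$validation_idx),
                 ratio = cfg$ratio,
                 covered = audit$covered,
                 anova_p = audit$anova$p),
    stats_cal = unclass(audit$stats_cal),
    stats_val = unclass(audit$stats_val),
    n_selected = length(sel$selected),
    selected_channels = sel$selected,
    selected_wavelengths = sel$wavelengths,
    selection_rmsev = sel$rmsev,
    svr = list(c = tuned$params$c, g = tuned$params$g,
               epsilon = tuned$params$epsilon, fitness = tuned$fitness,
               trajectory = tuned$trajectory),
    metrics = list(r_cal = metrics$r_cal, rmse_cal = metrics$rmse_cal,
                   r_val = metrics$r_val, rmse_val = metrics$rmse_val,
                   max_rel_err_cal = metrics$max_rel_err_cal,
                   max_rel_err_val = metrics$max_rel_err_val),
    predictions = list(cal = metrics$pred_cal, val = metrics$pred_val,
                       obs_cal = metrics$obs_cal, obs_val = metrics$obs_val),
    seeds = list(master = cfg$seed,
                 mcuve = derive_seed(cfg$seed, 2L),
                 pso = derive_seed(cfg$seed, 3L))),
    class = "evaluation_report")
  keep("report.json", function(p) write_report_json(report, p))
  if (persist) write_manifest(cfg$out_dir, artifacts)
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("SCC evaluation (%s + PSO-SVR, preprocessing: %s)\n",
              toupper(x$selection_method), x$preprocessing))
  cat(sprintf("  samples: %d (%d cal / %d val), selected wavelengths: %d\n",
              x$n_samples, x$split$n_cal, x$split$n_val, x$n_selected))
  cat(sprintf("  C = %.4f, g = %.4f, fitness (CV RMSE) = %.4f%%\n",
              x$svr$c, x$svr$g, x$svr$fitness))
  cat(sprintf("  calibration: R = %.3f, RMSE = %.4f%%\n",
              x$metrics$r_cal, x$metrics$rmse_cal))
  cat(sprintf("  validation:  R = %.3f, RMSE = %.4f%%\n",
              x$metrics$r_val, x$metrics$rmse_val))
  invisible(x)
}

write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

write_manifest <- function(out_dir, artifacts) {
  files <- list.files(out_dir, pattern = "\\.(csv|json)$")
  files <- setdiff(files, "manifest.json")
  hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(hashes) <- files
  jsonlite::write_json(hashes, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(hashes)
}

#' Render an evaluation report to files
#'
#' Always writes `report.json` (a faithful serialization of the report);
#' `"csv"` adds the metric and set-statistic tables; `"plots"` adds PNG
#' figures (PSO fitness curve and predicted versus measured scatter).
#'
#' @param report An `evaluation_report` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @param formats Subset of `c("json", "csv", "plots")`.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(report, out_dir, formats = "json") {
  stopifnot(inherits(report, "evaluation_report"))
  bad <- setdiff(formats, c("json", "csv", "plots"))
  if (length(bad))
    stop_scc("unknown format '%s'", bad[1], class = "scc_invalid")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(out_dir, "report.json")
  write_report_json(report, p)
  paths <- c(paths, p)
  if ("csv" %in% formats) {
    mt <- file.path(out_dir, "metrics.csv")
    utils::write.csv(data.frame(
      set = c("calibration", "validation"),
      n = c(report$split$n_cal, report$split$n_val),
      r = c(report$metrics$r_cal, report$metrics$r_val),
      rmse = c(report$metrics$rmse_cal, report$metrics$rmse_val),
      max_rel_err = c(report$metrics$max_rel_err_cal,
                      report$metrics$max_rel_err_val)),
      mt, row.names = FALSE)
    st <- file.path(out_dir, "set_statistics.csv")
    utils::write.csv(rbind(
      data.frame(set = "calibration", report$stats_cal),
      data.frame(set = "validation", report$stats_val)),
      st, row.names = FALSE)
    paths <- c(paths, mt, st)
    if (!is.null(report$comparison)) {
      cp <- file.path(out_dir, "preprocess_comparison.csv")
      utils::write.csv(report$comparison, cp, row.names = FALSE)
      paths <- c(paths, cp)
    }
  }
  if ("plots" %in% formats) {
    fc <- file.path(out_dir, "pso_fitness.png")
    grDevices::png(fc, width = 700, height = 500)
    plot(seq_along(report$svr$trajectory), report$svr$trajectory, type = "s",
         xlab = "PSO iteration", ylab = "Best fitness (CV RMSE, %)",
         main = "PSO convergence")
    grDevices::dev.off()
    paths <- c(paths, fc)
    sc <- file.path(out_dir, "predicted_vs_measured.png")
    grDevices::png(sc, width = 700, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    rng <- range(unlist(report$predictions))
    plot(report$predictions$obs_cal, report$predictions$cal, pch = 4,
         xlim = rng, ylim = rng, xlab = "Measured SCC (%)",
         ylab = "Predicted SCC (%)",
         main = sprintf("%s-PSO-SVR", toupper(report$selection_method)))
    graphics::points(report$predictions$obs_val, report$predictions$val,
                     pch = 1, col = "blue")
    graphics::abline(0, 1, lty = 2)
    graphics::legend("topleft", legend = c("calibration", "validation"),
                     pch = c(4, 1), col = c("black", "blue"))
    paths <- c(paths, sc)
  }
  invisible(paths)
}
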