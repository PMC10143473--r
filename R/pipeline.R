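.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

.fmt_row <- function(...) paste0(sprintf(...), "\n")

#' Run the full assessment pipeline
#'
#' Orchestrates every stage over one region table: descriptive statistics,
#' pollution/ecological indices with per-type summaries, deterministic
#' health risk for all receptor groups, Monte Carlo uncertainty per group,
#' hotspot-area aggregation and exceedance shares, and the yearly-median
#' temporal trend fit. All tabular outputs are CSV, the trend fit and run
#' manifest JSON, plus a human-readable `report.txt`. Given the same
#' config, inputs and seed, the report content is identical between runs.
#'
#' @param config A [read_config()] result, a YAML path, a plain list, or
#'   `NULL` for defaults.
#' @param regions A region data frame or path to a region CSV.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the config's Monte Carlo seed.
#' @return The run manifest (named list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = NULL, regions, out_dir, seed = NULL) {
  cfg <- if (inherits(config, "cr_config")) config else read_config(config)
  config_path <- if (is.character(config)) config else NULL
  input_path <- if (is.character(regions)) regions else NULL
  if (is.character(regions)) regions <- read_region_table(regions)
  regions <- validate_regions(regions)
  if (!is.null(seed)) {
    cfg$mc <- mc_spec(cfg$mc$n_iter, as.integer(seed), cfg$mc$params)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  outputs <- character(0)
  stages <- character(0)
  rpt <- character(0)

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      stop_stage(name, conditionMessage(e))
    })
    stages <<- c(stages, name)
    res
  }
  emit <- function(df, file) {
    outputs <<- c(outputs, .write_csv(df, file.path(out_dir, file)))
  }

  # -- descriptive statistics ------------------------------------------------
  desc <- run_stage("describe", function()
    describe_regions(regions, cfg$background, cfg$screening_value))
  emit(data.frame(desc[c("n", "min", "max", "mean", "median", "sd", "cv_pct",
                         "pct_above_background", "pct_above_screening")]),
       "summary_stats.csv")
  rpt <- c(rpt,
    "Soil Cr assessment report\n",
    "=========================\n\n",
    .fmt_row("Regions: %d   screening value: %g mg/kg   Tn: %g",
             desc$n, cfg$screening_value, cfg$tn),
    .fmt_row("Concentration range %.2f-%.2f mg/kg, mean %.2f, median %.2f, CV %.2f%%",
             desc$min, desc$max, desc$mean, desc$median, desc$cv_pct),
    .fmt_row("Above background: %.2f%%   above screening: %.2f%%\n",
             desc$pct_above_background, desc$pct_above_screening))

  # -- pollution / ecological indices ---------------------------------------
  idx <- run_stage("indices", function()
    assess_regions(regions, cfg$background, cfg$tn))
  emit(idx, "indices.csv")
  tsum <- run_stage("type_summary", function()
    suppressWarnings(summarize_by_type(idx, regions)))
  emit(tsum$means, "type_summary_means.csv")
  emit(tsum$igeo_class_fractions, "type_igeo_classes.csv")
  emit(tsum$e_class_fractions, "type_e_classes.csv")
  rpt <- c(rpt, "Per-type mean indices\n",
           paste0(utils::capture.output(print(
             within(tsum$means, {
               mean_igeo <- round(mean_igeo, 2)
               mean_e <- round(mean_e, 2)
             }), row.names = FALSE), type = "output"), "\n"), "\n")

  # -- deterministic health risk --------------------------------------------
  hr <- run_stage("health_risk", function()
    assess_health_risk(regions, cfg$receptors, cfg$toxicity, cfg$pathways))
  emit(hr, "health_risk.csv")
  hq <- run_stage("hq_summary", function()
    suppressWarnings(summarize_hq(hr, regions)))
  emit(hq$by_group, "hq_by_group.csv")
  emit(hq$by_type, "hq_by_type.csv")
  rpt <- c(rpt, "Hazard quotients (sum over pathways)\n",
           vapply(seq_len(nrow(hq$by_group)), function(i)
             .fmt_row("  %-12s mean HQ %.3e   HQ>1 in %.2f%% of regions",
                      hq$by_group$group[i], hq$by_group$mean_hq[i],
                      hq$by_group$pct_above_1[i]), character(1)),
           "\n")

  # -- Monte Carlo uncertainty ----------------------------------------------
  mc_rows <- run_stage("monte_carlo", function() {
    do.call(rbind, lapply(seq_along(cfg$receptors), function(i) {
      m <- mc_spec(cfg$mc$n_iter, cfg$mc$seed + i - 1L, cfg$mc$params)
      summary(run_mc(mean(regions$cr_conc), cfg$receptors[[i]],
                     cfg$toxicity, m, cfg$pathways))
    }))
  })
  emit(mc_rows, "mc_by_group.csv")
  rpt <- c(rpt, sprintf("Monte Carlo HQ (%d iterations, base seed %d)\n",
                        cfg$mc$n_iter, cfg$mc$seed),
           vapply(seq_len(nrow(mc_rows)), function(i)
             .fmt_row("  %-12s mean %.3e  p5 %.3e  p50 %.3e  p95 %.3e  P(HQ>1) %.4f",
                      mc_rows$group[i], mc_rows$mean[i], mc_rows$p5[i],
                      mc_rows$p50[i], mc_rows$p95[i],
                      mc_rows$prob_exceed_1[i]), character(1)),
           "\n")

  # -- spatial aggregation ---------------------------------------------------
  assignments <- run_stage("areas", function()
    assign_areas(regions, cfg$area_map))
  emit(assignments, "areas.csv")
  acd <- run_stage("area_classes", function()
    area_class_distribution(assignments, idx))
  emit(acd$igeo_class_fractions, "area_igeo_classes.csv")
  emit(acd$e_class_fractions, "area_e_classes.csv")
  exc <- run_stage("exceedance", function()
    exceedance_by_area(regions, assignments, cfg$screening_value))
  emit(exc, "exceedance_by_area.csv")
  rpt <- c(rpt, "Screening exceedances by hotspot area\n",
           vapply(seq_len(nrow(exc)), function(i)
             .fmt_row("  %-22s %3d of %3d regions exceed (share %.1f%%)",
                      exc$area[i], exc$n_exceed[i], exc$n_regions[i],
                      exc$share_pct[i]), character(1)),
           "\n")

  # -- temporal trend --------------------------------------------------------
  trend <- NULL
  if (any(!is.na(regions$sampling_year))) {
    ym <- run_stage("yearly_medians", function() yearly_medians(regions))
    emit(ym, "yearly_medians.csv")
    if (nrow(ym) >= cfg$trend$degree + 1) {
      trend <- run_stage("trend_fit", function()
        fit_trend(ym, cfg$trend$degree, cfg$trend$log_base))
      trend_json <- file.path(out_dir, "trend_fit.json")
      jsonlite::write_json(list(
        coefficients = as.list(trend$coefficients),
        vertex_year = trend$vertex_year,
        r_squared = trend$r_squared,
        n_years = trend$n_years,
        degree = trend$degree,
        log_base = trend$log_base
      ), trend_json, auto_unbox = TRUE, digits = NA, null = "null")
      outputs <- c(outputs, trend_json)
      rpt <- c(rpt, "Temporal trend of yearly median Cr\n",
               paste0("  ", utils::capture.output(print(trend)), "\n"), "\n")
    }
  }

  report_path <- file.path(out_dir, "report.txt")
  writeLines(paste(rpt, collapse = ""), report_path, sep = "")
  outputs <- c(outputs, report_path)

  cfg_file <- config_path
  if (is.null(cfg_file)) {
    cfg_file <- tempfile(fileext = ".yaml")
    yaml::write_yaml(cfg$raw, cfg_file)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("crsoil")),
    started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$mc$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    input_md5 = if (!is.null(input_path)) unname(tools::md5sum(input_path))
                else NA,
    stages = stages,
    outputs = outputs,
    outputs_exist = all(file.exists(outputs))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(manifest)
}
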