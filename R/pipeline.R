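#' Read and write the package's tabular file formats
#'
#' Plain CSV with declared headers is used for all tabular exchange; fitted
#' models and reports are serialized as JSON. `read_closures()` reconstructs
#' `closure_series` objects from the closure schema (`chamber_id`, `plot_id`,
#' `treatment`, `species`, `t_s`, `conc_nmol_mol`, `T_K`, `P_hPa`); samples
#' after the closure duration form the post-opening ambient window.
#'
#' @param closures list of `closure_series` (write) / CSV path (read).
#' @param path file path.
#' @param geometry a [chamber_geometry()] applied to all closures read.
#' @return `read_closures()` a list of `closure_series`; writers return
#'   `path` invisibly.
#' @export
write_closures <- function(closures, path) {
  if (inherits(closures, "closure_series")) closures <- list(closures)
  rows <- lapply(closures, function(cl)
    data.frame(chamber_id = cl$chamber_id, plot_id = cl$plot_id,
               treatment = cl$treatment, species = cl$species,
               t_s = cl$samples$t_s, conc_nmol_mol = cl$samples$conc,
               T_K = cl$T_K, P_hPa = cl$P_hPa))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_closures
#' @export
read_closures <- function(path, geometry = chamber_geometry()) {
  df <- read.csv(path)
  validate_inputs(df, "closures", .stop_on_error = TRUE)
  close_s <- geometry$closure_duration_min * 60
  key <- interaction(df$chamber_id, df$species, drop = TRUE)
  lapply(split(df, key), function(s) {
    s <- s[order(s$t_s), ]
    phase <- ifelse(s$t_s > close_s, "ambient",
                    ifelse(s$t_s < geometry$flush_min * 60, "flush", "closure"))
    amb <- if (any(phase == "ambient")) mean(s$conc_nmol_mol[phase == "ambient"])
    else s$conc_nmol_mol[1]
    structure(list(
      samples = data.frame(t_s = s$t_s, conc = s$conc_nmol_mol, phase = phase),
      species = s$species[1], T_K = mean(s$T_K), P_hPa = mean(s$P_hPa),
      ambient_C = amb, geometry = geometry,
      chamber_id = s$chamber_id[1], plot_id = s$plot_id[1],
      treatment = s$treatment[1], true_flux = NULL
    ), class = "closure_series")
  })
}

input_schemas <- function() {
  list(
    closures = list(
      required = c(chamber_id = "character", plot_id = "character",
                   treatment = "character", species = "character",
                   t_s = "numeric", conc_nmol_mol = "numeric",
                   T_K = "numeric", P_hPa = "numeric"),
      ranges = list(t_s = c(0, Inf), T_K = c(150, 350), P_hPa = c(500, 1200))
    ),
    soil = list(
      required = c(year = "numeric", doy = "numeric", plot_id = "character",
                   treatment = "character", layer = "character",
                   temperature = "numeric", moisture = "numeric"),
      ranges = list(doy = c(1, 366), temperature = c(-45, 45),
                    moisture = c(0, 2), wfps = c(0, 100))
    ),
    incubation = list(
      required = c(sample_id = "character", layer = "character",
                   treatment = "character", temp_C = "numeric",
                   nh4_before = "numeric", no3_before = "numeric",
                   nh4_after = "numeric", no3_after = "numeric",
                   days = "numeric"),
      ranges = list(temp_C = c(-5, 45), nh4_before = c(0, Inf),
                    no3_before = c(0, Inf), nh4_after = c(0, Inf),
                    no3_after = c(0, Inf), days = c(0.1, 365))
    ),
    site_table = list(
      required = c(site_id = "character", delta_t = "numeric",
                   delta_wfps_pct = "numeric", n2o_control = "numeric",
                   n2o_warmed = "numeric"),
      ranges = list(delta_t = c(0.1, 10), delta_wfps_pct = c(-100, 100))
    ),
    daily_flux = list(
      required = c(year = "numeric", doy = "numeric", treatment = "character",
                   species = "character", mean_flux = "numeric"),
      ranges = list(doy = c(1, 366))
    )
  )
}

#' Validate a tabular input against a declared schema
#'
#' Checks column presence (missing column = error), surplus columns
#' (warning only, for forward compatibility), coarse type agreement, and
#' physical ranges (e.g. WFPS within 0-100 %). Returns a report rather than
#' stopping, unless asked to.
#'
#' @param x a data.frame or a CSV path.
#' @param schema one of `"closures"`, `"soil"`, `"incubation"`,
#'   `"site_table"`, `"daily_flux"`.
#' @param .stop_on_error raise the first error instead of reporting?
#' @return data.frame of class `validation_report` with columns `level`
#'   (`"error"`/`"warning"`), `column`, `message`; zero rows = clean pass.
#' @export
validate_inputs <- function(x, schema, .stop_on_error = FALSE) {
  schemas <- input_schemas()
  schema <- match.arg(schema, names(schemas))
  sc <- schemas[[schema]]
  if (is.character(x)) {
    x <- tryCatch(read.csv(x), error = function(e)
      stop("malformed CSV '", x, "': ", conditionMessage(e)))
  }
  rep <- list()
  add <- function(level, column, msg)
    rep[[length(rep) + 1L]] <<- data.frame(level = level, column = column,
                                           message = msg)
  for (col in names(sc$required)) {
    if (!col %in% names(x)) {
      add("error", col, "required column missing")
      next
    }
    want <- sc$required[[col]]
    got <- if (is.numeric(x[[col]])) "numeric" else "character"
    if (want == "numeric" && got != "numeric")
      add("error", col, sprintf("expected numeric, got %s", got))
  }
  extra <- setdiff(names(x), c(names(sc$required), names(sc$ranges)))
  for (col in extra) add("warning", col, "column not in schema; ignored")
  for (col in names(sc$ranges)) {
    if (!col %in% names(x) || !is.numeric(x[[col]])) next
    rg <- sc$ranges[[col]]
    bad <- which(!is.na(x[[col]]) & (x[[col]] < rg[1] | x[[col]] > rg[2]))
    if (length(bad))
      add("error", col, sprintf("%d value(s) outside [%g, %g] (first at row %d)",
                                length(bad), rg[1], rg[2], bad[1]))
  }
  out <- if (length(rep)) do.call(rbind, rep) else
    data.frame(level = character(0), column = character(0),
               message = character(0))
  if (.stop_on_error && any(out$level == "error"))
    stop("validation failed: ", paste(out$message[out$level == "error"],
                                      collapse = "; "))
  class(out) <- c("validation_report", "data.frame")
  out
}

pipeline_stages <- c("simulate", "fluxes", "aggregate", "respond", "n2",
                     "rates", "effects", "meta")

#' Run the analysis pipeline end to end
#'
#' Orchestrates simulate -> fluxes -> aggregate -> respond -> n2 -> rates ->
#' effects -> meta with file artifacts under `out_dir` and a manifest
#' recording the config hash, seed, per-stage row counts and file
#' checksums. All randomness flows from the config seed; rerunning with an
#' identical config reproduces byte-identical numeric outputs. A stage run
#' without its upstream artifacts (in memory or on disk) raises an error
#' naming the stage to run first.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param stages subset of `c("simulate", "fluxes", "aggregate", "respond",
#'   "n2", "rates", "effects", "meta")`, or `"all"`.
#' @param measurement passed to [simulate_experiment()].
#' @param quiet suppress stage messages?
#' @return the manifest (list), invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir, stages = "all",
                         measurement = "daily", quiet = FALSE) {
  config <- validate_sim_config(config)
  if (identical(stages, "all")) stages <- pipeline_stages
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)
  say <- function(...) if (!quiet) message(...)
  manifest <- list(seed = config$seed, stages = stages,
                   measurement = measurement, counts = list())

  cfg_file <- pth("config.yaml")
  write_sim_config(config, cfg_file)
  manifest$config_hash <- unname(tools::md5sum(cfg_file))

  exp <- NULL
  need_exp <- function() {
    if (is.null(exp)) {
      if (!file.exists(pth("daily_fluxes.csv")))
        stop("upstream artifacts missing; run stage 'simulate'/'fluxes' first")
      exp <<- list(
        daily_fluxes = read.csv(pth("daily_fluxes.csv")),
        soil_daily = read.csv(pth("soil_daily.csv")),
        delta_t = jsonlite::read_json(pth("experiment.json"))$delta_t
      )
    }
    exp
  }

  if (any(c("simulate", "fluxes", "aggregate") %in% stages)) {
    say("stage simulate/fluxes/aggregate: running synthetic experiment")
    exp <- simulate_experiment(config, measurement = measurement)
    write.csv(exp$climate, pth("climate.csv"), row.names = FALSE)
    write.csv(soil_records(exp$climate), pth("soil.csv"), row.names = FALSE)
    write.csv(exp$soil_daily, pth("soil_daily.csv"), row.names = FALSE)
    write.csv(exp$flux_records, pth("flux_records.csv"), row.names = FALSE)
    write.csv(exp$daily_fluxes, pth("daily_fluxes.csv"), row.names = FALSE)
    jsonlite::write_json(list(delta_t = exp$delta_t),
                         pth("experiment.json"), auto_unbox = TRUE)
    ann <- cumulative_flux(exp$daily_fluxes, label = "annual_total")
    seas <- seasonal_partition(exp$daily_fluxes)
    write.csv(ann, pth("cumulative.csv"), row.names = FALSE)
    write.csv(seas, pth("seasonal.csv"), row.names = FALSE)
    manifest$counts$climate <- nrow(exp$climate)
    manifest$counts$flux_records <- nrow(exp$flux_records)
    manifest$counts$daily_fluxes <- nrow(exp$daily_fluxes)
  }

  if ("respond" %in% stages) {
    e <- need_exp()
    say("stage respond: temperature and moisture response fits")
    fit <- apparent_q10(e)
    d <- merge(e$daily_fluxes[e$daily_fluxes$species == "NO" &
                                e$daily_fluxes$treatment == "control", ],
               e$soil_daily, by = c("year", "doy", "treatment"))
    mbins <- bin_fluxes(d, "wfps", season = season_calendar()$growing)
    mfit <- tryCatch(fit_moisture_response(mbins), error = function(e) NULL)
    jsonlite::write_json(list(
      temperature = list(A = fit$A, k = fit$k, q10 = fit$q10, r2 = fit$r2,
                         n_bins = fit$n_bins, bins = fit$bins),
      moisture = if (!is.null(mfit))
        list(c2 = mfit$c2, c1 = mfit$c1, c0 = mfit$c0,
             optimum = mfit$optimum, r2 = mfit$r2, bins = mfit$bins)
    ), pth("response_fits.json"), auto_unbox = TRUE, digits = NA)
    manifest$counts$temp_bins <- fit$n_bins
  }

  if ("n2" %in% stages) {
    e <- need_exp()
    say("stage n2: moisture-scaled N2 fluxes")
    n2 <- seasonal_n2(e$daily_fluxes, e$soil_daily)
    write.csv(n2, pth("n2_seasonal.csv"), row.names = FALSE)
    manifest$counts$n2_rows <- nrow(n2)
  }

  if ("rates" %in% stages) {
    say("stage rates: incubation and Arrhenius extrapolation")
    inc <- simulate_incubation(config)
    rt <- net_rates(inc)
    write.csv(rt, pth("incubation_rates.csv"), row.names = FALSE)
    fits <- lapply(split(rt, interaction(rt$layer, rt$treatment)), function(s) {
      f <- fit_arrhenius(s$temp_C, s$r_miner)
      list(layer = s$layer[1], treatment = s$treatment[1],
           a = f$a, b = f$b, r2 = f$r2,
           rate_at_15C = predict_rate(f, 15))
    })
    jsonlite::write_json(unname(fits), pth("arrhenius_fits.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$counts$incubation_rows <- nrow(rt)
  }

  if ("effects" %in% stages) {
    e <- need_exp()
    say("stage effects: warming summary and effect sizes")
    ws <- warming_summary(e)
    jsonlite::write_json(list(
      delta_t = ws$delta_t, species = ws$species_table, total = ws$total
    ), pth("warming_summary.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
    manifest$counts$summary_species <- nrow(ws$species_table)
  }

  if ("meta" %in% stages) {
    say("stage meta: cross-study regression")
    site_file <- pth("site_table.csv")
    studies <- if (file.exists(site_file)) read.csv(site_file)
    else synthetic_site_table()
    mr <- meta_regression(studies)
    jsonlite::write_json(list(
      slope = mr$slope, intercept = mr$intercept, r2 = mr$r2,
      p_value = mr$p_value, n = mr$n, predictor = mr$predictor,
      studies = mr$studies
    ), pth("meta_regression.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
    manifest$counts$meta_sites <- mr$n
  }

  files <- list.files(out_dir, pattern = "\\.(csv|json)$", full.names = TRUE)
  files <- setdiff(files, pth("manifest.json"))
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
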