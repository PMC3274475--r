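# Pipeline orchestration and the command-line interface.

#' Run configuration for the full pipeline
#'
#' @param grid,bg,stations input CSV paths (`stations` optional: `NULL`
#'   disables validation).
#' @param out_dir output directory (created if absent).
#' @param pollutant `"pm25"` or `"ozone"` — selects the default daily
#'   standard.
#' @param threshold,class_width override the standard configuration.
#' @param k neighbours per block group.
#' @param levels aggregation levels.
#' @param min_days at-risk thresholds, days.
#' @param strata validation strata.
#' @param verbose log per-stage counts.
#' @return a validated `run_config` list.
#' @export
run_config <- function(grid, bg, out_dir, stations = NULL,
                       pollutant = "pm25", threshold = NULL, class_width = 10,
                       k = 4L, levels = c("tract", "county", "state", "national"),
                       min_days = c(7L, 14L, 28L), strata = c("year", "season"),
                       verbose = TRUE) {
  cfg <- standard_config(pollutant, threshold, class_width)
  stopifnot(k >= 1)
  for (p in c(grid, bg, stations)) {
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p))
  }
  structure(list(grid = grid, bg = bg, stations = stations,
                 out_dir = out_dir, std = cfg, k = as.integer(k),
                 levels = levels, min_days = as.integer(min_days),
                 strata = strata, verbose = verbose),
            class = "run_config")
}

#' Run the full pipeline: downscale, aggregate, summarise (and validate)
#'
#' Reads the grid and block-group tables, produces block-group daily
#' estimates, population-weighted exposure series for the requested levels,
#' percentile/exceedance summaries, population-at-risk tables, and — when a
#' station table is supplied — a stratified validation report. All outputs
#' are CSVs under `out_dir`; reruns on identical inputs are byte-identical
#' (no stage uses randomness).
#'
#' @param rc a [run_config()].
#' @return invisibly, a named list of the output file paths.
#' @export
run_pipeline <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  grid <- read_table(rc$grid, "grid")
  bgs <- read_table(rc$bg, "bg")
  check_geoid(bgs$geoid)

  bg_est <- downscale_all(grid, bgs, k = rc$k, verbose = rc$verbose)
  paths$bg_est <- file.path(rc$out_dir, "bg_est.csv")
  write_table(bg_est, paths$bg_est)

  exposures <- aggregate_all(bg_est, bgs, levels = rc$levels,
                             verbose = rc$verbose)
  paths$exposures <- file.path(rc$out_dir, "exposures.csv")
  write_table(exposures, paths$exposures)

  # BG-level summary: percentiles of mu plus exceedance-day counts
  bg_sum <- summarize_series(bg_est, rc$std, value_col = "mu",
                             count_exceedance = TRUE)
  bg_sum <- merge(bg_sum,
                  bgs[, c("geoid", "population")], by = "geoid")
  paths$bg_summary <- file.path(rc$out_dir, "bg_summary.csv")
  write_table(bg_sum, paths$bg_summary)

  # unit-level percentile summaries of PE
  level <- NULL
  unit_sum <- exposures[, {
    s <- summarize_series(.SD, rc$std, value_col = "pe",
                          count_exceedance = FALSE)
    s
  }, by = "level"]
  paths$unit_summary <- file.path(rc$out_dir, "unit_summary.csv")
  write_table(unit_sum, paths$unit_summary)

  # population at risk per aggregation level (exceedance measured on BG mu)
  exc <- bg_sum[, c("geoid", "days_exceeding", "population")]
  risk <- data.table::rbindlist(lapply(
    intersect(rc$levels, c("tract", "county", "state", "national")),
    function(lv) population_at_risk(exc, rc$min_days, level = lv)))
  paths$population_at_risk <- file.path(rc$out_dir, "population_at_risk.csv")
  write_table(risk, paths$population_at_risk)

  if (!is.null(rc$stations)) {
    stations <- read_table(rc$stations, "stations")
    pairs <- pair_observations(stations, bg_est)
    strata <- rc$strata
    if ("urban_rural" %in% strata && !"urban_rural" %in% names(pairs)) {
      stop("urban_rural stratum requested but stations table lacks the column")
    }
    report <- stratified_report(pairs, strata)
    paths$validation <- file.path(rc$out_dir, "validation.csv")
    write_table(report, paths$validation)
  }
  if (rc$verbose) {
    message(sprintf("pipeline: wrote %d output file(s) to %s",
                    length(paths), rc$out_dir))
  }
  invisible(paths)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `downscale`, `aggregate`, `summarize`,
#' `validate`, `run`. Invoke from a shell as
#' `Rscript -e 'gridshed::gridshed_cli()' <subcommand> [options]`, or via the
#' launcher installed at `system.file("cli", "gridshed.R", package =
#' "gridshed")`.
#'
#' @param args command-line arguments (default: from the process).
#' @return exit status, invisibly (0 on success).
#' @export
gridshed_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1] %in% c("-h", "--help")) {
    cat("usage: gridshed <simulate|downscale|aggregate|summarize|validate|run> [options]\n")
    return(invisible(0L))
  }
  if (args[1] == "--version") {
    cat(sprintf("gridshed %s\n", as.character(utils::packageVersion("gridshed"))))
    return(invisible(0L))
  }
  cmd <- args[1]
  rest <- args[-1]
  opt <- function(spec) optparse::parse_args(
    optparse::OptionParser(option_list = spec), args = rest)

  status <- tryCatch({
    switch(cmd,
      simulate = {
        o <- opt(list(
          optparse::make_option("--seed", type = "integer", default = 1L),
          optparse::make_option("--n-days", type = "integer", default = 30L),
          optparse::make_option("--out-dir", type = "character")))
        if (is.null(o$`out-dir`)) stop("simulate: --out-dir is required")
        cfg <- sim_config(seed = o$seed, n_days = o$`n-days`)
        ds <- simulate_dataset(cfg)
        dir.create(o$`out-dir`, showWarnings = FALSE, recursive = TRUE)
        write_table(ds$grid, file.path(o$`out-dir`, "grid.csv"))
        write_table(ds$bgs, file.path(o$`out-dir`, "bg.csv"))
        write_table(ds$stations, file.path(o$`out-dir`, "stations.csv"))
        write_table(ds$bg_truth, file.path(o$`out-dir`, "truth.csv"))
      },
      downscale = {
        o <- opt(list(
          optparse::make_option("--grid", type = "character"),
          optparse::make_option("--bg", type = "character"),
          optparse::make_option("--out", type = "character"),
          optparse::make_option("--k", type = "integer", default = 4L)))
        est <- downscale_all(read_table(o$grid, "grid"),
                             read_table(o$bg, "bg"), k = o$k)
        write_table(est, o$out)
      },
      aggregate = {
        o <- opt(list(
          optparse::make_option("--bg-est", type = "character"),
          optparse::make_option("--bg", type = "character"),
          optparse::make_option("--levels", type = "character",
                                default = "tract,county,state,national"),
          optparse::make_option("--out", type = "character")))
        exp <- aggregate_all(read_table(o$`bg-est`, "bg_est"),
                             read_table(o$bg, "bg"),
                             levels = strsplit(o$levels, ",")[[1]])
        write_table(exp, o$out)
      },
      summarize = {
        o <- opt(list(
          optparse::make_option("--bg-est", type = "character"),
          optparse::make_option("--bg", type = "character"),
          optparse::make_option("--pollutant", type = "character",
                                default = "pm25"),
          optparse::make_option("--standard", type = "double", default = NULL),
          optparse::make_option("--min-days", type = "character",
                                default = "7,14,28"),
          optparse::make_option("--out", type = "character")))
        std <- standard_config(o$pollutant, o$standard)
        bg_est <- read_table(o$`bg-est`, "bg_est")
        bgs <- read_table(o$bg, "bg")
        s <- summarize_series(bg_est, std)
        s <- merge(s, bgs[, c("geoid", "population")], by = "geoid")
        dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
        write_table(s, file.path(o$out, "bg_summary.csv"))
        md <- as.integer(strsplit(o$`min-days`, ",")[[1]])
        risk <- data.table::rbindlist(lapply(
          c("county", "state", "national"),
          function(lv) population_at_risk(
            s[, c("geoid", "days_exceeding", "population")], md, level = lv)))
        write_table(risk, file.path(o$out, "population_at_risk.csv"))
      },
      validate = {
        o <- opt(list(
          optparse::make_option("--bg-est", type = "character"),
          optparse::make_option("--stations", type = "character"),
          optparse::make_option("--strata", type = "character", default = ""),
          optparse::make_option("--out", type = "character")))
        pairs <- pair_observations(read_table(o$stations, "stations"),
                                   read_table(o$`bg-est`, "bg_est"))
        strata <- if (nzchar(o$strata)) strsplit(o$strata, ",")[[1]]
                  else character()
        write_table(stratified_report(pairs, strata), o$out)
      },
      run = {
        o <- opt(list(
          optparse::make_option("--grid", type = "character"),
          optparse::make_option("--bg", type = "character"),
          optparse::make_option("--stations", type = "character",
                                default = NULL),
          optparse::make_option("--pollutant", type = "character",
                                default = "pm25"),
          optparse::make_option("--out-dir", type = "character")))
        rc <- run_config(grid = o$grid, bg = o$bg, stations = o$stations,
                         out_dir = o$`out-dir`, pollutant = o$pollutant)
        run_pipeline(rc)
      },
      stop(sprintf("unknown subcommand: %s", cmd))
    )
    0L
  }, error = function(e) {
    message(sprintf("gridshed %s: %s", cmd, conditionMessage(e)))
    1L
  })
  invisible(status)
}
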