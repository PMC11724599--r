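# One-command orchestration: simulate (or read) -> filter -> residency ->
# space use -> connectivity -> stats -> report, with deterministic seeding,
# a config that round-trips through YAML, and a manifest that reconciles
# record counts across stages.

#' Pipeline configuration
#'
#' Holds either an embedded [simulation_config()] (synthetic runs) or a list
#' of input paths (`detections`, `deployments`, `stations`, and optionally
#' `landmask`, `mortality`), plus every analysis threshold: minimum residence
#' duration (strictly more than 5 days by default), minimum stations for a
#' minimum convex polygon (3), minimum station deployment span (90 days),
#' significance level (0.05), and calendar years excluded from statistics but
#' kept in data summaries.
#'
#' @param sim A [simulation_config()], or NULL when reading files.
#' @param input Named list of file paths, or NULL when simulating.
#' @param focal_region Focal region (default `"wadden_sea"`).
#' @param min_residence_days Strict inclusion threshold on residence
#'   duration (default 5).
#' @param min_stations_mcp Minimum distinct stations per fish-year for space
#'   use (default 3).
#' @param station_min_days Minimum station deployment span in days
#'   (default 90).
#' @param alpha Significance threshold (default 0.05).
#' @param exclude_years Years dropped from statistical outputs (default
#'   none).
#' @param mortality_mode Passed to [remove_mortality()].
#' @param outdir Output directory for the artefact bundle, or NULL to skip
#'   writing.
#' @param seed Seed recorded in the manifest (defaults to the simulation
#'   seed).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(), input = NULL,
                            focal_region = "wadden_sea",
                            min_residence_days = 5, min_stations_mcp = 3,
                            station_min_days = 90, alpha = 0.05,
                            exclude_years = integer(),
                            mortality_mode = "all",
                            outdir = NULL,
                            seed = if (!is.null(sim)) sim$seed else 1L) {
  if (is.null(sim) && is.null(input))
    stop_mt("provide either a simulation config or input paths")
  focal_region <- match.arg(focal_region, regions())
  for (f in c("min_residence_days", "min_stations_mcp", "station_min_days")) {
    if (get(f) <= 0) stop_mt(f, " must be positive")
  }
  if (alpha <= 0 || alpha >= 1) stop_mt("alpha must lie in (0, 1)")
  structure(list(sim = sim, input = input, focal_region = focal_region,
                 min_residence_days = min_residence_days,
                 min_stations_mcp = min_stations_mcp,
                 station_min_days = station_min_days, alpha = alpha,
                 exclude_years = as.integer(exclude_years),
                 mortality_mode = mortality_mode,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialise a pipeline configuration to YAML
#'
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$sim)) {
    sim <- unclass(x$sim)
    sim$species <- lapply(sim$species, unclass)
    sim$n_fish <- as.list(sim$n_fish)
    x$sim <- sim
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Rebuilds and re-validates the configuration, so a round trip through
#' [write_pipeline_config()] reproduces an equivalent object.
#'
#' @param path YAML file written by [write_pipeline_config()].
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(x$sim)) {
    s <- x$sim
    s$species <- lapply(s$species, function(sp) do.call(species_params, sp))
    s$n_fish <- unlist(s$n_fish)
    sim <- do.call(simulation_config, s)
  }
  pipeline_config(sim = sim, input = x$input, focal_region = x$focal_region,
                  min_residence_days = x$min_residence_days,
                  min_stations_mcp = x$min_stations_mcp,
                  station_min_days = x$station_min_days, alpha = x$alpha,
                  exclude_years = x$exclude_years %||% integer(),
                  mortality_mode = x$mortality_mode %||% "all",
                  outdir = x$outdir, seed = x$seed)
}

read_inputs <- function(input) {
  list(
    detections = read_detections(input$detections),
    deployments = read_deployments(input$deployments),
    stations = read_stations(input$stations),
    mask = if (!is.null(input$landmask)) read_landmask(input$landmask) else NULL,
    mortality = if (!is.null(input$mortality)) {
      m <- utils::read.csv(input$mortality, stringsAsFactors = FALSE)
      if ("death_time" %in% names(m)) m$death_time <- parse_timestamp(m$death_time)
      tibble::as_tibble(m)
    } else NULL,
    truth = NULL
  )
}

#' Run the full analysis pipeline
#'
#' Executes every stage on either simulated or file-based inputs and returns
#' the artefact bundle: filtered detections, filter report, residence table,
#' per-station medians, space-use table, movement events, weekly and monthly
#' presence summaries, the statistical report, and a run manifest recording
#' the seed, a configuration hash, and per-stage record counts. With an
#' `outdir`, every artefact is also written as delimited text / JSON;
#' identical configuration and seed give a byte-identical bundle.
#'
#' @param config A [pipeline_config()].
#' @return The bundle, invisibly (a named list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_mt("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }
  ds <- if (!is.null(config$sim)) {
    stage("simulate", simulate_dataset(config$sim))
  } else {
    stage("read", read_inputs(config$input))
  }
  mask <- ds$mask %||% NULL

  filt <- stage("filter", apply_filters(
    ds$detections, ds$deployments, stations = ds$stations,
    mortality = ds$mortality, mortality_mode = config$mortality_mode,
    station_min_days = config$station_min_days
  ))
  excl <- stage("exclude_stations",
                exclude_stations(ds$stations, min_days = config$station_min_days))

  residence <- stage("residency", residence_records(
    filt$detections, ds$deployments, ds$stations,
    region = config$focal_region,
    min_duration_days = config$min_residence_days
  ))
  usages <- stage("local_residency", local_residency_index(
    filt$detections, ds$deployments, ds$stations, region = config$focal_region
  ))
  medians <- stage("station_medians", station_medians(
    usages, residence, excluded_station_ids = excl$excluded$station_id
  ))
  mcp_tbl <- stage("space_use", mcp_table(
    filt$detections, ds$deployments, ds$stations, residence, mask = mask,
    min_stations = config$min_stations_mcp, region = config$focal_region
  ))
  movements <- stage("connectivity", extract_movements(
    filt$detections, ds$stations, ds$deployments,
    focal_region = config$focal_region
  ))
  weekly <- stage("presence_weekly", presence_summary(
    filt$detections, ds$stations, ds$deployments, "week"))
  monthly <- stage("presence_monthly", relative_presence(presence_summary(
    filt$detections, ds$stations, ds$deployments, "month")))

  stats_tbl <- stage("stats", pipeline_stats(
    residence, mcp_tbl, config$alpha, config$exclude_years))

  manifest <- list(
    package = "mullettrack",
    version = as.character(utils::packageVersion("mullettrack")),
    seed = config$seed,
    # the hash covers the scientific configuration, not the output location
    config_hash = rlang::hash(unclass(config)[setdiff(names(config), "outdir")]),
    counts = list(
      detections_in = filt$report$n_input,
      detections_filtered = filt$report$n_output,
      removed_by_rule = stats::setNames(as.list(filt$report$rules$removed),
                                        filt$report$rules$rule),
      residence_records = nrow(residence),
      station_usages = nrow(usages),
      mcp_fish_years = nrow(mcp_tbl),
      movement_events = nrow(movements),
      excluded_stations = nrow(excl$excluded)
    )
  )

  bundle <- list(
    filtered_detections = filt$detections,
    filter_report = filt$report,
    residence = residence,
    station_medians = medians,
    mcp = mcp_tbl,
    movements = movements,
    presence_weekly = weekly,
    presence_monthly = monthly,
    stats_report = stats_tbl,
    manifest = manifest,
    truth = ds$truth,
    stations = ds$stations,
    deployments = ds$deployments
  )

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$outdir, f)
    write_dataset(bundle$filtered_detections, p("filtered_detections.csv"))
    write_filter_report(bundle$filter_report, p("filter_report.json"))
    write_csv_strict(as.data.frame(bundle$residence), p("residence.csv"))
    write_csv_strict(as.data.frame(bundle$station_medians), p("station_medians.csv"))
    write_csv_strict(as.data.frame(bundle$mcp), p("mcp.csv"))
    write_csv_strict(as.data.frame(bundle$movements), p("movements.csv"))
    write_csv_strict(as.data.frame(bundle$presence_weekly), p("presence_weekly.csv"))
    write_csv_strict(as.data.frame(bundle$presence_monthly), p("presence_monthly.csv"))
    write_csv_strict(as.data.frame(bundle$stats_report), p("stats_report.csv"))
    jsonlite::write_json(bundle$manifest, p("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(bundle)
}

# the statistical comparisons the results report: species contrasts on
# timing/duration/RI (return years only) and on space use, plus year
# contrasts within species where two or more years are present
pipeline_stats <- function(residence, mcp_tbl, alpha = 0.05,
                           exclude_years = integer()) {
  comparisons <- list()
  timing <- residence[residence$included & residence$is_return_year &
                        !residence$year %in% exclude_years, ]
  timing$arrival_doy <- doy(timing$arrival)
  timing$departure_doy <- doy(timing$departure)
  for (metric in c("arrival_doy", "departure_doy", "duration_days", "RI")) {
    cm <- try(compare_species(timing, metric, "species", alpha), silent = TRUE)
    if (!inherits(cm, "try-error")) comparisons[[length(comparisons) + 1L]] <- cm
  }
  space <- residence[residence$included & !residence$year %in% exclude_years, ]
  cm <- try(compare_species(space, "n_stations", "species", alpha), silent = TRUE)
  if (!inherits(cm, "try-error")) comparisons[[length(comparisons) + 1L]] <- cm
  mcp_ok <- mcp_tbl[!mcp_tbl$degenerate & !mcp_tbl$year %in% exclude_years, ]
  cm <- try(compare_species(mcp_ok, "clipped_area_km2", "species", alpha),
            silent = TRUE)
  if (!inherits(cm, "try-error")) comparisons[[length(comparisons) + 1L]] <- cm
  # between-year contrasts within each species
  for (sp in unique(space$species)) {
    sub <- space[space$species == sp, ]
    sub$year_label <- as.character(sub$year)
    if (dplyr::n_distinct(sub$year_label) >= 2) {
      cm <- try(compare_species(sub, "n_stations", "year_label", alpha),
                silent = TRUE)
      if (!inherits(cm, "try-error")) {
        cm$grouping <- paste0("year|", sp)
        comparisons[[length(comparisons) + 1L]] <- cm
      }
    }
  }
  if (length(comparisons) == 0) {
    return(tibble::tibble(metric = character(), grouping = character(),
                          H = numeric(), df = integer(), p_value = numeric(),
                          significant = logical(), n = character()))
  }
  comparison_table(comparisons)
}

#' Summarise a pipeline bundle the way the results tables are laid out
#'
#' Produces (i) a per-region detection summary — unique fish, unique
#' stations, detection count — including zero rows for regions without
#' detections, and (ii) a per-species block of medians and interquartile
#' ranges for arrival and departure day-of-year, residence duration, and RI
#' over included return fish-years.
#'
#' @param bundle Output of [run_pipeline()].
#' @param deployments Tag deployments (needed to map tags to fish); taken
#'   from the bundle's truth when omitted on synthetic runs.
#' @param stations Station table; required for region mapping on file-based
#'   runs.
#' @return List of class `pipeline_report` with `region_summary` and
#'   `species_summary` tibbles.
#' @export
pipeline_report <- function(bundle, deployments = NULL, stations = NULL) {
  det <- bundle$filtered_detections
  if (is.null(deployments)) deployments <- bundle$deployments
  if (is.null(stations)) stations <- bundle$stations
  region_summary <- NULL
  if (!is.null(stations)) {
    reg_map <- unique(stations[, c("station_id", "region")])
    d <- dplyr::inner_join(det, reg_map, by = "station_id")
    if (!is.null(deployments))
      d <- dplyr::left_join(d, deployments[, c("tag_id", "fish_id")],
                            by = "tag_id")
    else d$fish_id <- d$tag_id
    rs <- dplyr::summarise(
      dplyr::group_by(d, .data$region),
      n_fish = dplyr::n_distinct(.data$fish_id),
      n_stations = dplyr::n_distinct(.data$station_id),
      n_detections = dplyr::n(),
      .groups = "drop"
    )
    region_summary <- dplyr::left_join(
      tibble::tibble(region = regions()), rs, by = "region"
    )
    region_summary[is.na(region_summary)] <- 0
  }
  res <- bundle$residence
  res <- res[res$included & res$is_return_year, ]
  qi <- function(x, p) stats::quantile(x, p, names = FALSE, type = 7)
  species_summary <- dplyr::summarise(
    dplyr::group_by(res, .data$species),
    n_fish_years = dplyr::n(),
    arrival_doy_median = stats::median(doy(.data$arrival)),
    arrival_doy_iqr = paste0(round(qi(doy(.data$arrival), 0.25)), "-",
                             round(qi(doy(.data$arrival), 0.75))),
    departure_doy_median = stats::median(doy(.data$departure)),
    departure_doy_iqr = paste0(round(qi(doy(.data$departure), 0.25)), "-",
                               round(qi(doy(.data$departure), 0.75))),
    duration_median = stats::median(.data$duration_days),
    duration_iqr = paste0(round(qi(.data$duration_days, 0.25)), "-",
                          round(qi(.data$duration_days, 0.75))),
    RI_median = stats::median(.data$RI),
    RI_iqr = paste0(round(qi(.data$RI, 0.25), 3), "-",
                    round(qi(.data$RI, 0.75), 3)),
    .groups = "drop"
  )
  structure(list(region_summary = region_summary,
                 species_summary = species_summary),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  if (!is.null(x$region_summary)) {
    cat("Detections by region (fish / stations / detections):\n")
    print(as.data.frame(x$region_summary), row.names = FALSE)
  }
  cat("\nReturn-year residence by species (median, IQR):\n")
  print(as.data.frame(x$species_summary), row.names = FALSE)
  invisible(x)
}
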