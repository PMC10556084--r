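# Tool surface: weather CSV reading with schema validation, YAML/JSON run
# configuration, and report/warning export. All files are plain delimited
# text or YAML/JSON with ISO-8601 dates.

weather_required_cols <- c(
  "date", "tmin", "tmean", "tmax", "rh_pct", "wind", "radiation", "precip_mm"
)

#' Read and validate a daily weather file
#'
#' Delimited text with a header naming the required columns `date, tmin,
#' tmean, tmax, rh_pct, wind, radiation, precip_mm` (plus optional `tsoil`).
#' Dates must be ISO-8601 and unique; records are returned date-sorted with
#' a gap report attached.
#'
#' @param path File path (comma- or tab-separated, inferred from the
#'   header line).
#' @return `data.frame` of daily records with attribute `gaps` (Dates
#'   immediately after each gap; empty when contiguous).
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) stop("weather file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path,
    header = TRUE, sep = sep, stringsAsFactors = FALSE
  )
  missing_cols <- setdiff(weather_required_cols, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    bad <- which(is.na(dates))
    stop("unparseable date at line(s) ",
      paste(bad + 1, collapse = ", "),
      call. = FALSE
    )
  }
  df$date <- dates
  if (anyDuplicated(df$date)) {
    stop("duplicated date(s): ",
      paste(unique(df$date[duplicated(df$date)]), collapse = ", "),
      call. = FALSE
    )
  }
  df <- df[order(df$date), , drop = FALSE]
  rownames(df) <- NULL
  bad_t <- df$tmin > df$tmean | df$tmean > df$tmax
  if (any(bad_t)) {
    stop("validation error: tmin <= tmean <= tmax violated on ",
      paste(df$date[bad_t], collapse = ", "),
      call. = FALSE
    )
  }
  if (any(df$rh_pct < 0 | df$rh_pct > 100)) {
    stop("validation error: rh_pct outside [0, 100]", call. = FALSE)
  }
  gaps <- df$date[c(FALSE, diff(df$date) != 1)]
  attr(df, "gaps") <- gaps
  df
}

#' Write a daily weather file
#'
#' @param weather Daily weather `data.frame` (columns as in
#'   [read_weather()]).
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_weather <- function(weather, path) {
  out <- weather[, intersect(
    c(weather_required_cols, "tsoil"), names(weather)
  ), drop = FALSE]
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' YAML (or JSON) document describing one vineyard run: `site` (latitude,
#' longitude, altitude), `rows` (azimuth, spacing, canopy height/width/base),
#' `soil` (sand/clay/OM percentages, depth), `floor` (zones with cover class
#' and area fraction, termination date), `weather` (path), and optional
#' `stage_windows`, `extraction_threshold`, `seed`, `output_dir`.
#'
#' @param path Path to a `.yml`/`.yaml`/`.json` file.
#' @return Object of class `run_config`: list with `geometry`
#'   ([vineyard_geometry()]), `soil` ([pedotransfer()]), `floor`
#'   ([floor_management()]) and the remaining raw fields.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("site", "rows", "soil")
  miss <- setdiff(need, names(doc))
  if (length(miss)) {
    stop("config missing section(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  geometry <- vineyard_geometry(
    latitude = doc$site$latitude,
    longitude = doc$site$longitude %||% 0,
    altitude = doc$site$altitude %||% 0,
    row_azimuth = doc$rows$azimuth,
    row_spacing = doc$rows$spacing,
    canopy_height = doc$rows$canopy_height,
    canopy_width = doc$rows$canopy_width,
    canopy_base_height = doc$rows$canopy_base_height %||% 0.6,
    slope = doc$site$slope %||% 0,
    aspect = doc$site$aspect %||% 0
  )
  soil <- pedotransfer(
    doc$soil$sand_pct, doc$soil$clay_pct, doc$soil$om_pct,
    depth_m = doc$soil$depth_m %||% 1
  )
  floor <- if (!is.null(doc$floor)) {
    zones <- do.call(rbind, lapply(doc$floor$zones, function(z) {
      data.frame(cover_class = z$cover_class, area_fraction = z$area_fraction)
    }))
    term <- doc$floor$termination_date
    floor_management(zones, if (is.null(term)) NULL else as.Date(term))
  } else {
    floor_management(
      data.frame(cover_class = "tilled", area_fraction = 1)
    )
  }
  structure(
    list(
      geometry = geometry, soil = soil, floor = floor,
      weather_path = doc$weather,
      extraction_threshold = doc$extraction_threshold %||% 0.5,
      seed = doc$seed %||% 1,
      output_dir = doc$output_dir %||% "."
    ),
    class = "run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a seasonal water balance
#'
#' Writes the daily balance as CSV (`date, precip_mm, ets_mm, tc_mm,
#' reservoir_mm, saw_pct, warning`) and the warning chronology as an
#' append-only transition log (`date, from, to`).
#'
#' @param balance A [run_season()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_balance <- function(balance, dir = ".", prefix = "balance") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  daily_path <- file.path(dir, paste0(prefix, "_daily.csv"))
  trans_path <- file.path(dir, paste0(prefix, "_warnings.csv"))
  days <- balance$days
  days$date <- format(days$date, "%Y-%m-%d")
  utils::write.csv(days, daily_path, row.names = FALSE, quote = FALSE)
  tr <- balance$transitions
  tr$date <- format(tr$date, "%Y-%m-%d")
  utils::write.csv(tr, trans_path, row.names = FALSE, quote = FALSE)
  invisible(c(daily = daily_path, transitions = trans_path))
}

#' Write a season report
#'
#' Human-readable text summary plus a machine-readable JSON with phenology
#' predictions per stage, the warning chronology and water-use totals.
#'
#' @param balance A [run_season()] result.
#' @param phenology Optional `data.frame` with `stage` and `predicted_doy`.
#' @param dir Output directory.
#' @return Paths of the two artifacts, invisibly.
#' @export
write_report <- function(balance, phenology = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  txt_path <- file.path(dir, "report.txt")
  json_path <- file.path(dir, "report.json")
  days <- balance$days
  totals <- list(
    days = nrow(days),
    precip_mm = sum(days$precip_mm),
    ets_mm = sum(days$ets_mm),
    tc_mm = sum(days$tc_mm),
    drainage_mm = sum(days$drainage_mm),
    unmet_mm = sum(days$unmet_mm),
    final_saw_pct = days$saw_pct[nrow(days)]
  )
  lines <- c(
    "Season report",
    sprintf("  period: %s to %s (%d days)",
      days$date[1], days$date[nrow(days)], nrow(days)
    ),
    sprintf("  reservoir capacity: %.1f mm", balance$capacity_mm),
    sprintf(
      "  totals: P %.1f, ETs %.1f, Tc %.1f, drainage %.1f mm",
      totals$precip_mm, totals$ets_mm, totals$tc_mm, totals$drainage_mm
    ),
    sprintf("  final SAW: %.1f%% (%s)",
      totals$final_saw_pct, days$warning[nrow(days)]
    )
  )
  if (nrow(balance$transitions) == 0) {
    lines <- c(lines, "  warnings: none (all-green season)")
  } else {
    lines <- c(lines, "  warnings:")
    lines <- c(lines, sprintf(
      "    %s: %s -> %s",
      balance$transitions$date, balance$transitions$from,
      balance$transitions$to
    ))
  }
  if (!is.null(phenology)) {
    lines <- c(lines, "  phenology predictions:")
    lines <- c(lines, sprintf(
      "    %s: DOY %s", phenology$stage,
      ifelse(is.na(phenology$predicted_doy), "no prediction",
        phenology$predicted_doy
      )
    ))
  }
  writeLines(lines, txt_path)
  tr <- balance$transitions
  tr$date <- format(tr$date, "%Y-%m-%d")
  doc <- list(
    totals = totals,
    warnings = tr,
    phenology = phenology
  )
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(text = txt_path, json = json_path))
}
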