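#' Write a trial to a TRC marker file
#'
#' Writes the OpenSim-dialect TRC format: a tab-separated header carrying
#' `DataRate`/`NumFrames`/`Units`, a marker-name row, and one row per frame
#' with `Frame#`, `Time` and X/Y/Z triplets. Marker columns are named
#' `L_<marker>` / `R_<marker>`. Coordinates are written in the package's
#' lab frame (+X anterior, +Y left, +Z up) in metres; missing samples are
#' written as empty fields.
#'
#' @param trial A [marker_trial()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_trc <- function(trial, path) {
  pres <- trial_markers(trial)
  keys <- paste(ifelse(pres$side == "left", "L", "R"), pres$marker, sep = "_")
  n <- trial$frame_count
  time <- (seq_len(n) - 1) / trial$sampling_rate
  mats <- purrr::map2(pres$marker, pres$side, function(m, s) marker_xyz(trial, m, s))

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines(paste(c("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                     "Units", "OrigDataRate", "OrigDataStartFrame",
                     "OrigNumFrames"), collapse = "\t"), con)
  writeLines(paste(c(format(trial$sampling_rate), format(trial$sampling_rate),
                     n, length(keys), "m", format(trial$sampling_rate), 1, n),
                   collapse = "\t"), con)
  writeLines(paste(c("Frame#", "Time", purrr::map_chr(keys, ~ paste0(.x, "\t\t"))),
                   collapse = "\t"), con)
  writeLines(paste(c("", "", purrr::imap_chr(keys, function(k, i) {
    paste(paste0(c("X", "Y", "Z"), i), collapse = "\t")
  })), collapse = "\t"), con)
  num <- function(v) ifelse(is.na(v), "", sprintf("%.9f", v))
  body <- vapply(seq_len(n), function(i) {
    cells <- unlist(lapply(mats, function(m) num(m[i, ])))
    paste(c(i, sprintf("%.5f", time[i]), cells), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Write a trial to a long-format CSV
#'
#' Columns: `trial_id`, `time_s`, `marker`, `side`, `x`, `y`, `z` (metres).
#' Trial metadata (participant, group, paretic side, belt speed, sampling
#' rate, units, axis convention) is stored in `#key=value` comment lines.
#'
#' @param trial A [marker_trial()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#participant_id=%s", trial$participant_id),
    sprintf("#group=%s", trial$group),
    sprintf("#paretic_side=%s", trial$paretic_side),
    sprintf("#belt_speed=%g", trial$belt_speed),
    sprintf("#sampling_rate=%g", trial$sampling_rate),
    "#units=m",
    "#axes=+X anterior, +Y left, +Z up"
  ), con)
  d <- trial$data
  d$trial_id <- trial$participant_id
  utils::write.csv(d[, c("trial_id", "time_s", "marker", "side", "x", "y", "z")],
                   con, row.names = FALSE)
  invisible(path)
}

#' Read a marker trial from TRC or long CSV
#'
#' Axes are remapped to the internal convention (+X anterior, +Y left,
#' +Z up) via `axis_map`, units converted to metres when the file header
#' declares millimetres, marker names normalized via `marker_name_map`, and
#' missing samples flagged as `NA`. A trial missing some markers (for
#' example both iliac crests) still loads; the affected metrics are later
#' reported missing.
#'
#' @param path File to read.
#' @param format `"trc"`, `"csv"`, or `"c3d"`. C3D is an optional runtime
#'   feature; no reader backend ships with this package, so requesting it
#'   signals an informative error. Text formats are first-class.
#' @param axis_map Named character vector mapping internal axes to file
#'   axes with optional sign, e.g. `c(x = "y", y = "-x", z = "z")`.
#' @param marker_name_map Named character vector mapping file marker names
#'   (without side prefix) to internal names; defaults to identity for the
#'   standard set.
#' @param participant_id,group,paretic_side,belt_speed Metadata overrides;
#'   defaults come from the file where available.
#' @return A [marker_trial()].
#' @export
read_trial <- function(path, format = c("trc", "csv", "c3d"),
                       axis_map = c(x = "x", y = "y", z = "z"),
                       marker_name_map = NULL,
                       participant_id = NULL, group = NULL,
                       paretic_side = NULL, belt_speed = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "c3d") {
    stop("C3D input is an optional feature without a bundled reader; ",
         "export the trial to TRC or long CSV instead")
  }
  raw <- switch(format, trc = read_trc_raw(path), csv = read_csv_raw(path))
  data <- raw$data
  # unit conversion
  if (tolower(raw$units) %in% c("mm", "millimeter", "millimeters")) {
    data$x <- data$x / 1000; data$y <- data$y / 1000; data$z <- data$z / 1000
  }
  # axis remap (orthonormal: permutation with signs)
  ax <- parse_axis_map(axis_map)
  remapped <- data
  for (axis in c("x", "y", "z")) {
    remapped[[axis]] <- ax[[axis]]$sign * data[[ax[[axis]]$src]]
  }
  data <- remapped
  # marker name normalization
  if (!is.null(marker_name_map)) {
    hit <- data$marker %in% names(marker_name_map)
    data$marker[hit] <- unname(marker_name_map[data$marker[hit]])
  }
  data <- data[data$marker %in% GAIT_MARKERS, ]
  if (!any(data$marker == "lateral_malleolus")) {
    stop("required markers absent after mapping: no lateral_malleolus series")
  }
  counts <- dplyr::count(data, .data$marker, .data$side)
  if (length(unique(counts$n)) > 1) {
    stop("frame-count mismatch among marker series")
  }
  meta <- raw$meta
  marker_trial(
    data,
    participant_id = participant_id %||% meta$participant_id %||% basename(path),
    group = group %||% meta$group %||% "neurotypical",
    paretic_side = paretic_side %||% meta$paretic_side %||% "none",
    belt_speed = belt_speed %||% meta$belt_speed %||% 1,
    sampling_rate = raw$sampling_rate
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_axis_map <- function(axis_map) {
  stopifnot(all(c("x", "y", "z") %in% names(axis_map)))
  out <- lapply(axis_map, function(spec) {
    spec <- gsub(" ", "", tolower(spec))
    sign <- if (startsWith(spec, "-")) -1 else 1
    src <- sub("^[+-]", "", spec)
    if (!src %in% c("x", "y", "z")) stop("axis map entries must be one of x, y, z")
    list(sign = sign, src = src)
  })
  srcs <- vapply(out, function(o) o$src, character(1))
  if (length(unique(srcs)) != 3) stop("axis map must be a permutation of x, y, z")
  out[c("x", "y", "z")]
}

read_trc_raw <- function(path) {
  lines <- readLines(path)
  hdr_names <- strsplit(lines[2], "\t")[[1]]
  hdr_vals <- strsplit(lines[3], "\t")[[1]]
  hdr <- stats::setNames(as.list(hdr_vals), hdr_names)
  rate <- as.numeric(hdr$DataRate)
  units <- hdr$Units %||% "m"
  marker_row <- strsplit(lines[4], "\t")[[1]]
  keys <- marker_row[marker_row != "" & !marker_row %in% c("Frame#", "Time")]
  body <- lines[-(1:5)]
  body <- body[nzchar(body)]
  cells <- strsplit(body, "\t")
  n <- length(cells)
  data <- purrr::imap_dfr(keys, function(k, j) {
    side <- if (startsWith(k, "L_")) "left" else "right"
    name <- sub("^[LR]_", "", k)
    col0 <- 2 + (j - 1) * 3
    get <- function(off) vapply(cells, function(r) {
      v <- if (length(r) >= col0 + off) r[col0 + off] else ""
      if (v == "" || is.na(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
    tibble::tibble(frame = seq_len(n), time_s = (seq_len(n) - 1) / rate,
                   marker = name, side = side,
                   x = get(1), y = get(2), z = get(3))
  })
  list(data = data, sampling_rate = rate, units = units, meta = list())
}

read_csv_raw <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  d <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                       stringsAsFactors = FALSE)
  needed <- c("time_s", "marker", "side", "x", "y", "z")
  if (!all(needed %in% names(d))) {
    stop("long CSV must have columns: trial_id, ", paste(needed, collapse = ", "))
  }
  rate <- as.numeric(meta$sampling_rate %||% NA)
  if (!is.finite(rate)) {
    dt <- diff(sort(unique(d$time_s)))
    rate <- 1 / stats::median(dt)
  }
  d <- dplyr::group_by(d, .data$marker, .data$side)
  d <- dplyr::mutate(d, frame = dplyr::row_number())
  d <- dplyr::ungroup(d)
  meta_out <- list(
    participant_id = meta$participant_id,
    group = meta$group, paretic_side = meta$paretic_side,
    belt_speed = as.numeric(meta$belt_speed %||% NA)
  )
  if (!is.finite(meta_out$belt_speed %||% NA)) meta_out$belt_speed <- NULL
  list(data = tibble::as_tibble(d[, c("frame", "time_s", "marker", "side", "x", "y", "z")]),
       sampling_rate = rate, units = meta$units %||% "m", meta = meta_out)
}

#' Write ground truth as a JSON sidecar
#'
#' @param truth The `truth` element returned by [generate_trial()].
#' @param path Destination `.json` file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(
    params = unclass(truth$params),
    events = truth$events,
    metrics = as.list(truth$metrics)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a participant metadata table
#'
#' Expects a CSV with columns `participant_id`, `group`, `paretic_side`,
#' `age`, `le_fugl_meyer` and either a semicolon-separated `speeds` column
#' or `speed_1`, `speed_2`, ... columns (empty cells for sessions with
#' fewer speeds). An optional logical `standing_calibration` column feeds
#' the inclusion filter.
#'
#' @param path CSV file.
#' @return Tibble with one row per participant and a `speeds` list column.
#' @export
read_metadata <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", "", "-", "–"))
  if (!"participant_id" %in% names(d)) stop("metadata needs a participant_id column")
  if (anyDuplicated(d$participant_id)) {
    stop("duplicate participant_id in metadata: ",
         paste(unique(d$participant_id[duplicated(d$participant_id)]), collapse = ", "))
  }
  if ("le_fugl_meyer" %in% names(d)) {
    bad <- !is.na(d$le_fugl_meyer) & (d$le_fugl_meyer < 0 | d$le_fugl_meyer > 34)
    if (any(bad)) {
      stop("le_fugl_meyer out of the 0-34 range for participant(s): ",
           paste(d$participant_id[bad], collapse = ", "))
    }
  }
  out <- tibble::as_tibble(d)
  if (!"speeds" %in% names(out)) {
    cols <- grep("^speed_", names(out), value = TRUE)
    if (length(cols) == 0) stop("metadata needs a speeds column or speed_* columns")
    out$speeds <- purrr::map(seq_len(nrow(out)), function(i) {
      v <- suppressWarnings(as.numeric(unlist(out[i, cols])))
      v[is.finite(v)]
    })
  } else if (is.character(out$speeds)) {
    out$speeds <- purrr::map(strsplit(out$speeds, ";"), function(v) {
      v <- suppressWarnings(as.numeric(v)); v[is.finite(v)]
    })
  }
  empty <- lengths(out$speeds) == 0
  if (any(empty)) {
    stop("no valid speeds for participant(s): ",
         paste(out$participant_id[empty], collapse = ", "))
  }
  if (any(unlist(out$speeds) <= 0)) stop("speeds must be positive")
  out
}

METRICS_TABLE_COLUMNS <- c("participant_id", "group", "speed_mps", "sla",
                           "dlsta", "slsta", "knee_flex_deg", "tla_deg",
                           "circumduction_m", "hip_hike_deg", "n_strides")

#' Write a gait-metrics table
#'
#' Long CSV with one row per participant-speed observation and the fixed
#' column order `participant_id, group, speed_mps, sla, dlsta, slsta,
#' knee_flex_deg, tla_deg, circumduction_m, hip_hike_deg, n_strides`.
#' Missing metrics are written as empty fields.
#'
#' @param records Tibble of metric records (e.g. rows from
#'   [compute_gait_metrics()], or [cohort_metrics()] output with a `speed`
#'   column).
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(records, path) {
  records <- tibble::as_tibble(records)
  if ("speed" %in% names(records) && !"speed_mps" %in% names(records)) {
    records$speed_mps <- records$speed
  }
  if (nrow(records) > 0) {
    if (!"n_strides" %in% names(records)) records$n_strides <- NA_integer_
    missing_cols <- setdiff(METRICS_TABLE_COLUMNS, names(records))
    if (length(missing_cols) > 0) {
      stop("records lack required columns: ", paste(missing_cols, collapse = ", "))
    }
    key <- paste(records$participant_id, records$speed_mps)
    if (anyDuplicated(key)) {
      stop("duplicate (participant, speed) rows: ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
    }
    records <- records[, METRICS_TABLE_COLUMNS]
  } else {
    records <- tibble::as_tibble(stats::setNames(
      rep(list(numeric(0)), length(METRICS_TABLE_COLUMNS)), METRICS_TABLE_COLUMNS))
  }
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a gait-metrics table written by [write_metrics_table()]
#'
#' @param path CSV file.
#' @return Tibble with the metrics-table schema (empty cells as `NA`).
#' @export
read_metrics_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  tibble::as_tibble(d)
}

#' Read a lab mapping configuration (YAML)
#'
#' Different motion-capture set-ups use different axis conventions and
#' marker names; a small YAML file with `axis_map` and `marker_name_map`
#' blocks adapts them to the internal convention.
#'
#' @param path YAML file with optional `axis_map` (named x/y/z entries) and
#'   `marker_name_map` (file-name: internal-name pairs).
#' @return List with `axis_map` and `marker_name_map` ready for
#'   [read_trial()].
#' @export
read_mapping_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  axis_map <- c(x = "x", y = "y", z = "z")
  if (!is.null(cfg$axis_map)) {
    # YAML 1.1 parses a bare y (key or value) as a boolean; map those back
    am <- vapply(cfg$axis_map, function(v) {
      if (isTRUE(v)) "y" else if (isFALSE(v)) "n" else as.character(v)
    }, character(1))
    nm <- names(am)
    nm[nm == "TRUE"] <- "y"; nm[nm == "FALSE"] <- "n"
    names(am) <- nm
    axis_map[nm] <- am
  }
  marker_name_map <- NULL
  if (!is.null(cfg$marker_name_map)) {
    marker_name_map <- unlist(cfg$marker_name_map)
  }
  list(axis_map = axis_map, marker_name_map = marker_name_map)
}
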