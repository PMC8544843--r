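#' Write a trial to the canonical long-format CSV
#'
#' Serializes a [trial3d()] or [trial2d()] to a self-describing CSV: a
#' metadata header block of `# key: value` lines followed by long-format
#' rows `frame, time_s, marker, axis, value`. Values are written with full
#' (17 significant digit) precision so that write-then-read round-trips are
#' exact; missing samples are serialized as empty fields and restored as
#' `NA`. Column and row order are deterministic (markers in input order,
#' axes X/Y/Z or h/v).
#'
#' @param trial A `trial3d` or `trial2d`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "trial3d") || inherits(trial, "trial2d"))
  meta <- trial$meta
  side <- if (inherits(trial, "trial3d")) "3d" else "2d"
  hdr <- c(
    "# fallkin_trial: 1",
    paste0("# side: ", side),
    paste0("# trial_id: ", meta$trial_id),
    paste0("# direction: ", meta$direction),
    paste0("# initiation: ", meta$initiation),
    paste0("# participant_height_m: ", sprintf("%.17g", meta$participant_height)),
    paste0("# fall_start_frame: ", meta$fall_start_frame),
    paste0("# fall_end_frame: ", meta$fall_end_frame),
    paste0("# sample_rate_hz: ", sprintf("%.17g", meta$sample_rate))
  )
  if (side == "2d") {
    hdr <- c(hdr,
             paste0("# camera_angle_deg: ", sprintf("%.17g", trial$camera_angle)),
             paste0("# unit: ", trial$unit),
             paste0("# resolution: ", paste(trial$resolution, collapse = "x")))
  }
  axes <- if (side == "3d") c("X", "Y", "Z") else c("h", "v")
  n <- trial$n_frames
  time_s <- (seq_len(n) - 1L) / meta$sample_rate
  rows <- lapply(names(trial$markers), function(mk) {
    m <- trial$markers[[mk]]
    do.call(rbind, lapply(seq_along(axes), function(j) {
      data.frame(frame = seq_len(n) - 1L, time_s = time_s, marker = mk,
                 axis = axes[j], value = m[, j], stringsAsFactors = FALSE)
    }))
  })
  long <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("frame,time_s,marker,axis,value", con)
  val <- ifelse(is.na(long$value), "", sprintf("%.17g", long$value))
  writeLines(sprintf("%d,%.17g,%s,%s,%s", long$frame, long$time_s,
                     long$marker, long$axis, val), con)
  invisible(path)
}

read_header_block <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", hdr))
  keys <- vapply(kv, function(x) if (length(x) == 3) x[2] else NA_character_,
                 character(1))
  vals <- vapply(kv, function(x) if (length(x) == 3) x[3] else NA_character_,
                 character(1))
  stats::setNames(as.list(vals[!is.na(keys)]), keys[!is.na(keys)])
}

#' Read a trial from the canonical long-format CSV
#'
#' Inverse of [write_trial_csv()].
#'
#' @param path File written by [write_trial_csv()].
#' @return A `trial3d` or `trial2d` according to the file's `side` field.
#' @export
read_trial_csv <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  meta_kv <- read_header_block(lines)
  if (is.null(meta_kv$fallkin_trial)) {
    stop("not a fallkin canonical trial CSV: ", path)
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE,
                        colClasses = c(frame = "integer", time_s = "numeric",
                                       marker = "character", axis = "character",
                                       value = "numeric"))
  side <- meta_kv$side
  meta <- trial_meta(
    trial_id = meta_kv$trial_id, direction = meta_kv$direction,
    initiation = meta_kv$initiation,
    participant_height = as.numeric(meta_kv$participant_height_m),
    fall_start_frame = as.integer(meta_kv$fall_start_frame),
    fall_end_frame = as.integer(meta_kv$fall_end_frame),
    sample_rate = as.numeric(meta_kv$sample_rate_hz)
  )
  axes <- if (side == "3d") c("X", "Y", "Z") else c("h", "v")
  mks <- unique(df$marker)
  n <- max(df$frame) + 1L
  markers <- lapply(mks, function(mk) {
    sub <- df[df$marker == mk, ]
    m <- matrix(NA_real_, n, length(axes), dimnames = list(NULL, axes))
    for (ax in axes) {
      sa <- sub[sub$axis == ax, ]
      m[sa$frame + 1L, ax] <- sa$value
    }
    m
  })
  names(markers) <- mks
  if (side == "3d") {
    trial3d(meta, markers)
  } else {
    res <- if (!is.null(meta_kv$resolution)) {
      as.numeric(strsplit(meta_kv$resolution, "x")[[1]])
    } else c(640, 480)
    trial2d(meta, markers, camera_angle = as.numeric(meta_kv$camera_angle_deg),
            unit = meta_kv$unit, resolution = res)
  }
}

#' Declarative layout for wide-format trial sheets
#'
#' Describes how marker trajectories are laid out in a supplementary-style
#' sheet: a header row of `marker_AXIS` columns (e.g. `head_X`, `knee_Z`),
#' optionally preceded by `key: value` annotation rows carrying the trial
#' metadata and event frames.
#'
#' @param header_row 1-based row index of the column-name row (annotation
#'   rows above it are parsed as `key: value` metadata).
#' @param pattern Column naming pattern; only `"{marker}_{axis}"` is
#'   currently supported.
#' @param ignore Column names to skip (e.g. frame counters).
#' @return A layout descriptor list.
#' @export
workbook_layout <- function(header_row = 1L,
                            pattern = "{marker}_{axis}",
                            ignore = c("frame", "time", "time_s")) {
  stopifnot(identical(pattern, "{marker}_{axis}"))
  list(header_row = as.integer(header_row), pattern = pattern,
       ignore = tolower(ignore))
}

parse_wide_sheet <- function(df, sheet, side, meta_kv, layout) {
  axes <- if (side == "3d") c("X", "Y", "Z") else c("X", "Z")
  nm <- names(df)
  keep <- !(tolower(nm) %in% layout$ignore)
  df <- df[, keep, drop = FALSE]
  nm <- names(df)
  mm <- regmatches(nm, regexec("^(.*)_([XYZxyz])$", nm))
  bad <- vapply(mm, length, integer(1)) != 3L
  if (any(bad)) {
    stop("sheet '", sheet, "': column(s) not matching marker_AXIS pattern: ",
         paste(nm[bad], collapse = ", "))
  }
  marker_raw <- vapply(mm, `[`, character(1), 2L)
  axis <- toupper(vapply(mm, `[`, character(1), 3L))
  markers_canon <- normalize_marker_label(marker_raw)
  # numeric coercion with cell-level error reporting
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad_cell <- which(!is.na(v) & v != "" & is.na(coerced))
      if (length(bad_cell)) {
        stop("sheet '", sheet, "': non-numeric cell at row ",
             bad_cell[1] + 1L, ", column '", nm[j], "' (value '",
             v[bad_cell[1]], "')")
      }
      df[[j]] <- coerced
    }
  }
  n <- nrow(df)
  out <- list()
  for (mk in unique(markers_canon)) {
    cols <- which(markers_canon == mk)
    have <- axis[cols]
    missing_ax <- setdiff(axes, have)
    if (length(missing_ax)) {
      stop("sheet '", sheet, "': marker '", mk, "' missing axis column(s): ",
           paste(missing_ax, collapse = ", "))
    }
    m <- matrix(NA_real_, n, length(axes))
    for (k in seq_along(axes)) m[, k] <- df[[cols[match(axes[k], have)]]]
    out[[mk]] <- m
  }
  req <- c("trial_id", "direction", "initiation", "participant_height_m",
           "sample_rate_hz")
  miss <- setdiff(req, names(meta_kv))
  if (length(miss)) {
    stop("sheet '", sheet, "': missing metadata: ", paste(miss, collapse = ", "))
  }
  if (is.null(meta_kv$fall_start_frame) || is.null(meta_kv$fall_end_frame)) {
    stop("sheet '", sheet, "': events absent (no fall_start_frame/",
         "fall_end_frame annotation or sidecar metadata)")
  }
  meta <- trial_meta(meta_kv$trial_id, meta_kv$direction, meta_kv$initiation,
                     as.numeric(meta_kv$participant_height_m),
                     as.integer(meta_kv$fall_start_frame),
                     as.integer(meta_kv$fall_end_frame),
                     as.numeric(meta_kv$sample_rate_hz))
  if (side == "3d") {
    trial3d(meta, out)
  } else {
    unit <- if (!is.null(meta_kv$unit)) meta_kv$unit else "metre"
    angle <- if (!is.null(meta_kv$camera_angle_deg)) {
      as.numeric(meta_kv$camera_angle_deg)
    } else 90
    # wide 2D sheets carry X (horizontal) and Z (vertical-up) in that order
    trial2d(meta, out, camera_angle = angle, unit = unit)
  }
}

sidecar_meta_for <- function(meta, sheet) {
  if (is.null(meta)) return(list())
  stopifnot(is.data.frame(meta), "sheet" %in% names(meta))
  row <- meta[meta$sheet == sheet, , drop = FALSE]
  if (nrow(row) == 0) return(list())
  as.list(row[1, setdiff(names(row), "sheet"), drop = FALSE])
}

#' Read a multi-fall trial workbook
#'
#' Reads a workbook in which each sheet holds one fall, in either of two
#' physical forms: an `.xlsx` file (one worksheet per fall; requires the
#' `readxl` package) or a directory of per-sheet CSV files. Sheets may be in
#' the package's canonical long format (as written by [write_trial_csv()])
#' or in the wide supplementary-style layout described by
#' [workbook_layout()], with metadata taken from `key: value` annotation
#' rows above the header or from a sidecar metadata table. Event frames must
#' be present; trials without them raise an "events absent" error rather
#' than defaulting silently.
#'
#' @param path Path to an `.xlsx` workbook or a directory of `.csv` sheets.
#' @param side `"3d"` or `"2d"`: which kind of trial the sheets hold.
#' @param layout A [workbook_layout()] for wide-format sheets.
#' @param meta Optional sidecar metadata data frame with a `sheet` column
#'   plus `trial_id`, `direction`, `initiation`, `participant_height_m`,
#'   `fall_start_frame`, `fall_end_frame`, `sample_rate_hz` (and for 2D,
#'   `camera_angle_deg`, `unit`).
#' @return List of [trial3d()] or [trial2d()] objects, one per sheet.
#' @export
read_trial_workbook <- function(path, side = c("3d", "2d"),
                                layout = workbook_layout(), meta = NULL) {
  side <- match.arg(side)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    if (!length(files)) stop("no .csv sheets found in ", path)
    trials <- lapply(files, function(f) {
      first <- readLines(f, n = 1L)
      if (grepl("^#\\s*fallkin_trial", first)) return(read_trial_csv(f))
      sheet <- sub("\\.csv$", "", basename(f))
      lines <- readLines(f)
      kv <- read_header_block(lines)
      body <- lines[!grepl("^#", lines)]
      df <- utils::read.csv(text = paste(body, collapse = "\n"),
                            stringsAsFactors = FALSE, check.names = FALSE)
      kv <- utils::modifyList(kv, sidecar_meta_for(meta, sheet))
      parse_wide_sheet(df, sheet, side, kv, layout)
    })
  } else if (grepl("\\.xlsx$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx workbooks requires the 'readxl' package")
    }
    sheets <- readxl::excel_sheets(path)
    trials <- lapply(sheets, function(sheet) {
      raw <- readxl::read_excel(path, sheet = sheet, col_names = FALSE,
                                .name_repair = "minimal")
      hr <- layout$header_row
      kv <- list()
      if (hr > 1L) {
        ann <- raw[seq_len(hr - 1L), 1:2]
        keys <- sub(":$", "", trimws(as.character(ann[[1]])))
        vals <- trimws(as.character(ann[[2]]))
        kv <- stats::setNames(as.list(vals[!is.na(keys) & keys != ""]),
                              keys[!is.na(keys) & keys != ""])
      }
      header <- as.character(unlist(raw[hr, ]))
      body <- raw[-seq_len(hr), , drop = FALSE]
      keep <- !is.na(header) & header != ""
      df <- as.data.frame(body[, keep, drop = FALSE])
      names(df) <- header[keep]
      kv <- utils::modifyList(kv, sidecar_meta_for(meta, sheet))
      parse_wide_sheet(df, sheet, side, kv, layout)
    })
  } else {
    stop("path must be an .xlsx workbook or a directory of .csv sheets: ",
         path)
  }
  names(trials) <- vapply(trials, function(t) t$meta$trial_id, character(1))
  trials
}

#' Write a batch of trials as a CSV workbook directory
#'
#' The directory form of the package's workbook: one canonical long-format
#' CSV per fall, readable back with [read_trial_workbook()]. Synthetic and
#' supplementary data are thereby interchangeable inputs.
#'
#' @param trials List of `trial3d`/`trial2d` objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_workbook <- function(trials, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(trials)) {
    id <- trials[[i]]$meta$trial_id
    write_trial_csv(trials[[i]], file.path(dir, paste0(id, ".csv")))
  }
  invisible(dir)
}

config_defaults <- function() {
  list(
    cutoffs = c(3, 5, 7, 10, 12, 14),
    ground_truth_cutoff = 20,
    camera_angles = c(30, 60, 90),
    calibration = "grid2d",
    grid_translation = 0,
    grid_rotation = 0,
    height_error = 0,
    noise_px = 1,
    seed = 1,
    n_trials = 36,
    out_dir = "."
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration and merges it over the defaults
#' (video-side cutoffs 3, 5, 7, 10, 12, 14 Hz; 20 Hz ground-truth cutoff;
#' camera angles 30/60/90 degrees; 2D grid calibration). Unknown keys are
#' rejected by name. Video-side cutoffs above 14 Hz are rejected: 14 Hz is
#' the Nyquist-safe maximum for 30 Hz video.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for pure
#'   defaults.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    stopifnot(file.exists(path))
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    }
    cfg <- utils::modifyList(cfg, user)
  }
  if (any(cfg$cutoffs > 14)) {
    stop("video-side cutoff(s) ", paste(cfg$cutoffs[cfg$cutoffs > 14],
         collapse = ", "),
         " Hz exceed the Nyquist-safe 14 Hz maximum for 30 Hz video")
  }
  if (any(cfg$cutoffs <= 0)) stop("cutoffs must be positive")
  if (!cfg$calibration %in% c("grid2d", "line1d")) {
    stop("calibration must be 'grid2d' or 'line1d'")
  }
  if (!all(cfg$camera_angles %in% c(30, 60, 90))) {
    stop("camera_angles must be drawn from 30, 60, 90")
  }
  if (abs(cfg$grid_translation) > 0.5) {
    stop("grid_translation outside the supported +/-0.5 m range")
  }
  if (abs(cfg$grid_rotation) > 45) {
    stop("grid_rotation outside the supported +/-45 degree range")
  }
  cfg
}
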