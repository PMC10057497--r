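#' Construct a swing trial from a wide marker table
#'
#' A swing trial is a tibble with one row per frame and columns `frame`,
#' `time` plus `<MARKER>_x/_y/_z` for the eight required markers (pelvis:
#' LASIS, RASIS, LPSIS, RPSIS; thorax: LACR, RACR; club: CLUB_GRIP,
#' CLUB_HEAD), positions in metres in a lab frame whose X axis is the
#' target line and whose Z axis is vertical. Participant id, trial index
#' and sample rate travel as attributes.
#'
#' @param data data frame with the columns described above.
#' @param participant_id participant identifier.
#' @param trial_index trial number within participant (>= 1).
#' @param sample_rate sampling rate in Hz.
#' @return a `swing_trial` tibble.
#' @export
swing_trial <- function(data, participant_id, trial_index, sample_rate = 200) {
  out <- as_tibble(data)
  need <- c("frame", "time", marker_cols())
  missing <- setdiff(need, names(out))
  if (length(missing) > 0) {
    abort(paste0("trial is missing column(s): ", paste(missing, collapse = ", ")),
          class = "golfswing_format_error")
  }
  out <- out[, need]
  if (nrow(out) < 2) abort("trial must have at least 2 frames")
  if (sample_rate <= 0) abort("sample_rate must be positive")
  bad <- !vapply(out[marker_cols()], function(v) all(is.finite(v)), logical(1))
  if (any(bad)) {
    abort(paste0("non-finite coordinates in: ",
                 paste(unique(sub("_[xyz]$", "", names(bad)[bad])), collapse = ", ")),
          class = "golfswing_quality_error")
  }
  structure(out,
            participant_id = as.character(participant_id),
            trial_index = as.integer(trial_index),
            sample_rate = sample_rate,
            class = c("swing_trial", class(out)))
}

#' @export
print.swing_trial <- function(x, ...) {
  cat(sprintf("<swing_trial> participant %s, trial %d, %d frames @ %g Hz\n",
              attr(x, "participant_id"), attr(x, "trial_index"),
              nrow(x), attr(x, "sample_rate")))
  NextMethod()
}

trial_sample_rate <- function(trial) attr(trial, "sample_rate")

#' Ground truth attached to a synthetic trial
#'
#' Returns the generator's analytic ground truth (event frames and swing
#' parameters) stored on a trial produced by [generate_trial()], or `NULL`
#' for trials read from disk.
#'
#' @param trial a `swing_trial`.
#' @return a list with elements `events` and `parameters`, or `NULL`.
#' @export
ground_truth <- function(trial) attr(trial, "ground_truth")

#' Read one trial from a marker CSV
#'
#' Expects a header with `frame` and/or `time` plus `<MARKER>_x/_y/_z`
#' columns for all eight markers, in any column order. The sample rate is
#' inferred from the time column when present, otherwise `sample_rate`
#' must be supplied. Up to 10% missing samples per marker are linearly
#' interpolated (with a warning); more is an error.
#'
#' @param path CSV file path.
#' @param participant_id,trial_index identifiers stored on the trial;
#'   default to values parsed from a `{participant_id}_{trial}.csv` name.
#' @param sample_rate sampling rate in Hz; inferred from `time` if `NULL`.
#' @param units `"m"` (default) or `"mm"`; millimetre inputs are converted.
#' @return a [swing_trial()].
#' @export
read_trial <- function(path, participant_id = NULL, trial_index = NULL,
                       sample_rate = NULL, units = c("m", "mm")) {
  units <- match.arg(units)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)

  for (m in SWING_MARKERS) {
    miss <- setdiff(paste0(m, "_", c("x", "y", "z")), names(raw))
    if (length(miss) > 0) {
      abort(paste0("marker ", m, " incomplete: missing ", paste(miss, collapse = ", ")),
            class = "golfswing_format_error")
    }
  }
  n <- nrow(raw)
  if (!"time" %in% names(raw)) {
    if (is.null(sample_rate)) {
      abort("file has no time column and no sample_rate was given",
            class = "golfswing_format_error")
    }
    raw$time <- (seq_len(n) - 1) / sample_rate
  } else {
    dt <- diff(raw$time)
    if (any(!is.finite(dt)) || any(dt <= 0)) {
      abort("time column is not strictly increasing", class = "golfswing_format_error")
    }
    if (is.null(sample_rate)) sample_rate <- 1 / stats::median(dt)
  }
  if (!"frame" %in% names(raw)) raw$frame <- seq_len(n)

  # gap policy: per marker, reject > 10% missing, interpolate otherwise
  for (m in SWING_MARKERS) {
    cols <- paste0(m, "_", c("x", "y", "z"))
    na_frac <- max(vapply(raw[cols], function(v) mean(!is.finite(v)), numeric(1)))
    if (na_frac > 0.10) {
      abort(sprintf("marker %s has %.1f%% missing samples (limit 10%%)",
                    m, 100 * na_frac),
            class = "golfswing_quality_error")
    }
    if (na_frac > 0) {
      warn(sprintf("marker %s: interpolating %.2f%% missing samples", m, 100 * na_frac))
      for (cc in cols) {
        v <- raw[[cc]]
        v[!is.finite(v)] <- NA_real_
        raw[[cc]] <- zoo::na.approx(v, x = raw$time, na.rm = FALSE, rule = 2)
      }
    }
  }
  if (units == "mm") {
    for (cc in marker_cols()) raw[[cc]] <- raw[[cc]] / 1000
  }

  if (is.null(participant_id) || is.null(trial_index)) {
    stem <- sub("\\.csv$", "", basename(path))
    parts <- regmatches(stem, regexec("^(.*)_([0-9]+)$", stem))[[1]]
    if (length(parts) == 3) {
      if (is.null(participant_id)) participant_id <- parts[2]
      if (is.null(trial_index)) trial_index <- as.integer(parts[3])
    } else {
      if (is.null(participant_id)) participant_id <- stem
      if (is.null(trial_index)) trial_index <- 1L
    }
  }
  swing_trial(raw, participant_id, trial_index, sample_rate)
}

#' Write a trial to CSV
#'
#' Inverse of [read_trial()]; numeric values survive the round trip at
#' full double precision.
#'
#' @param trial a `swing_trial`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  readr::write_csv(as_tibble(trial), path, progress = FALSE)
  invisible(path)
}

#' Assemble a cohort of participants and trials
#'
#' @param participants tibble with columns `participant_id` and `sex`
#'   (`"F"` or `"M"`).
#' @param trials list of [swing_trial()] objects.
#' @return a `swing_cohort` list with elements `participants` and `trials`.
#' @export
swing_cohort <- function(participants, trials) {
  participants <- as_tibble(participants)
  stopifnot(all(c("participant_id", "sex") %in% names(participants)))
  participants$participant_id <- as.character(participants$participant_id)
  if (anyDuplicated(participants$participant_id)) {
    abort("duplicate participant_id in metadata")
  }
  bad_sex <- setdiff(unique(participants$sex), c("F", "M"))
  if (length(bad_sex) > 0) {
    abort(paste0("invalid sex value(s): ", paste(bad_sex, collapse = ", ")))
  }
  ids <- vapply(trials, attr, character(1), "participant_id")
  idx <- vapply(trials, attr, integer(1), "trial_index")
  orphans <- setdiff(ids, participants$participant_id)
  if (length(orphans) > 0) {
    abort(paste0("trial(s) reference unknown participant(s): ",
                 paste(unique(orphans), collapse = ", ")))
  }
  key <- paste(ids, idx, sep = "_")
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (participant, trial) pair(s): ",
                 paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  structure(list(participants = participants, trials = setNames(trials, key)),
            class = "swing_cohort")
}

#' @export
print.swing_cohort <- function(x, ...) {
  cat(sprintf("<swing_cohort> %d participants (%d F, %d M), %d trials\n",
              nrow(x$participants), sum(x$participants$sex == "F"),
              sum(x$participants$sex == "M"), length(x$trials)))
  invisible(x)
}

#' Read a directory of trial CSVs plus a metadata table
#'
#' Trial files must be named `{participant_id}_{trial_index}.csv`; the
#' metadata CSV needs columns `participant_id` and `sex`.
#'
#' @param trial_dir directory containing trial CSVs.
#' @param metadata_path metadata CSV path.
#' @inheritParams read_trial
#' @return a [swing_cohort()].
#' @export
read_cohort <- function(trial_dir, metadata_path, sample_rate = NULL,
                        units = c("m", "mm")) {
  units <- match.arg(units)
  files <- list.files(trial_dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[basename(files) != basename(metadata_path)]
  if (length(files) == 0) abort(paste0("no trial CSVs in ", trial_dir))
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE, progress = FALSE)
  trials <- lapply(files, read_trial, sample_rate = sample_rate, units = units)
  swing_cohort(meta, trials)
}

#' Write all analysis artifacts to a directory
#'
#' Emits `parameters.csv` (one row per trial), `crp_curves.csv` (one row
#' per curve, columns `node_001..node_200` plus alignment metadata),
#' `spm.json` and `stats.json`. All files are re-readable and round-trip
#' their numeric content exactly.
#'
#' @param results a `swing_analysis` bundle from [run_swing_analysis()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_results <- function(results, out_dir) {
  stopifnot(inherits(results, "swing_analysis"))
  if (nrow(results$parameters) == 0) abort("no parameters to write")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create directory ", out_dir))

  paths <- c(parameters = file.path(out_dir, "parameters.csv"),
             crp = file.path(out_dir, "crp_curves.csv"),
             spm = file.path(out_dir, "spm.json"),
             stats = file.path(out_dir, "stats.json"))
  readr::write_csv(results$parameters, paths[["parameters"]], progress = FALSE)
  readr::write_csv(results$crp, paths[["crp"]], progress = FALSE)

  spm <- results$spm
  spm_json <- list(
    t_trajectory = spm$t,
    threshold = spm$threshold,
    df = spm$df, fwhm = spm$fwhm, alpha = spm$alpha,
    n1 = spm$n1, n2 = spm$n2,
    clusters = if (nrow(spm$clusters) > 0) spm$clusters else list(),
    metadata = spm$metadata
  )
  jsonlite::write_json(spm_json, paths[["spm"]], auto_unbox = TRUE, digits = NA)
  stats_json <- list(
    descriptives = results$descriptives,
    anova = results$anova,
    correlations = results$correlations,
    normality = results$normality,
    config = results$config
  )
  jsonlite::write_json(stats_json, paths[["stats"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' Write a cohort to disk in the trial-directory layout
#'
#' Companion to [read_cohort()]: one CSV per trial named
#' `{participant_id}_{trial_index}.csv` plus `metadata.csv`, so a synthetic
#' cohort can be analysed through the same file-based entry point as
#' recorded data.
#'
#' @param cohort a [swing_cohort()].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "swing_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$participants, file.path(out_dir, "metadata.csv"),
                   progress = FALSE)
  for (tr in cohort$trials) {
    fn <- sprintf("%s_%d.csv", attr(tr, "participant_id"), attr(tr, "trial_index"))
    write_trial(tr, file.path(out_dir, fn))
  }
  invisible(out_dir)
}
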