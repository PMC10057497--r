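#' Pipeline configuration
#'
#' All tunables of the end-to-end analysis in one list; the full
#' configuration is embedded in every written artifact for provenance.
#'
#' @param alpha significance level for SPM and group tests.
#' @param cutoff_hz marker low-pass cutoff (Hz); `NULL` disables.
#' @param n_nodes CRP curve length after time normalization.
#' @param align_fraction position of the pelvis-maximum alignment node.
#' @param align_strategy `"split"` or `"shift"` (see
#'   [align_and_normalize()]).
#' @param sign_convention CRP sign convention (see [crp_series()]).
#' @param pad_fraction mirror-padding fraction for the Hilbert phase.
#' @param balance_seed optional seed to subsample the larger sex group
#'   before SPM.
#' @param target_direction +1 target at +X (right-handed), -1 flipped.
#' @param max_failure_rate abort threshold for the fraction of trials
#'   failing event detection.
#' @return a `swing_config` list.
#' @export
swing_config <- function(alpha = 0.05, cutoff_hz = 10, n_nodes = 200,
                         align_fraction = 0.5,
                         align_strategy = c("split", "shift"),
                         sign_convention = c("phase", "display"),
                         pad_fraction = 0.2, balance_seed = NULL,
                         target_direction = 1, max_failure_rate = 0.2) {
  align_strategy <- match.arg(align_strategy)
  sign_convention <- match.arg(sign_convention)
  stopifnot(alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "swing_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [swing_config()]
#'   arguments; missing keys take the defaults.
#' @return a `swing_config`.
#' @export
read_swing_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(swing_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(swing_config, vals)
}

#' Run the full swing analysis on a cohort
#'
#' For every trial: event detection, discrete parameters, and the
#' aligned, time-normalized pelvis-thorax CRP curve. Per-player means
#' feed descriptives, a one-way sex ANOVA with partial eta squared per
#' parameter, Pearson correlations of each parameter with club velocity
#' per sex, a Shapiro-Wilk screen, and a two-sample SPM t test on the
#' per-player mean CRP curves (girls vs boys). Trials failing event
#' detection are excluded and counted; more than
#' `config$max_failure_rate` of them aborts the run.
#'
#' @param cohort a [swing_cohort()] from [read_cohort()] or
#'   [generate_cohort()].
#' @param config a [swing_config()].
#' @return a `swing_analysis` list: `parameters`, `crp` (wide, one row
#'   per trial), `player_means`, `mean_crp` (one row per player),
#'   `descriptives`, `anova`, `correlations`, `normality`, `spm`,
#'   `excluded`, `config`.
#' @export
run_swing_analysis <- function(cohort, config = swing_config()) {
  stopifnot(inherits(cohort, "swing_cohort"))
  cfg <- config
  params <- list(); crps <- list(); excluded <- character()

  for (key in names(cohort$trials)) {
    trial <- cohort$trials[[key]]
    res <- tryCatch({
      angles <- segment_angles(trial, cutoff_hz = cfg$cutoff_hz)
      club <- club_speed_accel(trial, cutoff_hz = cfg$cutoff_hz)
      events <- detect_events(trial, cutoff_hz = cfg$cutoff_hz,
                              target_direction = cfg$target_direction)
      pars <- extract_parameters(angles, events, club)
      crp <- trial_crp(angles, events, n_out = cfg$n_nodes,
                       align_fraction = cfg$align_fraction,
                       sign_convention = cfg$sign_convention,
                       pad_fraction = cfg$pad_fraction,
                       strategy = cfg$align_strategy)
      list(pars = pars, crp = crp)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded <- c(excluded, key)
      next
    }
    id <- attr(trial, "participant_id"); ix <- attr(trial, "trial_index")
    params[[key]] <- dplyr::bind_cols(
      tibble(participant_id = id, trial_index = ix), res$pars)
    wide <- setNames(as.list(res$crp$crp_deg),
                     sprintf("node_%03d", res$crp$node))
    crps[[key]] <- dplyr::bind_cols(
      tibble(participant_id = id, trial_index = ix,
             align_node = attr(res$crp, "align_node"),
             sign_convention = cfg$sign_convention),
      as_tibble(wide))
  }

  n_total <- length(cohort$trials)
  if (length(excluded) / n_total > cfg$max_failure_rate) {
    abort(sprintf("event detection failed for %d of %d trials (limit %.0f%%): %s",
                  length(excluded), n_total, 100 * cfg$max_failure_rate,
                  paste(head(excluded, 10), collapse = ", ")))
  }
  parameters <- bind_rows(params)
  crp <- bind_rows(crps)

  means <- player_means(parameters, cohort$participants)
  node_cols <- grep("^node_", names(crp), value = TRUE)
  mean_crp <- crp %>%
    group_by(.data$participant_id) %>%
    summarise(across(all_of(node_cols), mean), .groups = "drop") %>%
    left_join(cohort$participants, by = "participant_id")

  curves_f <- as.matrix(mean_crp[mean_crp$sex == "F", node_cols])
  curves_m <- as.matrix(mean_crp[mean_crp$sex == "M", node_cols])
  spm <- spm_ttest2(curves_f, curves_m, alpha = cfg$alpha,
                    balance_seed = cfg$balance_seed)
  spm$metadata$curve_unit <- "per-player mean CRP"
  spm$metadata$align_node <- unique(crp$align_node)[1]

  anova_tbl <- bind_rows(lapply(PARAM_COLS, function(pm) {
    dplyr::bind_cols(tibble(parameter = pm),
                     oneway_anova(means[[pm]], means$sex))
  }))

  structure(list(
    parameters = parameters, crp = crp,
    player_means = means, mean_crp = mean_crp,
    descriptives = descriptives(means),
    anova = anova_tbl,
    correlations = gcv_correlations(means),
    normality = normality_screen(means, strict = FALSE),
    spm = spm,
    excluded = excluded,
    config = cfg[!vapply(cfg, is.null, logical(1))]
  ), class = "swing_analysis")
}

#' Analyse a trial directory on disk
#'
#' File-based entry point: reads the cohort with [read_cohort()], runs
#' [run_swing_analysis()], and optionally writes all artifacts.
#'
#' @inheritParams read_cohort
#' @param out_dir if non-`NULL`, artifacts are written there via
#'   [write_results()].
#' @inheritParams run_swing_analysis
#' @return the `swing_analysis` bundle, invisibly if `out_dir` is set.
#' @export
analyze_trials <- function(trial_dir, metadata_path = file.path(trial_dir, "metadata.csv"),
                           config = swing_config(), out_dir = NULL,
                           sample_rate = NULL, units = c("m", "mm")) {
  cohort <- read_cohort(trial_dir, metadata_path, sample_rate = sample_rate,
                        units = units)
  res <- run_swing_analysis(cohort, config)
  if (!is.null(out_dir)) {
    write_results(res, out_dir)
    return(invisible(res))
  }
  res
}

#' @export
print.swing_analysis <- function(x, ...) {
  cat(sprintf("<swing_analysis> %d trials (%d excluded), %d players\n",
              nrow(x$parameters) + length(x$excluded), length(x$excluded),
              nrow(x$player_means)))
  print(x$spm)
  invisible(x)
}

#' @rdname run_swing_analysis
#' @param x a `swing_analysis`.
#' @param ... unused.
#' @method glance swing_analysis
#' @export
glance.swing_analysis <- function(x, ...) {
  tibble(n_players = nrow(x$player_means),
         n_trials = nrow(x$parameters),
         n_excluded = length(x$excluded),
         spm_threshold = x$spm$threshold,
         spm_clusters = nrow(x$spm$clusters),
         alpha = x$config$alpha)
}

fmt_num <- function(x, d = 2) formatC(x, format = "f", digits = d)

#' Human-readable markdown report
#'
#' Renders the descriptive table, the sex ANOVA, the correlation block
#' (r, p, n per sex) and an SPM summary into markdown. Every number
#' shown is taken from the corresponding bundle field.
#'
#' @param results a `swing_analysis` bundle.
#' @return a single markdown string (also usable via `writeLines()`).
#' @export
swing_report <- function(results) {
  stopifnot(inherits(results, "swing_analysis"))
  x <- results
  lines <- c("# Swing analysis report", "",
             sprintf("Players: %d; trials analysed: %d; excluded: %d.",
                     nrow(x$player_means), nrow(x$parameters),
                     length(x$excluded)),
             "", "## Descriptive statistics (mean ± SD by sex)", "",
             "| Parameter | Sex | Mean | SD | n |", "|---|---|---|---|---|")
  for (i in seq_len(nrow(x$descriptives))) {
    d <- x$descriptives[i, ]
    lines <- c(lines, sprintf("| %s | %s | %s | %s | %d |", d$parameter,
                              d$sex, fmt_num(d$mean), fmt_num(d$sd), d$n))
  }
  lines <- c(lines, "", "## One-way ANOVA (sex effect)", "",
             "| Parameter | F | p | eta_p2 | df |", "|---|---|---|---|---|")
  for (i in seq_len(nrow(x$anova))) {
    a <- x$anova[i, ]
    lines <- c(lines, sprintf("| %s | %s | %s | %s | (%d, %d) |", a$parameter,
                              fmt_num(a$F), fmt_num(a$p, 4),
                              fmt_num(a$eta_p2), a$df1, a$df2))
  }
  lines <- c(lines, "", "## Correlations with club velocity", "",
             "| Sex | Parameter | r | p | n |", "|---|---|---|---|---|")
  for (i in seq_len(nrow(x$correlations))) {
    cr <- x$correlations[i, ]
    lines <- c(lines, sprintf("| %s | %s | %s | %s | %d |", cr$sex,
                              cr$parameter, fmt_num(cr$r, 3),
                              fmt_num(cr$p, 4), cr$n))
  }
  spm <- x$spm
  lines <- c(lines, "", "## SPM: pelvis-thorax coupling, girls vs boys", "")
  if (is.null(spm)) {
    lines <- c(lines, "not computed")
  } else {
    lines <- c(lines,
      sprintf("|t| threshold %s (alpha = %g, df = %d, FWHM = %s nodes).",
              fmt_num(spm$threshold, 3), spm$alpha, spm$df, fmt_num(spm$fwhm, 1)),
      if (nrow(spm$clusters) == 0) "No suprathreshold clusters." else
        sprintf("Suprathreshold cluster(s): %s (alignment node %s).",
                paste(sprintf("[%d, %d]", spm$clusters$start, spm$clusters$end),
                      collapse = ", "),
                as.character(spm$metadata$align_node)))
  }
  paste(lines, collapse = "\n")
}
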