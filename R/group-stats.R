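PARAM_COLS <- c("tmax_deg", "pmax_deg", "xfac_deg", "sxfac_deg", "gcv_mps")

#' Per-player mean swing parameters
#'
#' Averages each swing parameter over a player's trials and joins the
#' participant metadata; player means are the unit of all downstream
#' inference (ANOVA, correlations, SPM group curves).
#'
#' @param parameters tibble of per-trial parameters with
#'   `participant_id` plus the five parameter columns.
#' @param participants tibble with `participant_id` and `sex`.
#' @return tibble of one row per player.
#' @export
player_means <- function(parameters, participants) {
  missing_players <- setdiff(participants$participant_id,
                             parameters$participant_id)
  if (length(missing_players) > 0) {
    abort(paste0("player(s) with zero trials: ",
                 paste(missing_players, collapse = ", ")))
  }
  parameters %>%
    group_by(.data$participant_id) %>%
    summarise(across(all_of(PARAM_COLS), mean), n_trials = n(),
              .groups = "drop") %>%
    left_join(participants, by = "participant_id") %>%
    select("participant_id", "sex", all_of(PARAM_COLS), "n_trials")
}

#' One-way ANOVA with partial eta squared
#'
#' Standard one-way decomposition (via [stats::aov()]); the effect size
#' is partial eta squared, `SSb / (SSb + SSw)`, which for the one-way
#' design satisfies `eta_p2 = F * df1 / (F * df1 + df2)` exactly.
#'
#' @param values numeric response.
#' @param groups factor (or coercible) of group labels.
#' @return one-row tibble: `F`, `p`, `eta_p2`, `df1`, `df2`.
#' @export
oneway_anova <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2) abort("need at least 2 groups")
  if (any(table(groups) < 2)) abort("every group needs at least 2 values")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  ssb <- tab["groups", "Sum Sq"]; ssw <- tab["Residuals", "Sum Sq"]
  if (ssw <= 0 && ssb <= 0) abort("undefined F: no variance at all")
  tibble(F = tab["groups", "F value"],
         p = tab["groups", "Pr(>F)"],
         eta_p2 = ssb / (ssb + ssw),
         df1 = tab["groups", "Df"],
         df2 = tab["Residuals", "Df"])
}

#' Pearson correlation with exact two-tailed significance
#'
#' Wraps [stats::cor.test()]; the p-value comes from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3), non-constant.
#' @return one-row tibble: `r`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) abort("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  p <- if (abs(r) >= 1) 0 else ct$p.value
  tibble(r = r, p = p, n = length(x))
}

#' Two-tailed p-value from a reported correlation coefficient
#'
#' Recovers the exact two-tailed significance of a Pearson r from the
#' coefficient and the number of pairs alone — useful for checking
#' published correlation tables.
#'
#' @param r Pearson coefficient.
#' @param n number of pairs (>= 3).
#' @return two-tailed p-value.
#' @export
pearson_p_from_r <- function(r, n) {
  stopifnot(abs(r) <= 1, n >= 3)
  if (abs(r) == 1) return(0)
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * pt(-abs(tstat), df = n - 2)
}

#' Shapiro-Wilk normality screen
#'
#' Runs [stats::shapiro.test()] per parameter and group. Reported for
#' transparency only; no automatic switch to nonparametric methods.
#'
#' @param data tibble with a `sex` column and the parameter columns.
#' @param params parameter columns to screen.
#' @param strict error on cells with n < 3 (default); when `FALSE` such
#'   cells get `NA` statistics instead.
#' @return tibble with `parameter`, `sex`, `W`, `p`, `n`.
#' @export
normality_screen <- function(data, params = PARAM_COLS, strict = TRUE) {
  rows <- list()
  for (pm in params) {
    for (sx in sort(unique(data$sex))) {
      v <- data[[pm]][data$sex == sx]
      if (length(v) < 3) {
        if (strict) abort(sprintf(
          "Shapiro-Wilk needs n >= 3 (parameter %s, group %s has %d)",
          pm, sx, length(v)))
        rows[[length(rows) + 1]] <- tibble(parameter = pm, sex = sx,
                                           W = NA_real_, p = NA_real_,
                                           n = length(v))
        next
      }
      sw <- stats::shapiro.test(v)
      rows[[length(rows) + 1]] <- tibble(parameter = pm, sex = sx,
                                         W = unname(sw$statistic),
                                         p = sw$p.value, n = length(v))
    }
  }
  bind_rows(rows)
}

#' Descriptive statistics by group
#'
#' Group mean and sample SD (n - 1 denominator) per parameter. A
#' single-value cell reports `sd = 0` and is flagged.
#'
#' @inheritParams normality_screen
#' @return tibble with `parameter`, `sex`, `mean`, `sd`, `n`,
#'   `singleton`.
#' @export
descriptives <- function(data, params = PARAM_COLS) {
  data %>%
    tidyr::pivot_longer(all_of(params), names_to = "parameter") %>%
    group_by(.data$parameter, .data$sex) %>%
    summarise(mean = mean(.data$value),
              sd = if (n() > 1) sd(.data$value) else 0,
              n = n(), singleton = n() == 1, .groups = "drop") %>%
    mutate(parameter = factor(.data$parameter, levels = params)) %>%
    arrange(.data$parameter, .data$sex) %>%
    mutate(parameter = as.character(.data$parameter))
}

#' Parameter-vs-club-velocity correlations by sex
#'
#' For each sex, correlates each body-movement parameter with club
#' velocity across players. Groups with fewer than three players (or a
#' constant parameter) get `NA` estimates instead of an error.
#'
#' @param means per-player means from [player_means()].
#' @return tibble with `sex`, `parameter`, `r`, `p`, `n`.
#' @export
gcv_correlations <- function(means) {
  rows <- list()
  for (sx in sort(unique(means$sex))) {
    sub <- means[means$sex == sx, ]
    for (pm in setdiff(PARAM_COLS, "gcv_mps")) {
      ct <- tryCatch(pearson_test(sub[[pm]], sub$gcv_mps),
                     error = function(e) tibble(r = NA_real_, p = NA_real_,
                                                n = nrow(sub)))
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble(sex = sx, parameter = pm), ct)
    }
  }
  bind_rows(rows)
}
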