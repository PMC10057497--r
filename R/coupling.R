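#' Instantaneous phase via the centered Hilbert transform
#'
#' The signal mean over the analysis interval is removed (centering),
#' the series is mirror-padded on both sides to push the Gibbs edge
#' artifact of the finite-length analytic signal out of the interval,
#' the Hilbert analytic signal is formed, and the phase is the unwrapped
#' four-quadrant angle of its real and imaginary parts. The padding
#' region is discarded.
#'
#' Unwrapping leaves each phase defined only up to whole turns: near the
#' interval edges the padded orbit can pass close to the origin and pick
#' up a spurious winding that offsets the rest of the series by 360
#' degrees. That ambiguity cancels only in relative phase and is
#' resolved there (see [crp_series()]).
#'
#' @param x real-valued series (length >= 16, non-constant).
#' @param pad_fraction fraction of the series length mirror-reflected on
#'   each side before the transform.
#' @return unwrapped phase in degrees, same length as `x`.
#' @export
centered_hilbert_phase <- function(x, pad_fraction = 0.2) {
  n <- length(x)
  if (n < 16) abort("signal too short for phase estimation (need >= 16 samples)")
  if (max(x) - min(x) < 1e-12) abort("phase undefined for a constant signal")
  xc <- x - mean(x)
  p <- max(1L, min(n - 1L, round(pad_fraction * n)))
  xp <- c(xc[(p + 1):2], xc, xc[(n - 1):(n - p)])
  z <- analytic_signal(xp)[(p + 1):(p + n)]
  signal::unwrap(atan2(Im(z), Re(z))) * 180 / pi
}

#' Pelvis-thorax continuous relative phase
#'
#' CRP(t) = phase(pelvis) - phase(thorax), both phases from
#' [centered_hilbert_phase()]; no pointwise re-wrapping is applied after
#' the subtraction of unwrapped phases. Each unwrapped phase is defined
#' only up to whole turns, so the relative phase carries a global
#' 360-degree ambiguity; it is resolved by requiring the mid-interval
#' CRP to lie in (-180, 180] — the two segments are assumed to be
#' within half a coordination cycle of each other mid-movement, the
#' standard reading in coordination analysis. Positive values mean the
#' first argument (pelvis) leads in phase space; set
#' `sign_convention = "display"` to negate, matching the plotting
#' convention in which negative CRP indicates a leading pelvis.
#'
#' @param pelvis,thorax equal-length angle series (degrees).
#' @param sign_convention `"phase"` (default) or `"display"`.
#' @inheritParams centered_hilbert_phase
#' @return CRP series in degrees.
#' @export
crp_series <- function(pelvis, thorax, sign_convention = c("phase", "display"),
                       pad_fraction = 0.2) {
  sign_convention <- match.arg(sign_convention)
  stopifnot(length(pelvis) == length(thorax))
  crp <- centered_hilbert_phase(pelvis, pad_fraction) -
    centered_hilbert_phase(thorax, pad_fraction)
  # fix the whole-turn anchor of the unwrapped difference mid-interval
  crp <- crp - 360 * round(crp[ceiling(length(crp) / 2)] / 360)
  if (sign_convention == "display") crp <- -crp
  crp
}

#' Align a CRP series on maximal pelvis rotation and normalize its length
#'
#' With the default `"split"` strategy the stroke is cut at the frame `m`
#' of maximal pelvis rotation between start and impact; the backswing
#' part `[start, m]` is linearly resampled to
#' `round(align_fraction * n_out)` nodes and the remainder `[m, impact]`
#' to the rest, concatenated without duplicating `m`, so every curve
#' holds its pelvis-rotation maximum at the same node. The `"shift"`
#' strategy instead resamples the whole stroke and shifts it (with
#' endpoint replication) until `m` lands on the alignment node.
#'
#' @param crp CRP series over the whole trial (or any series to align).
#' @param pelvis pelvis angle series on the same time base.
#' @param events a `swing_events`.
#' @param n_out number of output nodes.
#' @param align_fraction position of the alignment node as a fraction of
#'   `n_out`.
#' @param strategy `"split"` (default) or `"shift"`.
#' @return a `crp_curve`: tibble with `node` (1..n_out) and `crp_deg`,
#'   plus attributes `align_node` and `strategy`.
#' @export
align_and_normalize <- function(crp, pelvis, events, n_out = 200,
                                align_fraction = 0.5,
                                strategy = c("split", "shift")) {
  strategy <- match.arg(strategy)
  s <- events$start_frame; i <- events$impact_frame
  stopifnot(length(crp) == length(pelvis), i <= length(crp), s >= 1)
  m <- (s:i)[which.max(pelvis[s:i])]
  if (m == s || m == i) {
    abort("pelvis rotation has no interior maximum between start and impact")
  }
  k <- round(align_fraction * n_out)
  if (strategy == "split") {
    left <- resample_linear(crp[s:m], k)
    right <- resample_linear(crp[m:i], n_out - k + 1L)
    values <- c(left, right[-1])
    align_node <- k
  } else {
    values <- resample_linear(crp[s:i], n_out)
    m_node <- round((m - s) / (i - s) * (n_out - 1)) + 1L
    shift <- k - m_node
    if (shift > 0) {
      values <- c(rep(values[1], shift), values)[1:n_out]
    } else if (shift < 0) {
      values <- c(values[(-shift + 1):n_out], rep(values[n_out], -shift))
    }
    align_node <- k
  }
  out <- tibble(node = seq_len(n_out), crp_deg = values)
  attr(out, "align_node") <- align_node
  attr(out, "strategy") <- strategy
  class(out) <- c("crp_curve", class(out))
  out
}

#' Per-trial CRP curve from a trial's angle series and events
#'
#' Computes the pelvis-thorax CRP over the analysis interval
#' `[start_frame, impact_frame]` (centering and phase estimation are
#' restricted to that interval) and aligns/normalizes it.
#'
#' @param angles output of [segment_angles()].
#' @param events a `swing_events`.
#' @inheritParams crp_series
#' @inheritParams align_and_normalize
#' @return a `crp_curve` (see [align_and_normalize()]).
#' @export
trial_crp <- function(angles, events, n_out = 200, align_fraction = 0.5,
                      sign_convention = c("phase", "display"),
                      pad_fraction = 0.2, strategy = c("split", "shift")) {
  sign_convention <- match.arg(sign_convention)
  strategy <- match.arg(strategy)
  s <- events$start_frame; i <- events$impact_frame
  pe <- angles$pelvis_deg[s:i]
  th <- angles$thorax_deg[s:i]
  crp <- crp_series(pe, th, sign_convention = sign_convention,
                    pad_fraction = pad_fraction)
  ev <- structure(list(start_frame = 1L, top_frame = events$top_frame - s + 1L,
                       impact_frame = i - s + 1L), class = "swing_events")
  out <- align_and_normalize(crp, pe, ev, n_out = n_out,
                             align_fraction = align_fraction,
                             strategy = strategy)
  attr(out, "sign_convention") <- sign_convention
  out
}
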