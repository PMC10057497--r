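# Shared fixture builders. Everything is generated in code; no files ship
# with the tests beyond what the tests themselves write to tempdirs.

# Marker geometry used by the rigid-rotation oracles (distinct from the
# generator's internal constants on purpose).
rigid_geometry <- list(
  LASIS = c( 0.15, -0.05, 1.00), RASIS = c(-0.15, -0.05, 1.00),
  LPSIS = c( 0.15,  0.07, 1.04), RPSIS = c(-0.15,  0.07, 1.04),
  LACR  = c( 0.21,  0.02, 1.44), RACR  = c(-0.21,  0.02, 1.44),
  CLUB_GRIP = c(0.05, 0.40, 0.95), CLUB_HEAD = c(0.10, 1.40, 0.10)
)

# Trial whose body markers are the explicit rotation (about Z) of the
# setup geometry by theta_deg[i] at frame i; the club stays put unless a
# club_xyz function(frame) is given.
rigid_trial <- function(theta_deg, fs = 200, club_xyz = NULL) {
  n <- length(theta_deg)
  th <- theta_deg * pi / 180
  dat <- tibble::tibble(frame = seq_len(n), time = (seq_len(n) - 1) / fs)
  for (m in names(rigid_geometry)) {
    p0 <- rigid_geometry[[m]]
    if (m %in% c("CLUB_GRIP", "CLUB_HEAD") && !is.null(club_xyz)) {
      xyz <- t(vapply(seq_len(n), function(i) club_xyz(i, m), numeric(3)))
    } else if (m %in% c("CLUB_GRIP", "CLUB_HEAD")) {
      xyz <- matrix(p0, n, 3, byrow = TRUE)
    } else {
      xyz <- cbind(p0[1] * cos(th) - p0[2] * sin(th),
                   p0[1] * sin(th) + p0[2] * cos(th),
                   rep(p0[3], n))
    }
    dat[[paste0(m, "_x")]] <- xyz[, 1]
    dat[[paste0(m, "_y")]] <- xyz[, 2]
    dat[[paste0(m, "_z")]] <- xyz[, 3]
  }
  swing_trial(dat, "test", 1L, fs)
}

# Trial with every marker frozen at its setup position (no swing).
constant_trial <- function(n = 120, fs = 200) {
  rigid_trial(rep(0, n), fs = fs)
}
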