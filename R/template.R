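#' Within-cycle shape template
#'
#' Smooth, unitless template of the population within-cycle pattern: resting
#' heart rate falls from cycle onset to a nadir early in the follicular phase
#' and rises to a peak in the late luteal phase (the RMSSD pattern is the
#' sign-inverted mirror). The template is a warped cosine, `0.5 * cos(phi(d))`,
#' where the phase `phi` is a monotone periodic map equal to pi at `nadir_day`
#' and 2*pi at `peak_day`.
#'
#' The phase map is built from two requirements. First, within a
#' `shoulder`-day neighbourhood of each anchor the curve is exactly even
#' (mirror-symmetric) about that anchor: the long rise uses a quintic Hermite
#' phase and the short fall re-uses the rise's phase-displacement profile
#' near both anchors, with a fast monotone bridge in between, so that a
#' smoother applied to noisy data does not displace the extrema. Second, the
#' phase velocity at the anchors is `anchor_velocity * 2*pi/cycle_len`
#' (a multiple of the mean velocity of a plain cosine with the same period),
#' which sets the curvature of the extrema: larger values make the nadir and
#' peak days easier to localize statistically, at the cost of a more peaked
#' curve. The default 1.3 keeps the quintic phase monotone for the default
#' anchors (monotonicity requires `anchor_velocity * 2 * rise / cycle_len <
#' 15/7`).
#'
#' By construction the minimum is exactly -0.5 at `nadir_day`, the maximum
#' exactly +0.5 at `peak_day` (peak-to-nadir range exactly 1, so multiplying
#' by an amplitude injects it exactly), and the curve is continuous across
#' the cycle boundary, staying high through the cycle's conclusion before
#' dropping to the next follicular nadir.
#'
#' @param day Cycle day (day 1 = first day of menstrual bleeding). Vectorized;
#'   values are wrapped modulo `cycle_len`, making the template periodic.
#' @param cycle_len Cycle length in days.
#' @param nadir_day Cycle day of the template minimum (default 5).
#' @param peak_day Cycle day of the template maximum (default 26). Must exceed
#'   `nadir_day` and lie within the cycle.
#' @param shoulder Half-width in days of the mirror-symmetric neighbourhood
#'   around each anchor (default 3; shrunk automatically in short segments).
#' @param anchor_velocity Phase velocity at the anchors relative to
#'   `2*pi/cycle_len` (default 1.3).
#' @return Numeric vector of template values in \[-0.5, 0.5\].
#' @examples
#' cycle_template(5, 28)   # -0.5 at the nadir
#' cycle_template(26, 28)  # +0.5 at the peak
#' @export
cycle_template <- function(day, cycle_len, nadir_day = 5, peak_day = 26,
                           shoulder = 3, anchor_velocity = 1.3) {
  if (!is.numeric(cycle_len) || length(cycle_len) != 1 || cycle_len < 7) {
    stop("`cycle_len` must be a single number >= 7", call. = FALSE)
  }
  if (nadir_day >= peak_day) {
    stop("`nadir_day` must precede `peak_day`", call. = FALSE)
  }
  if (nadir_day < 1 || peak_day > cycle_len) {
    stop("anchor days must lie within [1, cycle_len]", call. = FALSE)
  }
  # position along the cycle, measured from the nadir
  pos <- (day - nadir_day) %% cycle_len
  rise <- peak_day - nadir_day
  fall <- cycle_len - rise
  d_r <- anchor_velocity * 2 * rise / cycle_len
  if (d_r >= 15 / 7) {
    stop("`anchor_velocity` too large for these anchors: phase map would be ",
         "non-monotone", call. = FALSE)
  }

  # quintic Hermite: h(0)=0, h(1)=1, h'(0)=h'(1)=d, h''(0)=h''(1)=0;
  # symmetric (h(1-t) = 1-h(t)) and monotone for d < 15/7
  herm <- function(t, d) d * t + (1 - d) * (10 * t^3 - 15 * t^4 + 6 * t^5)
  r_disp <- function(delta) pi * herm(delta / rise, d_r)     # radians
  r_slope <- function(delta) {
    t <- delta / rise
    (pi / rise) * (d_r + (1 - d_r) * 30 * t^2 * (1 - t)^2)
  }

  w <- min(shoulder, 0.4 * fall, 0.4 * rise)
  a <- r_disp(w)                      # phase shed across each shoulder
  sw <- r_slope(w)
  bridge_len <- fall - 2 * w
  # fall displacement g(delta), delta in [0, fall]: shoulders mirror the
  # rise profile; cubic Hermite bridge keeps the phase monotone and C1
  g <- function(delta) {
    u <- (delta - w) / bridge_len
    bridge <- a + (pi - 2 * a) * (3 * u^2 - 2 * u^3) +
      sw * bridge_len * ((u^3 - 2 * u^2 + u) + (u^3 - u^2))
    ifelse(delta <= w, r_disp(delta),
           ifelse(delta >= fall - w, pi - r_disp(fall - delta), bridge))
  }

  on_rise <- pos <= rise
  phase <- ifelse(on_rise,
                  pi + pi * herm(pos / rise, d_r),
                  2 * pi + g(pmax(pos - rise, 0)))
  0.5 * cos(phase)
}
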