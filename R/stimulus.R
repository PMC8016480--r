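#' Bar stimulus specification
#'
#' A vertical luminous bar on the cylindrical visual field: an azimuth
#' trajectory (degrees as a function of time), an angular width, a brightness
#' in `[0, 1]`, and an on/off window. Bars span the full elevation.
#'
#' @param azimuth_fun Function `time (s) -> azimuth (deg)`; vectorized.
#' @param width Angular width in degrees, `0 < width < 360`.
#' @param brightness Luminance in `[0, 1]`.
#' @param t_on,t_off Active window (s), `t_on < t_off`.
#' @param role Optional label (`"moving"`, `"static"`, ...).
#' @return A `cx_bar` list.
#' @export
bar_spec <- function(azimuth_fun, width, brightness, t_on, t_off,
                     role = "bar") {
  stopifnot(is.function(azimuth_fun), width > 0, width < 360,
            brightness >= 0, brightness <= 1, t_on < t_off)
  structure(list(azimuth_fun = azimuth_fun, width = width,
                 brightness = brightness, t_on = t_on, t_off = t_off,
                 role = role), class = "cx_bar")
}

#' Stimulus protocol
#'
#' A list of bars plus total duration and the angular resolution of the
#' rendered field. Luminance at any point is the maximum over the bars
#' covering it.
#'
#' @param bars List of [bar_spec()] objects.
#' @param duration Total protocol duration (s); must cover every bar's
#'   `t_off`.
#' @param az_step,el_step Field grid resolution (deg).
#' @param el_extent Total elevation extent (deg), centred on 0.
#' @return A `cx_protocol` list.
#' @export
stimulus_protocol <- function(bars, duration, az_step = 1, el_step = 1,
                              el_extent = 60) {
  stopifnot(all(vapply(bars, inherits, logical(1), "cx_bar")))
  if (length(bars) > 0 &&
      duration < max(vapply(bars, function(b) b$t_off, numeric(1)))) {
    stop("configuration error: duration must cover every bar's t_off")
  }
  structure(list(bars = bars, duration = duration, az_step = az_step,
                 el_step = el_step, el_extent = el_extent),
            class = "cx_protocol")
}

#' Triangle-wave azimuth sweep
#'
#' Back-and-forth sweep over the full `[0, 360)` azimuth: rises from
#' `a0` to `a0 + 360` over the first half period, returns over the second.
#' Before `t_start` the bar sits at `a0`.
#'
#' @param a0 Initial azimuth (deg).
#' @param period Full back-and-forth period (s).
#' @param t_start Time at which motion begins (s).
#' @return Vectorized function `t -> azimuth`.
#' @export
sweep_trajectory <- function(a0 = 0, period = 14.5, t_start = 1) {
  force(a0); force(period); force(t_start)
  function(t) {
    u <- pmax(t - t_start, 0) %% period
    x <- u / period
    p <- ifelse(x < 0.5, 720 * x, 720 * (1 - x))
    (a0 + p) %% 360
  }
}

#' The 35-second two-bar comparison protocol
#'
#' A bright moving bar, stationary at its initial azimuth during the first
#' second, then sweeping back and forth across the entire visual field until
#' 30 s, absent afterwards; a dimmer static bar fixed at 60 degrees until
#' 33 s; total darkness in the final 2 s of the 35 s protocol.
#'
#' @param cfg Optional protocol configuration overrides (see the `protocol`
#'   element of [default_config()]): `duration`, `bar_width`,
#'   `moving_brightness`, `static_brightness`, `static_azimuth`,
#'   `initial_azimuth`, `sweep_period`, `t_move_start`, `t_move_end`,
#'   `t_static_end`.
#' @return A `cx_protocol`.
#' @export
make_usecase4_protocol <- function(cfg = list()) {
  d <- utils::modifyList(default_config("B")$protocol, cfg)
  if (d$moving_brightness > 1 || d$static_brightness > 1 ||
      d$moving_brightness < 0 || d$static_brightness < 0) {
    stop("configuration error: brightness must lie in [0, 1]")
  }
  if (d$duration <= 0 || d$t_move_end <= d$t_move_start) {
    stop("configuration error: non-positive protocol durations")
  }
  moving <- bar_spec(
    sweep_trajectory(d$initial_azimuth, d$sweep_period, d$t_move_start),
    width = d$bar_width, brightness = d$moving_brightness,
    t_on = 0, t_off = d$t_move_end, role = "moving")
  static <- bar_spec(
    local({ az <- d$static_azimuth; function(t) rep(az, length(t)) }),
    width = d$bar_width, brightness = d$static_brightness,
    t_on = 0, t_off = d$t_static_end, role = "static")
  stimulus_protocol(list(moving = moving, static = static),
                    duration = d$duration)
}

#' Azimuth trace of a bar in a protocol
#'
#' Returns the bar's azimuth at the requested times and `NA` where the bar
#' is inactive.
#'
#' @param protocol A `cx_protocol`.
#' @param times Numeric vector of times (s).
#' @param role Bar role to look up (default `"moving"`).
#' @export
bar_azimuth <- function(protocol, times, role = "moving") {
  roles <- vapply(protocol$bars, function(b) b$role, character(1))
  b <- protocol$bars[[match(role, roles)]]
  if (is.null(b)) stop("no bar with role '", role, "' in protocol")
  az <- b$azimuth_fun(times)
  az[times < b$t_on | times >= b$t_off] <- NA_real_
  az
}

#' Render the luminance field at one time
#'
#' Returns the azimuth-by-elevation luminance array at time `t`; each grid
#' cell holds the maximum luminance over the bars covering it. Bars wrap
#' modulo 360 in azimuth and span the full elevation.
#'
#' @param protocol A `cx_protocol`.
#' @param t Time in `[0, duration]`.
#' @return Matrix (azimuth x elevation) in `[0, 1]` with attributes
#'   `az_centers` and `el_centers` (degrees), class `cx_field`.
#' @export
render <- function(protocol, t) {
  stopifnot(inherits(protocol, "cx_protocol"), length(t) == 1L)
  if (t < 0 || t > protocol$duration) {
    stop("t = ", t, " outside protocol duration [0, ", protocol$duration, "]")
  }
  az <- seq(protocol$az_step / 2, 360, by = protocol$az_step)
  el <- seq(-protocol$el_extent / 2 + protocol$el_step / 2,
            protocol$el_extent / 2, by = protocol$el_step)
  lum_az <- rep(0, length(az))
  for (b in protocol$bars) {
    if (t < b$t_on || t >= b$t_off) next
    c_b <- b$azimuth_fun(t)
    covered <- circ_dist_deg(az, c_b) < b$width / 2
    lum_az <- pmax(lum_az, ifelse(covered, b$brightness, 0))
  }
  field <- matrix(lum_az, nrow = length(az), ncol = length(el))
  attr(field, "az_centers") <- az
  attr(field, "el_centers") <- el
  class(field) <- c("cx_field", class(field))
  field
}

#' Receptive-field specifications
#'
#' `rf_rect()` is a rectangular receptive field covering `width` degrees of
#' azimuth and the full elevation; `rf_gauss()` is a Gaussian receptive
#' field with the same standard deviation in azimuth and elevation
#' (truncated to the visual field and normalized to unit mass).
#'
#' @param center Azimuth centre (deg).
#' @param width Azimuth width (deg), rectangular case.
#' @param sigma Standard deviation (deg), Gaussian case.
#' @param center_el Elevation centre (deg), Gaussian case (default
#'   mid-elevation).
#' @return An `cx_rf` list.
#' @export
rf_rect <- function(center, width) {
  stopifnot(width > 0, width <= 360)
  structure(list(shape = "rectangular", center = center %% 360,
                 width = width), class = "cx_rf")
}

#' @rdname rf_rect
#' @export
rf_gauss <- function(center, sigma = 9, center_el = 0) {
  stopifnot(sigma > 0)
  structure(list(shape = "gaussian", center = center %% 360,
                 sigma = sigma, center_el = center_el), class = "cx_rf")
}

#' Filter a rendered field through a receptive field
#'
#' Rectangular: area-normalized mean luminance over the field's sector (a
#' full-brightness, fully covering stimulus gives 1). Gaussian: luminance
#' integrated against a unit-mass truncated two-dimensional Gaussian.
#'
#' @param field A `cx_field` from [render()].
#' @param rf An [rf_rect()] or [rf_gauss()].
#' @return Drive scalar in `[0, 1]`.
#' @export
rf_filter <- function(field, rf) {
  stopifnot(inherits(field, "cx_field"), inherits(rf, "cx_rf"))
  az <- attr(field, "az_centers")
  el <- attr(field, "el_centers")
  if (rf$shape == "rectangular") {
    inside <- circ_dist_deg(az, rf$center) < rf$width / 2
    if (!any(inside)) return(0)
    mean(field[inside, , drop = FALSE])
  } else {
    waz <- stats::dnorm(circ_diff_deg(az, rf$center), sd = rf$sigma)
    wel <- stats::dnorm(el - rf$center_el, sd = rf$sigma)
    w <- outer(waz, wel)
    sum(w * field) / sum(w)
  }
}

# ---- analytic drives (closed-form arc integrals, vectorized in time) -------

# overlap length of arc [lo1, lo1+len1) with arc [lo2, lo2+len2) on the
# circle; all lengths < 360. Vectorized over lo2.
arc_overlap_len <- function(lo1, len1, lo2, len2) {
  d <- (lo2 - lo1) %% 360                      # start of arc2 in arc1 frame
  # candidate overlap with arc2 at d and at d - 360
  o1 <- pmax(0, pmin(len1, d + len2) - pmax(0, d))
  o2 <- pmax(0, pmin(len1, d - 360 + len2) - pmax(0, d - 360))
  o1 + o2
}

# mass of a (truncated, unit-mass) azimuthal Gaussian over an arc
gauss_arc_mass <- function(center, sigma, lo, len) {
  a <- circ_diff_deg(lo, center)
  z <- stats::pnorm(180 / sigma) - stats::pnorm(-180 / sigma)
  m <- 0
  for (k in c(-1, 0, 1)) {
    m <- m + stats::pnorm(pmin(pmax(a + len + 360 * k, -180), 180) / sigma) -
      stats::pnorm(pmin(pmax(a + 360 * k, -180), 180) / sigma)
  }
  m / z
}

# drive of one RF under the protocol at a vector of times; closed-form
# max-luminance combination for up to two simultaneously active bars.
# Returns a numeric vector along `times`.
rf_drive <- function(protocol, rf, times) {
  n <- length(times)
  # per-bar active mask, centre trace
  act <- list(); ctr <- list(); br <- numeric(); wd <- numeric()
  for (b in protocol$bars) {
    act[[length(act) + 1L]] <- times >= b$t_on & times < b$t_off
    ctr[[length(ctr) + 1L]] <- b$azimuth_fun(times)
    br <- c(br, b$brightness); wd <- c(wd, b$width)
  }
  nb <- length(br)
  measure <- function(lo, len) {
    if (rf$shape == "rectangular") {
      arc_overlap_len(rf$center - rf$width / 2, rf$width, lo, len) / rf$width
    } else {
      gauss_arc_mass(rf$center, rf$sigma, lo, len)
    }
  }
  drive <- rep(0, n)
  for (i in seq_len(nb)) {
    m <- measure(ctr[[i]] - wd[i] / 2, wd[i])
    drive <- drive + ifelse(act[[i]], br[i] * m, 0)
  }
  if (nb >= 2) {
    for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
      # subtract the double-counted overlap at the lower brightness
      lo_i <- (ctr[[i]] - wd[i] / 2) %% 360
      lo_j <- (ctr[[j]] - wd[j] / 2) %% 360
      d <- (lo_j - lo_i) %% 360
      start_rel <- pmax(0, ifelse(d > 180, d - 360, d))
      end_rel <- pmin(wd[i], ifelse(d > 180, d - 360, d) + wd[j])
      len <- pmax(0, end_rel - start_rel)
      both <- act[[i]] & act[[j]] & len > 0
      if (any(both)) {
        m_int <- measure((lo_i + start_rel) %% 360, pmax(len, 1e-12))
        drive[both] <- drive[both] -
          (min(br[i], br[j]) * m_int * (len > 0))[both]
      }
    }
  }
  pmin(pmax(drive, 0), 1)
}
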