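#' Per-wedge mean firing rates
#'
#' Computes, for every EB wedge `j`, the mean over its EB-LAL-PB neurons of
#' the spike trains convolved with the causal exponential kernel
#' `exp(-t / kernel_tau)`:
#' `r_j(t) = (1/N_j) sum_{i in I_j} sum_k exp(-(t - t_k^i)/kernel_tau)` for
#' `t >= t_k^i`. The kernel is deliberately not unit-normalized (the
#' estimator is reproduced as printed); set `normalize = TRUE` to divide by
#' `kernel_tau` for a Hz-scale reading. Only EB-LAL-PB neurons contribute.
#' Sampling on the regular grid is exact (recursive exponential update).
#'
#' @param spikes A `cx_spike_record`.
#' @param model The `cx_circuit` that produced it (identifies each
#'   EB-LAL-PB neuron's wedge).
#' @param p Estimator parameters: `kernel_tau` (s, default 0.7215),
#'   `sample_dt` (s, default 0.01), `normalize` (default `FALSE`).
#' @return A `cx_wedge_rates` object: list with `time` (s), `rates` (matrix
#'   time x wedge), `wedge` (0-based indices of included wedges),
#'   `wedge_centers` (deg), `n_per_wedge`, `kernel_tau`.
#' @export
wedge_rates <- function(spikes, model,
                        p = list(kernel_tau = 0.7215, sample_dt = 0.01,
                                 normalize = FALSE)) {
  stopifnot(inherits(spikes, "cx_spike_record"),
            inherits(model, "cx_circuit"))
  tau <- if (is.null(p$kernel_tau)) 0.7215 else p$kernel_tau
  sdt <- if (is.null(p$sample_dt)) 0.01 else p$sample_dt
  stopifnot(tau > 0, sdt > 0)
  n <- model$neurons
  eb <- n[n$cell_class == "EB-LAL-PB", ]
  nw <- model$topology$n_wedges
  grid <- seq(0, spikes$t_end, by = sdt)
  d <- exp(-sdt / tau)
  cols <- list(); wedges <- integer(); npw <- integer()
  for (w in 0:(nw - 1L)) {
    ids <- eb$id[eb$wedge == w]
    if (length(ids) == 0L) {
      warning("wedge ", w, " has no EB-LAL-PB neurons; excluded")
      next
    }
    tk <- sort(unlist(spikes$times[ids], use.names = FALSE))
    imp <- rep(0, length(grid))
    if (length(tk) > 0L) {
      # first grid point at or after each spike, with its partial decay
      j <- pmin(ceiling(tk / sdt) + 1L, length(grid))
      contrib <- exp(-(grid[j] - tk) / tau)
      for (q in seq_along(j)) imp[j[q]] <- imp[j[q]] + contrib[q]
    }
    r <- as.numeric(stats::filter(imp, d, method = "recursive"))
    r <- r / length(ids)
    if (isTRUE(p$normalize)) r <- r / tau
    cols[[length(cols) + 1L]] <- r
    wedges <- c(wedges, w)
    npw <- c(npw, length(ids))
  }
  rates <- do.call(cbind, cols)
  colnames(rates) <- paste0("wedge_", wedges)
  structure(list(time = grid, rates = rates, wedge = wedges,
                 wedge_centers = wedge_centers(model$topology)[wedges + 1L],
                 n_per_wedge = npw, kernel_tau = tau),
            class = "cx_wedge_rates")
}

#' @export
print.cx_wedge_rates <- function(x, ...) {
  cat("cx_wedge_rates:", length(x$wedge), "wedges x", length(x$time),
      "samples, kernel tau =", x$kernel_tau, "s\n")
  invisible(x)
}

# circular prominence of each local maximum of a profile sampled on a ring
circular_prominences <- function(r) {
  n <- length(r)
  if (n < 3L || max(r) <= 0) return(list(peaks = integer(), prom = numeric()))
  nxt <- function(i) (i %% n) + 1L
  prv <- function(i) ((i - 2L) %% n) + 1L
  is_peak <- vapply(seq_len(n), function(i) {
    r[i] > r[nxt(i)] && r[i] >= r[prv(i)]   # half-open tie break
  }, logical(1))
  peaks <- which(is_peak)
  if (length(peaks) == 0L) {
    # plateau-only profile (constant): no defined peak
    return(list(peaks = integer(), prom = numeric()))
  }
  prom <- vapply(peaks, function(i) {
    if (r[i] >= max(r[-i])) return(r[i] - min(r))
    # walk both ways to the nearest strictly higher value, tracking minima
    key <- -Inf
    for (dir in c(1L, -1L)) {
      j <- i; lo <- r[i]
      repeat {
        j <- if (dir == 1L) nxt(j) else prv(j)
        if (r[j] > r[i]) break
        lo <- min(lo, r[j])
        if (j == i) break
      }
      key <- max(key, lo)
    }
    r[i] - key
  }, numeric(1))
  list(peaks = peaks, prom = prom)
}

# FWHM (deg) of the circularly linearly-interpolated profile around peak j0
circular_fwhm <- function(r, theta, j0) {
  n <- length(r)
  half <- r[j0] / 2
  nxt <- function(i) (i %% n) + 1L
  prv <- function(i) ((i - 2L) %% n) + 1L
  gap <- function(a, b) (b - a) %% 360   # arc from a to b going "up"
  # walk up in angle until the profile drops below half
  walk <- function(dir) {
    i <- j0; total <- 0
    repeat {
      j <- if (dir == 1L) nxt(i) else prv(i)
      step_gap <- if (dir == 1L) gap(theta[i], theta[j]) else gap(theta[j], theta[i])
      if (r[j] < half) {
        frac <- (r[i] - half) / (r[i] - r[j])
        return(total + frac * step_gap)
      }
      total <- total + step_gap
      i <- j
      if (i == j0) return(360)  # never dropped below half
    }
  }
  w <- walk(1L) + walk(-1L)
  min(w, 360)
}

#' Bump metrics from wedge-rate traces
#'
#' Per time sample: the population-vector bump position
#' `peak_angle = arg sum_j r_j exp(i theta_j)` (wedge centres `theta_j`),
#' the vector strength `|sum r_j e^{i theta_j}| / sum r_j`, the bump
#' amplitude (profile maximum), the number of bumps (circular local maxima
#' with prominence at least `min_prominence` times the global maximum), and
#' the full width at half maximum of the circularly interpolated profile
#' around the dominant peak. All-zero profiles yield `defined = FALSE` and
#' `NA` metrics (explicit sentinel, never silent zeros).
#'
#' @param rates A [wedge_rates()] result.
#' @param min_prominence Prominence threshold as a fraction of the global
#'   maximum (default 0.2).
#' @return A `data.frame` (class `cx_bump_metrics`) with columns `time`,
#'   `peak_angle`, `amplitude`, `width`, `n_bumps`, `vector_strength`,
#'   `defined`.
#' @export
bump_metrics <- function(rates, min_prominence = 0.2) {
  stopifnot(inherits(rates, "cx_wedge_rates"))
  theta <- rates$wedge_centers
  nt <- length(rates$time)
  out <- data.frame(time = rates$time, peak_angle = NA_real_,
                    amplitude = NA_real_, width = NA_real_,
                    n_bumps = NA_integer_, vector_strength = NA_real_,
                    defined = FALSE)
  th_rad <- theta * pi / 180
  for (m in seq_len(nt)) {
    r <- rates$rates[m, ]
    tot <- sum(r)
    if (tot <= 0) next
    zx <- sum(r * cos(th_rad)); zy <- sum(r * sin(th_rad))
    out$vector_strength[m] <- sqrt(zx^2 + zy^2) / tot
    out$amplitude[m] <- max(r)
    cp <- circular_prominences(r)
    keep <- cp$prom >= min_prominence * max(r)
    out$n_bumps[m] <- sum(keep)
    if (out$vector_strength[m] > 1e-9) {
      out$peak_angle[m] <- (atan2(zy, zx) * 180 / pi) %% 360
      out$width[m] <- circular_fwhm(r, theta, which.max(r))
      out$defined[m] <- TRUE
    }
  }
  class(out) <- c("cx_bump_metrics", class(out))
  out
}

# circular median of angles (deg): re-centre around the circular mean and
# take the ordinary median of the signed deviations
circular_median_deg <- function(a) {
  a <- a[is.finite(a)]
  if (length(a) == 0L) return(NA_real_)
  mu <- atan2(mean(sin(a * pi / 180)), mean(cos(a * pi / 180))) * 180 / pi
  (mu + stats::median(circ_diff_deg(a, mu))) %% 360
}

#' Bump tracking error against the moving bar
#'
#' Per-time circular distance between the bump's population-vector angle and
#' the moving bar's azimuth. Because the absolute EB phase of the bump
#' relative to visual azimuth is model- and convention-dependent (and the
#' bump is slightly delayed), `offset_correction = TRUE` subtracts the
#' circular median offset measured over `window`.
#'
#' @param metrics A [bump_metrics()] result.
#' @param protocol The `cx_protocol` supplying the moving-bar azimuth.
#' @param offset_correction Subtract the median offset (default `TRUE`).
#' @param window Time window (s) over which the offset is estimated.
#' @param role Bar role to track (default `"moving"`).
#' @return `data.frame(time, bar_azimuth, error_deg)`; samples with an
#'   undefined bump or an inactive bar propagate as `NA`.
#' @export
tracking_error <- function(metrics, protocol, offset_correction = TRUE,
                           window = c(5, 30), role = "moving") {
  stopifnot(inherits(metrics, "cx_bump_metrics"))
  bar <- bar_azimuth(protocol, metrics$time, role)
  diffs <- circ_diff_deg(metrics$peak_angle, bar)
  diffs[!metrics$defined] <- NA_real_
  offset <- 0
  if (offset_correction) {
    inw <- metrics$time >= window[1] & metrics$time <= window[2] &
      is.finite(diffs)
    if (any(inw)) offset <- circular_median_deg(diffs[inw])
  }
  err <- abs(circ_diff_deg(metrics$peak_angle, (bar + offset) %% 360))
  err[!metrics$defined | !is.finite(bar)] <- NA_real_
  data.frame(time = metrics$time, bar_azimuth = bar, error_deg = err)
}

#' Bump persistence after stimulus removal
#'
#' Verdict is `TRUE` iff the mean bump amplitude over
#' `[t_off + horizon/2, t_off + horizon]` is at least `threshold` times the
#' mean amplitude over the second before `t_off`, and the response remains a
#' single bump (n_bumps == 1 for at least 90% of the defined late-window
#' samples).
#'
#' @param rates A [wedge_rates()] result.
#' @param t_off Stimulus removal time (s).
#' @param horizon Evaluation horizon after `t_off` (s).
#' @param threshold Amplitude-ratio threshold.
#' @param min_prominence Passed to [bump_metrics()].
#' @return List with `verdict` (logical), `ratio` (late/early amplitude),
#'   `single_bump_fraction`.
#' @export
persistence <- function(rates, t_off, horizon = 1.5, threshold = 0.3,
                        min_prominence = 0.2) {
  stopifnot(inherits(rates, "cx_wedge_rates"))
  if (t_off + horizon > max(rates$time) + 1e-9) {
    stop("horizon extends beyond the rate trace")
  }
  m <- bump_metrics(rates, min_prominence)
  early <- m$time >= t_off - 1 & m$time < t_off
  late <- m$time >= t_off + horizon / 2 & m$time <= t_off + horizon
  amp_early <- mean(ifelse(is.na(m$amplitude[early]), 0, m$amplitude[early]))
  amp_late <- mean(ifelse(is.na(m$amplitude[late]), 0, m$amplitude[late]))
  ratio <- if (amp_early > 0) amp_late / amp_early else NA_real_
  nb <- m$n_bumps[late]
  sbf <- if (all(is.na(nb))) 0 else mean(nb == 1, na.rm = TRUE)
  verdict <- isTRUE(ratio >= threshold) && sbf >= 0.9
  list(verdict = verdict, ratio = ratio, single_bump_fraction = sbf)
}
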