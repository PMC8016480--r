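#' Spatial scaffold of the central complex
#'
#' A `cx_topology` indexes the discrete ring coordinates of the circuit: the
#' ellipsoid-body (EB) wedges and the protocerebral-bridge (PB) glomeruli,
#' together with their retinotopic azimuth sectors and the wedge-to-glomerulus
#' correspondence used by the circuit builders.
#'
#' Azimuth convention: degrees in `[0, 360)`, increasing in one fixed
#' direction, with sector 0 anchored at 0 degrees; all sectors are half-open
#' intervals `[lo, hi)`. Wedge `j` covers `[j*360/n_wedges, (j+1)*360/n_wedges)`.
#' Glomeruli are split between the two PB hemispheres (`L0..L(n/2-1)`,
#' `R0..R(n/2-1)`); their receptive-field sectors interleave so that, jointly,
#' the `n_glomeruli` sectors of width `360/n_glomeruli` tile the full azimuth:
#' the left hemisphere takes the even tiles, the right hemisphere the odd ones.
#'
#' @param n_wedges Number of EB wedges (default 16).
#' @param n_glomeruli Total number of PB glomeruli across both hemispheres;
#'   must be even (default 18, 9 per hemisphere).
#' @return An object of class `cx_topology` with fields `n_wedges`,
#'   `n_glomeruli`, `wedge_sectors` (matrix with columns `lo`, `hi`),
#'   `glomerulus_sectors` (matrix with columns `lo`, `hi` plus rownames
#'   `L0..`, `R0..`), `glom_ids`, `glom_hemisphere`, `glom_centers`, and
#'   `wedge_to_glom_pair` (n_wedges x 2 matrix of glomerulus ids, columns
#'   `L` and `R`).
#' @examples
#' topo <- make_topology()
#' azimuth_to_wedge(topo, 60)      # 2
#' wedge_to_glomeruli(topo, 0)
#' @export
make_topology <- function(n_wedges = 16L, n_glomeruli = 18L) {
  if (!is.numeric(n_wedges) || length(n_wedges) != 1L || n_wedges < 1 ||
      n_wedges != round(n_wedges)) {
    stop("configuration error: n_wedges must be a positive integer")
  }
  if (!is.numeric(n_glomeruli) || length(n_glomeruli) != 1L ||
      n_glomeruli < 2 || n_glomeruli != round(n_glomeruli) ||
      n_glomeruli %% 2 != 0) {
    stop("configuration error: n_glomeruli must be an even integer >= 2")
  }
  n_wedges <- as.integer(n_wedges)
  n_glomeruli <- as.integer(n_glomeruli)

  ww <- 360 / n_wedges
  wedge_sectors <- cbind(lo = (0:(n_wedges - 1L)) * ww,
                         hi = (1:n_wedges) * ww)

  gw <- 360 / n_glomeruli
  n_half <- n_glomeruli %/% 2L
  # interleaved 20-degree tiles: L takes even tiles, R odd tiles
  l_lo <- (2 * (0:(n_half - 1L))) * gw
  r_lo <- (2 * (0:(n_half - 1L)) + 1) * gw
  glom_ids <- c(paste0("L", 0:(n_half - 1L)), paste0("R", 0:(n_half - 1L)))
  glomerulus_sectors <- cbind(lo = c(l_lo, r_lo), hi = c(l_lo, r_lo) + gw)
  rownames(glomerulus_sectors) <- glom_ids
  glom_centers <- (glomerulus_sectors[, "lo"] + glomerulus_sectors[, "hi"]) / 2
  glom_hemisphere <- c(rep("L", n_half), rep("R", n_half))
  names(glom_hemisphere) <- glom_ids

  topo <- structure(
    list(n_wedges = n_wedges,
         n_glomeruli = n_glomeruli,
         wedge_sectors = wedge_sectors,
         glomerulus_sectors = glomerulus_sectors,
         glom_ids = glom_ids,
         glom_hemisphere = glom_hemisphere,
         glom_centers = glom_centers),
    class = "cx_topology")
  topo$wedge_to_glom_pair <- t(vapply(
    0:(n_wedges - 1L),
    function(w) wedge_to_glomeruli(topo, w),
    character(2)))
  colnames(topo$wedge_to_glom_pair) <- c("L", "R")
  topo
}

#' Map an azimuth to its EB wedge
#'
#' Total after wrapping: azimuths outside `[0, 360)` are reduced modulo 360.
#'
#' @param topology A [make_topology()] object.
#' @param azimuth Azimuth(s) in degrees; vectorized.
#' @return Integer wedge index (0-based) for each azimuth.
#' @export
azimuth_to_wedge <- function(topology, azimuth) {
  stopifnot(inherits(topology, "cx_topology"), is.numeric(azimuth),
            all(is.finite(azimuth)))
  a <- azimuth %% 360
  w <- as.integer(floor(a / (360 / topology$n_wedges)))
  # guard against floating wrap at the upper boundary
  w[w >= topology$n_wedges] <- 0L
  w
}

#' Glomerulus pair innervating a wedge
#'
#' Returns, per hemisphere, the glomerulus whose receptive-field sector is
#' circularly nearest (by centre) to the wedge's centre azimuth, breaking ties
#' toward the lower index. With aligned grids (wedge and per-hemisphere
#' glomerulus sectors coincide) this is plain sector containment.
#'
#' @param topology A [make_topology()] object.
#' @param wedge 0-based wedge index.
#' @return Named character vector `c(L = <id>, R = <id>)`.
#' @export
wedge_to_glomeruli <- function(topology, wedge) {
  stopifnot(inherits(topology, "cx_topology"))
  if (!is.numeric(wedge) || length(wedge) != 1L || wedge != round(wedge) ||
      wedge < 0 || wedge >= topology$n_wedges) {
    stop("wedge index out of range [0, ", topology$n_wedges - 1L, "]")
  }
  ctr <- (topology$wedge_sectors[wedge + 1L, "lo"] +
          topology$wedge_sectors[wedge + 1L, "hi"]) / 2
  out <- c(L = NA_character_, R = NA_character_)
  for (h in c("L", "R")) {
    idx <- which(topology$glom_hemisphere == h)
    d <- circ_dist_deg(topology$glom_centers[idx], ctr)
    # strict minimum with ties toward the lower index
    out[h] <- topology$glom_ids[idx[which.min(round(d, 9))]]
  }
  out
}

#' Glomerulus id to 0-based index within the topology
#' @keywords internal
#' @noRd
glom_index <- function(topology, id) {
  i <- match(id, topology$glom_ids)
  if (anyNA(i)) stop("unknown glomerulus id(s): ",
                     paste(id[is.na(i)], collapse = ", "))
  i - 1L
}

#' Circular distance between azimuths, in degrees
#'
#' Shortest arc between two azimuths; always in `[0, 180]`. Vectorized.
#'
#' @param a,b Azimuths in degrees.
#' @export
circ_dist_deg <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

#' Signed circular difference a - b mapped to (-180, 180]
#' @keywords internal
#' @noRd
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' @export
print.cx_topology <- function(x, ...) {
  cat("cx_topology:", x$n_wedges, "EB wedges (",
      format(360 / x$n_wedges), "deg ),",
      x$n_glomeruli, "PB glomeruli (", format(360 / x$n_glomeruli),
      "deg, ", x$n_glomeruli %/% 2L, "per hemisphere )\n")
  invisible(x)
}

#' Centre azimuth of each wedge
#' @param topology A [make_topology()] object.
#' @return Numeric vector of wedge-centre azimuths in degrees.
#' @export
wedge_centers <- function(topology) {
  stopifnot(inherits(topology, "cx_topology"))
  (topology$wedge_sectors[, "lo"] + topology$wedge_sectors[, "hi"]) / 2
}
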