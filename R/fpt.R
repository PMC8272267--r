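# First passage time along an hourly trajectory and variance-maximising
# radius selection.
#
# FPT at fix i is the symmetric (Fauchald-Tveraa) passage time through the
# circle of a given radius centred on fix i: the time between the backward
# and forward crossings of the circle boundary. The trajectory between
# fixes is the linear-in-lon/lat polyline (the same model used by hourly
# interpolation). Crossing instants are bracketed by scanning fix-to-fix
# distances segment by segment and then refined by root-finding on the
# great-circle distance along the bracketing segment, so crossing times are
# exact for the polyline (within root tolerance) rather than linear
# approximations of a curved distance profile.

.rt_lon_unwrap <- function(rt) .unwrap_lon(rt$lon)

# full pairwise great-circle distance matrix in km
.rt_distmat <- function(rt) {
  p <- pi / 180
  lat <- rt$lat * p
  lon <- rt$lon * p
  n <- length(lat)
  slat <- sin(lat / 2); clat <- cos(lat)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    a <- sin((lat - lat[i]) / 2)^2 + clat[i] * clat * sin((lon - lon[i]) / 2)^2
    m[i, ] <- 2 * .EARTH_RADIUS_KM * asin(sqrt(pmin(a, 1)))
  }
  m
}

# exact crossing instant (seconds since epoch) of the circle of radius r_km
# centred on fix `ci`, inside the polyline segment (j0, j1); requires
# d(j0) <= r_km < d(j1).
.cross_time <- function(rt, lonu, ci, j0, j1, r_km) {
  t0 <- as.numeric(rt$timestamp[j0]); t1 <- as.numeric(rt$timestamp[j1])
  lo0 <- lonu[j0]; lo1 <- lonu[j1]
  la0 <- rt$lat[j0]; la1 <- rt$lat[j1]
  clon <- rt$lon[ci]; clat <- rt$lat[ci]
  f <- function(u) {
    haversine_km(.wrap_lon(lo0 + u * (lo1 - lo0)), la0 + u * (la1 - la0),
                 clon, clat) - r_km
  }
  f0 <- f(0)
  if (f0 >= 0) return(t0)
  u <- uniroot(f, c(0, 1), f.lower = f0, tol = 1e-7)$root
  t0 + u * (t1 - t0)
}

#' First passage time at one fix
#'
#' @param rt a `regular_track`.
#' @param i fix index.
#' @param radius_m circle radius in meters.
#' @param mode `"symmetric"` (default; backward + forward crossing) or
#'   `"forward"` (time from fix i to the forward crossing only).
#' @param .dists optional precomputed vector of distances (km) from fix i
#'   to all fixes.
#' @return passage time in hours, or NA if the trajectory never exits the
#'   circle on a required side before the data (segment) ends.
#' @export
first_passage_time <- function(rt, i, radius_m,
                               mode = c("symmetric", "forward"),
                               .dists = NULL) {
  mode <- match.arg(mode)
  n <- nrow(rt)
  if (i < 1 || i > n) stop("fix index out of range")
  stopifnot(radius_m > 0)
  r_km <- radius_m / 1000
  if (is.null(.dists)) {
    .dists <- haversine_km(rt$lon[i], rt$lat[i], rt$lon, rt$lat)
  }
  lonu <- attr(rt, ".lonu")
  if (is.null(lonu)) lonu <- .rt_lon_unwrap(rt)
  seg <- rt$segment[i]
  seg_idx <- which(rt$segment == seg)
  lo <- seg_idx[1]; hi <- seg_idx[length(seg_idx)]

  fwd <- NA_real_
  if (i < hi) {
    js <- (i + 1):hi
    k <- which(.dists[js] > r_km)[1]
    if (!is.na(k)) {
      j <- js[k]
      fwd <- .cross_time(rt, lonu, i, j - 1, j, r_km)
    }
  }
  if (mode == "forward") {
    if (is.na(fwd)) return(NA_real_)
    return((fwd - as.numeric(rt$timestamp[i])) / 3600)
  }
  bwd <- NA_real_
  if (i > lo) {
    js <- (i - 1):lo
    k <- which(.dists[js] > r_km)[1]
    if (!is.na(k)) {
      j <- js[k]
      # crossing inside segment (j, j+1), scanning backward in time
      t0 <- as.numeric(rt$timestamp[j]); t1 <- as.numeric(rt$timestamp[j + 1])
      lo0 <- lonu[j]; lo1 <- lonu[j + 1]
      la0 <- rt$lat[j]; la1 <- rt$lat[j + 1]
      clon <- rt$lon[i]; clat <- rt$lat[i]
      f <- function(u) {
        haversine_km(.wrap_lon(lo0 + u * (lo1 - lo0)), la0 + u * (la1 - la0),
                     clon, clat) - r_km
      }
      f1 <- f(1)
      if (f1 >= 0) {
        bwd <- t1
      } else {
        # d(j) > r >= d(j+1): root with f(0) > 0 > f(1); take the latest
        u <- uniroot(f, c(0, 1), f.upper = f1, tol = 1e-7)$root
        bwd <- t0 + u * (t1 - t0)
      }
    }
  }
  if (is.na(fwd) || is.na(bwd)) return(NA_real_)
  (fwd - bwd) / 3600
}

#' FPT profile of a track at one radius
#'
#' @param rt a `regular_track`.
#' @param radius_m circle radius in meters.
#' @param mode passed to [first_passage_time()].
#' @param .dmat optional precomputed pairwise distance matrix (km).
#' @return an `fpt_profile` list: `radius_m`, `fpt_h` (per-fix hours, NA
#'   allowed), `log_var` (variance of log FPT over finite entries; NA if
#'   fewer than 2).
#' @export
fpt_profile <- function(rt, radius_m, mode = "symmetric", .dmat = NULL) {
  n <- nrow(rt)
  stopifnot(n >= 1)
  if (is.null(.dmat)) .dmat <- .rt_distmat(rt)
  if (is.null(attr(rt, ".lonu"))) attr(rt, ".lonu") <- .rt_lon_unwrap(rt)
  fpt <- vapply(seq_len(n), function(i) {
    first_passage_time(rt, i, radius_m, mode = mode, .dists = .dmat[i, ])
  }, numeric(1))
  lf <- log(fpt[is.finite(fpt)])
  lv <- if (length(lf) >= 2) var(lf) else NA_real_
  structure(list(radius_m = radius_m, fpt_h = fpt, log_var = lv,
                 timestamp = rt$timestamp),
            class = "fpt_profile")
}

#' Select the FPT radius maximising the variance of log FPT
#'
#' Sweeps candidate radii and keeps the one with maximal `var(log FPT)`,
#' the scale at which behavioural heterogeneity (migration vs. restricted
#' movement) is most visible. Ties break toward the smaller radius.
#'
#' @param rt a `regular_track`.
#' @param r_min_m,r_max_m,step_m sweep bounds and step in meters
#'   (defaults 2500, 6000, 250).
#' @param mode passed to [first_passage_time()].
#' @return a `radius_selection` list: `candidate_radii_m`,
#'   `chosen_radius_m`, `log_var_by_radius`, `profile` (the profile at the
#'   chosen radius).
#' @export
select_radius <- function(rt, r_min_m = 2500, r_max_m = 6000, step_m = 250,
                          mode = "symmetric") {
  stopifnot(r_min_m <= r_max_m, step_m > 0)
  radii <- seq(r_min_m, r_max_m, by = step_m)
  dmat <- .rt_distmat(rt)
  attr(rt, ".lonu") <- .rt_lon_unwrap(rt)
  profiles <- lapply(radii, function(r) fpt_profile(rt, r, mode = mode, .dmat = dmat))
  lv <- vapply(profiles, function(p) p$log_var, numeric(1))
  if (all(is.na(lv))) stop("degenerate track: no finite FPT variance at any radius")
  best <- which(lv == max(lv, na.rm = TRUE))[1]
  structure(list(candidate_radii_m = radii,
                 chosen_radius_m = radii[best],
                 log_var_by_radius = lv,
                 profile = profiles[[best]]),
            class = "radius_selection")
}
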