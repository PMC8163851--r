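#' Monthly fractional fire contribution to simulated PM2.5
#'
#' The fraction of simulated PM2.5 attributable to open-fire emissions,
#' obtained by differencing paired chemical-transport-model runs with and
#' without fire emissions:
#' \deqn{\rho = (PM^{wfire} - PM^{nofire}) / PM^{wfire}}
#' Model nonlinearity can make the without-fire run exceed the with-fire run;
#' a negative fire contribution is physically uninterpretable, so the fraction
#' is clamped into \[0, 1\] (clamping is counted and reported via an
#' attribute). Cells where the with-fire run is exactly zero get
#' \eqn{\rho = 0}.
#'
#' @param pm_wfire,pm_nofire non-negative PM2.5 concentrations (ug/m3) from
#'   the with-fire and without-fire simulations; vectors or arrays of a common
#'   shape.
#' @return fire fraction(s) in \[0, 1\], same shape as the inputs, with an
#'   integer attribute `"n_clamped"` counting values clamped at either bound.
#' @examples
#' fire_fraction(60, 45)  # 0.25
#' fire_fraction(10, 12)  # 0, clamped
#' @seealso [calibration_rate()], [decompose_exposure()]
#' @export
fire_fraction <- function(pm_wfire, pm_nofire) {
  if (any(pm_wfire < 0, na.rm = TRUE) || any(pm_nofire < 0, na.rm = TRUE))
    stop("PM2.5 concentrations must be non-negative")
  rho <- ifelse(pm_wfire == 0, 0, (pm_wfire - pm_nofire) / pm_wfire)
  n_clamped <- sum(rho < 0 | rho > 1, na.rm = TRUE)
  rho <- pmin(pmax(rho, 0), 1)
  attr(rho, "n_clamped") <- as.integer(n_clamped)
  rho
}

#' Annual calibration rate against a satellite PM2.5 reference
#'
#' Scaling factor aligning the annual mean of the with-fire simulation with an
#' annual satellite-based PM2.5 estimate:
#' \deqn{\eta_y = PM^{satellite}_y / (\tfrac{1}{12}\sum_m PM^{wfire}_{m,y})}
#' The rate is constant across the months of one year and is applied
#' multiplicatively to the monthly simulated fields, so the calibrated annual
#' mean reproduces the reference exactly. A complete year (12 monthly values)
#' is required.
#'
#' @param pm_satellite_annual annual satellite PM2.5 (ug/m3), scalar.
#' @param monthly_wfire the 12 monthly with-fire PM2.5 values for that year.
#' @return the calibration rate, a positive scalar.
#' @examples
#' calibration_rate(40, rep(50, 12))  # 0.8
#' @export
calibration_rate <- function(pm_satellite_annual, monthly_wfire) {
  if (length(monthly_wfire) != 12L)
    stop("need exactly 12 monthly with-fire values, got ", length(monthly_wfire))
  denom <- mean(monthly_wfire)
  if (!is.finite(denom) || denom <= 0)
    stop("annual mean of with-fire PM2.5 is zero; calibration rate undefined")
  pm_satellite_annual / denom
}

#' Calibrated source decomposition of monthly PM2.5
#'
#' Converts a with-fire simulated concentration into calibrated total, fire,
#' and non-fire exposure metrics:
#' \deqn{Total = \eta\,PM^{wfire};\quad Fire = \eta\,\rho\,PM^{wfire};\quad
#'       Nonfire = \eta\,(1-\rho)\,PM^{wfire}}
#' so fire + non-fire = total identically.
#'
#' @param pm_wfire with-fire PM2.5 (ug/m3).
#' @param rho fire fraction(s) in \[0, 1\] (see [fire_fraction()]).
#' @param eta calibration rate(s), positive (see [calibration_rate()]).
#' @return a list with components `total`, `fire`, `nonfire`, each the shape
#'   of the inputs.
#' @examples
#' decompose_exposure(50, 0.25, 0.8)  # total 40, fire 10, nonfire 30
#' @export
decompose_exposure <- function(pm_wfire, rho, eta) {
  if (any(rho < 0 | rho > 1, na.rm = TRUE)) stop("rho must lie in [0, 1]")
  if (any(eta <= 0, na.rm = TRUE)) stop("eta must be positive")
  total <- eta * pm_wfire
  fire <- rho * total
  list(total = total, fire = fire, nonfire = total - fire)
}

# ---- inverse-distance-weighted downscaling --------------------------------

# Great-circle (haversine) distance in km between points given in degrees.
haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# For arbitrary query points over a regular coarse grid, return the k = 4
# nearest coarse cell centers (great-circle distance) and inverse-squared-
# distance weights. The 4 nearest centers of a regular lat/lon grid always lie
# in the 4 x 4 index window around the query point, so the search is local and
# vectorised. An exact hit on a coarse center gets all weight.
idw_weights <- function(qlat, qlon, grid_lat, grid_lon, k = 4L) {
  n <- length(qlat)
  nlat <- length(grid_lat); nlon <- length(grid_lon)
  if (nlat * nlon == 0L) stop("empty coarse field")
  res_lat <- if (nlat > 1) grid_lat[2] - grid_lat[1] else 1
  res_lon <- if (nlon > 1) grid_lon[2] - grid_lon[1] else 1
  i0 <- pmin(pmax(floor((qlat - grid_lat[1]) / res_lat) + 1L, 1L), nlat)
  j0 <- pmin(pmax(floor((qlon - grid_lon[1]) / res_lon) + 1L, 1L), nlon)
  offs <- c(-1L, 0L, 1L, 2L)
  cand_idx <- matrix(0L, n, 16L)
  cand_d <- matrix(Inf, n, 16L)
  c_ <- 0L
  for (di in offs) for (dj in offs) {
    c_ <- c_ + 1L
    ii <- pmin(pmax(i0 + di, 1L), nlat)
    jj <- pmin(pmax(j0 + dj, 1L), nlon)
    cand_idx[, c_] <- (jj - 1L) * nlat + ii
    cand_d[, c_] <- haversine_km(qlat, qlon, grid_lat[ii], grid_lon[jj])
  }
  # edge clamping repeats candidates; keep the first copy of each index.
  # Only rows whose 4 x 4 window was clamped can contain duplicates.
  edge <- i0 < 2L | i0 > nlat - 2L | j0 < 2L | j0 > nlon - 2L
  if (any(edge)) {
    er <- which(edge)
    dup <- t(apply(cand_idx[er, , drop = FALSE], 1L, duplicated))
    tmp <- cand_d[er, , drop = FALSE]
    tmp[dup] <- Inf
    cand_d[er, ] <- tmp
  }
  # pick the k nearest candidates per row (k passes of a vectorised row-min)
  idx_out <- matrix(1L, n, k)
  w_out <- matrix(0, n, k)
  d_out <- matrix(Inf, n, k)
  rows <- seq_len(n)
  for (c_ in seq_len(k)) {
    jmin <- max.col(-cand_d, ties.method = "first")
    flat <- rows + (jmin - 1L) * n
    d_out[, c_] <- cand_d[flat]
    idx_out[, c_] <- cand_idx[flat]
    cand_d[flat] <- Inf
  }
  d_out[!is.finite(d_out)] <- NA      # degenerate grids (< k cells)
  hit <- !is.na(d_out[, 1]) & d_out[, 1] < 1e-9
  w_raw <- 1 / d_out^2
  w_raw[is.na(w_raw)] <- 0
  w_out <- w_raw / rowSums(w_raw)
  if (any(hit)) {                      # exact hit on a coarse center
    w_out[hit, ] <- 0
    w_out[hit, 1] <- 1
  }
  list(idx = idx_out, w = w_out)
}

# Apply precomputed IDW weights to a (cells x layers) matrix of coarse values.
idw_apply <- function(wts, coarse_mat) {
  out <- wts$w[, 1] * coarse_mat[wts$idx[, 1], , drop = FALSE]
  for (c_ in 2:ncol(wts$w))
    out <- out + wts$w[, c_] * coarse_mat[wts$idx[, c_], , drop = FALSE]
  out
}

#' Inverse-distance-weighted downscaling of a coarse raster
#'
#' Interpolates a coarse regular lat/lon raster to fine-grid cell centers:
#' each fine value is the inverse-squared-great-circle-distance weighted mean
#' of the 4 nearest coarse cell centers. A fine center that coincides with a
#' coarse center returns that coarse value exactly, and because the weights
#' form a convex combination the fine field never exceeds the coarse field's
#' range.
#'
#' @param coarse matrix of coarse values, dimensions `length(lat) x length(lon)`,
#'   or a 3-d array with layers in the third dimension.
#' @param lat,lon coarse cell-center axes (degrees, strictly increasing).
#' @param fine_lat,fine_lon fine cell-center axes.
#' @return matrix (or 3-d array) of fine values, `length(fine_lat) x
#'   length(fine_lon)` (x layers).
#' @examples
#' z <- matrix(1:4, 2, 2)
#' idw_downscale(z, c(0, 1), c(0, 1), 0.5, 0.5)  # 2.5 by symmetry
#' @export
idw_downscale <- function(coarse, lat, lon, fine_lat, fine_lon) {
  if (length(lat) == 0L || length(lon) == 0L) stop("empty coarse field")
  stopifnot(length(lat) < 2 || all(diff(lat) > 0),
            length(lon) < 2 || all(diff(lon) > 0))
  q <- expand.grid(lat = fine_lat, lon = fine_lon, KEEP.OUT.ATTRS = FALSE)
  wts <- idw_weights(q$lat, q$lon, lat, lon)
  layers <- if (length(dim(coarse)) == 3L) dim(coarse)[3] else 1L
  cm <- matrix(coarse, nrow = length(lat) * length(lon), ncol = layers)
  fine <- idw_apply(wts, cm)
  if (layers == 1L) {
    matrix(fine, length(fine_lat), length(fine_lon))
  } else {
    array(fine, c(length(fine_lat), length(fine_lon), layers))
  }
}

#' Gestational-window mean of a monthly series
#'
#' Arithmetic mean of a monthly environmental series over an inclusive
#' gestational window, from the month of conception to the month of
#' termination (`conception + gestation - 1`). Every environmental variable
#' is averaged with the same rule. If any month of the window is missing from
#' the series the window is exposure-invalid and `NA` is returned; downstream
#' cohort construction drops such events.
#'
#' @param values monthly values, named or indexed by `months`.
#' @param months integer century-month codes aligned with `values`.
#' @param conception conception century-month code.
#' @param gestation gestation length in months (>= 1).
#' @return the window mean, or `NA_real_` if any window month is absent.
#' @examples
#' window_mean(c(1, 2, 3, 4), 1201:1204, 1201, 4)  # 2.5
#' @export
window_mean <- function(values, months, conception, gestation) {
  stopifnot(gestation >= 1)
  want <- seq.int(conception, conception + gestation - 1L)
  pos <- match(want, months)
  if (anyNA(pos)) return(NA_real_)
  mean(values[pos])
}
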