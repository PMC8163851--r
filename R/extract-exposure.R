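#' Calibrated exposure series at point locations
#'
#' Turns a simulated (or externally loaded) field stack into per-location
#' monthly exposure series following the exposure-assessment chain: each
#' location is assigned to its containing fine-grid cell (half-open intervals,
#' lower edge inclusive); the with-fire PM2.5 and the monthly fire fraction
#' are downscaled to that cell center by inverse-distance weighting of the
#' 4 nearest coarse centers; an annual calibration rate is computed per fine
#' cell and year against the satellite reference; and the calibrated total is
#' decomposed into fire and non-fire components. Burned-area fraction and
#' dry-matter emission are pixel products and are assigned from the containing
#' coarse cell without interpolation; temperature and humidity are downscaled
#' like the PM fields.
#'
#' @param fields a `field_stack` from [simulate_fields()] or [read_fields_nc()].
#' @param locations data.frame with columns `id`, `lat`, `lon`; one row per
#'   location (duplicate coordinates are shared internally).
#' @return an object of class `exposure_series`: `ids`, `months`, and
#'   matrices (`length(ids) x length(months)`) `total`, `fire`, `nonfire`,
#'   `burned_frac`, `dry_matter`, `temperature`, `humidity`, plus `eta`
#'   (`ids x years`). Row i of every matrix belongs to `ids[i]`.
#' @seealso [window_means()] for gestational-window averaging,
#'   [exposure_table()] for a long-format export.
#' @export
extract_exposure <- function(fields, locations) {
  stopifnot(all(c("id", "lat", "lon") %in% names(locations)))
  cfg <- fields$config
  n_loc <- nrow(locations)
  months <- fields$months
  n_m <- length(months)

  # containing fine cell per location
  fi <- cell_index(locations$lat, fields$fine_lat, cfg$fine_res)
  fj <- cell_index(locations$lon, fields$fine_lon, cfg$fine_res)
  fine_flat <- (fj - 1L) * length(fields$fine_lat) + fi
  qlat <- fields$fine_lat[fi]
  qlon <- fields$fine_lon[fj]

  # one IDW weight set per distinct fine cell, applied to all monthly layers
  u <- !duplicated(fine_flat)
  umap <- match(fine_flat, fine_flat[u])
  wts <- idw_weights(qlat[u], qlon[u], fields$lat, fields$lon)

  rho_coarse <- fire_fraction(fields$pm_wfire, fields$pm_nofire)
  wfire_ds <- idw_apply(wts, fields$pm_wfire)[umap, , drop = FALSE]
  rho_ds <- idw_apply(wts, rho_coarse)[umap, , drop = FALSE]
  temp_ds <- idw_apply(wts, fields$temperature)[umap, , drop = FALSE]
  hum_ds <- idw_apply(wts, fields$humidity)[umap, , drop = FALSE]
  rm(rho_coarse)

  # annual calibration per (location, year) against the satellite reference
  yr_of <- cmc_year(months)
  years <- fields$years
  sat_loc <- fields$satellite[fine_flat, , drop = FALSE]
  eta <- matrix(NA_real_, n_loc, length(years))
  eta_month <- matrix(NA_real_, n_loc, n_m)
  for (k in seq_along(years)) {
    sel <- yr_of == years[k]
    if (sum(sel) != 12L)
      stop("calibration requires complete years; year ", years[k],
           " has ", sum(sel), " months")
    denom <- rowMeans(wfire_ds[, sel, drop = FALSE])
    if (any(denom <= 0))
      stop("all-zero with-fire PM2.5 in year ", years[k],
           "; calibration rate undefined")
    eta[, k] <- sat_loc[, k] / denom
    eta_month[, sel] <- eta[, k]
  }

  dec <- decompose_exposure(wfire_ds, pmin(pmax(rho_ds, 0), 1), eta_month)
  rm(wfire_ds, rho_ds, eta_month)

  # pixel-product indicators from the containing coarse cell
  ci <- cell_index(locations$lat, fields$lat, cfg$coarse_res)
  cj <- cell_index(locations$lon, fields$lon, cfg$coarse_res)
  coarse_flat <- (cj - 1L) * length(fields$lat) + ci

  structure(
    list(ids = locations$id, months = months, years = years,
         total = dec$total, fire = dec$fire, nonfire = dec$nonfire,
         burned_frac = fields$burned_frac[coarse_flat, , drop = FALSE],
         dry_matter = fields$dry_matter[coarse_flat, , drop = FALSE],
         temperature = temp_ds, humidity = hum_ds, eta = eta),
    class = "exposure_series")
}

# Half-open containment: cell c covers [center - res/2, center + res/2).
cell_index <- function(x, centers, res) {
  if (length(centers) == 0L) stop("empty axis")
  idx <- floor((x - (centers[1] - res / 2)) / res) + 1L
  as.integer(pmin(pmax(idx, 1L), length(centers)))
}

#' @export
print.exposure_series <- function(x, ...) {
  cat(sprintf("Exposure series: %d locations x %d months\n",
              length(x$ids), length(x$months)))
  cat(sprintf("  mean total %.1f, fire %.2f, non-fire %.1f ug/m3\n",
              mean(x$total), mean(x$fire), mean(x$nonfire)))
  invisible(x)
}

#' Gestational-window means for a batch of events
#'
#' Vectorised version of [window_mean()]: for event e located at series row
#' `loc_row[e]`, averages each exposure variable over the inclusive window
#' `[conception[e], conception[e] + gestation[e] - 1]`. Events whose window
#' is not fully covered by the series get `NA` in every variable
#' (exposure-invalid; dropped during matching).
#'
#' @param series an `exposure_series`.
#' @param loc_row integer row index of each event's location in the series.
#' @param conception,gestation integer vectors, one entry per event.
#' @param vars variables to average.
#' @return data.frame with one row per event and one column per variable.
#' @export
window_means <- function(series, loc_row, conception, gestation,
                         vars = c("total", "fire", "nonfire", "burned_frac",
                                  "dry_matter", "temperature", "humidity")) {
  stopifnot(length(loc_row) == length(conception),
            length(conception) == length(gestation), all(gestation >= 1))
  months <- series$months
  n_m <- length(months)
  a <- match(conception, months)
  b <- a + gestation - 1L
  ok <- !is.na(a) & b <= n_m
  out <- as.data.frame(matrix(NA_real_, length(a), length(vars),
                              dimnames = list(NULL, vars)))
  if (!any(ok)) return(out)
  ia <- a[ok]; ib <- b[ok]; ir <- loc_row[ok]
  for (v in vars) {
    cs <- series[[v]]
    for (j in seq.int(2L, n_m)) cs[, j] <- cs[, j - 1L] + cs[, j]
    lo <- ifelse(ia > 1L, cs[cbind(ir, pmax(ia - 1L, 1L))], 0)
    out[[v]][ok] <- (cs[cbind(ir, ib)] - lo) / gestation[ok]
  }
  out
}

#' Long-format per-location exposure table
#'
#' Flattens an [extract_exposure()] result into one row per (location, month)
#' for export; see [write_exposure_csv()].
#'
#' @param series an `exposure_series`.
#' @return data.frame with columns `id`, `month_code`, `total`, `fire`,
#'   `nonfire`, `burned_frac`, `dry_matter`, `temperature`, `humidity`.
#' @export
exposure_table <- function(series) {
  n_loc <- length(series$ids)
  n_m <- length(series$months)
  data.frame(
    id = rep(series$ids, times = n_m),
    month_code = rep(series$months, each = n_loc),
    total = as.vector(series$total),
    fire = as.vector(series$fire),
    nonfire = as.vector(series$nonfire),
    burned_frac = as.vector(series$burned_frac),
    dry_matter = as.vector(series$dry_matter),
    temperature = as.vector(series$temperature),
    humidity = as.vector(series$humidity))
}

#' @rdname exposure_table
#' @param path output CSV path.
#' @export
write_exposure_csv <- function(series, path) {
  utils::write.csv(exposure_table(series), path, row.names = FALSE)
  invisible(path)
}
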