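#' NetCDF round trip for monthly field stacks
#'
#' Writes a `field_stack` to a CF-style NetCDF file: coarse monthly variables
#' on dimensions (lon, lat, time) with time in months since 1900-01, and the
#' annual satellite reference on its own fine grid (lon_fine, lat_fine, year).
#' `read_fields_nc()` restores an equivalent stack; the world configuration
#' is stored as a YAML string in a global attribute so a file is
#' self-describing.
#'
#' @param fields a `field_stack`.
#' @param path NetCDF file path.
#' @return `read_fields_nc()` returns a `field_stack`.
#' @export
write_fields_nc <- function(fields, path) {
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", fields$lat)
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", fields$lon)
  dtime <- ncdf4::ncdim_def("time", "months since 1900-01-01",
                            as.double(fields$months), unlim = TRUE)
  dflat <- ncdf4::ncdim_def("lat_fine", "degrees_north", fields$fine_lat)
  dflon <- ncdf4::ncdim_def("lon_fine", "degrees_east", fields$fine_lon)
  dyear <- ncdf4::ncdim_def("year", "calendar year", as.double(fields$years))

  units <- c(pm_wfire = "ug m-3", pm_nofire = "ug m-3", fire = "ug m-3",
             burned_frac = "%", dry_matter = "kg m-2 month-1",
             temperature = "degC", humidity = "%")
  vars <- lapply(names(units), function(v)
    ncdf4::ncvar_def(v, units[[v]], list(dlon, dlat, dtime), prec = "double"))
  names(vars) <- names(units)
  vars$satellite <- ncdf4::ncvar_def("satellite", "ug m-3",
                                     list(dflon, dflat, dyear),
                                     prec = "double")
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  nlat <- length(fields$lat); nlon <- length(fields$lon)
  for (v in names(units)) {
    arr <- array(fields[[v]], c(nlat, nlon, length(fields$months)))
    ncdf4::ncvar_put(nc, vars[[v]], aperm(arr, c(2, 1, 3)))
  }
  sat <- array(fields$satellite,
               c(length(fields$fine_lat), length(fields$fine_lon),
                 length(fields$years)))
  ncdf4::ncvar_put(nc, vars$satellite, aperm(sat, c(2, 1, 3)))
  ncdf4::ncatt_put(nc, 0, "world_config",
                   yaml::as.yaml(unclass_config(fields$config),
                                 precision = 17))
  invisible(path)
}

#' @rdname write_fields_nc
#' @export
read_fields_nc <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lat <- as.vector(nc$dim$lat$vals)
  lon <- as.vector(nc$dim$lon$vals)
  months <- as.integer(nc$dim$time$vals)
  fine_lat <- as.vector(nc$dim$lat_fine$vals)
  fine_lon <- as.vector(nc$dim$lon_fine$vals)
  years <- as.integer(nc$dim$year$vals)
  get_m <- function(v) {
    arr <- aperm(ncdf4::ncvar_get(nc, v, collapse_degen = FALSE), c(2, 1, 3))
    matrix(arr, length(lat) * length(lon), dim(arr)[3])
  }
  cfg_raw <- ncdf4::ncatt_get(nc, 0, "world_config")
  cfg <- if (cfg_raw$hasatt) {
    vals <- yaml::yaml.load(cfg_raw$value)
    vals <- vals[!vapply(vals, is.null, logical(1))]
    for (f in c("lat_range", "lon_range", "years", "age_effect",
                "loss_gestation_probs", "age_fire_log_or"))
      if (!is.null(vals[[f]])) vals[[f]] <- unlist(vals[[f]])
    if (!is.null(vals$fire_hotspots))
      vals$fire_hotspots <- as.data.frame(vals$fire_hotspots)
    do.call(world_config, vals)
  } else {
    stop("NetCDF file lacks the world_config attribute")
  }
  sat <- aperm(ncdf4::ncvar_get(nc, "satellite", collapse_degen = FALSE),
               c(2, 1, 3))
  structure(
    list(lat = lat, lon = lon, months = months,
         pm_wfire = get_m("pm_wfire"), pm_nofire = get_m("pm_nofire"),
         fire = get_m("fire"), burned_frac = get_m("burned_frac"),
         dry_matter = get_m("dry_matter"),
         temperature = get_m("temperature"), humidity = get_m("humidity"),
         fine_lat = fine_lat, fine_lon = fine_lon,
         satellite = matrix(sat, length(fine_lat) * length(fine_lon),
                            length(years)),
         years = years, hotspots = cfg$fire_hotspots, config = cfg),
    class = "field_stack")
}

# world_config as a plain list serialisable to YAML
unclass_config <- function(cfg) {
  out <- unclass(cfg)
  if (!is.null(out$fire_hotspots))
    out$fire_hotspots <- as.list(out$fire_hotspots)
  if (!is.null(out$age_fire_log_or))
    out$age_fire_log_or <- as.list(out$age_fire_log_or)
  out
}
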