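#' Gridded monthly field
#'
#' Container for a monthly (time x lat x lon) field on a regular
#' latitude-longitude grid with a land mask. Used for raw and anomaly SST,
#' velocity components and kinetic energy alike. Land cells (\code{mask ==
#' FALSE}) carry \code{NA} and are excluded from every downstream statistic.
#'
#' @param values numeric array with dimensions (time, lat, lon).
#' @param time vector of class \code{Date}, first-of-month timestamps,
#'   strictly increasing and monthly.
#' @param lat,lon numeric coordinate vectors in degrees, matching the
#'   second and third array dimensions.
#' @param mask logical (lat x lon) matrix, \code{TRUE} for ocean cells.
#'   Defaults to all-ocean.
#' @param units unit string carried along for bookkeeping (e.g. \code{"degC"},
#'   \code{"m/s"}, \code{"m2/s2"}).
#' @return An object of class \code{gridded_field}.
#' @export
gridded_field <- function(values, time, lat, lon, mask = NULL, units = "") {
  if (length(dim(values)) != 3L)
    stop_dm("`values` must be a (time x lat x lon) array")
  d <- dim(values)
  if (d[1L] != length(time) || d[2L] != length(lat) || d[3L] != length(lon))
    stop_dm("array dimensions (%d,%d,%d) do not match coordinates (%d,%d,%d)",
            d[1L], d[2L], d[3L], length(time), length(lat), length(lon))
  time <- as.Date(time)
  if (length(time) > 1L) {
    mo <- month_index(time)
    if (any(diff(mo) != 1L))
      stop_dm("`time` must be strictly increasing with a monthly step")
  }
  if (is.null(mask)) mask <- matrix(TRUE, d[2L], d[3L])
  if (!is.logical(mask) || !identical(dim(mask), d[2:3]))
    stop_dm("`mask` must be a logical (lat x lon) matrix")
  if (any(!mask)) {
    land <- which(!mask, arr.ind = TRUE)
    for (r in seq_len(nrow(land)))
      values[, land[r, 1L], land[r, 2L]] <- NA_real_
  }
  structure(list(values = values, time = time, lat = as.numeric(lat),
                 lon = as.numeric(lon), mask = mask, units = units),
            class = "gridded_field")
}

#' @export
print.gridded_field <- function(x, ...) {
  cat(sprintf("<gridded_field> %d months x %d lat x %d lon [%s]\n",
              length(x$time), length(x$lat), length(x$lon), x$units))
  cat(sprintf("  span %s .. %s, %d ocean cells (%.0f%%)\n",
              format(min(x$time)), format(max(x$time)),
              sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

## Months since year 0, used for monotonic monthly arithmetic.
month_index <- function(time) {
  lt <- as.POSIXlt(time)
  (lt$year + 1900L) * 12L + lt$mon
}

field_years <- function(field) as.POSIXlt(field$time)$year + 1900L
field_months <- function(field) as.POSIXlt(field$time)$mon + 1L

#' Monthly date sequence
#'
#' @param year first year.
#' @param n_months number of months.
#' @return a \code{Date} vector of consecutive month starts.
#' @export
monthly_dates <- function(year, n_months) {
  seq(as.Date(sprintf("%04d-01-01", year)), by = "month",
      length.out = n_months)
}

## Flatten ocean cells: returns list(idx = matrix (row=lat,col=lon),
## series = T x n matrix of ocean-cell series).
ocean_series <- function(field) {
  idx <- which(field$mask, arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])  # deterministic (lat, lon) order
  idx <- idx[ord, , drop = FALSE]
  n <- nrow(idx)
  tt <- dim(field$values)[1L]
  series <- matrix(NA_real_, tt, n)
  for (k in seq_len(n))
    series[, k] <- field$values[, idx[k, 1L], idx[k, 2L]]
  list(idx = idx, series = series)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$lat, b$lat)) && isTRUE(all.equal(a$lon, b$lon)) &&
    identical(a$mask, b$mask)
}

#' Write / read a gridded field as JSON
#'
#' Plain-text serialization (full double precision) of the field and its
#' coordinates, so that pipeline outputs round-trip losslessly through the
#' file system.
#'
#' @param field a \code{gridded_field}.
#' @param path file path.
#' @return \code{write_field} returns \code{path} invisibly;
#'   \code{read_field} returns the reconstructed \code{gridded_field}.
#' @export
write_field <- function(field, path) {
  obj <- list(
    dims = dim(field$values),
    values = as.vector(field$values),
    time = format(field$time),
    lat = field$lat, lon = field$lon,
    mask = as.vector(field$mask),
    units = field$units)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- as.integer(obj$dims)
  gridded_field(array(as.numeric(obj$values), d), as.Date(obj$time),
                obj$lat, obj$lon,
                matrix(as.logical(obj$mask), d[2L], d[3L]),
                obj$units %||% "")
}
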