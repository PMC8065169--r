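#' Remove the monthly climatology
#'
#' Subtracts, per ocean cell, the mean over all Januaries from every January,
#' and so on for each calendar month. A pure 12-month sinusoid is removed
#' exactly; the output's own climatology is zero to numerical tolerance.
#'
#' @param field a \code{gridded_field} with at least 24 months.
#' @return the deseasonalized \code{gridded_field}.
#' @export
deseasonalize <- function(field) {
  stopifnot(inherits(field, "gridded_field"))
  if (length(field$time) < 24L)
    stop_dm("deseasonalize needs at least 2 full years (24 months), got %d",
            length(field$time))
  mo <- field_months(field)
  vals <- field$values
  for (m in 1:12) {
    sel <- which(mo == m)
    if (!length(sel)) next
    clim <- colMeans(vals[sel, , , drop = FALSE], dims = 1L)
    vals[sel, , ] <- sweep(vals[sel, , , drop = FALSE], 2:3, clim)
  }
  out <- field
  out$values <- vals
  out
}

#' Remove a per-cell linear trend
#'
#' Fits ordinary least squares against the month index in every ocean cell
#' and removes the fitted line (slope and intercept, so the output has zero
#' mean and zero OLS slope per cell).
#'
#' @param field a \code{gridded_field} with at least 3 time points.
#' @return the detrended \code{gridded_field}.
#' @export
detrend <- function(field) {
  stopifnot(inherits(field, "gridded_field"))
  tt <- length(field$time)
  if (tt < 3L) stop_dm("detrend needs at least 3 time points")
  x <- seq_len(tt) - (tt + 1) / 2            # centred month index
  sxx <- sum(x^2)
  vals <- field$values
  flat <- matrix(vals, nrow = tt)            # time x (lat*lon)
  mu <- colMeans(flat)
  slope <- colSums(x * sweep(flat, 2L, mu)) / sxx
  fit <- outer(x, slope) + rep(mu, each = tt)
  out <- field
  out$values <- array(flat - fit, dim = dim(vals))
  out
}

#' Surface kinetic energy per unit mass
#'
#' \eqn{KE = (u^2 + v^2) / 2} pointwise, in m2/s2.
#'
#' @param u,v \code{gridded_field}s of the zonal and meridional velocity
#'   components on the same grid and time axis.
#' @return a \code{gridded_field} of kinetic energy.
#' @export
kinetic_energy <- function(u, v) {
  stopifnot(inherits(u, "gridded_field"), inherits(v, "gridded_field"))
  if (!same_grid(u, v) || !identical(u$time, v$time))
    stop_dm("u and v must share grid and time axis")
  out <- u
  out$values <- 0.5 * (u$values^2 + v$values^2)
  out$units <- "m2/s2"
  out
}

#' Analysis time slot
#'
#' A window of \code{delta} whole years starting at \code{yr_ini}:
#' years \code{yr_ini .. yr_ini + delta - 1} inclusive (half-open
#' \code{[yr_ini, yr_end)} with \code{yr_end = yr_ini + delta}).
#'
#' @param yr_ini first year of the slot.
#' @param delta slot length in years (>= 1).
#' @return a \code{time_slot}.
#' @export
time_slot <- function(yr_ini, delta) {
  stopifnot(delta >= 1)
  structure(list(yr_ini = as.integer(yr_ini), delta = as.integer(delta),
                 yr_end = as.integer(yr_ini + delta)),
            class = "time_slot")
}

#' @export
print.time_slot <- function(x, ...) {
  cat(sprintf("<time_slot> %d-%d (%d years)\n",
              x$yr_ini, x$yr_end - 1L, x$delta))
  invisible(x)
}

#' Extract a time slot from a field
#'
#' Retains the months with \code{yr_ini <= year < yr_end}: \code{12 * delta}
#' months for a slot fully inside the record.
#'
#' @param field a \code{gridded_field}.
#' @param slot a \code{time_slot} within the field's span.
#' @return the sliced \code{gridded_field}.
#' @export
slice_field <- function(field, slot) {
  stopifnot(inherits(field, "gridded_field"), inherits(slot, "time_slot"))
  yrs <- field_years(field)
  if (slot$yr_ini < min(yrs) || (slot$yr_end - 1L) > max(yrs))
    stop_dm("slot %d-%d outside field span %d-%d",
            slot$yr_ini, slot$yr_end - 1L, min(yrs), max(yrs))
  sel <- which(yrs >= slot$yr_ini & yrs < slot$yr_end)
  out <- field
  out$values <- field$values[sel, , , drop = FALSE]
  out$time <- field$time[sel]
  out
}

#' Sliding time slots with breakpoint exclusion
#'
#' Builds every slot \code{[y0 + n, y0 + n + delta)} that fits inside
#' \code{[y0, y_last]}. When breakpoint years split the record into regime
#' periods, a slot is kept only if it overlaps at most one period by more
#' than one year, so no slot straddles two regimes substantially.
#'
#' @param y0,y_last first and last year of the record (inclusive).
#' @param delta slot length in years.
#' @param breakpoints optional increasing vector of regime-boundary years
#'   strictly inside \code{(y0, y_last)}.
#' @return a list of \code{time_slot}s.
#' @export
make_timeslots <- function(y0, y_last, delta, breakpoints = NULL) {
  stopifnot(delta >= 1)
  starts <- seq.int(y0, y_last - delta + 1L)
  slots <- lapply(starts, time_slot, delta = delta)
  if (is.null(breakpoints) || !length(breakpoints)) return(slots)
  edges <- c(y0, sort(breakpoints), y_last + 1L)
  keep <- vapply(slots, function(s) {
    ov <- vapply(seq_len(length(edges) - 1L), function(p) {
      max(0L, min(s$yr_end, edges[p + 1L]) - max(s$yr_ini, edges[p]))
    }, 1L)
    sum(ov > 1L) <= 1L
  }, logical(1L))
  slots[keep]
}
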