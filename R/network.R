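## Lagged functional-network inference among domain signals.

#' Domain signal
#'
#' The latitude-weighted cumulative anomaly of a domain:
#' \eqn{X_A(t) = \sum_{i \in A} x_i(t) \cos\phi_i}, with \eqn{\phi_i} the
#' latitude of cell \eqn{i} in radians.
#'
#' @param cells two-column (lat, lon) index matrix of the domain's cells
#'   (e.g. \code{domain_set$domains[[k]]$cells}).
#' @param anoms the anomaly \code{gridded_field}.
#' @return numeric time series of length \code{T}.
#' @export
domain_signal <- function(cells, anoms) {
  stopifnot(inherits(anoms, "gridded_field"))
  if (is.null(dim(cells))) cells <- matrix(cells, ncol = 2L)
  if (nrow(cells) == 0L) stop_dm("empty domain has no signal")
  tt <- dim(anoms$values)[1L]
  out <- numeric(tt)
  for (r in seq_len(nrow(cells))) {
    w <- cos(anoms$lat[cells[r, 1L]] * pi / 180)
    out <- out + w * anoms$values[, cells[r, 1L], cells[r, 2L]]
  }
  out
}

#' Signals for every domain in a domain set
#'
#' @param dset a \code{domain_set}.
#' @param anoms the anomaly \code{gridded_field} the set was derived from.
#' @return a (T x D) matrix, one column per domain, named by domain id.
#' @export
domain_signals <- function(dset, anoms) {
  stopifnot(inherits(dset, "domain_set"))
  sig <- vapply(dset$domains, function(d) domain_signal(d$cells, anoms),
                numeric(dim(anoms$values)[1L]))
  colnames(sig) <- vapply(dset$domains, function(d) as.character(d$id), "")
  sig
}

#' Lagged Pearson cross-correlation
#'
#' \eqn{r_{AB}(\tau)} = Pearson correlation of \eqn{X_A(t)} with
#' \eqn{X_B(t+\tau)} over the overlapping \eqn{T - |\tau|} points, for
#' \eqn{\tau \in [-\tau_{max}, \tau_{max}]}. Satisfies the antisymmetry
#' \eqn{r_{AB}(\tau) = r_{BA}(-\tau)}. Lags with a zero-variance overlap are
#' \code{NA}.
#'
#' @param xa,xb numeric series of equal length \code{T > tau_max + 3}.
#' @param tau_max maximum lag in months.
#' @return named numeric vector over lags \code{-tau_max .. tau_max}.
#' @export
lagged_correlation <- function(xa, xb, tau_max) {
  tt <- length(xa)
  stopifnot(length(xb) == tt, tt > tau_max + 3)
  taus <- -tau_max:tau_max
  r <- vapply(taus, function(tau) {
    if (tau >= 0) { a <- xa[seq_len(tt - tau)]; b <- xb[seq_len(tt - tau) + tau] }
    else { a <- xa[seq_len(tt + tau) - tau]; b <- xb[seq_len(tt + tau)] }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, 1)
  names(r) <- taus
  r
}

## Truncated sample autocorrelation, demeaned, lags 1..L.
sample_acf <- function(x, L) {
  as.numeric(stats::acf(x, lag.max = L, plot = FALSE,
                        demean = TRUE)$acf)[-1L]
}

bartlett_lag_cap <- function(tt) min(floor(tt / 3), 50L)

## Core of the Bartlett test; rho_a/rho_b may be precomputed for speed.
bartlett_stat <- function(r, tt, tau, rho_a, rho_b) {
  v <- (1 + 2 * sum(rho_a * rho_b)) / (tt - abs(tau))
  clamped <- FALSE
  if (!is.finite(v) || v <= 0) { v <- 1 / (tt - abs(tau)); clamped <- TRUE }
  list(z = r / sqrt(v), var = v, clamped = clamped)
}

#' Bartlett-corrected significance of a lagged correlation
#'
#' Tests \eqn{r_{AB}(\tau)} against the null of two independent
#' autocorrelated series, with null variance from Bartlett's formula using
#' the product of the truncated sample autocorrelations of the two series:
#' \eqn{var = (1/(T-|\tau|)) \sum_k \hat\rho_A(k)\hat\rho_B(k)} (lags up to
#' \code{min(T/3, 50)}). The standardized statistic is referred to a t
#' distribution with \code{T - 2} degrees of freedom (or a standard normal).
#'
#' @param xa,xb the two series.
#' @param tau the lag at which \code{xb} follows \code{xa}.
#' @param level two-sided significance level in (0, 1).
#' @param dist \code{"t"} (default) or \code{"normal"} reference quantile.
#' @return logical; attributes \code{z} (standardized statistic), \code{var}
#'   (null variance) and \code{clamped} (whether the variance estimate was
#'   floored at the white-noise value \code{1/(T-|tau|)}).
#' @export
bartlett_significance <- function(xa, xb, tau, level = 0.03, dist = "t") {
  stopifnot(level > 0, level < 1)
  tt <- length(xa)
  L <- bartlett_lag_cap(tt)
  r <- lagged_correlation(xa, xb, abs(tau))[as.character(tau)]
  st <- bartlett_stat(r, tt, tau, sample_acf(xa, L), sample_acf(xb, L))
  crit <- if (dist == "normal") stats::qnorm(1 - level / 2)
          else stats::qt(1 - level / 2, df = tt - 2)
  out <- is.finite(st$z) && abs(st$z) > crit
  attr(out, "z") <- st$z
  attr(out, "var") <- st$var
  attr(out, "clamped") <- st$clamped
  out
}

## Direction rule on the significant-lag set: undirected if 0 is included,
## A->B if strictly positive, B->A if strictly negative; a mixed-sign set
## without lag 0 (possible only through spurious rejections) falls back to
## the sign of tau_star.
direction_from_lags <- function(lags, tau_star = NULL) {
  if (0L %in% lags) return("undirected")
  if (all(lags > 0L)) return("A->B")
  if (all(lags < 0L)) return("B->A")
  if (!is.null(tau_star) && tau_star != 0L)
    return(if (tau_star > 0L) "A->B" else "B->A")
  "undirected"
}

#' Infer the functional network among domain signals
#'
#' For every unordered pair of domains the lagged correlations over
#' \code{[-tau_max, tau_max]} are tested with the Bartlett-corrected
#' statistic. A link exists if any lag is significant. The reported lag set
#' \eqn{R_{AB}} is the contiguous run of significant lags containing
#' \eqn{\tau^*}, the significant lag maximizing \eqn{|r|}; isolated spurious
#' rejections far from the peak are thereby excluded. The link is undirected
#' if \eqn{0 \in R_{AB}}, directed A to B if \eqn{R_{AB}} is strictly
#' positive, B to A if strictly negative. The weight is the sample covariance
#' of the aligned series at \eqn{\tau^*} (denominator \code{N - 1}); the
#' strength of a domain is the sum of \eqn{|w|} over its links.
#'
#' @param signals (T x D) matrix of domain signals (see
#'   \code{\link{domain_signals}}), D >= 2.
#' @param tau_max maximum lag in months (default 12).
#' @param level two-sided significance level (default 0.03).
#' @param dist reference distribution for the Bartlett statistic, \code{"t"}
#'   (default) or \code{"normal"}.
#' @return an object of class \code{functional_network}: \code{nodes}
#'   (data.frame id, strength), \code{edges} (data.frame A, B, direction,
#'   tau_star, r, w, lag_set), \code{level}, \code{tau_max}.
#' @export
infer_network <- function(signals, tau_max = 12L, level = 0.03, dist = "t") {
  stopifnot(is.matrix(signals), ncol(signals) >= 2L)
  tt <- nrow(signals)
  if (tt <= tau_max + 3) stop_dm("series too short for tau_max = %d", tau_max)
  D <- ncol(signals)
  ids <- colnames(signals) %||% as.character(seq_len(D))
  L <- bartlett_lag_cap(tt)
  rho <- lapply(seq_len(D), function(j) sample_acf(signals[, j], L))
  crit <- if (dist == "normal") stats::qnorm(1 - level / 2)
          else stats::qt(1 - level / 2, df = tt - 2)
  taus <- -tau_max:tau_max
  edges <- list()
  for (a in seq_len(D - 1L)) for (b in (a + 1L):D) {
    r <- lagged_correlation(signals[, a], signals[, b], tau_max)
    sig <- logical(length(taus))
    for (k in seq_along(taus)) {
      if (is.na(r[k])) next
      st <- bartlett_stat(r[k], tt, taus[k], rho[[a]], rho[[b]])
      sig[k] <- is.finite(st$z) && abs(st$z) > crit
    }
    if (!any(sig)) next
    cand <- which(sig)
    kstar <- cand[which.max(abs(r[cand]))]
    ## contiguous significant run containing tau_star
    lo <- kstar; while (lo > 1L && sig[lo - 1L]) lo <- lo - 1L
    hi <- kstar; while (hi < length(taus) && sig[hi + 1L]) hi <- hi + 1L
    lag_set <- taus[lo:hi][sig[lo:hi]]
    tau_star <- taus[kstar]
    ## covariance of the aligned overlap at tau_star
    if (tau_star >= 0) {
      xa <- signals[seq_len(tt - tau_star), a]
      xb <- signals[seq_len(tt - tau_star) + tau_star, b]
    } else {
      xa <- signals[seq_len(tt + tau_star) - tau_star, a]
      xb <- signals[seq_len(tt + tau_star), b]
    }
    edges[[length(edges) + 1L]] <- data.frame(
      A = ids[a], B = ids[b],
      direction = direction_from_lags(lag_set, tau_star),
      tau_star = tau_star, r = unname(r[kstar]),
      w = stats::cov(xa, xb),
      lag_set = paste(lag_set, collapse = ","),
      stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(A = character(0), B = character(0),
                           direction = character(0), tau_star = integer(0),
                           r = numeric(0), w = numeric(0),
                           lag_set = character(0))
  strength <- setNames(numeric(D), ids)
  for (e in seq_len(nrow(edges))) {
    strength[edges$A[e]] <- strength[edges$A[e]] + abs(edges$w[e])
    strength[edges$B[e]] <- strength[edges$B[e]] + abs(edges$w[e])
  }
  structure(list(nodes = data.frame(id = ids, strength = unname(strength),
                                    stringsAsFactors = FALSE),
                 edges = edges, level = level, tau_max = as.integer(tau_max)),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf("<functional_network> %d nodes, %d edges (level %.3g, tau_max %d)\n",
              nrow(x$nodes), nrow(x$edges), x$level, x$tau_max))
  invisible(x)
}

#' Write / read a functional network
#'
#' The edge list goes to CSV (columns A, B, direction, tau_star, r, w,
#' lag_set), node strengths and settings to a JSON sidecar written at
#' \code{paste0(path, ".json")}.
#'
#' @param net a \code{functional_network}.
#' @param path CSV file path.
#' @return \code{write_network} returns \code{path} invisibly;
#'   \code{read_network} the reconstructed \code{functional_network}.
#' @export
write_network <- function(net, path) {
  utils::write.csv(net$edges, path, row.names = FALSE)
  jsonlite::write_json(list(nodes = net$nodes, level = net$level,
                            tau_max = net$tau_max),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  edges <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(A = "character", B = "character",
                                          lag_set = "character"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(nodes = data.frame(id = as.character(meta$nodes$id),
                                    strength = meta$nodes$strength,
                                    stringsAsFactors = FALSE),
                 edges = edges, level = meta$level,
                 tau_max = as.integer(meta$tau_max)),
            class = "functional_network")
}
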