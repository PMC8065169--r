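#' @keywords internal
"_PACKAGE"

## Run code with a temporary RNG state so generators are deterministic
## without clobbering the caller's random stream.
with_local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dm <- function(...) stop(sprintf(...), call. = FALSE)

## 4-neighbour offsets on a (lat, lon) matrix grid.
neighbors4 <- function(i, j, nlat, nlon) {
  di <- c(-1L, 1L, 0L, 0L)
  dj <- c(0L, 0L, -1L, 1L)
  ii <- i + di
  jj <- j + dj
  ok <- ii >= 1L & ii <= nlat & jj >= 1L & jj <= nlon
  cbind(ii[ok], jj[ok])
}
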