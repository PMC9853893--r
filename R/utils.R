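# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gm <- function(..., class) {
  stop(structure(
    class = c(class, "gmprog_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# Truncated normal via inverse-CDF; exact and vectorized, no rejection loop.
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

# Integer score draw with instrument-range clamping (models floor/ceiling
# effects of bounded cognitive instruments).
rscore <- function(n, mean, sd, lo = 0, hi = 30) {
  pmin(pmax(round(rnorm(n, mean, sd)), lo), hi)
}

# Linear index <-> (i,j,k) on a 3D grid, 1-based, column-major (R order).
index_to_ijk <- function(idx, dim) {
  idx0 <- idx - 1L
  i <- idx0 %% dim[1]
  j <- (idx0 %/% dim[1]) %% dim[2]
  k <- idx0 %/% (dim[1] * dim[2])
  cbind(i = i + 1L, j = j + 1L, k = k + 1L)
}

ijk_to_index <- function(ijk, dim) {
  (ijk[, 3] - 1L) * dim[1] * dim[2] + (ijk[, 2] - 1L) * dim[1] + ijk[, 1]
}

# Dice overlap of two logical arrays/vectors of equal length.
dice <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}

check_same_grid <- function(dims, what = "volumes") {
  ref <- dims[[1]]
  for (d in dims) {
    if (length(d) != 3 || !identical(as.integer(d), as.integer(ref))) {
      stop_gm("grid mismatch among ", what, ": ",
              paste(ref, collapse = "x"), " vs ", paste(d, collapse = "x"),
              class = "gmprog_shape_error")
    }
  }
  invisible(ref)
}
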