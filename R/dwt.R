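# Orthonormal Daubechies-2 discrete wavelet transform with periodic
# boundary handling. Written in-package because the artifact-correction
# step needs only this one transform; verified in the tests against an
# independent reference decomposition.

# db2 scaling (low-pass) filter; quadrature mirror gives the wavelet filter.
.db2_lo <- c(-0.12940952255092145, 0.22414386804185735,
             0.83651630373746899, 0.48296291314469025)
.db2_hi <- c(-0.48296291314469025, 0.83651630373746899,
             -0.22414386804185735, -0.12940952255092145)

# one analysis step: x (even length) -> list(approx, detail), periodised
.dwt_step <- function(x) {
  n <- length(x)
  stopifnot(n %% 2 == 0)
  hr <- rev(.db2_lo)
  gr <- rev(.db2_hi)
  k <- seq_len(n / 2)
  idx <- outer(2 * k - 3, 0:3, `+`) %% n + 1   # (2k-1+m) mod n, 0-based k
  xm <- matrix(x[idx], ncol = 4)
  list(approx = as.vector(xm %*% hr), detail = as.vector(xm %*% gr))
}

# one synthesis step, adjoint of .dwt_step (orthonormal => inverse)
.idwt_step <- function(approx, detail) {
  n <- 2L * length(approx)
  hr <- rev(.db2_lo)
  gr <- rev(.db2_hi)
  x <- numeric(n)
  k <- seq_len(n / 2)
  idx <- outer(2 * k - 3, 0:3, `+`) %% n + 1
  contrib <- outer(approx, hr) + outer(detail, gr)
  # indices within a column are distinct (stride-2 mod n), so plain
  # indexed addition is a valid scatter-add
  for (m in 1:4)
    x[idx[, m]] <- x[idx[, m]] + contrib[, m]
  x
}

# multilevel periodised decomposition; n must be a power of two
.dwt <- function(x, n_levels) {
  out <- list(details = vector("list", n_levels))
  a <- x
  for (lev in seq_len(n_levels)) {
    s <- .dwt_step(a)
    out$details[[lev]] <- s$detail
    a <- s$approx
  }
  out$approx <- a
  out
}

.idwt <- function(decomp) {
  a <- decomp$approx
  for (lev in rev(seq_along(decomp$details)))
    a <- .idwt_step(a, decomp$details[[lev]])
  a
}
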