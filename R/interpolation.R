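# Piecewise polynomial interpolants of the membrane potential over one
# communication interval. Order 3 (cubic Hermite from values and
# derivatives at substep boundaries, the default) and order 1 (linear from
# boundary values) are supported. An interpolant over an interval of S
# substeps is stored as (order + 1) * S coefficients: for each substep the
# local polynomial p(s) = c0 + c1 s + ... on s in [0, h].

#' Cubic Hermite coefficients for one substep
#'
#' Coefficients `(c0, c1, c2, c3)` of the cubic `p(s)` on `s` in `[0, h]`
#' with `p(0) = V0`, `p'(0) = dV0`, `p(h) = V1`, `p'(h) = dV1`. Vectorized:
#' with vector inputs an `n x 4` matrix is returned.
#'
#' @param V0,V1 values at the left/right substep boundary (mV)
#' @param dV0,dV1 time derivatives at the boundaries (mV/ms)
#' @param h substep duration (ms), positive
#' @return numeric vector of 4 coefficients, or an `n x 4` matrix
#' @export
hermite_coefficients <- function(V0, dV0, V1, dV1, h) {
  stopifnot(h > 0)
  c2 <- 3 * (V1 - V0) / h^2 - (2 * dV0 + dV1) / h
  c3 <- 2 * (V0 - V1) / h^3 + (dV0 + dV1) / h^2
  out <- cbind(c0 = V0, c1 = dV0, c2 = c2, c3 = c3, deparse.level = 0)
  colnames(out) <- c("c0", "c1", "c2", "c3")
  if (nrow(out) == 1L) out[1L, ] else out
}

# linear (order 1) coefficients: p(0) = V0, p(h) = V1
.linear_coefficients <- function(V0, V1, h) {
  out <- cbind(c0 = V0, c1 = (V1 - V0) / h, deparse.level = 0)
  colnames(out) <- c("c0", "c1")
  if (nrow(out) == 1L) out[1L, ] else out
}

#' Evaluate a piecewise interpolant within a communication interval
#'
#' Selects the substep containing `t_local` (`floor(t_local / h)`, with the
#' right edge of the interval assigned to the last substep) and evaluates
#' its local polynomial at the within-substep offset.
#'
#' @param coeffs numeric vector of `(order + 1) * S` coefficients for `S`
#'   substeps (substep-major: all coefficients of substep 1, then 2, ...)
#' @param t_local time within the interval, in `[0, S * h]` (ms)
#' @param h substep duration (ms)
#' @param order interpolation order (3 or 1)
#' @return interpolated membrane potential (mV); vectorized over `t_local`
#' @export
evaluate_interpolant <- function(coeffs, t_local, h, order = 3) {
  stopifnot(order %in% c(1L, 3L))
  nc <- order + 1L
  S <- length(coeffs) / nc
  if (S != round(S)) stop("coefficient count is not a multiple of order + 1")
  if (any(t_local < 0 | t_local > S * h + 1e-12))
    stop("t_local outside the communication interval")
  k <- pmin(floor(t_local / h), S - 1)
  s <- t_local - k * h
  base <- k * nc
  acc <- coeffs[base + nc]
  for (j in seq(nc - 1L, 1L)) acc <- coeffs[base + j] + s * acc
  unname(acc)
}

# Interval interpolant for all neurons at once: B is an n x (S+1) matrix of
# boundary values; DL and DR are n x S matrices holding, for each substep,
# the trajectory derivative at its left and right edge evaluated under that
# substep's (piecewise-constant) drive. Values are continuous across substep
# boundaries by construction; derivatives may jump with the noise current.
# Returns an n x ((order+1)*S) coefficient matrix, substep-major.
.interval_coefficients <- function(B, DL, DR, h, order = 3L) {
  S <- ncol(B) - 1L
  n <- nrow(B)
  nc <- order + 1L
  C <- matrix(0, n, nc * S)
  for (k in seq_len(S)) {
    idx <- (k - 1L) * nc
    if (order == 3L) {
      C[, idx + 1L] <- B[, k]
      C[, idx + 2L] <- DL[, k]
      C[, idx + 3L] <- 3 * (B[, k + 1L] - B[, k]) / h^2 -
        (2 * DL[, k] + DR[, k]) / h
      C[, idx + 4L] <- 2 * (B[, k] - B[, k + 1L]) / h^3 +
        (DL[, k] + DR[, k]) / h^2
    } else {
      C[, idx + 1L] <- B[, k]
      C[, idx + 2L] <- (B[, k + 1L] - B[, k]) / h
    }
  }
  C
}
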