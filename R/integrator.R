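# Embedded Runge-Kutta-Fehlberg 4(5) integration of the neuron dynamics
# with adaptive step-size control, vectorized over neurons.
#
# Step acceptance and step-size adaptation are controlled per neuron, using
# only that neuron's local error. The arithmetic performed for one neuron is
# therefore independent of which other neurons happen to share the state
# matrix, which makes trajectories bit-identical regardless of how the
# network is partitioned into ranks.

.RKF <- list(
  c2 = 1 / 4, c3 = 3 / 8, c4 = 12 / 13, c5 = 1, c6 = 1 / 2,
  a21 = 1 / 4,
  a31 = 3 / 32, a32 = 9 / 32,
  a41 = 1932 / 2197, a42 = -7200 / 2197, a43 = 7296 / 2197,
  a51 = 439 / 216, a52 = -8, a53 = 3680 / 513, a54 = -845 / 4104,
  a61 = -8 / 27, a62 = 2, a63 = -3544 / 2565, a64 = 1859 / 4104,
  a65 = -11 / 40,
  b41 = 25 / 216, b43 = 1408 / 2565, b44 = 2197 / 4104, b45 = -1 / 5,
  b51 = 16 / 135, b53 = 6656 / 12825, b54 = 28561 / 56430,
  b55 = -9 / 50, b56 = 2 / 55
)

.colmax8 <- function(M) {
  pmax(M[1L, ], M[2L, ], M[3L, ], M[4L, ], M[5L, ], M[6L, ], M[7L, ], M[8L, ])
}

# Advance every column of the 8 x n state matrix Y from local time 0 to h.
# drive_fn(tau, cols, V) must return the total applied current (pA) for the
# neurons in `cols` (indices into the original columns of Y) at local time
# tau (tau may be a vector, one entry per column in `cols`).
.rkf45_advance <- function(Y, params, h, abs_tol, drive_fn) {
  n <- ncol(Y)
  tt <- rep(0, n)
  dt <- rep(h, n)
  active <- rep(TRUE, n)
  K <- .RKF
  guard <- 0L
  rhs <- function(Ys, tau, cols) {
    .hh_rhs(Ys, params, drive_fn(tau, cols, Ys[1L, ]))
  }
  while (any(active)) {
    guard <- guard + 1L
    if (guard > 10000L) stop("integrator failed to reach the substep end")
    cols <- which(active)
    Ya <- Y[, cols, drop = FALSE]
    ta <- tt[cols]
    dta <- pmin(dt[cols], h - ta)
    dtm <- rep(dta, each = 8L)
    k1 <- rhs(Ya, ta, cols)
    k2 <- rhs(Ya + dtm * (K$a21 * k1), ta + K$c2 * dta, cols)
    k3 <- rhs(Ya + dtm * (K$a31 * k1 + K$a32 * k2), ta + K$c3 * dta, cols)
    k4 <- rhs(Ya + dtm * (K$a41 * k1 + K$a42 * k2 + K$a43 * k3),
              ta + K$c4 * dta, cols)
    k5 <- rhs(Ya + dtm * (K$a51 * k1 + K$a52 * k2 + K$a53 * k3 + K$a54 * k4),
              ta + K$c5 * dta, cols)
    k6 <- rhs(Ya + dtm * (K$a61 * k1 + K$a62 * k2 + K$a63 * k3 +
                            K$a64 * k4 + K$a65 * k5),
              ta + K$c6 * dta, cols)
    y4 <- Ya + dtm * (K$b41 * k1 + K$b43 * k3 + K$b44 * k4 + K$b45 * k5)
    y5 <- Ya + dtm * (K$b51 * k1 + K$b53 * k3 + K$b54 * k4 +
                        K$b55 * k5 + K$b56 * k6)
    err <- .colmax8(abs(y5 - y4))
    bad <- !is.finite(err)
    if (any(bad)) {
      badstate <- bad & dta < 1e-10
      if (any(badstate)) stop("non-finite state during integration")
      err[bad] <- Inf
    }
    accept <- err <= abs_tol
    if (any(!accept & dta < 1e-10))
      stop("step-size underflow in adaptive integrator")
    # 5th-order solution carried forward (local extrapolation)
    if (any(accept)) {
      acc <- cols[accept]
      Ynew <- y5[, accept, drop = FALSE]
      # gating variables live in [0, 1]
      Ynew[2:4, ] <- pmin(pmax(Ynew[2:4, , drop = FALSE], 0), 1)
      Y[, acc] <- Ynew
      tt[acc] <- ta[accept] + dta[accept]
      done <- tt[acc] >= h * (1 - 1e-12)
      active[acc[done]] <- FALSE
    }
    fac <- ifelse(err > 0, 0.9 * (abs_tol / err)^0.2, 5)
    fac <- pmin(pmax(fac, 0.2), 5)
    dt[cols] <- dta * fac
  }
  Y
}

#' Advance a neuron by one substep with adaptive integration
#'
#' Advances a single neuron state by exactly `h` ms using the embedded
#' Runge-Kutta-Fehlberg 4(5) pair with internal adaptive step-size control
#' to absolute tolerance `abs_tol`. The drive (external plus gap current) is
#' a function of time and membrane potential and is evaluated at the
#' internal integrator times.
#'
#' @param state named numeric state vector (see [hh_derivatives()])
#' @param params a [hh_params()] object
#' @param drive function `(t, V) -> pA` giving the total applied current at
#'   local time `t` in `[0, h]`; defaults to zero drive
#' @param h substep duration (ms), positive
#' @param abs_tol absolute error tolerance of the step controller
#' @return the state advanced by `h`
#' @export
integrate_substep <- function(state, params, drive = NULL, h = 0.1,
                              abs_tol = 1e-6) {
  stopifnot(h > 0, abs_tol > 0)
  state <- state[.STATE_NAMES]
  if (any(!is.finite(state))) stop("non-finite neuron state")
  if (is.null(drive)) drive <- function(t, V) 0
  drive_fn <- function(tau, cols, V) drive(tau, V)
  Y <- .rkf45_advance(matrix(as.numeric(state), 8L, 1L), params, h,
                      abs_tol, drive_fn)
  stats::setNames(Y[, 1L], .STATE_NAMES)
}
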