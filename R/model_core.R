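# Hodgkin-Huxley point neuron with alpha-shaped postsynaptic currents,
# gap-junction drive and piecewise-constant Gaussian noise current.
#
# State vector layout used throughout the package (one column per neuron):
#   1 V      membrane potential (mV)
#   2 m      Na activation gate
#   3 h      Na inactivation gate
#   4 n      K activation gate
#   5 dI_ex  derivative of excitatory alpha PSC (pA/ms)
#   6 I_ex   excitatory alpha PSC (pA)
#   7 dI_in  derivative of inhibitory alpha PSC (pA/ms)
#   8 I_in   inhibitory alpha PSC (pA)

.STATE_NAMES <- c("V", "m", "h", "n", "dI_ex", "I_ex", "dI_in", "I_in")

#' Hodgkin-Huxley neuron parameters
#'
#' Constructs the parameter set of the single-compartment Hodgkin-Huxley
#' point neuron with alpha-shaped postsynaptic currents used by the ring
#' benchmark. The shipped defaults are an implementation-chosen standard
#' squid-axon parameterization scaled to a 100 pF point neuron; all values
#' are configurable and no result in this package depends on the specific
#' defaults, only on structural properties of the dynamics.
#'
#' @param C_m membrane capacitance (pF)
#' @param g_Na,g_K,g_L peak sodium, potassium and leak conductances (nS)
#' @param E_Na,E_K,E_L reversal potentials (mV)
#' @param tau_syn_ex,tau_syn_in alpha-PSC time constants (ms)
#' @return a list of class `gapnet_params`
#' @export
hh_params <- function(C_m = 100, g_Na = 12000, g_K = 3600, g_L = 30,
                      E_Na = 50, E_K = -77, E_L = -54.402,
                      tau_syn_ex = 0.2, tau_syn_in = 2.0) {
  stopifnot(C_m > 0, g_Na >= 0, g_K >= 0, g_L >= 0,
            tau_syn_ex > 0, tau_syn_in > 0)
  structure(list(C_m = C_m, g_Na = g_Na, g_K = g_K, g_L = g_L,
                 E_Na = E_Na, E_K = E_K, E_L = E_L,
                 tau_syn_ex = tau_syn_ex, tau_syn_in = tau_syn_in),
            class = "gapnet_params")
}

# x / (1 - exp(-x / y)) with the removable singularity at x = 0 handled
.vtrap <- function(x, y) {
  r <- x / y
  small <- abs(r) < 1e-7
  out <- x
  out[small] <- y * (1 + r[small] / 2)
  out[!small] <- x[!small] / (1 - exp(-r[!small]))
  out
}

.alpha_m <- function(V) 0.1 * .vtrap(V + 40, 10)
.beta_m  <- function(V) 4 * exp(-(V + 65) / 18)
.alpha_h <- function(V) 0.07 * exp(-(V + 65) / 20)
.beta_h  <- function(V) 1 / (1 + exp(-(V + 35) / 10))
.alpha_n <- function(V) 0.01 * .vtrap(V + 55, 10)
.beta_n  <- function(V) 0.125 * exp(-(V + 65) / 80)

# Vectorized right-hand side. Y is an 8 x n state matrix, I_ext a length-n
# vector of total applied current (noise + gap + anything else, pA).
# Returns the 8 x n matrix of time derivatives.
.hh_rhs <- function(Y, p, I_ext) {
  V <- Y[1L, ]; m <- Y[2L, ]; hg <- Y[3L, ]; ng <- Y[4L, ]
  dIe <- Y[5L, ]; Ie <- Y[6L, ]; dIi <- Y[7L, ]; Ii <- Y[8L, ]
  I_ion <- -p$g_Na * m * m * m * hg * (V - p$E_Na) -
    p$g_K * ng^4 * (V - p$E_K) -
    p$g_L * (V - p$E_L)
  dV <- (I_ion + Ie + Ii + I_ext) / p$C_m
  dm <- .alpha_m(V) * (1 - m) - .beta_m(V) * m
  dh <- .alpha_h(V) * (1 - hg) - .beta_h(V) * hg
  dn <- .alpha_n(V) * (1 - ng) - .beta_n(V) * ng
  te <- p$tau_syn_ex; ti <- p$tau_syn_in
  rbind(dV, dm, dh, dn,
        -2 / te * dIe - Ie / (te * te), dIe,
        -2 / ti * dIi - Ii / (ti * ti), dIi, deparse.level = 0)
}

#' Gap-junction current
#'
#' Current flowing into the receiving neuron through a gap junction of
#' conductance `g`: `g * (V_partner - V_self)` (pA for nS and mV). Positive
#' current depolarizes the receiving neuron; the total gap drive on a neuron
#' is the sum of this expression over all coupled partners.
#'
#' @param g gap conductance (nS), non-negative
#' @param V_partner membrane potential of the coupled partner (mV)
#' @param V_self membrane potential of the receiving neuron (mV)
#' @return current in pA
#' @export
gap_current <- function(g, V_partner, V_self) {
  stopifnot(all(g >= 0))
  g * (V_partner - V_self)
}

#' Time derivative of the neuron state
#'
#' Evaluates the Hodgkin-Huxley right-hand side for a single neuron state:
#' capacitive voltage equation with ionic, synaptic, noise and gap currents,
#' first-order gating kinetics with voltage-dependent rates, and the damped
#' second-order alpha-PSC channels.
#'
#' @param state named numeric vector with elements
#'   `V, m, h, n, dI_ex, I_ex, dI_in, I_in`
#' @param params a [hh_params()] object
#' @param I_noise applied noise current (pA)
#' @param I_gap gap-junction current (pA)
#' @return named numeric vector of derivatives (same layout as `state`)
#' @export
hh_derivatives <- function(state, params, I_noise = 0, I_gap = 0) {
  state <- state[.STATE_NAMES]
  if (any(!is.finite(state)))
    stop("non-finite neuron state: numerical blow-up")
  d <- .hh_rhs(matrix(as.numeric(state), 8L, 1L), params, I_noise + I_gap)
  stats::setNames(d[, 1L], .STATE_NAMES)
}

#' Resting state of the neuron model
#'
#' Finds the resting fixed point (zero applied current) by root-finding on
#' the stationary voltage equation with gating variables at their
#' steady-state values, and returns the full 8-component state vector with
#' silent PSC channels.
#'
#' @param params a [hh_params()] object
#' @param interval search interval for the resting potential (mV)
#' @return named numeric state vector
#' @export
hh_resting_state <- function(params, interval = c(-90, -40)) {
  p <- params
  f <- function(V) {
    m <- .alpha_m(V) / (.alpha_m(V) + .beta_m(V))
    hg <- .alpha_h(V) / (.alpha_h(V) + .beta_h(V))
    ng <- .alpha_n(V) / (.alpha_n(V) + .beta_n(V))
    -p$g_Na * m^3 * hg * (V - p$E_Na) - p$g_K * ng^4 * (V - p$E_K) -
      p$g_L * (V - p$E_L)
  }
  V <- stats::uniroot(f, interval, tol = 1e-12)$root
  stats::setNames(
    c(V,
      .alpha_m(V) / (.alpha_m(V) + .beta_m(V)),
      .alpha_h(V) / (.alpha_h(V) + .beta_h(V)),
      .alpha_n(V) / (.alpha_n(V) + .beta_n(V)),
      0, 0, 0, 0),
    .STATE_NAMES)
}

#' Ring benchmark network
#'
#' Generates the gap-junction ring: neuron `i` is coupled to its `K_gap`
#' nearest neighbors `i +/- 1, ..., i +/- K_gap/2` (GIDs mod `N`, neighborhood
#' defined on creation order). Every physical junction is represented by two
#' directed connection entries, one stored at each endpoint, so the table has
#' exactly `N * K_gap` rows, all with weight `g`.
#'
#' @param N total number of neurons (>= 2)
#' @param K_gap gap junctions per neuron (even, < N)
#' @param g common gap conductance (nS)
#' @return data.frame with columns `source_gid`, `target_gid`, `weight`,
#'   `type` (all `"gap"`)
#' @export
build_ring <- function(N, K_gap, g = 0.1) {
  if (K_gap %% 2 != 0) stop("K_gap must be even")
  if (K_gap >= N) stop("K_gap must be smaller than N")
  if (N < 2) stop("N must be at least 2")
  offs <- c(seq_len(K_gap / 2), -seq_len(K_gap / 2))
  target <- rep(0:(N - 1), each = K_gap)
  source <- (target + offs) %% N
  data.frame(source_gid = source, target_gid = target,
             weight = g, type = "gap", stringsAsFactors = FALSE)
}

#' Random continuous-coupling network
#'
#' Directed network in which every neuron receives `K` continuous-data
#' connections from sources drawn uniformly at random (excluding itself).
#' Used for connectivity-sparsity experiments; unlike the ring it is not
#' symmetric.
#'
#' @param N total number of neurons
#' @param K incoming connections per neuron
#' @param g common weight (nS)
#' @param seed integer seed for the draw
#' @return data.frame as in [build_ring()]
#' @export
build_random_network <- function(N, K, g = 0.1, seed = 1) {
  stopifnot(N >= 2, K >= 1, K <= N - 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  target <- rep(0:(N - 1), each = K)
  source <- unlist(lapply(0:(N - 1), function(i)
    sample((0:(N - 1))[-(i + 1)], K)))
  data.frame(source_gid = source, target_gid = target,
             weight = g, type = "gap", stringsAsFactors = FALSE)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Noise specification
#'
#' Gaussian step-noise current: a fresh variate (constant over one update
#' substep of duration h) for every neuron and substep.
#'
#' @param mean mean current (pA)
#' @param std standard deviation (pA), non-negative
#' @param base_seed integer base seed of the counter-based stream
#' @return a list of class `gapnet_noise`
#' @export
noise_spec <- function(mean = 200, std = 250, base_seed = 1) {
  stopifnot(std >= 0)
  structure(list(mean = mean, std = std, base_seed = base_seed),
            class = "gapnet_noise")
}

#' Draw the noise current for (neuron, substep)
#'
#' The stream is counter-based: the returned value is a pure function of
#' `(base_seed, gid, step_index)` and therefore independent of the number of
#' ranks or threads and of iteration order. The same `(gid, step)` pair
#' always yields the same current, which also makes waveform-relaxation
#' re-integration of an interval well defined.
#'
#' @param spec a [noise_spec()] object
#' @param gid neuron global id (vectorized)
#' @param step_index 0-based global substep index (vectorized)
#' @return noise current(s) in pA
#' @export
draw_noise <- function(spec, gid, step_index) {
  stopifnot(all(step_index >= 0), all(gid >= 0))
  u <- .counter_uniform(spec$base_seed, gid, step_index)
  spec$mean + spec$std * stats::qnorm(u)
}

#' Detect threshold crossings
#'
#' Diagnostic spike detection: upward crossing of 0 mV between two
#' consecutive substep boundaries.
#'
#' @param V_prev,V_cur membrane potentials at consecutive boundaries (mV)
#' @return logical vector, TRUE where a spike occurred
#' @export
detect_spikes <- function(V_prev, V_cur) {
  V_prev < 0 & V_cur >= 0
}
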