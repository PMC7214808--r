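# Waveform-relaxation solver. Over each communication interval all neurons
# are integrated independently against piecewise-polynomial interpolants of
# their gap partners' membrane potentials; the interval is re-integrated
# (from the saved interval-start state and with identical noise values)
# until the exchanged trajectories converge or the iteration limit is
# reached. Each iteration writes fresh interpolation coefficients to the
# fixed send-buffer positions, exchanges them between the virtual ranks and
# delivers them through the receive-position tables.

# constant interpolant matrix (c0 = V on every substep) for one rank
.constant_coeffs <- function(V, sim) {
  C <- matrix(0, length(V), sim$slots)
  if (length(V)) C[, (0:(sim$S - 1L)) * sim$nc + 1L] <- V
  C
}

# evaluate the aggregated partner drive of each neuron at the interval end
# and freeze it into a constant interpolant (waveform-relaxation initial
# guess for the next interval)
.constant_from_A <- function(A, sim) {
  n <- nrow(A)
  if (!n) return(A)
  cols <- (sim$S - 1L) * sim$nc + seq_len(sim$nc)
  acc <- A[, cols[sim$nc]]
  for (j in seq(sim$nc - 1L, 1L)) acc <- A[, cols[j]] + sim$cfg$h * acc
  C <- matrix(0, n, sim$slots)
  C[, (0:(sim$S - 1L)) * sim$nc + 1L] <- acc
  C
}

# write the per-rank coefficient matrices to the send buffers, exchange
# them according to the plan, and deliver: store in each rank the n x slots
# matrix A of aggregated partner interpolants (sum over incoming
# connections of weight * source coefficients, accumulated in ascending
# source-GID order per target).
.exchange_and_deliver <- function(sim, Clist) {
  plan <- sim$infra$plan
  send <- lapply(seq_len(plan$M), function(q) {
    buf <- numeric(plan$send_size[q])
    rk <- sim$ranks[[q]]
    if (length(rk$w_buf)) buf[rk$w_buf] <- Clist[[q]][rk$w_src]
    buf
  })
  recv <- exchange(send, plan)
  for (q in seq_len(plan$M)) {
    rk <- sim$ranks[[q]]
    if (rk$n_conn > 0L) {
      P <- matrix(recv[[q]][rk$g_idx], rk$n_conn, sim$slots, byrow = TRUE)
      A0 <- rowsum(P * rk$conn_w, rk$conn_tl)
      A <- matrix(0, rk$n, sim$slots)
      A[as.integer(rownames(A0)), ] <- A0
    } else {
      A <- matrix(0, rk$n, sim$slots)
    }
    sim$ranks[[q]]$A <- A
  }
  sim
}

# integrate all neurons of one rank across the S substeps of an interval,
# starting from the rank's committed state, against the aggregated drive
# interpolant A_drive; returns end states, boundary potentials and the
# interpolation coefficients of the produced trajectories
.integrate_interval_rank <- function(rk, A_drive, noise_mat, sim) {
  n <- rk$n
  S <- sim$S; nc <- sim$nc
  h <- sim$cfg$h
  if (n == 0L)
    return(list(Y = rk$Y, B = matrix(0, 0, S + 1L),
                C = matrix(0, 0, sim$slots)))
  params <- sim$params
  gtot <- rk$gtot
  Y <- rk$Y
  B <- matrix(0, n, S + 1L)
  B[, 1L] <- Y[1L, ]
  DL <- matrix(0, n, S)
  DR <- matrix(0, n, S)
  allcols <- seq_len(n)
  for (k in seq_len(S)) {
    cfs <- A_drive[, (k - 1L) * nc + seq_len(nc), drop = FALSE]
    Ink <- noise_mat[, k]
    dr <- function(tau, cols, V) {
      acc <- cfs[cols, nc]
      for (j in seq(nc - 1L, 1L)) acc <- cfs[cols, j] + tau * acc
      acc - gtot[cols] * V + Ink[cols]
    }
    DL[, k] <- .hh_rhs(Y, params, dr(0, allcols, Y[1L, ]))[1L, ]
    Y <- .rkf45_advance(Y, params, h, sim$cfg$abs_tol, dr)
    DR[, k] <- .hh_rhs(Y, params, dr(h, allcols, Y[1L, ]))[1L, ]
    B[, k + 1L] <- Y[1L, ]
  }
  C <- .interval_coefficients(B, DL, DR, h,
                              order = sim$cfg$wfr$interpolation_order)
  list(Y = Y, B = B, C = C)
}

#' Prepare a simulation
#'
#' Builds the network, the connection infrastructure for the configured
#' communication mode, the per-rank integration plans (buffer write and
#' delivery index tables, aggregate conductances) and the initial neuron
#' states (resting state), and performs the initial exchange of constant
#' interpolants so that every rank knows its partners' starting potentials.
#'
#' @param config configuration overrides (see [default_config()])
#' @return a `gapnet_sim_state` object; advance it with [run_interval()]
#' @export
prepare_simulation <- function(config = list()) {
  cfg <- resolve_config(config)
  topo <- topology(cfg$M, cfg$T)
  conn <- if (cfg$network == "ring") build_ring(cfg$N, cfg$K_gap, cfg$g)
  else build_random_network(cfg$N, cfg$K_gap, cfg$g, seed = cfg$seed)
  S <- as.integer(round(cfg$comm_interval / cfg$h))
  nc <- as.integer(cfg$wfr$interpolation_order) + 1L
  slots <- nc * S
  infra <- build_infrastructure(conn, topo, slots, n_neurons = cfg$N,
                                mode = cfg$mode)
  params <- do.call(hh_params, cfg$params)
  nspec <- noise_spec(cfg$noise$mean, cfg$noise$std, base_seed = cfg$seed)
  rest <- hh_resting_state(params)
  ranks <- lapply(seq_len(topo$M), function(q) {
    gids <- infra$neurons[[q]]
    n <- length(gids)
    Y <- matrix(rest, 8L, n)
    if (!is.null(cfg$init_V)) Y[1L, ] <- cfg$init_V[gids + 1L]
    sp <- infra$pre$send_positions[[q]]
    sp <- sp[sp$type %in% .CONTINUOUS_TYPES, , drop = FALSE]
    li <- match(sp$gid, gids)
    nsp <- nrow(sp)
    w_buf <- if (nsp) rep(sp$pos, each = slots) + seq_len(slots)
    else integer(0)
    w_src <- if (nsp) rep(li, each = slots) +
      rep((0:(slots - 1L)) * n, times = nsp)
    else integer(0)
    tb <- infra$post$tables[[q]]
    cont <- tb[!is.na(tb$recv_pos), , drop = FALSE]
    cont <- cont[order(cont$target_gid, cont$source_gid), , drop = FALSE]
    n_conn <- nrow(cont)
    g_idx <- if (n_conn) rep(cont$recv_pos, each = slots) + seq_len(slots)
    else integer(0)
    conn_tl <- match(cont$target_gid, gids)
    gtot <- numeric(n)
    if (n_conn) {
      gs <- rowsum(cont$weight, conn_tl)
      gtot[as.integer(rownames(gs))] <- gs
    }
    list(gids = gids, n = n, Y = Y,
         w_buf = as.integer(w_buf), w_src = as.integer(w_src),
         g_idx = as.integer(g_idx), n_conn = n_conn,
         conn_tl = conn_tl, conn_w = cont$weight, gtot = gtot,
         src_mask = gids %in% sp$gid)
  })
  sim <- structure(list(cfg = cfg, topo = topo, infra = infra,
                        params = params, noise = nspec,
                        S = S, nc = nc, slots = slots,
                        ranks = ranks, interval = 0L),
                   class = "gapnet_sim_state")
  .exchange_and_deliver(sim, lapply(sim$ranks,
                                    function(rk) .constant_coeffs(rk$Y[1L, ],
                                                                  sim)))
}

#' Advance a simulation by one communication interval
#'
#' Runs the waveform-relaxation loop for the next interval: iteration 1
#' integrates against constant extrapolation of the partners' last known
#' potentials; every iteration re-integrates all neurons from the saved
#' interval-start states (with the same per-(neuron, substep) noise
#' values), exchanges the resulting interpolation coefficients, and
#' delivers them. Convergence is reached when the maximum change of the
#' substep-boundary potentials of all communicated sources between two
#' successive iterations falls below the tolerance; the loop also stops
#' after `max_iterations`. The final iteration's end states are committed
#' and the clock advances by one communication interval.
#'
#' @param sim a `gapnet_sim_state` object
#' @return list with the advanced `sim`, the `iterations` used, the final
#'   convergence `residual`, and `B` (per rank, the committed
#'   substep-boundary membrane potentials, one row per local neuron)
#' @export
run_interval <- function(sim) {
  cfg <- sim$cfg
  M <- sim$topo$M
  tol <- cfg$wfr$tolerance
  maxit <- cfg$wfr$max_iterations
  step0 <- sim$interval * sim$S
  noise_mats <- lapply(sim$ranks, function(rk) {
    if (!rk$n) return(matrix(0, 0, sim$S))
    matrix(draw_noise(sim$noise, rep(rk$gids, times = sim$S),
                      rep(step0 + 0:(sim$S - 1L), each = rk$n)),
           rk$n, sim$S)
  })
  drive <- lapply(sim$ranks, function(rk) .constant_from_A(rk$A, sim))
  prevB <- NULL
  it <- 0L
  metric <- NA_real_
  repeat {
    it <- it + 1L
    res <- lapply(seq_len(M), function(q)
      .integrate_interval_rank(sim$ranks[[q]], drive[[q]], noise_mats[[q]],
                               sim))
    B <- lapply(res, `[[`, "B")
    if (!is.null(prevB)) {
      metric <- max(0, vapply(seq_len(M), function(q) {
        mask <- sim$ranks[[q]]$src_mask
        if (!any(mask)) return(0)
        max(abs(B[[q]][mask, -1L, drop = FALSE] -
                  prevB[[q]][mask, -1L, drop = FALSE]))
      }, 0))
    }
    sim <- .exchange_and_deliver(sim, lapply(res, `[[`, "C"))
    drive <- lapply(sim$ranks, `[[`, "A")
    if ((!is.na(metric) && metric < tol) || it >= maxit) break
    prevB <- B
  }
  for (q in seq_len(M)) sim$ranks[[q]]$Y <- res[[q]]$Y
  sim$interval <- sim$interval + 1L
  list(sim = sim, iterations = it, residual = metric, B = B)
}

#' Run a complete benchmark simulation
#'
#' Builds the network and infrastructure, then advances interval by
#' interval through the initial period (`init_ms`) and the main simulation
#' (`duration_ms`), recording the membrane potentials of the requested
#' neurons at every substep boundary and collecting run statistics:
#' per-interval waveform-relaxation iteration counts and residuals,
#' exchange-buffer slot totals, and per-phase wall times (informational
#' metadata only).
#'
#' @param config configuration overrides (see [default_config()])
#' @return object of class `gapnet_sim` with elements `config`,
#'   `recordings` (data.frame `time_ms`, `gid`, `V_mV`), `spikes`
#'   (data.frame `time_ms`, `gid`), and `stats`
#' @export
run_simulation <- function(config = list()) {
  t0 <- proc.time()[["elapsed"]]
  sim <- prepare_simulation(config)
  build_time <- proc.time()[["elapsed"]] - t0
  cfg <- sim$cfg
  n_init <- as.integer(round(cfg$init_ms / cfg$comm_interval))
  n_sim <- as.integer(round(cfg$duration_ms / cfg$comm_interval))
  n_tot <- n_init + n_sim
  rec_gids <- if (is.null(cfg$record_gids)) 0:(cfg$N - 1L)
  else sort(as.integer(cfg$record_gids))
  rec_local <- lapply(seq_len(sim$topo$M), function(q) {
    which(sim$ranks[[q]]$gids %in% rec_gids)
  })
  n_rec <- length(rec_gids)
  Vrec <- matrix(NA_real_, n_rec, n_tot * sim$S + 1L)
  rec_rows <- unlist(lapply(seq_len(sim$topo$M), function(q)
    match(sim$ranks[[q]]$gids[rec_local[[q]]], rec_gids)))
  Vrec[rec_rows, 1L] <- unlist(lapply(seq_len(sim$topo$M), function(q)
    sim$ranks[[q]]$Y[1L, rec_local[[q]]]))
  iterations <- integer(n_tot)
  residuals <- numeric(n_tot)
  spike_time <- numeric(0)
  spike_gid <- integer(0)
  t1 <- proc.time()[["elapsed"]]
  init_time <- NA_real_
  for (i in seq_len(n_tot)) {
    step <- run_interval(sim)
    sim <- step$sim
    iterations[i] <- step$iterations
    residuals[i] <- step$residual
    cols <- (i - 1L) * sim$S + 1L + seq_len(sim$S)
    for (q in seq_len(sim$topo$M)) {
      loc <- rec_local[[q]]
      if (length(loc)) {
        rows <- match(sim$ranks[[q]]$gids[loc], rec_gids)
        Vrec[rows, cols] <- step$B[[q]][loc, -1L, drop = FALSE]
      }
      # diagnostic spike detection on the committed trajectory
      Bq <- step$B[[q]]
      if (nrow(Bq)) {
        up <- detect_spikes(Bq[, -ncol(Bq), drop = FALSE],
                            Bq[, -1L, drop = FALSE])
        if (any(up)) {
          w <- which(up, arr.ind = TRUE)
          spike_gid <- c(spike_gid, sim$ranks[[q]]$gids[w[, 1L]])
          spike_time <- c(spike_time,
                          ((i - 1L) * sim$S + w[, 2L]) * cfg$h)
        }
      }
    }
    if (i == n_init) init_time <- proc.time()[["elapsed"]] - t1
  }
  t2 <- proc.time()[["elapsed"]]
  sim_time <- t2 - t1 - ifelse(is.na(init_time), 0, init_time)
  if (n_init == 0L) init_time <- 0
  times <- c(0, seq_len(n_tot * sim$S) * cfg$h)
  recordings <- data.frame(
    time_ms = rep(times, each = n_rec),
    gid = rep(rec_gids, times = length(times)),
    V_mV = as.vector(Vrec))
  spikes <- data.frame(time_ms = spike_time, gid = spike_gid)
  spikes <- spikes[order(spikes$time_ms, spikes$gid), , drop = FALSE]
  row.names(spikes) <- NULL
  stats <- list(
    n_neurons = cfg$N,
    connection_entries = cfg$N * cfg$K_gap,
    mode = cfg$mode,
    M = cfg$M, T = cfg$T,
    slots_per_pair = sim$slots,
    recv_slots_per_rank = sim$infra$plan$recv_size,
    send_slots_per_rank = sim$infra$plan$send_size,
    wfr_iterations = iterations,
    wfr_residuals = residuals,
    phase_seconds = c(build = build_time, init = init_time, sim = sim_time))
  structure(list(config = cfg, recordings = recordings, spikes = spikes,
                 stats = stats),
            class = "gapnet_sim")
}

#' @export
print.gapnet_sim <- function(x, ...) {
  cat("gapnet simulation:", x$stats$n_neurons, "neurons,",
      x$stats$connection_entries, "gap connection entries\n")
  cat("  mode:", x$stats$mode, " M =", x$stats$M, " T =", x$stats$T, "\n")
  cat("  simulated:", x$config$init_ms + x$config$duration_ms,
      "ms biological time,",
      length(x$stats$wfr_iterations), "communication intervals\n")
  it <- x$stats$wfr_iterations
  if (length(it))
    cat("  WFR iterations per interval: mean", round(mean(it), 2),
        " max", max(it), "\n")
  cat("  spikes recorded:", nrow(x$spikes), "\n")
  invisible(x)
}

#' Brute-force dense-exchange reference solution
#'
#' Independent reference for the waveform-relaxation solver: the entire
#' coupled network is integrated as one system of ODEs, with every gap
#' current evaluated from the partners' instantaneous membrane potentials
#' at the internal integrator times (no interpolation, no communication
#' interval). Uses the same Runge-Kutta-Fehlberg 4(5) pair with global
#' adaptive step-size control and the identical counter-based noise stream,
#' so differences to [run_simulation()] isolate the error of the
#' interpolation/relaxation scheme. Intended for small networks.
#'
#' @param config configuration overrides (mode/M/T are irrelevant here)
#' @param abs_tol absolute tolerance of the global step controller
#' @return data.frame `time_ms`, `gid`, `V_mV` at all substep boundaries
#' @export
run_dense_reference <- function(config = list(), abs_tol = 1e-10) {
  cfg <- resolve_config(config)
  conn <- if (cfg$network == "ring") build_ring(cfg$N, cfg$K_gap, cfg$g)
  else build_random_network(cfg$N, cfg$K_gap, cfg$g, seed = cfg$seed)
  N <- cfg$N
  W <- matrix(0, N, N)
  W[cbind(conn$target_gid + 1L, conn$source_gid + 1L)] <- conn$weight
  gtot <- rowSums(W)
  params <- do.call(hh_params, cfg$params)
  nspec <- noise_spec(cfg$noise$mean, cfg$noise$std, base_seed = cfg$seed)
  Y <- matrix(hh_resting_state(params), 8L, N)
  if (!is.null(cfg$init_V)) Y[1L, ] <- cfg$init_V
  h <- cfg$h
  n_steps <- as.integer(round((cfg$init_ms + cfg$duration_ms) / h))
  Vout <- matrix(NA_real_, N, n_steps + 1L)
  Vout[, 1L] <- Y[1L, ]
  K <- .RKF
  rhs <- function(Y, Inoise) {
    V <- Y[1L, ]
    .hh_rhs(Y, params, Inoise + as.vector(W %*% V) - gtot * V)
  }
  for (s in seq_len(n_steps)) {
    Inoise <- draw_noise(nspec, 0:(N - 1L), s - 1L)
    tt <- 0
    dt <- h
    while (tt < h * (1 - 1e-12)) {
      dta <- min(dt, h - tt)
      k1 <- rhs(Y, Inoise)
      k2 <- rhs(Y + dta * (K$a21 * k1), Inoise)
      k3 <- rhs(Y + dta * (K$a31 * k1 + K$a32 * k2), Inoise)
      k4 <- rhs(Y + dta * (K$a41 * k1 + K$a42 * k2 + K$a43 * k3), Inoise)
      k5 <- rhs(Y + dta * (K$a51 * k1 + K$a52 * k2 + K$a53 * k3 +
                             K$a54 * k4), Inoise)
      k6 <- rhs(Y + dta * (K$a61 * k1 + K$a62 * k2 + K$a63 * k3 +
                             K$a64 * k4 + K$a65 * k5), Inoise)
      y4 <- Y + dta * (K$b41 * k1 + K$b43 * k3 + K$b44 * k4 + K$b45 * k5)
      y5 <- Y + dta * (K$b51 * k1 + K$b53 * k3 + K$b54 * k4 +
                         K$b55 * k5 + K$b56 * k6)
      err <- max(abs(y5 - y4))
      if (!is.finite(err)) {
        if (dta < 1e-10) stop("non-finite state in reference integration")
        dt <- dta * 0.2
        next
      }
      if (err <= abs_tol) {
        y5[2:4, ] <- pmin(pmax(y5[2:4, , drop = FALSE], 0), 1)
        Y <- y5
        tt <- tt + dta
      } else if (dta < 1e-10) {
        stop("step-size underflow in reference integration")
      }
      fac <- if (err > 0) 0.9 * (abs_tol / err)^0.2 else 5
      dt <- dta * min(max(fac, 0.2), 5)
    }
    Vout[, s + 1L] <- Y[1L, ]
  }
  times <- (0:n_steps) * h
  data.frame(time_ms = rep(times, each = N),
             gid = rep(0:(N - 1L), times = n_steps + 1L),
             V_mV = as.vector(Vout))
}
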