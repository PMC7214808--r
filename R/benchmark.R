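# Benchmark drivers: run a configured simulation and write its artifacts
# (recordings CSV, run statistics JSON, resolved config YAML), and evaluate
# scaling grids. A count-only mode reports network and buffer sizes for
# large configurations without integrating any dynamics, so configuration
# arithmetic at full benchmark scale can be checked in seconds.

# Continuous receive-buffer slots per rank for a ring network, by direct
# enumeration of the unique sources needed on rank 0 (all ranks are
# equivalent by the rotational symmetry of ring + round-robin).
.ring_unique_sources_per_rank <- function(N, K_gap, M) {
  gids0 <- seq(0L, N - 1L, by = M)
  offs <- c(seq_len(K_gap / 2), -seq_len(K_gap / 2))
  length(unique(as.vector(outer(gids0, offs, `+`)) %% N))
}

#' Count-only network and buffer statistics
#'
#' Computes, without building connection objects or integrating dynamics:
#' the total neuron count, the number of directed gap connection entries
#' (`N * K_gap`), the per-rank continuous receive-buffer slots under the
#' directed (Alltoallv) layout and under the legacy global-state
#' (Allgather) layout, and the predicted relevant-data fraction.
#'
#' @param N total neurons
#' @param K_gap gap junctions per neuron
#' @param M ranks
#' @param slots_per_pair payload slots per source pair (default: cubic
#'   interpolants on 10 substeps, i.e. 40)
#' @return named list of counts
#' @export
count_only_stats <- function(N, K_gap, M, slots_per_pair = 40L) {
  stopifnot(K_gap %% 2 == 0, K_gap < N, M >= 1)
  uniq <- .ring_unique_sources_per_rank(N, K_gap, M)
  list(n_neurons = N,
       connection_entries = N * K_gap,
       unique_pairs_per_rank = uniq,
       alltoallv_slots_per_rank = uniq * slots_per_pair,
       allgather_slots_per_rank = N * slots_per_pair,
       relevant_fraction_ring = relevant_fraction(M, K = K_gap,
                                                  topology = "ring"))
}

#' Run a benchmark configuration and write its artifacts
#'
#' Executes the build / init / sim phases for a configuration and writes
#' to `out_dir`: `recordings.csv` (`time_ms`, `gid`, `V_mV`),
#' `statistics.json` (neuron and connection-entry counts, per-rank buffer
#' slots, per-interval waveform-relaxation iteration counts, per-phase wall
#' times as informational metadata) and `config.yaml` (the resolved
#' configuration, which re-runs to identical outputs under the same seed).
#' With `count_only = TRUE` no dynamics are integrated and only the
#' configuration counts are reported and written.
#'
#' @param config configuration overrides (see [default_config()])
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing
#' @param count_only evaluate sizes only
#' @return the statistics list (invisibly the full simulation object as
#'   attribute `sim` when dynamics were run)
#' @export
run_benchmark <- function(config = list(), out_dir = NULL,
                          count_only = FALSE) {
  cfg <- resolve_config(config)
  S <- as.integer(round(cfg$comm_interval / cfg$h))
  slots <- (as.integer(cfg$wfr$interpolation_order) + 1L) * S
  if (count_only) {
    stats <- count_only_stats(cfg$N, cfg$K_gap, cfg$M,
                              slots_per_pair = slots)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(stats, file.path(out_dir, "statistics.json"),
                           auto_unbox = TRUE, digits = NA)
      config_write(cfg, file.path(out_dir, "config.yaml"))
    }
    return(stats)
  }
  sim <- run_simulation(cfg)
  stats <- sim$stats
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(sim$recordings, file.path(out_dir, "recordings.csv"),
                     row.names = FALSE)
    jsonlite::write_json(stats, file.path(out_dir, "statistics.json"),
                         auto_unbox = TRUE, digits = NA)
    config_write(cfg, file.path(out_dir, "config.yaml"))
  }
  out <- stats
  attr(out, "sim") <- sim
  invisible(out)
}

#' Scaling report over a grid of rank counts
#'
#' For every M in the grid computes (without simulating) the total network
#' size, the number of directed connection entries, the per-rank
#' continuous-buffer slots under the directed and the global-state layout,
#' and the predicted relevant-data fractions. In the weak-scaling flavor
#' the per-rank neuron count `N_M` is fixed (`N = M * N_M`); in the
#' strong-scaling flavor the total `N` is fixed.
#'
#' @param M_grid vector of rank counts
#' @param N_M neurons per rank (weak scaling; used if `N` is NULL)
#' @param N total neurons (strong scaling)
#' @param K_gap gap junctions per neuron
#' @param slots_per_pair payload slots per source pair
#' @return data.frame, one row per M
#' @export
scaling_report <- function(M_grid = c(2, 4, 8, 16, 32, 64, 128, 256, 512,
                                      1024, 2048, 3328),
                           N_M = 185, N = NULL, K_gap = 60,
                           slots_per_pair = 40L) {
  rows <- lapply(M_grid, function(M) {
    Ntot <- if (is.null(N)) M * N_M else N
    st <- count_only_stats(Ntot, K_gap, M, slots_per_pair)
    data.frame(M = M, N = Ntot,
               connection_entries = st$connection_entries,
               unique_pairs_per_rank = st$unique_pairs_per_rank,
               alltoallv_slots_per_rank = st$alltoallv_slots_per_rank,
               allgather_slots_per_rank = st$allgather_slots_per_rank,
               relevant_fraction_ring = st$relevant_fraction_ring,
               relevant_fraction_random =
                 relevant_fraction(M, Ntot / M, K_gap, method = "approx"))
  })
  do.call(rbind, rows)
}
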