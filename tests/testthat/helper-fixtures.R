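# Shared fixtures: tiny networks and infrastructures built in code.

# the hand-enumerable 4-neuron ring distributed over 2 ranks
tiny_ring_infra <- function(slots = 1L, M = 2L, T_threads = 1L,
                            mode = "alltoallv") {
  conn <- build_ring(4L, 2L, g = 0.5)
  build_infrastructure(conn, topology(M, T_threads), slots,
                       n_neurons = 4L, mode = mode)
}

# mixed-type toy network: gap ring plus spiking connections with chosen
# source/target pairs
mixed_network <- function() {
  gap <- build_ring(8L, 2L, g = 0.1)
  spk <- data.frame(source_gid = c(1L, 1L, 5L),
                    target_gid = c(0L, 2L, 3L),
                    weight = 1.5, type = "static_spike",
                    stringsAsFactors = FALSE)
  rbind(gap, spk)
}

# maximum |V| difference between two recording data.frames on the common
# (time, gid) grid
max_V_diff <- function(a, b) {
  m <- merge(a, b, by = c("time_ms", "gid"))
  max(abs(m$V_mV.x - m$V_mV.y))
}

expect_no_dup <- function(x) expect_equal(anyDuplicated(x), 0L)
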