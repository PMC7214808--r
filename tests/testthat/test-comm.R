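# Emulated collective exchanges and payload delivery.

test_that("alltoallv moves each section verbatim to its destination", {
  infra <- tiny_ring_infra(slots = 1L)
  plan <- infra$plan
  # counts are [[0,2],[2,0]]: two slots cross in each direction
  expect_equal(plan$send_counts, matrix(c(0L, 2L, 2L, 0L), 2, 2))
  send <- list(c(10, 20), c(30, 40))
  recv <- alltoallv_exchange(send, plan)
  expect_equal(recv[[1]], c(30, 40))
  expect_equal(recv[[2]], c(10, 20))
  # conservation: multiset of sent slots equals multiset of received slots
  expect_setequal(unlist(recv), unlist(send))
  expect_error(alltoallv_exchange(list(c(1), c(2, 3)), plan), "mismatch")
})

test_that("alltoallv with all-zero counts yields empty receive buffers", {
  conn <- data.frame(source_gid = 0L, target_gid = 2L, weight = 0.1,
                     type = "gap")
  # source and target both live on rank 0 (M = 2, T = 2): no cross traffic
  infra <- build_infrastructure(conn, topology(2, 2), 4L, n_neurons = 4L)
  expect_equal(sum(infra$plan$send_counts[, 2]), 0L)
  expect_equal(sum(infra$plan$send_counts[2, ]), 0L)
  recv <- alltoallv_exchange(make_buffers(infra$plan)$send, infra$plan)
  expect_equal(length(recv[[2]]), 0L)
})

test_that("allgather concatenates all send buffers in rank order", {
  send <- list(1, 2, 3)
  recv <- allgather_exchange(send)
  for (r in 1:3) expect_equal(recv[[r]], c(1, 2, 3))
  # receive size grows with the number of ranks at fixed send size
  recv5 <- allgather_exchange(as.list(as.numeric(1:5)))
  expect_equal(length(recv5[[1]]), 5L)
  # M = 1: receive equals send
  expect_equal(allgather_exchange(list(c(7, 8)))[[1]], c(7, 8))
  expect_error(allgather_exchange(list(1, c(1, 2))), "equal")
})

test_that("payload writes hit exactly the recorded positions, idempotently", {
  buf <- numeric(10)
  out <- write_gap_payload(buf, positions = c(0, 6), coeffs = c(1, 2))
  expect_equal(out, c(1, 2, 0, 0, 0, 0, 1, 2, 0, 0))
  expect_equal(write_gap_payload(out, c(0, 6), c(1, 2)), out)
  expect_error(write_gap_payload(buf, 9, c(1, 2)), "range")
  # neuron with no continuous targets: no positions, buffer unchanged
  expect_equal(write_gap_payload(buf, integer(0), c(1, 2)), buf)
})

test_that("write + exchange + deliver round-trips each payload", {
  infra <- tiny_ring_infra(slots = 2L)
  plan <- infra$plan
  send <- make_buffers(plan)$send
  # each source writes a payload encoding its gid
  for (q in 1:2) {
    sp <- infra$pre$send_positions[[q]]
    for (i in seq_len(nrow(sp)))
      send[[q]] <- write_gap_payload(send[[q]], sp$pos[i],
                                     c(sp$gid[i], sp$gid[i] + 100))
  }
  recv <- exchange(send, plan)
  for (r in 1:2) {
    del <- deliver_continuous(recv[[r]], infra$post$tables[[r]], 2L)
    expect_equal(del$payload[, 1], del$connections$source_gid)
    expect_equal(del$payload[, 2], del$connections$source_gid + 100)
    # delivery order: ascending source within ascending target
    expect_false(is.unsorted(del$connections$target_gid))
  }
  # neuron 0 on rank 0 receives the payloads of sources 1 and 3
  del0 <- deliver_continuous(exchange(send, plan)[[1]],
                             infra$post$tables[[1]], 2L)
  got <- del0$connections$source_gid[del0$connections$target_gid == 0]
  expect_equal(got, c(1, 3))
})

test_that("allgather oracle mode delivers the same payloads", {
  for (mode in c("alltoallv", "allgather")) {
    infra <- build_infrastructure(build_ring(8L, 4L, 0.3), topology(3, 2),
                                  3L, n_neurons = 8L, mode = mode)
    send <- make_buffers(infra$plan)$send
    for (q in seq_along(send)) {
      sp <- infra$pre$send_positions[[q]]
      for (i in seq_len(nrow(sp)))
        send[[q]] <- write_gap_payload(send[[q]], sp$pos[i],
                                       sp$gid[i] * c(1, 10, 100))
    }
    recv <- exchange(send, infra$plan)
    del <- deliver_continuous(recv[[1]], infra$post$tables[[1]], 3L)
    expect_equal(del$payload[, 2], del$connections$source_gid * 10)
  }
})

test_that("spikes are routed only to ranks hosting targets", {
  conn <- mixed_network()
  infra <- build_infrastructure(conn, topology(4, 1), 4L, n_neurons = 8L)
  # neuron 1 has spike targets 0 and 2 -> ranks 0 and 2; neuron 5 -> 3
  spikes <- data.frame(gid = c(1L, 5L), lag = c(0.3, 0.7))
  out <- route_spikes(spikes, infra, section_size = 8L)
  placed <- vapply(1:4, function(r)
    sum(vapply(out$sections, function(s) nrow(s[[r]]), 0L)), 0L)
  expect_equal(placed, c(1L, 0L, 1L, 1L)) # sections by destination rank
  # conservation: delivered spike-connection events = sum of target counts
  ndel <- sum(vapply(out$delivered, nrow, 0L))
  expect_equal(ndel, 3L)
  expect_equal(out$delivered[[1]]$target_gid, 0L)
  # no spikes: everything empty
  none <- route_spikes(data.frame(gid = integer(0), lag = numeric(0)),
                       infra, 8L)
  expect_equal(sum(vapply(none$delivered, nrow, 0L)), 0L)
  # overflow of the fixed-size sections is detected
  many <- data.frame(gid = rep(1L, 9), lag = runif(9))
  expect_error(route_spikes(many, infra, section_size = 8L), "overflow")
})
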