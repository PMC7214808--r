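# Round-robin assignment and two-tier connection infrastructure.

test_that("round-robin GID assignment follows vp = gid mod (M*T)", {
  expect_equal(assign_vp(0, topology(2, 12)), data.frame(rank = 0, thread = 0))
  expect_equal(assign_vp(3, topology(2, 2)), data.frame(rank = 1, thread = 1))
  av <- assign_vp(0:9, topology(1, 1))
  expect_true(all(av$rank == 0) && all(av$thread == 0))
  av <- assign_vp(0:11, topology(3, 2))
  expect_equal(av$rank, (0:11) %% 6 %% 3)
  expect_equal(av$thread, (0:11) %% 6 %/% 3)
})

test_that("postsynaptic tables store each connection once on its target rank", {
  conn <- build_ring(4L, 2L, g = 0.5)
  post <- populate_postsynaptic(conn, topology(2, 1))
  t0 <- post$tables[[1]]
  expect_setequal(paste(t0$source_gid, t0$target_gid),
                  c("1 0", "3 0", "1 2", "3 2"))
  expect_equal(sum(vapply(post$tables, nrow, 0L)), 4L * 2L)
  # degenerate topology: single rank holds everything
  p1 <- populate_postsynaptic(conn, topology(1, 1))
  expect_equal(nrow(p1$tables[[1]]), 8L)
  expect_error(populate_postsynaptic(conn, topology(2, 1), n_neurons = 3L),
               "out of range")
})

test_that("sorting by source is idempotent and permutes tables in lockstep", {
  conn <- build_ring(9L, 4L, g = 0.1)
  conn <- conn[rev(seq_len(nrow(conn))), ] # reversed creation order
  post <- populate_postsynaptic(conn, topology(2, 2))
  s1 <- sort_by_source(post)
  s2 <- sort_by_source(s1)
  expect_identical(s1$tables, s2$tables)
  for (tb in s1$tables) {
    for (th in unique(tb$thread)) {
      src <- tb$source_gid[tb$thread == th]
      expect_true(all(diff(src) >= 0))
    }
  }
  # multiset of (source, target) pairs unchanged by the permutation
  all_sorted <- do.call(rbind, s1$tables)
  expect_setequal(paste(all_sorted$source_gid, all_sorted$target_gid),
                  paste(conn$source_gid, conn$target_gid))
})

test_that("receive positions follow the five-step construction", {
  infra <- tiny_ring_infra(slots = 1L)
  # rank 0 needs sources {1, 3}, both living on rank 1
  expect_equal(infra$post$recv_counts[1, ], c(0L, 2L))
  t0 <- infra$post$tables[[1]]
  pos <- function(s, t) t0$recv_pos[t0$source_gid == s & t0$target_gid == t]
  expect_equal(pos(1, 0), pos(1, 2)) # shared slot for the shared source
  expect_equal(pos(3, 0), pos(3, 2))
  expect_setequal(c(pos(1, 0), pos(3, 0)), c(0L, 1L))
})

test_that("thread-separated targets of one source share a buffer slot", {
  # N=8 ring on 2 ranks x 2 threads: source 1 targets 0 (thread 0) and
  # 2 (thread 1), both on rank 0 -> one unique pair, one slot
  conn <- build_ring(8L, 2L, g = 0.1)
  infra <- build_infrastructure(conn, topology(2, 2), 1L, n_neurons = 8L)
  t0 <- infra$post$tables[[1]]
  p1 <- unique(t0$recv_pos[t0$source_gid == 1])
  expect_length(p1, 1L)
  targets <- t0$target_gid[t0$source_gid == 1]
  th <- assign_vp(targets, topology(2, 2))$thread
  expect_gt(length(unique(th)), 1L) # genuinely thread-separated
})

test_that("single-rank layout assigns consecutive pair positions", {
  conn <- build_ring(6L, 2L, g = 0.1)
  infra <- build_infrastructure(conn, topology(1, 1), 1L, n_neurons = 6L)
  pr <- infra$post$pairs[[1]]
  expect_equal(sort(pr$abs_slot), 0:(nrow(pr) - 1L))
})

test_that("presynaptic send positions serve all targets on a rank once", {
  infra <- tiny_ring_infra(slots = 1L)
  sp1 <- infra$pre$send_positions[[2]] # rank 1 holds neurons 1 and 3
  n1 <- sp1[sp1$gid == 1, ]
  expect_equal(nrow(n1[n1$dest_rank == 0, ]), 1L)
  expect_no_dup(sp1[c("gid", "type", "pos")])
  # plan symmetry
  expect_equal(infra$plan$send_counts, t(infra$plan$recv_counts))
})

test_that("infrastructure invariants hold on randomized networks", {
  set.seed(7)
  for (case in 1:6) {
    N <- sample(6:40, 1)
    K <- sample(seq(2, min(8, N - 2), by = 2), 1)
    M <- sample(1:4, 1)
    Tt <- sample(1:3, 1)
    slots <- sample(c(1L, 4L, 40L), 1)
    conn <- build_random_network(N, K, seed = case)
    infra <- build_infrastructure(conn, topology(M, Tt), slots,
                                  n_neurons = N)
    # bijection: every continuous connection has a receive position ...
    allpos <- unlist(lapply(infra$post$tables, function(tb) tb$recv_pos))
    expect_false(anyNA(allpos))
    # ... and every allotted slot block is referenced by >= 1 connection
    for (r in seq_len(M)) {
      tb <- infra$post$tables[[r]]
      npair <- nrow(infra$post$pairs[[r]])
      expect_setequal(unique(tb$recv_pos), (0:(npair - 1L)) * slots)
      expect_equal(sum(infra$plan$recv_counts[r, ]), npair * slots)
    }
    # send-position uniqueness per sender
    for (q in seq_len(M))
      expect_no_dup(infra$pre$send_positions[[q]][c("gid", "type", "pos")])
    # plan symmetry and conservation of connection entries
    expect_equal(infra$plan$send_counts, t(infra$plan$recv_counts))
    expect_equal(sum(vapply(infra$post$tables, nrow, 0L)), N * K)
    # directed layout never needs more slots than the global-state layout
    ag <- build_infrastructure(conn, topology(M, Tt), slots,
                               n_neurons = N, mode = "allgather")
    expect_true(all(infra$plan$recv_size <= ag$plan$recv_size))
  }
})

test_that("exchange plan is independent of the thread count", {
  conn <- build_random_network(30L, 4L, seed = 2)
  plans <- lapply(c(1L, 2L, 5L), function(Tt)
    build_infrastructure(conn, topology(3, Tt), 40L, n_neurons = 30L)$plan)
  expect_equal(plans[[1]]$send_counts, plans[[2]]$send_counts)
  expect_equal(plans[[1]]$send_counts, plans[[3]]$send_counts)
  expect_equal(plans[[1]]$recv_displ, plans[[2]]$recv_displ)
})
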