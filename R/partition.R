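# Round-robin distribution of neurons over virtual ranks and threads, and
# construction of the two-tier connection infrastructure: postsynaptic
# connection/source/receive-position tables, presynaptic send-position and
# spike-target tables, and the exchange plan (per-rank-pair slot counts and
# displacements) that drives the Alltoallv-semantics communication.
#
# Ranks and threads are virtual: all "ranks" live in one R process and the
# rank boundary is a strict data interface (no state is read across ranks
# except through an exchange). Threads are logical containers that shape
# the table layout; execution is serial.

# synapse types carrying continuous payloads (as opposed to spike events)
.CONTINUOUS_TYPES <- c("gap", "rate")
.TYPE_ORDER <- c("gap", "rate", "static_spike")

.type_code <- function(type) {
  code <- match(type, .TYPE_ORDER)
  if (anyNA(code)) stop("unknown synapse type: ",
                        paste(unique(type[is.na(code)]), collapse = ", "))
  code
}

#' Virtual topology
#'
#' @param M number of (virtual) MPI ranks, >= 1
#' @param T_threads threads per rank, >= 1
#' @return a list of class `gapnet_topology`
#' @export
topology <- function(M = 1, T_threads = 1) {
  stopifnot(M >= 1, T_threads >= 1)
  structure(list(M = as.integer(M), T = as.integer(T_threads)),
            class = "gapnet_topology")
}

#' Round-robin GID to (rank, thread) assignment
#'
#' A neuron's virtual process is `vp = gid mod (M * T)`; its rank is
#' `vp mod M` and its thread `vp div M`. The rank of any neuron can thus be
#' recovered from its GID alone, which the receive-position construction
#' relies on.
#'
#' @param gid neuron global id(s), 0-based
#' @param topo a [topology()] object
#' @return data.frame with columns `rank` and `thread`
#' @export
assign_vp <- function(gid, topo) {
  stopifnot(all(gid >= 0))
  vp <- gid %% (topo$M * topo$T)
  data.frame(rank = vp %% topo$M, thread = vp %/% topo$M)
}

#' Build the postsynaptic connection and source tables
#'
#' Stores every directed connection exactly once, on the rank and thread of
#' its target neuron, grouped by thread and synapse type. Each table row
#' plays the role of three positionally-locked entries of the connection
#' infrastructure: the connection object (`target_gid`, `weight`), the
#' source entry (`source_gid`), and -- after
#' [compute_receive_positions()] -- the receive-buffer position.
#'
#' @param connections data.frame with `source_gid`, `target_gid`, `weight`
#'   and optionally `type` (default `"gap"`)
#' @param topo a [topology()] object
#' @param n_neurons total number of neurons (for GID validation); defaults
#'   to `max(gid) + 1`
#' @return list of class `gapnet_post` with one data.frame per rank
#'   (`thread`, `type`, `index`, `source_gid`, `target_gid`, `weight`)
#' @export
populate_postsynaptic <- function(connections, topo, n_neurons = NULL) {
  conn <- connections
  if (is.null(conn$type)) conn$type <- "gap"
  if (is.null(n_neurons))
    n_neurons <- max(conn$source_gid, conn$target_gid) + 1
  if (any(conn$target_gid < 0 | conn$target_gid >= n_neurons))
    stop("target gid out of range")
  if (any(conn$source_gid < 0 | conn$source_gid >= n_neurons))
    stop("source gid out of range")
  vp <- assign_vp(conn$target_gid, topo)
  conn$thread <- vp$thread
  tables <- lapply(0:(topo$M - 1), function(r) {
    rows <- conn[vp$rank == r, , drop = FALSE]
    # group by thread then synapse type, creation order within groups
    ord <- order(rows$thread, .type_code(rows$type))
    rows <- rows[ord, , drop = FALSE]
    idx <- stats::ave(seq_len(nrow(rows)),
                      rows$thread, rows$type, FUN = seq_along)
    data.frame(thread = rows$thread, type = rows$type,
               index = if (nrow(rows)) as.integer(idx) else integer(0),
               source_gid = rows$source_gid, target_gid = rows$target_gid,
               weight = rows$weight, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  structure(list(tables = tables, topology = topo,
                 n_neurons = as.integer(n_neurons)),
            class = "gapnet_post")
}

#' Sort postsynaptic tables by source GID
#'
#' Within each (thread, synapse type) group, orders the entries by
#' ascending source GID. The connection, source and receive-position
#' entries are one data.frame row, so they are permuted in lockstep by
#' construction. Optional optimization step; all downstream constructions
#' work on sorted and unsorted tables alike.
#'
#' @param post a `gapnet_post` object
#' @return the sorted `gapnet_post` object
#' @export
sort_by_source <- function(post) {
  post$tables <- lapply(post$tables, function(tb) {
    ord <- order(tb$thread, .type_code(tb$type), tb$source_gid)
    tb <- tb[ord, , drop = FALSE]
    tb$index <- if (nrow(tb))
      as.integer(stats::ave(seq_len(nrow(tb)), tb$thread, tb$type,
                            FUN = seq_along)) else integer(0)
    row.names(tb) <- NULL
    tb
  })
  post
}

#' Compute receive-buffer positions for continuous-data connections
#'
#' Implements the five construction steps on every rank: (i) retrieve
#' source GID and synapse type for each continuous-data connection, (ii)
#' form the set of unique (source GID, type) pairs across all local
#' threads, (iii) group the pairs by the rank of their source (recovered
#' from the GID via the round-robin distribution), ordering pairs within
#' each rank block deterministically by (type, source GID) and tracking the
#' data volume expected from every rank, (iv) turn relative positions into
#' absolute receive-buffer positions by concatenating the rank blocks in
#' ascending source-rank order, and (v) store the absolute position for
#' every continuous-data connection. Each unique pair occupies
#' `slots_per_pair` consecutive payload slots.
#'
#' @param post a `gapnet_post` object
#' @param slots_per_pair payload slots per (source, type) pair
#' @return the `gapnet_post` object with a `recv_pos` column (0-based
#'   absolute first slot; NA for spiking connections), per-rank `pairs`
#'   tables, and a `recv_counts` M x M matrix (`[r, q]` = slots rank r
#'   receives from rank q)
#' @export
compute_receive_positions <- function(post, slots_per_pair) {
  stopifnot(slots_per_pair >= 1)
  topo <- post$topology
  M <- topo$M
  recv_counts <- matrix(0L, M, M)
  pairs_by_rank <- vector("list", M)
  for (r in seq_len(M)) {
    tb <- post$tables[[r]]
    cont <- tb$type %in% .CONTINUOUS_TYPES
    if (!any(cont)) {
      post$tables[[r]]$recv_pos <- rep(NA_integer_, nrow(tb))
      pairs_by_rank[[r]] <- data.frame(type = character(0),
                                       source_gid = integer(0),
                                       src_rank = integer(0),
                                       rel_slot = integer(0),
                                       abs_slot = integer(0))
      next
    }
    key <- paste(tb$type[cont], tb$source_gid[cont])
    pairs <- tb[cont, c("type", "source_gid")][!duplicated(key), ,
                                               drop = FALSE]
    pairs$src_rank <- assign_vp(pairs$source_gid, topo)$rank
    pairs <- pairs[order(pairs$src_rank, .type_code(pairs$type),
                         pairs$source_gid), , drop = FALSE]
    n_from <- tabulate(pairs$src_rank + 1L, nbins = M)
    recv_counts[r, ] <- n_from * slots_per_pair
    displ <- cumsum(c(0L, utils::head(n_from, -1L))) * slots_per_pair
    rel_idx <- as.integer(stats::ave(seq_len(nrow(pairs)), pairs$src_rank,
                                     FUN = seq_along)) - 1L
    pairs$rel_slot <- rel_idx * slots_per_pair
    pairs$abs_slot <- displ[pairs$src_rank + 1L] + pairs$rel_slot
    row.names(pairs) <- NULL
    pairs_by_rank[[r]] <- pairs
    pos <- rep(NA_integer_, nrow(tb))
    pos[cont] <- pairs$abs_slot[match(key, paste(pairs$type,
                                                 pairs$source_gid))]
    post$tables[[r]]$recv_pos <- pos
  }
  post$pairs <- pairs_by_rank
  post$recv_counts <- recv_counts
  post$slots_per_pair <- as.integer(slots_per_pair)
  post
}

#' Build the presynaptic infrastructure and the exchange plan
#'
#' From the receive positions computed on every rank, derives on each
#' sending rank the table of send-buffer positions (one per unique
#' (destination rank, source, type) combination, so each send position
#' appears exactly once per sender), the spike target tables, and the
#' exchange plan whose send counts mirror the receive counts of the
#' destination ranks (`send_counts[q, r] == recv_counts[r, q]`).
#'
#' @param post a `gapnet_post` object after [compute_receive_positions()]
#' @return list of class `gapnet_presyn` with `send_positions` (per rank),
#'   `spike_targets` (per rank), and `plan` (class `gapnet_plan`)
#' @export
build_presynaptic <- function(post) {
  topo <- post$topology
  M <- topo$M
  slots <- post$slots_per_pair
  recv_counts <- post$recv_counts
  send_counts <- t(recv_counts)
  send_displ <- t(apply(send_counts, 1L, function(x)
    cumsum(c(0L, utils::head(x, -1L)))))
  if (M == 1L) send_displ <- matrix(0L, 1L, 1L)
  recv_displ <- t(apply(recv_counts, 1L, function(x)
    cumsum(c(0L, utils::head(x, -1L)))))
  if (M == 1L) recv_displ <- matrix(0L, 1L, 1L)
  send_positions <- vector("list", M)
  for (q in seq_len(M)) {
    acc <- vector("list", M)
    for (r in seq_len(M)) {
      pr <- post$pairs[[r]]
      mine <- pr[pr$src_rank == q - 1L, , drop = FALSE]
      if (!nrow(mine)) next
      acc[[r]] <- data.frame(gid = mine$source_gid, type = mine$type,
                             dest_rank = r - 1L,
                             pos = send_displ[q, r] + mine$rel_slot,
                             stringsAsFactors = FALSE)
    }
    sp <- do.call(rbind, acc)
    if (is.null(sp))
      sp <- data.frame(gid = integer(0), type = character(0),
                       dest_rank = integer(0), pos = integer(0))
    # a send position must appear only once per sender
    sp <- sp[!duplicated(sp[c("gid", "type", "pos")]), , drop = FALSE]
    sp <- sp[order(sp$gid, .type_code(sp$type), sp$pos), , drop = FALSE]
    row.names(sp) <- NULL
    send_positions[[q]] <- sp
  }
  # spike targets: for every spiking connection, the location of the target
  # connection (rank, thread, type, index) recorded on the source's rank
  spike_targets <- vector("list", M)
  for (q in seq_len(M)) spike_targets[[q]] <- list()
  for (r in seq_len(M)) {
    tb <- post$tables[[r]]
    sp <- tb[!(tb$type %in% .CONTINUOUS_TYPES), , drop = FALSE]
    if (!nrow(sp)) next
    src_rank <- assign_vp(sp$source_gid, topo)$rank
    for (q in unique(src_rank)) {
      rows <- sp[src_rank == q, , drop = FALSE]
      spike_targets[[q + 1L]][[length(spike_targets[[q + 1L]]) + 1L]] <-
        data.frame(source_gid = rows$source_gid, dest_rank = r - 1L,
                   thread = rows$thread, type = rows$type,
                   index = rows$index, stringsAsFactors = FALSE)
    }
  }
  spike_targets <- lapply(spike_targets, function(x) {
    if (length(x)) {
      tt <- do.call(rbind, x)
      tt <- tt[order(tt$source_gid, tt$dest_rank, tt$thread, tt$index), ,
               drop = FALSE]
      row.names(tt) <- NULL
      tt
    } else data.frame(source_gid = integer(0), dest_rank = integer(0),
                      thread = integer(0), type = character(0),
                      index = integer(0))
  })
  plan <- .make_plan(send_counts, recv_counts, send_displ, recv_displ,
                     mode = "alltoallv")
  # plan validation: slots promised by send positions match the plan
  for (q in seq_len(M)) for (r in seq_len(M)) {
    npos <- sum(send_positions[[q]]$dest_rank == r - 1L)
    if (npos * slots != send_counts[q, r])
      stop("inconsistent exchange plan: rank ", q - 1L, " -> ", r - 1L)
  }
  structure(list(send_positions = send_positions,
                 spike_targets = spike_targets, plan = plan),
            class = "gapnet_presyn")
}

.make_plan <- function(send_counts, recv_counts, send_displ, recv_displ,
                       mode) {
  if (!isTRUE(all.equal(send_counts, t(recv_counts))))
    stop("exchange plan asymmetric: send_counts[q, r] != recv_counts[r, q]")
  structure(list(send_counts = send_counts, recv_counts = recv_counts,
                 send_displ = send_displ, recv_displ = recv_displ,
                 send_size = rowSums(send_counts),
                 recv_size = rowSums(recv_counts),
                 mode = mode, M = nrow(send_counts)),
            class = "gapnet_plan")
}

#' Build the complete connection infrastructure
#'
#' Convenience driver: postsynaptic tables, optional sort by source,
#' receive positions, presynaptic tables and exchange plan, for either the
#' directed (`alltoallv`) layout or the legacy global-state (`allgather`)
#' layout used as correctness oracle. In allgather mode every rank sends
#' the interpolants of all its local sources (padded to a common section
#' size) and every rank receives the rank-ordered concatenation of all send
#' buffers; receive positions then index into the global receive buffer.
#'
#' @param connections connection data.frame (see [populate_postsynaptic()])
#' @param topo a [topology()] object
#' @param slots_per_pair payload slots per (source, type) pair
#' @param n_neurons total neuron count
#' @param mode `"alltoallv"` or `"allgather"`
#' @param sort sort postsynaptic tables by source GID first
#' @return a list of class `gapnet_infra`
#' @export
build_infrastructure <- function(connections, topo, slots_per_pair,
                                 n_neurons = NULL,
                                 mode = c("alltoallv", "allgather"),
                                 sort = TRUE) {
  mode <- match.arg(mode)
  post <- populate_postsynaptic(connections, topo, n_neurons)
  if (sort) post <- sort_by_source(post)
  if (mode == "alltoallv") {
    post <- compute_receive_positions(post, slots_per_pair)
    pre <- build_presynaptic(post)
  } else {
    built <- .allgather_layout(connections, post, topo, slots_per_pair)
    post <- built$post
    pre <- built$pre
  }
  neurons <- lapply(0:(topo$M - 1), function(r) {
    gids <- 0:(post$n_neurons - 1)
    gids[assign_vp(gids, topo)$rank == r]
  })
  structure(list(topology = topo, mode = mode,
                 slots_per_pair = as.integer(slots_per_pair),
                 post = post, pre = pre, plan = pre$plan,
                 neurons = neurons, n_neurons = post$n_neurons),
            class = "gapnet_infra")
}

# Legacy layout: each rank's send buffer holds one section per local source
# pair in (type, gid) order, padded to the maximum section size across
# ranks; the receive buffer is the concatenation of all send buffers.
.allgather_layout <- function(connections, post, topo, slots_per_pair) {
  M <- topo$M
  conn <- connections
  if (is.null(conn$type)) conn$type <- "gap"
  cont <- conn[conn$type %in% .CONTINUOUS_TYPES, , drop = FALSE]
  key <- paste(cont$type, cont$source_gid)
  src <- cont[!duplicated(key), c("type", "source_gid"), drop = FALSE]
  src$src_rank <- assign_vp(src$source_gid, topo)$rank
  src <- src[order(src$src_rank, .type_code(src$type), src$source_gid), ,
             drop = FALSE]
  src$local_idx <- as.integer(stats::ave(seq_len(nrow(src)), src$src_rank,
                                         FUN = seq_along)) - 1L
  sect <- max(c(0L, tabulate(src$src_rank + 1L, nbins = M))) * slots_per_pair
  src$send_pos <- src$local_idx * slots_per_pair
  src$recv_pos <- src$src_rank * sect + src$send_pos
  lk <- paste(src$type, src$source_gid)
  for (r in seq_len(M)) {
    tb <- post$tables[[r]]
    controw <- tb$type %in% .CONTINUOUS_TYPES
    pos <- rep(NA_integer_, nrow(tb))
    pos[controw] <- src$recv_pos[match(paste(tb$type[controw],
                                             tb$source_gid[controw]), lk)]
    post$tables[[r]]$recv_pos <- pos
  }
  post$slots_per_pair <- as.integer(slots_per_pair)
  send_positions <- lapply(0:(M - 1), function(q) {
    mine <- src[src$src_rank == q, , drop = FALSE]
    # single write per source: the whole buffer goes to every rank
    data.frame(gid = mine$source_gid, type = mine$type, dest_rank = NA,
               pos = mine$send_pos, stringsAsFactors = FALSE)
  })
  send_counts <- matrix(sect, M, M)
  recv_counts <- matrix(sect, M, M)
  displ <- t(apply(send_counts, 1L, function(x)
    cumsum(c(0L, utils::head(x, -1L)))))
  if (M == 1L) displ <- matrix(0L, 1L, 1L)
  plan <- structure(list(send_counts = send_counts,
                         recv_counts = recv_counts,
                         send_displ = displ, recv_displ = displ,
                         send_size = rep(sect, M),
                         recv_size = rep(sect * M, M),
                         mode = "allgather", M = M),
                    class = "gapnet_plan")
  pre <- structure(list(send_positions = send_positions,
                        spike_targets = vector("list", M), plan = plan),
                   class = "gapnet_presyn")
  list(post = post, pre = pre)
}

#' Summarize the infrastructure
#'
#' Per-rank table sizes and exchange-plan counts, exportable as JSON for
#' inspection.
#'
#' @param infra a `gapnet_infra` object
#' @return a list (JSON-ready)
#' @export
infrastructure_summary <- function(infra) {
  list(mode = infra$mode,
       M = infra$topology$M, T = infra$topology$T,
       n_neurons = infra$n_neurons,
       slots_per_pair = infra$slots_per_pair,
       connection_entries = vapply(infra$post$tables, nrow, 0L),
       unique_pairs = if (!is.null(infra$post$pairs))
         vapply(infra$post$pairs, nrow, 0L)
       else NA,
       send_size = infra$plan$send_size,
       recv_size = infra$plan$recv_size,
       send_counts = infra$plan$send_counts)
}
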