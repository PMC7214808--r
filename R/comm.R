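# Emulated collective exchanges between virtual ranks. All buffers are
# plain numeric vectors held in one R process; an "exchange" is pure data
# movement between per-rank buffer objects according to the plan. Ranks
# never read each other's state except through an exchange, so the
# emulation preserves the semantics of the distributed algorithm.

#' Allocate send and receive buffers for a plan
#'
#' @param plan a `gapnet_plan` object
#' @return list with elements `send` and `recv`, each a list of numeric
#'   vectors (one per rank) sized by the plan
#' @export
make_buffers <- function(plan) {
  list(send = lapply(plan$send_size, numeric),
       recv = lapply(plan$recv_size, numeric))
}

#' Variable-size all-to-all exchange (Alltoallv semantics)
#'
#' The section of rank q's send buffer destined for rank r (as given by the
#' plan's counts and displacements) appears verbatim in rank r's receive
#' block for q. Pure data movement; no interpretation of the payload.
#'
#' @param send_buffers list of per-rank numeric send buffers
#' @param plan a `gapnet_plan` object
#' @return list of per-rank numeric receive buffers
#' @export
alltoallv_exchange <- function(send_buffers, plan) {
  M <- plan$M
  if (length(send_buffers) != M)
    stop("expected ", M, " send buffers")
  for (q in seq_len(M))
    if (length(send_buffers[[q]]) != plan$send_size[q])
      stop("send buffer size mismatch on rank ", q - 1L)
  lapply(seq_len(M), function(r) {
    pieces <- lapply(seq_len(M), function(q) {
      cnt <- plan$send_counts[q, r]
      if (cnt == 0L) return(numeric(0))
      send_buffers[[q]][plan$send_displ[q, r] + seq_len(cnt)]
    })
    unlist(pieces, use.names = FALSE)
  })
}

#' Allgather exchange (legacy-scheme oracle)
#'
#' Every rank receives the rank-ordered concatenation of all send buffers,
#' i.e. the global state. Requires equal (padded) send-buffer sizes.
#' Simulations run in this mode must produce dynamics identical to
#' Alltoallv mode.
#'
#' @param send_buffers list of per-rank numeric send buffers, equal lengths
#' @return list of per-rank receive buffers (all identical)
#' @export
allgather_exchange <- function(send_buffers) {
  sizes <- lengths(send_buffers)
  if (length(unique(sizes)) > 1L)
    stop("allgather requires equal send-buffer sizes")
  all <- unlist(send_buffers, use.names = FALSE)
  lapply(seq_along(send_buffers), function(r) all)
}

#' Exchange dispatch by plan mode
#'
#' @param send_buffers list of per-rank numeric send buffers
#' @param plan a `gapnet_plan` object (`mode` `"alltoallv"` or
#'   `"allgather"`)
#' @return list of per-rank receive buffers
#' @export
exchange <- function(send_buffers, plan) {
  if (plan$mode == "allgather") allgather_exchange(send_buffers)
  else alltoallv_exchange(send_buffers, plan)
}

#' Write a neuron's interpolant payload to its send positions
#'
#' Writes the coefficient payload at each recorded send position of the
#' neuron (one per destination rank in alltoallv mode, one in total in
#' allgather mode). Writing the same payload twice leaves the buffer
#' unchanged (idempotent); no other slot is modified.
#'
#' @param buffer numeric send buffer of one rank
#' @param positions 0-based first-slot positions recorded for the neuron
#' @param coeffs numeric payload, `slots_per_pair` values
#' @return the updated buffer
#' @export
write_gap_payload <- function(buffer, positions, coeffs) {
  slots <- length(coeffs)
  for (p in positions) {
    if (p < 0 || p + slots > length(buffer))
      stop("send position out of range")
    buffer[p + seq_len(slots)] <- coeffs
  }
  buffer
}

#' Deliver continuous-data payloads to their target connections
#'
#' Iterates over the receive-position table of one rank: for every
#' continuous-data connection the payload at its receive position is read
#' from the rank's receive buffer and handed over together with the
#' connection weight. Delivery order within a target neuron is ascending
#' source GID.
#'
#' @param recv_buffer numeric receive buffer of the rank
#' @param table the rank's postsynaptic table (with `recv_pos`)
#' @param slots_per_pair payload slots per pair
#' @return list with `connections` (data.frame `target_gid`, `source_gid`,
#'   `weight`, ordered by target then source) and `payload` (matrix, one
#'   row per connection)
#' @export
deliver_continuous <- function(recv_buffer, table, slots_per_pair) {
  cont <- table[!is.na(table$recv_pos), , drop = FALSE]
  cont <- cont[order(cont$target_gid, cont$source_gid), , drop = FALSE]
  n <- nrow(cont)
  payload <- matrix(0, n, slots_per_pair)
  if (n) {
    idx <- rep(cont$recv_pos, each = slots_per_pair) +
      seq_len(slots_per_pair)
    payload <- matrix(recv_buffer[idx], n, slots_per_pair, byrow = TRUE)
  }
  list(connections = data.frame(target_gid = cont$target_gid,
                                source_gid = cont$source_gid,
                                weight = cont$weight, row.names = NULL),
       payload = payload)
}

#' Route spikes through fixed-size per-rank sections (Alltoall semantics)
#'
#' Each spike `(gid, lag)` is placed once into the send-buffer section of
#' every rank that hosts at least one target of the spiking neuron, then
#' delivered to the target connections via the spike target tables. Ranks
#' without targets of the neuron receive nothing.
#'
#' @param spikes data.frame with `gid` and `lag` (substep offset within the
#'   communication interval)
#' @param infra a `gapnet_infra` object (alltoallv mode)
#' @param section_size fixed per-destination section capacity (records)
#' @return list with `sections` (per source rank: per destination rank,
#'   data.frame of records placed) and `delivered` (per destination rank:
#'   data.frame of spike events joined with target connection locations)
#' @export
route_spikes <- function(spikes, infra, section_size = 64L) {
  M <- infra$topology$M
  targets <- infra$pre$spike_targets
  src_rank <- assign_vp(spikes$gid, infra$topology)$rank
  sections <- lapply(seq_len(M), function(q)
    lapply(seq_len(M), function(r)
      data.frame(gid = integer(0), lag = numeric(0))))
  for (q in seq_len(M)) {
    sp <- spikes[src_rank == q - 1L, , drop = FALSE]
    if (!nrow(sp)) next
    tt <- targets[[q]]
    for (i in seq_len(nrow(sp))) {
      dests <- unique(tt$dest_rank[tt$source_gid == sp$gid[i]])
      for (d in dests) {
        sec <- sections[[q]][[d + 1L]]
        if (nrow(sec) >= section_size)
          stop("spike section overflow (rank ", q - 1L, " -> ", d, ")")
        sections[[q]][[d + 1L]] <- rbind(sec, sp[i, c("gid", "lag")])
      }
    }
  }
  # emulated Alltoall: destination r gathers section r of each source rank,
  # then resolves target connections from its postsynaptic table
  delivered <- lapply(seq_len(M), function(r) {
    inc <- do.call(rbind, lapply(seq_len(M), function(q)
      sections[[q]][[r]]))
    tb <- infra$post$tables[[r]]
    sp_rows <- tb[!(tb$type %in% .CONTINUOUS_TYPES), , drop = FALSE]
    if (is.null(inc) || !nrow(inc) || !nrow(sp_rows))
      return(data.frame(gid = integer(0), lag = numeric(0),
                        target_gid = integer(0), weight = numeric(0)))
    m <- merge(inc, sp_rows, by.x = "gid", by.y = "source_gid")
    data.frame(gid = m$gid, lag = m$lag, target_gid = m$target_gid,
               weight = m$weight, row.names = NULL)
  })
  list(sections = sections, delivered = delivered)
}
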