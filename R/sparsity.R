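# Fraction of communicated activity data that is relevant to a given rank,
# as a function of the number of ranks M, neurons per rank N_M and
# connections per neuron K. Under a global-state (Allgather) scheme every
# rank receives every source's data; a source is relevant to a rank only if
# at least one of its targets lives there. Under uniform random targets the
# exact per-source relevance probability is hypergeometric; the standard
# approximation replaces it with independent Bernoulli target placement.

#' Fraction of received data relevant to one rank
#'
#' For uniformly random targets: `approx` gives
#' `1 - (1 - 1/M)^K` and `exact` gives
#' `1 - choose(N - N_M, K) / choose(N, K)` with `N = M * N_M` (the
#' probability that a source with `K` uniform targets hits at least one of
#' the rank's `N_M` neurons). For the ring topology the fraction is
#' computed combinatorially from the neighborhood offsets: under the
#' round-robin distribution a source at GID `i` has targets on the ranks
#' `(i + d) mod M` for the offsets `d = +/-1 ... +/-K/2`.
#'
#' @param M number of ranks
#' @param N_M neurons per rank
#' @param K connections per neuron
#' @param topology `"random"` (uniform targets) or `"ring"`
#' @param method `"approx"` or `"exact"` (random topology only)
#' @return fraction in `[0, 1]`
#' @export
relevant_fraction <- function(M, N_M = 10000, K,
                              topology = c("random", "ring"),
                              method = c("approx", "exact")) {
  topology <- match.arg(topology)
  method <- match.arg(method)
  stopifnot(M >= 1, K >= 1, N_M >= 1)
  if (topology == "ring") {
    if (K %% 2 != 0) stop("ring topology requires even K")
    offs <- c(seq_len(K / 2), -seq_len(K / 2))
    return(vapply(M, function(m) length(unique(offs %% m)) / m, 0))
  }
  if (method == "approx") {
    1 - (1 - 1 / M)^K
  } else {
    N <- M * N_M
    # with a single rank everything is local whatever K is
    if (any(K > N - 1 & M > 1)) stop("exact mode requires K <= N - 1")
    ifelse(M == 1, 1, 1 - exp(lchoose(N - N_M, K) - lchoose(N, K)))
  }
}

#' Monte-Carlo estimate of the relevant-data fraction
#'
#' Draws `replicates` source neurons, each with `K` targets sampled
#' uniformly without replacement from the other `N - 1` neurons, and counts
#' the sources with at least one target among the `N_M` neurons of a fixed
#' rank (rank 0 under the round-robin distribution, i.e. GIDs divisible by
#' `M`). Serves as the simulation oracle for [relevant_fraction()].
#'
#' @param M number of ranks
#' @param N_M neurons per rank
#' @param K targets per source
#' @param replicates number of simulated sources (>= 100)
#' @param seed integer seed
#' @return list with `estimate` and `se` (binomial standard error)
#' @export
monte_carlo_relevant_fraction <- function(M, N_M = 10000, K,
                                          replicates = 10000, seed = 1) {
  stopifnot(replicates >= 100, M >= 1, K >= 1)
  N <- M * N_M
  if (K > N - 1) stop("K must be at most N - 1")
  if (M == 1) return(list(estimate = 1, se = 0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  hits <- 0L
  # hashed sampling keeps each draw O(K) instead of O(N) for large N
  use_hash <- N - 1L > 100000L && K <= (N - 1L) / 2
  sources <- sample.int(N, replicates, replace = TRUE) - 1L
  for (i in seq_len(replicates)) {
    src <- sources[i]
    # targets drawn among the other N-1 gids: sample from 0..N-2 and shift
    # the slots at/above the source up by one
    tg <- sample.int(N - 1L, K, useHash = use_hash) - 1L
    tg <- ifelse(tg >= src, tg + 1L, tg)
    if (any(tg %% M == 0L)) hits <- hits + 1L
  }
  p <- hits / replicates
  list(estimate = p, se = sqrt(p * (1 - p) / replicates))
}

#' Relevant-fraction curves over a grid of rank counts
#'
#' Evaluates the relevant-data fraction for spiking connectivity
#' (`K_spike` connections per neuron) and gap-junction connectivity
#' (`K_gap` per neuron) on a grid of rank counts, with `N_M` neurons per
#' rank.
#'
#' @param M_grid vector of rank counts
#' @param N_M neurons per rank
#' @param K_spike chemical synapses per neuron
#' @param K_gap gap junctions per neuron
#' @param method `"approx"` or `"exact"`
#' @return data.frame with columns `M`, `fraction_spike`, `fraction_gap`
#' @export
sparsity_curve <- function(M_grid = 2^(0:12), N_M = 10000,
                           K_spike = 10000, K_gap = 60,
                           method = "approx") {
  stopifnot(length(M_grid) >= 1)
  data.frame(
    M = M_grid,
    fraction_spike = relevant_fraction(M_grid, N_M, K_spike,
                                       method = method),
    fraction_gap = relevant_fraction(M_grid, N_M, K_gap, method = method))
}
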