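# Counter-based uniform stream on 32-bit integer arithmetic emulated in
# doubles (all intermediates stay below 2^53, so the arithmetic is exact).
# The per-call value is a pure function of (seed, gid, step): simulations
# get identical noise regardless of how neurons are grouped into ranks and
# threads or in which order streams are consumed.

# xor of two numbers in [0, 2^32), elementwise
.xor32 <- function(a, b) {
  ahi <- a %/% 65536; alo <- a %% 65536
  bhi <- b %/% 65536; blo <- b %% 65536
  bitwXor(as.integer(ahi), as.integer(bhi)) * 65536 +
    bitwXor(as.integer(alo), as.integer(blo))
}

# (a * b) mod 2^32 for a vector a and scalar b, both in [0, 2^32)
.mul32 <- function(a, b) {
  alo <- a %% 65536; ahi <- a %/% 65536
  blo <- b %% 65536; bhi <- b %/% 65536
  lo <- alo * blo
  mid <- (alo * bhi + ahi * blo) %% 65536
  (lo + mid * 65536) %% 4294967296
}

# murmur3 32-bit finalizer: full avalanche mixing
.fmix32 <- function(x) {
  x <- .xor32(x, x %/% 65536)        # x ^= x >> 16
  x <- .mul32(x, 2246822507)         # 0x85ebca6b
  x <- .xor32(x, x %/% 8192)         # x ^= x >> 13
  x <- .mul32(x, 3266489909)         # 0xc2b2ae35
  .xor32(x, x %/% 65536)
}

# uniform in (0, 1), pure function of (seed, gid, step); vectorized over
# gid and step with the usual recycling
.counter_uniform <- function(seed, gid, step) {
  s <- .fmix32((seed + 374761393) %% 4294967296)
  g <- .fmix32((.xor32(gid %% 4294967296, s) + 2654435761) %% 4294967296)
  h <- .fmix32((.xor32(step %% 4294967296, g) + 1779033703) %% 4294967296)
  (h + 0.5) / 4294967296
}
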