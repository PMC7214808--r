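---
title: "Methods: waveform relaxation and directed communication for gap-junction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: waveform relaxation and directed communication for gap-junction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapnet)
```

## The problem

Electrical synapses (gap junctions) couple neurons through the
instantaneous current $I_{\mathrm{gap},ij}(t) = g_{ij}\,(V_i(t) - V_j(t))$.
In a distributed simulator this is awkward: spiking interactions tolerate
communication once per minimum synaptic delay (here 1 ms), but a gap
junction seems to require partner potentials at the neuronal update
resolution ($h = 0.1$ ms). `gapnet` implements, at desk scale and with
*virtual* MPI ranks inside one R process, the combination of two
techniques that resolves this: waveform relaxation over the communication
interval, and a directed communication layout that exchanges only data
that is actually consumed.

The package emulates communication faithfully but does not model transport:
no latency, no timing of collectives, no real MPI. Wall-clock and memory
scaling of a real cluster are outside its scope; what is reproducible at
desk scale is the *correctness* of the scheme (identical dynamics under
any partitioning and either communication layout) and the *counts* (buffer
slots, connection entries, relevant-data fractions) that drive the scaling
argument.

## Neuron model

Single-compartment Hodgkin-Huxley dynamics with alpha-shaped postsynaptic
currents:

$$C_m \dot V = -g_{\mathrm{Na}} m^3 h (V - E_{\mathrm{Na}})
              - g_K n^4 (V - E_K) - g_L (V - E_L)
              + I_{\mathrm{syn}} + I_{\mathrm{noise}} + I_{\mathrm{gap}},$$

with first-order gating kinetics ($\dot x = \alpha_x(V)(1-x) - \beta_x(V)x$
for $x \in \{m, h, n\}$) and each alpha-PSC channel a critically damped
second-order filter. The reference literature for the benchmark defers the
parameter values to a source that is not reprinted here, so the shipped
defaults are an implementation choice: the classic squid-axon
parameterization scaled to a 100 pF point neuron
(`hh_params()`: $g_{\mathrm{Na}} = 12\,\mu S$, $g_K = 3.6\,\mu S$,
$g_L = 30$ nS, $E_{\mathrm{Na}} = 50$ mV, $E_K = -77$ mV,
$E_L = -54.402$ mV, $\tau_{\mathrm{syn}}$ 0.2/2.0 ms), resting near
$-65$ mV. No test or reported quantity depends on these specific values,
only on structural properties of the dynamics. With the default noise
(200 ± 250 pA) these neurons fire only occasionally; the full-scale model
this emulates may sit in a different excitability regime.

The noise current is redrawn independently per neuron and per $h$-substep
and held constant across the substep (so the variance of the filtered
current is proportional to $h$). The stream is **counter-based**: a hash of
`(seed, gid, step)` mapped through the normal quantile function. This makes
every draw a pure function of its counters — the same neuron receives the
same noise regardless of how many ranks or threads the network is split
over, in which order streams are consumed, and on which waveform-relaxation
iteration the interval is re-integrated. The last point is essential:
re-drawing noise within an interval would leave the relaxation without a
fixed point.

## Integration

Each neuron advances by an embedded Runge-Kutta-Fehlberg 4(5) pair with
adaptive step-size control (absolute tolerance, default $10^{-6}$,
configurable via `abs_tol`). The integrator is vectorized across neurons,
but acceptance and step-size adaptation are controlled *per neuron* from
that neuron's local error only. Consequently the floating-point operations
performed for one neuron are independent of which other neurons share the
state matrix — the mechanical basis for the bit-identical rank-invariance
the tests assert. Gating variables are clamped to $[0, 1]$ after each
accepted step; non-finite states and step-size underflow raise errors.

## Waveform relaxation

Time is divided into communication intervals of 1 ms = 10 substeps. For
one interval, from the saved interval-start states:

1. **Iteration 1** integrates every neuron against *constant* partner
   potentials (the partners' last exchanged values) — the standard initial
   guess for waveform relaxation.
2. After each iteration, every source's trajectory is condensed into a
   piecewise cubic Hermite interpolant: per substep, the 4 coefficients
   matching $V$ and $\dot V$ at both substep edges ($\dot V$ evaluated
   under that substep's piecewise-constant noise, so edge derivatives are
   one-sided). Interpolation order 3 is the default; order 1 (linear from
   boundary values) is supported.
3. Coefficients are written to fixed send-buffer positions, exchanged, and
   delivered; the next iteration re-integrates the same interval (same
   noise) against the fresh interpolants.
4. Convergence: the maximum change of substep-boundary potentials of all
   communicated sources between successive iterations falls below the
   tolerance ($10^{-5}$ by default, max-norm chosen because the tolerance's
   norm is not fixed by the framework being emulated); at most
   `max_iterations` (default 5) sweeps. The final sweep's end states are
   committed.

Spikes (upward crossings of 0 mV) are detected on the committed trajectory
only; the benchmark has no chemical synapses, so spike routing exists as
its own tested operation but does not feed back into the dynamics.

Two consequences of this design are worth noting. First, a neuron sees its
partners through interpolants while its own potential is exact, so exact
symmetry cancellations (identical neurons, identical drive) hold only to
interpolation accuracy (~$10^{-9}$ mV on smooth trajectories) unless the
trajectory is constant, and the constant initial guess costs one extra
iteration whenever the potentials move. Second, the committed trajectory
carries a per-interval error of the order of the convergence tolerance;
in excitable regimes such errors are amplified along the trajectory
(strongly so near spike upstrokes), so end-of-run maximum deviations from
a reference are seed-dependent and can exceed a small multiple of the
tolerance when spikes occur.

The aggregated partner drive of neuron $i$ is accumulated as
$\sum_j g_{ij}\, p_j(\tau) - \big(\sum_j g_{ij}\big) V_i$, with the sum
taken in ascending source-GID order — a fixed floating-point summation
order, again for partition invariance.

## Partitioning and the two-tier infrastructure

Neurons are assigned round-robin to $M \times T$ virtual processes:
`vp = gid mod (M*T)`, rank `vp mod M`, thread `vp div M`. Threads are
logical containers shaping table layout (execution is serial); the
exchange plan is provably independent of $T$, which the tests check.

On each (virtual) rank the postsynaptic side stores, per thread and
synapse type, positionally-locked connection, source and receive-position
entries — in R, rows of one data frame. Receive positions are constructed
in five steps: collect the (source GID, synapse type) pairs of all local
continuous-data connections; reduce to unique pairs *across threads* (one
buffer slot serves every local target of a source); group pairs by source
rank (recoverable from the GID by round-robin); order deterministically
within each rank block (type, then GID — the emulated framework fixes no
order, determinism is our choice); concatenate blocks in ascending source
rank. Each pair occupies `(order + 1) * (interval / h)` consecutive slots
(40 by default: one cubic per substep). The presynaptic side mirrors this:
each sender records, per destination rank, the absolute send-buffer
position that lands its payload at the destination's expected offset; a
send position appears exactly once per sender. Send counts equal the
destinations' receive counts, giving the constant per-rank-pair
counts/displacements of an Alltoallv plan. Construction-time redundancy of
per-thread messages in the emulated framework (a known inefficiency there)
is not reproduced; pairs are deduplicated before plan assembly.

The legacy layout (`mode = "allgather"`) pads all send buffers to a common
section size and gives every rank the rank-ordered concatenation of all
buffers; receive positions then index into that global buffer. Both modes
deliver identical payload values, so simulated dynamics agree exactly —
the central correctness property, asserted to $10^{-12}$ mV (observed: 0).

## Sparsity model

Under a global-state exchange, the fraction of received source data
relevant to one rank with $N_M$ neurons out of $N = M N_M$, for sources
with $K$ uniform targets, is
$1 - \binom{N - N_M}{K}\big/\binom{N}{K}$ (exact hypergeometric), with the
independent-placement approximation $1 - (1 - 1/M)^K$. A Monte-Carlo
routine that actually draws targets serves as the oracle. For the ring
topology the fraction follows from the neighborhood offsets:
$|\{d \bmod M : d = \pm 1 \ldots \pm K/2\}| / M$. With one rank everything
is local and the fraction is 1 for any $K$ (the $K \le N - 1$ bound
applies only to multi-rank sampling). Note that for very few ranks the
fractions for $K = 60$ and $K = 10{,}000$ both round to 1 in double
precision; comparisons between the curves are made where the dense curve
has left saturation.

## Numerical and design choices

- **Integrator tolerance** defaults to $10^{-6}$ (absolute, mV-scale
  states dominate). For comparisons of the relaxation scheme against the
  dense-exchange reference, both sides are run at $10^{-9}$ so that
  accumulated solver truncation (~$5\times10^{-4}$ mV over 50 ms at the
  default) does not mask the scheme error being measured.
- **Dense-exchange reference**: the entire coupled network integrated as
  one ODE system with gap currents evaluated from instantaneous partner
  potentials at the internal integrator times (global step control,
  tolerance $10^{-10}$) — brute force, sharing only the noise stream and
  the Butcher tableau with the production path.
- **Initial states**: all neurons start at the model's resting state
  (found by root-finding), optionally overridden per neuron via `init_V`.
- **Spike buffers** use fixed, configurable section sizes (the emulated
  framework's resizing protocol is out of scope); overflow errors rather
  than resizes.
- **GIDs** are 0-based and consecutive in creation order; the ring
  neighborhood is defined on GIDs.

## Problem sizes in the tests

The shipped tests and the acceptance script use desk-scale networks:
correctness oracles on a 40-neuron ring with $K_{\mathrm{gap}} = 6$ over
100 ms (modes alltoallv/allgather, $M \in \{1, 2, 4\}$), solver accuracy
on a 12-neuron ring over 50 ms, randomized infrastructures up to ~50
neurons, and Monte-Carlo sparsity checks with $10^4$ replicates. Full
benchmark configurations (94,720 and 615,680 neurons, $5.7 \times 10^6$
and $3.7 \times 10^7$ connection entries) are exercised through real ring
construction and count-only arithmetic, not through dynamics. What passing
tests show is the internal consistency and partition-invariance of the
algorithms; they do not show hardware scaling, nor fidelity to any
particular biological parameterization.

## Known limitations

- Gap conductances are constant (no voltage dependence or rectification);
  neurons are single-compartment; chemical synapses exist structurally
  (alpha-PSC state, spike routing) but are unused by the benchmark.
- Communication is emulated by in-memory copies; nothing is measured about
  real collectives.
- The relevant-fraction model assumes uniform random targets or the exact
  ring; other topologies are out of scope.
- Interpolation orders above 3 and adaptive communication intervals are
  not supported.
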