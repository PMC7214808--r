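Package: gapnet
Title: Directed-Communication Simulation of Spiking Networks with Gap Junctions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator for spiking neuronal networks with
    electrical (gap-junction) coupling under a directed, sparsity-exploiting
    communication scheme. Implements Hodgkin-Huxley point neurons with
    alpha-shaped postsynaptic currents and step-noise drive, a ring benchmark
    network, round-robin neuron distribution over virtual MPI ranks and
    threads, the two-tier connection infrastructure with precomputed
    continuous-data buffer positions, emulated Allgather/Alltoall/Alltoallv
    collective exchanges, a waveform-relaxation solver that exchanges
    piecewise cubic Hermite interpolants of membrane potentials once per
    communication interval, and analytic plus Monte-Carlo models of the
    fraction of communicated data relevant to a rank.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
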