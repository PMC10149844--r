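Package: epinav
Title: Episodic Memory Modes in Spatial Reinforcement Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework comparing three modes of using episodic
    memory in spatial reinforcement learning: one-shot learning via
    model-free episodic control, replay learning via deep/tabular
    Q-learning with random or biologically motivated sequential replay,
    and online learning without a memory store. Provides a parametric
    family of tunnel-maze gridworld environments with oriented states,
    a deterministic random-feature observation codec with
    Johnson-Lindenstrauss random projection, a strength-similarity-
    inhibition sequential replay sampler with inverse-temperature
    sampling, and the full analysis suite (learning curves, escape
    latencies, solution-state accounting, route classification, replay
    batch similarity, relative performance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
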