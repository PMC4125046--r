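Package: collectivelearning
Title: Collective Learning and Consensus Decision-Making in Animal Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates associative (Rescorla-Wagner) learning by individuals
    embedded in groups that reach consensus decisions, for environments with
    one high-observational-correlation cue (a single shared signal per trial)
    and one low-correlation cue (independent per-individual signals). Provides
    exact Condorcet-style analytics for the collective accuracy of any voting
    behavior, the provably optimal probability of following the low-correlation
    cue, globally optimal supermajority-threshold benchmarks and a
    full-information Bayes bound, simulation protocols for learning across
    environments, isolated-versus-collective learning comparisons and dynamic
    transitions in group size or cue reliability, plus a minimal zonal
    collective-motion model validating the majority-rule abstraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
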