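Package: branchlearn
Title: Branch-Point Sequence Learning in Birdsong: Analysis and Closed-Loop Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying reinforcement-driven modification of
    syllable sequencing in birdsong. Reads syllable-level song annotations,
    segments song bouts, estimates branch-point transition probabilities
    (including transitions to the end of a bout), computes degree of learning
    from catch trials, per-bout transition entropy, song rate and song speed,
    binned early-learning curves, and white-noise targeting accuracy. Includes
    a closed-loop simulator of differential white-noise reinforcement
    experiments across social contexts (male alone, male-female, male-male)
    with catch-trial scheduling and imperfect targeting, so that every
    analysis stage can be validated against programmed ground truth. A small
    statistical layer reproduces the cross-context comparisons (two-proportion
    test, one-way ANOVA with Tukey comparisons, main-effects three-way ANOVA,
    paired t-tests, Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
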