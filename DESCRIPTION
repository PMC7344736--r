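Package: markovcea
Title: Markov Cohort Cost-Effectiveness Analysis for Adjuvant Trastuzumab
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time Markov cohort modelling for health economic
    evaluation, built around a four-state (stable, recurrence, metastasis,
    death) model of one-year adjuvant trastuzumab versus chemotherapy alone
    in HER2-positive early breast cancer. Estimates transition matrices from
    transition count tables, runs discounted cohort traces with half-cycle
    correction, computes incremental cost-effectiveness ratios, dominance
    and the efficiency frontier, net monetary benefit, one-way deterministic
    (tornado) and probabilistic (Monte Carlo) sensitivity analyses with
    cost-effectiveness acceptability curves, and simulates synthetic
    patient-level state histories for pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: graphics, stats, utils, yaml
Suggests: jsonlite, testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
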