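Package: traumanet
Title: Firing-Rate Circuit Model of Post-Traumatic Stress Disorder and Its
    Therapies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a biologically inspired firing-rate network of the
    sensory cortices, hippocampus, amygdala and prefrontal cortex, with
    Bienenstock-Cooper-Munro (BCM) synaptic plasticity, to model the
    acquisition and persistence of trauma memories and their remission
    under prolonged exposure (PE) and eye movement desensitization and
    reprocessing (EMDR) therapy. Provides trial-based experiment
    protocols (trauma establishment, resilience, mild-emotion tagging,
    therapy with frozen-learning test trials), a symptom-index extractor
    based on cue-evoked amygdala activation, and a grid-search fitting
    engine over the prefrontal inhibition magnitude (phi) and the
    cortical plasticity gain (psi), including synthetic symptom-curve
    generation for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
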