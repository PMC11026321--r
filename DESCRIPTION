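Package: scrollclick
Title: Modelling Click-Position Selection for Scrolling Actions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying where people click on scrollable screen
    objects. Implements the geometry and drag mechanics of a vertical
    number-line scrolling task, candidate click-selection strategy models
    (minimal cursor-trajectory optimisation, target-square aiming,
    screen-border buffering, and a two-component direction-plus-amplitude
    heuristic with task-context adaptation and motor hysteresis), a
    synthetic trial-log generator for two within-participant designs,
    trial-log reduction to standard dependent variables, repeated-measures
    ANOVA with Greenhouse-Geisser correction and generalized eta squared,
    consecutive paired contrasts, a hysteresis linear mixed model with
    by-participant random slopes, and simulation-based power analyses for
    both designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
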