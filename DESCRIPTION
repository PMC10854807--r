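Package: lfpturn
Title: Local Field Potential Analysis of Turning Behavior Under Midbrain
    Microstimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multichannel local field potential (LFP)
    recordings from behaving birds during free and electrically evoked turning.
    Provides a synthetic session generator emulating state-dependent band
    oscillations and biphasic stimulation artifact trains, a template-based
    stimulation-artifact suppression algorithm (threshold detection, tail
    template subtraction, spike excision with flank in-fill), a preprocessing
    chain (polyphase downsampling to 512 Hz, 1-200 Hz band-pass, linear
    detrending, 50 Hz notch and stimulation-frequency comb filters, bipolar
    re-referencing, noisy-channel rejection), Welch power spectral density and
    Morlet time-frequency estimation with five-band absolute power extraction,
    and a three-way repeated-measures ANOVA with Mauchly sphericity tests,
    Greenhouse-Geisser correction, partial eta-squared effect sizes, simple
    effects and Fisher LSD post hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
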