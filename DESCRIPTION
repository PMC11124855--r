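Package: myoreg
Title: Simultaneous Proportional Three-DoF Myoelectric Control Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for simultaneous, proportional myoelectric control of
    three degrees of freedom from multichannel surface EMG: sliding-window
    RMS feature extraction, per-degree-of-freedom adaptive linear decoding
    with normalized least-mean-squares (NLMS), open-loop and closed-loop
    (co-adaptive) training protocols over a 27-target space, a virtual
    target-acquisition test with hold-to-hit detection, its real-time
    performance metrics (completion rate, path efficiency, attempt ratio),
    and a seeded virtual-user EMG synthesizer so complete control
    experiments can be run and replicated without human subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
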