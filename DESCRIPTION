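Package: magbee
Title: Magnitude-Cue Models of Numerosity Discrimination in Bees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study how continuous (non-numerical) visual cues can
    carry numerosity discrimination tasks. Generates element-count stimulus
    displays with constant total black area, quantifies their continuous
    cues (area, total edge length, convex hull, spatial-frequency power via
    the radially averaged 2-D Fourier power spectrum), and simulates a
    minimal nine-neuron magnitude network (seven Gaussian-tuned sensory
    neurons, a sigmoidal decision neuron and a reinforcement signal) trained
    with a reward-gated online gradient rule. Includes a two-alternative
    choice experiment pipeline over populations of seeded model bees and the
    rank statistics (Wilcoxon signed-rank z, Kruskal-Wallis, Spearman) used
    to summarise the resulting choice behaviour.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
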