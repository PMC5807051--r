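Package: colonyprofiler
Title: Voxel-Based Radial Profiling of Micropatterned Stem Cell Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative image analysis for circular micropatterned
    pluripotent stem cell colonies imaged as multi-channel confocal
    z-stacks. Implements voxel-based radial fluorescence profiling
    (distance-from-center binning, cross-colony averaging, max-100 and
    Hoechst-relative normalisation), voxel-level two-marker coexpression
    gating against a 0 hr reference, colony and embryo morphometrics
    (height-versus-radius profiles, nuclei per 100 micrometres,
    inter-nuclear distances), region-of-interest quantification of 2D
    sections normalised to the nuclear stain, a deterministic synthetic
    colony generator with ground truth for validation, and an end-to-end
    pipeline runner. Results are tibbles designed for dplyr/ggplot2
    workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
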