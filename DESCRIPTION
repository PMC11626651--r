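Package: fermbalance
Title: Electron and Carbon Balancing for Batch-Bottle Syngas Co-Fermentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative bookkeeping for anaerobic batch-bottle fermentations
    fed with syngas (CO, CO2, H2 in N2) and supplemented acetate. Converts
    headspace pressure/composition time series with gas-sampling and
    flush-repressurisation events into cumulative per-species gas balances via
    the ideal gas law, combines them with liquid metabolite concentration
    changes into electron-mole and carbon-mole space-time rates, product
    yields and electron recoveries, computes undissociated acetic acid by
    Henderson-Hasselbalch speciation, evaluates Gibbs free energies of
    catabolic reactions under non-standard conditions, and ships an
    event-driven bottle simulator with known ground truth for validating the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
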