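Package: regrowr
Title: Secondary-Forest Regrowth, Drivers and Carbon Accounting from Annual Land-Cover Maps
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs per-pixel secondary-forest history (age, repeated
    deforestations, fire exposure) from annual binary land-cover stacks, builds
    bias-corrected median aboveground-carbon chronosequences by driver group and
    climate region, fits asymptote-constrained Chapman-Richards regrowth curves,
    ranks driver importance with repeated subsample tree ensembles, partitions
    the landscape into climate regions by K-means, and closes the loop with
    carbon-stock accounting, a no-disturbance counterfactual and preservation
    scenario projections.  A synthetic-landscape generator with known ground
    truth makes the full pipeline testable without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    minpack.lm,
    ranger,
    rlang,
    stats,
    tibble
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
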