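Package: jackmap
Title: Iterative Jackknife Reliability and Post-Hoc Power for fMRI Group Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses the spatial reliability of second-level (random-effects)
    fMRI group activation maps by iteratively re-fitting the group GLM after
    removing one or more subjects ("third-level" analysis). Reduced thresholded
    maps are compared to the original with the Dice similarity index, combined
    into group percent overlap maps (gPOMs), and classified into reliability
    classes. A post-hoc power scan sweeps group sizes downward to assign every
    significant voxel and cluster the minimum group size at which it is safely
    detected, ranking clusters by observable effect size. Includes a seeded
    synthetic-cohort generator (Gaussian activation blobs plus subject noise,
    optional sign-inverted deviant subjects) so the whole pipeline is testable
    without imaging data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
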