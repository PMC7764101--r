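Package: midparc
Title: Connectivity-Based Parcellation of Striatum and Dopaminergic Midbrain on Digital Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step connectivity-based parcellation of a striatum-like seed
    and a dopaminergic-midbrain-like seed by probabilistic streamline
    tractography, implemented end-to-end on synthetic digital phantoms with
    known ground-truth topography. Provides a phantom generator (label
    volumes, discrete per-voxel fiber-orientation mixtures, per-subject
    fractional-anisotropy volumes for a two-group cohort), a probabilistic
    tracker with target-inclusion termination, track-density mapping with
    mean-intensity normalization and winner-take-all classification,
    group-level maximum probability maps, streamline density indices, mean
    FA sampled along streamlines, and the group-level three-way ANOVA with
    Bonferroni-adjusted post-hoc contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    car,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    emmeans,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
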