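Package: tmstdti
Title: Structure-Behavior Analysis for Temporal Motor Sequence Learning with Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking performance on a temporal motor sequence task (TMST)
    to white-matter microstructure. Scores trial-level key-press logs into
    percent-correct (PCOR) and percent-synchronization (PSYN) measures with
    final-performance and slope-of-improvement summaries; fits the diffusion
    tensor and derives FA, MD, axial and radial diffusivity maps; builds a
    mean-FA skeleton and runs voxelwise permutation partial-correlation with
    threshold-free cluster enhancement (TFCE) and nuisance covariates;
    performs probabilistic streamline tractography with waypoint and
    exclusion masks; and simulates behavioral logs and crossing-fiber
    diffusion-weighted phantoms with known ground truth so that every stage
    of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
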