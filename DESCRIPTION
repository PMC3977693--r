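Package: grnkf
Title: Gene Regulatory Network Inference with Sigma-Point Kalman Filters and Prior Constraints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the structure of small gene regulatory networks from
    time-series expression data using point-based Gaussian approximation
    filters (unscented Kalman filter, third- and fifth-degree cubature
    Kalman filters) on a sigmoid state-space model with the regulatory
    coefficient matrix and sigmoid steepness parameters augmented into the
    state. Prior network knowledge is incorporated either through
    L1-penalized maximum a posteriori updates solved by iterative soft
    thresholding with Barzilai-Borwein steps (sparsity, known non-edges,
    strength-weighted priors) or through truncated-Gaussian range
    constraints on the regulatory coefficients. Includes a trajectory
    simulator, link calling and TPR/FPR/PPV evaluation, and a seeded
    Monte-Carlo benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
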