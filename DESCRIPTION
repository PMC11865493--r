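Package: mitorestore
Title: Mitochondria-Prioritized Restoration of Fluorescence Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to restore mitochondrial cristae in low-resolution
    fluorescence microscopy images with a residual U-Net trained under a
    region-prioritizing structural-dissimilarity loss. Includes a seeded
    synthetic phantom generator (curvilinear mitochondria with transverse
    cristae ridges and exact masks), a paired-data synthesis pipeline
    (Gaussian blur, Poisson-Gaussian noise, Richardson-Lucy target
    enhancement), mitochondria-focused patch sampling built on the Anscombe
    transform and robust MAD noise estimation, masked evaluation metrics
    (NRMSE, PSNR, SSIM restricted to mitochondria or cristae pixels), and
    FWHM line-profile resolution measurement.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
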