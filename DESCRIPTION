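Package: ctinpaint
Title: Mask-Attention Adversarial Inpainting of Tumor Regions in CT Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesizes tumor-bearing liver-CT-like slices by adversarial
    inpainting: lesion pixels are whitened to form an attention map, and a
    two-path U-shaped generator with mask-attention feature fusion and dilated
    convolutions fills the whitened regions with realistic lesion texture,
    judged by a patch-based discriminator. Includes a procedural CT phantom
    generator, tumor-patch harvesting and augmentation (flip/rotate/scale),
    mask implantation onto healthy slices, an adversarial training loop with
    checkpointing, and PSNR-based evaluation with difference maps.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    tiff,
    RNifti,
    yaml,
    Rcpp,
    stats,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
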