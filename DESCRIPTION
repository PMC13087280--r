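Package: echogen
Title: Radiofrequency Ultrasound Synthesis from B-Mode Images with
    Quantitative Ultrasound Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying conditional generative synthesis of raw
    radiofrequency (RF) ultrasound echo data from B-mode images, validated
    end to end with quantitative ultrasound (QUS) tissue characterization.
    Includes a physics-based speckle simulator for paired RF/B-mode phantom
    scenes with known scatterer microstructure, reference-phantom spectral
    parametrization (mid-band fit, spectral slope, spectral intercept,
    effective scatterer diameter, effective acoustic concentration) with
    two-layer attenuation correction, gray-level co-occurrence texture
    features, three conditional GAN translator variants (U-Net Pix2Pix and
    shallow/deep vision-transformer generators with a patch discriminator)
    trained with weighted reconstruction losses, sample-level fidelity
    metrics, and a benign/malignant lesion classification protocol with
    two-step feature selection, RBF support-vector classification, and
    bootstrap evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    rlang,
    signal,
    Matrix,
    EBImage,
    glmnet,
    e1071,
    pROC,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
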