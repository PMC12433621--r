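Package: btd
Title: Bone and Tissue Decomposition of Single X-Ray Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes a single grayscale radiograph into a smooth
    soft-tissue image and a contrast-enhanced bone image. The soft-tissue
    component is recovered as the harmonic (Laplace-Dirichlet) interpolant
    of the image values on the boundary of a flexible bone-covering mask;
    a closed-form global scale parameter alpha >= 1 then yields a bone
    image whose maximum is one and whose gradients are provably at least
    as large as those of the input wherever the tissue is locally flat.
    Includes mask estimation by thresholding and morphology, an exact
    sparse direct solver plus a fast pyramid solver, synthetic radiograph
    phantoms with known ground truth, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    igraph,
    png,
    tiff,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
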