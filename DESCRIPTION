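Package: osseoquant
Title: Automated Quantification of Bone Ingrowth in Porous Implant Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures osseointegration in optical micrographs of sectioned
    porous (lattice-structured) titanium implants. A two-stage pipeline first
    extracts the implant cross-section from the background (global mean
    thresholding, Sobel edge detection with a sliding-window foreground
    classifier, and morphological closing), then partitions the implant region
    into metal surface, ingrown bone, and empty pore space using a Chan-Vese
    active-contour model for the dark pore holes and a Roberts-gradient
    texture-roughness rule for the bone/metal remainder. The bone-ingrowth
    ratio BI = A_Oss / (A_Oss + A_Hole) is computed per image and summarised
    per lattice type, with ordinary least-squares agreement statistics against
    manually outlined masks. A seeded synthetic-micrograph generator renders
    ground-truthed cross-sections of six lattice patterns (gyroid, cube,
    cylinder, tetrahedron, double pyramid, Voronoi) plus solid controls for
    validation without animal-study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
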