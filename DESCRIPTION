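Package: oatomo
Title: Optoacoustic-Ultrasound Breast Imaging Simulation and Functional Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates ultrawide-band optoacoustic signals from digital breast
    phantoms, reconstructs two-dimensional images by weighted filtered
    back-projection, and converts dual-wavelength (757/1064 nm) image pairs
    into depth-normalized functional maps of total hemoglobin and blood
    oxygen saturation, rendered as RGBA overlays on a co-registered grayscale
    anatomical background. Includes a digital phantom generator for
    blood-filled tube and tumor scenes, a transducer model with
    electro-acoustic and spatial impulse responses, Wiener deconvolution and
    zero-phase bandpass conditioning, spectral unmixing of oxy- and
    deoxyhemoglobin, and an end-to-end pipeline with scene files and run
    manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    yaml,
    jsonlite,
    png,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
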