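Package: bioconvect
Title: Bioconvection in Photoactive Microbial Suspensions: Simulation and
    Image Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying light-controlled bioconvection in suspensions
    of swimming microalgae. Provides stochastic simulators for run-and-tumble
    and gyrotactic swimmers, Beer-Lambert transmitted-light image synthesis,
    Hamming-windowed Fourier quantification of pattern wavelength and growth
    dynamics, relative-density densitometry, circular-Hough cell detection
    with trajectory linking and velocity-autocorrelation motility statistics,
    multipass FFT particle image velocimetry, and the gyrotactic continuum
    theory: dimensionless numbers, inverse-sedimentation base states, a
    linear-stability eigensolver for the critical Rayleigh number, and a 2D
    stream-function-vorticity solver. A pipeline driver orchestrates
    generation and analysis stages from a config file with reproducible seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
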