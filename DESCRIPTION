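Package: scpsize
Title: Sizing and Counting of Small Cellular Particles by Nanotracking and
    Dynamic Light Scattering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the hydrodynamic radius and number density
    of sub-micron particles (extracellular vesicles, liposomes, protein
    aggregates) from two complementary optical measurements: single-particle
    nanotracking (interferometric light microscopy style), where per-track
    mean squared displacements yield diffusion coefficients and
    Stokes-Einstein radii plus counts in a fixed detection volume, and
    dynamic light scattering, where the intensity autocorrelation is reduced
    via the Siegert relation and a regularized non-negative inverse-Laplace
    inversion (CONTIN style) to an intensity-weighted size distribution with
    peak fractions.  Includes a synthetic generator for Brownian and
    subdiffusive (fractional Brownian) trajectories, rod-shaped diffusers,
    and multi-exponential correlograms, a greedy nearest-neighbour track
    linker, and the cross-method comparison arithmetic (dilution-consistency
    ratios, replicate errors, within-error agreement) used in multi-method
    particle characterization studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
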