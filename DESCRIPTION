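Package: pepconf
Title: Conformational Analysis of Chalcogen Hydrogen Bonds in Capped Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the conformational analysis of capped model peptides
    carrying sulfur or selenium side chains (Ac-Met-Phe-NH2 and its
    seleno-methionine analogue).  Provides a geometric hydrogen-bond
    nomenclature based on covalent ring counting (C5/C7/C10 backbone bonds,
    6-delta and 7-delta side-chain-to-backbone bonds, NH-pi contacts),
    side-chain rotamer classification, conformer fingerprinting and
    clustering, Boltzmann populations at arbitrary temperature,
    mode-dependent scaling of harmonic NH-stretch frequencies, assignment of
    experimental band lists to candidate conformers by RMS and maximum
    unsigned error, and summation of natural bond orbital second-order
    stabilization energies for designated hydrogen bonds.  A synthetic
    builder assembles capped-dipeptide conformers from internal coordinates
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
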