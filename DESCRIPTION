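Package: mockforge
Title: Design and Quality Control of Defined Bacterial Mock Communities
Version: 0.1.0
Authors@R: person("Mockforge", "Developers", role = c("aut", "cre"),
    email = "mockforge@example.org")
Description: Tools for producing and scoring defined bacterial mock
    communities used as ground-truth controls in metagenomic sequencing.
    Converts raw enumeration measurements (adenine released from
    depurinated genomes and quantified by HPLC, flow-cytometry event
    counts against reference beads, microscopy field counts) into genome
    or cell concentrations; generates mixing recipes for cell mocks
    (equal genome copies per strain at a target community concentration)
    and DNA mocks (equimolar genomes at a target mass concentration);
    turns droplet digital PCR droplet counts and shotgun-sequencing
    count tables into relative abundances; and scores mock quality by
    coefficient of variation, absolute fold difference against the
    theoretical equimolar composition, and Welch's t-test between
    preparation methods. Includes a seeded simulator of every
    measurement type so the whole pipeline is testable end to end, and
    a registry of 15 reference strains with genome size, GC content and
    16S rRNA gene copy number.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
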