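Package: midtail
Title: Middle-Down Quantification of Histone H3 Tail Proteoforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of combinatorially modified histone H3 N-terminal
    tail proteoforms from chimeric EThcD tandem mass spectra of sortase-ligated,
    TMT 6-plex labelled tail peptides. Provides the monoisotopic mass model for
    the tagged tails (fixed TMT on the C-terminal histidine, ligation-scar
    C-terminal mass offset, combinatorial acetyl/methyl/phospho/propionyl
    marks), theoretical a/b/c/y/z fragment ladders with neutral losses,
    spectrum annotation with heavy-isotope confirmation, equal-split
    attribution of shared fragment intensity across co-isolated peptide
    spectrum matches, proteoform relative abundance, TMT reporter extraction
    with isotopic-impurity correction and channel normalization, differential
    proteoform statistics between treatment conditions, site-level
    marginalization for comparison with bottom-up data, and a seeded simulator
    of ground-truth spectra and search-engine exports for validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
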