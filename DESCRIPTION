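Package: locuspav
Title: Locus-Centric Structural Variant Genotyping, Haplotype Typing and
    Prime-Editing Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising and genotyping structural variation at a
    single gene locus, exemplified by the rice heading-date gene Ghd7. Provides
    exact k-mer anchoring and dot-plot segmentation of assembly-versus-reference
    comparisons; presence/absence calling of a gene from short-read depth over
    three diagnostic flanking/internal intervals; design and simulation of a
    two-primer-pair PCR deletion assay; haplotype typing of a gene region from
    SNP matrices with subpopulation frequency tables and neighbor-joining trees;
    variant-effect annotation against a single-transcript gene model including a
    cryptic splice-acceptor consequence predictor; and pegRNA/PE3 reagent design
    for corrective prime editing. A synthetic-data module generates reference
    loci, SV-bearing accession assemblies, depth profiles and SNP matrices with
    machine-readable truth tables so every stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    ape,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
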