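Package: dnmtrio
Title: Trio-Based De Novo Mutation Discovery and Base-Editor Off-Target
    Burden Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-calling analysis of family-based trio whole-genome
    sequencing experiments that measure the genome-wide mutational burden
    introduced by CRISPR base editors.  Implements the full multi-stage
    filtering cascade for multi-sample small-variant calls (site-level hard
    filters, repeat/blacklist mask exclusion, per-sample genotype, depth,
    excess-depth and allele-fraction filters, indel-proximity and
    structural-variant overlap exclusions), parental subtraction to obtain
    per-offspring de novo callsets with a per-variant filter decision trace,
    coincidence of de novo SNVs with predicted sgRNA off-target sites,
    mutational-spectrum tabulation, and nonparametric group comparison
    (exact Mann-Whitney U and Kruskal-Wallis tests).  A synthetic
    trio-cohort generator with a machine-readable truth table makes every
    stage testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
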