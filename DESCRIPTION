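Package: cloneseed
Title: Clone-Tree Based Inference of Metastatic Seeding Histories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing metastatic seeding histories from
    multi-region tumour sequencing summaries. Starting from per-region
    cancer cell fractions of mutation clusters and allele-specific
    fractional copy-number segments, the package scores and enumerates
    clone-tree topologies under the pigeonhole and crossing constraints,
    infers subclone proportions and clonality classes, computes SNV and
    copy-number diversity metrics, labels clone trees with tumours under
    three seeding models by weighted parsimony to recover migration
    histories with ensemble confidence, validates migrations against
    conserved loss of heterozygosity and radiological detection times,
    quantifies subclone seeding capacity by Monte Carlo multinomial
    testing, and refits mutational signature activities per subclone.
    A synthetic-cohort generator with full ground truth supports
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
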