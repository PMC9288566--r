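Package: mnutill
Title: Mutation Spectrum Analysis and In Silico TILLING for Chemically Mutagenized Rice Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing whole-genome-sequenced M1 mutant libraries
    produced by alkylating mutagens such as N-methyl-N-nitrosourea (MNU).
    Curates a joint multi-sample VCF down to cohort-unique heterozygous
    mutations, computes 12-class substitution spectra with Ts/Tv summaries,
    per-plant mutation rates, window densities and InDel size distributions,
    profiles flanking-nucleotide bias around mutated guanines against a
    randomized-G null, annotates variant effects from first principles
    against longest-isoform gene models, and supports library-level
    reporting: in silico TILLING queries, transmission summaries,
    seed-setting correlation and cohort-size saturation extrapolation.
    Includes a synthetic-cohort simulator emitting a joint VCF plus truth
    tables so the whole pipeline is testable without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
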