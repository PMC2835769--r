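Package: abmap
Title: Across-Breed Mapping of Breed-Fixed Traits from SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for mapping traits that are fixed within dog breeds by
    contrasting breeds that carry the trait against breeds that do not.
    Implements PLINK-style PED/MAP input with genotype quality control,
    per-SNP allelic chi-square association with genome-wide max-T
    permutation correction, haplotype-block definition by the four-gamete
    rule with EM haplotype-frequency estimation and chromosome-wide
    permutation tests, a normalized relative-heterozygosity scan for
    selective sweeps, fine mapping by intersecting homozygous haplotypes
    shared across affected breeds, and a multi-breed genotype simulator
    with known ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
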