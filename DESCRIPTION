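Package: kmerploidy
Title: Genome Profiling of Diploids and Tetraploids from k-mer Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based analysis of k-mer count spectra from whole-genome
    short reads of a single diploid, autotetraploid, or allotetraploid
    individual. Expected spectra are mixtures of overdispersed coverage peaks
    whose masses follow allele-partition probabilities under the
    infinite-alleles coalescent: the Ewens sampling formula for panmictic
    samples of two or four genomes, and an exact two-population split model
    for the 2+2 sample an allotetraploid represents. Bounded nonlinear least
    squares ("autofit") estimates per-copy sequencing depth, haploid
    single-copy genome size, a peak-width bias parameter, the
    population-scaled mutation rate theta, and the homoeologous sub-genome
    divergence time T, from which per-nucleotide heterozygosity and
    sub-genome divergence are derived. Includes a forward simulator of
    synthetic spectra, a Monte-Carlo structured-coalescent oracle for the
    closed-form partition probabilities, model selection across ploidy
    models, ggplot2 visualisation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
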