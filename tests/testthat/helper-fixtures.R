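# Shared fixtures: parameters calibrated to the per-nucleotide statistics
# typical of allotetraploid eyebright genomes (heterozygosity 0.2 %,
# sub-genome divergence 5 %, k = 21), and small simulated spectra.

calib <- calibrate_block_params(0.2, 5, k = 21)

allo_params <- function(genome_size = 2e5) {
  model_params("allotetraploid", coverage = 30, genome_size = genome_size,
               bias = 2, theta = calib$theta, T = calib$T, k = 21)
}

diploid_params <- function(genome_size = 2e5) {
  model_params("diploid", coverage = 30, genome_size = genome_size,
               bias = 2, theta = calib$theta, k = 21)
}

auto_params <- function(genome_size = 2e5) {
  model_params("autotetraploid", coverage = 30, genome_size = genome_size,
               bias = 2, theta = calib$theta, k = 21)
}

# exact expected curve re-expressed as a noiseless "observed" spectrum
noiseless_spectrum <- function(params, bins = 1:220) {
  cv <- expected_spectrum(params, bins)
  kmer_spectrum(data.frame(multiplicity = cv$multiplicity, count = cv$expected),
                k = params$k, label = "noiseless")
}

relerr <- function(est, truth) abs(est / truth - 1)
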