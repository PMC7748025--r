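#' Parameters of a generative k-mer spectrum model
#'
#' Bundles everything needed to predict a k-mer spectrum: the ploidy model,
#' the per-copy (1x) sequencing depth `coverage`, the haploid single-copy
#' genome size `genome_size` (in k-mer loci; one locus is roughly one base
#' of non-repetitive sequence), the peak-width `bias` (variance inflation
#' of the coverage peaks relative to Poisson; `bias = 1` is the Poisson
#' limit), the block-scaled mutation rate `theta`, the sub-genome
#' divergence time `T` (used only by the allotetraploid model), and the
#' k-mer length `k`.
#'
#' @param model `"diploid"`, `"autotetraploid"`, or `"allotetraploid"`.
#' @param coverage Per-copy sequencing depth c (> 0); a j-copy k-mer peaks
#'   near `j * coverage`.
#' @param genome_size Haploid single-copy genome size G in k-mer loci (> 0).
#' @param bias Peak-width bias b (>= 1): coverage peaks have variance
#'   `bias * mean`.
#' @param theta Scaled mutation rate per block (>= 0).
#' @param T Sub-genome divergence time in 2 Ne generations (>= 0; ignored
#'   unless `model = "allotetraploid"`).
#' @param k K-mer length.
#' @return A list of class `kmer_model_params`.
#' @examples
#' model_params("allotetraploid", coverage = 30, genome_size = 2e6,
#'              bias = 2, theta = 0.043, T = 24)
#' @export
model_params <- function(model = c("diploid", "autotetraploid", "allotetraploid"),
                         coverage, genome_size, bias = 2, theta = 0, T = 0,
                         k = 21) {
  model <- match.arg(model)
  stopifnot(is.numeric(coverage), length(coverage) == 1L, coverage > 0,
            is.numeric(genome_size), length(genome_size) == 1L, genome_size > 0,
            is.numeric(bias), length(bias) == 1L, bias >= 1,
            is.numeric(theta), length(theta) == 1L, theta >= 0,
            is.numeric(T), length(T) == 1L, T >= 0,
            is.numeric(k), length(k) == 1L, k >= 1)
  if (model != "allotetraploid") T <- 0
  structure(list(model = model, coverage = coverage, genome_size = genome_size,
                 bias = bias, theta = theta, T = T, k = as.integer(k)),
            class = "kmer_model_params")
}

#' @export
print.kmer_model_params <- function(x, ...) {
  cat(sprintf("%s spectrum model (k = %d)\n", x$model, x$k))
  cat(sprintf("  coverage c = %.4g, genome size G = %.4g loci, bias b = %.4g\n",
              x$coverage, x$genome_size, x$bias))
  cat(sprintf("  theta = %.5g%s\n", x$theta,
              if (x$model == "allotetraploid") sprintf(", T = %.5g", x$T) else ""))
  invisible(x)
}

#' Ploidy (number of genome copies) of a model kind
#' @param model Model kind string.
#' @return 2 or 4.
#' @export
ploidy_of <- function(model) {
  switch(match.arg(model, c("diploid", "autotetraploid", "allotetraploid")),
         diploid = 2L, autotetraploid = 4L, allotetraploid = 4L)
}

#' Coverage-peak probability mass
#'
#' Mass function of the observed multiplicity of a k-mer present in
#' `copy_class` genome copies: negative binomial with mean
#' `copy_class * coverage` and variance `bias * mean` (Poisson when
#' `bias = 1`), renormalised over multiplicities >= 1 because k-mers that
#' happen to receive zero reads never enter the spectrum.
#'
#' @param d Multiplicity bin(s), integer >= 1 (vectorised).
#' @param copy_class Copy number j (>= 1) of the k-mer.
#' @param coverage Per-copy depth c (> 0).
#' @param bias Variance inflation b (>= 1).
#' @return Probability mass at each `d`.
#' @examples
#' sum(peak_shape(1:200, copy_class = 2, coverage = 10, bias = 1))  # ~1
#' @export
peak_shape <- function(d, copy_class, coverage, bias = 1) {
  stopifnot(copy_class >= 1, coverage > 0, bias >= 1)
  if (any(d < 1)) stop("multiplicity bins must be >= 1")
  mu <- copy_class * coverage
  if (bias <= 1 + 1e-12) {
    p0 <- stats::dpois(0, mu)
    stats::dpois(d, mu) / (1 - p0)
  } else {
    size <- mu / (bias - 1)  # NB: var = mu + mu^2/size = bias * mu
    p0 <- stats::dnbinom(0, size = size, mu = mu)
    stats::dnbinom(d, size = size, mu = mu) / (1 - p0)
  }
}

#' Expected k-mer spectrum under a generative model
#'
#' The expected count of distinct k-mers at multiplicity `d` is a mixture
#' over copy-number classes:
#' `E[count_d] = G * sum_j E[a_j](theta, T) * peak_shape(d, j, c, b)`,
#' where `E[a_j]` are the expected allele-class counts from the model's
#' allele-partition distribution. With `theta = 0` the spectrum collapses
#' to a single peak at `m * c` with total mass `G`.
#'
#' @param params A [model_params()] object.
#' @param bins Integer multiplicity bins (>= 1) at which to evaluate.
#' @return A tibble with columns `multiplicity` and `expected`.
#' @export
expected_spectrum <- function(params, bins) {
  stopifnot(inherits(params, "kmer_model_params"))
  bins <- as.numeric(bins)
  if (any(bins < 1) || any(bins != floor(bins))) {
    stop("`bins` must be integers >= 1")
  }
  cls <- class_multiplicities(
    partition_probs(params$model, theta = params$theta, T = params$T))
  expected <- numeric(length(bins))
  for (i in seq_len(nrow(cls))) {
    if (cls$e_classes[i] <= 0) next
    expected <- expected + cls$e_classes[i] *
      peak_shape(bins, cls$copy_class[i], params$coverage, params$bias)
  }
  tibble::tibble(multiplicity = bins, expected = params$genome_size * expected)
}

#' Per-nucleotide summary statistics of a model
#'
#' Converts the fitted block-level parameters into the per-nucleotide
#' statistics usually reported:
#' * `heterozygosity_pct` — 100 x the per-site difference implied by the
#'   within-population block identity `1/(1+theta)`;
#' * `divergence_pct` (allotetraploid only, `NA` otherwise) — 100 x the
#'   per-site difference implied by the cross-sub-genome block identity
#'   `exp(-theta*T)/(1+theta)`; this is total divergence, including
#'   ancestral polymorphism;
#' * `divergence_net_pct` — the contribution of the isolation phase alone
#'   (`exp(-theta*T)`), i.e. divergence net of ancestral coalescence;
#' * `genome_size_Mb` — haploid single-copy genome size in megabases
#'   (one k-mer locus ~ one base of single-copy sequence).
#'
#' @param params A [model_params()] object.
#' @return A one-row tibble.
#' @examples
#' cal <- calibrate_block_params(0.2, 5, k = 21)
#' derived_stats(model_params("allotetraploid", 30, 2e6, 2,
#'                            theta = cal$theta, T = cal$T))
#' @export
derived_stats <- function(params) {
  stopifnot(inherits(params, "kmer_model_params"))
  k <- params$k
  het <- 100 * block_to_site(block_identity_within(params$theta), k)
  if (params$model == "allotetraploid") {
    div <- 100 * block_to_site(block_identity_cross(params$theta, params$T), k)
    div_net <- 100 * block_to_site(exp(-params$theta * params$T), k)
  } else {
    div <- NA_real_
    div_net <- NA_real_
  }
  tibble::tibble(heterozygosity_pct = het,
                 divergence_pct = div,
                 divergence_net_pct = div_net,
                 genome_size_Mb = params$genome_size * 1e-6)
}
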