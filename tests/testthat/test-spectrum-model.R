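test_that("coverage peaks reduce to a truncated Poisson at bias 1", {
  d <- 1:200
  expect_equal(peak_shape(d, copy_class = 2, coverage = 10, bias = 1),
               dpois(d, 20) / (1 - dpois(0, 20)))
})

test_that("coverage peak masses are proper and truncation lifts the mean", {
  # far-tail summation: mass sums to 1
  d <- 1:3000
  expect_equal(sum(peak_shape(d, 1, 25, bias = 2)), 1, tolerance = 1e-9)
  expect_equal(sum(peak_shape(d, 4, 30, bias = 5)), 1, tolerance = 1e-9)
  # dropping the unobservable zero bin raises the mean above j*c, and the
  # excess vanishes as coverage grows
  mean_at <- function(cv) sum(d * peak_shape(d, 1, cv, bias = 3))
  expect_gt(mean_at(2), 2)
  expect_gt(mean_at(8), 8)
  expect_lt(mean_at(8) - 8, mean_at(2) - 2)
  expect_equal(mean_at(30), 30, tolerance = 1e-6)
})

test_that("peak variance is bias times the mean", {
  d <- 1:4000
  for (b in c(2, 6)) {
    # use high coverage so zero-truncation is negligible
    mass <- peak_shape(d, 2, 100, bias = b)
    mu <- sum(d * mass)
    v <- sum((d - mu)^2 * mass)
    expect_equal(v / mu, b, tolerance = 1e-6)
  }
})

test_that("a mutation-free genome yields a single m*c peak of total mass G", {
  p <- model_params("diploid", coverage = 10, genome_size = 1000, bias = 1,
                    theta = 0)
  cv <- expected_spectrum(p, 1:120)
  expect_equal(sum(cv$expected), 1000, tolerance = 1e-6)
  expect_equal(cv$expected, 1000 * dpois(1:120, 20) / (1 - dpois(0, 20)),
               tolerance = 1e-9)
  # Poisson(20) ties its mode at 19 and 20
  expect_lte(abs(cv$multiplicity[which.max(cv$expected)] - 20), 1)
})

test_that("expected spectra are non-negative with the conserved totals", {
  p <- allo_params()
  cv <- expected_spectrum(p, 1:400)
  expect_true(all(cv$expected >= 0))
  cls <- class_multiplicities(partition_probs("allotetraploid",
                                              theta = p$theta, T = p$T))
  # distinct-k-mer mass: G * sum_j E[a_j] (zero-truncation negligible at c=30)
  expect_equal(sum(cv$expected), p$genome_size * sum(cls$e_classes),
               tolerance = 1e-6)
  # occurrence mass: sum_j j E[a_j] = m gives m * c * G
  expect_equal(sum(cv$multiplicity * cv$expected),
               4 * p$coverage * p$genome_size, tolerance = 1e-6)
})

test_that("2x/4x peak mass ratio rises with divergence time", {
  ratio <- vapply(seq(0, 10, by = 1), function(Tv) {
    p <- model_params("allotetraploid", 30, 1e5, 2, theta = 0.3, T = Tv)
    cv <- expected_spectrum(p, 1:400)
    near <- function(j) sum(cv$expected[abs(cv$multiplicity - j * 30) <= 10])
    near(2) / near(4)
  }, numeric(1))
  expect_true(all(diff(ratio) > 0))
})

test_that("high diversity inflates the 1x peak of an autotetraploid", {
  mass1x <- vapply(c(0.01, 1), function(th) {
    p <- model_params("autotetraploid", 30, 1e5, 2, theta = th)
    cv <- expected_spectrum(p, 1:400)
    sum(cv$expected[abs(cv$multiplicity - 30) <= 10])
  }, numeric(1))
  expect_gt(mass1x[2], mass1x[1])
})

test_that("qualitative spectrum shapes separate the three models", {
  # high-theta autotetraploid: prominent 1x peak; diverged allotetraploid:
  # prominent 2x peak
  arg_peak <- function(p) {
    cv <- expected_spectrum(p, 5:400)  # skip the truncation spike near d=1
    cv$multiplicity[which.max(cv$expected)]
  }
  auto_hi <- model_params("autotetraploid", 30, 1e5, 2, theta = 1.5)
  expect_lt(abs(arg_peak(auto_hi) - 30), 8)
  allo <- allo_params()
  expect_lt(abs(arg_peak(allo) - 60), 8)
})

test_that("derived statistics convert block parameters to per-site values", {
  # zero mutation rate: no heterozygosity
  p0 <- model_params("diploid", 30, 1e6, 2, theta = 0)
  expect_equal(derived_stats(p0)$heterozygosity_pct, 0)
  expect_true(is.na(derived_stats(p0)$divergence_pct))

  # theta chosen so block identity is (1-0.002)^21: heterozygosity 0.2 %
  th <- 1 / (1 - 0.002)^21 - 1
  p2 <- model_params("diploid", 30, 1e6, 2, theta = th)
  expect_equal(derived_stats(p2)$heterozygosity_pct, 0.2, tolerance = 1e-9)

  # calibrated allotetraploid: divergence 5 %, genome size in Mb
  pa <- allo_params(genome_size = 2e8)
  ds <- derived_stats(pa)
  expect_equal(ds$divergence_pct, 5, tolerance = 1e-9)
  expect_equal(ds$heterozygosity_pct, 0.2, tolerance = 1e-9)
  expect_equal(ds$genome_size_Mb, 200)
  expect_lt(ds$divergence_net_pct, ds$divergence_pct)
})

test_that("parameter validation rejects nonsense", {
  expect_error(model_params("diploid", coverage = -1, genome_size = 1e5))
  expect_error(model_params("diploid", coverage = 10, genome_size = 1e5,
                            bias = 0.5))
  expect_error(peak_shape(0:5, 1, 10), ">= 1")
  expect_error(expected_spectrum(allo_params(), c(0, 1)), ">= 1")
})
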