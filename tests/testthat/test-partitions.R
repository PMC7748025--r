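test_that("pairwise Ewens probabilities match the closed form", {
  # no mutation: always monomorphic
  expect_equal(panmictic_partition_probs(2, 0)$prob, c(1, 0))
  # theta = 1: identity probability 1/(1+theta) = 0.5
  d <- panmictic_partition_probs(2, 1)
  expect_equal(d$partition, c("2", "1+1"))
  expect_equal(d$prob, c(0.5, 0.5))
  # general theta
  th <- 0.37
  expect_equal(panmictic_partition_probs(2, th)$prob,
               c(1 / (1 + th), th / (1 + th)))
})

test_that("four-genome Ewens probabilities match independent identities", {
  # monomorphism probability is prod_{i=1..3} i/(i+theta), derived from the
  # coalescent directly (no mutation on any branch), independent of the
  # partition formula
  for (th in c(0.01, 0.5, 1, 3)) {
    d <- panmictic_partition_probs(4, th)
    expect_equal(sum(d$prob), 1, tolerance = 1e-12)
    expect_equal(d$prob[d$partition == "4"],
                 prod((1:3) / (1:3 + th)), tolerance = 1e-12)
  }
  expect_equal(panmictic_partition_probs(4, 1)$prob[1], 0.25)
})

test_that("partition distributions are proper and conserve copy number", {
  grid <- expand.grid(theta = c(0, 0.01, 0.5, 1, 5), T = c(0, 0.5, 2, 10))
  for (i in seq_len(nrow(grid))) {
    d <- structured_partition_probs(grid$theta[i], grid$T[i])
    expect_true(all(d$prob >= 0 & d$prob <= 1))
    expect_equal(sum(d$prob), 1, tolerance = 1e-12)
    cm <- class_multiplicities(d)
    expect_identical(cm$copy_class, 1:4)
    expect_equal(sum(cm$copy_class * cm$e_classes), 4, tolerance = 1e-12)
  }
})

test_that("the split model is continuous at T = 0 and degenerate at theta = 0", {
  for (th in c(0.01, 0.5, 1)) {
    expect_equal(structured_partition_probs(th, 0)$prob,
                 panmictic_partition_probs(4, th)$prob, tolerance = 1e-9)
  }
  for (Tv in c(0, 1, 10, 50)) {
    expect_equal(structured_partition_probs(0, Tv)$prob, c(1, 0, 0, 0, 0))
  }
})

test_that("deep splits give independent sub-genome pairs", {
  # as T -> Inf each sub-genome pair is monomorphic with prob 1/(1+theta)
  # and cross-identity vanishes, so P(2+2) -> (1/(1+theta))^2
  for (th in c(0.5, 1)) {
    d <- structured_partition_probs(th, 50)
    expect_equal(d$prob[d$partition == "2+2"], (1 / (1 + th))^2,
                 tolerance = 1e-9)
    expect_equal(d$prob[d$partition == "4"], 0, tolerance = 1e-9)
  }
})

test_that("doubleton mass grows with divergence time, monomorphism falls with theta", {
  th <- 0.5
  p22 <- vapply(seq(0, 10, by = 0.5), function(Tv) {
    d <- structured_partition_probs(th, Tv)
    d$prob[d$partition == "2+2"]
  }, numeric(1))
  expect_true(all(diff(p22) > 0))

  for (Tv in c(0, 2)) {
    pmono <- vapply(c(0.01, 0.1, 0.5, 1, 2), function(th) {
      d <- structured_partition_probs(th, Tv)
      d$prob[d$partition == "4"]
    }, numeric(1))
    expect_true(all(diff(pmono) < 0))
  }
})

test_that("expected class counts follow the partition structure", {
  d22 <- structured_partition_probs(1, 50)
  # fabricate a point mass to check the counting rule directly
  pm <- d22
  pm$prob <- c(0, 0, 1, 0, 0)  # all mass on 2+2
  cm <- class_multiplicities(pm)
  expect_equal(cm$e_classes, c(0, 2, 0, 0))
  pm$prob <- c(1, 0, 0, 0, 0)  # all mass on 4
  expect_equal(class_multiplicities(pm)$e_classes, c(0, 0, 0, 1))
})

test_that("block/site conversions invert each other and match known values", {
  expect_equal(block_to_site(1, 21), 0)
  expect_equal(site_to_block(0.05, 21), 0.95^21)
  expect_equal(block_to_site(0.95^21, 21), 0.05, tolerance = 1e-12)
  for (d in c(0, 1e-4, 0.002, 0.05, 0.3)) {
    expect_equal(block_to_site(site_to_block(d, 21), 21), d, tolerance = 1e-12)
  }
  expect_error(block_to_site(1.2, 21), "within")
  expect_error(site_to_block(-0.1, 21), "within")
})

test_that("calibration inverts the per-nucleotide statistics", {
  cal <- calibrate_block_params(0.2, 5, k = 21)
  expect_equal(100 * block_to_site(block_identity_within(cal$theta), 21), 0.2,
               tolerance = 1e-10)
  expect_equal(100 * block_to_site(block_identity_cross(cal$theta, cal$T), 21),
               5, tolerance = 1e-10)
  expect_error(calibrate_block_params(5, 0.2), "at least")
})
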