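test_that("initialisation reads landmarks off a simulated spectrum", {
  p <- diploid_params()
  sp <- simulate_spectrum(p, n_loci = 2e5, seed = 4)
  start <- init_params(sp, "diploid")
  expect_lt(relerr(start$coverage, 30), 0.2)
  expect_lt(relerr(start$genome_size, 2e5), 0.3)

  # allotetraploid: dominant peak assigned to 2x
  spa <- simulate_spectrum(allo_params(), n_loci = 2e5, seed = 4)
  starta <- init_params(spa, "allotetraploid")
  expect_lt(relerr(starta$coverage, 30), 0.2)
})

test_that("a pure error tail is rejected as featureless", {
  sp <- kmer_spectrum(data.frame(multiplicity = 1:50,
                                 count = round(1e5 * exp(-(1:50) / 3))))
  expect_error(init_params(sp, "diploid"), "featureless")
  expect_error(autofit(sp, "diploid"), "featureless")
})

test_that("autofit recovers generating parameters exactly from a noiseless curve", {
  for (gen in list(diploid_params(), auto_params(), allo_params())) {
    sp <- noiseless_spectrum(gen)
    fit <- autofit(sp, gen$model)
    expect_true(fit$converged)
    for (nm in c("coverage", "genome_size", "bias", "theta")) {
      expect_lt(relerr(fit$params[[nm]], gen[[nm]]), 1e-3)
    }
    if (gen$model == "allotetraploid") {
      expect_lt(relerr(fit$params$T, gen$T), 1e-3)
    }
  }
})

test_that("autofit is deterministic and never worse than its start", {
  sp <- simulate_spectrum(allo_params(), n_loci = 2e5, seed = 8)
  f1 <- autofit(sp, "allotetraploid")
  f2 <- autofit(sp, "allotetraploid")
  expect_identical(glance(f1), glance(f2))
  expect_identical(tidy(f1)$estimate, tidy(f2)$estimate)

  start_resid <- {
    cv <- expected_spectrum(f1$start, f1$data$multiplicity)
    sum(f1$data$weight * (f1$data$observed - cv$expected)^2)
  }
  expect_lte(f1$objective, start_resid)
})

test_that("autofit recovers the generating allotetraploid regime from noise", {
  gen <- allo_params(genome_size = 5e5)
  sp <- simulate_spectrum(gen, n_loci = 5e5, seed = 21)
  fit <- autofit(sp, "allotetraploid")
  g <- glance(fit)
  expect_true(fit$converged)
  expect_lt(abs(g$divergence_pct - 5), 0.5)
  expect_lt(relerr(fit$params$coverage, 30), 0.02)
  expect_lt(relerr(fit$params$genome_size, 5e5), 0.05)
  expect_gt(g$heterozygosity_pct, 0.1)
  expect_lt(g$heterozygosity_pct, 0.4)
})

test_that("derived statistics are recomputable from the fitted parameters", {
  sp <- simulate_spectrum(allo_params(), n_loci = 2e5, seed = 2)
  fit <- autofit(sp, "allotetraploid")
  expect_equal(fit$derived, derived_stats(fit$params))
  expect_gte(fit$objective, 0)
  expect_gte(fit$window[["d_min"]], min(sp$multiplicity))
  expect_lte(fit$window[["d_max"]], max(sp$multiplicity))
})

test_that("T is flagged unidentifiable when theta collapses to zero", {
  gen <- model_params("allotetraploid", 30, 1e5, 2, theta = 0, T = 10)
  sp <- noiseless_spectrum(gen)
  expect_warning(fit <- autofit(sp, "allotetraploid"), "unidentifiable")
  expect_false(fit$t_identifiable)
  expect_false(glance(fit)$t_identifiable)
})

test_that("manual mode matches the expected-spectrum contract", {
  p <- allo_params()
  bins <- 10:200
  expect_identical(manual_curve(p, bins), expected_spectrum(p, bins))
  p0 <- model_params("diploid", 20, 1e4, 1, theta = 0)
  cv <- manual_curve(p0, 1:80)
  expect_lte(abs(cv$multiplicity[which.max(cv$expected)] - 40), 1)
  # export then re-import preserves the curve to text precision
  f <- withr::local_tempfile()
  utils::write.table(cv, f, sep = "\t", row.names = FALSE, col.names = FALSE)
  back <- utils::read.table(f, col.names = c("multiplicity", "expected"))
  expect_equal(back$expected, cv$expected, tolerance = 1e-12)
})

test_that("single-bin windows are rejected", {
  sp <- simulate_spectrum(diploid_params(), n_loci = 1e4, seed = 1)
  expect_error(autofit(sp, "diploid", window = c(60, 60)), "single bin")
})

test_that("model selection ranks the generating model first", {
  gens <- list(diploid_params(), auto_params(), allo_params())
  for (gen in gens) {
    sp <- simulate_spectrum(gen, n_loci = 2e5, seed = 13)
    sel <- select_model(sp)
    expect_equal(sel$model[1L], gen$model)
    expect_equal(sel$rank, seq_len(nrow(sel)))
    expect_true(all(diff(sel$aicc) >= 0))
  }
})

test_that("a single candidate is returned at rank 1", {
  sp <- simulate_spectrum(diploid_params(), n_loci = 1e5, seed = 6)
  sel <- select_model(sp, models = "diploid")
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$rank, 1L)
  expect_equal(sel$model, "diploid")
})

test_that("broom-style accessors expose the fit", {
  sp <- simulate_spectrum(diploid_params(), n_loci = 1e5, seed = 3)
  fit <- autofit(sp, "diploid")
  td <- tidy(fit)
  expect_identical(td$term, c("coverage", "genome_size", "bias", "theta"))
  expect_true(all(is.finite(td$estimate)))
  au <- augment(fit)
  expect_identical(nrow(au), nrow(fit$data))
  expect_equal(au$residual, au$observed - au$fitted)
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
})
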