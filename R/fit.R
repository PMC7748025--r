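#' Locate the error trough and dominant peak of a spectrum
#'
#' Internal helpers for data-driven initialisation. The trough is the first
#' local minimum of the 3-bin running-median-smoothed counts (the boundary
#' between the sequencing-error tail and the signal peaks); if the spectrum
#' rises from its very first bin there is no error region and the trough is
#' the first bin. The dominant peak is the highest smoothed bin at or after
#' the trough.
#'
#' @param spectrum A `kmer_spectrum`.
#' @return A list with `trough` and `peak` multiplicities.
#' @keywords internal
spectrum_landmarks <- function(spectrum) {
  d <- spectrum$multiplicity
  s <- stats::runmed(spectrum$count, 3)
  n <- length(s)
  if (n < 3L) stop("spectrum too short to locate a coverage peak")
  trough_i <- 1L
  if (s[2L] < s[1L]) {  # falling error tail at the start: find first rise
    rises <- which(diff(s) > 0)
    if (length(rises) == 0L) {
      stop("featureless spectrum: counts decrease monotonically ",
           "(no coverage peak above the error tail); use manual mode")
    }
    trough_i <- rises[1L]
  }
  peak_i <- trough_i - 1L + which.max(s[trough_i:n])
  if (s[peak_i] <= 0) {
    stop("featureless spectrum: no k-mers above the error trough")
  }
  list(trough = d[trough_i], peak = d[peak_i])
}

#' Default fit window of a spectrum
#'
#' Lower bound: the error trough (first local minimum of the smoothed
#' spectrum). Upper bound: `1.5 * m * coverage` for the per-copy coverage
#' estimate implied by assigning the dominant peak to `peak_class` — beyond
#' the highest model peak, below the repeat region, which the model does
#' not describe.
#'
#' @param spectrum A `kmer_spectrum`.
#' @param model Model kind.
#' @param peak_class Copy-number class assigned to the dominant peak.
#' @return `c(d_min, d_max)`.
#' @keywords internal
default_window <- function(spectrum, model, peak_class) {
  lm <- spectrum_landmarks(spectrum)
  m <- ploidy_of(model)
  c_hat <- lm$peak / peak_class
  d_max <- min(max(spectrum$multiplicity), ceiling(1.5 * m * c_hat))
  c(lm$trough, d_max)
}

# Copy-number class alternatives for the dominant peak, primary first.
# Diploids and allotetraploids show a prominent 2x peak; autotetraploids a
# 4x peak unless diversity is high, so both assignments are tried and the
# better fit kept.
peak_assignments <- function(model) {
  switch(model,
         diploid = c(2L, 1L),
         autotetraploid = c(4L, 2L),
         allotetraploid = c(2L, 4L))
}

#' Data-driven starting parameters for a spectrum fit
#'
#' Per-copy coverage from the dominant peak position divided by its
#' assigned copy-number class; genome size from total k-mer occurrences in
#' the window divided by `m * coverage` (the model's total occurrence
#' mass); `bias = 2`, `theta = 0.01`, `T = 1`.
#'
#' @param spectrum A `kmer_spectrum`.
#' @param model Model kind.
#' @param peak_class Copy-number class for the dominant peak; default is
#'   the model's primary assignment.
#' @param window Optional `c(d_min, d_max)` override.
#' @return A [model_params()] object.
#' @export
init_params <- function(spectrum, model = c("diploid", "autotetraploid",
                                            "allotetraploid"),
                        peak_class = NULL, window = NULL) {
  model <- match.arg(model)
  if (is.null(peak_class)) peak_class <- peak_assignments(model)[1L]
  lm <- spectrum_landmarks(spectrum)
  m <- ploidy_of(model)
  c0 <- max(lm$peak / peak_class, 1)
  if (is.null(window)) window <- default_window(spectrum, model, peak_class)
  win <- spectrum_window(spectrum, window[1L], window[2L])
  G0 <- max(n_occurrences(win) / (m * c0), 1e3)
  model_params(model, coverage = c0, genome_size = G0, bias = 2,
               theta = 0.01, T = if (model == "allotetraploid") 1 else 0,
               k = spectrum_k(spectrum))
}

fit_par_names <- function(model) {
  if (model == "allotetraploid") c("coverage", "genome_size", "bias", "theta", "T")
  else c("coverage", "genome_size", "bias", "theta")
}

fit_bounds <- function(model) {
  nm <- fit_par_names(model)
  lower <- c(coverage = 1, genome_size = 1e3, bias = 1, theta = 0, T = 0)[nm]
  upper <- c(coverage = 1e4, genome_size = 1e10, bias = 50, theta = 10, T = 50)[nm]
  list(lower = lower, upper = upper)
}

params_from_vector <- function(p, model, k) {
  model_params(model, coverage = p[["coverage"]], genome_size = p[["genome_size"]],
               bias = p[["bias"]], theta = p[["theta"]],
               T = if (model == "allotetraploid") p[["T"]] else 0, k = k)
}

#' Fit a spectrum model by bounded weighted least squares ("autofit")
#'
#' Minimises `sum_d (observed_d - expected_d)^2 / max(observed_d, 1)` over
#' the windowed spectrum, with box bounds (`coverage` in `[1, 1e4]`,
#' `genome_size` in `[1e3, 1e10]`, `bias` in `[1, 50]`, `theta` in
#' `[0, 10]`, `T` in `[0, 50]`), by Levenberg-Marquardt. Both copy-number
#' assignments of the dominant peak are used as starts and the lower final
#' objective wins; objective ties (< 1e-9 relative) break toward smaller
#' `T`, then smaller `theta`, so results are deterministic.
#'
#' For the allotetraploid model with a fitted `theta` near zero, `T` is
#' unidentifiable (without within-population variation no mutations date
#' the split); the fit is then flagged and a warning emitted rather than
#' reporting a spurious divergence time.
#'
#' @param spectrum A `kmer_spectrum`.
#' @param model Model kind.
#' @param window Optional `c(d_min, d_max)`; default from
#'   [default_window()] under the model's primary peak assignment.
#' @param control A [minpack.lm::nls.lm.control()] list.
#' @return An object of class `kmerploidy_fit`: fitted [model_params()],
#'   derived per-nucleotide statistics, objective, window, convergence
#'   flag, evaluation count, start values, and the windowed data with
#'   fitted values.
#' @examples
#' sp <- simulate_spectrum(model_params("diploid", 25, 5e4, 2, theta = 0.05),
#'                         n_loci = 5e4, seed = 1)
#' fit <- autofit(sp, "diploid")
#' glance(fit)
#' @export
autofit <- function(spectrum, model = c("diploid", "autotetraploid",
                                        "allotetraploid"),
                    window = NULL,
                    control = minpack.lm::nls.lm.control(maxiter = 200,
                                                         ftol = 1e-13,
                                                         ptol = 1e-13)) {
  model <- match.arg(model)
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  assignments <- peak_assignments(model)
  if (is.null(window)) {
    window <- default_window(spectrum, model, assignments[1L])
  }
  win <- spectrum_window(spectrum, window[1L], window[2L])
  if (nrow(win) < 2L) stop("fit window contains a single bin; widen it")
  obs <- win$count
  bins <- win$multiplicity
  w <- 1 / pmax(obs, 1)
  k <- spectrum_k(spectrum)
  bounds <- fit_bounds(model)
  nm <- fit_par_names(model)

  residual_fn <- function(p) {
    names(p) <- nm
    prm <- params_from_vector(p, model, k)
    sqrt(w) * (obs - expected_spectrum(prm, bins)$expected)
  }

  runs <- lapply(assignments, function(cls) {
    start <- tryCatch(init_params(spectrum, model, peak_class = cls,
                                  window = window),
                      error = function(e) NULL)
    if (is.null(start)) return(NULL)
    p0 <- pmin(pmax(unlist(start[nm]), bounds$lower), bounds$upper)
    fit <- minpack.lm::nls.lm(par = p0, lower = bounds$lower,
                              upper = bounds$upper, fn = residual_fn,
                              control = control)
    list(start = start, fit = fit, objective = fit$deviance)
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0L) stop("initialisation failed for every peak assignment")

  objs <- vapply(runs, `[[`, numeric(1), "objective")
  best <- which(objs <= min(objs) * (1 + 1e-9))
  if (length(best) > 1L) {  # tie-break: smaller T, then smaller theta
    tv <- vapply(runs[best], function(r) {
      p <- stats::coef(r$fit)
      if ("T" %in% names(p)) p[["T"]] else 0
    }, numeric(1))
    th <- vapply(runs[best], function(r) stats::coef(r$fit)[["theta"]], numeric(1))
    best <- best[order(tv, th)]
  }
  run <- runs[[best[1L]]]
  p <- stats::coef(run$fit)
  names(p) <- nm
  params <- params_from_vector(p, model, k)
  converged <- run$fit$info %in% 1:3
  if (!converged) {
    warning("optimizer did not converge (", run$fit$message,
            "); returning best parameters so far")
  }
  t_identifiable <- !(model == "allotetraploid" && params$theta < 1e-4)
  if (!t_identifiable) {
    warning("fitted theta is ~0: the divergence time T is unidentifiable ",
            "from this spectrum (no within-population variation)")
  }
  fitted <- expected_spectrum(params, bins)$expected
  structure(list(params = params,
                 derived = derived_stats(params),
                 objective = run$fit$deviance,
                 window = c(d_min = win$multiplicity[1L],
                            d_max = win$multiplicity[nrow(win)]),
                 converged = converged,
                 t_identifiable = t_identifiable,
                 n_evaluations = length(run$fit$rsstrace),
                 start = run$start,
                 data = tibble::tibble(multiplicity = bins, observed = obs,
                                       fitted = fitted, weight = w),
                 spectrum = spectrum),
            class = "kmerploidy_fit")
}

#' Expected curve for a user-chosen parameter set ("manual" mode)
#'
#' Evaluates the expected spectrum for explicit parameters, to overlay on
#' an observed spectrum or to explore what a model predicts. Identical
#' contract to [expected_spectrum()].
#'
#' @inheritParams expected_spectrum
#' @return A tibble with `multiplicity` and `expected`.
#' @export
manual_curve <- function(params, bins) expected_spectrum(params, bins)

#' Rank ploidy models on one spectrum
#'
#' Fits each candidate model on a window shared by all candidates (error
#' trough up to three times the dominant peak position, covering the 4x
#' peak under every assignment) and ranks them by the small-sample
#' corrected information criterion
#' `AICc = n log(RSS_w / n) + 2p + 2p(p+1)/(n - p - 1)` computed from the
#' weighted residual sum of squares, with `p` = 4 free parameters for the
#' panmictic models and 5 for the allotetraploid.
#'
#' @param spectrum A `kmer_spectrum`.
#' @param models Candidate model kinds (>= 2, unless deliberately one).
#' @param window Optional shared window override.
#' @return A `kmerploidy_model_selection`: a tibble with one row per
#'   candidate (`model`, `objective`, `n_par`, `aicc`, `delta_aicc`,
#'   `rank`, `converged`), with the per-model fits in attribute `fits`.
#' @export
select_model <- function(spectrum,
                         models = c("diploid", "autotetraploid",
                                    "allotetraploid"),
                         window = NULL) {
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(window)) {
    lm <- spectrum_landmarks(spectrum)
    window <- c(lm$trough, min(max(spectrum$multiplicity), 3 * lm$peak))
  }
  fits <- lapply(models, function(mdl) {
    tryCatch(autofit(spectrum, mdl, window = window),
             error = function(e) e)
  })
  names(fits) <- models
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) stop("every candidate model failed to fit")
  rows <- purrr::map2_dfr(fits[ok], models[ok], function(f, mdl) {
    n <- nrow(f$data)
    p <- length(fit_par_names(mdl))
    aicc <- n * log(f$objective / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
    tibble::tibble(model = mdl, objective = f$objective, n_par = p,
                   n_bins = n, aicc = aicc, converged = f$converged)
  })
  rows <- dplyr::arrange(rows, .data$aicc)
  rows$delta_aicc <- rows$aicc - rows$aicc[1L]
  rows$rank <- seq_len(nrow(rows))
  failed <- models[!ok]
  structure(rows,
            fits = fits[ok],
            failed = failed,
            window = window,
            class = c("kmerploidy_model_selection", class(rows)))
}

#' @export
print.kmerploidy_model_selection <- function(x, ...) {
  cat("Model selection over k-mer spectrum (window [",
      attr(x, "window")[1L], ", ", attr(x, "window")[2L], "])\n", sep = "")
  NextMethod()
  failed <- attr(x, "failed")
  if (length(failed)) {
    cat("excluded from ranking (fit failed):", paste(failed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.kmerploidy_fit <- function(x, ...) {
  cat(sprintf("kmerploidy fit: %s model, window [%d, %d], %s\n",
              x$params$model, x$window[1L], x$window[2L],
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  d <- x$derived
  cat(sprintf("  heterozygosity %.3g%%", d$heterozygosity_pct))
  if (!is.na(d$divergence_pct)) {
    cat(sprintf(", sub-genome divergence %.3g%%", d$divergence_pct))
  }
  cat(sprintf(", genome size %.4g Mb\n", d$genome_size_Mb))
  cat(sprintf("  objective %.6g after %d evaluations\n",
              x$objective, x$n_evaluations))
  invisible(x)
}

#' Tidy a spectrum fit into a parameter table
#'
#' @param x A `kmerploidy_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `start`.
#' @method tidy kmerploidy_fit
#' @export
tidy.kmerploidy_fit <- function(x, ...) {
  nm <- fit_par_names(x$params$model)
  tibble::tibble(term = nm,
                 estimate = unlist(x$params[nm]),
                 start = unlist(x$start[nm]))
}

#' One-row summary of a spectrum fit
#'
#' @param x A `kmerploidy_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model, objective, convergence, window,
#'   evaluation count, and the derived per-nucleotide statistics.
#' @method glance kmerploidy_fit
#' @export
glance.kmerploidy_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(model = x$params$model, objective = x$objective,
                   converged = x$converged,
                   t_identifiable = x$t_identifiable,
                   d_min = x$window[[1L]], d_max = x$window[[2L]],
                   n_evaluations = x$n_evaluations),
    x$derived)
}

#' Per-bin observed and fitted values of a spectrum fit
#'
#' @param x A `kmerploidy_fit`.
#' @param ... Unused.
#' @return A tibble with `multiplicity`, `observed`, `fitted`, `weight`,
#'   and `residual` columns over the fit window.
#' @method augment kmerploidy_fit
#' @export
augment.kmerploidy_fit <- function(x, ...) {
  dplyr::mutate(x$data, residual = .data$observed - .data$fitted)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment
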