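#' Simulate a synthetic k-mer spectrum
#'
#' Forward simulation matching the generative model exactly, so that
#' parameter-recovery experiments isolate the fitter: each of `n_loci`
#' independent k-mer blocks draws an allele partition from the model's
#' partition distribution; each allele class of size `j` contributes one
#' distinct k-mer whose observed multiplicity is drawn from the
#' negative-binomial coverage peak with mean `j * coverage` and variance
#' `bias * mean`; draws of zero are discarded (unobservable k-mers).
#' Optionally a low-multiplicity noise component mimics sequencing-error
#' k-mers: `Poisson(error_kmers_per_locus * n_loci)` extra k-mers with
#' multiplicity `1 + Geometric` of mean `error_depth_mean`.
#'
#' @param params A [model_params()] object; `genome_size` is ignored in
#'   favour of `n_loci`.
#' @param n_loci Number of independent k-mer blocks (plays the role of G).
#' @param error_kmers_per_locus Expected noise k-mers per locus (>= 0;
#'   default 0, off).
#' @param error_depth_mean Mean multiplicity of noise k-mers (> 1).
#' @param seed Integer random seed; fixed seed gives a fully reproducible
#'   spectrum.
#' @return A [kmer_spectrum()].
#' @examples
#' sp <- simulate_spectrum(model_params("diploid", 20, 1e4, bias = 1),
#'                         n_loci = 1e4, seed = 1)
#' @export
simulate_spectrum <- function(params, n_loci,
                              error_kmers_per_locus = 0,
                              error_depth_mean = 1.2,
                              seed = NULL) {
  stopifnot(inherits(params, "kmer_model_params"),
            is.numeric(n_loci), length(n_loci) == 1L, n_loci >= 1,
            error_kmers_per_locus >= 0, error_depth_mean > 1)
  if (!is.null(seed)) set.seed(seed)
  dist <- partition_probs(params$model, theta = params$theta, T = params$T)
  parts <- lapply(strsplit(dist$partition, "+", fixed = TRUE), as.integer)
  m <- attr(dist, "m")
  # number of loci of each partition type
  type_n <- as.vector(stats::rmultinom(1, size = n_loci, prob = dist$prob))
  # total distinct k-mers to draw per copy-number class
  class_n <- vapply(seq_len(m), function(j) {
    sum(type_n * vapply(parts, function(p) sum(p == j), numeric(1)))
  }, numeric(1))
  depths <- integer(0)
  for (j in seq_len(m)) {
    if (class_n[j] == 0) next
    mu <- j * params$coverage
    dj <- if (params$bias <= 1 + 1e-12) {
      stats::rpois(class_n[j], mu)
    } else {
      stats::rnbinom(class_n[j], size = mu / (params$bias - 1), mu = mu)
    }
    depths <- c(depths, dj[dj > 0L])
  }
  if (error_kmers_per_locus > 0) {
    n_err <- stats::rpois(1, error_kmers_per_locus * n_loci)
    if (n_err > 0) {
      depths <- c(depths, 1L + stats::rgeom(n_err, prob = 1 / error_depth_mean))
    }
  }
  if (length(depths) == 0L) stop("simulation produced no observable k-mers")
  counts <- tabulate(depths)
  kmer_spectrum(tibble::tibble(multiplicity = seq_along(counts), count = counts),
                k = params$k,
                label = sprintf("simulated %s", params$model))
}

#' Monte-Carlo allele-partition frequencies under the coalescent
#'
#' Independent simulation route for the closed-form partition
#' distributions: runs the (structured) infinite-alleles coalescent for 2,
#' 4, or 2+2 lineages with exponential coalescence times and
#' mutation-killing at rate `theta/2` per lineage. For the allotetraploid,
#' the two demes evolve in isolation for time `T` (no cross-deme
#' coalescence), then surviving lineages enter the common ancestral
#' population. A lineage hit by a mutation is cut off: the sampled copies
#' it subtends form one finished allele class.
#'
#' Everything is vectorised across replicates, so 10^6 replicates run in
#' seconds.
#'
#' @param model `"diploid"`, `"autotetraploid"`, or `"allotetraploid"`.
#' @param theta Scaled mutation rate per block (>= 0).
#' @param T Divergence time (allotetraploid only).
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer random seed.
#' @return A `partition_dist` tibble with columns `partition`, `prob`
#'   (empirical frequency), and `se` (binomial standard error).
#' @examples
#' simulate_partitions_mc("diploid", theta = 1, n_reps = 1e4, seed = 1)
#' @export
simulate_partitions_mc <- function(model = c("diploid", "autotetraploid",
                                             "allotetraploid"),
                                   theta, T = 0, n_reps, seed = NULL) {
  model <- match.arg(model)
  stopifnot(is.numeric(theta), theta >= 0, is.numeric(T), T >= 0,
            n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_reps <- as.integer(n_reps)
  m <- ploidy_of(model)
  # B: block size carried by each live lineage (NA = no lineage);
  # FR: finished allele classes, counted by size 1..m
  B <- matrix(NA_real_, n_reps, m)
  FR <- matrix(0L, n_reps, m)
  kill_rate <- theta / 2

  rexp_safe <- function(n, rate) {
    if (rate <= 0) rep(Inf, n) else stats::rexp(n, rate)
  }

  if (model == "allotetraploid") {
    # isolation phase: each deme starts with two singleton lineages
    for (deme in 1:2) {
      cols <- if (deme == 1) 1:2 else 3:4
      e1 <- rexp_safe(n_reps, 1 + theta)
      coal <- stats::runif(n_reps) < 1 / (1 + theta)
      e2 <- e1 + rexp_safe(n_reps, kill_rate)
      none <- e1 >= T                      # no event: two singletons survive
      B[none, cols] <- 1
      cb <- !none & coal                   # coalesced at e1
      B[cb & e2 >= T, cols[1]] <- 2        # merged block survives
      i <- which(cb & e2 < T)              # merged block killed: class of 2
      FR[i, 2] <- FR[i, 2] + 1L
      kb <- !none & !coal                  # one lineage killed at e1
      FR[kb, 1] <- FR[kb, 1] + 1L
      B[kb & e2 >= T, cols[1]] <- 1        # other singleton survives
      i <- which(kb & e2 < T)              # both killed
      FR[i, 1] <- FR[i, 1] + 1L
    }
    # compact live lineages to the left (vectorised: target column of each
    # live cell is the running count of live cells in its row)
    live <- !is.na(B)
    cs <- live
    for (j in 2:m) cs[, j] <- cs[, j - 1L] + live[, j]
    B2 <- matrix(NA_real_, n_reps, m)
    for (j in seq_len(m)) {
      r <- which(live[, j])
      if (length(r)) B2[cbind(r, cs[r, j])] <- B[r, j]
    }
    B <- B2
  } else {
    B[, seq_len(m)] <- 1
  }

  n_lin <- rowSums(!is.na(B))
  # panmictic killing process on exchangeable lineages, vectorised by
  # grouping replicates with the same live-lineage count
  while (any(n_lin > 0L)) {
    one <- which(n_lin == 1L)
    if (length(one)) {                     # last lineage: one finished class
      sz <- B[one, 1L]
      idx <- cbind(one, sz)
      FR[idx] <- FR[idx] + 1L
      B[one, 1L] <- NA_real_
      n_lin[one] <- 0L
    }
    for (n in 2:m) {
      rows <- which(n_lin == n)
      if (!length(rows)) next
      npair <- n * (n - 1) / 2
      p_coal <- npair / (npair + n * kill_rate)
      coal <- stats::runif(length(rows)) < p_coal
      # coalescence: merge a uniformly chosen unordered pair
      rc <- rows[coal]
      if (length(rc)) {
        i <- sample.int(n, length(rc), replace = TRUE)
        j <- sample.int(n - 1L, length(rc), replace = TRUE)
        j <- ifelse(j >= i, j + 1L, j)
        B[cbind(rc, i)] <- B[cbind(rc, i)] + B[cbind(rc, j)]
        B[cbind(rc, j)] <- B[cbind(rc, n)]   # move last lineage into slot j
        B[cbind(rc, n)] <- NA_real_
      }
      # killing: a uniformly chosen lineage finishes as an allele class
      rk <- rows[!coal]
      if (length(rk)) {
        i <- sample.int(n, length(rk), replace = TRUE)
        sz <- B[cbind(rk, i)]
        idx <- cbind(rk, sz)
        FR[idx] <- FR[idx] + 1L
        B[cbind(rk, i)] <- B[cbind(rk, n)]
        B[cbind(rk, n)] <- NA_real_
      }
      n_lin[rows] <- n - 1L
    }
  }

  # encode each replicate's class-size profile and tabulate
  code <- FR %*% (10L^(seq_len(m) - 1L))
  labs <- names(allele_partitions(m))
  lab_code <- vapply(allele_partitions(m), function(p) {
    sum(tabulate(p, m) * 10^(seq_len(m) - 1))
  }, numeric(1))
  freq <- vapply(lab_code, function(cd) sum(code == cd), numeric(1))
  if (sum(freq) != n_reps) stop("internal error: replicate lost in tabulation")
  p <- freq / n_reps
  out <- new_partition_dist(labs, p, m = m)
  out$se <- sqrt(p * (1 - p) / n_reps)
  out
}

#' Chi-square consistency of empirical vs analytic partition frequencies
#'
#' Goodness-of-fit of Monte-Carlo partition frequencies against a
#' closed-form distribution on the same support: Pearson chi-square
#' statistic `n * sum (p_emp - p_ana)^2 / p_ana` over partitions with
#' analytic mass, with a point mass at zero handled conservatively (any
#' empirical mass on an analytically impossible partition gives a zero
#' tail probability).
#'
#' @param empirical A `partition_dist` of empirical frequencies.
#' @param analytic A `partition_dist` of model probabilities.
#' @param n Number of Monte-Carlo replicates behind `empirical`.
#' @return A one-row tibble with `statistic`, `df`, and `p_value`.
#' @export
chisq_consistency <- function(empirical, analytic, n) {
  stopifnot(inherits(empirical, "partition_dist"),
            inherits(analytic, "partition_dist"))
  if (!identical(empirical$partition, analytic$partition)) {
    stop("empirical and analytic distributions have different supports")
  }
  pe <- empirical$prob
  pa <- analytic$prob
  if (any(pe > 0 & pa == 0)) {
    return(tibble::tibble(statistic = Inf, df = NA_integer_, p_value = 0))
  }
  pos <- pa > 0
  stat <- n * sum((pe[pos] - pa[pos])^2 / pa[pos])
  df <- sum(pos) - 1L
  tibble::tibble(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
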