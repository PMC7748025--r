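#' Integer partitions of the genome copy number
#'
#' At a single k-mer block, the `m` genome copies of an individual group
#' into allelic classes; the unordered class sizes form an integer
#' partition of `m`. Under the infinite-alleles model every mutation
#' creates a novel allele, so two copies belong to the same class iff no
#' mutation separates them on the coalescent tree.
#'
#' @param m Number of genome copies (2 for a diploid, 4 for a tetraploid).
#' @return A named list of integer vectors, each a partition of `m` in
#'   decreasing order, named like `"2+1+1"`.
#' @examples
#' allele_partitions(4)
#' @export
allele_partitions <- function(m) {
  if (!(m %in% c(2L, 4L))) stop("`m` must be 2 or 4")
  parts <- if (m == 2L) {
    list(2L, c(1L, 1L))
  } else {
    list(4L, c(3L, 1L), c(2L, 2L), c(2L, 1L, 1L), c(1L, 1L, 1L, 1L))
  }
  stats::setNames(parts, vapply(parts, partition_label, character(1)))
}

partition_label <- function(part) paste(sort(part, decreasing = TRUE), collapse = "+")

new_partition_dist <- function(labels, probs, m) {
  structure(tibble::tibble(partition = unname(labels), prob = unname(probs)),
            m = as.integer(m),
            class = c("partition_dist", class(tibble::tibble())))
}

#' Ewens sampling formula probability of one allele partition
#'
#' For a panmictic sample of `n` genomes under the infinite-alleles
#' coalescent with scaled mutation rate `theta` per block, the probability
#' of observing allele-class sizes `part` is
#' `n! / theta_(n) * prod_j (theta/j)^(a_j) / a_j!`, where `a_j` is the
#' number of classes of size `j` and `theta_(n)` is the rising factorial.
#'
#' @param part Integer partition (vector of class sizes).
#' @param theta Scaled mutation rate per block (>= 0).
#' @return Probability of the partition.
#' @keywords internal
esf_prob <- function(part, theta) {
  n <- sum(part)
  if (n == 0L) return(1)  # empty sample: one (empty) configuration
  if (theta == 0) return(as.numeric(length(part) == 1L))
  a <- tabulate(part, nbins = n)
  rising <- prod(theta + 0:(n - 1L))
  factorial(n) / rising * prod((theta / seq_len(n))^a / factorial(a))
}

#' Allele-partition distribution for a panmictic sample
#'
#' Diploids (and autotetraploids) are modelled as samples of two (four)
#' genomes from a single panmictic population; the allele partition at
#' each block then follows the Ewens sampling formula.
#'
#' @param n Sample size, 2 or 4.
#' @param theta Scaled mutation rate per k-mer block (>= 0).
#' @return A `partition_dist` tibble with columns `partition` and `prob`,
#'   summing to 1 over all integer partitions of `n`.
#' @examples
#' panmictic_partition_probs(2, theta = 1)  # P(1+1) = theta/(1+theta) = 0.5
#' @export
panmictic_partition_probs <- function(n, theta) {
  if (!(n %in% c(2L, 4L))) stop("`n` must be 2 or 4")
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0) {
    stop("`theta` must be a single non-negative number")
  }
  parts <- allele_partitions(n)
  new_partition_dist(names(parts),
                     vapply(parts, esf_prob, numeric(1), theta = theta),
                     m = n)
}

# Probabilities of the five possible fates of the two lineages sampled from
# one sub-genome population during the isolation phase of length T (time in
# units of 2*Ne generations; pair coalescence rate 1, killing/mutation rate
# theta/2 per lineage).  A "killed" lineage's descendants form a finished
# allele class; a surviving lineage carries its block into the ancestral
# population.  Outcomes: both survive uncoalesced (A), survive as one
# coalesced block of 2 (B), one frozen singleton + one surviving singleton
# (C), frozen doubleton (D), two frozen singletons (E).
deme_outcomes <- function(theta, T) {
  if (T == 0) {
    return(list(A = 1, B = 0, C = 0, D = 0, E = 0))
  }
  r1 <- 1 + theta            # total event rate with two lineages
  r2 <- theta / 2            # kill rate of a single remaining lineage
  a <- exp(-r1 * T)
  # f = P(first event is a coalescence at s < T, no kill of the merged
  # lineage before T); by symmetry theta*f for the kill-first analogue
  f <- if (abs(r1 - r2) < 1e-12) {
    T * exp(-r1 * T)
  } else {
    (exp(-r2 * T) - exp(-r1 * T)) / (r1 - r2)
  }
  g <- (1 - a) / r1 - f      # first event before T and second kill also before T
  g <- max(g, 0)             # guard tiny negative round-off
  list(A = a, B = f, C = theta * f, D = g, E = theta * g)
}

# All set partitions of 1..n as lists of index vectors (restricted-growth
# enumeration; n <= 4 here so the state space is tiny).
set_partitions <- function(n) {
  if (n == 0L) return(list(list()))
  out <- list(list(1L))
  if (n == 1L) return(out)
  for (i in 2:n) {
    nxt <- list()
    for (p in out) {
      for (b in seq_along(p)) {
        q <- p
        q[[b]] <- c(q[[b]], i)
        nxt[[length(nxt) + 1L]] <- q
      }
      nxt[[length(nxt) + 1L]] <- c(p, list(i))
    }
    out <- nxt
  }
  out
}

# Number of set partitions of n labelled items with the given block sizes.
n_set_partitions_with_sizes <- function(sizes) {
  n <- sum(sizes)
  a <- tabulate(sizes, nbins = n)
  factorial(n) / prod(factorial(seq_len(n))^a * factorial(a))
}

# Distribution over set partitions of n exchangeable lineages under the
# panmictic infinite-alleles killing process (run to completion): the ESF
# probability of the size profile divided equally among the set partitions
# sharing it.
ancestral_setpart_dist <- function(n, theta) {
  sps <- set_partitions(n)
  probs <- vapply(sps, function(p) {
    sizes <- lengths(p)
    esf_prob(sizes, theta) / n_set_partitions_with_sizes(sizes)
  }, numeric(1))
  list(partitions = sps, probs = probs)
}

#' Allele-partition distribution for an allotetraploid (2+2 split sample)
#'
#' An allotetraploid carries two homoeologous sub-genomes contributed by
#' two populations that diverged `T` coalescent time units (2 Ne
#' generations) ago, with no gene flow since. Its four genome copies are a
#' structured sample: two lineages from each population. During the
#' isolation phase each pair may coalesce (rate 1) or be cut off by a
#' mutation (rate theta/2 per lineage, infinite alleles); lineages
#' surviving to the split continue in the common ancestral population,
#' where the allele classes of the remaining (exchangeable) lineages follow
#' the Ewens sampling formula. Both phases are evaluated in closed form and
#' combined by exact enumeration.
#'
#' At `T = 0` the distribution reduces to [panmictic_partition_probs()]
#' with `n = 4`; at `theta = 0` all four copies are identical
#' (`P(4) = 1`); as `T` grows with `theta > 0` fixed, mass moves into the
#' `2+2` partition, approaching `(1/(1+theta))^2` — the signature of
#' sub-genome divergence that produces the prominent 2x peak.
#'
#' @param theta Scaled mutation rate per k-mer block (>= 0), assumed equal
#'   in both populations and the ancestor.
#' @param T Divergence time of the two source populations in units of
#'   2 Ne generations (>= 0).
#' @return A `partition_dist` tibble over the partitions of 4.
#' @examples
#' structured_partition_probs(theta = 1, T = 50)$prob  # P(2+2) ~ 0.25
#' @export
structured_partition_probs <- function(theta, T) {
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0) {
    stop("`theta` must be a single non-negative number")
  }
  if (!is.numeric(T) || length(T) != 1L || T < 0) {
    stop("`T` must be a single non-negative number")
  }
  dem <- deme_outcomes(theta, T)
  # per-outcome (surviving block sizes, finished class sizes)
  cfg <- list(A = list(surv = c(1L, 1L), froz = integer(0)),
              B = list(surv = 2L,        froz = integer(0)),
              C = list(surv = 1L,        froz = 1L),
              D = list(surv = integer(0), froz = 2L),
              E = list(surv = integer(0), froz = c(1L, 1L)))
  labs <- names(allele_partitions(4L))
  acc <- stats::setNames(numeric(length(labs)), labs)
  anc_cache <- list()
  for (o1 in names(cfg)) {
    p1 <- dem[[o1]]
    if (p1 <= 0) next
    for (o2 in names(cfg)) {
      p2 <- dem[[o2]]
      if (p2 <= 0) next
      surv <- c(cfg[[o1]]$surv, cfg[[o2]]$surv)
      froz <- c(cfg[[o1]]$froz, cfg[[o2]]$froz)
      ns <- length(surv)
      key <- as.character(ns)
      if (is.null(anc_cache[[key]])) anc_cache[[key]] <- ancestral_setpart_dist(ns, theta)
      anc <- anc_cache[[key]]
      for (i in seq_along(anc$probs)) {
        pa <- anc$probs[i]
        if (pa <= 0) next
        merged <- vapply(anc$partitions[[i]], function(ix) sum(surv[ix]), numeric(1))
        lab <- partition_label(c(merged, froz))
        acc[[lab]] <- acc[[lab]] + p1 * p2 * pa
      }
    }
  }
  new_partition_dist(labs, unname(acc[labs]), m = 4L)
}

#' Allele-partition distribution for a ploidy model
#'
#' Dispatcher over the three generative models: `diploid` and
#' `autotetraploid` use the panmictic Ewens sampling formula (n = 2 and 4);
#' `allotetraploid` uses the two-population split model.
#'
#' @param model `"diploid"`, `"autotetraploid"`, or `"allotetraploid"`.
#' @param theta Scaled mutation rate per block (>= 0).
#' @param T Sub-genome divergence time (allotetraploid only; ignored
#'   otherwise).
#' @return A `partition_dist` tibble.
#' @export
partition_probs <- function(model = c("diploid", "autotetraploid", "allotetraploid"),
                            theta, T = 0) {
  model <- match.arg(model)
  switch(model,
         diploid = panmictic_partition_probs(2L, theta),
         autotetraploid = panmictic_partition_probs(4L, theta),
         allotetraploid = structured_partition_probs(theta, T))
}

#' Expected allele-class counts by copy number
#'
#' For each copy-number class `j = 1..m`, the expected number of allele
#' classes of size `j` at a block: `E[a_j] = sum_partitions P(partition) *
#' (# parts of size j)`. Classes of size `j` produce k-mers covered at
#' about `j` times the per-copy depth, so `E[a_j]` are the relative masses
#' of the jx coverage peaks. Conservation `sum_j j * E[a_j] = m` holds
#' exactly.
#'
#' @param dist A `partition_dist` (from [partition_probs()] and friends).
#' @return A tibble with columns `copy_class` (j) and `e_classes` (`E[a_j]`).
#' @export
class_multiplicities <- function(dist) {
  stopifnot(inherits(dist, "partition_dist"))
  m <- attr(dist, "m")
  parts <- lapply(strsplit(dist$partition, "+", fixed = TRUE), as.integer)
  e <- vapply(seq_len(m), function(j) {
    sum(dist$prob * vapply(parts, function(p) sum(p == j), numeric(1)))
  }, numeric(1))
  tibble::tibble(copy_class = seq_len(m), e_classes = e)
}

#' Convert between block-level identity and per-nucleotide difference
#'
#' The model works on k-mer blocks; reported statistics are per
#' nucleotide. Assuming independent sites within a block, a block of `k`
#' bases is identical between two copies iff all `k` sites match, so the
#' block identity probability `I` and per-site difference probability `d`
#' are linked by `I = (1 - d)^k`, i.e. `d = 1 - I^(1/k)`. (The linear
#' approximation `d ~ D_block / k` breaks down at the ~5 % divergence
#' typical of homoeologous sub-genomes, where `(1 - d)^k` is far from
#' `1 - k d`.)
#'
#' @param identity Block identity probability in `[0, 1]`.
#' @param site_diff Per-nucleotide difference probability in `[0, 1]`.
#' @param k K-mer length.
#' @return The converted probability.
#' @examples
#' block_to_site(0.95^21, k = 21)  # 0.05
#' @export
block_to_site <- function(identity, k) {
  check_prob(identity, "identity")
  1 - identity^(1 / k)
}

#' @rdname block_to_site
#' @export
site_to_block <- function(site_diff, k) {
  check_prob(site_diff, "site_diff")
  (1 - site_diff)^k
}

check_prob <- function(p, name) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("`", name, "` must be within [0, 1]")
  }
  invisible(p)
}

#' Pairwise block identity probabilities
#'
#' `block_identity_within()` is the probability that two genome copies
#' drawn from the same (panmictic) population carry an identical block:
#' the pair coalesces (rate 1) before either lineage mutates (total rate
#' theta), so `1/(1+theta)`. It drives per-nucleotide heterozygosity and
#' is the same for diploids, autotetraploids, and within an
#' allotetraploid sub-genome.
#'
#' `block_identity_cross()` is the identity probability for one copy from
#' each sub-genome of an allotetraploid: both lineages must survive the
#' isolation phase unmutated (`exp(-theta * T)`) and then coalesce before
#' mutating in the ancestral population, giving
#' `exp(-theta*T) / (1+theta)`. It includes ancestral polymorphism (the
#' `1/(1+theta)` factor) and drives total sub-genome divergence.
#'
#' @param theta Scaled mutation rate per block (>= 0).
#' @param T Sub-genome divergence time (>= 0).
#' @return Identity probability in `[0, 1]`.
#' @export
block_identity_within <- function(theta) 1 / (1 + theta)

#' @rdname block_identity_within
#' @export
block_identity_cross <- function(theta, T) exp(-theta * T) / (1 + theta)

#' Calibrate block parameters from per-nucleotide targets
#'
#' Inverts the identity conversions: finds the `theta` whose within-
#' population block identity yields a given per-nucleotide heterozygosity,
#' and (optionally) the `T` whose cross-sub-genome identity yields a given
#' per-nucleotide divergence. Useful to parameterise simulations in terms
#' of the biologically interpretable per-site statistics.
#'
#' @param heterozygosity_pct Target per-nucleotide heterozygosity in percent.
#' @param divergence_pct Target total per-nucleotide sub-genome divergence
#'   in percent (optional; requires `divergence_pct >= heterozygosity_pct`).
#' @param k K-mer length.
#' @return A list with `theta` and (if requested) `T`.
#' @examples
#' calibrate_block_params(0.2, 5, k = 21)
#' @export
calibrate_block_params <- function(heterozygosity_pct, divergence_pct = NULL, k = 21) {
  het <- heterozygosity_pct / 100
  check_prob(het, "heterozygosity_pct/100")
  I_within <- site_to_block(het, k)
  theta <- 1 / I_within - 1
  if (is.null(divergence_pct)) return(list(theta = theta))
  div <- divergence_pct / 100
  check_prob(div, "divergence_pct/100")
  I_cross <- site_to_block(div, k)
  if (I_cross > I_within) {
    stop("divergence_pct must be at least heterozygosity_pct")
  }
  T <- if (theta == 0) 0 else -log(I_cross * (1 + theta)) / theta
  list(theta = theta, T = T)
}
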