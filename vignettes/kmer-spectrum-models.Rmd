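---
title: "Modelling k-mer spectra of diploids, autotetraploids, and allotetraploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling k-mer spectra of diploids, autotetraploids, and allotetraploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4)
library(kmerploidy)
library(dplyr)
```

## The problem

A k-mer spectrum — the histogram of distinct DNA words of length $k$ by
their multiplicity in a whole-genome read set — can be computed from reads
alone, with no reference genome and no alignment. For a single individual
it carries a surprising amount of population-genetic information: sequence
present in $j$ of the $m$ genome copies produces k-mers covered at roughly
$j$ times the per-copy sequencing depth $c$, so the *relative masses of the
coverage peaks* record how genetic variation is distributed across the
genome copies. This is especially valuable for polyploids, where reference
assembly and homology inference are hard, and where the key biological
question — is this tetraploid a within-species genome doubling
(autotetraploid) or a hybrid carrying two diverged sub-genomes
(allotetraploid)? — is visible directly in the spectrum's shape.

kmerploidy implements generative models for the spectra of diploids,
autotetraploids, and allotetraploids, fits them to observed histograms
(from `jellyfish histo` or `kmc_tools transform histogram` output), and
reports per-nucleotide heterozygosity, sub-genome divergence, and the
haploid single-copy genome size.

## The model

### Allele partitions under the infinite-alleles coalescent

Each k-mer locus ("block") is treated as an independent, non-recombining
unit with population-scaled mutation rate $\theta$ per block, under the
infinite-alleles assumption: every mutation creates a novel allele, so two
genome copies carry an identical block iff no mutation occurred on the
lineages joining them to their common ancestor. At one block the $m$
copies group into allelic classes; the unordered class sizes form an
integer partition of $m$ (for $m=4$: $4$, $3{+}1$, $2{+}2$, $2{+}1{+}1$,
$1{+}1{+}1{+}1$).

* **Diploids and autotetraploids** are modelled as samples of $n = 2$ or
  $4$ genomes from one panmictic population; the partition probabilities
  are the Ewens sampling formula,
  $$P(a_1,\dots,a_n) = \frac{n!}{\theta_{(n)}}
  \prod_{j=1}^n \frac{(\theta/j)^{a_j}}{a_j!},$$
  with $\theta_{(n)} = \theta(\theta+1)\cdots(\theta+n-1)$. In an
  autotetraploid most variant blocks carry singleton alleles ($3{+}1$ or
  $2{+}1{+}1$), which is why high diversity shows up as a prominent
  1&times; peak.

* **Allotetraploids** are a structured sample: two copies from each of two
  populations that split $T$ coalescent time units ($2N_e$ generations)
  ago with no subsequent gene flow. `structured_partition_probs()`
  evaluates this exactly in two phases. During isolation, each deme's pair
  can coalesce (rate 1) or be cut off by mutation (rate $\theta/2$ per
  lineage); the five possible per-deme outcomes have closed-form
  probabilities. Lineages surviving to the split enter the common
  ancestral population, where the killing process runs to completion; by
  exchangeability the set partition of the surviving lineages follows the
  Ewens formula divided equally over set partitions with the same block
  sizes. Enumerating both demes' outcomes against the ancestral set
  partitions gives the exact partition distribution. Diverged sub-genomes
  put most variant blocks in the $2{+}2$ class — the prominent 2&times;
  peak that visually diagnoses allotetraploidy; as $T \to \infty$,
  $P(2{+}2) \to (1+\theta)^{-2}$.

The implementation is verified against an independent Monte-Carlo
structured-coalescent sampler (`simulate_partitions_mc()`), vectorised
across replicates so $10^6$ draws take seconds:

```{r oracle}
emp <- simulate_partitions_mc("allotetraploid", theta = 0.5, T = 2,
                              n_reps = 2e5, seed = 1)
ana <- structured_partition_probs(theta = 0.5, T = 2)
left_join(ana, emp, by = "partition", suffix = c("_analytic", "_mc"))
chisq_consistency(emp, ana, n = 2e5)
```

### From partitions to a spectrum

With $E[a_j]$ the expected number of allele classes of size $j$
(`class_multiplicities()`; $\sum_j j\,E[a_j] = m$ exactly), the expected
count of distinct k-mers at multiplicity $d$ is the mixture

$$E[\text{count}_d] = G \sum_{j=1}^{m} E[a_j]\;\phi(d \mid j c, b),$$

where $G$ is the haploid single-copy genome size in k-mer loci and
$\phi(\cdot \mid \mu, b)$ is a negative-binomial mass with mean $\mu = jc$
and variance $b\mu$. The bias parameter $b \ge 1$ widens the coverage
peaks relative to the Poisson limit ($b = 1$), absorbing library and
mapping-free coverage overdispersion; a single $b$ is shared across peaks
to keep the fit identifiable. The negative-binomial
variance-inflation form is an explicit modelling assumption of this
package. Because k-mers drawn at depth zero never enter a spectrum, each
peak is renormalised over $d \ge 1$; at typical depths ($c \ge 15$) the
correction is negligible but it is applied throughout.

Not modelled: repetitive k-mers (multiplicity $\gg mc$), sequencing-error
k-mers, contamination, GC bias. Errors and repeats are excluded by the
fit window instead (below).

### Per-nucleotide statistics

Block-level identities convert to per-site statistics through the
geometric root: a block of $k$ sites is identical iff all sites match, so
$d_\text{site} = 1 - I^{1/k}$. (A linear $d \approx D/k$ approximation is
invalid in the relevant regime: at 5 % per-site divergence and $k = 21$
most homoeologous blocks differ.) The within-population block identity is
$1/(1+\theta)$, giving heterozygosity; the cross-sub-genome identity is
$e^{-\theta T}/(1+\theta)$, giving **total** divergence including
ancestral polymorphism, with the isolation-phase contribution
($e^{-\theta T}$) also reported separately as `divergence_net_pct`.
`calibrate_block_params()` inverts these maps so simulations can be
parameterised directly in per-site units.

## Fitting

`autofit()` minimises the weighted least squares
$\sum_d (o_d - e_d)^2 / \max(o_d, 1)$ over the windowed spectrum by
bounded Levenberg–Marquardt (`minpack.lm::nls.lm`), with bounds
$c \in [1, 10^4]$, $G \in [10^3, 10^{10}]$, $b \in [1, 50]$,
$\theta \in [0, 10]$, $T \in [0, 50]$. Weighted least squares rather than
a Poisson likelihood is a deliberate choice: distinct-k-mer bin counts
are overdispersed and correlated across bins, and WLS matches the
visual-overlay semantics of manual fitting; the objective is isolated in
one residual function and straightforward to swap.

*Initialisation* is data-driven: the error trough is the first local
minimum of the 3-bin running-median-smoothed counts (first bin if the
spectrum rises from the start); the dominant peak is the highest smoothed
bin beyond it. The per-copy depth starts at the peak position divided by
its assigned copy-number class — 2&times; for diploids and
allotetraploids, 4&times; for autotetraploids — and the alternative
assignment (1&times;, 2&times; resp.) is run as a second start, with the
lower final objective winning. Ties (&lt; $10^{-9}$ relative) break
toward smaller $T$, then smaller $\theta$, so fits are deterministic.
$G$ starts at the windowed occurrence mass divided by $m\hat c$ (the
model's exact total), $b = 2$, $\theta = 0.01$, $T = 1$. A monotonically
decreasing spectrum (pure error tail) raises an error directing the user
to manual mode.

*Window*: by default from the error trough up to $1.5\,m\hat c$ —
beyond the highest model peak, below the repeat region. Both bounds can
be overridden (`window = c(min, max)`).

*Identifiability*: at $\theta \to 0$ the allotetraploid $T$ drops out of
the model (no mutations date the split). Fits with $\theta < 10^{-4}$
are flagged `t_identifiable = FALSE` and warn rather than reporting a
spurious divergence.

`select_model()` refits all candidate models on one shared window (trough
to three times the dominant peak) and ranks them by
$\mathrm{AICc} = n \log(\mathrm{RSS}_w/n) + 2p + 2p(p+1)/(n-p-1)$ with
$p = 4$ (panmictic) or $5$ (allotetraploid) parameters.

```{r fit}
cal <- calibrate_block_params(heterozygosity_pct = 0.2,
                              divergence_pct = 5, k = 21)
gen <- model_params("allotetraploid", coverage = 30, genome_size = 5e5,
                    bias = 2, theta = cal$theta, T = cal$T)
sp <- simulate_spectrum(gen, n_loci = 5e5, seed = 42)
fit <- autofit(sp, "allotetraploid")
glance(fit)
autoplot(fit)
select_model(sp)
```

## The simulator and what passing tests show

`simulate_spectrum()` draws, per locus, an allele partition from the
model's distribution and a depth per allele class from the matching
negative-binomial peak, discarding zero draws; optional noise k-mers
(geometric-like, mean multiplicity 1.2, off by default) let tests
exercise the error-trough windowing. The simulator deliberately matches
the fitted model *exactly* — independent loci, no k-mer overlap, no
linkage — so recovery experiments isolate the estimator. Consequently,
passing recovery tests demonstrate correctness of the machinery and
self-consistency of the model, not robustness to the ways real data
violate it: adjacent k-mers sharing a SNP are correlated, repeats and
errors are only windowed out rather than modelled, and real coverage has
GC and PCR structure beyond a single overdispersion parameter.

Default simulation conditions used across the test-suite and the
acceptance script mirror the regime the method targets in practice:
per-copy depth 30&times;, bias 2, $k = 21$, $2 \times 10^6$ single-copy
loci, and $\theta$, $T$ calibrated to 0.2 % heterozygosity and 5 %
sub-genome divergence (1.1 % heterozygosity for the outcrossed-sample
variant). At these settings a spectrum simulates and refits in about two
seconds, and estimator noise sits well inside the tolerances asserted:
divergence is recovered within half a percentage point, depth within 2 %
and genome size within 5 %, while heterozygosity — driven by the small
1&times; peak — is only held to a factor of two, reflecting its genuinely
higher sampling noise.

## Numerical choices and limitations

* Partition enumeration, the two-phase split model, and the per-deme
  closed forms are exact; the only tolerance-bearing steps are the
  optimiser ($\text{ftol} = \text{ptol} = 10^{-13}$) and far-tail peak
  summation, both validated to $10^{-9}$ or better in the tests.
* The two sub-genome source populations are assumed equal and constant in
  size, the ancestral population the same size, and gene flow zero after
  the split — the minimal symmetric model; `theta` is shared by both
  demes and the ancestor. Ancestral polymorphism is included in total
  divergence.
* $\theta$ is per *block*; per-nucleotide values come only from the
  $k$-th-root conversion. Both scales are exposed.
* Terminal overflow bins from k-mer counters are kept as ordinary bins;
  window below them.
* Hexaploids and higher, migration after the split, unequal $N_e$, and
  bootstrap confidence intervals are out of scope.
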