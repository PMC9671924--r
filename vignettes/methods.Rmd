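---
title: "Cohort mutational skew: model, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort mutational skew: model, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seismic)
```

## 1. The statistical question

Somatic driver detection usually compares a gene's mutation *count* to a
background expectation. That expectation inherits every weakness of the
background model: absolute mutation rates vary by orders of magnitude
between tumours and are modulated by sequence context, replication
timing, expression and more. A misspecified rate translates directly into
false positives or lost power.

This package conditions the count away. For each region we observe a set
$M$ of mutated tumours with $|M| = k$, and we ask whether the *identity*
of those $k$ tumours is consistent with neutral mutagenesis. Under
neutrality, a tumour's chance of appearing in $M$ grows with its
mutational burden and with how well its mutational signature matches the
region's sequence. Positive selection breaks this coupling: driver
mutations confer an advantage in any tumour, so low-burden tumours appear
in $M$ far more often than their background rates predict. We call this
departure *cohort mutational skew*.

Two properties follow by construction:

* **Rate blindness.** Multiplying all background rates by a constant
  leaves the test statistic, the null ensemble and the p-value exactly
  unchanged (bit-for-bit, not just approximately; see §4).
* **Recurrence blindness.** A tumour with ten mutations in a region
  contributes exactly like a tumour with one. Recurrence-based signals
  (hotspots) are deliberately ignored; the method is complementary to
  recurrence tests, not a replacement.

## 2. Background models

### 2.1 Trinucleotide channels

Single-nucleotide variants are classified into the standard 96 channels:
6 pyrimidine-centred substitutions (C>A, C>G, C>T, T>A, T>C, T>G) × 16
flanking-base combinations, written e.g. `A[C>T]G`. Purine-centred
changes are strand-collapsed by reverse complement. Genomic *territory*
is tallied per pyrimidine-centred trinucleotide context (32 contexts);
positions whose context contains an ambiguous base are excluded from both
territory and classification. Channels are ordered substitution-major,
then alphabetically by 5′ and 3′ flank, so `mutationChannels()[1:3]` are

```{r}
mutationChannels()[1:3]
```

Territory is counted on the reference strand only. Because channels are
strand-collapsed, a site contributes to exactly one context whichever
strand carries the pyrimidine, so a single-strand tally is complete and
double-counting by also scanning the reverse complement would be wrong.
The test suite verifies that the channel classification itself is
invariant under reverse-complementing the genome.

### 2.2 Per-tumour rates

For whole genomes (`mode = "wgs"`), tumour $j$'s rate in channel $c$ is
its own count in $c$ divided by the genome-wide territory of $c$'s
context. Exomes carry too few mutations per tumour for a stable 96-channel
spectrum, so for `mode = "wxs"` we estimate one cohort spectrum (pooled
counts over pooled territory, restricted to the captured regions) and
scale it per tumour by burden share: tumour $j$ gets the cohort spectrum
multiplied by $b_j / \sum_{j'} b_{j'}\,$·(number of tumours), where $b_j$
is the tumour's total SNV count. Burden is measured on *all* SNVs, not
only the qualifying (missense/nonsense) ones: burden proxies the exposure
of the mutational process, and synonymous and non-coding mutations are
equally informative about exposure while being unaffected by selection —
using only qualifying mutations would let selection leak into the
background model. With `perCancerType = TRUE`, the cohort spectrum and
burden shares are computed within each cancer-type scope separately.

### 2.3 Region profiles

For a coding region we enumerate every possible single-base change in its
spans, annotate each with its coding effect, and keep the *qualifying*
changes — by default missense and nonsense. Stop-loss and start-loss
changes alter the protein product without truncating it, so they are
classed as missense rather than given categories of their own; synonymous
changes never qualify. Non-coding regions (`kind = "interval"`, e.g.
promoters) qualify every possible change. Summing each tumour's channel
rates over the qualifying changes gives the per-tumour expected count
$\lambda_j$ for the region.

## 3. Recurrence scaling

Let $k$ be the number of distinct tumours mutated in the region. We map
rates to probabilities through

$$\tilde p_j = 1 - e^{-s\,\lambda_j},$$

choosing the single scale factor $s > 0$ so that $\sum_j \tilde p_j = k$.
This is the Poisson probability of at least one hit under rate
$s\lambda_j$, and the constraint makes the expected number of mutated
tumours equal the observed number — the test retains no information about
how *many* tumours are mutated, only *which*.

Numerical contract: the root is found by bisection with a Newton polish
and must satisfy $|\sum_j \tilde p_j - k| < 10^{-6}$; the symmetric case
(all $\lambda_j$ equal) is solved in closed form and is exact. To make
rate blindness *bit-exact* rather than merely within floating-point
noise, the profile is normalised by its maximum and rounded to 9
significant digits before solving: any two profiles that are scalar
multiples of one another then present the identical vector to the solver
and yield identical $\tilde p$, statistics and simulations. Nine digits
is far below the $10^{-6}$ contract's resolution yet coarse enough to
absorb the one-ulp differences that division by different scalars
produces.

```{r}
lam <- c(T1 = 0.02, T2 = 0.10, T3 = 0.35, T4 = 1.10)
sc <- scaleToRecurrence(lam, k = 2)
round(scaledProb(sc), 4)
identical(scaledProb(sc), scaledProb(scaleToRecurrence(1000 * lam, k = 2)))
```

## 4. The statistic and its null

The observed set $M$ is scored by the Bernoulli log-likelihood of the
whole cohort configuration,

$$\ell(M) = \sum_{j \in M} \ln \tilde p_j
          + \sum_{j \notin M} \ln (1 - \tilde p_j),$$

and the reported statistic is the deviance $D = -\ell(M)$ (large $D$ =
surprising set). Using $-\ell$ rather than a likelihood *ratio* keeps the
statistic monotone in the implausibility of the set and needs no
alternative model; since the null distribution is simulated from the same
$\tilde p$, any fixed monotone transform of $\ell$ yields the same
p-values.

### 4.1 Null law: conditional Bernoulli

The null ensemble must answer: *given independent mutation indicators
with success probabilities $\tilde p_j$, what sets of size $k$ arise?*
The exact answer is the independent-Bernoulli law conditioned on the
total being $k$ — the *conditional Bernoulli* distribution,

$$P(M) \;\propto\; \prod_{j \in M} \frac{\tilde p_j}{1 - \tilde p_j},
\qquad |M| = k.$$

We sample it exactly: a dynamic-programming table of elementary symmetric
sums (kept in log space for stability) gives, scanning tumours in order,
the probability that tumour $i$ is included given how many slots remain —
a standard exact sampler that is $O(nk)$ per table and vectorises across
simulations.

A tempting alternative is *sequential* sampling: draw $k$ tumours one at
a time without replacement, each proportional to $\tilde p_j$ among the
remainder (equivalently, a weighted race). We implement it too
(`law = "sequential"`), but it is **not** the conditioned product-
Bernoulli law, and the difference matters in practice. On realistic
cohorts — 200 tumours with a 100-fold burden spread — we measured the
sequential law's p-values against their own ensembles within this
package's calibration harness: the empirical distribution of neutral
p-values deviated from uniform by a Kolmogorov–Smirnov sup-norm of
0.26–0.62 depending on conditions, a gross miscalibration, because the
sequential scheme over-weights heavy tumours relative to the conditioned
law when the $\tilde p_j$ are far from uniform. The conditional-Bernoulli
sampler under identical conditions gave sup-norms of 0.03–0.06 and a
type-I error at the 5% level inside its exact binomial interval. The
package therefore defaults to `law = "conditional"` everywhere; the
sequential law remains available behind the same interface for
comparison. Both laws are validated in the test suite against exact
enumeration over all $\binom{n}{k}$ subsets (`exactSubsetP`), which for
the conditional law normalises the product-of-odds weights directly —
an oracle independent of the DP sampler.

### 4.2 Tail smoothing

With `nSim` simulations the empirical p-value

$$p_{\mathrm{emp}} = \frac{1 + \#\{D^{(s)} \ge D_{\mathrm{obs}}\}}{nSim + 1}$$

is unbiased but granular at $1/(nSim+1)$. To rank strong candidates
beyond that floor, a gamma distribution (shape/rate, location 0) is
fitted to the simulated $D$ values by maximum likelihood and the reported
`p` is its upper tail at $D_{\mathrm{obs}}$. Degenerate ensembles
(constant $D$, e.g. symmetric profiles) fall back to the empirical
p-value and are flagged. Both values are reported; `p_empirical` is the
model-free reference.

## 5. Cohort pipeline

`seismicTest()` chains: quality filters → territory → background models →
per-region qualifying changes, joined to observed mutations in a single
interval-overlap pass → testable-region selection → per-region scaling,
statistic, simulation and tail fit → Benjamini–Hochberg adjustment.

Filters, with their boundary conventions:

* **Dominant tumour.** Any tumour carrying ≥ 10% of the cohort's
  mutations is removed, in a single pass against the *original* totals
  (no iteration — iterating would cascade arbitrarily far on small
  cohorts). With `scope =` cancer types, the fraction is assessed within
  each scope: a tumour dominant in a small cohort-wide minority type
  should be removed even if globally negligible, and conversely. If the
  pass removes every tumour the cohort is rejected with an error.
* **Hypermutators.** With `hypermutatorAbsolute = N`, burden ≥ N is
  removed (boundary inclusive).
* **Testable regions.** A region qualifies with ≥ 3 qualifying mutations;
  cohorts yielding fewer than `minRegions` testable regions abort. No
  leave-one-out re-estimation of the background per region is performed:
  a single region's mutations are a vanishing fraction of a cohort's
  total, so the contamination of the cohort spectrum by the tested
  region is negligible, while leave-one-out would make every region's
  background (and hence territory-normalised rates) different objects,
  multiplying cost for no measurable benefit at cohort scale.

## 6. Diagnostics

The cumulative mutated-tumour (CMT) curve orders tumours by increasing
$\tilde p_j$ and plots the running count of observed mutated tumours
against the simulated envelope. Neutral regions track the envelope;
drivers accumulate mutated tumours too early (among low-probability
tumours):

```{r, fig.width = 6, fig.height = 4}
set.seed(1)
lam <- stats::setNames(exp(stats::runif(40, -3, 0)), sprintf("t%02d", 1:40))
sc <- scaleToRecurrence(lam, k = 8)
ens <- simulateNull(sc, nSim = 1000L, seed = 2)
driverLike <- names(sort(scaledProb(sc)))[1:8]
plotCmt(cmtSeries(sc, ens, driverLike))
```

## 7. Synthetic cohorts and their limits

`generateCohortFixture()` builds a genome of tandem gene models separated
by intergenic spacers, draws per-tumour burdens log-uniformly over a
configurable range, places mutations according to a chosen 96-channel
signature (uniform, or a UV-like signature with 80% of mass on
C>T at dipyrimidines), and can inject drivers: for each driver gene,
`driverRecurrence` tumours are chosen *uniformly* — ignoring burden,
which is exactly the selection signal the test looks for — and each
receives one qualifying (missense/nonsense) mutation.

Realism limits worth keeping in mind: mutations are placed independently
and uniformly within a context (no kataegis or clustered processes);
every tumour shares one signature (real cohorts mix signatures per
tumour); gene models are single-exon and of equal length; copy number,
expression, replication timing and chromatin covariates — all known
modulators of regional mutation rate — are absent. The fixture validates
the statistical machinery, not the biology of any particular cohort.

Problem sizes used in the shipped validation (cohorts of 100–200 tumours,
burden spreads of 10–100×, 50–300 genes of 300 bp, 2 000–100 000 null
simulations) were chosen to exercise the regimes where the method's
guarantees are informative while keeping the full suite within minutes on
a single core.

## 8. Validation summary

The acceptance tests (in `tests/testthat/test-acceptance.R`) check, at
fixed tolerances: Monte-Carlo p-values against exact subset enumeration
on small cohorts; uniformity of neutral-cohort p-values (exact binomial
interval on the 5% type-I rate plus an ECDF sup-norm bound); recovery of
injected drivers; bit-exact rate blindness along the full pipeline path;
the recurrence-scaling residual contract; effect annotation against an
independent translation of all 576 codon substitutions; FDR adjustment
against a reference step-up implementation; recovery of the generating
signature by the cohort model; and the documented filter boundaries.
`scripts/acceptance.R` recomputes the headline quantities and writes them
as JSON.
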