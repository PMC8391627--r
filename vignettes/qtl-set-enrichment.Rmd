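---
title: "Score-weighted gene set enrichment testing against QTL regions"
author: "qtlsea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Score-weighted gene set enrichment testing against QTL regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlsea)
```

## The problem

In crop genomics, most traits of interest — drought tolerance, salinity
response, disease resistance — are quantitative and polygenic. Quantitative
trait loci (QTLs) are genomic intervals statistically linked to such traits
by mapping studies, and public databases catalogue them with physical
coordinates. Gene expression studies of the same stresses produce long
ranked lists of differentially expressed (DE) genes. The question this
package answers: *is a set of top-ranked DE genes enriched in trait-specific
QTL regions beyond what chance placement would give?* A positive answer
ties the expression response (genotype) to the mapped trait (phenotype) and
nominates the gene set as QTL candidates for breeding programmes.

Classical over-representation analysis (ORA) answers this by counting: how
many genes of the set fall inside a QTL, compared to a hypergeometric null.
Counting throws away the DE scores — a gene barely past the threshold
counts as much as one with overwhelming evidence. The test implemented here
weights each gene's QTL-overlap status by its DE score.

## The statistic and its null

Fix a gene universe $\Omega$ of $N$ genes with genomic coordinates, of
which $V$ overlap at least one QTL interval ("hits"). Rank the genes by a
non-negative DE score $D_i$ and carve the top-$n$ set $G$ off the list.
With $h_i \in \{0, 1\}$ the hit flag, the enrichment statistic is the
within-set contrast

$$ S \;=\; \sum_{i \in G,\, h_i = 1} D_i \;-\; \sum_{i \in G,\, h_i = 0} D_i . $$

Under the competitive null — hit status falls on the ranked list at random,
so $G$ is no more QTL-covered than its complement — the number of hit genes
in $G$, $N_{GQ}$, is hypergeometric:

$$ P[N_{GQ} = v] = \binom{V}{v}\binom{N - V}{n - v}\Big/\binom{N}{n},
   \qquad E(N_{GQ}) = \frac{nV}{N},\qquad
   V(N_{GQ}) = \frac{nV(N-V)(N-n)}{(N-1)N^2}. $$

Conditioning on the score values in $G$ (mean $E(X)$, population variance
$V(X)$) and placing the $v$ hits uniformly within $G$, finite-population
sampling algebra gives the exact moments

$$ E(S) = 2\,E(X)\,E(N_{GQ}) - n\,E(X), $$
$$ V(S) = 4\left[\frac{V(X)}{n-1}\Big(E(N_{GQ})\big(n - E(N_{GQ})\big) -
   V(N_{GQ})\Big) + E(X)^2\, V(N_{GQ})\right], $$

so $Z = (S - E(S))/\sqrt{V(S)}$ is referred to N(0,1) with a one-sided
upper tail (the alternative is *more* QTL overlap among the selected
genes). The test suite validates these moments against a $10^5$-draw
Monte-Carlo oracle (mean within 1%, variance within 2%) and checks that
with constant scores the procedure collapses *exactly* (to $10^{-12}$)
onto the standardised hypergeometric count — ORA with a normal
approximation. The statistic is scale-equivariant: rescaling all scores
leaves $Z$ and $p$ unchanged, which is why the optional
`normalize_scores` max-scaling is statistical a no-op and exists only to
tame very large likelihood-ratio values numerically.

Two points where the procedure is defined more precisely than the loose
verbal description, and why:

* **Which contrast.** An alternative reading subtracts the hit genes of
  the *complement* $G^c$ rather than the non-hit genes of $G$. The analytic
  moments above are the moments of the within-set contrast — the
  complement form has different (and non-analytic) moments. Using
  mismatched moments breaks the type-I error, so the within-set form is
  the default; the complement form is available as `form = "literal"`
  with moments estimated by permutation (`B_perm` draws).
* **Which count.** A gene overlapping $k$ QTLs contributes $k$ to the
  descriptive pair count (reported as `NQHits`) but only 1 to $N_{GQ}$;
  the hypergeometric null is only well defined for the distinct-gene
  count. Both are reported.

The population (divide-by-$n$) variance is used for $V(X)$ because the
$n-1$ factor in $V(S)$ is the finite-population correction that pairs with
it in the derivation.

Across the $K$ nested set sizes (default 200, 300, ..., 2000), the $K$
p-values receive the Hochberg step-up adjustment (family-wise control;
all sets treated as equally important) and Benjamini–Hochberg values are
attached as an FDR column. The Hochberg decision rule is implemented
independently of the adjusted values, and the suite verifies the two
routes agree on a thousand random vectors.

## DE scores

Scores must be non-negative (signed statistics are rejected at input):

* `nb_lrt_scores()` for RNA-seq counts: per-gene likelihood-ratio
  statistics from a negative-binomial GLM with log link and size-factor
  offsets, $\log_2 E(Z_{ij}) = \beta_{0i} + \beta_{1i} X_j$, variance
  $\mu + \phi\mu^2$ ($\phi \to 0$ recovers Poisson). With a binary group
  covariate the alternative model factorises into two one-parameter fits,
  so each gene needs three concave 1-D maximisations, done by vectorised
  Newton iteration; the suite cross-checks against `glm()` with a
  negative-binomial family and a numeric optimiser.
* `t_scores()` for continuous (microarray-style) values: absolute Welch
  (default) or pooled two-sample t statistics.
* `read_scores()` for precomputed scores from any external DE tool.

Dispersion is estimated per gene by a pooled within-group
method-of-moments estimator floored at $10^{-8}$ — deliberately simple
and pluggable (pass `dispersion =` to override, or supply precomputed
scores). It is *not* a shrinkage estimator: with few replicates it is
noisy and the null LRT distribution becomes anticonservative (about 25%
inflation of the 95th percentile over $\chi^2_1$ at 6 samples per group,
about 9% at 12 per group in the packaged simulations). Ranking — the role
the scores actually play here — is robust to this miscalibration, but the
raw LRT values should not be reused as calibrated single-gene tests at
low replication.

Size factors default to median-of-ratios over genes positive in every
sample, falling back to library-size scaling for very sparse matrices.

## Interval conventions

Coordinates are 1-based inclusive internally (GFF3 convention); BED input
is converted on read. A gene is a hit when it shares at least one base
with a QTL on the same chromosome (`mode = "any"`); full containment of
the gene in the QTL is available (`mode = "containment"`), and since QTL
intervals are megabase-scale the two rarely disagree. Any-overlap is the
default as the least-surprise convention in interval genomics. Chromosome
labels are compared after trimming and case-folding a leading "chr", so
unknown labels never match and such genes are simply never hit. Strand is
ignored. The universe is whatever gene annotation the user supplies; if
the expression pipeline pre-filtered genes, the filtered list is the
universe the competitive null sees — supply it consistently.

## The simulator

`simulation_scenario()` bundles the generator parameters; defaults emulate
a rice-like study: 12 chromosomes, $N = 2000$ genes (0.5–5 kb, gaps
0.2–3 kb), 30 QTLs targeted at 20% gene coverage, 12 samples per group
(the replication of the motivating salinity study), 10% DE genes at
$|\beta_1| = 1$ (2-fold), dispersion $\phi = 0.1$, relative depths
0.7–1.3, and baseline $\log_2$ means N(5, 2). Coverage targeting redraws
QTL placements (up to 200 attempts) until the realised covered fraction
is within 10% relative of the target. The DE–QTL coupling $\rho$ is the
probability a DE gene lies in a QTL region: $\rho$ equal to the realised
coverage is the null of no association; larger $\rho$ creates the
enrichment signal. Each stage (genome, QTLs, counts) draws from its own
seed substream, so changing count parameters never perturbs the genome.

What the simulator does *not* emulate: linkage disequilibrium and gene
clustering (genes are placed independently), correlated expression between
genes, isoform structure, zero inflation beyond the NB, and mapping
artefacts. Passing tests on synthetic data therefore validate the
*statistical machinery* — moments, calibration, power ordering — not the
biological fidelity of any particular dataset.

## Problem sizes used in the checks

The packaged validation runs at desk scale, chosen to make the checks
sharp but quick: moment oracle at $N=200, V=60, n=20$ with $10^5$ draws;
null calibration on 2,000 simulated datasets at $N=2000, V=400, n=200$
(rejection rate at $\alpha = 0.05$ must fall in [0.035, 0.065] and the
Kolmogorov–Smirnov distance of the p-values from uniform below 0.05); and
comparative power on 200 replicate coupled scenarios ($\rho = 0.4$ vs
coverage 0.2) over the size grid 200–1800. On the grid the weighted test's
median $-\log_{10} p$ is about 9 against about 2.4 for count-only ORA,
with ORA decaying as sets grow while the weighted statistic holds. The
advantage comes precisely from sets that mix high-score hit-enriched genes
with low-score background: when a set contains *only* strong DE genes
(size equal to the number of DE genes), hit status is uncorrelated with
score inside the set and weighting gains nothing — visible in the per-size
pattern, and worth remembering when choosing set sizes in practice.

## Known limitations

* The normal reference for $Z$ is an approximation; for very small sets
  (tens of genes) or very skewed scores the tail is not exact. The
  `literal` permutation form provides a slower but assumption-free check.
* The moments condition on the observed scores of each set, which is the
  standard competitive-testing stance; inter-gene correlation (co-expressed
  clusters inside QTL regions) is not modelled and can inflate
  significance, as in all competitive gene-set tests of this family.
* QTL intervals from mapping studies can be extremely wide; with
  `mode = "any"` a megabase QTL covers many genes and $V/N$ grows, which
  the null absorbs, but biological interpretation of single hits weakens.
* The dispersion estimator trades accuracy for transparency (see above).
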