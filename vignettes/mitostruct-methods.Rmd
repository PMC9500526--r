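---
title: "Methods: mitochondrial population structure and demographic model choice"
author: "mitostruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitochondrial population structure and demographic model choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitostruct)
```

# Scope and data model

`mitostruct` analyses grouped, heterochronous whole-mitogenome alignments:
equal-length sequences over `{A,C,G,T,N,-}` on a fixed coordinate frame
(the 16,569-site rCRS frame for human mtDNA), partitioned into named
groups, each sample optionally carrying a calendar age in years BP. The
package never realigns; multiple sequence alignment is an upstream,
external step, and all statistics assume a common site frame. Gaps (`-`)
are pooled with `N` as missing throughout: mtDNA indel calls in ancient
consensus sequences are unreliable, and treating them as a fifth state
would manufacture spurious segregating sites.

Printed archaeological dates become ages through one documented rule: a
BCE interval maps to its midpoint plus 1950 (calibrated intervals are
treated identically), an "Nth cen. BCE" to the century midpoint. Only
coarse ages are needed — they position serial samples on the coalescent
time axis, where an error of a few decades is far below one coalescent
time unit for any plausible effective size.

# Haplogroup frequency structure

Fine haplogroup calls (e.g. `T2b3+151`) collapse to macro-haplogroups by
longest-prefix matching against an ordered scheme
(`L0..L5, HV, H, V, J, T, U, K, I, W, X, N, R, M`), after stripping
extra-mutation suffixes. Longest-prefix matching is what makes `HV0a`
collapse to `HV` rather than `H`; unlisted `L` sub-lineages collapse to
`L`, and anything else fails loudly — the frequency table drives the
headline ordination, and silently pooling unmatched labels into an
"other" class would bias it.

The PCA operates on relative frequencies (count / group size),
column-centered; unit-variance scaling is available behind a flag but off
by default. With compositional data on a common scale, centering alone
preserves the interpretation of loadings as frequency contrasts, while
unit-variance scaling would inflate rare haplogroups observed once or
twice. Constant columns are dropped with a warning. Whether counts or
frequencies, scaled or not, went into the original biplots is not
recoverable from most publications; both options are therefore exposed
and the default documented.

# Diversity and differentiation statistics

Within each group the package reports the haplotype count $K$, haplotype
(gene) diversity $H = \frac{n}{n-1}(1 - \sum_i p_i^2)$, segregating sites
$S$, and the mean number of pairwise differences $\pi$, reported as a
count of differing sites rather than per site. Missing data are handled
by complete deletion for $K$, $H$ and $S$ (sites containing any `N`/gap
removed first) and pairwise deletion for $\pi$ by default, mirroring
common practice in the Arlequin/arlsumstat lineage of tools; both
policies are exposed because published analyses rarely state the setting.
Tajima's $D$ uses the classical constants and is undefined (`NA`) for
monomorphic data and refused below $n = 4$, where its variance terms are
unstable.

Differentiation is distance-based throughout. The working metric is the
raw pairwise difference count under pairwise deletion; a Kimura
two-parameter matrix ($d = -\tfrac12\ln[(1-2P-Q)\sqrt{1-2Q}]$, with
saturated pairs set `NA`) is available for phylogenetic-style distances.
"F~ST~" here always means the molecular $\Phi_{ST}$ of a one-level
distance AMOVA with difference counts playing the role of squared
distances:

$$\Phi_{ST} = \frac{\sigma^2_a}{\sigma^2_a + \sigma^2_w},$$

with the among-group component estimated from
$SSD_{among}/(P-1) - \sigma^2_w$ scaled by the unequal-sample-size factor
$n' = (N - \sum_k n_k^2/N)/(P-1)$. Significance comes from permuting
individual group labels; the p-value is +1-smoothed
($p = (b+1)/(n_{perm}+1)$, ties counted as exceedances — conservative)
and reported with its binomial standard error, matching the
"p ± se" convention of permutation-based AMOVA software. The default is
10,000 permutations. Negative pairwise $\Phi_{ST}$ estimates are retained
in tables (they are informative sampling noise around zero) and clamped
to zero only on entry to classical MDS, which requires a dissimilarity.
MDS itself is Torgerson scaling — double-centering of the squared
dissimilarities followed by eigendecomposition — as implemented by
`stats::cmdscale`; dimensions beyond the positive eigenvalues are trimmed
with a warning.

# The serial coalescent simulator

The simulator is a standard haploid coalescent with heterochronous
sampling. $N$ counts transmitting lineages (the mtDNA effective size):
with $k$ active lineages in a deme of size $N$, the next coalescence
arrives at rate $\binom{k}{2}/N$ per generation. Lineages activate when
the backwards clock passes their sampling age; ages convert to
generations at 25 years per generation, the conventional human value.

Two demographic topologies describe the origin of the younger sampled
group (the Sicanian-like deme B) relative to the older one (the Bronze
Age deme A):

* **Continuity** — one panmictic deme of constant size `N_anc` holds both
  groups serially: B descends directly from the population A was drawn
  from. No size change is modelled — the hypothesis as drawn has no
  bottleneck — but the constructor is the single place a piecewise size
  hook would attach.
* **Discontinuity** — B coalesces within its own deme of size `N_sic`
  until the divergence time `T_div` (years BP, constrained to predate the
  oldest sample), when survivors merge into the `N_anc` deme.

Mutations follow a finite-sites Jukes–Cantor process: per branch of
length $b$ generations the count is Poisson with mean
$\mu \cdot g \cdot L \cdot b$, each hit striking a uniform site and
substituting a uniform different base, with the ancestral sequence drawn
uniformly at the root. Finite sites (rather than infinite sites) matches
what sequence-level simulators in this field do; at 16.6 kb and ancient
timescales recurrent hits are rare but free to model. A branch expecting
more than $L/2$ mutations triggers a saturation warning. Internally,
simulated datasets are carried as the ancestral sequence plus mutated
columns only, which is what makes reference tables of $10^4$ simulations
cheap; `sim_to_grouped()` expands to the full frame and both paths give
identical statistics.

## Priors and study conditions

The sampling design defaults to the study conditions: 8 samples of deme A
at 3,500 BP and 17 of deme B at 2,450 BP, on a 16,569-site locus. The
original prior specification lives in supplementary material distributed
with the source study; the defaults here are chosen once as
field-conventional and are fully substitutable through `prior_set()` or a
YAML prior file:

| parameter | prior | rationale |
|---|---|---|
| `N_anc`, `N_sic` | log-uniform on [10^2^, 10^5^] | spans small isolated demes to large regional mtDNA pools; log-uniform is the standard weakly-informative choice for a scale parameter |
| `T_div` | uniform on [6,000, 8,000] BP | the Neolithic window named by the discontinuity hypothesis |
| `mu` | log-uniform on [10^-8^, 5×10^-8^] /site/year | brackets published whole-mtDNA pedigree and phylogenetic rate estimates |

Reproducing the published numbers exactly therefore requires substituting
the supplementary priors and the real alignments (see the README's
reproduction section); everything else in the pipeline is identical.

# ABC model choice with random forests

Each simulated (and the observed) dataset is summarized by 11 statistics
in a fixed order: $K$, $H$, $S$, $D$, $\pi$ per deme, plus the pairwise
$\Phi_{ST}$. $D$ is imputed as 0 — flagged, and only inside this feature
vector — when a deme is monomorphic (or smaller than 4), because forest
features cannot be missing and discarding degenerate simulations would
bias the prior predictive. The Fisher linear discriminant between the two
model labels, fitted on the reference table only, is appended as a 12th
feature (with two models there is exactly one axis); a singular
within-class scatter is ridge-regularized at a relative 10^-8^. The
discriminant direction is unit-normalized with a fixed sign convention so
projections are invariant to row order.

A 500-tree classification forest (ranger, `mtry` at its default
$\sqrt{p}$, no depth cap, single-threaded and seeded for full
determinism) is trained on the reference table. Out-of-bag predictions
give the confusion matrix and per-model classification errors — the
power estimate of the whole procedure. The observed vector's votes are
the per-tree predictions at that point; the selected model is the
majority (ties, essentially impossible at 500 trees, break
lexicographically with a warning). The posterior probability of the
selected model is estimated as one minus the predicted misclassification
probability at the observed point, obtained from a regression forest
fitted to the OOB misclassification indicator as a function of the
features — the ABC-RF construction. Raw vote shares are also reported,
since they are what older summaries print. One practical caveat the test
suite encodes: the posterior must be evaluated at a point *not* in the
reference table, because forests partially memorize in-bag rows and the
error regression is biased at training points.

# Synthetic data and what the tests show

`make_structured_alignment()` wraps the simulator at three fixed
divergence rungs under the study's sampling design: *low* (one panmictic
deme of 10,000; $\Phi_{ST} \approx 0$), *medium* (split at 10,000 BP,
deme sizes 2,000; moderate structure), *high* (split at 60,000 BP, deme
sizes 1,000; $\Phi_{ST}$ well above 0.3). The generator emulates grouped,
heterochronous, clonally inherited sequences with controlled divergence —
it does not emulate ancient-DNA damage, contamination, reference bias or
haplogroup-correlated sampling, so passing tests demonstrate statistical
correctness of the machinery, not robustness to those artefacts.
Consensus-quality input sequences are assumed.

Test and analysis problem sizes are the package's own choices, scaled for
a desk run: reference tables of 5,000 simulations per model (the source
analysis used 50,000), 2,000-replicate Monte-Carlo checks of the
simulator against Watterson's $E[S] = \theta a_{n-1}$, the $n=2$
$E[T_{MRCA}] = N$, and the near-zero neutral mean of Tajima's $D$; and
400 held-out pseudo-observations for classifier calibration
(OOB error vs. empirical misclassification within ±0.05).

# Numerical choices and limitations

* Permutation tests, prior draws, genealogies, mutation placement and
  forests are all seedable; the pipeline derives per-stage seeds
  deterministically from one master seed, so a run is reproducible from
  its manifest.
* $\Phi_{ST}$ is defined as 0 when both variance components are zero
  (identical monomorphic groups), the only defensible value for "no
  variance anywhere".
* Tied permutation statistics count as exceedances; p-values can never be
  0 or 1.
* The K2P log argument going non-positive (saturation) yields `NA` plus a
  warning rather than an arbitrary cap.
* Limitations: one-level AMOVA only (no hierarchical designs); two demes
  and two models only in the simulator and classifier (no migration
  matrices, no recombination — mtDNA is clonal); no ABC parameter
  estimation, only model choice; haplogroup labels are inputs, never
  called from sequence.
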