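---
title: "Methods: probe-enrichment statistics and the homolog survey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probe-enrichment statistics and the homolog survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobascreen)
```

# Scope

`cobascreen` implements two connected analyses from the study of
vitamin-B12 acquisition in gut *Bacteroidetes*. The first is the
statistical pipeline behind an affinity-based-probe (ABP) chemoproteomics
screen: cells are grown with a clickable, photo-crosslinking B12 probe or
with unlabeled B12, probe-bound proteins are enriched and quantified by
label-free mass spectrometry (LFQ), and proteins reproducibly more
abundant in the probe condition are called B12-binding candidates. The
second is a comparative-genomics survey of the *btuH* family of surface
B12-binding lipoproteins: homologs are called from similarity-search hit
tables at an E-value cutoff, their N-terminal domain architectures are
assigned, their operons are classified by co-occurrence with the *btuB*
outer-membrane transporter, and the association between a genome's
cobamide-biosynthetic capacity and its *btuH* content is tested.

Upstream steps (peptide-spectrum matching, LFQ computation, the BLAST
searches themselves, operon prediction) are out of scope: the package
consumes their standard output formats (proteinGroups-style TSV, BLAST
outfmt 6, membership tables).

# The enrichment model

## Filtering

For each screen the quantification table is reduced to analyzable
proteins: contaminant-flagged rows and proteins identified by fewer than
three peptides are removed, and a protein must have been observed
(intensity > 0) in *all* replicates of at least one of the two compared
groups. The last rule keeps both completely observed proteins and
probe-only (or control-only) proteins — the latter are often the strongest
binders, visible only after enrichment — while discarding proteins too
sparsely observed to compare.

## Left-censored imputation

LFQ dropout is missing-not-at-random: low-abundance proteins fall below
the detection limit. After `log2` transformation the pipeline therefore
imputes from a left-censored model:

1. the censoring floor $m$ is the minimum observed log2 abundance over all
   proteins and samples of the comparison;
2. missing cells are provisionally filled with $m$ and each protein's
   normal mean $\mu_p$ is the mean of its filled values;
3. a single shared standard deviation $\sigma$ is the average over
   proteins of the per-protein sample SD of the filled values;
4. each missing cell is replaced by an independent draw from
   $\mathcal{N}(\mu_p, \sigma)$, in row-major order from one seeded
   generator.

The published description is ambiguous on three points, so each is a
switch with a documented default: the floor may instead be per-protein
(`fill = "per_protein"`); $\sigma$ may instead average per-sample SDs
(`sigma_from = "sample"`); and the draw granularity (one draw per missing
cell, row-major) is our choice — the text does not state it. Draws are not
truncated to the observed range; with $\sigma = 0$ the imputation is
deterministic and seed-independent.

## Testing and error control

Each protein is tested with a right-tailed two-sample t test (alternative:
probe mean > control mean). The default is the pooled-variance Student
statistic with $n_1 + n_2 - 2$ degrees of freedom — the classical reading
of "two-sample t test" — with Welch's unequal-variance statistic available
as `test_variant = "welch"`. Degenerate zero-variance cases use the
convention $t = 0, p = 1$ for equal means and $p \in \{0, 1\}$ by the sign
of the difference otherwise. Raw p-values are adjusted with the
Benjamini–Hochberg step-up rule over all tested proteins of the screen,
and hits satisfy adjusted $p < \alpha$ strictly (default
$\alpha = 0.05$). The log2 fold change is the difference of
post-imputation group means, matching the description of fold changes as
differences of average replicate log2 abundances; computing it
pre-imputation is not offered because probe-only proteins would have no
control mean.

Each screen is analyzed fully independently (its own filter, floor,
$\sigma$ and BH family), and `intersect_screens()` reports the proteins
significant in both screens (the high-confidence table) and in one or both
(the union table).

# The synthetic screen generator

`simulate_lfq_screen()` emulates the screen design, not the instrument:
per-protein log2 baselines are $\mathcal{N}(\mu_0, \sigma_0)$ (defaults
25 and 2, typical of log2 LFQ intensities), replicate noise is
$\mathcal{N}(0, 0.5)$, both conditions are in biological quadruplicate,
and a planted set of 50 of 1000 proteins gets a +3 log2 shift in the probe
group — strong, as expected for an enrichment pulldown. Dropout is
logistic in the log2 intensity with midpoint 22 and scale 1, i.e. cells
about three SD below the population mean are missing about half the time,
which produces realistic 5–20% missingness concentrated in low-abundance
proteins. Five percent of proteins are contaminant-flagged and ten percent
are low-peptide decoys; planted effects are never assigned to decoys so
recovery is well defined. The structural draws (decoy assignment, planted
set, baselines) are separated from the noise draws so two screens can
share truth (`noise_seed`), emulating independent biological replicates of
the same underlying experiment.

What the generator does *not* emulate: correlated dropout within samples,
intensity-dependent variance, shared peptides between protein groups,
normalization artifacts across runs, or batch structure. Passing
calibration and recovery tests on this generator therefore shows the
pipeline is correct under its stated model, not that real screens meet
that model.

# The homolog survey

Homolog calls pool the hits of three queries (the two *btuH* paralogs and
the *btuG* fusion used in the study) and designate any subject with
E-value $\le 0.03$ for at least one query; the cutoff is inclusive,
matching the published "$\le 0.03$" wording, and a subject hit by several
queries yields one call with the minimum E-value (union-with-dedup
semantics; the study reports "homologs across all three searches" without
stating the dedup rule). Domain architectures use a second, stricter
inclusive cutoff of $10^{-3}$: a β-propeller-query hit labels the call
`beta_propeller`, a hit from either PKD-region query (coding-sequence
sub-ranges bp 91–294 and 364–540 of the *btuH2* query) labels it `pkd`
with the number of qualifying PKD hits recorded. A subject qualifying for
both — a case the study never presents — is classified by the lower
E-value with both flags recorded.

BLAST tabular output carries no genome column, so subjects are attributed
to genomes by the `"<genome>|<protein>"` id convention, overridable with
an explicit map. *btuB* calls and operon membership are inputs, not
recomputed, because the study reuses previously published annotations.
Operons containing at least one called homolog or one *btuB* member are
classified into exactly one of `btuh_only`, `btub_only`, `both`; the
summary reports the fraction of genomes with at least one homolog and the
fraction of operon-assigned homologs whose operon class is `both`.

The panel generator plants an ordered biosynthesis category per genome
(early-precursor salvage < late-precursor salvage < transport-only, the
three categories reported for gut *Bacteroidetes*), draws per-genome
homolog counts as Poisson with category-dependent mean (default 0.3, 1, 2
— increasing with transport dependence, the direction the study observes),
and makes each homolog co-operonic with *btuB* with probability 0.8
(matching the reported "more than 80%" co-operonic fraction). Poisson
copy numbers are the simplest count model with a monotone mean; real
panels have phylogenetic correlation the generator deliberately omits, so
recovery tests certify the statistics, not phylogenetic robustness.

# Association statistics

The presence/absence-by-category table is tested with Pearson's
chi-square test of independence, no continuity correction (the published
2×3 test has df = 2, where no correction applies; none is used anywhere
for uniformity). The copy-number association uses Spearman rank
correlation with average ranks for ties; the two-sided p-value uses the t
approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of
freedom, with an exhaustive ($n \le 8$) or seeded Monte-Carlo permutation
alternative. The t approximation was chosen as the default because the
study's printed (rho = 0.47581, n = 89) pair reproduces its printed
p-value under it to four significant figures; the (rho = 0.68128, n = 58)
pair does not reproduce its printed p under this or any standard method we
tried at the printed rho and n, so that printed value appears internally
inconsistent and the package reports the honestly computed one.

Categories are coded 1..k by *increasing* dependence on transport, so the
reported inverse association between biosynthetic capacity and *btuH*
content appears as a positive rho, matching the sign convention of the
printed statistics; the coding is recorded in the output.

# Numerical choices

All tail probabilities are computed in-package: the chi-squared upper tail
via the regularized upper incomplete gamma function $Q(df/2, x/2)$
(series for $x < a+1$, Lentz continued fraction otherwise) and the t tails
via the regularized incomplete beta function (continued fraction with the
symmetry split at $x = (a+1)/(a+b+2)$). Both terminate at a relative step
below $10^{-16}$ and are validated in the suite against closed-form
identities (df = 2: $p = e^{-x/2}$; df = 1: the squared-normal tail) and
against the stats package to $10^{-12}$. Ranking uses average ranks;
permutation counts use a $10^{-12}$ slack when comparing $|\rho|$ values
to absorb floating-point ties. BH adjustment is the exact step-up rule
(cummin over the sorted sequence), order-equivariant and validated against
a naive $O(m^2)$ oracle.

# Problem sizes

The calibration and recovery checks run 100 seeded screens of 1000
proteins (quadruplicate, MNAR dropout) for the null and planted error-rate
estimates, and 100 panels of 500 genomes for direction recovery — sizes at
which the Monte-Carlo standard errors are small compared to the
thresholds being checked while a full run stays around a minute.

# Known limitations

- The imputation reproduces the published procedure, including its known
  statistical quirk: imputed values enter the t test as if observed, which
  understates uncertainty when many cells are imputed. The FDR-control
  simulations show the composite pipeline is nonetheless conservative
  under the generator's conditions.
- The survey's prevalence fractions depend entirely on the supplied hit
  tables and operon predictions; the package makes no attempt to
  reproduce the study's specific 58-genome or 181-operon datasets.
- The association tests ignore phylogenetic non-independence between
  genomes, as the originals do.
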