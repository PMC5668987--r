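---
title: "Clonality-aware escape calling and the surrounding sex-bias analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonality-aware escape calling and the surrounding sex-bias analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xciescape)
```

# The problem

In female cells one X chromosome is transcriptionally silenced
(X-chromosome inactivation, XCI), but a minority of X-linked genes
*escape* and are expressed from both copies. At a heterozygous exonic
site, escape shows up as biallelic expression: the allelic ratio —
coverage of the major allele over total coverage, a number in
$[0.5, 1]$ — sits near 0.5, whereas a silenced gene expressed from a
single X sits near 1.

The complication in lymphoblastoid cell lines (LCLs) is clonality.
An oligoclonal or monoclonal line has the *same* X inactive in most of
its cells, so even genuinely silenced genes show allelic ratios skewed
toward 1 by an amount that differs from individual to individual, and in
a polyclonal line the skew can be far from 1. A fixed ratio threshold
therefore cannot separate escape from silencing across individuals.

`xciescape` implements a classifier that absorbs this nuisance with a
**per-individual null**: for each sample, the mean $\mu_s$ and standard
deviation $\sigma_s$ of allelic ratios over a curated list of known
silent genes estimate that sample's clonality. Every other gene is then
tested against the distribution those two moments define. Around the
classifier sit the downstream analyses of sex-biased expression: a
gene-list permutation test for transcription-factor binding-site (TFBS)
enrichment near transcription start sites, basepair-weighted per-gene
replication timing, entropy of sex-biased gene content per topologically
associating domain (TAD), and linear models linking selection pressure
(dN/dS) and expression breadth to escape status and sex bias.

# The escape classifier

## Per-individual null

`fit_clonality_null()` pools the per-site allelic ratios of the known
silent genes within each sample and records $(\mu_s, \sigma_s, n_s)$.
Pooling sites (rather than per-gene means) maximises $n_s$; a per-gene
mode is available. Two guard rails matter in practice:

* `sigma_min` (default 0.01) floors $\sigma_s$ so that a monoclonal,
  high-coverage sample — whose silent ratios can be essentially
  identical — does not produce unbounded z-scores.
* `min_null_obs` (default 10) marks samples with too few silent-gene
  observations as unusable; such samples yield *no* calls, which is
  deliberately distinct from "silent" calls.

## Per-(gene, sample) test

`test_gene_sample()` aggregates a gene's sites into one ratio per
sample (coverage-weighted mean by default; an unweighted mode exists
because multi-site aggregation is a genuinely open choice) and forms

$$z = \frac{r_{gs} - \mu_s}{\sigma_s}.$$

Two implementation choices deserve explanation, because both were made
after measuring the classifier's operating characteristics on the
synthetic cohorts described below.

**Reference distribution.** $\mu_s$ and $\sigma_s$ are estimates from
$n_s$ observations, not known constants. Testing a *new* observation
against a normal with estimated moments calls for the Student-t
predictive distribution: $z / \sqrt{1 + 1/n_s}$ with $n_s - 1$ degrees
of freedom. With the plain normal the per-call false-escape rate at
$\alpha = 0.05$ runs about 0.8 percentage points high at $n_s = 50$;
the predictive t removes that excess. `null_dist = "normal"` restores
the plain-normal tail probability.

**Sidedness.** The default test is two-sided: a gene escapes in a
sample when its ratio is significantly *different* from the silent
null. A one-sided lower-tail variant (`sided = "lower"`) matches the
intuition that escape pulls ratios toward 0.5. The two-sided default
is not merely cosmetic: allelic ratios at ~50x coverage are
left-skewed (a binomial proportion with $p \approx 0.85$ has skewness
about $-0.28$), so a one-sided lower test has true size ≈ 0.058 at
nominal 0.05 and *cannot* be calibrated by any choice of reference
distribution, while for a symmetric two-sided split the skewness
corrections of the two tails cancel at third order and the realised
size is ≈ 0.050. Detection of real escape is unaffected — an escaping
gene under a clonal null sits many standard deviations below $\mu_s$,
where both versions reject.

## Population aggregation and cutoff calibration

`aggregate_population()` calls a gene an escape gene when it escapes in
strictly more than a cutoff fraction (default 0.30) of its informative
samples, requiring at least `min_informative = 5` samples; genes below
that floor are reported as `insufficient_data` rather than forced into
a class. `roc_calibrate()` sweeps the cutoff against curated
known-escape and known-silent lists, reporting sensitivity and
specificity per cutoff, the trapezoidal AUC, the Youden-optimal cutoff
(ties resolved toward the smallest cutoff), and the misclassification
rate of known escape genes at that cutoff. The positive class is the
known *silent* gene — a true positive is a silent gene correctly kept
silent — with the escape-oriented view obtainable by swapping the two
columns; the AUC is identical either way.

# TFBS enrichment

Binding sites within 2 kb of a TSS (strand-agnostic, closed window on
the genomic axis) are "proximal"; a site may be proximal to several
genes and counts for each. For a gene list of interest — e.g. genes
with nominal differential-expression $p < 0.05$, split by the sign of
the female-vs-male log2 fold change — `permutation_test()` draws
`n_perm` random lists of the same size, uniformly *without* replacement
from a reference universe, and reports

$$p = \frac{1 + \#\{\text{null} \ge \text{observed}\}}{n_{\text{perm}} + 1},$$

the add-one estimator, which is never zero and slightly conservative.
The per-TF count is, by default, the number of listed genes with at
least one proximal site of that TF ("genes" mode, robust to site
clustering); a "sites" mode sums sites instead. Fold change is
observed/null-mean. Nominal significance is reported at permutation
$p < 0.05$; a Benjamini-Hochberg column is emitted alongside because
nine-of-many nominal hits rarely survive correction.

# Genome features

**Replication timing per gene** is the basepair-weighted average of
segment values over the gene body:
$R_{\text{gene}} = \sum_i R_i \cdot \text{bpOverlap}_i /
\text{totalBpInGene}$. By a literal reading of that formula, gene
basepairs not covered by any segment contribute zero to the numerator
while the denominator stays the full gene length; an alternative mode
renormalises by covered length. A gene with no covered basepairs is
missing, not zero. Overlapping segments within one track violate the
track's contract and abort.

**TAD entropy** uses the single-term expression $-p \ln p$, where $p$
is the proportion of a TAD's genes (assigned by TSS containment) that
are sex-biased, with $-0 \ln 0 := 0$ by continuity. The natural log is
used; the base rescales all values uniformly and cannot change
rankings. This single-term form — maximal at $p = 1/e$, zero at both
$p = 0$ and $p = 1$ — is not the binary Shannon entropy; a
`binary = TRUE` flag provides the two-term version for users expecting
the standard definition. Genes whose TSS falls outside every TAD are
counted and reported, never silently dropped.

# Association models

All model fits are ordinary least squares with dummy-coded categorical
terms and t-based p values (`fit_dnds_model()`,
`fit_breadth_model()`, `fit_univariate()`):

* dN/dS on {X-added vs X-conserved region, XY-pair status, average
  expression, escape status, disease status};
* expression breadth (tissues expressed in, 1–56) on {sex-bias
  category, dN/dS, average expression};
* any single response on any single predictor, which for a two-level
  predictor reduces exactly to the difference of group means.

Reference levels are XAR, non-escape, unbiased, and `FALSE` for the
logical flags, so reported coefficients read "XCR vs XAR", "escape vs
non-escape", "female-biased vs unbiased", and so on. Missing data is
handled complete-case per model with a logged count. Rank-deficient
designs abort naming the collinear terms rather than silently dropping
them; three-group comparisons are available as the F test of the
categorical term.

# The synthetic-data generator

The generator defines the conditions under which the pipeline's
guarantees are tested; it is first-class, tested code, not a fixture.

**Cohorts** (`simulate_cohort()`). Each sample's clonal skew is
$\theta_s = 0.5 + 0.5\,\mathrm{Beta}(\alpha, \beta)$ — a flexible,
bounded family on $[0.5, 1)$; the defaults $\alpha = 7, \beta = 3$ give
a mean skew of 0.85 with substantial spread, reflecting how variable
LCL clonality is across individuals. Silenced genes draw haplotype
counts $\mathrm{Binomial}(c, \theta_s)$ and escape genes
$\mathrm{Binomial}(c, 0.5)$ at per-site coverage
$c \sim \mathrm{Poisson}(50)$ (negative-binomial optional); the
emitted table carries both the raw haplotype count, whose expected
fraction is exactly the simulated allele probability, and the derived
major-allele count that downstream analysis consumes. One informative
heterozygous site per gene per sample is the default — in real allelic
data most genes contribute a single usable exonic heterozygous SNP per
individual — and this is also the regime in which a site-pooled null is
exactly matched to single-site gene scores; with multi-site genes the
coverage-weighted gene ratio has smaller variance than the site-pooled
null and the test becomes conservative by construction. A per-gene
escape-penetrance parameter models inter-individual variability in
escape; it defaults to 1 (every escape gene escapes in everyone)
because no quantitative value is established to default to. One seed
drives everything, fanned out deterministically per sample, so adding
samples never reshuffles existing ones and identical seeds give
byte-identical outputs.

**Genomes** (`simulate_genome()`). Genes are placed uniformly per
chromosome in proportion to length; TF binding sites are uniform
background plus, for designated "enriched" TFs, extra sites planted in
the 2 kb proximal window of a target gene set at a configurable
per-gene rate. The replication signal is moving-average-smoothed white
noise rescaled to a fixed range, piecewise constant on tiles; TADs tile
each chromosome exactly (regular tiles by default, so a mean TAD size
equal to the chromosome length yields exactly one TAD; a CV parameter
adds size variation).

**Covariates** (`simulate_covariates()`). dN/dS and breadth tables are
generated so the stated linear models hold with Gaussian noise.
Breadth is clamped to the 1–56 tissue range but left continuous by
default so that zero-noise data is recovered *exactly* by the
regression stages; `integer_breadth = TRUE` rounds to whole tissue
counts (more realistic, recovery then only approximate). Default
coefficients are chosen so neither the breadth clamp nor the dN/dS
non-negativity floor binds.

What the simulator does *not* emulate: linkage and haplotype phase,
reference-mapping bias at heterozygous sites, shared regulatory
structure between neighbouring genes, partial-escape expression
gradients, or any population-genetic realism beyond the
binomial/clonality model. Passing tests therefore demonstrate that the
statistical machinery is correct and calibrated under its stated
assumptions — not that those assumptions exhaust the behaviour of real
LCL data.

# Problem sizes, tolerances, determinism

The shipped tests and the acceptance script use cohorts of 50–100
samples and 100–180 genes, a 200-gene/10-TF genome, 1000 permutations,
and 20-cohort calibration sweeps; these sizes give stable Monte-Carlo
estimates (binomial bands at fifty thousand pooled calls, permutation
standard errors below 0.005) while keeping a full run in the tens of
seconds on one CPU. Exact arithmetic identities (the bp-weighted
replication formula against a per-basepair brute force) are held to
1e-12; closed forms to machine precision; stochastic recoveries to
3 standard errors or to 95% binomial bands. Every random stage takes an
explicit seed, and the pipeline's single master seed is fanned out into
per-stage sub-streams, so two runs with the same configuration are
byte-identical — checked file-by-file with checksums.

One calibration check deserves a caveat: per-(gene, sample) escape
calls within a sample share the same estimated null and the same clonal
skew, so per-cohort false-escape rates carry extra-binomial variance.
The binomial band is therefore applied to the rate pooled across
cohorts, which is the quantity the binomial reference actually
describes.

# Known limitations

* The mapping-quality threshold (default `mq_min = 175`) follows a
  summed-quality convention from upstream tooling and exceeds the
  conventional 0–60 per-read scale; it is configurable, and the
  configuration validator notes the anomaly rather than rejecting it.
* Escape is summarised as the fraction of informative samples escaping;
  the continuous fraction of expression from the inactive X is out of
  scope.
* Gene-to-TAD assignment is by TSS containment; genes spanning TAD
  boundaries are assigned to exactly one TAD.
* The permutation reference universe is the supplied annotation; no
  matching on expression level or gene length is attempted.
* Exclusion-region matching is by single-position containment in
  half-open intervals after 1- to 0-based conversion; no window or
  merge semantics are applied.
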