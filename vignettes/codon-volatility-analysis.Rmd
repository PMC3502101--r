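---
title: "Codon volatility, codon usage and what drives them: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon volatility, codon usage and what drives them: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question

Synonymous codons are not used uniformly. Three broad explanations compete
for why a genome's codon usage — and statistics derived from it, such as
codon volatility — vary between genes:

* **protein-level selection**, which should leave a footprint in dN/dS;
* **translational selection**, which predicts a correlation between codon
  usage and expression level; and
* **mutational bias**, a systematic asymmetry in mutation (here, toward or
  away from G/C at synonymous third positions) that shapes composition
  with no selection at all.

`codvol` implements all the machinery needed to put these against each
other in a single genome: per-gene volatility significance, RSCU/ENC/GC3
and correspondence analysis of usage, pairwise dN/dS (counting and
maximum likelihood), the association stage that quantifies each
comparison, and a synthetic-genome generator in which the competing
forces are explicit dials, so that every claim can be exercised at desk
scale with known ground truth.

# Codon volatility

The volatility of a sense codon is the probability that a random point
mutation produces a nonsynonymous change, given that stop codons are
disallowed both as inputs and as mutational neighbours. For AGA
(arginine), eight of the nine single-base variants are sense codons, two
of them synonymous (CGA, AGG), so the unweighted volatility is 6/8.
Mutational realism enters through the transition:transversion ratio
`kappa`: transitions receive weight `kappa`, transversions weight 1. The
package default for genome scans is `kappa = 4.1`, a value typical of
plant nuclear genomes; `kappa = 1` recovers plain counting.

A gene's score is the **sum** of its codon volatilities (the mean is also
reported). Significance is assessed against a *synonymous re-encoding
null*: each residue's codon is redrawn independently from that amino
acid's genome-wide synonymous frequencies. This null conditions on the
protein, so amino-acid composition cannot drive significance — only the
gene's *choice among synonyms* can. Two P-value methods ship:

* `exact_normal` — the per-site null mean and variance are exact and add
  across sites; the tail probability uses a normal approximation. Fast,
  adequate in the distribution body; its skewness error at 300 codons can
  reach ~0.02 in the tails.
* `monte_carlo` — `n_samples` re-encodings with the add-one estimator
  `(1 + #{samples >= observed}) / (1 + n_samples)`, which never returns 0
  and is the authoritative choice for extreme tails. Per-family
  multinomial sampling makes this cheap (one `rmultinom` call per amino
  acid, not per site).

P-values are oriented so that **small P means elevated volatility**; the
genome scan flags genes at `P < 1e-6` by default. (Descriptions of the
statistic elsewhere sometimes use the opposite orientation, with "P close
to 1" for elevated genes; the selection rule implemented here is the
small-P convention, and the threshold is configurable.) Whether the
original volatility servers scored the sum or the mean is not documented;
the sum is used because the gene score is defined as the sum, and the two
are monotonically related once the protein is fixed.

# Codon usage: RSCU, ENC, GC3, correspondence analysis

Only the 59 synonymously degenerate sense codons (all but ATG and TGG)
enter usage space. RSCU is `family_size * count / family_total`; families
absent from a gene are flagged missing, reported as `NA` per gene, and
enter correspondence analysis as 0 — the behaviour of a zero count in a
contingency view, chosen over imputing 1 so that absence is not mistaken
for unbiased usage.

ENC uses Wright's (1990) class-based estimator with family homozygosity
`F = (n * sum(p^2) - 1) / (n - 1)`, classes {2-fold x9, 3-fold x1 (Ile),
4-fold x5, 6-fold x3}, and `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, clipped
to [20, 61]. Families with fewer than two codons observed (or `F <= 0`)
are excluded from their class mean; a class with no estimable family is
imputed from the family-count-weighted mean of the estimable classes, and
this imputation is visible in the output metadata. Note that `F` carries
a finite-sample correction of order 1/n, so ENC of a gene concatenated
with itself differs from the original by ~1 unit at 1000 codons; the
estimator is only asymptotically concatenation-invariant.

Correspondence analysis decomposes the genes x 59 RSCU matrix in the
chi-square metric: SVD of `(P - rc')/sqrt(rc')`, inertia per axis equal
to squared singular values, total inertia equal to the table's chi-square
statistic over its grand total. Axes are reported in decreasing inertia
order; axes above a 5% inertia fraction are marked significant by
default. Because CA axis signs are mathematically arbitrary,
`usage_axes()` orients every axis so that the summed loadings of
GC-ending codons are non-negative — a presentation convention that makes
orientation reproducible across datasets. Genes shorter than 100 bp are
excluded from the usage stage (and logged), mirroring standard practice
for short-gene noise.

# Pairwise dN/dS

Ortholog pairs are aligned at the protein level (Smith–Waterman local by
default, for partial fragments; Needleman–Wunsch global optional) with
BLOSUM62 and gap open/extend 11/1, delegated to
`Biostrings::pairwiseAlignment`. The protein alignment guides a
whole-codon back-translation, so frame is never broken; coverage of the
reference CDS is reported as the percentage of its codons in ungapped
columns.

Two estimators are implemented:

* **NG86** (Nei–Gojobori 1986): site counts per codon with stop-creating
  changes excluded from numerator and denominator; multi-hit codon pairs
  averaged over all minimal mutational pathways, pathways through stops
  excluded (with a fallback to unrestricted averaging in the rare case
  that every pathway is blocked); Jukes–Cantor correction on the
  proportions, flagged `saturated` when a proportion reaches 3/4. The
  estimator is symmetric in sequence order and uses pairwise deletion of
  gapped columns. Note that a *single* synonymous difference in a very
  short alignment can exceed the correction limit (pS >= 3/4) — that is a
  property of the estimator, and such estimates are flagged rather than
  repaired.
* **M0** (one-ratio codon model): maximum likelihood over
  `(t, kappa, omega)` for the 61-state process with rates proportional to
  `pi_j * kappa^[transition] * omega^[nonsynonymous]`, zero for
  multi-nucleotide changes, rate matrix normalized to one expected
  substitution per codon per unit time. Equilibrium frequencies default
  to F3x4 (position-specific nucleotide frequencies), with F61 and
  uniform available. The likelihood is evaluated through the reversible
  symmetrization eigendecomposition; optimization is L-BFGS-B on log
  parameters from three omega starts (0.1, 0.5, 2.0) with an absolute
  log-likelihood tolerance near 1e-8, and non-convergence is flagged, not
  hidden. dN and dS are derived by the standard rate decomposition
  (expected synonymous/nonsynonymous flux over the fitted time divided by
  site fractions computed at omega = 1), under which dN/dS equals the
  fitted omega. On 5000-codon pairs simulated at
  `omega = 0.3, kappa = 4.1, t = 0.5`, the fit recovers omega within
  ±0.05 and kappa within ±0.5 (see `scripts/acceptance.R`).

# The synthetic genome generator

`generate_genome()` draws, per gene: a length (uniform in codons, default
100–400, minimum 34 so every gene passes the 100-bp filter), an
amino-acid sequence from a fixed average-proteome-like composition, a
log2 expression value (normal, default mean 6.44, SD 2.02 — an RMA-like
microarray distribution), and a **GC3 target** from a Beta distribution
with mean `gc3_bias` and SD `gc3_sd` (default 0.08). Per-gene targets —
rather than one genome-wide constant — emulate the between-gene variation
in mutational environment that real genomes show, and they are what makes
a genome-wide usage axis correlated with GC3 recoverable at all;
`gc3_sd = 0` produces an exchangeable null genome in which volatility
P-values are uniform.

Within a synonymous family, the GC-ending codons share probability `g`
(the gene's target) and the AT-ending codons `1 - g`, distributed within
each partition proportionally to a fixed plant-like baseline usage table.
The baseline matters: a partition-uniform convention would make ATA as
common as ATT, which no real genome shows, and (see below) it also
degenerates the volatility–GC3 coupling. The expected third-position G+C
fraction of a draw equals `g` exactly, so realized GC3 is monotone in
`gc3_bias` by construction.

Translational selection is a mixture: codon probability
`(p_gc3 + w * [codon is optimal]) / (1 + w)` with
`w = max(0, selection_strength * standardized expression)` and one fixed,
configurable optimal codon per amino acid. `selection_strength = 0`
removes the expression–usage coupling entirely, which is the regime used
to test that a *negative* expression result is detectable as a true
absence.

Ortholog pairs are produced by `evolve_pair()`: exact Gillespie
simulation of the same 61-state process used by the M0 fit, per codon
site, for `t` expected substitutions per codon, so the simulator and
estimator are twins with independently verifiable behaviour (site
pattern frequencies are checked against `exp(Qt)` computed by an
independent oracle in the tests). `truncate_to_fragment()` emulates
shotgun-read partial coverage with a contiguous seeded window.

What the generator does **not** emulate: introns/UTRs, indels, assembly
artifacts, context-dependent (dinucleotide) mutation, amino-acid
composition gradients correlated with GC3 (composition is independent of
the GC3 target by design, which is precisely why the protein-conditioned
null is exactly calibrated on it), and any realistic gene-family
structure. Passing tests on this generator therefore demonstrate
correctness of the statistics and the internal consistency of the
pipeline — not that real-genome conclusions transfer automatically.

# A finding worth recording: the kappa = 4.1 cancellation

Because the volatility P-value conditions on the protein, a GC3 signal
can reach it only through within-family synonymous choice. The
per-family volatility contrast between GC-ending and AT-ending codons is
positive for Arg (~+0.04) and Gly/Leu/Ser (~+0.01) but negative for Ile
(~-0.05, driven by the high volatility of ATA), and at `kappa = 4.1` the
amino-acid-weighted aggregate almost exactly cancels. On synthetic
mutational-bias genomes the volatility-P ~ GC3 rank correlation is
therefore weak at the scan default (`rho ~ +0.05..+0.11` at 600 genes,
hovering around the alpha = 0.01 boundary), while the *unweighted*
(`kappa = 1`) scan shows a clear coupling (`rho ~ -0.22`,
`p ~ 1e-7`) whose negative direction matches the volatility regression
reported for real plant data. The acceptance suite keeps the check at
the package defaults and reports both channels; the lesson is that a
strand-symmetric third-position GC bias alone transmits only a marginal
GC3 signal into transition-weighted, protein-conditioned volatility
P-values — observed couplings in real genomes must also involve usage
structure beyond that minimal mechanism.

# Numerical and design choices

* **Validation**: trailing stop codons are stripped silently; internal
  stops, frame violations and ambiguity codons are typed rejections,
  never silent repairs. Rejection counts are logged by the pipeline so
  attrition is auditable.
* **Null frequencies** are estimated from the gene set being scanned
  (self-referential, as a single-genome method requires); an external
  frequency table can be supplied.
* **Degenerate nulls** (all-Met/Trp proteins) give P = 1 under the
  `>=` convention, not an error.
* **Ties and determinism**: high-expression flagging breaks ties by gene
  id; every stochastic step takes a seed; a pipeline rerun with the same
  configuration is byte-identical, and the resolved configuration is
  written back next to the outputs.
* **Multiple testing**: none is applied across the headline comparisons;
  both Pearson (with the OLS line) and Spearman are reported, the latter
  because volatility P-values are heavy-tailed.
* **Problem sizes**: the test suite and acceptance script use 500-gene
  null calibrations (200 codons each, 2000 Monte-Carlo samples),
  600-gene association genomes, and 5000-codon M0 recovery alignments —
  sizes at which every statistical expectation tested has comfortable
  power while a full run stays in the tens of seconds.

# Limitations

* Only the standard nuclear genetic code ships (the code table is
  injectable for toy codes in tests).
* The M0 fit is pairwise; no site- or branch-model tests, and no
  across-gene sharing of parameters.
* Ortholog discovery, gene prediction and expression preprocessing are
  out of scope: inputs are coding sequences (and optional expression
  tables) that are already matched and validated.
* The exact conventions of historical codon-usage software (missing-data
  handling, CA input scaling) are not documented in the literature that
  motivated this package; the conventions used here are stated above and
  in the function documentation as conventions, not as claims about
  those programs.
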