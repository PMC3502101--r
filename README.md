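# codvol

**Codon volatility, codon usage bias and pairwise dN/dS — and the tools
to ask which force actually drives them.**

Codon volatility is a single-genome statistic: for a sense codon it is
the (optionally transition/transversion-weighted) proportion of its
non-stop single-point-mutation neighbours that encode a different amino
acid, and a gene's score is the sum over its codons,

    v(c) = sum over non-stop neighbours j of w_j * [aa(j) != aa(c)]
           / sum over non-stop neighbours j of w_j,
    w_j = kappa for transitions, 1 for transversions,

with significance assessed against a synonymous re-encoding null that
conditions on the protein. Originally proposed as a proxy for selective
pressure, volatility in practice tracks codon usage and base composition.
`codvol` implements everything needed to put the candidate explanations
against each other within one genome:

* **volatility**: per-codon and per-gene scores, exact-moment and
  Monte-Carlo P-values, genome scans flagging elevated genes
  (default `kappa = 4.1`, `P < 1e-6`);
* **codon usage**: RSCU, Wright's effective number of codons (ENC), GC3,
  and correspondence analysis of the 59-dimensional RSCU space with
  per-axis inertia;
* **pairwise selection**: protein-guided codon alignment, Nei–Gojobori
  (1986) counting dN/dS, and maximum-likelihood fits of the one-ratio
  (M0) codon substitution model giving `(t, kappa, omega)`;
* **association**: OLS plus Pearson/Spearman reports for volatility vs
  dN/dS, usage vs expression, and usage/volatility vs GC3, with overlay
  summaries of flagged gene sets on the usage axes;
* **synthetic data**: a generator of coding-sequence genomes with
  tunable GC3 mutational bias, tunable coupling of codon optimality to
  expression, RMA-like expression values, plus ortholog pairs diverged
  under the same codon process the M0 fit estimates.

It is aimed at molecular-evolution researchers who want a reproducible,
fully testable version of this analysis chain that runs at desk scale.

## Worked example

```r
library(codvol)

codon_volatility("AGA")                              # 0.75  (= 6/8)
codon_volatility("AGA", model = mutation_model(4.1)) # 0.7052023

# a 300-gene genome shaped by GC3 mutational bias only (no selection)
genome <- generate_genome(synthetic_genome_spec(
  n_genes = 300, gc3_bias = 0.7, selection_strength = 0, seed = 1))
cds <- validate_cds_set(genome$sequences)$cds

scan <- volatility_scan(cds)
scan
#> Codon volatility scan
#>   genes scored : 300
#>   kappa        : 4.1
#>   method       : exact_normal
#>   elevated (P < 1e-06) : 0

axes <- usage_axes(cds)
axes
#> Codon usage axes: 300 genes (0 excluded by length filter)
#>   Axis 1: 14.0% inertia, Axis 2: 5.5% inertia
#>   significant axes (> threshold): 1, 2

gmt <- gene_metric_table(scan, axes, expression = genome$expression)
association_report(gmt)
#> Association report (300 genes)
#>   axis1_vs_expression      r = -0.040 (P = 0.489), rho = -0.029 (P = 0.622), R^2 = 0.002, n = 300
#>   volatilityP_vs_gc3       r = +0.042 (P = 0.474), rho = +0.026 (P = 0.654), R^2 = 0.002, n = 300
#>   v_mean_vs_gc3            r = -0.021 (P = 0.717), rho = +0.017 (P = 0.763), R^2 = 0.000, n = 300
#>   axis1_vs_gc3             r = +0.971 (P = 2.86e-187), rho = +0.970 (P = 3.91e-186), R^2 = 0.943, n = 300
```

Reading the output: no gene reaches elevated volatility in a neutral
genome; the leading usage axis is essentially the GC3 gradient
(r = 0.97), while expression — which was generated independently of
codon choice — shows no usage correlation. That is exactly the
mutational-bias signature the association stage is built to detect.

Ortholog divergence and dN/dS recovery:

```r
anc  <- sample_cds(2000, seed = 2)
pair <- evolve_pair(anc, ortholog_sim_spec(omega = 0.3, kappa = 4.1,
                                           t = 0.5, seed = 3))
dnds_pair(pair$ancestor, pair$derived, method = "M0", mode = "global")
#> <dnds_estimate> [M0] random_cds / random_cds_derived
#>   dN = 0.1067, dS = 0.3171, dN/dS = 0.3365, kappa = 4.61, t = 0.515  [ok]
```

The fit recovers the simulated `omega = 0.3`, `kappa = 4.1`, `t = 0.5`
within sampling error at this alignment length.

The end-to-end pipeline (simulate → volatility → usage → dN/dS →
associate, one TSV per stage plus a run manifest and the resolved
configuration) is a single call:

```r
res <- run_pipeline(default_config(n_genes = 100), out_dir = "run1")
```

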