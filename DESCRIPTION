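Package: codvol
Title: Codon Volatility, Codon Usage Bias and Pairwise dN/dS Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-codon and per-gene codon volatility with
    significance against a synonymous re-encoding null, relative synonymous
    codon usage (RSCU), Wright's effective number of codons (ENC), GC3
    composition and correspondence analysis of codon usage; estimates
    pairwise dN/dS by the Nei-Gojobori (1986) counting method and by
    maximum likelihood under the one-ratio (M0) codon substitution model;
    and quantifies the associations between volatility, usage axes, gene
    expression, GC3 and dN/dS. A synthetic-genome generator simulates
    coding sequences under tunable GC3 mutational bias and translational
    selection, plus ortholog pairs diverged under the codon model, so the
    full pipeline runs at desk scale without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    MASS,
    ape,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
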