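# strlr

Semi-continuous likelihood ratios for forensic STR profiles.

`strlr` weighs complex forensic DNA evidence — low-template, partial, and
mixed short-tandem-repeat (STR) profiles — by computing the likelihood ratio

```
LR = P(E | H1) / P(E | H2)
```

where `E` is the set of alleles detected at each locus and `H1`, `H2` are
competing hypotheses about the contributors (e.g. "suspect plus one unknown"
versus "two unknowns", or "an unrelated unknown" versus "a sibling of the
suspect"). It is written for forensic scientists and statisticians who need
an auditable, scriptable engine rather than a GUI.

The model is semi-continuous: peak heights are not modelled directly. Per
locus, each allele carried in `c` copies by the hypothesized contributors
drops out with probability `alpha^(c-1) * P(D_O)^c`; at most one allele may
drop in, with probability `P(D_I) * p_d`; alleles detected from *assumed*
(undisputed) contributors mask matching peaks and are outside the drop-out
model. Unknown contributors are summed out by the law of total probability
with allelic-level Balding–Nichols coancestry conditioning,

```
P(a | m counts) = (m_a * theta + (1 - theta) * p_a) / (1 + (m - 1) * theta),
```

using a dynamic program over allele-count vectors whose correctness is
checked against exhaustive enumeration. Rare alleles in the evidence or
suspect profile are floored at `5/2n` (`n` = frequency-database size). Up to
four unknown contributors are supported (three alongside a named suspect),
and one unknown may be a relative specified by IBD probabilities
`(k0, k1, k2)`. A logistic-regression helper predicts `P(D_O)` from average
peak height using laboratory-supplied coefficients.

See `vignettes/semicontinuous-lr.Rmd` for the full model description and the
design decisions.

## Worked example

Everything below is synthetic and self-contained — no external frequency
data is required (the reader supports any long-format `Marker,Allele,
Frequency` CSV, such as one converted from a published population study).

```r
library(strlr)

# a 5-locus panel with 8 alleles per locus, database of 1036 individuals
tab      <- make_frequency_table(seed = 11, markers = 5, alleles_per_marker = 8,
                                 n_individuals = 1036, population = "synthA")
suspect  <- sample_reference_profile(tab, "POI", seed = 12)
bystander <- sample_reference_profile(tab, "WIT", seed = 13)

# two-person mixture with 25% drop-out and 1% drop-in
evidence <- simulate_evidence(list(suspect, bystander), p_do = 0.25,
                              p_di = 0.01, tab, seed = 14)

# H1: suspect + 1 unknown;  H2: 2 unknowns
hyp    <- hypothesis_pair(hypothesis(TRUE, 1L), hypothesis(FALSE, 2L))
params <- lr_params(p_dropout = 0.25)   # P(D_I)=0.01, theta=0.01, alpha=0.5

validate_case(evidence, suspect, hyp, tab)
res <- compute_case(evidence, suspect, hyp, params, tab)
res[[1]]
```

```
Case validation: OK
Likelihood ratios, population 'synthA'
  M01          5.33595
  M02          9.7639
  M03          1.75991
  M04          1.48475
  M05          2.08279
  Overall      283.547
```

The per-locus LRs say how strongly each marker favours the suspect's
presence over an extra unknown contributor; their product, the overall LR of
about 284 (log10 ≈ 2.45), is moderate support — as expected for only five
loci under heavy drop-out. A full 13-locus panel separates true contributors
from non-contributors by many orders of magnitude (the test suite asserts
this on simulated mixtures).

The same computation is available from a shell via the bundled CLI:

```sh
strlr --evidence evidence.csv --evidence-sample ITEM1 \
      --suspect refs.csv --suspect-sample POI \
      --freqs caucasian.csv:Caucasian:361 \
      --pdo 0.25 --num-unknowns-numerator 1 --num-unknowns-denominator 2 \
      --out results.csv
```

`--pdo 0.1,0.3,0.5` sweeps several drop-out values in one run; `--assumed
FILE:NAME` conditions on undisputed contributors; `--relative-ibd
0.25,0.5,0.25` makes one denominator unknown a sibling; `--dropout-model
model.json` derives `P(D_O)` from the average peak height. The results file
is a spreadsheet-friendly CSV echoing every parameter.

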