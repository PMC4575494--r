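---
title: "The semi-continuous likelihood model behind strlr"
author: "strlr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The semi-continuous likelihood model behind strlr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strlr)
```

## The problem

Forensic DNA profiles from low-template or degraded samples are frequently
incomplete (allelic drop-out), contaminated at a low level (drop-in), and
mixed (several contributors). The weight of such evidence is naturally
expressed as a likelihood ratio

$$
LR \;=\; \frac{P(E \mid H_1)}{P(E \mid H_2)},
$$

where $E$ is the set of alleles detected at each STR locus and $H_1$, $H_2$
are competing accounts of who contributed — typically "the suspected
contributor plus $k$ unknowns" against "$k+1$ unknowns", possibly with one
unknown replaced by a relative of the suspect. `strlr` computes this LR under
a *semi-continuous* model: peak heights are not modelled directly; the data
per locus are summarized by which alleles are present, and height
information enters only through the user's estimate of the drop-out
probability.

## The evidence model at one locus

Given the multiset of alleles carried by the hypothesized contributors at a
locus (each contributor contributes two copies), the probability of the
observed evidence set is a product of independent per-allele factors, closed
by a drop-in term:

* an allele carried in $c$ copies drops out entirely with probability
  $\alpha^{c-1} P(D_O)^c$, and is detected with one minus that. With
  $\alpha = 1$ copies would drop independently; the default $\alpha = 0.5$
  encodes the empirical observation that complete drop-out of a homozygote
  (and, generally, of a multiply-carried allele) is rarer than independence
  predicts;
* an allele detected in the evidence that is carried by an *assumed*
  (undisputed) contributor is treated as certainly present — factor 1 — even
  if suspects or unknowns also carry it. Assumed contributors are outside
  the drop-out model altogether: their alleles either mask matching evidence
  peaks or, if not detected, are simply excluded from the masking set (an
  undetected peak cannot hide anything). That exclusion is reported as a
  validation warning, not an error;
* evidence alleles carried by no contributor and not masked are *unexplained*.
  At most one drop-in per locus is modelled: zero unexplained alleles cost
  $(1 - P(D_I))$, one unexplained allele $d$ costs $P(D_I)\,p_d$ with $p_d$
  its (floored, non-$\theta$-adjusted) population frequency, and two or more
  unexplained alleles make the configuration impossible. This literal
  "exactly one allele may drop in" reading keeps the drop-in term a nuisance
  correction rather than a contamination model; drop-in alleles do not enter
  the coancestry conditioning, since they represent laboratory contamination
  rather than a sampled population allele.

An evidence row with no detected alleles is analyzed as complete locus
drop-out — all contributor alleles take drop-out factors and the locus
contributes $(1-P(D_I))$ — rather than being skipped; discarding it would
throw away information.

## Population model

**Minimum frequency.** Any allele appearing in the evidence or in the
suspected contributor's profile with database frequency below $5/2n$ (with
$n$ the number of individuals in the frequency database) is raised to
$5/2n$; alleles absent from the database are inserted at that value. No
renormalization follows, so a floored locus may sum to slightly more than 1
— this matches common forensic practice and avoids perturbing the unflagged
frequencies. Property tests that rely on exact normalization therefore use
un-floored tables.

**Coancestry.** The $\theta$ (also written $F_{ST}$) correction for distant
relatedness between the suspected and the true contributor is applied at the
allelic level. Each allele draw for an unknown contributor is conditioned,
through the Balding–Nichols sampling formula, on the alleles already
"sampled":

$$
P(a \mid \text{counts } m) \;=\;
\frac{m_a\,\theta + (1-\theta)\,p_a}{1 + (m - 1)\,\theta},
$$

where $m_a$ is the number of copies of $a$ among the $m$ conditioning
copies. The conditioning set contains the suspect's genotype — on **both**
sides of the LR, since population-level relatedness between the suspect and
the true contributor is precisely what the correction models — plus all
assumed contributors' genotypes, plus any unknown alleles drawn earlier
within the same term. Detected evidence alleles do *not* enter the
conditioning counts: the minimum-frequency floor replaces the older
pseudo-count scheme that added them to the database.

One caveat worth stating: the conditional match probability *rises* with
$\theta$ (hence the single-source LR falls) only for the moderately rare
alleles typical of STR loci. For allele frequencies approaching 0.5 the
Balding–Nichols heterozygote match probability can decrease in $\theta$.
The monotonicity property test therefore draws frequencies capped at 0.3;
nothing in the engine itself depends on monotonicity.

**Relatives.** A denominator (or numerator) unknown may be a relative of the
suspect, specified by the probabilities $(k_0,k_1,k_2)$ of sharing 0, 1 or 2
alleles identical by descent. The relative's genotype probability is the
IBD mixture: $k_2$ on the suspect's genotype, $k_1$ on sharing one allele
(chosen uniformly between a heterozygous suspect's two alleles, by Mendelian
symmetry) with the other allele drawn $\theta$-conditionally, and $k_0$ on
an ordinary unrelated draw. The non-IBD draws use the same conditional
sampling as unrelated unknowns, keeping the coancestry model consistent
across kinship states. $(1,0,0)$ reproduces an unrelated unknown exactly and
$(0,0,1)$ an identical twin (forcing LR = 1 under otherwise symmetric
hypotheses); both limits are asserted in the test suite.

## Summing over unknown contributors

The denominator (and any side with unknowns) is a law-of-total-probability
sum over all genotype assignments to the unknown contributors. Enumerating
genotype tuples directly costs $\left(A(A+1)/2\right)^U$ terms for $A$
alleles and $U$ unknowns. `strlr` instead exploits two structural facts:

1. the evidence probability depends on the unknowns only through their
   allele-*count* vector;
2. sequential Balding–Nichols sampling is exchangeable — the probability of
   an ordered sequence of $2U$ allele draws depends only on its counts,
   because draw $t$'s denominator $1 + (T_0 + t - 2)\theta$ depends only on
   the position ($T_0$ being the initial conditioning total) and the
   numerators factor per allele.

So the sum collapses to a convolution over the allele universe with state
(copies assigned so far, number of unexplained evidence alleles so far),
weighting a count vector $c$ by $\binom{2U}{c}$ ordered sequences times the
per-sequence probability times the evidence factor. The drop-in frequency
is folded in at the moment an evidence allele receives zero copies; a second
such allele terminates the path. This runs in $O(A \cdot U^2)$ per locus
rather than exponential time.

Correctness of the dynamic program is owed to `brute_force_sum()`, the
definitional nested enumeration over ordered genotype tuples with sequential
conditioning, kept in the package as an independent oracle. The two routes
are compared on hundreds of randomized cases (2–8 alleles, 0–3 unknowns,
grids over $\theta$, $P(D_O)$, $P(D_I)$, with and without masking and
kinship) at relative tolerance $10^{-9}$ in `tests/testthat/` and in
`scripts/acceptance.R`. A relative contributor is enumerated explicitly
around the DP (their genotype space is small, and at most one relative is
supported), with their alleles added to the conditioning of the remaining
unknowns — a typed-individual treatment, chosen for consistency with how
assumed contributors condition the draws.

**Degenerate cases.** A zero denominator is reported rather than thrown:
$0/0$ yields LR 1 with a warning flag (no information either way), and a
positive numerator over a zero denominator yields `Inf` with a warning —
useful diagnostics when, say, $P(D_I)=0$ makes an unexplained allele
impossible. The per-locus LR of a single-suspect hypothesis can never exceed
the inverse conditional match probability $1/P(G_s \mid G_s, \theta)$,
because the denominator sum always contains the term $j = G_s$; the suite
asserts this bound across randomized sweeps.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| $P(D_O)$ | per-allele drop-out probability | none (required) | estimate empirically, e.g. via the logistic model below |
| $P(D_I)$ | probability exactly one allele drops in at a locus | 0.01 | deliberately generous; larger values signal a laboratory problem |
| $\theta$ | coancestry coefficient | 0.01 | the value most US laboratories use |
| $\alpha$ | multi-copy drop-out correction | 0.5 | $\alpha = 1$ recovers independent copies |
| $(k_0,k_1,k_2)$ | IBD sharing probabilities of the hypothesized relative | — | siblings $(\tfrac14,\tfrac12,\tfrac14)$, parent–child $(0,1,0)$ |

The same $P(D_O)$ applies to every locus and every non-assumed contributor;
locus- or contributor-specific drop-out is out of scope. `lr_cli()` accepts
a comma list for `--pdo` and emits one results block per value, replacing
the manual workflow of re-running with different drop-out rates.

## Estimating drop-out from peak heights

`predict_dropout()` applies a user-supplied logistic regression
$\mathrm{logit}\,P(D_O) = \beta_0 + \beta_1 T(\bar h)$ to the average height
$\bar h$ of the detected peaks, with $T$ either the identity or $\log_{10}$
— the transform must be stated explicitly, because published calibrations
differ and silently guessing would corrupt the estimate. Coefficients are
configuration, never hard-coded: laboratories should fit them on their own
validation data for their own kit and instrument. Predictions are clipped to
$[10^{-6}, 1-10^{-6}]$ so a degenerate 0/1 never enters the engine. The
coefficients used in the test suite are synthetic fixtures.

## The synthetic data generator

`make_frequency_table()`, `sample_reference_profile()` and
`simulate_evidence()` make every test self-contained. Defaults emulate a
standard autosomal panel — 13 markers, 8 alleles per marker labelled by
repeat count from 8, a database of $n = 1036$ individuals — with per-locus
frequencies drawn as normalized Gamma(1.5) variates, giving the uneven
allele spectra real STR loci show. All randomness is confined behind an
explicit seed (`withr::with_seed`), leaving the caller's RNG untouched.

The simulator drops each allele *copy* independently (so per-allele survival
matches the engine's factors exactly when $\alpha = 1$) and, with
probability $P(D_I)$, adds one allele drawn by population frequency. Two
honest mismatches with the likelihood are worth knowing:

* the engine's $\alpha = 0.5$ correction has no generative counterpart —
  it is a likelihood-side adjustment — so simulator-vs-engine agreement is
  tested at $\alpha = 1$, and $\alpha \ne 1$ behaviour is checked through
  closed-form factor identities instead;
* the simulator's drop-in can land on an allele a contributor already
  carries and collapse into the detected set, while the engine's drop-in
  factor prices only *unexplained* alleles (the engine's outcome
  distribution is deliberately sub-normalized, as is standard for this
  drop-in approximation). At the study conditions used ($P(D_I) = 0.01$,
  $10^5$ replicates) the resulting bias is an order of magnitude below the
  Monte-Carlo 4-standard-error band the agreement test uses.

The generator emulates genotype sampling, drop-out and drop-in only; it does
not model stutter, degradation curves, peak-height variance or population
substructure. Passing the simulation-based tests therefore says the engine
is internally coherent and well-calibrated against its own model — not that
the model captures every artefact of real electropherograms.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` use desk-scale cases chosen to
exercise every code path while staying quick to re-run: 200 randomized
DP-vs-enumeration cases (capped near $5 \times 10^4$ enumerated
combinations each), 500 parameter draws for the match-probability bound,
$10^5$ simulation replicates for generative agreement, and a 13-locus
two-person mixture at $P(D_O) = 0.3$ with 100 known non-contributors for the
separation check. The acceptance script recomputes all of these from
scratch under a caller-supplied seed.

## Known limitations

No peak-height likelihood (heights inform only the drop-out estimate); no
stutter model; at most one drop-in per locus; a single $P(D_O)$ across loci
and contributors; at most one relative per hypothesis side; no replicate
amplifications; autosomal markers only, with at most two alleles per
genotype. Whether the drop-in allele should be weighted by raw or
$\theta$-adjusted frequency, and whether denominator unknowns should
condition on assumed donors' genotypes, are genuinely open modelling
choices; `strlr` uses the raw floored frequency and does condition on
assumed donors (they are typed individuals), and both choices are localized
in the code should a laboratory prefer otherwise.
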