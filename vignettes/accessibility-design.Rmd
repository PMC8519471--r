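---
title: "Accessibility-guided design of translation initiation regions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accessibility-guided design of translation initiation regions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tirdesign)
```

## The problem

Recombinant protein yield in expression hosts such as *E. coli* is to a
large extent decided before elongation ever starts: the ribosome must find
and open the mRNA around the start codon. A translation initiation region
that is sequestered in secondary structure initiates poorly regardless of
how well its codons match the host's tRNA pool. `tirdesign` quantifies
this with the **opening energy** of a start-codon-anchored region and
redesigns the first few codons — synonymously, so the protein is untouched
— to make that region more single-stranded.

## Opening energy

For a region $i..j$ of a transcript, the opening energy is the
pseudo-energy required to force every base of the region to be unpaired,
averaged over the whole Boltzmann ensemble of secondary structures:

$$\mathrm{OE}(i..j) \;=\; -RT \,\ln \frac{Z_{\text{unpaired}}}{Z},$$

where $Z$ is the total partition function, $Z_{\text{unpaired}}$ the
partition function restricted to structures in which $i..j$ is entirely
single-stranded, and $RT = 0.6163$ kcal/mol at 37 °C. The ratio is the
probability that the region is simultaneously unpaired, so the opening
energy is zero exactly when nothing ever pairs the region and grows as
structure locks it up. Unlike the minimum free energy (MFE) of a single
best structure, it accounts for every suboptimal structure, including
pairings that reach in from outside the region.

Coordinates are start-codon-anchored: +1 is the first nucleotide of the
start codon, −1 the nucleotide immediately upstream, and there is no
position 0. A region may equivalently be addressed by its end position
$i$ and length $l$; `endpos_len_to_region(24, 48)` is the region −24:24,
the default scoring region for *E. coli* (other host presets: −7:89 for
*S. cerevisiae*, −8:11 for *M. musculus*, −24:89 otherwise).

### Engines

Two interchangeable engines compute $Z_{\text{unpaired}}/Z$:

* **production** — a subprocess adapter around ViennaRNA's `RNAplfold`
  (sliding windows `-W 210 -u 210` by default; the window covers the
  region plus generous flanks), `RNAfold` for MFE and `RNAup` for
  RNA–RNA interaction energies. Used for real design work.
* **toy** — a self-contained nested-structure partition function with a
  uniform per-pair energy (−1 kcal/mol by default, deliberately
  non-physical), Watson–Crick + GU pairing and a minimum hairpin loop of
  3 nt, computed exactly over the full sequence by dynamic programming in
  C++. Its whole purpose is verifiability: `toy_partition_oracle()`
  enumerates *every* structure of sequences up to 30 nt and sums
  Boltzmann weights directly, so the engine's bookkeeping
  ($Z_{\text{unpaired}} \le Z$, the $-RT\ln p$ conversion, interval
  blocking) is checked to machine precision in the test suite. The two
  engines differ in values but obey the same contract: non-negative
  opening energies, monotone growth under region extension, identical
  grid geometry.

Regions that would extend past the available flanking sequence are
reported as undefined, never silently truncated.

## Synonymous annealing

Finding the most accessible synonymous variant is combinatorial: nine
codons with three synonyms each already give $3^9 - 1 = 19{,}682$
variants. `anneal()` runs simulated annealing over the synonymous space
of the first $N$ codons (default 9 — a window short enough to re-encode
with a single PCR primer; the start and stop codons are never touched):

* exponential cooling $T_k = T_0\,\alpha^k$ with defaults $T_0 = 1$,
  $\alpha = 0.99$; the published description fixes only the shape
  (exponential), not the constants, so these are package defaults;
* move size coupled to temperature,
  $m = \max(1, \mathrm{round}(T/T_0 \cdot n_{\text{replaceable}}))$: the
  first move rewrites every replaceable codon, late moves are single-codon
  refinements;
* Metropolis acceptance: improving moves always, worsening moves with
  probability $\exp(-|\Delta E|/T)$. (Taken literally, the published
  criterion "accept when $R(0,1) \ge p_2/p_1$" with $p \propto e^{E/T}$
  would reject every worsening move; we read it as the standard rule.)
* candidates containing a forbidden motif — AarI, BsaI, BsmBI recognition
  sites by default, on either strand — are rejected at proposal time so
  the chain never leaves the constrained space;
* termination on `patience` iterations without improvement (default 200)
  or `max_iterations`; several independent chains run per call and the
  best-so-far sequence of each is kept, deduplicated and ranked.

`exhaustive_optimum()` enumerates the full space (guarded at 50,000
variants) and is used by the tests to confirm that annealing reaches the
global optimum on small instances in ≥95% of seeded runs.

## Competing sequence features

For feature comparisons the package computes CAI, tAI and codon context
(geometric means of per-codon or per-codon-pair weights, excluding start
and trailing stop codons), global and regional G+C, and an ncRNA
avoidance score. The avoidance of a construct is the hybridization energy
$\Delta G_h$ of the *most stable* interaction between mRNA region 1:30
and any ncRNA of a user-supplied set; the unfolding component
$\Delta G_u$ of the interaction decomposition
$\Delta G_{int} = \Delta G_u + \Delta G_h$ is computed but deliberately
excluded, to avoid double-weighting accessibility. CAI weights are the
classical Sharp & Li *E. coli* relative adaptiveness values (via
`seqinr`); because the reference tAI and codon-pair tables are not
redistributable here, `synthetic_tai_table()` and `synthetic_cc_table()`
provide clearly-labelled deterministic stand-ins and real tables can be
supplied as plain two-column data frames.

## The Expression Score

Given a labeled panel (opening energy, expressed-or-not), the package
builds a probabilistic score:

1. **PLR curve.** At each threshold $t$, records with OE $\le t$ are
   called positive; the positive likelihood ratio is
   $\mathrm{PLR}(t) = \frac{TP/(TP+FN)}{FP/(FP+TN)}$ from the cumulative
   counts. Percentile bootstrap CIs (10,000 resamples by default) are
   available per threshold; resamples missing a class are redrawn and
   eventually dropped with a warning.
2. **4PL fit.** Because raw PLRs are unstable where few records fall
   below the threshold, a four-parameter logistic
   $y = d + (a-d)/(1 + (x/c)^b)$ is fitted to $(t, \mathrm{PLR}(t))$ by
   multi-start Levenberg–Marquardt (`minpack.lm`), infinite PLRs
   excluded, constant curves flagged degenerate.
3. **Bayes.** With prior success probability $\pi$ (default 0.49, the
   Expressed/Cloned fraction 21,046/42,774 of a large structural-genomics
   campaign), the score of an opening energy $x$ is
   $100 \cdot \frac{\mathrm{odds}}{1+\mathrm{odds}}$ with
   $\mathrm{odds} = \frac{\pi}{1-\pi}\,\widehat{\mathrm{PLR}}(x)$.

One semantic point deserves emphasis: since the PLR is built from
*cumulative* ("less than type") counts, prior odds × PLR$(t)$ is by Bayes'
theorem the posterior $P(\text{success} \mid \mathrm{OE} \le t)$ — the
success probability of the *population of sequences at least this
accessible*, not of a sequence with exactly that opening energy. The two
quantities coincide for no non-constant label model (differentiating
$E[p(X)\mid X\le t] = p(t)$ forces $p$ constant), so the package's
recovery tests compare the fitted score against the generator-implied
cumulative success probability $E[p_{\text{gen}}(X) \mid X \le t]$, which
it reproduces within ~1–2 percentage points at $n = 5{,}000$. Consistency
also requires the prior to be the empirical success rate of the panel the
curve was fitted on — which is exactly what 0.49 is for the published
panel.

`roc_auc()` (midrank Mann–Whitney), `ks_distance()` (sup-norm ECDF
distance) and `labeled_fixture()` (uniform energies on 2–30 kcal/mol,
Bernoulli labels from a decreasing logistic with midpoint 12 kcal/mol and
slope 0.25 per kcal/mol) complete the module. The fixture emulates the
*shape* of real success/failure panels — a smooth monotone link between
accessibility and success — but none of their confounders (protein
family, solubility, toxicity, batch structure), so passing recovery tests
demonstrate correctness of the statistical machinery, not real-data
performance.

## The production simulator

`run_simulation()` implements a deliberately small stochastic model of a
reporter-expression experiment. A panel of constructs spans opening
energies binned on $[2, 32)$ kcal/mol in steps of 2 (bin centres 3, 5,
…, 31); each of 3 replicate runs realizes a construct's energy as bin
centre + Gaussian jitter (sd 1 kcal/mol, truncated positive). Per
iteration and per cell:

* transcription: plasmid copy number uniform on [30, 60], each plasmid
  transcribed with probability 0.5;
* translation: every mRNA initiates with probability
  $1/(1+e^{(\mathrm{OE}-12)/2})$ — 0.5 at the favourable cutoff of 12
  kcal/mol, near 1 for highly accessible constructs, decaying above;
* turnover: an mRNA translated more than 10 times decays with
  probability 0.5 per iteration — this is what creates the *diminishing
  returns* plateau, because once initiation is fast the yield per mRNA
  saturates at ~12 proteins regardless of how low the opening energy is;
* demography: a cell whose protein tally exceeds $10^6$ copies is
  burdened: it stops reproducing and suffers an extra death hazard.

Runs start from 100 cells and stop at 10,000 iterations or extinction.
Populations are represented per-cell up to a tracked cap (100 cells) and
beyond it as subsampled cells times a scale factor, which bounds memory
without changing per-cell dynamics. Daughter cells start with empty mRNA
and protein pools (the mother keeps its content); division semantics are
otherwise unspecified in the source material.

The per-iteration demographic rates (reproduction $2.5\times10^{-4}$,
burdened extra death $2\times10^{-4}$, baseline death $1\times10^{-4}$)
are the one place where this package departs from naive per-iteration
probabilities of order one: with 100 starting cells and a 10,000-iteration
horizon, order-one net growth would overflow any representation within a
few hundred iterations. The rates were chosen once so that (i) viability
beats death and the population grows steadily (~4–5× over a run, matching
the published growth-curve insets' order of magnitude), and (ii) a cell
producing at the saturated rate (~270 proteins/iteration) reaches the
$10^6$ burden threshold within a typical lifetime — otherwise the
toxicity rule could never fire and no protein cost could emerge.

With the default configuration the simulator reproduces the two published
qualitative signatures: per-cell protein yield falls with opening energy
(replicate-averaged Spearman ≈ −0.95 here versus −0.75 reported; our
smooth logistic initiation gate orders the high-energy bins more cleanly
than the published near-step description "optimum of 12 kcal/mol or less,
occasionally allowing production above" would), and high-yield constructs
grow to smaller endpoint populations (protein cost, Spearman ≈ −0.9).

## Numerical and design choices

* **Alphabet** — DNA internally (U mapped to T on input), standard
  genetic code only.
* **Coordinate bridge** — anchored regions map to 0-based half-open
  offsets; all bounds violations are errors stating the missing flank.
* **RT** — $0.0019872 \cdot (273.15 + T_C)$ kcal/mol; 0.6163 at 37 °C.
* **4PL initialization** — starts at $a = \max y$, $d = \min y$, $c$ at
  the x-quartiles, $b \in \{0.5, 1, 2, 4, 8\}$; best converged RSS wins;
  noiseless recovery is exact to $10^{-4}$ relative.
* **Ties** — AUC uses midranks; annealing breaks equal-energy solution
  ranks lexicographically for determinism.
* **Determinism** — every stochastic entry point takes a seed and
  restores the caller's RNG state; fixed seeds give byte-identical
  results (tested).
* **Problem sizes in the test-suite** — enumeration oracles run on ≤22 nt
  sequences, annealing-vs-exhaustive on ≤4 substitutable codons, recovery
  studies at $n = 5{,}000$ × 50 seeds, and the simulator at its full
  default configuration; these sizes are the package's own choice of
  desk-scale reproduction.

## Limitations

* The toy energy model is not physical; production work must use the
  ViennaRNA engine, and absolute opening energies depend on the ViennaRNA
  version's parameter set.
* The Expression Score is a cumulative posterior (see above) and is only
  calibrated for panels resembling the one it was fitted on.
* The simulator is a caricature: no nutrient limitation, no plasmid loss,
  no elongation model, no exact-time kinetics — it exists to show that
  accessibility-gated initiation plus translation-triggered decay plus a
  protein-burden hazard suffice to generate the observed yield plateau
  and growth cost.
* The shipped tAI/codon-context tables are synthetic illustrations, and
  the packaged ncRNA set is a 5-sequence synthetic fixture; supply real
  tables and the host's ncRNA complement for real analyses.
* Terminator scanning of designed sequences (an external covariance-model
  search in the original workflow) is exposed only as a hook on the
  command line, not implemented.
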