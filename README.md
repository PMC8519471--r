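# tirdesign

Accessibility-guided scoring and redesign of mRNA translation initiation
regions.

Whether a recombinant gene expresses well in a host such as *E. coli* is
strongly predicted by how *accessible* — single-stranded — its mRNA is
around the start codon. `tirdesign` quantifies this with the **opening
energy** of a start-codon-anchored region,

    OE(i..j) = -RT * ln( Z_unpaired / Z ),

the ensemble pseudo-energy needed to unpair the region (RT = 0.6163
kcal/mol at 37 °C; `Z_unpaired/Z` is the Boltzmann probability that the
region is unpaired, computed with ViennaRNA over sliding windows, or with
a built-in exactly-verifiable toy partition function). Low opening energy
means high accessibility and a high chance of expression.

On top of that single quantity the package provides, for bench scientists
and sequence-design pipelines:

* **Synonymous optimization** (`anneal()`, `optimize_constructs()`):
  simulated annealing over synonymous variants of the first N codons
  (default 9 — re-encodable with one PCR primer), Metropolis acceptance,
  exponential cooling, temperature-coupled move sizes, restriction-site
  avoidance (AarI/BsaI/BsmBI by default, both strands), multiple chains,
  and an exhaustive oracle for small search spaces.
* **Expression Score** (`fit_score_model()`, `expression_score()`):
  threshold-wise positive likelihood ratios from a labeled
  success/failure panel, bootstrap confidence intervals, a four-parameter
  logistic fit, and Bayesian posterior scoring on a 0–100 scale with
  prior 0.49 (the Expressed/Cloned fraction 21,046/42,774 of a large
  structural-genomics campaign).
* **Competing codon features** (`feature_table()`): CAI (Sharp & Li
  weights), tAI, codon context, G+C, regional G+C, and ncRNA-avoidance
  hybridization energy (strongest mRNA:ncRNA ΔG_h over a set, via RNAup).
* **A stochastic production simulator** (`run_simulation()`):
  plasmid-templated transcription, accessibility-gated initiation,
  translation-count-triggered mRNA decay, protein-burden cell death and
  population growth — reproducing the diminishing-returns yield plateau
  and the protein cost of over-expression.
* **(i, l) accessibility scans** (`scan_profile()`, `scan_constructs()`)
  over end-position × length grids, with Spearman/Bonferroni correlation
  reports against measured abundances.

Everything takes and returns tibbles, fitted objects have
`tidy()`/`glance()` methods, result types have `autoplot()` methods, and
every stochastic entry point is seeded. A thin command-line wrapper lives
at `inst/cli/tirdesign` (`optimize`, `scan`, `features`, `score`,
`fitscore`, `simulate`).

## Worked example

Redesign the first nine codons of a gene for accessibility in *E. coli*
(scoring region −24:24), then score the input and the best variant:

```r
library(tirdesign)

gene <- random_construct(60, utr5_len = 24, seed = 42, id = "demo_gene")
cfg <- anneal_config(
  n_codons = 9, chains = 4, max_iterations = 150, patience = 60,
  seed = 1, fold = fold_config("production")
)
res <- anneal(gene, cfg)
res
#> <anneal_result: input 9.997 kcal/mol -> best 6.708 kcal/mol, 3 solution(s)>
#> # A tibble: 3 × 6
#>    rank cds                  opening_energy n_substitutions codons_changed chain
#>   <int> <chr>                         <dbl>           <int>          <int> <int>
#> 1     1 ATGATGTCATTCTACCACG…           6.71               4              3     1
#> 2     2 ATGATGTCCTTCTATCACG…           7.14               7              6     3
#> 3     3 ATGATGTCCTTCTACCACG…           7.21               5              5     2

panel <- labeled_fixture(5000, seed = 7)          # synthetic labeled panel
model <- fit_score_model(panel, prior = mean(panel$outcome))
score_energies(
  c(res$input$opening_energy, res$solutions$opening_energy[1]), model
)
#> # A tibble: 2 × 4
#>   id       opening_energy score score_rounded
#>   <chr>             <dbl> <dbl>         <int>
#> 1 input001          10.00  80.3            80
#> 2 input002           6.71  87.5            88
```

Four nucleotide substitutions in codons 2–10 drop the opening energy of
the −24:24 region from 10.0 to 6.7 kcal/mol; under the fitted score model
(trained here on a synthetic panel) the Expression Score — the posterior
probability, in percent, that a sequence at least this accessible
expresses successfully — rises from 80 to 88. With a model fitted on real
panel data the same two calls score real constructs.

The simulator shows why returns diminish below ~12 kcal/mol:

```r
sim <- run_simulation(sim_config(), seed = 1)
summarize_simulation(sim)
#> # A tibble: 1 × 4
#>   spearman_energy_yield_replicates spearman_energy_yield_averaged
#>                              <dbl>                          <dbl>
#> 1                           -0.916                         -0.957
#>   spearman_yield_cells_averaged n_extinct
#>                           <dbl>     <int>
#> 1                        -0.982         0
autoplot(sim)
```

Protein yield per cell anti-correlates with opening energy, and the
best-producing constructs grow to the smallest endpoint populations — the
protein cost of over-expression.

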