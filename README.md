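# eggspot

Comparative expression evolution of cichlid anal-fin pigmentation
ornaments (egg-spots and blotches).

Haplochromine cichlids carry striking anal-fin ornaments whose form
differs between lineages: discrete egg-spots in most, diffuse blotches
in others. This package implements the computational core of a
comparative study of how those ornaments evolve, from two directions at
once:

- **Expression**: comparative-CT (ΔΔCT) qPCR quantification of candidate
  pigmentation genes between ornamented and plain fin tissue, a
  normality/variance-gated statistical test cascade, and discrete
  per-gene expression calls (0 = under, 1 = no difference, 2 = over).
  The resulting gene × species call matrix is clustered by mean
  character difference, neighbor joining and character bootstrap, asking
  whether species that share an ornament type share an expression
  profile.
- **Sequence**: ortholog recovery from BLAST hit tables (strict
  identity/length/bit-score filters, all-species presence, plurality
  consensus, reading-frame validation) and pairwise dN/dS by
  Nei–Gojobori (1986) counting with Jukes–Cantor correction, asking
  whether differentially expressed genes evolve at elevated rates
  relative to a background set.

Every stage has a seeded synthetic-data generator with known ground
truth, so the whole pipeline is testable end to end without external
data. See the methods vignette (`vignettes/eggspot-methods.Rmd`) for
the full model description and design decisions.

## Worked example

Simulate a pair of 500-codon sequences diverged under purifying
selection (true dN/dS = 0.3) and estimate the rate:

```r
library(eggspot)

sim <- simulate_codon_pair(500, omega = 0.3, subs_per_site = 0.2, seed = 42)
pairwise_dnds(sim$sequences[[1]], sim$sequences[[2]])
#> Nei-Gojobori pairwise rate (500 codons compared, 0 skipped)
#>   S = 384.589  N = 1115.411  Sd = 70.250  Nd = 68.750
#>   dS = 0.20934  dN = 0.064317  dN/dS = 0.30724
```

Quantify a gene with a true 4-fold expression difference between
ornamented and plain tissue in six individuals, route it through the
test cascade and call it:

```r
ct <- simulate_ct_table(n_genes = 1, n_individuals = 6, log2fc = 2,
                        sigma_ct = 0.3, seed = 7)
rq  <- relative_quantification(ct)
rq$rq                                     # relative quantification
#> [1] 3.820908
dec <- choose_test(rq$dct_focal, rq$dct_reference)
dec$test_used
#> [1] "paired_t"
str(call_expression(rq$rq, dec$p_value))  # state 2 = over-expression
#> List of 4
#>  $ state    : int 2
#>  $ trend    : logi FALSE
#>  $ p_value  : num 0.000174
#>  $ direction: int 1
```

Run the whole comparative design on synthetic ground truth — two
species share an expression profile, differentially expressed gene sets
evolve at elevated dN/dS — and check that the design recovers it:

```r
recapitulate(seed = 1)
#> Synthetic recapitulation (seed 1)
#>   - Shared-profile species pair (eggspot_A, eggspot_B) forms a clade
#>     in the NJ tree with 100% bootstrap support.
#>   - Differentially expressed gene sets simulated at elevated dN/dS:
#>     over vs background p = 2.96e-10, under vs background p = 6.86e-12.
```

## Analysis workflow

The `analysis/` directory contains numbered drivers that run the full
workflow stage by stage, writing artifacts under `results/`:

| script | stage |
|---|---|
| `01_simulate_inputs.R` | synthetic BLAST hit tables and gene variants |
| `02_ortholog_filtering.R` | strict filters, all-species presence, consensus, frame check |
| `03_dnds.R` | per-gene Nei–Gojobori dN/dS and gene-set Welch comparisons |
| `04_qpcr_calls.R` | ΔΔCT quantification, test cascade, discrete call matrix |
| `05_expression_tree.R` | mean character distances, neighbor joining, bootstrap |
| `06_recapitulate.R` | end-to-end run with manifest and findings report |

Run them in order from the package root, e.g.
`Rscript analysis/01_simulate_inputs.R`.

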