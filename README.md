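# coassoc

Entropy-based screening of signaling receptors co-associated with EMT and
cell-cycle activity in transcriptomic data.

## What problem this solves

Tumor progression couples two functional programs: mitotic (cell-cycle)
activity drives in-situ growth, and the epithelial–mesenchymal transition
(EMT) drives invasion. Receptors whose expression tracks *both* programs —
especially the inversely co-correlated ones — are candidate regulators of
the whole progression axis and candidate tumor suppressors. `coassoc` is
for computational biologists who want to run that screen on gene-by-sample
expression matrices (bulk or single-cell), and to validate every stage of
it on synthetic data with planted ground truth.

The pipeline:

1. **Activity scores.** Per-sample program activity is the differential
   mean of `log2(CPM + 1)` between the program genes and a control pool of
   expression-rank-matched background genes: genes are ranked by mean
   expression, split into 25 rank bins, and the top 100 non-program genes
   of every program-occupied bin form the controls.
2. **Information statistics.** Each gene is quantile-discretized (default
   10 equal-frequency levels after a zeros-to-one / total / log2
   transform) and tested against the two scores with plugin Shannon
   entropy in bits. Mutual information is the inclusion–exclusion sum over
   variable subsets: for two variables `MI = H(X)+H(Y)-H(X,Y)`; for three
   it is the co-information
   `H(X)+H(Y)+H(Z)-H(XY)-H(XZ)-H(YZ)+H(XYZ)`, signed (redundancy > 0,
   synergy < 0). Normalized MI divides by the square root of the product
   of the marginal entropies.
3. **Permutation significance and screening.** Per-gene permutation
   p-values (one-sided on pairwise MI; two-sided around the permutation
   mean for the bias-dominated triple statistic), BH-FDR within each of
   the three families, set intersection, receptor filtering, and Spearman
   directionality ranking (most-negative-vs-EMT first).
4. **Conserved correlation.** For one focal gene across several datasets:
   per-dataset Spearman screen with BH, conservation under the "significant
   in at least k of N datasets" rule (default k = 2), and hypergeometric
   over-representation analysis of the conserved set against GMT pathways.
5. **Synthetic data.** A negative-binomial generator with lognormal,
   copula-correlated latent EMT/mitotic activities, program genes tracking
   them, receptors with calibrated saturating (nonlinear, monotone) links
   of either sign, exactly-independent null genes, and multi-dataset
   versions with a planted focal-gene module.

## Worked example

Simulate a 400-gene, 300-sample cohort with two 50-gene programs and three
receptors coupled to both programs (two negative, one positive), score the
programs, and run the screen:

```r
library(coassoc)

cfg <- sim_config(
  n_genes = 400, n_samples = 300,
  receptor_effects = receptor_effects(c("both", "both", "both"),
                                      c("-", "-", "+"), 0.5),
  seed = 19
)
d <- simulate_bulk(cfg)
d
#> <synthetic_dataset> 400 genes x 300 samples (seed 19)
#> # A tibble: 4 x 2
#>   role              n
#>   <chr>         <int>
#> 1 null            297
#> 2 program_cycle    50
#> 3 program_emt      50
#> 4 receptor          3

cpm <- cpm_normalize(d$expression)
emt <- score_activity(cpm, d$truth$gene[d$truth$role == "program_emt"], attribute = "EMT")
cyc <- score_activity(cpm, d$truth$gene[d$truth$role == "program_cycle"], attribute = "mitotic")
head(tibble::as_tibble(emt), 3)
#> # A tibble: 3 x 3
#>   sample attribute  score
#>   <chr>  <chr>      <dbl>
#> 1 S001   EMT       -3.35
#> 2 S002   EMT       -0.103
#> 3 S003   EMT       -2.25

scr <- run_screen(d$expression, emt, cyc,
                  receptors = d$truth$gene[d$truth$role == "receptor"],
                  n_perm = 1999, q_threshold = 0.05, seed = 7)
scr
#> <screen_result> 400 genes | significant: EMT 55, cycle 65, joint 107 | intersection 11 (receptors 2)

rank_receptors(scr)[, c("gene", "rho_emt", "rho_cycle", "nmi_emt", "nmi_cycle", "q_joint")]
#> # A tibble: 2 x 6
#>   gene   rho_emt rho_cycle nmi_emt nmi_cycle q_joint
#>   <chr>    <dbl>     <dbl>   <dbl>     <dbl>   <dbl>
#> 1 RCP002  -0.490    -0.456   0.124     0.118 0.00196
#> 2 RCP001  -0.488    -0.497   0.131     0.133 0.00196
```

The EMT score of sample `S001` is −3.35: its program genes sit about 3.4
log2 units below their expression-matched controls, i.e. low EMT activity.
Two of the three planted receptors pass all three significance families
and land in the receptor-filtered intersection; both are recovered with
the planted negative sign against *both* scores (Spearman rho ≈ −0.5, the
calibration target), with the most EMT-inverse receptor ranked first.
Detection is statistics, not bookkeeping — the third receptor missed one
family's FDR cut in this replicate; across 20 replicates of the bundled
power study ~93–97% of planted receptors are recovered.

`tidy(scr)` returns the full per-gene table (MI, NMI, p, q, rho per
family, set memberships), `glance(scr)` the set sizes, `autoplot(scr)` the
directionality plot. `correlate_focal()`, `ora()`, `run_pipeline()` and
the `inst/cli/coassoc` command-line wrapper cover the conserved-correlation
follow-up and end-to-end runs; see the methods vignette
(`vignettes/coassoc-methods.Rmd`) for the statistical details and design
choices.

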