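# deltastats

Five-taxon Δ-statistics: site-pattern tests that detect admixture *and its
direction* from biallelic SNP data.

The classic four-taxon D-statistic compares the discordant allelic
patterns ABBA and BABA: incomplete lineage sorting produces both equally
often, so an imbalance signals gene flow — but not who donated and who
received. With five populations the extra tree symmetry makes direction
recoverable. `deltastats` implements a family of statistics of the form

    Δ* = (n(L) − n(R)) / (n(L) + n(R))

where `L` and `R` are disjoint sets of polarized five-taxon allelic
patterns (minority allele = `B`, no outgroup polarization) drawn from
*equal probability sets* — pattern pairs whose null probabilities are
forced equal by exchangeability within the tree. Three tree shapes are
fully covered, each with a fixed panel of preferred scaled statistics:

| shape | topology | panel |
|---|---|---|
| symmetric `S` | `(((1,2),(3,4)),5)` | 8 statistics |
| asymmetric `A` | `((((1,2),3),4),5)` | 4 statistics |
| quasisymmetric `Q` | `(((1,2),3),(4,5))` | 8 statistics |

Each statistic gets a binomial Z-score and a `{+, −, 0}` class at level
`alpha` (threshold `qnorm(1 − alpha/2)`, 2.576 at the default 0.01). The
ordered classes form a *signature* that is matched against encoded
prediction tables covering every unidirectional gene-flow event with a
detectable effect (32 events on `S`, 18 on `A`, 34 on `Q`); all other
events predict the all-zero signature. Statistics built on singleton
patterns require mutation rates that depend only on time (the
synchronization assumption) and are dropped for ancient samples via the
collapsed panels/tables. DFOIL and the Partitioned D are exposed as the
special cases of composed statistics they are. A windowed genome scan
classifies local ancestry per window, and a built-in structured-coalescent
simulator (exponential pairwise coalescence, unidirectional admixture
edges, ghost populations, ancient "dead" tips) validates every predicted
signature.

Intended users: population geneticists testing introgression hypotheses
among five populations from VCF or site-table SNP data, including designs
with ancient specimens.

## Worked example

Simulate gene flow 2→3 on tree S (admixture proportion 0.1) and ask the
statistics who did it, using the ancient-data-safe collapsed panel:

```r
library(deltastats)

model  <- add_gene_flow(species_model("S"), "2>3", beta = 0.1)
counts <- simulate_pattern_counts(model, 2e5, seed = 7)
panel  <- compute_panel(counts, tree = "S", include_singletons = FALSE)
panel
#> Delta-statistic panel, tree S (singletons excluded, alpha = 0.01)
#>  name   nL   nR unscaled   scaled      Z wald_radius class
#>  S1-6 2970 1682     1288  0.27687 18.884     0.03629     +
#>  S2-6 3582 1595     1987  0.38381 27.616     0.03306     +
#>  S3-5 1788 2415     -627 -0.14918 -9.671     0.03929     -
#>  S4-5 1720 1648       72  0.02138  1.241     0.04437     0
#> signature: (++-0)

match_signature(panel_signature(panel),
                prediction_table("S", include_singletons = FALSE))
#> $category
#> [1] "2>3"
#> $events
#> [1] "2>3"
```

Reading the output: `nL`/`nR` are the weighted pattern counts on each side
of every statistic, `scaled` is the Δ\*-value in [−1, 1], `Z` its binomial
Z-score and `wald_radius` the 99% Wald interval radius. The signature
`(++-0)` equals exactly one prediction-table row — gene flow from
population 2 into population 3, the scenario we simulated. Had several
events shared that signature, `events` would list the whole ambiguity
class.

Real data enter through `read_sites()` (VCF + population map, or a plain
TSV site table) and `scan_windows()` for per-window classification;
`aggregate_scan()` tallies windows per scenario. A command-line wrapper
(`inst/cli/delta`, subcommands `count`, `stats`, `dfoil`, `scan`,
`simulate`, `tables`) covers the same surface from a shell.

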