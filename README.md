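# dloopr

Population-genetic analysis of aligned mitochondrial control-region
(D-loop) sequences, built for intraspecific phylogeography surveys of the
kind used to trace the origin and spatial structure of domestic-animal
populations: a sample of haploid sequences from several localities, a
question about where the population came from, and a question about how it
is structured in space.

The package implements the full pipeline as composable R functions plus a
one-config driver:

* **Sequence handling** — aligned-FASTA input, the missing-data site
  filter (drop sites where > 70 % of individuals carry a gap, `N` or other
  ambiguity code), haplotype collapsing, pairwise difference counts under
  pairwise deletion, nearest-reference haplogroup assignment.
* **Diversity and demography** — nucleotide diversity
  π = mean(d<sub>ij</sub>/comparable<sub>ij</sub>), haplotype diversity
  H = n/(n−1)(1−Σp<sub>i</sub>²), Tajima's D with the beta-approximation
  significance flag, the mismatch distribution with a least-squares
  Rogers–Harpending sudden-expansion fit (τ, θ₀, θ₁), and the two
  mutation-rate datings t = τ/(2μ<sub>seq</sub>) and
  t = d<sub>A</sub>/(2μ<sub>site</sub>).
* **Haplotype networks** — median-joining networks (ε-relaxed minimum
  spanning network plus majority-consensus median vectors).
* **Spatial structure** — within/between/net population distances,
  neighbor-joining trees with midpoint rooting, AMOVA variance components
  (Φ<sub>CT</sub>, Φ<sub>SC</sub>, Φ<sub>ST</sub>), and a SAMOVA-style
  simulated-annealing search for the K-group partition maximizing
  Φ<sub>CT</sub>, with an exhaustive K = 2 reference.
* **Coalescent simulation and ABC** — a haploid structured coalescent for
  three-population colonization scenarios with HKY+I+Γ sequence evolution,
  DIYABC-style summary statistics, MAD-standardized rejection, multinomial
  logistic scenario posterior probabilities, and Beaumont local-linear
  parameter posteriors with weighted 95 % HPD intervals.
* **Synthetic data** — a study-like generator (recent star expansion,
  Highland/Lowland split, divergent port-city outliers) so the whole
  pipeline is testable offline.

## Worked example

```r
library(dloopr)

# a study-like dataset: 78 birds, 11 localities, 2 divergent outliers
d <- generate_study_like(study_config(), seed = 1)
keep <- setdiff(rownames(d$aln$seqs), d$truth$outlier_ids)
aln  <- subset_alignment(filter_sites(d$aln), keep)
meta <- d$meta[d$meta$sample_id %in% keep, ]

str(tajimas_d(aln), digits.d = 4)
#> List of 8
#>  $ n            : int 76
#>  $ S            : int 9
#>  $ k_hat        : num 0.6035
#>  $ pi_site      : num 0.0004907
#>  $ H            : num 0.5375
#>  $ tajima_D     : num -1.748
#>  $ tajima_p     : num 0.05735
#>  $ tajima_p_flag: chr "ns"

# dating: tau = 2 * mu_seq * t, so t = tau / (2 * mu_seq)
expansion_time(0.248, rate_constants(L = 1230))
#> [1] 322.0863
divergence_time(2.85e-4, rate_constants())
#> [1] 455.2716

samova(aln, meta, K = 2, seed = 1)
#> K = 2  FCT = 0.7591  FSC = -0.0135  FST = 0.7558
#>   group1 : Beloha, FortDauphin, Mahajanga, Mahanoro, Manakara,
#>            Morondava, Toamasina, Tulear
#>   group2 : Ambohimanga, Anjozorobe, Manja
```

The K = 2 partition separates the two Highland localities plus the deme
the generator seeded from the Highland genetic cluster — the
generator-truth grouping — with 76 % of the molecular variance among
groups (Φ_CT = 0.759). The datings convert mutational time (τ = 2μt) and
net per-site distance (d = 2μt) into years with the chicken
control-region rate 3.13 × 10⁻⁷ mutations/site/year.

Scenario choice on a simulated three-population dataset (an informative
pseudo-observation with moderate effective sizes, so the topology signal
is visible at this reduced table size):

```r
scns <- lapply(1:3, demographic_scenario)
sizes <- c(Madagascar = 38, EastAfrica = 15, WestAsia = 25)
tab  <- build_reference_table(scns, 1000, sizes, seed = 1)
obs  <- generate_scenario_pseudoobs(2, params = list(T2 = 1900, Ta = 900,
          N_Madagascar = 500, N_EastAfrica = 500, N_WestAsia = 500),
          sample_sizes = sizes, seed = 5)
ss   <- summary_stats(obs$aln, obs$meta$population)
rej  <- abc_reject(ss, tab, tolerance = 0.1)
scenario_posterior(tab, rej, ss)
#> ABC scenario posterior (mnlogit, 300 retained)
#>  scenario         pp       lo        hi
#>         1 0.05114505 0.000000 0.1887920
#>         2 0.90107140 0.692735 1.0000000
#>         3 0.04778354 0.000000 0.1737628
```

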