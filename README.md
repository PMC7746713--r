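# cernaFrontier

Rank competing endogenous RNA (ceRNA) interactions by integrating
tissue-specific expression with miRNA-binding evidence through Pareto
Frontier Analysis, then annotate individual circRNAs with the genes and
pathways their sponged miRNAs would otherwise repress.

Sequence-only circRNA-miRNA catalogues ignore that a sponge and its miRNA
must be co-expressed in the same tissue at consequential levels. This
package is for computational biologists who have per-tissue expression
panels (SRPBM for circRNAs, CPM for miRNAs/genes), circRNA mature
sequences, and miRNA-gene evidence tables, and want a principled combined
ranking plus per-circRNA functional annotation — without collapsing
incomparable evidence onto one scale.

## Method at a glance

* **Expression score.** Per tissue, expressed features get their
  empirical-CDF value among expressed features, `S ∈ (0, 1]`; the
  pair score is `S_exp^{c|m} = max_t min(S^{c|t}, S^{m|t})` — high iff
  some tissue expresses both partners highly.
* **Binding score.** Canonical seed sites (6mer / 7mer-A1 / 7mer-m8 /
  8mer, seed = miRNA positions 2-7) are counted on the circular mature
  sequence (junction-spanning sites included) and length-normalized to
  MREs/kb.
* **Pareto integration.** Edge `x` dominates `y` when `x ≥ y` in every
  criterion and `>` in one. Successive non-dominated fronts are scored
  `S_P = (n_total − c_{<k}) / n_total`; front 1 scores exactly 1, edges
  on one front share one score, absent pairs score 0. miRNA-gene edges
  are ranked the same way on (TargetScan MRE count, miRTarBase
  publication count).
* **Annotation.** For a circRNA and its miRNA set `M_k`,
  `S_P^{c|g} = Σ_i S_P^{c|m_i} · S_P^{m_i|g}`; significance by permuting
  the miRNA subset (`p = (#{null ≥ obs} + 1)/(N + 1)`), then one-sided
  Fisher enrichment of the significant genes with BH-adjusted p-values.

## Worked example

Everything runs on generated data — no downloads. The fixture generator
plants three sponge circRNAs (tied-maximal co-expression with their
miRNAs in one tissue, 2 seeded sites/kb, boosted evidence toward one
gene set each) among 200 background circRNAs:

```r
library(cernaFrontier)

bundle <- generate_fixtures(fixture_config(seed = 7))
res <- run_pipeline(bundle, config = list(seed = 7, n_perm = 1000, n_max = 60))

head(rank_edges(res$circ_mir, "pareto"))[, c(1:4, 6:7)]
#>   source_id target_id S_exp mre_per_kb front_index pareto_score
#> 1   circ001    miR-01 1.000       4.44           1            1
#> 2   circ081    miR-01 0.578       6.38           1            1
#> 3   circ001    miR-02 1.000       2.22           2            1
#> 4   circ001    miR-03 1.000       2.22           2            1
#> 5   circ002    miR-04 1.000       2.22           2            1
#> 6   circ002    miR-05 1.000       2.22           2            1
```

The planted sponge `circ001` tops the ranking: its co-expression score is
exactly 1 (it and `miR-01` are the most-expressed features of one
tissue) *and* it carries a high site density, so nothing dominates it.
`circ081` sits on front 1 too on binding evidence alone — Pareto keeps
the extremes of either criterion rather than trading them off (front-2
scores print as 1 at three digits: 5998/6000).

```r
ann <- res$annotations[["circ001"]]
ann$mirna_set
#> [1] "miR-01" "miR-02" "miR-03" "miR-17" "miR-10"
head(ann$enrichment, 3)[, c(1:2, 4, 6:8)]
#>   set_name n_hits n_set_in_universe odds_ratio  p_value adjusted_p
#> 1    SET01     30                30        Inf 7.95e-35 7.95e-34
#> 2    SET10      2                29      0.478 9.12e-01 1.00e+00
#> 3    SET09      1                26      0.253 9.76e-01 1.00e+00
```

The permutation test flags 36 genes at `p ≤ 0.05` and Fisher enrichment
puts the planted target set (`SET01`, all 30 members hit) first by ~34
orders of magnitude. The ranking comparison shows why the integration
matters — of the three planted circRNAs found among the top 60 edges:

```r
subset(res$comparison, n == 60)
#>        method  n recall precision
#>        pareto 60   1.00     0.079
#>          nMRE 60   0.67     0.062
#>   nMRE_per_kb 60   0.67     0.061
```

Raw site counts reward long sequences; length normalization alone still
ignores expression; the Pareto ranking recovers all three sponges.

A command-line dispatcher with the same stages
(`make-fixtures`, `score-expression`, `score-binding`, `pareto-rank`,
`annotate`, `evaluate`, `run`) is installed at
`system.file("cli", "cernafrontier.R", package = "cernaFrontier")`.

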