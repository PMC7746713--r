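---
title: "Prioritizing and annotating circRNA ceRNA interactions with Pareto frontiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing and annotating circRNA ceRNA interactions with Pareto frontiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernaFrontier)
```

## The problem

Circular RNAs (circRNAs) can act as competing endogenous RNAs (ceRNAs):
by carrying binding sites for a miRNA they sequester it and de-repress the
miRNA's other targets. Sequence-based catalogues of circRNA-miRNA sites
ignore a necessary condition for this mechanism — the circRNA and the
miRNA must actually be co-expressed, at consequential levels, in the same
tissue. `cernaFrontier` ranks candidate ceRNA interactions by combining
two heterogeneous lines of evidence, expression and binding, without
forcing them onto a common scale, and then annotates individual circRNAs
with the genes and pathways their sponged miRNAs would otherwise repress.

## Expression evidence

Inputs are per-tissue mean normalized expression panels: back-splice
junction abundance for circRNAs (SRPBM — spliced reads per billion mapped
reads), CPM for miRNAs and genes. Helpers are provided for the standard
normalizations (`cpm()`, `srpbm()`, `median_of_ratios_normalize()`, the
size-factor method used by bulk RNA-seq tools) and for the customary
two-stage low-expression filter (`filter_low_expression()`: total raw
count at least 10 *and* mean normalized value at least 10). Replicates
are expected to be averaged into one column per tissue before scoring.

Within each tissue, features with zero expression are excluded and each
expressed feature receives its empirical CDF value among the expressed
features of its class:

$$S_{exp}^{f|t} = \frac{\#\{g : x_g \le x_f\}}{\#\{\text{expressed}\}} \in (0, 1].$$

We use the right-continuous convention, so tied values share the higher
score and the (tied) maximum scores exactly 1; this is what guarantees
the $(0,1]$ range. The pan-tissue co-expression score of a pair is

$$S_{exp}^{c|m} = \max_{t} \min\left(S_{exp}^{c|t},\ S_{exp}^{m|t}\right),$$

i.e. a pair scores high exactly when *some* tissue expresses both
partners at relatively high levels. Pairs with no shared expressed tissue
score 0. The score is rank-based, hence invariant to any monotone
rescaling of expression within a tissue, and monotone: raising a
feature's expression can never lower any of its pair scores.

Gene (linear RNA) ECDF scores can be computed with the same function but
enter no downstream score by default; co-expression is defined for
circRNA-miRNA pairs only.

## Binding evidence

`find_seed_sites()` counts canonical miRNA seed-match sites on circRNA
mature sequences. The seed is positions 2-7 of the mature miRNA
(5'→3'); a site is a reverse-complement match to it on the target,
classified by the canonical hierarchy — a match to miRNA position 8 on
the site's 5' flank (7mer-m8), an adenosine opposite miRNA position 1 on
its 3' flank (7mer-A1), both (8mer), or neither (6mer). This is a site
*counter*, not a context-scoring model: only the number of sites enters
the interaction score, so conservation and site-context features are out
of scope by design. 6mers are counted by default (`min_site_type` raises
the floor) because no site-type floor is imposed on the evidence.

Because circRNA mature sequences are covalently closed, targets are
scanned as circles by default: sites may span the back-splice junction,
and flank checks wrap around the sequence end. Positions are reported
0-based, half-open, modulo the mature length. Linear-mode hits are always
a subset of circular-mode hits at the level of seed-match offsets.

Longer sequences accumulate more sites by chance, so the pair-level score
is length-normalized:

$$S_{MRE}^{c|m} = \frac{n_{MRE} \times 1000}{L_c}\ \text{(MREs/kb)}.$$

miRNA-gene binding evidence is consumed from tables rather than computed:
predicted MRE counts (TargetScan-style, conserved and non-conserved
families summed per pair) and experimental support as publication counts
(miRTarBase-style), outer-joined with absent evidence as 0
(`load_mir_gene_evidence()`). An optional id-mapping table collapses
family names onto mature miRNA ids; no mapping is guessed.

## Pareto integration

Expression and binding scores live on incomparable scales. Rather than a
weighted sum, edges are stratified by Pareto dominance: edge $x$
dominates $y$ when $x \ge y$ in every criterion and $x > y$ in at least
one. Front 1 is the non-dominated set; removing it and repeating yields
successive fronts. Every edge of a front receives one score

$$S_P = \frac{n_{total} - c_{<k}}{n_{total}},$$

where $c_{<k}$ counts edges on strictly better fronts. Front 1 scores
exactly 1; scores decrease strictly with front index; pairs absent from
the ranking score 0 ("no evidence"). The rescaling rule for within-front
ties is genuinely underdetermined by the verbal description "rank
re-scaled by the total number of pairs"; we use the block-maximum rule
above because it satisfies both fixed points (front 1 at exactly 1,
equal-criteria edges sharing one score). The alternative rescaling by
front index is available via `pareto_scores(..., method = "front_rank")`
and is stamped into output metadata when used.

The shipped pipelines use exactly two criteria per edge type —
circRNA-miRNA: $(S_{exp}, \text{MREs/kb})$; miRNA-gene: (TargetScan MRE
count, miRTarBase publication count) — but `pareto_rank()` accepts any
number. Two criteria are ranked by an $O(n \log n)$-per-front
sort-and-sweep; three or more fall back to repeated non-dominated
filtering, which is ample at the package's problem sizes. All criteria
are maximized; callers pre-orient their scores.

## Functional annotation of a circRNA

For a circRNA $c$, the eligible miRNA set $M_k$ contains partners with
$S_P^{c|m} > 0$, optionally restricted to scores $\ge \tau$ (default
$\tau = 0.95$, the near-front band) or to the top $n$. Gene association
scores are the score-vector product

$$S_P^{c|g} = \sum_{i \le k} S_P^{c|m_i}\, S_P^{m_i|g},$$

and significance is assessed by permuting the miRNA subset: each of $N$
iterations draws $k$ miRNAs uniformly without replacement from the full
universe (the observed subset may recur), substitutes their columns of
the gene × miRNA score matrix while holding the observed circ-miRNA
score vector fixed, and recomputes the products. The p-value is

$$p_g = \frac{\#\{S^{null}_g \ge S^{obs}_g\} + 1}{N + 1},$$

so $p \ge 1/(N+1)$ and an untargeted gene ($S^{obs}_g = 0$) has $p = 1$.
Draws are canonical $k$-subsets (columns substituted in index order), so
the null depends only on *which* miRNAs are drawn — this makes the
small-universe null exactly enumerable, which the test suite exploits.
Holding the circ-miRNA vector fixed makes p-values invariant to common
positive rescaling of that vector, and matches the product formula being
permuted. $N$ defaults to 10,000; the fixture-scale analyses in the
tests use 1,000.

Genes with raw $p \le \alpha$ (default 0.05) feed a one-sided Fisher's
exact test per gene set over a fixed universe (default: all genes of the
miRNA-gene matrix). Benjamini-Hochberg adjusted p-values are reported
alongside raw ones; gene-level selection is deliberately unadjusted by
default, with `adjust = TRUE` available, since set-level testing is
where multiplicity is controlled. Sets disjoint from the universe are
skipped with a warning; GO terms are treated as flat sets (no DAG
propagation).

## Ranking evaluation

`precision_recall_curves()` reproduces the ranking comparison
methodology: order edges by a method (Pareto score, raw MRE count, or
MREs/kb; ties broken deterministically by ids), take the distinct
circRNAs among the top-$n$ edges, and intersect with a reference list.
Recall divides by the reference size, precision by the number of
distinct top-$n$ circRNAs (the natural denominator, recorded here since
verbal descriptions leave it open). Reference lists are plain text, one
circRNA id per line; no database content is bundled, and matching is by
user-supplied id only.

## Synthetic fixtures and what they do (not) show

`generate_fixtures()` builds a complete input bundle: log-normal
background expression with per-tissue dropout, uniform-random circular
sequences, sparse background miRNA-gene evidence, a disjoint gene-set
partition, and *planted* sponge circRNAs — raised to a target expression
quantile in one tissue shared with their planted miRNAs, seeded with
exact 8mer sites at a set density, and given elevated evidence against
one target gene set. Defaults are the package's study conditions: 5
tissues, 200 circRNAs, 30 miRNAs, 300 genes, 10 sets, three planted
sponges with three miRNAs each at strength 1.0 and 2 sites/kb, log-normal
sdlog 1.0, 70% expression probability, circRNA lengths log-uniform on
300-3000 nt with planted sequences at the short end (450 nt), so that
raw site counts remain length-confounded for the background only — the
failure mode length normalization exists to fix.

The end-to-end checks in the test suite run these conditions over 50
seeds with $N = 1000$ permutations and evaluate recall at the top 60
edges (1% of the 6,000 ranked edges — the same "top sliver" regime as
evaluating a few thousand edges out of millions). Passing them shows the
machinery recovers a strong planted signal through every stage — it does
not certify performance on real panels, where expression is not
log-normal i.i.d., sites are not exact 8mers, evidence databases are
biased toward well-studied genes, and the reference lists are themselves
noisy.

## Numerical conventions and edge cases

* Ties: ECDF ties share the higher score; exceedance counting uses
  $\ge$ exactly; ranking ties break lexicographically by ids.
* Degenerate inputs are errors, not warnings: empty rankings, a circRNA
  with no ceRNA edges, $k$ larger than the miRNA universe, an empty
  enrichment universe, zero library sizes, sequences shorter than a seed
  site (these yield an empty hit list).
* A tissue with no expressed feature is omitted from scoring with a
  warning.
* Determinism: every stochastic step takes a mandatory seed; the
  pipeline refuses to permute without one, and a re-run with the same
  config and inputs is byte-identical. Generators and scoring functions
  save and restore the caller's RNG state.
* Expression TSVs are written with 17 significant digits so write/read
  round-trips are bit-exact.

## Known limitations

Mature-sequence estimation for novel circRNAs, read-level processing,
context/conservation site scoring, miRNA-family collapsing conventions,
and disease-database identifier liftover are all out of scope; the
package consumes what those upstream steps produce. Whether a miRNA
family's site counts should be summed across its mature members is left
to the optional id-mapping table rather than decided silently.
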