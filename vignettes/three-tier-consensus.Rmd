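---
title: "Three-tiered consensus analysis of multi-aetiology expression compendia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-tiered consensus analysis of multi-aetiology expression compendia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A disease that can be reached from many different causes — heart failure is
the motivating case, with eleven aetiologies from dilated cardiomyopathy to
postpartum cardiomyopathy — raises the question of what its end stage has in
common at the molecular level. Public expression compendia hold the raw
material: many small case/control microarray studies, each with its own
platform, gene coverage and group sizes. `tritier` implements a three-tier
consensus analysis over such a compendium:

1. **Gene tier.** Per comparison (one dataset x condition x tissue stratum),
   rank-product differential expression with permutation-based *pfp*
   (proportion of false positives); genes called at pfp < 0.05. Genes DE in
   at least 60% of comparisons form the consensus signature of *frequently
   differentially expressed genes* (FDEGs).
2. **Pathway tier.** Per disease sample, a pre-ranked gene set enrichment
   analysis against a size- and redundancy-filtered pathway collection;
   pathways significant (nominal p < 0.05) in a strict majority of a
   condition's samples are dysregulated for that condition, and pathways
   significant in more than 60% of *all* disease samples are *frequently
   dysregulated*.
3. **Regulatory tier.** Every transcription factor in a TF→target network is
   tested against every frequently dysregulated pathway with a one-sided
   Fisher's exact test; edges pass at BH-adjusted p < 0.05 and pathway
   coverage > 0.2.

A synthetic-compendium generator with a ground-truth manifest makes the whole
chain testable end to end.

# Tier 1: rank products

For a comparison with $n_d$ disease and $n_c$ control samples, all
$K = n_d n_c$ pairwise log2 ratios are formed. Within each pair, genes are
ranked by ratio (descending for the up direction, ascending for down;
average ties), and the rank product of gene $g$ is the geometric mean
$\mathrm{RP}(g) = (\prod_k r_{gk})^{1/K}$, which lives in $[1, G]$ whatever
$K$ is, and orders genes identically to the raw product.

**Permutation null.** Each of `n_perm` (default 100) permutations shuffles
the gene labels *within every sample* and recomputes the pair ratios, ranks
and all $G$ null rank products. Shuffling at the sample level matters: the
$K$ ratio columns share samples and are therefore correlated, and a null
that instead draws an independent random permutation of ranks per pair
ignores this correlation and is strongly anticonservative (about 19% of
global-null genes at p < 0.05 in the 5v5 configuration, versus 5.2% for the
sample-level scheme, which reproduces the joint distribution of the observed
data under the null exactly). The pair-independent scheme remains available
in `permutation_null()` when only a ratio table exists, with a warning.

With $c(g)$ the number of pooled null rank products at or below the observed
$\mathrm{RP}(g)$ and $s(g)$ the gene's ascending-sort position:
$p = c / (n_\mathrm{perm} G)$ and
$\mathrm{pfp} = (c / n_\mathrm{perm}) / s$, both floored at $c = 1$ so that
p-values stay in $(0, 1]$. pfp is an expected-false-positive ratio, not a
probability, and is deliberately not clipped at 1. A gene significant in
both directions resolves to the smaller pfp; an exact tie is called `none`
and logged.

**Consensus.** "More than 60% (of 25 comparisons)" is read as
$n_\mathrm{DE} \ge \lceil 0.6 \times 25 \rceil = 15$: the boundary count
qualifies. FDEG direction is the majority call; an up/down tie breaks by the
sign of the summed rank evidence $\sum (\mathrm{RP_{down}} -
\mathrm{RP_{up}})$ across comparisons, i.e. by where the gene's ranks
generally sit.

# Tier 2: per-sample enrichment

The ranking metric for disease sample $j$ is
$m_g = x_{gj} - \overline{x}_{g,\mathrm{controls}}$ on the log2 scale — a
per-sample fold change against the dataset's control mean. This per-sample
contrast is what makes a per-pathway p-value *per disease sample* possible;
ties break by gene name so orderings are reproducible.

The collection is pre-filtered: optional exclusions first, then universe
intersection, then the [5, 300] size window, then redundancy pruning in
descending-size order dropping any set whose overlap coefficient
$|A \cap B| / \min(|A|, |B|)$ with an already-kept set exceeds 0.8. Keeping
the larger set maximizes retained gene coverage; every drop is recorded with
its reason. The filter is idempotent.

The enrichment score is the classic weighted Kolmogorov-Smirnov running sum
(weight exponent 1): members add $|m_g| / N_R$, non-members subtract
$1/(N - N_H)$, and the score is the extremum of largest magnitude (a
magnitude tie resolves to the positive extremum; if all member metrics are
zero the hit increments fall back to $1/N_H$ with a warning). The
implementation evaluates the running sum only at hit positions — $O(N_H)$
after the sort — and the test suite checks it against a full cumulative-sum
oracle to 1e-12.

Nominal significance comes from gene permutation: `n_perm` (default 1000)
random same-size gene sets, with add-one smoothing among same-signed nulls,
$p = (1 + \#\{|ES_0| \ge |ES|\}) / (1 + \#\{\mathrm{same\ sign}\})$. The
null depends only on the ranked metrics and the set size, so null
distributions are shared across same-size pathways within a sample.
Significance is nominal p < 0.05 — deliberately not an FDR q-value, because
the downstream consensus consumes per-sample significance flags, and the
frequency thresholds (strict majority per condition; > 60% of all samples
pooled, so 249 of 414 qualifies and 248 does not) provide the multiplicity
control that matters at the pathway-consensus level.

The consensus scatter uses $x = M^{up} + N^{down}$, $y = M^{up} - N^{down}$
(proportions of samples significantly up/down), so $x \ge |y|$ always.

# Tier 3: regulatory screen

For TF targets $T$ and pathway $P$ within universe $U$:
$a = |T \cap P \cap U|$, Fisher's one-sided upper-tail p, and coverage ratio
$a / |P \cap U|$. Two genuinely open choices, resolved as follows:

* **Ratio denominator.** "Proportion of TF targets in the pathway" is
  ambiguous between $a/|P|$ and $a/|T|$. Coverage $a/|P|$ is used: a 0.2
  floor on $a/|T|$ could never be met by hub TFs with thousands of targets
  against a ≤300-gene pathway, which would contradict the hub-rich character
  of regulatory screens (ETS1/MYC/SP1-type regulators). Configurable.
* **Universe.** Unstated upstream; the union of all network target genes and
  all genes of the filtered collection is used, so both margins of the 2x2
  table are drawn from one population. Configurable.

BH adjustment is applied once across the full TF x pathway grid (not per
pathway), matching the reporting of the passing edges as a single set.
Degree summaries use as denominators the TFs/pathways with at least one
passing edge.

# The synthetic world

`generator_config()` states the world; the defaults are the conditions the
analysis is designed for, chosen once:

| parameter | default | meaning |
|---|---|---|
| design | 12 strata, 25 comparisons, 11 conditions | mirrors the unbalanced multi-study compendium structure |
| `n_genes` | 2000 | shared universe; 5% missing per dataset |
| `disease_range`, `control_range` | 4-20, 4-16 | per-comparison group sizes |
| `baseline_mean`, `baseline_sd` | 8, 2 log2 units | per-gene baseline |
| `noise_sd` | 0.5 log2 units | per-sample Gaussian noise |
| `n_fdeg`, `fdeg_effect` | 100, 1.5 | planted signature, sign fixed per gene |
| `fdeg_condition_prob` | 0.9 | per-condition activity (creates mixed up/down rows) |
| `n_pathways`, sizes | 100, 10-50 | gene sets, sampled without replacement |
| active per condition | 15 = 10 core + 5 specific | `pathway_effect` 1.0, sign per pathway-condition |
| `n_tfs` | 50 (25 coupled + 25 decoys) | coverage 0.3 of one core pathway + 30 random targets |

Two generator design points deserve explanation:

* **Core pathways.** If every condition drew its 15 active pathways
  independently, no pathway could ever be significant in more than ~15% of
  samples and the compendium-wide "frequent" tier would be vacuous. The
  `n_core_pathways` (10) shared across all conditions are the pathways that
  *can* become frequently dysregulated, and the TF couplings attach to them
  so the regulatory tier has recoverable truth.
* **Orthogonal plantings.** Pathway members are drawn from the non-FDEG
  genes. Allowing overlap would give an FDEG inside an always-active pathway
  a realized net effect (e.g. $1.5 - 1.0 = 0.5$ in conditions where the
  pathway shifts down) different from the effect the manifest records — the
  manifest would be false for such genes. Orthogonality keeps the
  ground-truth manifest true; it is a structural choice, not an effect-size
  tuning.

The manifest records the planted signature (`fdeg_genes`, with directions
and per-condition activity), the per-condition active pathways with signs,
the core pathways, the TF couplings and decoys, and `frequent_de_genes` —
the union of the planted signature and the core-pathway members, which by
construction are also genuinely frequently DE. Signature *recall* is
measured against `fdeg_genes`; *precision* against `frequent_de_genes`
(measuring precision against the signature alone would mislabel genuinely
frequent genes as false positives).

**What the generator does not emulate:** batch/platform effects,
heavy-tailed intensity noise, probe-level artefacts, RNA-seq counts,
correlated co-expression beyond the planted shifts. A green recovery test
therefore establishes that the pipeline's logic and thresholds work on data
satisfying its assumptions — not that the pipeline is robust to confounding
between datasets.

# Numerical choices and degenerate inputs

* Fisher tests with an empty query or reference margin return p = 1 (no
  evidence), never an error: TF target sets and pathways may legitimately
  miss the universe.
* Rank-product p-values are floored at $1/(n_\mathrm{perm} G)$.
* A disease sample identical to the control mean yields an all-zero metric:
  the enrichment score is still defined but the p-value is meaningless, and
  a warning says so.
* Duplicate gene rows are averaged on load; gene identifiers are
  case-sensitive symbols with no alias mapping; matrices are assumed
  normalized and log2-scale upstream — no normalization is performed.
* Pipeline stage seeds derive from the global seed by fixed offsets so any
  stage reruns identically in isolation; reruns with the same config are
  byte-identical.

# Known limitations

* The classifier pools samples across datasets without batch correction, so
  its absolute AUC is optimistic under dataset confounding; the comparison
  against the size-matched random-gene baseline is the meaningful readout.
  In the default synthetic world that comparison *saturates*: with ~520
  planted informative genes and no batch heterogeneity, any random
  signature of matched size also separates the classes almost perfectly,
  both AUCs sit at or within a hair of 1, and in some realizations the null
  AUC distribution collapses to exactly 1 — zero variance, so the baseline
  t-test is undefined and `random_gene_baseline()` reports `t_p = NA` with
  a message. The signature-beats-baseline check is therefore only
  degenerately meaningful on synthetic data; on real, noisy compendia the
  comparison is informative. The world is documented rather than tuned.
* Under the zero-effect generator the planted list is exchangeable with any
  random list, so its one-shot CV AUC scatters around the null mean with
  sd about 0.034; calibration is therefore asserted on the difference
  averaged over independent zero-effect worlds, not on a single
  realization.
* The rank-sum variant, paired designs, phenotype-permutation GSEA,
  FDR/normalized-ES machinery, leading-edge extraction and ontology-DAG
  propagation for annotation are out of scope; annotation ORA treats terms
  as flat gene lists.
* Multi-tissue datasets are handled as separate strata (one comparison per
  dataset x condition x tissue), which is the reading the comparison count
  of the motivating compendium implies.
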