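---
title: "Methods: inheritance modes, allele-specific expression, and cis/trans decomposition in expression trios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inheritance modes, ASE, and cis/trans decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioexpr)
```

## The setting

An F1 hybrid and its two inbred parents are sequenced (bulk RNA-seq) at one
or more developmental stages with replicated libraries. Three questions are
asked gene by gene. First, where does F1 expression sit relative to the
parents — at the midparent value (additivity), at one parent (expression-level
dominance), or outside the parental range (over-/underdominance)? Second,
inside the hybrid, are the two parental alleles of a gene expressed equally
(allele-specific expression)? Third, is parental expression divergence
driven by cis-regulatory differences (which travel with the allele and are
visible as allelic imbalance inside the hybrid), by trans factors (shared
by both alleles in the hybrid nucleus), or by combinations? The package
implements these three classifications, the stage-transition accounting
between two stages, and replicate-based mid-/better-parent heterosis
indices for phenotypic traits.

## Inheritance modes

For one stage, four contrasts are computed per gene: F1 vs MPV, F1 vs P1,
F1 vs P2, and P1 vs P2. The midparent value is represented by
pseudo-replicates: parental replicates are paired by sorted replicate
index and each pair contributes `(P1_i + P2_i)/2` on the size-factor
normalised scale, rounded to an integer so the pseudo-sample can enter the
same test engine as real samples. Pseudo-samples preserve replicate-level
variance, which a single averaged column would not; the averaging halves
the variance of the MPV group, which is simply what averaging two
independent parental replicates does.

The built-in test engine is a Welch two-sample test on
`log2(normalised count + 0.5)` with a BH correction within each contrast
family. A negative-binomial count model (as dedicated differential
expression packages fit) is deliberately not re-implemented: the
classification layer is the contribution here and is engine-agnostic, so
`trio_contrasts()` accepts externally computed per-gene `(log2fc, p)`
tables through its `external` argument and only re-applies the BH step.
The pseudocount 0.5 appears in every log2 ratio of counts to keep zeros
finite; significance never depends on it because all tests act on raw
counts or on the log-transformed replicate values, not on the pseudocounted
point estimate.

The decision cascade is ordered to resolve rule conflicts deterministically:

1. `q(F1 vs MPV) >= 0.05` → **additive**, regardless of the parental
   contrasts;
2. F1 indistinguishable from the high parent and different from the low
   parent → **high-parent dominance** (mirror case → low-parent dominance);
3. F1 significantly above both parents → **overdominant**; below both →
   **underdominant**;
4. everything else → **unclassified**, reported rather than dropped. The
   main occupant of this cell is a gene that differs from the MPV but from
   neither parent individually.

When the normalised parental means tie exactly there is no high or low
parent, so the dominance rules are skipped and the gene falls through to
rules 3–4. The classification universe defaults to genes that pass the DEG
threshold (`|log2FC| >= 1`, inclusive, and `q < 0.05`, strict) in at least
one of the four contrasts; `universe = "all"` classifies every gene, which
is the right choice when comparing against simulation truth, since truth
labels are defined for all genes.

## Allele-specific expression

ASE works on allele-count tables in the layout of GATK's ASEReadCounter:
one row per SNP site with reference/alternative allele counts, one file per
role (P1 sample, P2 sample, hybrid). At parse time, indel records are
rejected, sites are joined across the three roles on (contig, 1-based
position), the parent carrying the reference base is inferred from the
parental consensus (sites where the parents do not disagree are dropped as
uninformative), and hybrid ref/alt counts are relabelled to P1-allele and
P2-allele counts. Sites outside every interval of the gene annotation are
dropped; every dropped row is tallied by reason so that consumed plus
rejected equals the input row count.

Site QC then applies, in a fixed order with first-failure logging:
minimum depth 10 in the hybrid and in both parents; hybrid depth inside
the central `[5%, 95%]` band of the hybrid site-depth distribution
(computed on the sites that survived the depth filter — the band guards
against collapsed repeats and poorly covered sites); and a reference-skew
guard rejecting hybrid ref:alt ratios outside `[1/2, 2]`. The skew guard
is a mapping-bias heuristic, and it visibly tensions with genuine strong
ASE: a true 2:1 allelic bias sits exactly at the boundary, so about half
of such sites fluctuate past it. The filter is therefore switchable
(`ref_skew = Inf`), the number of sites it removes is always logged, and
analyses of simulated data — which contain no mapping bias by
construction — run with it off.

Gene-level calls sum the retained hybrid allele counts per gene
(SNP-qualified genes are exactly those with at least one retained site),
re-run the exact binomial test on the sums, and record discordant sites —
sites whose individual direction opposes the gene-level direction — as a
data-quality flag. With q from a BH correction across SNP-qualified genes,
the classes are: monoallelic (`q < 0.05` and ratio ≥ 0.95 *or* ≤ 0.05 —
the mirrored tail is added so the rule is parent-agnostic), preferential
(`q < 0.05` and ratio ≥ 0.67 or ≤ 0.33), biallelic (`q ≥ 0.05` and ratio
strictly inside (0.33, 0.67)), and undetermined for the two cells those
definitions do not cover (significant but mildly imbalanced;
non-significant but extreme). Undetermined genes are reported, never
silently assigned. Note a quirk of the conventional 0.67 threshold: an
exact 2:1 bias is 0.6667 and falls *below* it, so genes with a true
two-fold allelic effect are typically significant-but-undetermined rather
than preferential; the threshold is kept as conventionally stated and is
configurable.

The stage comparison reduces each gene to a joint state over
{P1-biased, P2-biased, unbiased} (biased = significant and directional)
and cross-tabulates the states of genes observed at both stages, counting
stable, switched, newly biased and lost-bias genes; genes covered at only
one stage are excluded and counted.

## Cis/trans decomposition

Per SNP-qualified gene, with `c1, c2` the summed parental read counts at
its retained sites, `h1, h2` the summed hybrid allele counts, and `s1, s2`
parental library sizes:

* `P = log2((c2 + 0.5)/(c1 + 0.5)) − log2(s2/s1)` — total parental
  divergence; exact binomial test of `c2` out of `c1 + c2` with null
  proportion `s2/(s1 + s2)`, so the null and the effect estimate share one
  normalisation. Library sizes default to the total retained-site parental
  counts; the pipeline passes stage-level totals explicitly.
* `H = log2((h2 + 0.5)/(h1 + 0.5))` — allelic imbalance inside the hybrid,
  the cis component; exact binomial against 0.5.
* `T = P − H` — the trans component, exactly by construction; significance
  from a two-sided Fisher exact test of `[[c1, c2], [h1, h2]]`. A table
  with a zero margin is uninformative and yields p = 1.

Each statistic is BH-adjusted across genes separately (three families per
stage), matching the per-test FDR interpretation of the thresholds. The
category logic, with `sig = q < 0.05`: P,H only → cis-only; P,T only →
trans-only; all three with `sign(H) = sign(T)` → cis+trans (synergistic),
with opposite signs → cis×trans (antagonistic); H,T without P →
compensatory; none → conserved; any remaining pattern → ambiguous. The
percent-cis contribution is `100·|H|/(|H| + |T|)`, the standard relative
magnitude definition; it is undefined when both components are exactly
zero and such genes are excluded from binned summaries. Divergence
magnitude is summarised per category as `2^median|P|` (a fold change), the
cis-only and trans-only `|P|` distributions are compared with a two-sided
rank-sum test (a fully tied comparison is reported as p = 1), and mean
percent-cis is binned by `|P|` in 0.5-log2 bins.

## Trait heterosis

`MPH = 100·(mean(F1) − MP)/MP` with `MP` the mean of the parental means,
and `BPH = 100·(mean(F1) − BP)/BP` with `BP` the **higher-value** parental
mean regardless of agronomic desirability — so a hybrid shorter than its
taller parent has negative plant-height BPH. Significance uses Welch tests
of the F1 replicates against per-replicate midparent pseudo-values (MPH)
and against the better parent's replicates (BPH); Welch is chosen as a
replicate-level test without an equal-variance assumption, standing in for
multiple-range procedures that need full field-design information.
Reported percentages are rounded half-away-from-zero to two decimals, the
convention of printed trait tables.

## The simulator

`simulate_trio_experiment()` draws the full input set — count matrix,
per-role allele tables for both stages, gene map, truth table — from a
configuration that doubles as the statement of the study conditions:

* **Design**: three genotypes × two stages × `n_replicates = 3`, matching
  a trio design with three biological replicates per genotype per stage.
* **Counts**: negative binomial with `variance = mu + dispersion·mu²`, the
  standard RNA-seq overdispersion form. `baseline_mean = 500` puts genes at
  the depth where the cascade's guarantees are stated. The default
  `dispersion = 0.002` (replicate CV ≈ 6–7% at that depth) is chosen for
  power rather than estimated from data: the motivating design pools many
  plants per replicate and reports very high replicate consistency, and no
  empirical dispersion estimate is available, so the default describes a
  clean, well-powered experiment. Noisier settings are one argument away.
* **Inheritance truth** sets the F1 mean: midparent for additive, the
  extreme parent for dominance, `2^(±effect)` times the extreme parent for
  over-/underdominance, with `effect_log2fc = 1` by default.
* **Regulatory truth** sets `(H_true, T_true)` per class (cis-only:
  `H = ±e, T = 0`; trans-only: `H = 0, T = ±e`; cis+trans: `H = T = ±e`;
  cis×trans: `H = ±e, T = ∓e/2`; compensatory: `H = ±e, T = ∓e`;
  conserved: zeros) and `P_true = H_true + T_true` exactly. Hybrid allele
  counts are binomial with P2-allele probability `2^H/(1 + 2^H)` at
  Poisson site depths (`site_depth_mean = 100`); parental site depths are
  Poisson with means `∝ 2^{∓P/2}`. `snps_per_gene = 4` reflects the four
  to five informative SNPs per SNP-qualified gene seen in real wheat trio
  data.
* **Coupling**: every gene carries both labels. The count-scale parental
  divergence follows `P_true` where it is nonzero; a dominance-mode gene
  whose regulatory class leaves `P_true = 0` receives a count-scale
  parental shift of `±effect_log2fc`, because expression-level dominance
  is undefined without divergent parents. The truth table records this
  shift separately from `P_true`.
* **Determinism**: one seed in the configuration; identical configurations
  reproduce bit-identical files.

What the simulator does *not* emulate — and what green tests therefore do
not certify about real data: mapping bias (hence the skew guard is off in
simulation-based checks), homoeolog cross-mapping in polyploids,
GC/length biases, correlated sites within a gene beyond the shared truth,
stage-dependent truth changes, and library-composition effects beyond
global size factors.

## Numerical choices and degenerate inputs

* Exact binomial p-values use the minimum-likelihood two-sided definition
  (sum of outcome probabilities not exceeding the observed outcome's);
  they match brute-force enumeration in the tests.
* BH is the standard step-up; `q >= p` and monotonicity are asserted
  against a literal step-up oracle.
* Thresholds: significance is strict (`q < 0.05`), non-significance
  inclusive (`q >= 0.05`); the DEG fold-change threshold is inclusive
  (`|log2FC| >= 1`). Expression bins are left-inclusive
  (`<1`, `[1,20)`, `[20,50)`, `>=50` FPKM).
* Depth-tail percentiles use the default continuous quantile definition;
  on a fixture of 100 distinct depths the 5% tails remove exactly the five
  highest and five lowest sites.
* All-zero genes in a contrast get `log2fc = 0, p = 1`; zero-variance
  Welch comparisons give p = 1 when means agree and p = 0 otherwise; a
  zero-margin Fisher table and a zero-total binomial site are skipped or
  given p = 1, with logging.
* Parent-label swaps negate `P, H, T`, swap dominance and bias labels, and
  leave every class membership unchanged; this symmetry is property-tested.

## Problem sizes used in the checks

The shipped test-suite and the acceptance script run: null calibration on
2,000 genes at site depth 100 (one SNP per gene, so the site-level and
gene-level null rates are measured on the same draws), and label recovery
on 500 + 500 genes (five inheritance classes × 100; cis-only, trans-only,
compensatory, conserved × 125) at four SNPs per gene and site depth 100,
i.e. about 400 hybrid reads per gene, with 1-log2 effects. These sizes
keep full-suite runtime around half a minute while leaving Monte-Carlo
error on the reported rates near one percentage point.

## Known limitations

* The Welch engine on log counts is less powerful than a tuned count model
  at very low depth; the external-results pathway exists for exactly that
  case.
* The cis×trans subtype split uses only `sign(H)` vs `sign(T)`; finer
  sub-scenarios of same-allele versus opposite-allele enhancement are not
  operationalised because their published definitions are not precise
  enough to implement unambiguously.
* `% cis` compresses two signed magnitudes to one unsigned share; genes
  with near-zero `|H| + |T|` are excluded rather than reported as noise.
* The multi-transcript length question for FPKM is delegated to the user:
  a per-gene length table is a required input, and FPKM feeds only the
  expression bins, never a test.
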