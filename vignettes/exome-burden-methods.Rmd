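---
title: "Methods: rare-variant prioritization and carrier-collapsing burden tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant prioritization and carrier-collapsing burden tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exburden)
```

## Scope and model

`exburden` implements the association workflow used in small case-control
exome studies of a rare disease in an isolated founder-like cohort — on the
order of 47 cases and 53 controls — where single-variant power is minimal
and the analysis leans on variant prioritization and gene-level collapsing.
The pipeline consumes a multi-sample VCF (GT and per-sample DP), a sidecar
annotation table (gene, consequence, SIFT/PolyPhen2 calls, conservation
flag, external population allele frequency, dbSNP novelty), and a phenotype
table, and proceeds through:

1. **Sample QC** — samples with overall call rate below
   `sample_call_rate_min` (default 0.9) are dropped. The retained samples
   form the *analysis set*, whose sizes are the fixed denominators of every
   carrier table downstream. This is why a cohort enrolled as 47/53 can be
   analysed as, say, 46/51.
2. **Site QC** — a site passes when at least `min_fraction_at_depth`
   (default 0.95) of samples reach `min_depth` reads (default 10), and when
   its exact Hardy-Weinberg p-value is at least `hwe_alpha` (default
   `1e-5`).
3. **MAF stratification** — folded minor allele frequency over non-missing
   genotypes; common (`maf >= 0.05`), low-frequency (`0.01 <= maf < 0.05`),
   rare otherwise.
4. **Single-variant association** — five models per variant (below).
5. **Prioritization** — the case-only candidate filter (below).
6. **Burden scan** — per-gene carrier collapsing with a one-sided Fisher
   exact test over all externally rare, damaging variants.
7. **Gene-wise masks** — the same collapsing engine under two functional
   masks, with a Manhattan-plot export.
8. **Panel verification** — exact variant-key lookup of a candidate panel in
   an independent cohort, counting carriers per group.

## The carrier-collapsing burden test

For gene $g$, let $a$ of $n_1$ cases and $c$ of $n_0$ controls carry at
least one qualifying variant (dosage $\ge 1$ at one or more variants;
a sample counts once however many it carries). With all margins fixed, the
one-sided p-value is the hypergeometric upper tail

$$ p = P(X \ge a), \qquad X \sim
   \mathrm{Hypergeom}(N = n_1 + n_0,\; K = a + c,\; n = n_1), $$

i.e. Fisher's exact test with `alternative = "greater"` on the 2×2 carrier
table. Three choices are deliberate and verified by the test suite against
the published carrier-count table shipped in `inst/extdata/`:

* the test is **carrier-level** (persons, not alleles);
* the **standard tail** is used, not the mid-p variant — the 4/46 vs 0/51
  configuration has the closed form
  $\frac{46 \cdot 45 \cdot 44 \cdot 43}{97 \cdot 96 \cdot 95 \cdot 94}
  = 0.047097413$, which matches the printed value only for the standard
  tail;
* denominators are the **fixed analysis-set sizes**, not per-gene
  non-missing counts (a `per_gene_denominators` flag provides the
  alternative).

Raw p-values are primary, mirroring how such tables are published;
Bonferroni and Benjamini-Hochberg columns are reported alongside but do not
drive the headline flagging.

**Which genes enter the scan.** The burden scan collapses over
`burden_qualifying_map()`: every QC-passing variant that is damaging and
rare in external reference genomes (`external_af < 0.05`). It does *not*
collapse over the case-only candidate list: published carrier tables of
this design include genes with many control carriers (e.g. 39/46 vs
30/51), which a "not carried by controls" filter could never produce. The
case-only filter is a separate, stricter prioritization stage.

## The case-only candidate filter

A variant is a *candidate* when, in order: site QC passed; external
frequency is below `external_af_max` (default 0.05); the variant is
damaging; it is conserved (when `require_conserved`, the default); it is
novel (only when `require_novel`); it has at least `min_case_carriers`
(default 2) case carriers and at most `max_control_carriers` (default 0)
control carriers. The per-variant pass/fail trail of every rule is attached
to the result, so the retained set can be reconstructed by replaying the
trail — the property the test suite checks on randomized cohorts.

*Damaging* means: frameshift, stop-gain, splice-affecting, or missense
called damaging by **either** SIFT or PolyPhen2. Requiring both predictors
is the main alternative reading; either-predictor was chosen because
splice-acceptor and predictor-discordant variants appear among published
follow-up candidates of this design, and it is the inclusive convention of
qualifying-variant pipelines. A variant with *unknown* external frequency
passes the rarity rule by default — absence from reference genome panels
means the variant is at most rare — with `strict_external_af` available for
the conservative reading.

## The exact Hardy-Weinberg test

Site QC uses the conditional exact test: with $n$ genotypes and the minor
allele count $n_A$ fixed, the probability of $h$ heterozygotes under random
mating is

$$ P(h \mid n, n_A) =
   \frac{n!}{n_{AA}!\, h!\, n_{aa}!} \, 2^h
   \Big/ \frac{(2n)!}{n_A!\,(2n - n_A)!}, $$

and the p-value sums $P(h)$ over every attainable $h$ with
$P(h) \le P(h_{obs})$ — two-sided by probability ordering. The
implementation walks the support with the standard adjacent-count
recurrence in log space; the test suite checks it against a direct
log-factorial enumeration for **every** genotype configuration with
$n \le 50$ at $10^{-12}$, and the acceptance script re-runs that sweep. The
test is computed on all samples by default; `hwe_population = "controls"`
restricts it to controls, the other common convention — published methods
of this design rarely state which was used.

## The five single-variant models

With case counts $(r_0, r_1, r_2)$ and control counts $(s_0, s_1, s_2)$ by
dosage:

* **trend** — Cochran-Armitage score test with weights $(0, 1, 2)$
  (`stats::prop.trend.test`), df 1;
* **allelic** — Pearson $\chi^2$ on allele counts
  $(2r_0 + r_1,\; r_1 + 2r_2)$ vs the control analogue, df 1;
* **dominant** — carriers $(r_1 + r_2)$ vs non-carriers, df 1;
* **recessive** — hom-alt $r_2$ vs rest, df 1;
* **genotypic** — Pearson $\chi^2$ on the 2×k table of occupied genotype
  columns, df $k - 1$.

No continuity correction is applied, matching the convention of
case-control genetics toolchains; an optional Fisher fallback replaces the
p-value when any expected cell is below 5 (off by default). Degenerate
tables (a single occupied genotype column, an empty phenotype group, a zero
margin) return an explicit undefined-test signal (`NA` statistic and p with
a reason) rather than a number.

A note on verification: the permutation distribution of the trend statistic
at these sample sizes is discrete, with a sizeable probability atom at the
observed value. The asymptotic $\chi^2$ tail approximates the permutation
**mid-p** (half the atom counted); the test suite therefore compares
against the mid-p at 10,000 label shuffles, which agrees to well within
Monte-Carlo error, while the raw permutation tail can sit a tenth above the
asymptotic p purely through the atom.

## Gene-wise masks

Two masks select variants for gene-wise collapsing, both bounded at cohort
`maf < 0.05`:

* `stopgain_frameshift` — the damaging classes (stop-gain, frameshift,
  splice, damaging missense);
* `nonsynonymous` — all protein-altering consequences, a strict superset.

Both reuse the burden engine, so a mask equal to a gene's qualifying set
reproduces the burden p exactly — an invariant in the test suite. The
Manhattan export orders genes by genome position and carries the
significance line as metadata; rendering is left to the caller.

## The synthetic cohort generator

No raw data of the motivating design is publicly deposited, so the
generator is a first-class module: every pipeline stage is tested against
cohorts whose ground truth is planted and recorded. Defaults emulate the
study conditions: 47 cases / 53 controls; a rare-heavy frequency mixture
(60% Beta(0.4, 60), 20% Uniform(0.01, 0.05), 20% Uniform(0.05, 0.5));
consequence proportions with missense most common (0.55) and stop-loss
rarest (0.005); mean 120× negative-binomial depth (size 8) with 5% of sites
collapsing to mean 5× to exercise the depth filter; 2% missingness; two
planted risk genes (carrier probabilities 0.28 vs 0.04, and 0.10 vs 0 —
one Table-1-like, one case-only-like); and three heterozygote-deficit sites
(Wright-style distortion $f = 0.9$ at MAF 0.25–0.5) to exercise the HWE
filter. Risk planting is parameterized directly by group carrier
probabilities — the burden test's own contract — realized as heterozygotes
at designated signal variants; an additive-dosage mode (`planted_sva`)
exists for single-variant power studies. External allele frequency tracks
the true frequency with multiplicative noise and can be unknown only below
1% true frequency, since reference panels catalogue anything common.

What the generator does **not** emulate: linkage disequilibrium, population
substructure and relatedness, batch effects, annotation errors, and
sequencing artefacts correlated with phenotype. Passing calibration on
these cohorts therefore demonstrates correctness of the statistics under
clean sampling assumptions, not robustness to the confounders of real
exome data.

## Numerical choices

* Fisher tails come from the hypergeometric distribution function; the
  suite verifies them against full enumeration for **every** margin
  configuration with table total ≤ 60 at $10^{-12}$.
* HWE probability ties are compared with a $1 + 10^{-9}$ relative guard so
  mathematically equal configurations (which differ only by floating-point
  route) are included on both sides.
* Result TSVs print numerics with at most nine decimal places, trailing
  zeros dropped, never scientific — the precision at which published
  carrier tables print — so write→read→write is byte-identical.
* Multi-allelic sites are decomposed per alternate allele (records inherit
  the site depth); genotypes containing `.` (including half calls like
  `./1`) are missing; missing genotype and zero depth are recorded
  separately. "More than 10×" is read as depth ≥ 10, the conventional
  inclusive depth filter; the comparator is configurable.
* Variant identity is the normalized `chrom:pos:ref/alt` key — the sole
  join key between genotypes, annotations, panels and results.

## Problem sizes in tests and the acceptance script

The suite runs 2000-replicate null calibrations of both scans (burden on
15-gene rare cohorts; single-variant on common variants at MAF 0.1–0.5),
500-replicate planted-gene recovery (carrier probability 0.25 vs 0.02 at
47/53, top-decile criterion), exhaustive oracle sweeps (Fisher to table
total 60; HWE to 50 genotypes), and 10,000-shuffle permutation checks. The
acceptance script repeats the same computations at 500/200 replicates and
slightly smaller sweeps — sizes chosen so a complete from-scratch run
remains a coffee-break affair on one CPU while keeping Monte-Carlo error
well below the assertion bands.

## Known limitations

* Collapsing is presence/absence with equal weights (CMC-style); no
  frequency-weighted or variance-component (SKAT-like) statistics.
* No covariates, relatedness correction, or genomic-control inflation
  adjustment — appropriate for a small homogeneous isolate, not for mixed
  cohorts.
* The recessive and genotypic models are conservative at modest minor
  allele frequencies through the discreteness of small hom-alt counts; the
  calibration tests assert non-anti-conservatism for them rather than
  exact nominal level.
* Panel verification matches exact normalized keys only: no liftover, no
  HGVS resolution, no fuzzy indel matching.
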