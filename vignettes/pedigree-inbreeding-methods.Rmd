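---
title: "Methods: pedigree inbreeding, marker heterozygosity and the avoidance test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree inbreeding, marker heterozygosity and the avoidance test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedavoid)
```

`pedavoid` quantifies inbreeding in group-living animal populations with
multi-generational pedigrees — the motivating system is a large, genetically
isolated macaque colony with female philopatry, male natal dispersal, male
reproductive skew and a sizeable founder cohort — and asks whether breeding
between kin occurs less often than demography alone would predict. This
vignette records the models, conventions and design choices behind each
stage, and what the validation experiments do and do not demonstrate.

## Pedigree inbreeding

The kinship coefficient $f(i,j)$ is the probability that two alleles, one
drawn at random from each individual, are identical by descent (IBD) within
the pedigree. It is computed by the classical recursion, expanding whichever
member of a pair has the larger generation number (and therefore cannot be an
ancestor of the other):

$$f(i,j) = \tfrac{1}{2}\left[f(\mathrm{sire}_i, j) + f(\mathrm{dam}_i, j)\right],
\qquad f(i,i) = \tfrac{1}{2}\left[1 + f(\mathrm{sire}_i, \mathrm{dam}_i)\right],$$

with a missing parent contributing 0. The additive relatedness is $r = 2f$,
and the inbreeding coefficient of an offspring is the kinship of its parents,
$F = f(\mathrm{sire}, \mathrm{dam})$. Founders — individuals without recorded
parents, including auto-created stubs for parents referenced but absent from
the table — are assumed unrelated and non-inbred. That assumption is
reasonable for founder cohorts drawn from a large, spread-out source
population, and it is the same one made by every pedigree study that cannot
observe ancestry before its records begin.

**Generation-counting convention.** All depth arguments count *ancestor
generations above the focal individual*: parents are generation 1,
grandparents 2. A "complete three-generation pedigree" in the usual field
phrasing (focal + parents + grandparents) is `ancestor_complete_depth(...) >= 2`;
four generations is depth 3. `ancestor_complete_depth()` requires all $2^g$
ancestors at every generation $g \le d$ to exist as non-stub records.

**Depth truncation.** `kinship()`, `inbreeding_coefficient()` and
`classify_inbreeding()` accept a `depth_limit`: ancestors beyond the limit
are replaced by fresh, mutually unrelated founders. A node at the boundary
keeps its identity but loses its parents, so an inbreeding loop through a
great-grandparent is visible at depth 3 and invisible at depth 2 — exactly
the behaviour needed to contrast three- and four-generation analyses, where
the count of detected inbred individuals can only grow with depth while the
mean $F$ among them falls (deeper loops contribute smaller coefficients).
When the two lineages of a pair meet the same individual with different
residual budgets, the smaller budget is used; this is the conservative choice
(it can only shrink $f$) and affects no canonical configuration. Whether a
study's $F$ values truncated ancestry at the completeness depth or used all
known ancestors is rarely stated; truncation is the default here because it
makes the depth-d analysis a function of the depth-d pedigree alone, but
`depth_limit = Inf` gives the untruncated coefficient.

**Case classification.** `classify_inbreeding()` enumerates common-ancestor
paths between the parents of an inbred individual under Wright's
path-counting rule (the two branches of a path share no individual besides
the common ancestor; each path contributes
$(1/2)^{L_s + L_d + 1}(1 + F_A)$). Path-length signatures map to the field's
taxonomy: shared parent(s) give half- or full siblings, a length-0 branch
gives parent–offspring, a sibling link one generation apart gives
uncle–niece (sire is the sibling) or aunt–nephew (dam is), and shared
grandparents give first cousins; anything deeper collapses to `"other"` with
the raw path lengths retained. The *kin line* is read off the sex-of-parent
of each breeder's first step toward the common ancestor (both via sires =
paternal, both via dams = maternal, mixed = maternal-and-paternal; for
parent–offspring pairs only the descendant steps count). Note that avuncular
and cousin links through a *single* common ancestor (i.e. via a half-sibling
connection) yield $F = 0.0625$ and $F = 0.03125$ — half of the textbook
full-link values — and `canonical_mating()` builds exactly these minimal
configurations, because that is the form in which such cases are typically
reported from colony pedigrees.

**Gene-dropping oracle.** `gene_drop_F()` estimates $F$ by simulating the
transmission of two distinct founder alleles per founder down the pedigree
and counting autozygous replicates. It shares no code with the recursion
(it is plain Mendelian sampling restricted to the focal individual's
ancestor closure) and serves as the independent check: on random pedigrees
the two agree within three Monte-Carlo standard errors at $10^5$ replicates.

## Marker-based estimators

For diploid codominant genotypes (two alleles per locus, whole-genotype
missingness) the package computes, per individual over its typed loci:

* **SH**, standardized heterozygosity: the proportion of heterozygous loci
  divided by the mean population heterozygosity of the loci the individual
  was typed at. The denominator uses *observed* heterozygosity by default —
  the phrase "mean heterozygosity of the typed loci" is ambiguous between
  observed and expected, and observed matches the estimator's reference
  implementations — with expected ($1 - \sum_k p_k^2$) available via
  `use_expected`/`sh_expected`.
* **IR**, internal relatedness:
  $\mathrm{IR} = (2H - \sum f_i) / (2N - \sum f_i)$, where $H$ is the number
  of homozygous loci, $N$ the number of typed loci and $\sum f_i$ the summed
  sample frequencies of the individual's $2N$ allele copies; sharing rare
  alleles weighs more, the range is $[-1, 1]$.
* **HL**, homozygosity by loci:
  $\mathrm{HL} = \sum_h E_h / (\sum_h E_h + \sum_j E_j)$, expected
  heterozygosities summed over homozygous ($h$) and heterozygous ($j$) loci;
  1 means all loci homozygous, 0 all heterozygous.

Allele frequencies are computed on the full genotyped sample *including* the
focal individual (again matching common practice; `freq_exclude_focal` gives
the leave-one-out variant). Individuals typed at fewer than `min_loci`
(default 10) are reported with missing estimates, never dropped silently.
No Hardy–Weinberg or null-allele correction is applied: genotypes are taken
at face value, as the estimators assume. By construction HL and IR rise with
homozygosity while SH falls, so their pairwise rank correlations have fixed
signs; on gene-dropped data the correlations with pedigree $F$ have the
matching directions, though their magnitude is modest at 30 microsatellites —
which is precisely why marker panels of this size complement rather than
replace pedigrees.

## The inbreeding-avoidance permutation test

The question is whether the parents that actually bred were less related
than expected if females took sires as demography offers them. The null
model assigns each offspring's sire in three steps:

1. **Category partition.** A fixed fraction of offspring (default 24%) gets
   an extra-group sire, a fraction (16%) a natal sire (a male still living
   in his birth group, which also is the mother's group), and the remainder
   (60%) a within-group non-natal sire. The partition uses exact counts
   (`round(p * n)`, remainder randomly placed) rather than per-offspring
   Bernoulli draws, matching the phrasing "x% of offspring were assigned";
   a Bernoulli mode is available.
2. **Eligibility.** Candidate sires must be alive at the offspring's
   conception (birth date minus `conception_offset`, default 166 days — a
   macaque gestation), at least `maturity_age` (default 4 years) old, and
   pass the pedigree completeness filter.
3. **Reproductive skew.** Within-group assignments draw from a subsample of
   `skew_fraction` (default 20%) of the group's available males, drawn once
   per group and birth cohort per simulated dataset; an optional age window
   (e.g. 9–11 years) restricts the subsample first, falling back to the
   whole pool if the restriction empties it. The default considers all
   available group males because the skew description supports both
   readings; the window is a switch, not the default.

An offspring whose assigned category pool is empty falls back to the
within-group pool (then the remaining pools), logged; `empty_pool_action =
"drop"` removes it instead. Offspring with no eligible sire anywhere are
excluded from both the observed and the simulated datasets, keeping the two
comparable.

**Completeness filter.** Both members of every (actual or potential) pair
must have `completeness_filter_depth` (default 2: parents and grandparents)
fully known, and parental relatedness is evaluated at that same depth. This
keeps the observed and null relatedness on the same footing: a pair can
never look unrelated merely because one member's pedigree is shallow. At
depth 2 the smallest positive relatedness is $r = 0.0625$ (a single shared
grandparent), which is why observed distributions concentrate on the classes
$\{0, 0.0625, 0.125, 0.25, 0.5\}$; values off the grid land in an `"other"`
class.

**The P-value.** The observed dataset counts as one of `n_sim` (default
1000) datasets and $P$ is the fraction with mean relatedness at least as
small as observed — one-sided, because the hypothesis is avoidance. $P$
therefore lies in $[1/n_\mathrm{sim}, 1]$ and can never be 0. Ties count
toward $P$, which makes the test conservative when the mean can only take
few distinct values (small pair sets); this is visible in the calibration
experiment below and disappears as the pair count grows.

## The synthetic population generator

`generate_founders()` + `simulate_years()` produce populations with the
statistical structure the analysis assumes, so every stage can be tested
without restricted colony data. Defaults mirror the printed founding
conditions of the motivating colony: 409 founders (183 adult females, 40
adult males, the rest immatures), several social groups, ~30 codominant
loci with 8 alleles each. Yearly steps with one birth season: each mature
female gives birth with probability `birth_prob`; sires are assigned by
*the same* category/skew machinery the avoidance null uses (this shared code
path is what makes the calibration experiment exact); offspring stay in the
mother's group; males disperse to another group at an age drawn uniformly
from 3–6 years (median 4.5); infants die with probability 0.144 in their
first year; adults face a constant annual hazard. Adult founder males are
marked as immigrants (birth group ≠ current group) so they never count as
natal; immature founder males disperse later like everyone else.

The printed record gives no birth or adult-mortality rates, so those
defaults are order-of-magnitude choices: `birth_prob = 0.65` and
`adult_mortality = 0.05` give a mature female roughly a dozen breeding
seasons and a lifetime output in the single digits, consistent with the
published lifetime means (≈7.7 offspring per female) without being fitted
to them. Genotypes are standard Mendelian gene dropping from Hardy–Weinberg
founder draws, with optional whole-genotype missingness; there is no
mutation and no genotyping error, matching the analysis's assumptions.

**Mate choice.** `mate_choice_model(theta, r_threshold)` rejects a related
candidate ($r \ge$ threshold, default 0.0625) with probability `theta`.
`theta = 0` reproduces the null scheme exactly; `theta = 1` takes the first
unrelated candidate in random pool order (uniform over the unrelated subset)
and lets the female skip the season when none exists, so no realised pair is
related at or above the threshold.

**What the generator does *not* emulate:** hurricanes and epidemics, group
fission, dominance hierarchies, mate fidelity, seasonal condition effects,
genotyping error, and real dispersal decisions (which respond to kin
presence, not a drawn age). Passing tests therefore show that the *methods*
behave correctly on data satisfying their assumptions — not that any real
population satisfies them.

## Validation experiments and their problem sizes

The test suite runs four simulation experiments, sized for desk-scale
runtime (a few minutes on one CPU):

* **Oracle equivalence:** on 20 random pedigrees of 25–40 members,
  gene-dropped $\hat F$ at $10^5$ replicates agrees with the recursion
  within $3\,\mathrm{SE}$.
* **Depth monotonicity:** on simulated populations, per-individual $F$ and
  the count of inbred individuals are non-decreasing in the depth limit, and
  full-depth $F$ equals the simulator's ground truth exactly.
* **Calibration:** one random-mating population (60 founders, 24 seasons,
  ≈90 filtered pairs); 200 replicate tests whose "observed" sire assignment
  is itself drawn from the null scheme. By exchangeability the P-value is
  uniform up to ties, and the rejection rate at $\alpha = 0.05$ must sit
  within the binomial 95% CI around 0.05. The measured rate runs slightly
  below nominal — the tie-conservativeness discussed above; it moves toward
  0.05 as the population (hence the number of distinct attainable means)
  grows.
* **Power:** 100 independent populations with strict avoidance
  (`theta = 1`; 60 founders, 22 seasons) must be rejected at
  $\alpha = 0.05$ in at least 90% of runs. In practice the observed mean is
  exactly 0 at depth 2 (every pair with $r \ge 0.0625$ was vetoed) while
  every simulated reassignment contains related pairs, so $P$ bottoms out
  at $1/n_\mathrm{sim}$.

## Numerical and degenerate-input conventions

* Ages are computed as days / 365.25; all intervals (demography group
  membership) are half-open `[start, end)`; dates are ISO-8601 only.
* Missing parents read as `NA` or `0`; a missing parent makes $F$
  *undefined* (`NA` with a warning), never silently 0.
* Date-order violations (parent born on/after offspring) warn by default
  and are errors in strict mode — colony birth dates are occasionally
  approximate, so a hard failure is opt-in.
* Parent-link cycles and sex-inconsistent parent roles are hard errors
  naming an offender.
* Kinship is memoised in an environment keyed by individual indices and
  residual depth budgets; iteration orders are deterministic, and every
  stochastic stage takes a single integer seed, so identical seeds give
  bit-identical pedigrees, genotype tables and null distributions.
* Estimator denominators of zero (all typed loci monomorphic, degenerate
  frequencies) yield `NA` with a warning, and correlation summaries are
  `NA` when fewer than two individuals have defined estimates or the
  estimates have zero variance.

## Known limitations

Pedigree $F$ captures only loops inside the recorded (and, with truncation,
the retained) generations; background relatedness among founders is assumed
away. The avoidance test detects a *difference from its null scheme*, not a
mechanism: pre-copulatory choice, post-copulatory processes and demographic
structure missing from the null are indistinguishable. The three marker
estimators summarise the same ~30-locus information and are strongly
inter-correlated; none is a precise surrogate for $F$ at this panel size.
The simulator's yearly time step assigns deaths and dispersals at season
granularity, so eligibility at a conception date inherits that resolution.
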