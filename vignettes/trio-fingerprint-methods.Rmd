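---
title: "Methods: trio fingerprint classification, MSAP methylation typing and the mid-parent U test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio fingerprint classification, MSAP methylation typing and the mid-parent U test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msaptrio)
```

# The problem

Wide (intergeneric) plant hybrids often show changes that simple
additive inheritance does not predict: parental fingerprint bands
missing from the F1, bands present in neither parent, and genome-wide
shifts in cytosine methylation — the "genomic shock" response to the
forced union of two divergent genomes. msaptrio implements the
comparative analysis that quantifies these effects from dominant-marker
fingerprints of parent–parent–hybrid trios:

1. **Inheritance classification** of AFLP / cDNA-AFLP bands into the
   eight trio presence classes, with the count and percentage tables a
   fingerprinting study reports.
2. **Methylation typing** of CCGG sites from paired MSAP lanes
   (EcoRI+HpaII vs EcoRI+MspI digests) into non-, fully- and
   hemi-methylated types.
3. **Mid-parent comparison**: a pooled two-proportion U statistic
   testing whether the hybrid's methylation level departs from the
   average of its parents.
4. A **synthetic-trio generator** that emulates the whole data layer,
   with ground truth, so every stage is testable without wet-lab data.

The package ships the observed count tables of two chrysanthemum-group
crosses (*C. nankingense* × *T. vulgare*, cross 1, and the decaploid
*C. crassum* × *Cr. chinense*, cross 2) as reference inputs
(`reference_fragment_counts()`, `reference_methylation_counts()`); the
numbered scripts under `analysis/` re-derive every reported quantity
from them.

# Band scoring and its assumptions

Dominant markers score band presence (1) or absence (0) only; a
heterozygous band carrier is indistinguishable from a homozygous one.
Two scoring rules are applied before any classification:

* **Reproducibility (strict AND).** A band counts as present for a
  biological sample only if it appears in *every* replicate lane
  (`reconcile_replicates()`). With two replicates this is exactly the
  requirement that a fragment be reproducible across both runs. AND is
  conservative: reconciled calls never exceed any single lane, a
  property the tests assert on random matrices.
* **Size window.** Only fragments of 100–500 bp are reliably sized and
  scored on these gels; `filter_by_size()` keeps the window inclusive
  on both ends and passes unsized fragments through with a warning
  (reference matrices arrive pre-filtered, so the filter is optional).

Fragment identity is row-label based: the package assumes bands have
already been aligned across samples (co-migration matching on a gel is
upstream of this analysis and no general rule exists for redoing it
from a score matrix).

# Inheritance classes

For presence bits (F, M, H) of female parent, male parent and hybrid,
the $2^3$ patterns partition into eight classes
(`classify_fragment()`): `common` (1,1,1), `female_specific` (1,0,1),
`male_specific` (0,1,1), `novel` (0,0,1), `female_loss` (1,0,0),
`male_loss` (0,1,0), `common_loss` (1,1,0) and `absent_everywhere`
(0,0,0). Two semantic choices matter:

* **Loss classes are parent-exclusive.** `female_loss` counts bands
  present *only* in the female parent and untransmitted; a band in both
  parents but not the hybrid is `common_loss`, attributable to neither
  parent alone. This is the only reading under which the reference
  tables are arithmetically consistent: with it, the partition
  identities
  $$\text{hybrid} = c + f_s + m_s + n,\quad
    \text{female} = c + c_l + f_s + f_l,\quad
    \text{male} = c + c_l + m_s + m_l$$
  reproduce every printed total of cross 1 exactly (429/355/321
  genomic, 307/259/234 cDNA). For the cross-2 cDNA table the identities
  give 273/238 where the source prints 271/236 — an internal
  inconsistency of two bands in that table; the tests pin the
  identities, which cannot be violated by construction, not the
  discrepant totals.
* **Reported loss rates** divide the single-parent loss count by that
  parent's full band total (e.g. 18/355 = 5.1% maternal, 35/321 = 10.9%
  paternal in cross 1), matching how such rates are conventionally
  quoted; `loss_rates()` returns both the fraction and the 1-decimal
  percentage.

Percentages use round-half-up to one decimal (`round(42.85)`-style
banker's rounding would disagree with conventionally reported values);
all internal arithmetic is full precision. `absent_everywhere` loci are
tallied but excluded from every denominator — they are unobservable on
a real gel and arise only in simulation.

# MSAP methylation typing

HpaII cuts CCGG only when unmethylated on both strands; MspI also cuts
when the internal cytosine is methylated. Per site and sample the
(H, M) lane bits therefore map bijectively to: type I non-methylated
(1,1), type II fully methylated (0,1), type III hemi-methylated (1,0),
absent (0,0) (`classify_site()`).

A double-absent site is excluded from that sample's denominator
(`summarize_methylation()`). This is deliberate: per-sample totals in
the reference data differ (584/572/567 and 585/572/573), which is only
possible if no-band patterns are dropped per sample. The flip side is a
known blind spot shared with the assay itself: a site hypermethylated
beyond both enzymes' tolerance is indistinguishable from a genuinely
absent site, so "absent" conflates the two. The methylation level is
$(\mathrm{II} + \mathrm{III}) / (\mathrm{I} + \mathrm{II} + \mathrm{III})$.

**Mid-parent values** (`mid_parent()`) average the two parents' *raw
counts* class by class (so half-integral counts are legitimate), not
their percentages. Averaging percentages would weight the parents
equally regardless of how many sites each yielded; averaging counts is
also the convention under which the reference U statistics reproduce
exactly, which settles the choice empirically.

# The U statistic

With mid-parent count and total $(y_1, n_1)$ and hybrid $(y_2, n_2)$,
$$p = \frac{y_1 + y_2}{n_1 + n_2},\qquad q = 1 - p,\qquad
\delta = \sqrt{pq\Big(\tfrac{1}{n_1} + \tfrac{1}{n_2}\Big)},\qquad
U = \frac{p_1 - p_2}{\delta},$$
the pooled two-sample proportion statistic, compared two-sided against
the 5% normal quantile 1.96. Numerical choices:

* **No continuity correction** — the reference values (1.36, 1.31,
  1.31, 1.06, 0.21) reproduce only without one, and the tests verify
  agreement with `prop.test(correct = FALSE)` (an independent pooled-z
  implementation) to $10^{-12}$ relative tolerance on 1,000 random
  inputs.
* **Degenerate inputs** ($p \in \{0, 1\}$, so $\delta = 0$) return an
  explicit result with `U = NA` and `degenerate = TRUE` rather than
  dividing by zero; report tables show an empty U cell.
* **No multiple-testing adjustment** across the six cross × class
  tests; they are reported as six individual 5%-level tests, matching
  how such panels are conventionally read.
* One reference value is *not* reproducible: the cross-2
  hemi-methylation comparison computes to $U \approx 0.42$ from the
  table counts (the source quotes 0.47). The package reports the
  computed value; the formula is pinned by the other five statistics
  and the independent oracle.

`compare_hybrid_to_mpv()` runs the test for total, fully and hemi
methylated counts; at the reference counts all six statistics fall
below 1.96 — the hybrids' hypomethylation is consistent in direction
but individually non-significant at these site counts.

```{r utest-example}
f <- methylation_summary(type_I = 274, type_II = 178, type_III = 132, "female")
m <- methylation_summary(type_I = 275, type_II = 164, type_III = 133, "male")
h <- methylation_summary(type_I = 292, type_II = 148, type_III = 127, "hybrid")
u_test_table(compare_hybrid_to_mpv(mid_parent(f, m), h))
```

# The synthetic-trio generator

`simulate_trio_aflp()` draws, per locus, a parental category
(band in both parents, female only, male only, neither) and then the
hybrid's band by an independent Bernoulli: shared bands fail to
transmit with probability `loss_common`, single-parent bands with
`loss_maternal` / `loss_paternal`, and parent-absent loci band de novo
with `p_novel`. There is no linkage: transmission is independent across
loci, which matches the marginal count tables the analysis consumes (no
joint information exists to calibrate anything richer). Replicate lanes
add independent per-lane dropout.

The loss parameters are **conditional** probabilities (given the
parental category) — the natural Bernoulli rates of a generative model.
The familiar reported rates are derived: with cross-1 calibration,
`loss_paternal = 35/130` of male-only bands yields the reported
35/321 = 10.9% of all paternal bands. Defaults are calibrated to
cross 1 by method-of-moments on its count tables: category frequencies
191/520, 164/520, 130/520; conditional losses 7/191, 18/164, 35/130;
`p_novel = 4/35`. The locus total 520 (so 35 never-banding loci) is a
modelling choice — the unobservable `absent_everywhere` stratum must be
given *some* size for `p_novel` to be a probability; 520 keeps the
observable scale at the reference 489 loci. `replicate_dropout`
defaults to 0 because the reference matrices are post-reproducibility
filter; it is an explicit knob for exercising the reconciliation step.

`simulate_trio_msap()` draws each parent's site state i.i.d. from
`msap_state_probs` (default: cross-1 parental means scaled by a 4%
absent fraction, i.e. roughly 600 candidate sites per ~580 scored), and
the hybrid inherits the state of a uniformly chosen parent, reverting
an inherited methylated state to type I with probability
`demethylation_shift` (default 0.076, the relative drop from 52.5% to
48.5%). Hybrid site loss is not modelled separately, so simulated
hybrid totals track the parental mean rather than dipping as the
reference hybrid's does — a known simplification.

What passing simulation tests shows, and what it does not: the
generator emulates the *statistical* structure the pipeline assumes —
independent dominant loci, per-category Bernoulli transmission,
marginal methylation states. It does not emulate co-migration
artefacts, partial digestion, linkage blocks, or scoring subjectivity,
so recovery of parameters here validates the pipeline's arithmetic and
estimators, not the wet-lab scoring process.

`recover_parameters()` closes the loop truth-free: it re-estimates
every rate from classification counts and lane-pattern tallies alone
and checks each against its exact (Clopper–Pearson) 99% interval around
the generating value; the `demethylation_shift` interval is approximate
(transformed from the hybrid proportion's interval, parental level
treated as known). The shipped checks run 60 study-scale replicates
plus one large run at $10^5$ loci / $5 \times 10^4$ sites — sizes chosen
so binomial intervals are tight (half-width $\lesssim 0.01$) while the
whole suite stays interactive.

# Determinism and reporting

Every simulation call is fully determined by the `seed` in its
parameter object; the file-writing drivers (`run_classify()`,
`run_msap()`, `run_simulate()`) stamp each output with a provenance
header (package version, config hash, seed) and are byte-identical on
re-run. The output directory is excluded from the config hash: where
results land must not change what they say.

# Known limitations

* Band identity across gels is assumed resolved upstream; no
  co-migration model.
* Dominant scoring cannot separate heterozygous from homozygous band
  presence, so "novel" bands cannot be attributed to parental
  heterozygosity versus mutation/deletion — the classification reports
  the pattern, not its cause.
* The MSAP typing inherits the assay's blindness to hypermethylation
  that blocks both isoschizomers, and to methylation context (CpG vs
  CHG) beyond the three band types.
* The U test is a large-sample normal approximation; at the reference
  site counts (~570 per line) this is unproblematic, but for small
  panels an exact test would be preferable and is out of scope.
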