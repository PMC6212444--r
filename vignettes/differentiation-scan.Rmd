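---
title: "Scanning two populations for spatially varying selection: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning two populations for spatially varying selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffscan)
```

# The problem

Two populations of *Drosophila melanogaster* sampled along an environmental
gradient — say a northern and a southern European population — share most of
their genetic variation, but loci under spatially varying selection diverge
in allele frequency faster than drift alone allows. With a few dozen
individually sequenced, passively inbred isofemale lines per population, the
practical detection strategy is an *empirical outlier scan*: estimate
per-SNP differentiation, treat the genome-wide (per-arm) distribution as the
null, and call the extreme tail candidate loci. `diffscan` implements that
scan end to end, together with the companion analyses that interpret the
outliers: functional-category enrichment against a neutral background,
gene-level scores, GO enrichment, and transposable-element differentiation.

# Models and estimators

## Weir & Cockerham variance components

Per biallelic site, with $r = 2$ populations, $n_i$ called diploid
individuals, alternate-allele frequency $p_i$ and observed heterozygote
fraction $h_i$ in population $i$, the estimator decomposes allele-frequency
variance into among-population ($a$), among-individual-within-population
($b$) and within-individual ($c$) components (`wc_components()`), and

$$\hat\theta = \frac{a}{a + b + c}.$$

Sites where $a + b + c \le 0$ (no variance: monomorphic in both samples)
are flagged unusable and logged, not silently dropped. Negative $\hat\theta$
values are *retained* in the empirical distribution — they carry information
about the null — and the global estimate over a site set is the weighted
ratio of sums $\sum a / \sum(a+b+c)$, never the mean of per-site ratios:
the mean of ratios is biased downward (about 0.08 at a true
differentiation of 0.1 with 25 + 15 strains in our simulations) while the
ratio of sums is consistent.

$\hat\theta = 1$ exactly (to floating-point rounding) when the two samples
are fixed for different alleles, and the estimator is symmetric in the
population labels; both properties are tested, as is agreement with a
literal scalar re-implementation of the component formulas to $10^{-12}$.

## The Balding–Nichols generator

The synthetic cohort draws each population's allele frequency from
$\mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$ around an
ancestral frequency $p$. Under this model the among-population variance is
$F\,p(1-p)$, so the dispersion parameter $F$ *is* the estimand of the W&C
estimator — giving the package a closed-form recovery target: a cohort
simulated at $F = 0.1$ must yield a global weighted $\hat\theta$ in
$[0.08, 0.12]$, and does, across seeds.

Key generator parameters (defaults in `sim_config()`):

* **26 + 16 strains** — the two-population inbred-line design the pipeline
  is meant for; the recovery tests also run at 25 + 15.
* **`inbreeding = 0.95`** — each strain is homozygous at a site with this
  probability, else a Hardy–Weinberg draw. Inbreeding is modelled per site
  rather than by pedigree; that is sufficient to exercise the
  heterozygosity-dependent terms ($h$, the $c$ component, pseudo-haploid
  sampling) without simulating genealogies.
* **`mean_depth = 28.6`** — Poisson total depth per call, matching the
  cohort-scale coverage such studies report; heterozygotes split reads
  $\mathrm{Binomial}(DP, 1/2)$, homozygotes put all reads on the carried
  allele.
* **Five arms (2L, 2R, 3L, 3R, X) of 1.2 Mb, 10,000 SNPs, 1,000 genes** —
  a desk-scale genome. The gene count matters: the per-arm rank
  inverse-normal Z is bounded by $\Phi^{-1}((n_{\text{arm}}-0.5)/n_{\text{arm}})$,
  and with only ~100 genes per arm a SNP-count bin whose median Z is high
  can *never* reach the genome-wide candidate cut — an artifact of small
  cohorts, not of the method. At ~200 genes per arm the cap (≈ 2.8) sits
  comfortably above the cut.
* **Planted selected loci** (`selected_F = 0.6`, fraction 0.002, clusters
  of 3). A "selected" locus must be *realizedly* divergent, not just
  divergent in expectation: unconditioned Beta draws at $F = 0.6$ leave
  ~1/3 of sites with modest realized divergence (both populations can draw
  the same tail of a U-shaped Beta), which no scan could or should flag.
  Selected frequencies are therefore accepted only when
  $(p_1-p_2)^2 / (2\bar p(1-\bar p)) \ge F$ with pooled frequency in
  $[0.1, 0.9]$ (so planted loci are not removed by the MAF filter by
  construction). Loci are planted as clusters of three adjacent SNPs — the
  multi-SNP footprint a sweep leaves — so gene-level recovery measures the
  sweep signal rather than a single binomial draw.
* **Inversion region** with planted carrier strains (rounded to whole
  strains, so the marker-based frequency estimate has an exact target) and
  a mild dispersion multiplier (1.3) for neutral sites inside it, giving
  the Mann–Whitney inside/outside contrast a signal.
* **TE table** with planted classes: 55 % fixed in both populations, 30 %
  rare, 2 % missing-data-heavy (an exact 40 % of strains uncalled, safely
  past the 30 % undetermined rule), 2 selected (conditioned divergence as
  above), remainder segregating at the baseline F.

What the generator does **not** emulate: linkage disequilibrium beyond the
3-SNP selected clusters (sites are otherwise independent), mutation-rate or
recombination-rate heterogeneity, reference bias and mapping artifacts,
real demographic history (bottlenecks, admixture), and sequencing error in
genotype calls. Passing tests on this cohort therefore demonstrate that the
estimators and rules are implemented correctly and recover planted truth
under the stated statistical model — not that the pipeline is robust to
every pathology of real resequencing data.

# Filtering

Filters run in a fixed order (euchromatin inclusion → repeat exclusion →
indel proximity → biallelic SNV → non-singleton → genotype coverage QC →
call rate → pooled MAF), each stage logged with in/out counts; filtering is
idempotent. Boundary conventions, chosen once and tested at the boundary:

* "coverage lower than 10×" reads as $DP < 10$ (a call at exactly 10 is
  kept); the per-strain upper threshold is the 0.975 *nearest-rank*
  quantile of that strain's depths, kept at equality.
* "within 5 bp of an indel" reads as distance ≤ 5 from the indel's affected
  span: a SNP 5 bp away is removed, 6 bp away is kept.
* A singleton is a site whose minor allele occurs in exactly one allele
  copy.
* Pooled MAF is computed over both focal populations combined, missing
  calls excluded from numerator and denominator; a site at exactly 5 % is
  kept. A per-population mode (`maf_scope = "per_population"`: keep sites
  reaching the MAF floor in at least one focal population) is available but
  off by default. The genotyping rate is computed over all strains of the
  two focal populations — the natural choice when the scan is run on the
  two-population cohort.
* VCF coordinates are 1-based inclusive, BED 0-based half-open; all
  internal coordinates are 1-based inclusive with converters at the I/O
  boundary. The euchromatin bounds of the reference arms ship as the
  default inclusion mask.

# Outlier tiers and the inversion contrast

Tiers are defined by *rank*: per arm, tail $t$ holds exactly
$\lfloor t\,n_{\text{arm}}\rfloor$ top sites (ties broken by genomic
position, earlier first), and the tier's critical value is the smallest
$\hat\theta$ inside it. Rank-based tiers are exactly reproducible and make
the candidate arithmetic exact — 13,140 scored genes give exactly 657
top-5 % candidates. The default tails are 5 % / 1 % / 0.5 %.

Arm heterogeneity is tested by one-way ANOVA on raw $\hat\theta$ (no
transformation). The inversion contrast compares $\hat\theta$ inside a
region against the rest of the same arm with a two-sided Mann–Whitney U
test (exact for small tie-free samples, normal approximation with tie
correction otherwise) and additionally emits per-tier inside/outside 2×2
tables. Inversion frequency is the mean across marker SNPs of the
tagging-allele frequency.

# Functional categories and stratified enrichment

Each SNP receives exactly one category by precedence: coding >
splice site (the two intronic bases at each intron end) > 5′ UTR > 3′ UTR >
intron > core promoter (TSS−1..−316, strand-aware) > promoter
(TSS−317..−1000) > intergenic. Within introns, positions 8–30 from the 5′
end (transcribed strand) of introns ≤ 65 bp form the near-neutral
`small_intron_bg` class — the canonical neutral reference in *Drosophila* —
and all other intronic positions are `intron_other`. Coding SNPs are
translated against the CDS (standard genetic code, reverse-complemented for
minus-strand genes); a reference allele that contradicts the CDS base makes
the codon unresolvable, which is reported rather than guessed. When a SNP
touches several genes, the highest-precedence call wins.

Enrichment of a category's SNPs in an outlier tier, against the small-intron
background, controls for pooled-MAF bin × arm × inversion status by
combining the per-stratum 2×2 tables with the Cochran–Mantel–Haenszel
common-odds-ratio test; the unstratified two-sided Fisher test is reported
alongside. The default MAF binning is *quintiles*: with the background
class holding ~50–100 SNPs at this scale, decile strata leave 0–2
background sites each and the asymptotic CMH test miscalibrates (its null
p-values fail a uniformity check); quintile strata restore calibration
(null KS p ≈ 0.17 over 50 replicates) while still absorbing the MAF and
arm structure. `maf_bins` is an argument, so decile strata remain available
where the background is richer.

# Gene scores

A gene's statistic is the *maximum* $\hat\theta$ over SNPs in its
transcript plus the strand-aware 1 kb upstream window (a SNP may serve
several overlapping genes; zero-SNP genes are excluded and listed).
"Normalising to a Z score using the chromosome-specific empirical
distribution" is implemented as the rank-based inverse-normal transform
$Z = \Phi^{-1}((\text{rank} - 0.5)/n)$ with average ranks for ties: the
max-F statistic is strongly skewed, and only the rank transform makes the
resulting scores approximately normal; a mean/sd standardisation mode is
available behind a flag.

Because a maximum over more SNPs is stochastically larger, Z correlates
with SNP count (Spearman ≈ 0.5 on the default cohort). Genes are sorted by
SNP count into 16 equal-occupancy bins — ties at a boundary stay together —
and $Z_{ST} = Z - \mathrm{median}(Z\,|\,\text{bin})$. Median centring only:
no dispersion rescaling is applied, keeping the correction minimal and
monotone within bins. The corrected score's correlation with SNP count
collapses (|Spearman| < 0.05). Candidates are the genome-wide (not per-arm)
top $\lfloor 0.05\,N\rfloor$ by $Z_{ST}$, ties at the cut broken by gene id
and flagged.

# GO enrichment

The ontology layer is deliberately self-contained: an OBO 1.2 parser
(`[Term]` stanzas, `is_a` edges, obsolete terms dropped with a warning,
cycles rejected), true-path propagation of gene annotations, and three
tests — classic one-sided Fisher (terms with ≥ 5 candidate genes),
a one-sided two-sample KS on gene scores (alternative: the term's scores
are stochastically larger; terms with ≥ 5 scored genes), and *elim*.
`elim` walks the DAG bottom-up (children strictly before parents, term-id
tie-break), tests each term on its current gene set, and when a term's p
falls below the cutoff (default 0.01, the conventional choice) removes its
originally annotated genes from all ancestors before those are tested.
Raw elim p-values are treated as final — the algorithm itself suppresses
the topological redundancy that multiple-testing corrections would
otherwise have to absorb. The weight/weight01 variants are out of scope.
For the KS test the ≥ 5 rule is applied to annotated scored genes (the
Fisher rule "5 or more differentiated genes" has no direct analogue for a
score-based test).

# Transposable elements

Presence/absence calls per strain are classified per population frequency
(presence count / called strains): `undetermined` when either population
has > 30 % missing calls (the threshold is a package choice; the upstream
caller's own failure rule is not numerically specified anywhere),
`fixed_both` at frequency exactly 1 in both, `low_freq_both` below 5 % in
both, else `testable`. Testable TEs are encoded as homozygous diploid
loci (present = 1/1, absent = 0/0) — consistent with inbred strains — and
scored by the same W&C code path (equality is asserted exactly in tests).
Candidates are TEs whose $\hat\theta$ reaches the SNP-derived per-arm
critical values, so the sparse TE set borrows its null from the rich SNP
distribution.

# Diversity

Per-site nucleotide diversity is the unbiased pair count
$c_{\text{ref}}c_{\text{alt}}/\binom{n}{2}$, summed over non-overlapping
windows of a fixed *SNP count* (default 10,000; the trailing partial
window is flagged). Both per-bp (window span denominator) and per-SNP means
are reported, since either convention is found in practice. The
pseudo-haploid estimator redraws one allele per strain per site with
probability proportional to the allelic read depths (uniform over the two
genotype alleles when depths are unusable, with a fallback count reported) —
the guard against isofemale strains contributing more or fewer than two
effective alleles. Note that haploidising *changes the sample size* $n$ in
$\binom{n}{2}$, so pseudo-haploid and diploid π agree only asymptotically
even on fully inbred data; the invariant actually guaranteed, and tested,
is that allele *frequencies* are preserved exactly when every call is
homozygous.

# Numerical and degenerate-input conventions

* Nearest-rank quantiles everywhere a percentile is taken (exact
  reproducibility, no interpolation).
* Ties: by genomic position in outlier ranking; average ranks in the
  inverse-normal transform; same-bin retention in SNP-count binning; gene
  id at the candidate cut; term id in DAG traversal order.
* Single-gene arms get Z = 0 with a warning; fewer genes than bins
  collapses bins with a warning; arms with too few sites for the smallest
  tail are skipped with a warning.
* An empty filter output is legal — the log shows where sites died.
* Seeds: every stochastic step (cohort generation, pseudo-haploid
  sampling) takes an explicit seed; fixed seed means byte-identical output
  files.

# Problem sizes used by the test-suite and acceptance script

The shipped validation runs use the default cohort (10,000 SNPs, 42
strains, 1,000 genes), 5 × 10,000-site cohorts for parameter recovery,
3 seeds pooled for sensitivity rates (per-seed planted-gene counts are
single digits, too few for a stable rate), and 50 replicates of a reduced
null cohort (4,000 SNPs, 3 arms, 300 genes) for calibration checks —
sizes chosen so the whole suite completes in a few minutes on one core
while every check retains adequate resolution.

# Known limitations

* Independent sites: no LD-aware null, so the empirical tails are slightly
  tighter than they would be on autocorrelated real data.
* The enrichment CMH is asymptotic; with very sparse background classes it
  should be re-run with coarser strata (or the reported plain Fisher used).
* Gene models are single-transcript; multi-isoform precedence conflicts are
  resolved by the canonical (first) transcript.
* The scan is two-population by design; $r > 2$ would need the general
  W&C components.
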