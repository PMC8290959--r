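---
title: "Detecting domestication sweeps and haplotype-group trait effects with haplosweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting domestication sweeps and haplotype-group trait effects with haplosweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplosweep)
library(dplyr)
```

## The analysis this package implements

Crop domestication leaves a characteristic footprint at selected loci:
cultivated accessions lose nucleotide diversity around the selected gene,
differentiate sharply from their wild relatives, and carry unusually long
stretches of haplotype homozygosity. `haplosweep` implements the standard
three-statistic scan for such footprints in a panel of re-sequenced
accessions partitioned into wild (S), landrace (L) and improved cultivar
(C) subpopulations, followed by a gene-level haplotype analysis of any
candidate region:

1. **Windowed nucleotide diversity** $\pi$ per subpopulation, the wild /
   cultivar diversity ratio, and the **Hudson estimator of $F_{ST}$**
   between wild and cultivar, in sliding windows along the chromosome.
2. **XP-EHH**: the log ratio of the integrated extended-haplotype
   homozygosity (iHH) of the two populations at every common variant,
   z-normalized genome-wide.
3. **Empirical outlier thresholds** (top 5% of the genome per statistic)
   and a **multi-statistic sweep caller** that merges windows exceeding
   thresholds in at least `min_support` statistics into candidate regions,
   annotated against gene/QTL intervals.
4. **Gene-region haplotyping** under a minor-allele-frequency filter
   (variants with MAF < 0.01 removed), a **median-joining network** of the
   distinct haplotypes, and **major-group assignment** (H_I, H_II, H_III,
   labelled by wild-enrichment) by cutting the network's longest links.
5. **Haplotype-frequency shifts** between subpopulations (two-proportion
   z-tests) and **trait association**: per-group summaries of 100-seed
   weight (g), fatty-acid content (% DW) and protein content (% DW), all
   pairwise Student's t-tests, and a compact letter display.

A forward-in-time Wright–Fisher simulator of the whole domestication
scenario makes every stage testable against known truth without external
data.

## Statistical definitions and conventions

**Per-site diversity.** With $k$ alternate alleles among $n$ non-missing
chromosomes, $\pi_{site} = 2k(n-k) / (n(n-1))$, the mean pairwise
difference. A window's value is the sum over its sites divided by the full
window span in bp (monomorphic sites contribute zero; the simulator has no
inaccessible reference regions, so the span needs no accessibility
correction). Windows covering fewer cohort-variant sites than
`min_sites_per_window` (default 3) are reported as `NaN`: the gate guards
against data-sparse windows. A well-covered window that is monomorphic
*within one population* legitimately reports $\pi = 0$ — that is the sweep
signal itself — which is why the gate counts the cohort's variant sites
rather than sites segregating within the population.

**Diversity ratio.** $\pi_S / \pi_C$ per window; `NaN` when $\pi_C = 0$
(guarded division) or either input is `NaN`. High values mean diversity
lost in cultivars.

**Hudson $F_{ST}$.** Per site, numerator
$(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)$ and denominator
$p_1(1-p_2) + p_2(1-p_1)$; windows use the ratio of summed numerators to
summed denominators (Bhatia's "ratio of averages"), which is robust to
unequal sample sizes. Reported values are clipped to $[0,1]$ with the raw
ratio kept in a `raw` column.

**EHH and iHH.** EHH at an extent is the probability that two random
chromosomes of the population are identical over the sites between the
core and the extent (the core site itself does not partition, so EHH at
distance zero is 1). iHH is the trapezoid integral of the EHH curve over
physical distance, left plus right flank, truncated where EHH first drops
below `ehh_truncation` (default 0.05) or where adjacent sites are more
than `max_gap_bp` (default 200 kb) apart. Physical distance is used
throughout — no genetic map exists for the synthetic chromosome and none
is assumed for real input. When a flank reaches the chromosome edge before
truncation the default policy is to keep the partial integral and count
the clip (`edge_policy = "clip"`); `"discard"` yields `NaN`. Raw XP-EHH is
$\ln \mathrm{iHH}_C - \ln \mathrm{iHH}_S$ (computed as a difference of
logs so that swapping populations negates the score exactly); cores are
all sites with pooled MAF ≥ 0.05, and normalization subtracts the
genome-wide mean and divides by the population (divide-by-N) standard
deviation. Windowed XP-EHH is the maximum normalized score among a
window's cores.

**Thresholds and calling.** The genome-wide threshold of a statistic is
the $\lceil q W \rceil$-th smallest of its $W$ finite window values
(default $q = 0.95$); a window is flagged only when *strictly* above the
threshold, so a tie-free track with $W$ divisible by $1/(1-q)$ flags
exactly $(1-q)W$ windows. Windows flagged by at least `min_support`
statistics merge into regions when their starts are within
`step + merge_gap_bp`; `NaN` windows never flag and (at the default
`merge_gap_bp = 0`) break merges. The default `min_support = 3` demands
coincident evidence from all three statistics; sweep-recovery experiments
use 2 because the three statistics peak on slightly different parts of a
sweep at simulation scale. If a track has too few finite windows for a
genome-wide threshold (the π-ratio track can be sparse when the cultivar
panel is largely monomorphic), that statistic is dropped from flagging
with a warning rather than aborting the caller.

**Median-joining network.** Observed haplotypes are compared by Hamming
distance (SNPs and In/Dels count equally as single steps). The network
starts from the minimum-spanning network (all links participating in some
minimum spanning tree, with tolerance `epsilon`, default 0); for every
pair of links sharing a node the coordinate-wise majority vector of the
three haplotypes is added as an inferred median when doing so reduces the
total connection cost (the MST weight of the node set); this repeats to a
fixed point, then medians of degree ≤ 1 are pruned. Ties are broken by
lexicographic allele string, so a fixed input order gives a bit-identical
network. Major groups are connected components after removing links of
weight ≥ a cutoff; `target_k` chooses the smallest cutoff that yields
exactly *k* groups of observed haplotypes. Groups are labelled H_I, H_II,
… by descending wild-chromosome count, so H_I reads as the wild group.

**Haplotype modes.** The default `"chromosome"` mode counts every phased
chromosome. The `"accession"` mode counts only accessions homozygous
across the retained sites (twice each) and tallies excluded
heterozygotes; it exists because highly selfing crop panels are usually
tabulated by accession and near-homozygosity makes the loss small. The
same homozygosity rule maps accessions to groups for trait association;
heterozygous accessions are excluded and tallied rather than guessed.

**Trait tests.** Pooled-variance Student's t by default (`welch = TRUE`
for the unequal-variance form), per-pair $\alpha$ with no multiple-testing
correction by default (a Bonferroni flag exists) — matching how such
panels are conventionally reported. Zero pooled variance is handled
explicitly: $p = 1$ for equal means, $p = 0$ (with a warning) otherwise.
The compact letter display assigns letters so two groups share a letter
exactly when their pairwise $p \ge \alpha$, with groups ordered by
descending mean so `a` marks the top cluster; for up to 12 groups the
assignment is an exact minimum clique cover of the non-significance graph
(provably the fewest letters), with the classic insert-and-absorb
procedure as the fallback beyond that.

## The synthetic domestication cohort

`simulate_domestication()` runs a discrete-generation Wright–Fisher model
with selfing:

* a wild population of `n_ancestral = 500` diploids evolves neutrally for
  the whole simulation (`t_total = 150` generations);
* at `t_split = 50` a bottleneck of `n_bottleneck = 50` founders starts
  the domesticated lineage; the founding is near-instantaneous
  (`t_subsplit = t_split + 3`), after which the lineage splits into
  landrace and cultivar populations of 1000 diploids each;
* fitness at the focal site is additive (1, 1+s/2, 1+s) in the
  domesticated lineage only — artificial selection — with `s = 0.1` by
  default; the wild lineage is always neutral;
* each offspring is produced by selfing with probability 0.95 (soybean is
  a predominant selfer), recombination happens with probability
  `r = 2e-3` per adjacent-site interval, and mutation flips alleles with
  probability `1e-5` per site per generation (sites stay biallelic);
* standing variation: 80% of the 2000 evenly spaced sites on the 1-Mb
  chromosome start polymorphic at uniform(0.05, 0.95) frequencies —
  variation ascertained as common in a diversity panel;
* the adaptive haplotype enters at the founding as 15% of founder
  chromosomes, all copies of a single founder chromosome (one favoured
  plant multiplied at the onset of domestication, i.e. a hard sweep), and
  carries private derived alleles at the focal site and the 9 nearest
  sites — ten clustered gene-region variants distinguishing the
  cultivar haplotype from all wild haplotypes;
* finally 60/80/60 accessions are sampled from wild/landrace/cultivar,
  and seed traits are generated per accession from its focal-allele
  dosage (0/1/2 copies define truth groups H_I/H_II/H_III):
  `baseline + group effect + Gaussian noise`, with defaults that raise
  100-seed weight (+4 g per step, sd 2) and fatty acid (+2% DW, sd 1.5)
  and lower protein (−2% DW, sd 1.5) from H_I to H_III.

These demographic settings are a deliberate desk-scale calibration, chosen
once by measuring the full scan under neutral and selected conditions.
Two constraints shape them. First, drift must not mimic selection: with
95% selfing the effective size is roughly halved, so divergence times must
stay well below the coalescent scale of the smallest population or
genome-wide drift fixation produces $F_{ST}$ outliers indistinguishable
from sweeps; that rules out long bottlenecks and small post-split sizes.
Second, the selected allele must usually fix within the simulated time at
$s = 0.1$. The chosen configuration keeps the neutral genome-wide
$F_{ST}$ moderate, retains cultivar background diversity for the π-ratio
denominator, lets the sweep complete, and runs in about a second per
replicate. At these settings the focal position falls inside a called
region (`min_support = 2`) in roughly 90% of selection replicates and
essentially never in neutral ones.

**What the generator does and does not emulate.** It reproduces the
qualitative structure of a domestication panel — subpopulation
differentiation, selfing-driven homozygosity, a hard sweep with a private
cultivar haplotype, group-separable seed traits. It does not model real
soybean demography (effective sizes, bottleneck intensity and ages are not
calibrated to the species), recombination-map heterogeneity, multiple
chromosomes, polygenic trait architecture, genotype-by-environment
effects, or ascertainment bias of real variant calling. Passing tests on
synthetic cohorts therefore demonstrate the *correctness of the
statistical machinery* and its power under a controlled hard-sweep
scenario, not expected power on any particular real data set.

## Degenerate inputs and numerical choices

* Missing genotypes: frequencies and MAF use non-missing chromosome
  counts; chromosomes hitting a missing allele inside an EHH span leave
  the computation with the denominator decremented. No imputation.
* Unphased heterozygotes mark the whole matrix unphased; EHH-based
  statistics refuse unphased input. Unphased homozygotes are accepted
  (phase is unambiguous).
* $F_{ST}$ windows with a zero denominator sum are `NaN`; negative raw
  ratios are floored at 0 in the clipped output only.
* Normalization of XP-EHH errors on constant scores rather than emitting
  zeros.
* All coordinates are 1-based inclusive at VCF ingestion and 0-based
  half-open everywhere else (windows, BED, regions).
* Every stochastic step flows from a single integer seed; the pipeline
  derives one substream per stage (`seed + stage index`) so stages are
  individually rerunnable yet jointly deterministic, and the run manifest
  records md5 checksums of every artifact.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- run_config(out_dir = "sweep_run", min_support = 2, seed = 1)
res <- run_pipeline(cfg)

res$regions          # called sweep regions with per-statistic peaks
res$hap_table        # gene-region haplotypes with S/L/C counts
res$shift            # wild-vs-cultivar frequency shift per major group
glance(res$association)  # one row per trait
autoplot(res$association)
```

Problem sizes throughout the package's own test suite and reproduction
script are the generator defaults above (2000 sites on 1 Mb, 200 sampled
accessions, 20 replicates per condition), which keep a full run in
minutes on a single core.

## Known limitations

* XP-EHH has limited power in heavily selfing panels at this scale: long
  background homozygosity means the 0.05 truncation is often reached only
  near the chromosome edge, compressing the contrast between swept and
  neutral regions. The scan reports it faithfully; region calling in
  practice leans on $F_{ST}$ and the π-ratio, which is why coincidence of
  two statistics (not three) is the recommended recovery setting.
* The π-ratio is undefined (`NaN`) exactly where a completed sweep leaves
  the cultivar window monomorphic; the caller treats such windows as
  non-flagging rather than inventing a value.
* The median-joining search adds one best median per iteration and stops
  when no candidate lowers the connection cost; with `epsilon > 0` the
  feasible-link set grows but the same greedy rule applies. This is the
  standard construction for gene-scale haplotype sets (tens of
  haplotypes), not a phylogenetics replacement.
* `target_k` grouping is a deterministic stand-in for the judgment call a
  human makes when partitioning a published network figure; for loci
  whose haplotypes do not separate into distance-delimited clusters the
  achievable component counts are reported in the error message.
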