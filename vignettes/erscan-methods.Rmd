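---
title: "Models and methods behind erscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind erscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`erscan` analyses replicated evolve-and-resequence (E&R) experiments
sequenced as pools. This vignette is the package's own account of the
models it implements, the parameters that matter, the choices made where
the design was genuinely open, and what the test suite does and does not
establish about real data.

## The inference problem

Each sequenced population is a pool: at a biallelic SNP the minor-allele
read count is approximately `Binomial(coverage, p)` around the population
frequency `p`. Between two time points, `p` moves for three reasons —
genetic drift, the two sampling layers (pool and reads), and, at selected
loci, selection. The scan must find alleles whose movement is consistent
across replicates and larger than drift plus sampling can explain.

The chain is: mask and call SNPs → per-SNP Cochran–Mantel–Haenszel (CMH)
test between two time points → re-simulate the whole experiment under
neutral drift, coverage-matched, and push the simulations through the same
filters and test → use the simulated p-value distribution to set
thresholds and estimate an empirical false discovery rate → characterize
the surviving candidates (trajectory shape, fixation, enrichment).

## SNP calling

Counts arrive in the sync text convention (`A:T:C:G:N:del` per
population). Masks remove repeat annotations, indel neighborhoods (an
indel supported by ≥ 2 reads in any population masks ± 5 bp) and manually
excluded regions; masks are held as reduced `GRanges`, the Bioconductor
interval container, so BED (0-based half-open) and GFF (1-based closed)
inputs are converted exactly once, at import.

A site is called when exactly two of A/C/G/T carry reads, or when the
third-ranked allele has ≤ 2 reads in total, in which case it is zeroed as
sequencing noise; anything stronger drops the site, keeping every
downstream table strictly 2×2×k. The three quality filters: the minor
allele needs ≥ 1 read in at least `min_populations_detected = 2`
populations, ≥ `min_minor_total = 10` reads summed over all populations,
and every population's coverage must stay ≤ `max_coverage = 500` (applied
per population: a single outlier pool signals CNV or paralogy). The minor
allele is defined on counts summed over all populations, ties broken
alphabetically, so its identity cannot flip between time points.

Windowed diversity (`window_pi()`) uses the unbiased per-site
heterozygosity `n/(n−1)·(1 − Σ f²)` with `n` the A+C+G+T read depth,
averaged over genotyped sites per 10-kb window. This treats reads as
sampled chromosomes; it omits the pool-size correction of the full
Pool-Seq diversity estimators and is intended for relative,
along-the-genome comparisons, not absolute estimates.

## The CMH scan

For a SNP and a contrast of two time points, each replicate contributes a
2×2 stratum (rows: minor/major reads, columns: the two time points). The
statistic is

    X² = ( |Σₖ (aₖ − Eₖ)| − c )² / Σₖ Vₖ ,

with `aₖ` the minor count at the first time point, `Eₖ` and `Vₖ` the
stratum's hypergeometric mean and variance, referred to χ²₁. The
continuity correction `c` defaults to off — Pool-Seq counts are large and
the asymptotic reference is used; when enabled it follows the standard
rule of applying the 0.5 only when `|Σ(aₖ−Eₖ)| ≥ 0.5`, which keeps the
result identical to `stats::mantelhaen.test`. Replicates with zero
coverage at either time point are dropped per SNP (`k_used` records the
remainder); a SNP monomorphic in all used populations reports `NA`.

The sampling unit of the table is the read, not the chromosome. That is
deliberate: the resulting pseudo-replication (drift is invisible to the
read-level variance `Vₖ`) is absorbed by the simulation-based null, not by
rescaling counts.

## The drift null and the empirical FDR

`simulate_null_experiment()` rebuilds the experiment under neutrality:
starting from the base-population frequencies (taken jointly with their
per-SNP coverage vectors, so the coverage–frequency correlation of the
real data survives), each replicate's frequency is propagated by the
haploid Wright–Fisher recursion `p_{t+1} = Binomial(N, p_t)/N` through its
own generation schedule (e.g. 15/15/23 to the middle time point, 37 to the
end), sharing the lineage within a replicate across time points. Reads are
then drawn binomially at matched (or parametric) coverages, the calling
filters re-applied, and the CMH scan re-run.

A drifting null makes the read-level CMH p-values strongly
anticonservative: over `t` generations drift adds variance
`p(1−p)(1−(1−1/N)^t)` — at `N = 200`, `t = 15` about 1.7× the read-sampling
variance at 47× coverage — so the null statistic is overdispersed roughly
2.7-fold and its p-values pile up near zero. Only with drift switched off
(the `N → ∞` limit, or comparing two samples of the same generation) are
the p-values uniform; the test suite checks exactly that dichotomy. This
overdispersion is the entire reason the thresholds come from simulation:

* `empirical_threshold()` — the highest p-value of the top `top_fraction`
  (default 1e-5) of simulated SNPs, i.e. the clamped
  `⌈top_fraction·n⌉`-th order statistic;
* `empirical_fdr()` — `fdr = n_sim_below · (n_exp/n_sim) / max(n_exp_below, 1)`,
  the drift-only discoveries rescaled to the experimental SNP count over
  the experimental discoveries. Ties at the threshold count as below,
  which can only inflate the FDR (conservative);
* `fdr_top_n()` — the same with the threshold at the n-th smallest
  experimental p-value (candidate sets of fixed size, default 2000).

Calibration is validated by running an independent equal-size null as the
"experimental" data: tail fractions match their nominal levels and the
top-2000 FDR lands near 1.

Randomness uses R's global Mersenne–Twister generator with a recorded
seed: identical seed and configuration reproduce every table exactly. No
per-SNP parallel substreams are provided; the simulations are vectorized
across SNPs instead.

## Temporal Ne

`temporal_f()` computes the standardized variance of allele-frequency
change, `Fc = (x−y)²/(z(1−z))` with `z = (x+y)/2`, aggregated in the
ratio-of-means form `ΣΔ²/Σ z(1−z)` (lower variance at extreme frequencies
than averaging per-SNP ratios). Two-stage sampling noise is subtracted
with the effective chromosome-sample size `S = n_pool·cov/(n_pool + cov)`
— the harmonic composition of pool (2 × 500 chromosomes) and read
sampling — averaged with the same `z(1−z)` weights, and the drift
component is inverted:

    Ne = t / F_drift          (haploid, default)
    Ne = t / (2 F_drift)      (ploidy = "diploid")

The haploid scaling is the default because it is the inverse of the
package's own drift engine: the simulator drifts `N` chromosomes per
generation, so the estimator must return that same `N` on simulated data
(the classical diploid form, which counts generations in units of `2Ne`
chromosomes, returns `N/2` there; it is available via `ploidy`). A
non-positive drift component (sampling noise explains everything) returns
an `Inf` sentinel rather than a negative size. Confidence intervals are
bootstrap percentile intervals over SNPs. Sampling is treated as
non-destructive relative to the breeders (plan II); no census-size term is
subtracted. Estimation uses intermediate-frequency SNPs
(`simulate_temporal_sample()` draws p₀ ~ U(0.1, 0.9)); alleles near the
boundaries carry little drift signal and destabilize the denominator.

## Trajectories

Candidates (default: the 2000 smallest p-values, ties broken by position)
are oriented to their selected allele — the one whose replicate-mean
change over the identification contrast is positive; exact zero keeps the
minor allele, and replicates disagreeing in sign are flagged. Per-interval
allele-frequency change (AFC) telescopes exactly:
`AFC(B→M) + AFC(M→E) = AFC(B→E)` per replicate.

Classification uses the replicate-mean rise `AFC(B→M)` and late change
`AFC(M→E)`:

* **plateau** — `rise ≥ rise_min` and `|late| ≤ flat_max`;
* **continuous** — `rise ≥ rise_min/2` and `late ≥ flat_max`;
* **other** — the rest. Plateau wins on the boundary, so the three labels
  partition the set.

The automatic thresholds are the median candidate rise (`rise_min`) and
the 95th percentile of the absolute late change of drift-simulated SNPs
(`flat_max`) — a genuinely flat trajectory must stay inside the drift
envelope, and both the envelope and the data summaries use replicate
means so they live on the same scale. Fixation is reported at both
conventions in use (frequency ≥ 0.99, and > 0.90), from replicate-mean
frequencies by default with a per-replicate alternative.

`flanking_decay()` stacks 100-bp (or any width) windows around the
candidates, excluding the candidates themselves, and reports the median
base-to-final AFC per distance bin, plus a parallel curve for
position-adjusted controls shifted 500 kb upstream — elevation at small
distances can then only come from linked flanking SNPs.

## Enrichment

The annotator evaluates every SNP against every overlapping transcript:
coding positions are classified synonymous/non-synonymous by substituting
both alleles into the codon (strand-aware, via the standard genetic code),
UTR positions as `utr5`/`utr3`, other intragenic positions as introns, and
positions within 200 bp of the transcript ends as upstream/downstream by
strand. A SNP with no transcript relation is intergenic — exclusive of
all other labels, while a SNP may carry several labels from overlapping
genes or isoforms, each counted separately. Feature and region
over/under-representation use the Pearson chi-square (1 df) of candidates
vs non-candidates against carrying vs not carrying the label, each
feature tested against its own complement.

GO enrichment must not be done at the gene level: long genes hold more
SNPs, hence collect more false-positive candidates, and any gene-level
test then favours categories of long genes. The permutation test redraws
SNPs uniformly without replacement until the induced gene set (gene span
± 200 bp, consistent with the upstream/downstream rule) matches the
observed candidate gene count, and records per-category gene hits;
`p = (1 + #{perm ≥ obs}) / (1 + n_perm)`, bounded below by
`1/(1+n_perm)`. The default `n_perm = 1e5` keeps desk-scale runs fast
(the p-value floor is reported; raise it when smaller floors are needed).
Benjamini–Hochberg and a permutation-ensemble FDR are both reported, the
latter estimating, at each observed p-value, the expected number of
categories reaching it under the null. A naive gene-level Fisher test
(`go_fisher_test()`) is included purely as the biased baseline for
comparison.

## The synthetic generator

`generate_experiment()` is first-class, tested code, not a fixture. It
emulates: a base population of unlinked biallelic SNPs with a folded
neutral site-frequency spectrum (allele count weight ∝ 1/i in a notional
100-chromosome sample; a Beta spectrum is available); three replicates
drifting at haploid `Ne = 200` through the generation schedule B = 0,
M = 15/15/23, (optional 27), E = 37; per-SNP per-population coverage
uniform on {30..64}; and planted selected loci with starting frequencies
U(0.05, 0.2).

Selection acts deterministically before each binomial drift draw, the
standard discretization:

* **additive** — genic selection, fitness `1 + s` per copy of the selected
  allele (genotypes `1+2s : 1+2hs : 1`, `h = 0.5` by default). The
  per-copy convention is chosen deliberately: it matches the haploid drift
  engine's per-generation time scale, so `s` means the same thing in the
  selection and drift halves of the model, and an `s = 0.1` allele rises
  from ~0.1 to ~0.85 over 37 generations — a realistic strong E&R
  response. Under the alternative convention (heterozygote effect `hs`,
  homozygote `s`) the same nominal `s` produces half the logit slope and
  plateaus near 0.46 by generation 37.
* **overdominant** — both homozygotes penalized, `1−s1 : 1 : 1−s2`,
  maintaining the allele at `p̂ = s2/(s1+s2)`. Defaults `s1 = 0.3`,
  `s2 = 0.45` give `p̂ = 0.6`, reached from p₀ ≤ 0.2 before generation
  15 — the mechanism used to plant plateauing trajectories that stop at
  intermediate frequency, the hallmark the plateau class is meant to
  capture. Balancing this strong is a modelling device for trajectory
  shape, not a claim about typical fly loci.

The diploid fitness step over a haploid drift kernel is a documented
hybrid: the generator's purpose is controllable trajectory shapes with
exact ground truth, not full population-genetic realism. Loci are
unlinked — there is no haplotype structure, no recombination, no new
mutation during the experiment, no demographic change. Consequently,
passing recovery tests shows the statistical chain works when SNPs are
independent; it says nothing about linked sweeps, hitchhiking, or
inversion-scale structure in real data, where candidate counts can be
inflated by linkage.

## Numerical choices and degenerate inputs

* CMH strata with an empty margin are skipped; if all strata are
  degenerate the SNP reports `NA` rather than 0.
* `empirical_threshold` clamps to the smallest simulated p-value when the
  requested fraction selects less than one SNP.
* Threshold ties count as discoveries in both numerator sets (inclusive
  `≤`), inflating, never deflating, the FDR.
* Tie-breaks are deterministic everywhere: alleles alphabetically,
  candidates by (p, chrom, pos).
* `estimate_ne` returns `Inf` (not an error) when no drift is detectable;
  bootstrap intervals may include `Inf`.
* Stratified subsampling uses largest-remainder rounding, so per-arm
  counts are within one of exact proportionality.

## Problem sizes in the test suite

The suite validates at sizes chosen to keep a full run within minutes on
one core while leaving Monte-Carlo error well below the tested margins:
drift-moment and read-sampling checks at 10⁵ draws; null-calibration runs
at 10⁵ SNPs; Ne recovery as 100 replicate estimates of 1000 SNPs at each
of three true sizes; the end-to-end recovery experiment at 10⁴ neutral +
150 planted loci; GO exactness on a 6-SNP/4-gene universe where full
enumeration (720 orderings) is the oracle, with 2×10⁴ permutations.

## Known limitations

* The π estimator lacks the pool-size correction; values are comparative.
* The annotator covers the feature classes above only — no splice-site,
  start/stop-loss, or GO-graph propagation beyond the supplied
  associations.
* The CMH scan tests marginal, per-SNP consistency; it does not model
  linkage, and the empirical FDR inherits whatever independence the SNP
  set actually has.
* The moment-based Ne estimator is not a likelihood method; at very low
  coverage or extreme starting frequencies its sampling correction
  dominates and the bootstrap interval widens accordingly.
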