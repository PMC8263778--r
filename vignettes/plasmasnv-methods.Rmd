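---
title: "Calling low-frequency somatic SNVs from cell-free DNA: models and methods"
author: "plasmasnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling low-frequency somatic SNVs from cell-free DNA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmasnv)
```

## The problem

Plasma cell-free DNA (cfDNA) is a mixture: the overwhelming majority of
fragments come from normal (mostly hematopoietic) cells, and a small
fraction — often well under 10%, and under 1% in early disease — from tumor
cells. A somatic mutation carried by the tumor therefore appears in plasma at
a variant allele frequency (VAF) far below the heterozygous 50% that callers
designed for solid tumors expect, frequently below 5%, where individual
variant reads are hard to tell apart from sequencing errors. `plasmasnv`
implements a caller built specifically for this regime. It takes matched
plasma and white-blood-cell (WBC) pileups, models the plasma sample as a
two-subpopulation mixture, discovers *clusters* of mutations that share a
cfDNA frequency (the clonal structure of the tumor), and suppresses errors at
three levels: overlapping read-mate consensus, site-level filters, and a
read-level random-forest classifier.

## The joint-genotype mixture model

Every quantity in the caller reduces to the probability of one observed base.
A read observation with mapping quality $m$ and base quality $q$ (both
Phred-scaled) is wrong with probability

$$\epsilon = 1 - (1 - 10^{-m/10})(1 - 10^{-q/10}),$$

treating mismapping and miscalling as independent. Given a diploid genotype
$g$ over the locus alleles A (reference) and B (alternate), and assuming all
error directions equally likely,

$$P(A \mid g) =
\begin{cases}
1 - \epsilon & g = AA\\
\tfrac12(1-\epsilon) + \tfrac16\epsilon & g = AB\\
\tfrac13\epsilon & g = BB,
\end{cases}$$

with the symmetric expressions for B and $\epsilon/3$ for each non-genotype
base, so the four base probabilities sum to one ('N' calls, and observations
with $\epsilon \ge 0.75$, contribute likelihood 1).

The plasma sample holds two subpopulations: tumor-derived cfDNA with genotype
$g_T$ and normal cfDNA with genotype $g_N$. A read comes from the tumor
subpopulation with probability $\theta$ — the *cluster frequency* — so its
likelihood is the mixture

$$P(X_r \mid g_T, g_N, \theta) = \theta\,P(B_r \mid g_T) +
(1-\theta)\,P(B_r \mid g_N).$$

The WBC sample pins down the germline: its reads are scored under a third
genotype $g_W$, and the prior over the triplet $(g_T, g_N, g_W)$ is zero
unless $g_W = g_N$ (normal cfDNA is dominated by white blood cells). The
remaining prior mass over $(g_N, g_T)$ is a diploid germline prior
(heterozygosity $h = 10^{-3}$) composed with a per-allele somatic transition
probability $s$. We ship $s = 10^{-5}$: at the operating depths of this
package (~200x) this places the posterior evidence threshold for a somatic
call at roughly three variant-supporting reads, the same threshold the
pipeline applies everywhere else (locus candidacy and the confirmed-read
rule), so the model and the heuristics agree on what counts as support. Both
rates are arguments of `default_prior_table()`, and a table from any other
source can be loaded with `read_prior_table()`.

### Classification at a locus

`map_joint_genotype()` scores the nine prior-valid triplets in log space and
returns the maximizer; ties prefer non-somatic triplets. The triplet maps to
a call class: somatic ($g_N = AA$, $g_T \ne AA$), germline
($g_T = g_N \ne AA$), LOH (a non-reference $g_N$ altered in the tumor), or
reference. `fitness_ratio()` exposes the ratio between the best somatic and
best non-somatic likelihoods; comparing it at $\theta$ near the mutation
frequency against $\theta = 1$ (the pure-tumor assumption of conventional
callers) quantifies how much the mixture parameter is worth — for VAF
below 5% at depth 200 the fold change is astronomically large, far beyond
the 40-fold that already makes low-frequency mutations separable.

## Estimating the cluster frequency

A single locus at depth 200 sees only a handful of tumor reads, so $\theta$
is estimated by pooling reads across *potential mutation loci*: positions
with adequate coverage (germline $\ge$ 30, plasma $\ge$ 80), a germline
pileup containing only reference alleles, mean error probability below the
observed VAF, mean mapping quality $\ge$ 20 in both samples, no strong strand
bias (two-sided Fisher exact $p \ge 0.005$), and at least 3 variant reads.
The pooled log-likelihood

$$\ell(\theta) = \sum_r \log \sum_{G} P(G)\,
\big[\theta P(X_r \mid g_T) + (1-\theta) P(X_r \mid g_N)\big]$$

is maximized by grid search (step 0.01, refined to 0.001) or EM (per-read
tumor-membership responsibilities; tolerance $10^{-4}$); the two agree to
about $10^{-3}$ and the grid mode is the reference. Reads spanning several
potential loci contribute one term per locus: the exact joint enumeration
over locus combinations grows exponentially and candidate loci are sparse at
exome scale.

The prior $P(G)$ used *here* is not the global somatic prior: with
$s \approx 10^{-5}$ the pooled likelihood is nearly flat in $\theta$, because
every alternate read is cheaper to explain as an error than as a
$10^{-5}$-improbable somatic genotype. Selection criterion (b) already
guarantees a clean germline at these loci, so `theta_prior_table()` fixes
$g_W = g_N = AA$ and spreads mass uniformly over $g_T$. The uniform spread is
not arbitrary: term by term it makes the tumor-component density equal the
heterozygous-genotype density exactly, which is the natural reference model
for a candidate somatic site, and it makes $\hat\theta$ an unbiased
maximum-likelihood estimate of the planted cluster frequency (recovered to
within $\pm 0.02$ down to $\theta^* = 0.02$ at 300 loci x depth 200).

### One cluster at a time

Mutations sharing a clone share a VAF, so the caller works top-down:

1. select potential loci; group their VAFs with Jenks natural breaks and
   seed $\theta$ from the highest class;
2. MAP-screen every candidate locus (adequate coverage, $\ge$ 3 variant
   reads) at that $\theta$; sort the somatic candidates into
   pass / hold / reject with the site filters, whose essential binomial VAF
   test keeps only candidates whose VAF is plausible for this cluster;
3. re-estimate $\theta$ from the pass candidates inside the seeded class and
   repeat until $|\Delta\theta| < 0.01$ (`mode = "quick"` performs a single
   round; convergence typically takes two);
4. emit the cluster (pass + hold members), mask its loci from the data, and
   start again; stop when pass and hold are both empty, when no potential
   loci remain, when $\theta$ falls below `min_theta` (0.005, half the
   convergence tolerance — a cluster thinner than the tolerance cannot be
   tracked), or at `max_clusters` (10).

Two design points deserve explanation because the iteration is where naive
implementations fail. First, the *seed grouping*: `top_jenks_class()` scans
2–4 Jenks classes and accepts a split only when the top class sits more than
1.8 standard deviations above the class below it, where the deviation is the
*expected binomial* spread $\sqrt{\bar v(1-\bar v)/\bar d}$ at the class mean
rather than the empirical one. An empirical spread shrinks artificially when
a single cluster is cut in two, which makes any empirical-sd criterion
unstable exactly at its threshold; the binomial-expected spread does not, so
artificial splits of one cluster score below ~1.2 while genuinely distinct
cluster pairs score above ~2.0 even after the $\ge$-3-reads selection bias
inflates the lower cluster's apparent VAF. Second, *anchoring*: the
refinement re-estimates $\theta$ only from pass candidates inside the seeded
class. The binomial test at level $10^{-4}$ is deliberately permissive, so
the upper VAF tail of the *next* cluster survives it; without anchoring,
each refinement round absorbs a little more of that tail and $\theta$ drifts
downward until adjacent clusters merge.

Candidate screening is deliberately less strict than potential-locus
selection: it requires only coverage and $\ge$ 3 variant reads, leaving
germline evidence and strand balance to the joint-genotype model and the
site filters. Requiring a literally error-free germline pileup at candidate
level would discard a third of true sites at realistic germline error rates
for no gain, since the MAP step weighs the germline reads probabilistically
anyway. For the same reason the site filters count as "germline support"
only germline reads carrying the candidate's alternate allele.

## Error suppression

**Read-mate consensus.** cfDNA fragments peak near 166 bp, so 2x100 bp mates
overlap by ~34 bp and 2x150 bp mates by ~130 bp. `merge_read_pair()`
collapses overlapping mates: concordant overlap bases are confirmed and
boosted to `min(q1 + q2, 60)` (the cap quantifies "high quality" for a
double observation); discordant bases go to the higher-quality call (ties
emit N at quality 2, unresolvable evidence); and a fragment contributes one
observation per locus, removing the VAF bias of double-counted overlaps.
Defaults `min_overlap = 10` and `max_mismatch_density = 0.25` mirror common
read mergers and are configurable, since merger settings should track the
fragment- and read-length profile of the library.

**Site filters.** Essential failures reject a candidate: mean base quality
< 20, mean mapping quality < 30, Fisher strand-bias $p < 0.005$, more than
one germline read carrying the alternate allele, or a binomial VAF test
$p < 10^{-4}$ against the cluster expectation ($\theta/2$ for $g_T = AB$,
$\theta$ for $BB$). Non-essential failures (depth < 80, a nearby indel,
repeat context) put the candidate on hold: reported, but never used to
refine $\theta$. The conventional filter against variants clustered at a
fixed read offset is intentionally absent — cfDNA is non-randomly
fragmented, with preferred start and end positions, so true mutations
legitimately pile up at constant offsets. In its place,
`misalignment_cooccurrence_filter()` flags a candidate only when at least
two *additional* mismatch positions co-occur on $\ge$ 90% of its
variant-supporting reads while appearing on $\le$ 5% of reference reads:
the signature of misalignment is correlated mismatches, not position.

**Read-level classifier.** The last line of defense scores each
variant-supporting read with a random forest (100 trees, depth 10, balanced
class weights — `ranger` backs the implementation) over read, mate and
context features: base and mapping quality, fragment length, distances of
the locus from both fragment ends, mate mapping quality, mismatch counts on
read and mate, soft-clip length, strand, the trinucleotide reference context
and the variant base (one-hot), and — for overlapping pairs — whether the
base was confirmed in both mates. Separate models serve overlapping and
non-overlapping pairs, since the consensus features only exist for the
former. Training labels come from technical replicates
(`label_reads_for_training()`): sites supported concordantly in every
replicate donate true-variant reads; deeply covered sites (> 80x) whose only
non-reference read is high-quality (base quality $\ge$ 20, mapping quality
$\ge$ 40) in every replicate donate error reads — the intersection across
replicates concentrates systematic error sites, which is what makes the
labels informative. A candidate survives only if $\ge$ 3 supporting reads
score above the 0.5 decision threshold. The filter runs last, after
clustering, where ~50x fewer reads need inspection.

## Tumor fraction and burden metrics

`estimate_tumor_fraction()` applies the same natural-breaks grouping to the
VAFs of the final calls, keeps the highest class, and re-runs the $\theta$
estimator on those loci; with fewer than 5 calls the estimate uses all call
loci and is flagged low-confidence. Downstream, a call is *truncal* when its
VAF exceeds 60% of the mean of the five highest VAFs in the sample, and

$$\mathrm{truncal\mbox{-}bTMB} =
\frac{\sum(\mathrm{VAF\ of\ truncal\ nonsynonymous\ calls})}
     {\sum(\mathrm{highest\ 5\ VAF})/5},$$

a burden measure normalized so that multiplying every VAF by a constant
(i.e., changing the tumor fraction of the draw) leaves it unchanged. The
denominator uses the top five VAFs of *all* calls — the defining formula
does not restrict it — with `nonsyn_denominator = TRUE` available. The plain
bTMB is the count of nonsynonymous calls with VAF $\ge$ 0.15 (inclusive).
`confirm_calls()` checks calls in an independent sample: confirmed at
$\ge$ 3 variant reads, not confirmed when fewer are seen despite binomial
power $\ge 0.9$ to see them, indeterminate otherwise (excluded from the
confirmation-rate denominator). Effect annotations are consumed from a
table or VCF INFO field; the package does not run an annotator.

## The synthetic-data generator

`simulate_sample()` emulates the statistical structure the caller assumes,
with ground truth for every read. Defaults reflect a cfDNA WES experiment:
fragments $N(166, 10)$ bp sequenced 2x100 (so essentially all pairs
overlap, and a locus falls inside the overlap ~20% of the time), mean
plasma depth 200x and germline 100x, base qualities drawn 85% from
$N(37, 2)$ and 15% from a Uniform(13, 32) error-prone tail, declining by
0.08 Phred per sequencing cycle, mapping quality 60 for 95% of reads.
Planted clusters are specified as (target VAF, count); fragments are
tumor-derived with probability $\theta = 2 \times$ VAF and carriers hold
the alternate allele on one haplotype, so VAF relates to $\theta$ exactly as
the heterozygous model assumes. Germline heterozygous sites appear in both
samples at ~50%.

Sequencing errors are injected at the model's own $\epsilon(m, q)$ —
a deliberately model-matched (favorable) regime, with an optional
overdispersed mode jittering per-site error rates — plus three error modes
that real libraries exhibit and that the read-level classifier's feature
families presuppose: alignment-artifact fragments (3% of fragments, 15% at
the 10% of background loci designated mapping-difficult hotspots) carrying
correlated mismatches and soft-clips on both mates; and strand-specific
oxidative-damage miscalls (G read as T on forward-strand fragments, 0.003
per mate call). Under direction-symmetric independent flips alone, features
like mismatch counts, strand or context carry no signal and a read
classifier has nothing to learn; the added modes restore the structure that
makes the cross-replicate labeling protocol meaningful. What the generator
still does *not* emulate: GC and capture bias, indels and structural
variation, barcode/duplex structure, CHIP mutations in the germline, and
depth heterogeneity across targets. Passing tests therefore demonstrate
correctness of the algorithms under the stated model, not performance on
any particular real library; in particular real-data classifier AUCs
(~0.95 in comparable published settings) exceed what the model-matched
simulator can honestly support (~0.87-0.91 here).

`spike_in_mix()` recreates titration experiments by subsampling a
mutation-bearing pool against a clean pool at a known dilution (the
recovered tumor fraction tracks dilutions of 2-20% with Pearson r > 0.99 at
170x), and `simulate_mutation_pileup()` plants an exact alternate-read count
at a single locus for the fitness-ratio experiments.

## Numerical and scale choices

All likelihoods accumulate in log space; the per-read mixture density is
linear in $\theta$, so the pooled likelihood and its EM update need one
density pair per read regardless of the genotype space. Jenks natural breaks
are computed by the exact $O(n^2 k)$ dynamic program on sorted values —
adequate for the thousands of loci involved. The test suite and the
acceptance script size their simulations (hundreds of loci x depth 200 for
recovery studies; ~3,000 planted SNVs over an 8-level VAF ladder for the
end-to-end benchmark; 100 replicates for the fitness-ratio experiment) so
that sampling error sits well inside the tolerances being asserted while a
full run stays in the minutes range on one core. Sensitivity saturates near
0.99 above 8% VAF in this regime, so the benchmark asserts monotonicity of
sensitivity in VAF within one-sided binomial sampling error of each adjacent
pair of ladder levels, rather than on the raw sample path whose saturated
levels differ only by noise.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(
  clusters = data.frame(target_vaf = c(0.20, 0.08, 0.02),
                        n_mutations = c(50, 150, 100)),
  depth = 200, n_background = 500, n_germline_het = 40, seed = 5)
s <- simulate_sample(cfg)
cs <- call_variants(s$plasma, s$germline)
sapply(cs$clusters, function(cl) cl$theta$theta)  # ~0.40, 0.16, 0.04
cs$tumor_fraction                                 # ~0.40
write_vcf(cs, "calls.vcf")
```

## Known limitations

The caller assumes a single plasma sample with a matched germline; it does
not model copy number (tumor fraction is uncorrected for CNAs), multiallelic
sites, indels, or tumor-biopsy-paired designs. Cluster resolution is bounded
by binomial noise: clusters whose frequencies differ by less than roughly
two binomial standard deviations of the VAF at the operating depth are
reported as one. The misalignment co-occurrence filter requires per-read
mismatch positions, which flow from BAM input or read-level simulation but
not from bare pileup tables; `call_variants()` applies it only when that
information is present.
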