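# plasmasnv

Somatic single-nucleotide variant calling and tumor-fraction estimation from
plasma cell-free DNA (cfDNA) with a matched white-blood-cell (WBC) germline
sample.

cfDNA is a mixture: a small fraction of fragments is tumor-derived, so
somatic mutations appear at variant allele frequencies (VAF) far below the
50% of a heterozygous solid-tumor variant — often under 5%, where variant
reads and sequencing errors look alike. `plasmasnv` models a plasma read as
drawn from tumor-derived cfDNA with probability θ (the *mutation cluster
frequency*) and from normal cfDNA otherwise, and scores the joint genotype
triplet (g_T, g_N, g_W) of tumor cfDNA, normal cfDNA and WBC DNA:

    P(X_r | g_T, g_N, θ) = θ · P(B_r | g_T) + (1 − θ) · P(B_r | g_N)
    ε = 1 − (1 − 10^(−m/10)) (1 − 10^(−q/10))

with per-base likelihoods driven by the combined mapping/base-quality error
probability ε, and a prior that forces g_W = g_N. Because mutations sharing
a tumor clone share a VAF, the caller runs a divide-and-conquer loop: pool
reads across automatically selected loci to estimate θ of the most frequent
cluster, MAP-screen candidate loci at that θ, filter sites
(pass / hold / reject, including an exact binomial VAF test against the
cluster expectation), refine θ to convergence (|Δθ| < 0.01), emit the
cluster, mask its loci, repeat. Errors are suppressed at three levels:
overlapping read-mate consensus (cfDNA fragments peak at ~166 bp, so
paired-end mates overlap), site-level filters aware of non-random cfDNA
fragmentation (a co-occurrence filter replaces the conventional
clustered-read-position artifact rule), and a read-level random forest that
classifies each variant-supporting read as true variant vs sequencing error.
Downstream utilities compute the Jenks-natural-breaks tumor fraction,
truncal/branch classification, truncal-bTMB and bTMB burden metrics, and
cross-sample confirmation rates. A synthetic-data module generates pileups
and read pairs with full ground truth.

## Worked example

Simulate a plasma/WBC pair with three mutation clusters — 50 mutations at
VAF 20%, 150 at 8%, 100 at 2% (cluster frequencies 0.40 / 0.16 / 0.04) —
then call variants:

```r
library(plasmasnv)

cfg <- simulation_config(
  clusters = data.frame(target_vaf = c(0.20, 0.08, 0.02),
                        n_mutations = c(50, 150, 100)),
  depth = 200, n_background = 500, n_germline_het = 40, seed = 5)
s  <- simulate_sample(cfg)
cs <- call_variants(s$plasma, s$germline)

cs
#> <snv_callset> 268 calls in 3 clusters, tumor fraction 0.407
sapply(cs$clusters, function(cl) cl$theta$theta)
#> [1] 0.400 0.153 0.035
head(cs$calls[, c("pos", "ref", "alt", "vaf", "depth", "cluster_index")], 3)
#>    pos ref alt       vaf depth cluster_index
#> 1 2226   A   T 0.1774194   186             1
#> 2 2861   A   T 0.1932367   207             1
#> 3 3104   T   G 0.1837838   185             1

write_vcf(cs, "calls.vcf")
```

The three clusters come out in decreasing frequency order with θ estimates
0.400, 0.153 and 0.035 against the planted 0.40 / 0.16 / 0.04; the reported
tumor fraction (0.407) is θ re-estimated on the highest-VAF class of the
final calls. Against the simulator's truth this run has precision 1.00 and
sensitivity 0.89 (the misses are 2%-cluster loci that drew fewer than three
variant reads). Burden metrics work on any call table with VAFs and effect
annotations:

```r
calls <- data.frame(vaf = c(0.5, 0.4, 0.3, 0.2, 0.1), effect = "missense")
truncal_btmb(calls)   # 4.667  =  (0.5+0.4+0.3+0.2) / (1.5/5)
btmb(data.frame(vaf = c(0.20, 0.15, 0.14), effect = "missense"))  # 2
```

A thin command-line wrapper lives at `inst/cli/plasmasnv.R`
(`call`, `train-filter`, `burden` subcommands over pileup-TSV/VCF files).

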