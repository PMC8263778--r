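# Synthetic cfDNA generator.
#
# Emulates the statistical structure the caller assumes: plasma cfDNA as a
# two-subpopulation mixture (normal + tumor-derived at cluster frequency
# theta = 2 x target VAF for heterozygous tumor genotypes), short fragments
# (~166 bp) sequenced 2x100 so that mates overlap, Phred-driven sequencing
# errors injected at the same eps(m, q) closed form the model uses, and a
# matched clean germline sample with planted heterozygous sites.

#' Simulation configuration
#'
#' @param clusters data.frame with columns `target_vaf` and `n_mutations`;
#'   each cluster plants `n_mutations` somatic loci whose fragments carry the
#'   alternate allele with probability `target_vaf` (tumor fraction
#'   `theta = 2 * target_vaf`, heterozygous tumor genotype).
#' @param depth Mean plasma coverage (Poisson per locus).
#' @param germline_depth Mean germline (WBC) coverage.
#' @param n_background Unmutated loci to emit alongside the planted ones.
#' @param n_germline_het Heterozygous germline loci planted in both samples.
#' @param fragment_mean,fragment_sd cfDNA fragment length distribution (bp).
#' @param read_length Read length of each mate (bp).
#' @param highq_base,highq_frac Base qualities: `highq_frac` of bases come
#'   from `Normal(highq_base, 2)`, the rest from `Uniform(13, 32)` (the
#'   error-prone tail).
#' @param mapq_max,lowmapq_frac Mapping qualities: `1 - lowmapq_frac` of
#'   reads at `mapq_max`, the rest `Uniform(20, mapq_max)`.
#' @param qual_decay Base-quality decline per sequencing cycle (Phred units
#'   per bp, default 0.08), reproducing the 3'-end quality decay of Illumina
#'   reads; sequencing errors therefore cluster toward read ends.
#' @param artifact_frac Fraction of fragments that are alignment artifacts
#'   (mismapped or chimeric, default 0.03): both mates carry an elevated
#'   mismatch rate (`artifact_flip` per base), extra read/mate mismatches
#'   and frequent soft-clips, emulating the correlated-error reads that
#'   read-level filtration targets.
#' @param artifact_flip Per-base mismatch probability on artifact fragments
#'   (default 0.03).
#' @param hotspot_frac Fraction of background loci that are error-prone
#'   (mapping-difficult regions, default 0.10); artifact fragments
#'   concentrate there at rate `hotspot_artifact`. Such systematic sites
#'   are what the cross-replicate error-labeling protocol is designed to
#'   find.
#' @param hotspot_artifact Artifact-fragment rate at hotspot loci
#'   (default 0.15).
#' @param damage_rate Per-mate-call probability of a strand-specific
#'   oxidative-damage miscall (G read as T on forward-strand fragments,
#'   default 0.003), emulating 8-oxoG-type artifacts.
#' @param overdispersed If `TRUE`, per-site error rates are jittered by a
#'   lognormal factor (sd 0.5 on the log scale), stressing model robustness.
#' @param seed Integer seed; all outputs are reproducible under a fixed seed.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(clusters = data.frame(target_vaf = 0.1,
                                                    n_mutations = 100L),
                              depth = 200, germline_depth = 100,
                              n_background = 1000L, n_germline_het = 50L,
                              fragment_mean = 166, fragment_sd = 10,
                              read_length = 100L,
                              highq_base = 37, highq_frac = 0.85,
                              mapq_max = 60, lowmapq_frac = 0.05,
                              qual_decay = 0.08, artifact_frac = 0.03,
                              artifact_flip = 0.03, hotspot_frac = 0.10,
                              hotspot_artifact = 0.15, damage_rate = 0.003,
                              overdispersed = FALSE,
                              seed = 1L) {
  stopifnot(all(clusters$target_vaf > 0), all(clusters$target_vaf <= 0.5),
            depth > 0)
  structure(as.list(environment()), class = "sim_config")
}

.sim_base_quals <- function(n, cfg) {
  hi <- runif(n) < cfg$highq_frac
  q <- numeric(n)
  q[hi] <- pmin(pmax(round(rnorm(sum(hi), cfg$highq_base, 2)), 33), 41)
  q[!hi] <- round(runif(sum(!hi), 13, 32))
  q
}

.sim_map_quals <- function(n, cfg) {
  lo <- runif(n) < cfg$lowmapq_frac
  m <- rep(cfg$mapq_max, n)
  m[lo] <- round(runif(sum(lo), 20, cfg$mapq_max - 1))
  m
}

.other_bases <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")

# flip each template base with probability eps to a uniformly chosen other
# base; returns the observed calls
.sequence_bases <- function(template, eps) {
  n <- length(template)
  flip <- runif(n) < eps
  if (any(flip)) {
    pick <- ceiling(runif(sum(flip)) * 3)
    pool <- .other_bases[template[flip]]
    template[flip] <- substring(pool, pick, pick)
  }
  template
}

# Simulate one sample's observations over `loci` (data.table with locus_id,
# ref, alt, carrier_prob, theta). Returns the obs data.table.
.sim_sample_obs <- function(loci, mean_depth, cfg) {
  depth <- rpois(nrow(loci), mean_depth)
  idx <- rep(seq_len(nrow(loci)), depth)
  n <- length(idx)
  ref <- loci$ref[idx]
  alt <- loci$alt[idx]
  theta <- loci$theta[idx]

  # fragment origin and template allele (tumor genotype AB: carrier fragments
  # hold the alternate allele; germline-het loci carry it in both origins)
  tumor <- runif(n) < theta
  germ_het <- loci$germ_het[idx]
  carrier <- (tumor | germ_het) & (runif(n) < 0.5)
  template <- ifelse(carrier, alt, ref)

  L <- cfg$read_length
  flen <- pmin(pmax(round(rnorm(n, cfg$fragment_mean, cfg$fragment_sd)),
                    L + 10L), 2L * L)
  d5p <- floor(runif(n) * flen)
  d3p <- flen - 1L - d5p
  covered1 <- d5p < L   # mate 1 reads from the fragment 5' end
  covered2 <- d3p < L   # mate 2 from the 3' end
  in_overlap <- covered1 & covered2

  # base quality declines along the sequencing cycle (3'-end decay)
  cyc1 <- pmin(d5p, L - 1L)
  cyc2 <- pmin(d3p, L - 1L)
  q1 <- pmax(.sim_base_quals(n, cfg) - round(cfg$qual_decay * cyc1), 6)
  q2 <- pmax(.sim_base_quals(n, cfg) - round(cfg$qual_decay * cyc2), 6)
  m1 <- .sim_map_quals(n, cfg)
  m2 <- .sim_map_quals(n, cfg)

  # alignment-artifact fragments: correlated mismatches on both mates,
  # concentrated at error-prone (mapping-difficult) loci
  hot <- if (is.null(loci$hotspot)) rep(FALSE, n) else loci$hotspot[idx]
  artifact <- runif(n) < ifelse(hot, cfg$hotspot_artifact, cfg$artifact_frac)
  strand <- ifelse(runif(n) < 0.5, "+", "-")

  jitter <- if (cfg$overdispersed) exp(rnorm(n, 0, 0.5)) else 1
  eps1 <- pmin(error_probability(m1, q1) * jitter, 1)
  eps2 <- pmin(error_probability(m2, q2) * jitter, 1)
  eps1[artifact] <- pmax(eps1[artifact], cfg$artifact_flip)
  eps2[artifact] <- pmax(eps2[artifact], cfg$artifact_flip)
  call1 <- .sequence_bases(template, eps1)
  call2 <- .sequence_bases(template, eps2)

  # strand-specific oxidative damage: G template read as T on forward-strand
  # fragments, independently per mate (mispairing during amplification)
  dmg1 <- template == "G" & strand == "+" & runif(n) < cfg$damage_rate
  dmg2 <- template == "G" & strand == "+" & runif(n) < cfg$damage_rate
  call1[dmg1] <- "T"
  call2[dmg2] <- "T"

  # consensus of overlapping mates: agreement boosts quality, disagreement is
  # resolved toward the higher-quality call (ties -> N at quality 2); outside
  # the overlap the covering mate's call stands alone
  base <- ifelse(covered1, call1, call2)
  bq <- ifelse(covered1, q1, q2)
  mq <- ifelse(covered1, m1, m2)
  confirmed <- rep(FALSE, n)
  agree <- in_overlap & call1 == call2
  base[agree] <- call1[agree]
  bq[agree] <- pmin(q1[agree] + q2[agree], 60)
  mq[agree] <- pmax(m1, m2)[agree]
  confirmed[agree] <- TRUE
  r2wins <- in_overlap & call1 != call2 & q2 > q1
  base[r2wins] <- call2[r2wins]
  bq[r2wins] <- q2[r2wins]
  mq[r2wins] <- pmax(m1, m2)[r2wins]
  tie <- in_overlap & call1 != call2 & q1 == q2
  base[tie] <- "N"
  bq[tie] <- 2

  mm_rate1 <- L * (10^(-q1 / 10) + 10^(-m1 / 10))
  mm_rate2 <- L * (10^(-q2 / 10) + 10^(-m2 / 10))
  mm_rate1[artifact] <- mm_rate1[artifact] + L * cfg$artifact_flip
  mm_rate2[artifact] <- mm_rate2[artifact] + L * cfg$artifact_flip
  read_mm <- pmin(rpois(n, mm_rate1), 15L)
  mate_mm <- pmin(rpois(n, mm_rate2), 15L)
  sc_prob <- ifelse(artifact, 0.7, 0.05)
  softclip <- ifelse(runif(n) < sc_prob, rpois(n, ifelse(artifact, 8, 4)), 0L)

  origin <- ifelse(base != template, "error",
                   ifelse(tumor, "tumor", "normal"))

  data.table::data.table(
    locus_id = loci$locus_id[idx],
    base = base, bq = bq, mq = mq,
    strand = strand,
    d5p = d5p, d3p = d3p, flen = flen,
    confirmed = confirmed, merged = TRUE,
    pair_overlap = flen < 2L * L,
    mate_mq = m2, read_mm = read_mm, mate_mm = mate_mm,
    softclip = as.integer(softclip),
    read_id = paste0("f", seq_len(n)),
    origin = origin
  )
}

#' Simulate a matched plasma / germline sample pair with ground truth
#'
#' Plants the configured somatic mutation clusters and germline heterozygous
#' sites on a synthetic contig, draws fragment-level observations for a
#' plasma and a germline sample, and returns pileup sets plus the truth
#' tables needed to score a caller.
#'
#' @param cfg A [simulation_config()].
#' @param replicates Number of plasma technical replicates to draw over the
#'   same locus panel and truth (default 1). Replicates share the planted
#'   mutations but have independent read sampling and sequencing errors.
#' @return List with `plasma` and `germline` (each a `pileup_set`: `obs`
#'   data.table + `loci` table + `sample_role`), `truth` (list with
#'   `somatic` and `germline_het` locus tables; per-read origins are the
#'   `origin` column of each `obs`), and `config`. With `replicates > 1`,
#'   also `plasma_replicates` (list of `pileup_set`s, the first being
#'   `plasma`).
#' @export
simulate_sample <- function(cfg = simulation_config(), replicates = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  bases <- c("A", "C", "G", "T")

  n_som <- sum(cfg$clusters$n_mutations)
  n_tot <- n_som + cfg$n_germline_het + cfg$n_background
  pos <- sort(sample.int(n_tot * 400L, n_tot))
  ref <- sample(bases, n_tot, replace = TRUE)
  alt <- vapply(ref, function(b) {
    sample(setdiff(bases, b), 1L)
  }, "")
  kind <- rep(c("somatic", "germline_het", "background"),
              c(n_som, cfg$n_germline_het, cfg$n_background))
  kind <- sample(kind)  # interleave along the contig
  cluster <- integer(n_tot)
  cluster[kind == "somatic"] <-
    rep(seq_len(nrow(cfg$clusters)), cfg$clusters$n_mutations)
  true_vaf <- ifelse(kind == "somatic",
                     cfg$clusters$target_vaf[pmax(cluster, 1L)], 0)
  true_vaf[kind != "somatic"] <- 0

  # infeasible VAF/depth pairs: expected alternate reads below one
  infeasible <- kind == "somatic" & true_vaf * cfg$depth < 1
  if (any(infeasible)) {
    warning(sum(infeasible), " planted loci skipped: expected alt reads < 1")
    kind[infeasible] <- "background"
    cluster[infeasible] <- 0L
    true_vaf[infeasible] <- 0
  }

  ctx_l <- sample(bases, n_tot, replace = TRUE)
  ctx_r <- sample(bases, n_tot, replace = TRUE)
  loci <- data.table::data.table(
    locus_id = seq_len(n_tot), chrom = "sim1", pos = pos,
    ref = ref, alt = alt,
    context = paste0(ctx_l, ref, ctx_r),
    kind = kind, cluster = cluster, true_vaf = true_vaf,
    theta = 2 * true_vaf,
    germ_het = kind == "germline_het",
    hotspot = kind == "background" & runif(n_tot) < cfg$hotspot_frac
  )

  loci_pub <- loci[, c("locus_id", "chrom", "pos", "ref", "context")]
  reps <- lapply(seq_len(replicates), function(i) {
    pileup_set(.sim_sample_obs(loci, cfg$depth, cfg), loci_pub, "plasma")
  })
  gl <- data.table::copy(loci)
  gl$theta <- 0  # no tumor-derived fragments in the WBC sample
  germline_obs <- .sim_sample_obs(gl, cfg$germline_depth, cfg)

  truth <- list(
    somatic = loci[kind == "somatic",
                   c("locus_id", "chrom", "pos", "ref", "alt",
                     "cluster", "true_vaf", "theta")],
    germline_het = loci[kind == "germline_het",
                        c("locus_id", "chrom", "pos", "ref", "alt")]
  )
  out <- list(
    plasma = reps[[1L]],
    germline = pileup_set(germline_obs, loci_pub, "germline"),
    truth = truth,
    config = cfg
  )
  if (replicates > 1L) out$plasma_replicates <- reps
  out
}

#' Pileup-set container
#'
#' The pipeline currency: all observations of one sample over a panel of
#' loci, as a single data.table keyed by `locus_id`, plus the locus table.
#'
#' @param obs Observation data.table (see [simulate_sample()]).
#' @param loci Locus table with `locus_id`, `chrom`, `pos`, `ref` (and
#'   optionally `context`).
#' @param sample_role `"plasma"`, `"germline"` or `"tumor_biopsy"`.
#' @export
pileup_set <- function(obs, loci, sample_role = "plasma") {
  obs <- data.table::as.data.table(obs)
  loci <- data.table::as.data.table(loci)
  data.table::setkey(obs, locus_id)
  structure(list(obs = obs, loci = loci, sample_role = sample_role),
            class = "pileup_set")
}

#' @export
print.pileup_set <- function(x, ...) {
  cat(sprintf("<pileup_set> %s: %d loci, %d observations\n",
              x$sample_role, nrow(x$loci), nrow(x$obs)))
  invisible(x)
}

# extract one locus as a locus_pileup
set_locus_pileup <- function(ps, id, alt = NA_character_) {
  li <- ps$loci[list(locus_id = id), on = "locus_id"]
  obs <- ps$obs[list(locus_id = id), on = "locus_id", nomatch = NULL]
  locus_pileup(li$chrom, li$pos, li$ref, as.data.frame(obs), alt = alt,
               sample_role = ps$sample_role)
}

# drop a set of loci (masking between cluster iterations)
mask_loci <- function(ps, ids) {
  if (!length(ids)) return(ps)
  pileup_set(ps$obs[!list(locus_id = ids), on = "locus_id"],
             ps$loci[!ps$loci$locus_id %in% ids], ps$sample_role)
}

#' Mix tumor-like and normal-like read pools at a known dilution
#'
#' Emulates a spike-in titration: observations are subsampled without
#' replacement per locus at ratio `dilution : (1 - dilution)` from the two
#' pools up to `total_depth`, and the true tumor fraction of the mixture is
#' recorded.
#'
#' @param tumor,normal `pileup_set`s over the same loci.
#' @param dilution Fraction of reads drawn from the tumor pool, in `[0, 1]`.
#' @param total_depth Target mean depth of the mixture.
#' @return A `pileup_set` with attribute `true_fraction = dilution`.
#' @export
spike_in_mix <- function(tumor, normal, dilution, total_depth) {
  stopifnot(dilution >= 0, dilution <= 1)
  take <- function(obs_locus, k) {
    if (k > nrow(obs_locus)) stop("requested depth exceeds pool depth")
    obs_locus[sample.int(nrow(obs_locus), k)]
  }
  mixed <- lapply(tumor$loci$locus_id, function(id) {
    to <- tumor$obs[list(locus_id = id), on = "locus_id", nomatch = NULL]
    no <- normal$obs[list(locus_id = id), on = "locus_id", nomatch = NULL]
    k_t <- rbinom(1L, total_depth, dilution)
    rbind(take(to, k_t), take(no, total_depth - k_t))
  })
  out <- pileup_set(data.table::rbindlist(mixed), tumor$loci, "plasma")
  attr(out, "true_fraction") <- dilution
  out
}

#' Simulate a single mutated locus pileup with a clean matched germline
#'
#' Plants exactly `round(vaf * depth)` alternate-allele templates among
#' `depth` plasma observations (plus sequencing errors injected at the
#' closed-form error probability), with a clean germline pileup alongside.
#' Used by the model-to-data fitness-ratio experiment.
#'
#' @param vaf Variant allele frequency in `[0, 1]`.
#' @param depth Plasma depth.
#' @param germline_depth Germline depth (default 100).
#' @param cfg A [simulation_config()] supplying the quality distributions.
#' @param seed Optional seed.
#' @return List with `plasma` and `germline` [locus_pileup()]s.
#' @export
simulate_mutation_pileup <- function(vaf, depth, germline_depth = 100,
                                     cfg = simulation_config(), seed = NULL) {
  stopifnot(vaf >= 0, vaf <= 1)
  if (!is.null(seed)) set.seed(seed)
  ref <- "A"
  alt <- "T"
  one <- function(n, n_alt, role) {
    if (n == 0L) {
      return(locus_pileup("sim1", 1000L, ref,
                          data.frame(base = character(), bq = numeric(),
                                     mq = numeric(), strand = character(),
                                     d5p = integer(), d3p = integer(),
                                     flen = integer(), confirmed = logical(),
                                     merged = logical(), read_id = character()),
                          alt = alt, sample_role = role))
    }
    template <- c(rep(alt, n_alt), rep(ref, n - n_alt))
    q <- .sim_base_quals(n, cfg)
    m <- .sim_map_quals(n, cfg)
    base <- .sequence_bases(template, error_probability(m, q))
    flen <- pmin(pmax(round(rnorm(n, cfg$fragment_mean, cfg$fragment_sd)),
                      cfg$read_length + 10L), 2L * cfg$read_length)
    d5p <- floor(runif(n) * flen)
    locus_pileup("sim1", 1000L, ref,
                 data.frame(base = base, bq = q, mq = m,
                            strand = ifelse(runif(n) < 0.5, "+", "-"),
                            d5p = d5p, d3p = flen - 1L - d5p, flen = flen,
                            confirmed = FALSE, merged = TRUE,
                            read_id = paste0(role, seq_len(n)),
                            stringsAsFactors = FALSE),
                 alt = alt, sample_role = role)
  }
  list(plasma = one(depth, round(vaf * depth), "plasma"),
       germline = one(germline_depth, 0L, "germline"))
}
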