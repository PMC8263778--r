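# Shared fixtures and independent oracles for the test suite.

# Direct evaluation of the base-call probability table, written from the
# closed form (independent of base_likelihood_matrix's vectorized path).
oracle_base_lik <- function(base, g, eps, ref, alt) {
  if (base == "N" || eps >= 0.75) return(1)
  others <- setdiff(c("A", "C", "G", "T"), c(ref, alt))
  if (g == "AA") {
    if (base == ref) 1 - eps else eps / 3
  } else if (g == "BB") {
    if (base == alt) 1 - eps else eps / 3
  } else {
    if (base %in% c(ref, alt)) 0.5 * (1 - eps) + eps / 6 else eps / 3
  }
}

# Brute-force MAP joint genotype: enumerate all 27 triplets (including the
# zero-prior ones) with plain loops and log arithmetic.
oracle_map_genotype <- function(plasma, germline, theta, prior) {
  gts <- c("AA", "AB", "BB")
  p <- unclass(prior)
  best <- NULL
  best_lp <- -Inf
  for (gT in gts) for (gN in gts) for (gW in gts) {
    pri <- if (gW == gN) p[gN, gT] else 0
    if (pri == 0) next
    lp <- log(pri)
    for (i in seq_len(nrow(plasma$obs))) {
      eps <- plasmasnv::error_probability(plasma$obs$mq[i], plasma$obs$bq[i])
      lT <- oracle_base_lik(plasma$obs$base[i], gT, eps, plasma$ref, plasma$alt)
      lN <- oracle_base_lik(plasma$obs$base[i], gN, eps, plasma$ref, plasma$alt)
      lp <- lp + log(theta * lT + (1 - theta) * lN)
    }
    for (i in seq_len(nrow(germline$obs))) {
      eps <- plasmasnv::error_probability(germline$obs$mq[i], germline$obs$bq[i])
      lp <- lp + log(oracle_base_lik(germline$obs$base[i], gW, eps,
                                     plasma$ref, plasma$alt))
    }
    # tie-break identical to the implementation: prefer non-somatic
    somatic <- gN == "AA" && gT != "AA"
    if (lp > best_lp + 1e-9 ||
        (abs(lp - best_lp) <= 1e-9 && !somatic && !is.null(best) &&
         best["g_N"] == "AA" && best["g_T"] != "AA")) {
      best_lp <- lp
      best <- c(g_T = gT, g_N = gN, g_W = gW)
    }
  }
  best
}

# quick random single-locus pileup pair for oracle comparisons
random_pileup_pair <- function(depth_p = 40, depth_g = 30, p_alt = 0.1) {
  ref <- sample(c("A", "C", "G", "T"), 1)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  mk <- function(n, alt_prob, role) {
    base <- ifelse(runif(n) < alt_prob, alt, ref)
    flip <- runif(n) < 0.02
    base[flip] <- sample(c("A", "C", "G", "T"), sum(flip), replace = TRUE)
    plasmasnv::locus_pileup("sim1", 500L, ref,
      data.frame(base = base,
                 bq = sample(15:40, n, replace = TRUE),
                 mq = sample(25:60, n, replace = TRUE),
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 d5p = 0L, d3p = 0L, flen = 166L,
                 confirmed = FALSE, merged = TRUE,
                 read_id = paste0(role, seq_len(n)),
                 stringsAsFactors = FALSE),
      alt = alt, sample_role = role)
  }
  list(plasma = mk(depth_p, p_alt, "plasma"),
       germline = mk(depth_g, 0, "germline"))
}

# small, memoized simulated dataset shared by several test files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- plasmasnv::simulation_config(
        clusters = data.frame(target_vaf = 0.1, n_mutations = 40L),
        depth = 150, germline_depth = 80, n_background = 400L,
        n_germline_het = 30L, seed = 404L)
      cache <<- plasmasnv::simulate_sample(cfg)
    }
    cache
  }
})
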