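# Mutation-cluster frequency estimation.
#
# Tumor-derived cfDNA is too sparse to estimate its fraction at any single
# locus, so reads are pooled across automatically selected potential mutation
# loci and the cluster frequency theta maximizes the pooled mixture
# likelihood: each read is tumor-derived with probability theta and normal
# with probability 1 - theta, and its per-genotype density comes from the
# Phred-driven base likelihood.

#' Potential mutation locus selection thresholds
#'
#' @param min_germline_depth,min_plasma_depth Minimum coverage (defaults 30
#'   and 80).
#' @param min_mapq Minimum mean mapping quality in both samples (default 20).
#' @param min_variant_reads Minimum plasma variant-supporting reads
#'   (default 3).
#' @param strand_bias_alpha Two-sided Fisher exact p-value below which a
#'   locus is considered strand-biased (default 0.005).
#' @param max_germline_alt Maximum non-reference reads tolerated in the
#'   germline pileup (default 0: only reference alleles).
#' @param max_loci Cap on ranked loci used for theta (default 3000).
#' @export
selection_config <- function(min_germline_depth = 30L, min_plasma_depth = 80L,
                             min_mapq = 20, min_variant_reads = 3L,
                             strand_bias_alpha = 0.005,
                             max_germline_alt = 0L, max_loci = 3000L) {
  stopifnot(min_germline_depth >= 0, min_plasma_depth >= 0,
            min_variant_reads >= 0)
  structure(as.list(environment()), class = "selection_config")
}

# per-locus summary of a pileup set: depth, major non-reference allele and
# its count, VAF, mean eps / base / mapping quality, strand counts
.locus_summary <- function(ps) {
  obs <- data.table::copy(ps$obs)
  obs <- ps$loci[, c("locus_id", "ref")][obs, on = "locus_id"]
  obs[, `:=`(eps = error_probability(mq, bq),
             is_nonref = base != ref & base != "N")]
  # major non-reference base per locus
  altt <- obs[obs$is_nonref,
              list(n = .N), by = c("locus_id", "base")]
  data.table::setorderv(altt, c("locus_id", "n", "base"), c(1L, -1L, 1L))
  altt <- altt[!duplicated(altt$locus_id), ]
  data.table::setnames(altt, "base", "alt")
  obs <- altt[, c("locus_id", "alt")][obs, on = "locus_id"]
  obs[, is_alt := !is.na(alt) & base == alt]
  sm <- obs[, list(
    depth = .N,
    nonref = sum(is_nonref),
    alt_count = sum(is_alt),
    mean_eps = mean(eps),
    mean_bq = mean(bq),
    mean_mq = mean(mq),
    alt_fwd = sum(is_alt & strand == "+"),
    alt_rev = sum(is_alt & strand == "-"),
    ref_fwd = sum(base == ref & strand == "+"),
    ref_rev = sum(base == ref & strand == "-")
  ), by = "locus_id"]
  sm <- altt[, c("locus_id", "alt")][sm, on = "locus_id"]
  sm[, vaf := alt_count / depth]
  ps$loci[sm, on = "locus_id"]
}

# two-sided Fisher exact p for alt/ref x fwd/rev
strand_bias_p <- function(ref_fwd, ref_rev, alt_fwd, alt_rev) {
  mapply(function(rf, rr, af, ar) {
    if (af + ar == 0L || rf + rr == 0L) return(1)
    fisher.test(matrix(c(rf, rr, af, ar), 2L))$p.value
  }, ref_fwd, ref_rev, alt_fwd, alt_rev)
}

#' Select potential mutation loci from matched plasma / germline pileups
#'
#' A locus qualifies when (a) germline depth >= 30 and plasma depth >= 80,
#' (b) the germline pileup contains only reference alleles, (c) the mean
#' sequencing-error probability is below the observed VAF, (d) mean mapping
#' quality is >= 20 in both samples, (e) the alt/ref strand table shows no
#' strong bias (two-sided Fisher exact p >= `strand_bias_alpha`), and
#' (f) at least `min_variant_reads` plasma reads support the variant.
#' Qualifying loci are ranked by plasma coverage (descending), VAF
#' (descending), germline non-reference count (ascending), then genomic
#' coordinate, and capped at `max_loci`.
#'
#' @param plasma,germline `pileup_set`s over a common locus panel.
#' @param cfg A [selection_config()].
#' @return An object of class `potential_loci`: the ranked locus table with
#'   per-locus plasma/germline statistics (zero rows if nothing qualifies).
#' @export
select_potential_loci <- function(plasma, germline, cfg = selection_config()) {
  psum <- .locus_summary(plasma)
  gsum <- .locus_summary(germline)
  g <- gsum[, c("locus_id", "depth", "nonref", "mean_mq")]
  data.table::setnames(g, c("depth", "nonref", "mean_mq"),
                       c("gdepth", "galt", "gmean_mq"))
  tab <- g[psum, on = "locus_id"]
  tab[is.na(tab$gdepth), `:=`(gdepth = 0L, galt = 0L, gmean_mq = 0)]

  keep <- tab$gdepth >= cfg$min_germline_depth &
    tab$depth >= cfg$min_plasma_depth &
    tab$galt <= cfg$max_germline_alt &
    !is.na(tab$alt) &
    tab$alt_count >= cfg$min_variant_reads &
    tab$mean_eps < tab$vaf &
    tab$mean_mq >= cfg$min_mapq & tab$gmean_mq >= cfg$min_mapq
  tab <- tab[keep]
  if (nrow(tab)) {
    sb <- strand_bias_p(tab$ref_fwd, tab$ref_rev, tab$alt_fwd, tab$alt_rev)
    tab <- tab[sb >= cfg$strand_bias_alpha]
  }
  data.table::setorderv(tab, c("depth", "vaf", "galt", "chrom", "pos"),
                        c(-1L, -1L, 1L, 1L, 1L))
  tab <- head(tab, cfg$max_loci)
  structure(tab, class = c("potential_loci", class(tab)))
}

#' Candidate loci for joint-genotype screening
#'
#' Loci eligible for MAP screening in one caller round: adequate coverage in
#' both samples and at least `min_variant_reads` plasma reads supporting a
#' non-reference allele. Unlike [select_potential_loci()] (which feeds the
#' pooled theta estimate and demands a pristine germline), candidacy leaves
#' germline evidence, error rates and strand balance to the joint-genotype
#' model and the site filters, so that sporadic germline sequencing errors
#' do not silently discard true somatic sites.
#'
#' @inheritParams select_potential_loci
#' @return Locus table with the same per-locus statistics.
#' @export
candidate_loci <- function(plasma, germline, cfg = selection_config()) {
  psum <- .locus_summary(plasma)
  gsum <- .locus_summary(germline)
  g <- gsum[, c("locus_id", "depth")]
  data.table::setnames(g, "depth", "gdepth")
  tab <- g[psum, on = "locus_id"]
  tab[is.na(tab$gdepth), "gdepth"] <- 0L
  keep <- tab$gdepth >= cfg$min_germline_depth &
    tab$depth >= cfg$min_plasma_depth &
    !is.na(tab$alt) &
    tab$alt_count >= cfg$min_variant_reads
  tab <- tab[keep]
  data.table::setorderv(tab, c("chrom", "pos"))
  tab
}

# Pool the plasma observations at the given loci and precompute the mixture
# densities m_T, m_N per read under `prior` (marginal genotype weights).
pooled_read_densities <- function(plasma, loci_tab,
                                  prior = theta_prior_table()) {
  sel <- loci_tab[, c("locus_id", "ref", "alt")]
  obs <- plasma$obs[list(locus_id = sel$locus_id), on = "locus_id",
                    nomatch = NULL]
  obs <- sel[obs, on = "locus_id"]
  eps <- error_probability(obs$mq, obs$bq)
  L <- base_likelihood_matrix(obs$base, eps, obs$ref, obs$alt)
  p <- unclass(prior)
  w_n <- rowSums(p)   # marginal over g_N
  w_t <- colSums(p)   # marginal over g_T
  list(m_T = as.vector(L %*% w_t), m_N = as.vector(L %*% w_n),
       n_loci = nrow(loci_tab), n_reads = nrow(obs))
}

#' Pooled log-likelihood of a cluster frequency
#'
#' Sum over all reads at the potential mutation loci of
#' `log sum_G P(G) [theta P(X|g_T) + (1 - theta) P(X|g_N)]`. A read covering
#' several loci contributes one term per locus (per-locus factorization).
#'
#' @param loci A `potential_loci` table (from [select_potential_loci()]), or
#'   any locus table with `locus_id`, `ref`, `alt`.
#' @param plasma The plasma `pileup_set`.
#' @param theta Cluster frequency in `[0, 1]` (vectorized).
#' @param prior `prior_table` for `P(G)` (default [theta_prior_table()]).
#' @return Log-likelihood value(s).
#' @export
theta_log_likelihood <- function(loci, plasma, theta,
                                 prior = theta_prior_table()) {
  stopifnot(all(theta >= 0), all(theta <= 1))
  if (!nrow(loci)) stop("empty potential locus set")
  d <- pooled_read_densities(plasma, loci, prior)
  vapply(theta, function(th) sum(log(th * d$m_T + (1 - th) * d$m_N)), 0)
}

#' Estimate the frequency of the current mutation cluster
#'
#' Maximizes the pooled mixture likelihood over theta, either by grid search
#' (coarse step 0.01 over `[0, 1]`, then local refinement at step 0.001) or
#' by EM (per-read tumor-membership E-step, closed-form M-step, initialized
#' from the coarse grid, tolerance 1e-4). The two modes agree to ~1e-3 on
#' well-behaved data.
#'
#' @inheritParams theta_log_likelihood
#' @param method `"grid"` or `"em"`.
#' @param em_tol,max_iter EM stopping rule (defaults 1e-4, 200).
#' @return A `theta_estimate`: list with `theta`, `log_likelihood`,
#'   `n_loci`, `n_reads`, `method`, `converged`.
#' @export
estimate_theta <- function(loci, plasma, prior = theta_prior_table(),
                           method = c("grid", "em"),
                           em_tol = 1e-4, max_iter = 200L) {
  method <- match.arg(method)
  if (!nrow(loci)) stop("empty potential locus set")
  d <- pooled_read_densities(plasma, loci, prior)
  ll <- function(th) sum(log(th * d$m_T + (1 - th) * d$m_N))

  coarse <- seq(0, 1, by = 0.01)
  ll_c <- vapply(coarse, ll, 0)
  th0 <- coarse[which.max(ll_c)]
  converged <- TRUE

  if (method == "grid") {
    fine <- seq(max(0, th0 - 0.01), min(1, th0 + 0.01), by = 0.001)
    ll_f <- vapply(fine, ll, 0)
    theta <- fine[which.max(ll_f)]
    llv <- max(ll_f)
  } else {
    theta <- min(max(th0, 1e-4), 1 - 1e-4)
    llv <- ll(theta)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- theta * d$m_T / (theta * d$m_T + (1 - theta) * d$m_N)
      theta_new <- mean(w)
      if (abs(theta_new - theta) < em_tol) {
        theta <- theta_new
        converged <- TRUE
        break
      }
      theta <- theta_new
    }
    llv <- ll(theta)
    if (!converged) {
      warning("EM did not converge; returning best grid value")
      theta <- th0
      llv <- max(ll_c)
    }
  }
  structure(list(theta = theta, log_likelihood = llv,
                 n_loci = d$n_loci, n_reads = d$n_reads,
                 method = method, converged = converged),
            class = "theta_estimate")
}

#' @export
print.theta_estimate <- function(x, ...) {
  cat(sprintf("<theta_estimate> theta=%.4f (%s, %d loci, %d reads, logL=%.1f)\n",
              x$theta, x$method, x$n_loci, x$n_reads, x$log_likelihood))
  invisible(x)
}

#' Tumor fraction from the highest-VAF class of detected mutations
#'
#' Partitions the VAFs of the final calls by Jenks natural breaks (2 classes
#' by default, with a goodness-of-variance-fit check), then re-estimates the
#' cluster frequency restricted to the loci of the highest-VAF class. With
#' fewer than 5 calls the estimate uses all call loci and is flagged
#' low-confidence.
#'
#' @param calls Data frame of calls with `locus_id` and `vaf` columns (e.g.
#'   the output of [call_variants()]).
#' @param plasma Plasma `pileup_set`.
#' @param prior Prior for the theta likelihood.
#' @param k_max Maximum number of Jenks classes scanned (default 4; the
#'   smallest class count whose partition clears the goodness-of-variance
#'   fit is used).
#' @return List with `fraction`, `estimate` (the `theta_estimate`),
#'   `loci_used`, `low_confidence`.
#' @export
estimate_tumor_fraction <- function(calls, plasma,
                                    prior = theta_prior_table(), k_max = 4L) {
  if (!nrow(calls)) stop("no detected mutations")
  low_conf <- nrow(calls) < 5L
  in_top <- if (low_conf) rep(TRUE, nrow(calls))
            else top_jenks_class(calls$vaf, calls$depth, k_max = k_max)
  loci_tab <- data.table::data.table(locus_id = calls$locus_id[in_top],
                                     ref = calls$ref[in_top],
                                     alt = calls$alt[in_top])
  est <- estimate_theta(loci_tab, plasma, prior = prior)
  list(fraction = est$theta, estimate = est,
       loci_used = loci_tab$locus_id, low_confidence = low_conf)
}
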