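# Per-locus MAP joint-genotype inference under the two-subpopulation mixture.
#
# For a locus with plasma reads X_P and germline (WBC) reads X_W, the
# posterior of a joint genotype G = (g_T, g_N, g_W) is proportional to
#   P(G) * prod_r [(1 - theta) P(X_r | g_N) + theta P(X_r | g_T)]
#        * prod_r' P(X_r' | g_W)
# and the prior is zero unless g_W == g_N, leaving nine triplets to score.

MIN_CLASSIFY_DEPTH <- 10L

#' MAP joint genotype at one locus
#'
#' Scores every prior-valid joint genotype triplet `(g_T, g_N, g_W)` (those
#' with `g_W == g_N`) in log space and returns the maximizer together with
#' the full posterior table and the locus classification. Ties are broken in
#' favor of non-somatic triplets (conservative calling).
#'
#' @param plasma,germline [locus_pileup()]s at the same position.
#' @param theta Mixture fraction of the current mutation cluster.
#' @param prior A `prior_table` (default [default_prior_table()]).
#' @return An object of class `posterior_table`: list with `table` (triplets
#'   and unnormalized log posteriors), `g_map` (named character vector),
#'   `classification`, `skipped` (depth below the classification minimum).
#' @export
map_joint_genotype <- function(plasma, germline, theta,
                               prior = default_prior_table()) {
  stopifnot(theta >= 0, theta <= 1)
  if (pileup_depth(plasma) == 0L || pileup_depth(germline) == 0L) {
    stop("classification undefined on an empty pileup")
  }
  alt <- plasma$alt
  skipped <- pileup_depth(plasma) < MIN_CLASSIFY_DEPTH

  eps_p <- error_probability(plasma$obs$mq, plasma$obs$bq)
  eps_g <- error_probability(germline$obs$mq, germline$obs$bq)
  Lp <- base_likelihood_matrix(plasma$obs$base, eps_p, plasma$ref, alt)
  Lg <- base_likelihood_matrix(germline$obs$base, eps_g, germline$ref, alt)
  p <- unclass(prior)

  trip <- valid_triplets()
  trip$somatic <- trip$g_N == "AA" & trip$g_T != "AA"
  trip <- trip[order(trip$somatic), ]  # non-somatic first for tie-breaking
  lg_by_g <- colSums(log(Lg))
  trip$log_lik <- vapply(seq_len(nrow(trip)), function(i) {
    mix <- (1 - theta) * Lp[, trip$g_N[i]] + theta * Lp[, trip$g_T[i]]
    sum(log(mix)) + lg_by_g[[trip$g_W[i]]]
  }, 0)
  trip$log_prior <- log(p[cbind(trip$g_N, trip$g_T)])
  trip$log_post <- trip$log_lik + trip$log_prior

  best <- which.max(trip$log_post)
  g_map <- c(g_T = trip$g_T[best], g_N = trip$g_N[best], g_W = trip$g_W[best])
  structure(list(
    chrom = plasma$chrom, pos = plasma$pos, ref = plasma$ref, alt = alt,
    table = trip[, c("g_T", "g_N", "g_W", "log_lik", "log_prior", "log_post")],
    g_map = g_map,
    classification = classify_locus(g_map["g_T"], g_map["g_N"], g_map["g_W"]),
    theta = theta, skipped = skipped
  ), class = "posterior_table")
}

#' @export
print.posterior_table <- function(x, ...) {
  cat(sprintf("<posterior_table> %s:%d G_MAP=(%s,%s,%s) %s\n",
              x$chrom, x$pos, x$g_map["g_T"], x$g_map["g_N"], x$g_map["g_W"],
              x$classification))
  invisible(x)
}

#' Classify a joint genotype triplet
#'
#' `somatic` when the tumor genotype departs from a reference-homozygous
#' normal genotype; `germline` when normal and tumor share a non-reference
#' genotype; `LOH` when a heterozygous (or non-reference) normal genotype
#' changes in the tumor; `reference` when all three are `AA`.
#'
#' @param g_T,g_N,g_W Genotypes; `g_W` must equal `g_N` (prior-valid triplet).
#' @return One of `"somatic"`, `"germline"`, `"LOH"`, `"reference"`.
#' @export
classify_locus <- function(g_T, g_N, g_W) {
  stopifnot(g_W == g_N)
  if (g_N == "AA" && g_T == "AA") return("reference")
  if (g_N == "AA") return("somatic")
  if (g_T == g_N) return("germline")
  "LOH"
}

#' Model-to-data fitness ratio at a locus
#'
#' The ratio between the maximum likelihood over somatic joint genotypes
#' (`g_N = AA`, `g_T` heterozygous or homozygous alternate) and the maximum
#' likelihood over the remaining (non-somatic) triplets, evaluated at a given
#' cluster frequency. By default the genotype prior is excluded so the ratio
#' isolates model fit; set `include_prior = TRUE` for the posterior-weighted
#' variant. Comparing the ratio at the cluster frequency against the ratio at
#' `theta = 1` (no mixture: the conventional pure-tumor assumption) measures
#' how much the mixture parameter improves the fit of low-frequency
#' mutations.
#'
#' @inheritParams map_joint_genotype
#' @param include_prior Multiply likelihoods by the genotype prior.
#' @return List of class `fitness_ratio` with `log_ratio`, `ratio` and
#'   `theta_used`.
#' @export
fitness_ratio <- function(plasma, germline, theta,
                          prior = default_prior_table(),
                          include_prior = FALSE) {
  post <- map_joint_genotype(plasma, germline, theta, prior)
  tab <- post$table
  score <- if (include_prior) tab$log_post else tab$log_lik
  somatic <- tab$g_N == "AA" & tab$g_T != "AA"
  log_ratio <- max(score[somatic]) - max(score[!somatic])
  structure(list(log_ratio = log_ratio, ratio = exp(log_ratio),
                 theta_used = theta), class = "fitness_ratio")
}
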