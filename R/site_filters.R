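# Site-level pass / hold / reject filtration of somatic candidates.
#
# Essential filters catch likely artifacts (quality, strand bias, germline
# contamination, VAF inconsistent with the current cluster frequency);
# failing any of them rejects the candidate. Non-essential filters flag
# candidates we cannot adjudicate yet; failing only those holds the
# candidate. The conventional clustered-read-position artifact filter is
# deliberately absent: cfDNA fragments have preferred start/end positions,
# so true mutations can legitimately pile up at fixed read offsets. In its
# place a co-occurrence filter flags candidates whose supporting reads
# exclusively share additional mismatches (a misalignment signature).

#' Site-filter thresholds
#'
#' @param min_mean_bq,min_mean_mq Essential minimum mean base / mapping
#'   quality of the plasma pileup (defaults 20, 30).
#' @param strand_bias_alpha Essential two-sided Fisher strand-bias level
#'   (default 0.005).
#' @param max_germline_alt Essential maximum germline non-reference reads
#'   (default 1).
#' @param binom_alpha Essential binomial VAF-test level (default 1e-4).
#' @param min_depth Non-essential minimum plasma depth (default 80).
#' @param indel_window Non-essential: nearby indel within this many bp holds
#'   the candidate (default 5).
#' @export
filter_config <- function(min_mean_bq = 20, min_mean_mq = 30,
                          strand_bias_alpha = 0.005, max_germline_alt = 1L,
                          binom_alpha = 1e-4, min_depth = 80L,
                          indel_window = 5L) {
  structure(as.list(environment()), class = "filter_config")
}

#' Binomial VAF consistency test
#'
#' Under the current cluster frequency `theta` the expected VAF of a cluster
#' member is `theta / 2` for a heterozygous tumor genotype and `theta` for a
#' homozygous one. The candidate is kept when a two-sided exact binomial
#' test of `alt_count` out of `depth` against that expectation has
#' p >= `alpha` — i.e. the VAF is plausible for this cluster.
#'
#' @param alt_count,depth Variant-supporting reads and total depth.
#' @param theta Cluster frequency in `(0, 1]`.
#' @param g_T Tumor genotype, `"AB"` or `"BB"`.
#' @param alpha Rejection level (default 1e-4).
#' @return List with `keep` (logical) and `p_value`.
#' @export
binomial_vaf_test <- function(alt_count, depth, theta, g_T = "AB",
                              alpha = 1e-4) {
  stopifnot(theta > 0, theta <= 1, alt_count >= 0, alt_count <= depth)
  if (depth == 0L) return(list(keep = FALSE, p_value = NA_real_))
  p0 <- if (g_T == "BB") theta else theta / 2
  p0 <- min(p0, 1)
  pv <- binom.test(alt_count, depth, p0)$p.value
  list(keep = pv >= alpha, p_value = pv)
}

#' Site statistics for one candidate locus
#'
#' Summarizes a plasma pileup (with its matched germline pileup) into the
#' statistics consumed by [apply_site_filters()].
#'
#' @param plasma,germline [locus_pileup()]s.
#' @param nearby_indel,repeat_context Sequence-context flags supplied by the
#'   caller (defaults `FALSE`; pileups carry no reference window).
#' @return List of class `site_stats`.
#' @export
site_stats <- function(plasma, germline, nearby_indel = FALSE,
                       repeat_context = FALSE) {
  obs <- plasma$obs
  alt <- plasma$alt
  is_alt <- !is.na(alt) & obs$base == alt
  is_ref <- obs$base == plasma$ref
  structure(list(
    mean_base_qual = mean(obs$bq),
    mean_map_qual = mean(obs$mq),
    strand_counts = c(ref_fwd = sum(is_ref & obs$strand == "+"),
                      ref_rev = sum(is_ref & obs$strand == "-"),
                      alt_fwd = sum(is_alt & obs$strand == "+"),
                      alt_rev = sum(is_alt & obs$strand == "-")),
    depth = nrow(obs),
    alt_count = sum(is_alt),
    vaf = if (nrow(obs)) sum(is_alt) / nrow(obs) else NA_real_,
    nearby_indel = nearby_indel,
    repeat_context = repeat_context,
    # germline support for the candidate's variant allele; other-base
    # sequencing errors in the germline pileup are not evidence against it
    germline_alt_count = if (is.na(alt)) 0L
                         else sum(germline$obs$base == alt)
  ), class = "site_stats")
}

#' Sort a somatic candidate into pass / hold / reject
#'
#' Essential filters (failing any rejects the candidate): mean base quality,
#' mean mapping quality, Fisher strand bias, germline non-reference count,
#' and the binomial VAF test against the cluster frequency. Non-essential
#' filters (failing only these holds it): depth, nearby indel, repeat
#' context.
#'
#' @param stats A [site_stats()].
#' @param theta Current cluster frequency (for the VAF test).
#' @param g_T Tumor genotype of the candidate (`"AB"`/`"BB"`).
#' @param cfg A [filter_config()].
#' @return List of class `filter_verdict`: `category` in
#'   `{"pass","hold","reject"}`, `failed_filters`, `essential_failed`.
#' @export
apply_site_filters <- function(stats, theta, g_T = "AB",
                               cfg = filter_config()) {
  stopifnot(inherits(stats, "site_stats"))
  failed <- character()

  if (stats$mean_base_qual < cfg$min_mean_bq) failed <- c(failed, "mean_base_qual")
  if (stats$mean_map_qual < cfg$min_mean_mq) failed <- c(failed, "mean_map_qual")
  sc <- stats$strand_counts
  sb_p <- strand_bias_p(sc["ref_fwd"], sc["ref_rev"], sc["alt_fwd"], sc["alt_rev"])
  if (sb_p < cfg$strand_bias_alpha) failed <- c(failed, "strand_bias")
  if (stats$germline_alt_count > cfg$max_germline_alt) {
    failed <- c(failed, "germline_alt")
  }
  bt <- binomial_vaf_test(stats$alt_count, stats$depth, theta, g_T,
                          cfg$binom_alpha)
  if (!bt$keep) failed <- c(failed, "binomial_vaf")
  essential_failed <- length(failed) > 0L

  if (stats$depth < cfg$min_depth) failed <- c(failed, "depth")
  if (isTRUE(stats$nearby_indel)) failed <- c(failed, "nearby_indel")
  if (isTRUE(stats$repeat_context)) failed <- c(failed, "repeat_context")

  category <- if (essential_failed) "reject"
              else if (length(failed)) "hold" else "pass"
  structure(list(category = category, failed_filters = failed,
                 essential_failed = essential_failed,
                 binom_p = bt$p_value, strand_p = unname(sb_p)),
            class = "filter_verdict")
}

#' Misalignment co-occurrence filter
#'
#' Misaligned reads typically carry several mismatches together, so a false
#' candidate created by misalignment shows additional mismatch positions
#' that co-occur exclusively on its variant-supporting reads. A candidate is
#' flagged as an artifact when at least `min_cooccurring` other mismatch
#' positions are present on at least `co_frac` of its variant-supporting
#' reads and on at most `bg_frac` of its reference reads. A clustered
#' position of the variant base on the reads alone does not flag the
#' candidate: non-random cfDNA fragmentation produces exactly that pattern
#' for true mutations, which this filter rescues.
#'
#' @param variant_reads List (one entry per candidate) of lists: per
#'   variant-supporting read, the integer positions of its other mismatches.
#' @param reference_reads Same structure for the candidate's reference reads.
#' @param min_cooccurring Mismatch positions required to flag (default 2).
#' @param co_frac Minimum fraction of variant reads sharing the mismatch
#'   (default 0.9).
#' @param bg_frac Maximum fraction of reference reads carrying it
#'   (default 0.05).
#' @return Logical vector: `TRUE` where the candidate is a likely
#'   misalignment artifact.
#' @export
misalignment_cooccurrence_filter <- function(variant_reads, reference_reads,
                                             min_cooccurring = 2L,
                                             co_frac = 0.9, bg_frac = 0.05) {
  mapply(function(vr, rr) {
    if (!length(vr)) return(FALSE)
    pos_tab <- table(unlist(vr))
    if (!length(pos_tab)) return(FALSE)
    v_frac <- pos_tab / length(vr)
    bg <- if (length(rr)) table(factor(unlist(rr),
                                       levels = names(pos_tab))) / length(rr)
          else setNames(rep(0, length(pos_tab)), names(pos_tab))
    exclusive <- v_frac >= co_frac & as.numeric(bg) <= bg_frac
    sum(exclusive) >= min_cooccurring
  }, variant_reads, reference_reads, USE.NAMES = FALSE)
}
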