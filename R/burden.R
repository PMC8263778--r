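# Mutational-burden metrics on cfDNA calls.
#
# The VAF of a plasma mutation reflects its clonality: mutations present in
# all tumor clones (truncal) ride at the tumor fraction, subclonal (branch)
# mutations below it. The truncal blood tumor mutational burden normalizes
# truncal nonsynonymous VAFs by the mean of the five highest VAFs, making
# the metric invariant to the overall tumor fraction of the draw.

#' Split calls into truncal and branch sets
#'
#' A call is truncal when its VAF exceeds 60% of the mean VAF of the five
#' most frequent mutations in the sample (all calls are used for the top-5
#' mean; with fewer than five calls the mean is over what is available and
#' the result is flagged).
#'
#' @param calls Data frame with a `vaf` column.
#' @param frac Threshold fraction of the top-5 mean (default 0.6).
#' @return List: `truncal` and `branch` (row subsets of `calls`),
#'   `threshold`, `top5_mean_vaf`, `flagged_few_calls`.
#' @export
classify_truncal <- function(calls, frac = 0.6) {
  if (!nrow(calls)) stop("empty call list")
  top5 <- head(sort(calls$vaf, decreasing = TRUE), 5L)
  top5_mean <- mean(top5)
  threshold <- frac * top5_mean
  is_truncal <- calls$vaf > threshold
  list(truncal = calls[is_truncal, , drop = FALSE],
       branch = calls[!is_truncal, , drop = FALSE],
       threshold = threshold, top5_mean_vaf = top5_mean,
       flagged_few_calls = nrow(calls) < 5L)
}

# nonsynonymous / high-impact effect classes (treated the same)
NONSYN_CLASSES <- c("nonsynonymous", "missense", "missense_variant",
                    "stop_gained", "stop_lost", "start_lost", "high",
                    "nonsense", "frameshift_variant")

.is_nonsyn <- function(effect) {
  tolower(effect) %in% NONSYN_CLASSES
}

#' Truncal blood tumor mutational burden
#'
#' \deqn{\mathrm{truncal\mbox{-}bTMB} =
#'   \frac{\sum \mathrm{VAF\ of\ truncal\ nonsynonymous\ mutations}}
#'        {\sum(\mathrm{highest\ 5\ VAF}) / 5}}
#' The denominator uses the five highest VAFs of all calls by default
#' (`nonsyn_denominator = TRUE` restricts it to nonsynonymous calls).
#' Scale-invariant: multiplying every VAF by a constant leaves it unchanged.
#'
#' @param calls Data frame with `vaf` and `effect` columns (effect classes
#'   such as `"missense"`, `"synonymous"`; high-impact classes count as
#'   nonsynonymous).
#' @param frac Truncal threshold fraction (default 0.6).
#' @param nonsyn_denominator Restrict the top-5 mean to nonsynonymous calls.
#' @return Non-negative number; 0 when there are no nonsynonymous calls.
#' @examples
#' calls <- data.frame(vaf = c(0.5, 0.4, 0.3, 0.2, 0.1),
#'                     effect = "missense")
#' truncal_btmb(calls)  # 1.4 / 0.3 = 4.667
#' @export
truncal_btmb <- function(calls, frac = 0.6, nonsyn_denominator = FALSE) {
  if (!nrow(calls)) return(0)
  nonsyn <- calls[.is_nonsyn(calls$effect), , drop = FALSE]
  if (!nrow(nonsyn)) return(0)
  denom_set <- if (nonsyn_denominator) nonsyn else calls
  top5_mean <- mean(head(sort(denom_set$vaf, decreasing = TRUE), 5L))
  cls <- classify_truncal(calls, frac)
  truncal_nonsyn <- nonsyn$vaf[nonsyn$vaf > cls$threshold]
  if (!length(truncal_nonsyn)) return(0)
  sum(truncal_nonsyn) / top5_mean
}

#' Blood tumor mutational burden
#'
#' Count of nonsynonymous calls with VAF at or above the threshold
#' (boundary inclusive).
#'
#' @inheritParams truncal_btmb
#' @param min_vaf VAF threshold (default 0.15).
#' @return Integer count.
#' @export
btmb <- function(calls, min_vaf = 0.15) {
  if (!nrow(calls)) return(0L)
  sum(.is_nonsyn(calls$effect) & calls$vaf >= min_vaf)
}

#' Confirm calls in an independent sample
#'
#' A call is `confirmed` when the confirming sample (tumor biopsy or a
#' second plasma draw) shows at least `min_reads` variant-supporting reads
#' at the locus; `not_confirmed` when it shows fewer while the binomial
#' power to have seen that many — `P(X >= min_reads)` with
#' `X ~ Binomial(depth_other, VAF_call)` — is at least `min_power`;
#' otherwise `indeterminate` (excluded from the confirmation rate).
#'
#' @param calls Data frame with `vaf`, `alt`, `locus_id` columns.
#' @param other `pileup_set` of the confirming sample (raw pileups).
#' @param min_reads Supporting-read threshold (default 3).
#' @param min_power Power threshold (default 0.9).
#' @return List: `status` (character per call), `confirmation_rate`,
#'   `power`, `other_alt_count`, `other_depth`.
#' @export
confirm_calls <- function(calls, other, min_reads = 3L, min_power = 0.9) {
  if (!nrow(calls)) stop("empty call list")
  pobs <- .split_obs(other, calls$locus_id)
  depth <- vapply(pobs, nrow, 0L)
  altn <- vapply(seq_len(nrow(calls)), function(i) {
    sum(pobs[[i]]$base == calls$alt[i])
  }, 0L)
  power <- unname(1 - stats::pbinom(min_reads - 1L, depth, calls$vaf))
  status <- ifelse(altn >= min_reads, "confirmed",
                   ifelse(power >= min_power, "not_confirmed",
                          "indeterminate"))
  status[depth == 0L & altn < min_reads] <- "indeterminate"
  denom <- sum(status != "indeterminate")
  rate <- if (denom) sum(status == "confirmed") / denom else NA_real_
  list(status = status, confirmation_rate = rate, power = power,
       other_alt_count = altn, other_depth = depth)
}

#' Burden report for a call set
#'
#' Bundles the truncal/branch classification, truncal-bTMB and bTMB for a
#' call table with effect annotations, plus the high/low burden split helper
#' value (the population median is supplied by the caller when comparing
#' samples).
#'
#' @inheritParams truncal_btmb
#' @return List of class `burden_report`.
#' @export
burden_report <- function(calls, frac = 0.6) {
  cls <- classify_truncal(calls, frac)
  structure(list(
    truncal_btmb = truncal_btmb(calls, frac),
    btmb = btmb(calls),
    n_truncal = nrow(cls$truncal), n_branch = nrow(cls$branch),
    threshold = cls$threshold, top5_mean_vaf = cls$top5_mean_vaf,
    flagged_few_calls = cls$flagged_few_calls
  ), class = "burden_report")
}

#' Split samples into high / low burden groups at the median
#'
#' `> median` is high (the median sample itself falls in the low group).
#'
#' @param values Numeric burden values, one per sample.
#' @return Character vector `"high"` / `"low"`.
#' @export
burden_groups <- function(values) {
  ifelse(values > stats::median(values), "high", "low")
}
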