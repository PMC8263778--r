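# Read-level sequencing-error suppression.
#
# Site statistics are unreliable for mutations supported by a handful of
# reads, so each variant-supporting read is classified individually as true
# variant vs sequencing error by a random forest over read, mate and context
# features. Overlapping and non-overlapping read pairs get separate models:
# the overlap consensus (confirmed bases, boosted qualities) is only defined
# for the former. A candidate survives only if enough of its supporting
# reads are confirmed by the classifier.

BASES4 <- c("A", "C", "G", "T")

.onehot <- function(x, levels, prefix) {
  m <- outer(as.character(x), levels, `==`) * 1
  colnames(m) <- paste0(prefix, levels)
  m
}

#' Extract classifier features for variant-supporting observations
#'
#' Builds the fixed-dimension numeric feature matrix for one or more read
#' observations: base and mapping quality, distances of the locus from the
#' fragment 5'/3' ends, fragment length, mate mapping quality, mismatch
#' counts on read and mate, soft-clip length, one-hot strand, one-hot
#' flanking reference bases, one-hot variant base, and (for the overlapping
#' feature set) whether the base was confirmed in both mates.
#'
#' @param obs Observation data.frame (columns as produced by the simulator /
#'   pileup builders: `bq`, `mq`, `d5p`, `d3p`, `flen`, `mate_mq`,
#'   `read_mm`, `mate_mm`, `softclip`, `strand`, `confirmed`). Missing mate
#'   columns fall back to the read's own values and are flagged.
#' @param context Trinucleotide reference context per observation (e.g.
#'   `"ACG"` for locus base C); the two flanking bases are encoded.
#' @param variant_base The candidate alternate allele per observation.
#' @param feature_set `"overlapping"` or `"nonoverlapping"`.
#' @return Numeric matrix, one row per observation; the feature set is kept
#'   as an attribute.
#' @export
extract_read_features <- function(obs, context, variant_base,
                                  feature_set = c("overlapping",
                                                  "nonoverlapping")) {
  feature_set <- match.arg(feature_set)
  n <- nrow(obs)
  mate_mq <- if (is.null(obs$mate_mq)) obs$mq else obs$mate_mq
  mate_mm <- if (is.null(obs$mate_mm)) rep(0L, n) else obs$mate_mm
  read_mm <- if (is.null(obs$read_mm)) rep(0L, n) else obs$read_mm
  softclip <- if (is.null(obs$softclip)) rep(0L, n) else obs$softclip
  ctx <- toupper(context)
  left <- substring(ctx, 1L, 1L)
  center <- substring(ctx, 2L, 2L)
  right <- substring(ctx, 3L, 3L)
  m <- cbind(
    base_qual = obs$bq, map_qual = obs$mq,
    d5p = obs$d5p, d3p = obs$d3p, fragment_length = obs$flen,
    mate_map_qual = mate_mq, mate_mismatch = mate_mm,
    read_mismatch = read_mm, softclip = softclip,
    .onehot(obs$strand, c("+", "-"), "strand"),
    .onehot(left, BASES4, "ctx5_"),
    .onehot(center, BASES4, "ref"),
    .onehot(right, BASES4, "ctx3_"),
    .onehot(variant_base, BASES4, "alt")
  )
  if (feature_set == "overlapping") {
    m <- cbind(m, overlap_confirmed = as.numeric(obs$confirmed))
  }
  attr(m, "feature_set") <- feature_set
  m
}

#' Label reads for classifier training from technical replicates
#'
#' Two sequencing datasets of the same cfDNA sample act as technical
#' replicates: sites behaving concordantly in all replicates supply
#' trustworthy labels. True-variant reads are the variant-supporting reads
#' at sites carrying the same non-reference allele with at least
#' `min_concordant_alt` supporting reads in every replicate (germline
#' heterozygous and shared somatic sites both qualify). Error reads are the
#' single non-reference reads at sufficiently covered sites (depth >
#' `error_site_depth`) whose only non-reference read is high-quality (base
#' quality >= 20, mapping quality >= 40) in every replicate.
#'
#' @param replicates List of >= 2 plasma `pileup_set`s over the same loci.
#' @param min_concordant_alt Minimum supporting reads per replicate for a
#'   true-variant site (default 3).
#' @param error_site_depth Depth threshold for error sites (default 80).
#' @return A `labeled_read_set`: data.table of observations with `label`
#'   (`"true_variant"`/`"error"`), `site_id`, `variant_base`, `context`,
#'   `feature_set`.
#' @export
label_reads_for_training <- function(replicates, min_concordant_alt = 3L,
                                     error_site_depth = 80L) {
  stopifnot(length(replicates) >= 2L)
  summaries <- lapply(replicates, .locus_summary)

  alt_of <- function(sm) setNames(sm$alt, sm$locus_id)
  base_sm <- summaries[[1L]]
  concordant_var <- base_sm$locus_id[
    !is.na(base_sm$alt) & base_sm$alt_count >= min_concordant_alt]
  error_sites <- base_sm$locus_id[base_sm$depth > error_site_depth &
                                    base_sm$nonref == 1L]
  for (sm in summaries[-1L]) {
    ok <- !is.na(sm$alt) & sm$alt_count >= min_concordant_alt &
      sm$alt == alt_of(base_sm)[as.character(sm$locus_id)]
    concordant_var <- intersect(concordant_var, sm$locus_id[ok])
    error_sites <- intersect(error_sites,
                             sm$locus_id[sm$depth > error_site_depth &
                                           sm$nonref == 1L])
  }

  grab <- function(ps, sm, ids, label) {
    if (!length(ids)) return(NULL)
    sel <- sm[sm$locus_id %in% ids, c("locus_id", "ref", "alt")]
    obs <- ps$obs[list(locus_id = sel$locus_id), on = "locus_id",
                  nomatch = NULL]
    obs <- sel[obs, on = "locus_id"]
    obs <- obs[obs$base != obs$ref & obs$base != "N" & !is.na(obs$alt) &
                 obs$base == obs$alt, ]
    if (label == "error") {
      obs <- obs[obs$bq >= 20 & obs$mq >= 40, ]
    }
    if (!nrow(obs)) return(NULL)
    ctx <- if ("context" %in% names(ps$loci)) {
      setNames(ps$loci$context, ps$loci$locus_id)[as.character(obs$locus_id)]
    } else paste0("N", obs$ref, "N")
    data.table::data.table(obs, label = label, site_id = obs$locus_id,
                           variant_base = obs$alt, context = ctx)
  }

  parts <- list()
  for (i in seq_along(replicates)) {
    parts[[length(parts) + 1L]] <-
      grab(replicates[[i]], summaries[[i]], concordant_var, "true_variant")
    parts[[length(parts) + 1L]] <-
      grab(replicates[[i]], summaries[[i]], error_sites, "error")
  }
  out <- data.table::rbindlist(Filter(Negate(is.null), parts), fill = TRUE)
  if (!nrow(out) || length(unique(out$label)) < 2L) {
    stop("no qualifying sites for both labels")
  }
  ov <- if (is.null(out$pair_overlap)) rep(FALSE, nrow(out)) else out$pair_overlap
  out$feature_set <- ifelse(ov, "overlapping", "nonoverlapping")
  structure(out, class = c("labeled_read_set", class(out)))
}

#' Train the read-level error classifier
#'
#' Fits one random forest per feature set (overlapping / non-overlapping
#' read pairs) with 100 trees, maximum depth 10 and balanced class weights;
#' reproducible under a fixed seed. Out-of-bag AUC is recorded per model.
#'
#' @param labeled A `labeled_read_set` from [label_reads_for_training()], or
#'   any data.frame with the observation columns plus `label`,
#'   `variant_base`, `context`, `feature_set`.
#' @param num_trees,max_depth Forest size and depth cap (defaults 100, 10).
#' @param seed Integer seed.
#' @return A `read_classifier`: fitted models, decision threshold (0.5) and
#'   out-of-bag AUCs.
#' @export
train_read_classifier <- function(labeled, num_trees = 100L, max_depth = 10L,
                                  seed = 1L) {
  stopifnot(all(c("label", "variant_base", "context", "feature_set")
                %in% names(labeled)))
  if (length(unique(labeled$label)) < 2L) stop("both labels required")
  fit_one <- function(fs) {
    d <- labeled[labeled$feature_set == fs, ]
    if (!nrow(d) || length(unique(d$label)) < 2L) return(NULL)
    X <- extract_read_features(d, d$context, d$variant_base, fs)
    y <- factor(d$label, levels = c("error", "true_variant"))
    tab <- table(y)
    cw <- as.numeric(sum(tab) / (2 * tab))  # 'balanced' class weights
    fit <- ranger::ranger(
      x = as.data.frame(X), y = y,
      num.trees = num_trees, max.depth = max_depth,
      probability = TRUE, class.weights = cw,
      seed = seed, num.threads = 1L
    )
    oob <- fit$predictions[, "true_variant"]
    list(fit = fit, oob_auc = auc_rank(oob, y == "true_variant"))
  }
  models <- list(overlapping = fit_one("overlapping"),
                 nonoverlapping = fit_one("nonoverlapping"))
  if (all(vapply(models, is.null, TRUE))) stop("no trainable feature set")
  structure(list(models = models, threshold = 0.5,
                 num_trees = num_trees, max_depth = max_depth, seed = seed),
            class = "read_classifier")
}

#' Rank-based AUC (Mann-Whitney)
#'
#' @param scores Numeric scores, higher meaning more positive.
#' @param truth Logical vector of positives.
#' @return Area under the ROC curve.
#' @export
auc_rank <- function(scores, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Score observations with the read classifier
#'
#' @param classifier A `read_classifier`.
#' @param obs Observation data.frame with `variant_base` and `context`
#'   columns (or passed separately).
#' @param context,variant_base Optional overrides.
#' @return Probability of being a true variant, per observation.
#' @export
predict_read_probs <- function(classifier, obs, context = obs$context,
                               variant_base = obs$variant_base) {
  fs <- if (!is.null(obs$pair_overlap)) {
    ifelse(obs$pair_overlap, "overlapping", "nonoverlapping")
  } else rep("nonoverlapping", nrow(obs))
  # fall back to the other model when one feature set was untrainable
  avail <- !vapply(classifier$models, is.null, TRUE)
  fs[!avail[fs]] <- names(avail)[avail][1L]
  out <- numeric(nrow(obs))
  for (set in unique(fs)) {
    i <- fs == set
    X <- extract_read_features(obs[i, ], context[i], variant_base[i], set)
    out[i] <- stats::predict(classifier$models[[set]]$fit,
                      data = as.data.frame(X),
                      num.threads = 1L)$predictions[, "true_variant"]
  }
  out
}

#' Confirmed-supporting-read filter for one candidate
#'
#' Scores every variant-supporting observation of a candidate; a read is
#' confirmed when its true-variant probability reaches the classifier's
#' decision threshold, and the candidate is kept only if at least
#' `min_confirmed` reads are confirmed. Without a classifier the filter is
#' disabled (all supporting reads count as confirmed) with a warning.
#'
#' @param supporting Observation data.frame of the candidate's
#'   variant-supporting reads (with `context` and `variant_base`).
#' @param classifier A `read_classifier` or `NULL`.
#' @param min_confirmed Threshold on confirmed reads (default 3).
#' @return List: `keep`, `n_supporting`, `n_confirmed`, `probs`.
#' @export
filter_candidate_by_reads <- function(supporting, classifier,
                                      min_confirmed = 3L) {
  stopifnot(nrow(supporting) >= 1L)
  if (is.null(classifier)) {
    warning("no read classifier supplied; read-level filter disabled")
    n <- nrow(supporting)
    return(list(keep = n >= min_confirmed, n_supporting = n,
                n_confirmed = n, probs = rep(NA_real_, n)))
  }
  probs <- predict_read_probs(classifier, supporting)
  n_conf <- sum(probs >= classifier$threshold)
  list(keep = n_conf >= min_confirmed, n_supporting = nrow(supporting),
       n_confirmed = n_conf, probs = probs)
}
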