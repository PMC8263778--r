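# The iterative divide-and-conquer caller.
#
# Each round: select potential mutation loci, seed the cluster frequency
# theta from the highest-VAF group, screen every candidate locus for a
# somatic MAP joint genotype at that theta, filter sites (pass/hold/reject,
# including the binomial VAF test that keeps the cluster coherent), refine
# theta on the pass set until |delta theta| < 0.01, then emit the cluster
# and mask its loci from the data. Rounds repeat until no candidate reaches
# pass or hold. Read-level filtration and the tumor-fraction estimate run
# once on the union of all clusters.

#' Caller configuration
#'
#' @param selection A [selection_config()].
#' @param filters A [filter_config()].
#' @param prior Joint-genotype prior for MAP screening
#'   ([default_prior_table()]).
#' @param theta_prior Prior used for cluster-frequency estimation
#'   ([theta_prior_table()]).
#' @param mode `"full"` iterates each cluster to convergence
#'   (`|delta theta| < conv_tol`); `"quick"` performs one round per cluster.
#' @param conv_tol Convergence tolerance on theta (default 0.01).
#' @param max_refine_rounds Refinement cap per cluster (default 20).
#' @param max_clusters Cap on detected clusters (default 10).
#' @param cluster_sep Separation multiple required to accept a Jenks
#'   cluster seed split: the top VAF class must sit more than this many
#'   pooled within-class spreads above the class below it (default 1.8, on the RMS of the binomial-expected spreads).
#' @param min_theta Cluster frequencies below this terminate the search
#'   (default 0.005: half the convergence tolerance).
#' @param classifier Optional [train_read_classifier()] model for read-level
#'   filtration.
#' @param min_confirmed Confirmed supporting reads required per call
#'   (default 3).
#' @param seed Recorded in output metadata; the caller itself is
#'   deterministic.
#' @export
caller_config <- function(selection = selection_config(),
                          filters = filter_config(),
                          prior = default_prior_table(),
                          theta_prior = theta_prior_table(),
                          mode = c("full", "quick"),
                          conv_tol = 0.01, max_refine_rounds = 20L,
                          max_clusters = 10L, cluster_sep = 1.8,
                          min_theta = 0.005,
                          classifier = NULL, min_confirmed = 3L,
                          seed = NA_integer_) {
  mode <- match.arg(mode)
  structure(as.list(environment()), class = "caller_config")
}

# split the observations of a pileup set at the given loci into per-locus
# data.frames (one keyed join, then split)
.split_obs <- function(ps, locus_ids) {
  obs <- ps$obs[list(locus_id = locus_ids), on = "locus_id", nomatch = NULL]
  split(as.data.frame(obs), factor(obs$locus_id, levels = locus_ids))
}

# MAP-screen candidate loci at a fixed theta and apply the site filters;
# returns one row per locus with classification and verdict
.screen_loci <- function(pot, plasma, germline, theta, cfg) {
  ids <- pot$locus_id
  pobs <- .split_obs(plasma, ids)
  gobs <- .split_obs(germline, ids)
  rows <- lapply(seq_along(ids), function(i) {
    po <- pobs[[i]]
    go <- gobs[[i]]
    if (!nrow(po) || !nrow(go)) return(NULL)
    lp <- locus_pileup(pot$chrom[i], pot$pos[i], pot$ref[i], po,
                       alt = pot$alt[i], sample_role = "plasma")
    lg <- locus_pileup(pot$chrom[i], pot$pos[i], pot$ref[i], go,
                       alt = pot$alt[i], sample_role = "germline")
    post <- map_joint_genotype(lp, lg, theta, cfg$prior)
    if (post$skipped || post$classification != "somatic") return(NULL)
    st <- site_stats(lp, lg)
    verdict <- apply_site_filters(st, theta, g_T = post$g_map[["g_T"]],
                                  cfg = cfg$filters)
    data.frame(locus_id = ids[i], chrom = pot$chrom[i], pos = pot$pos[i],
               ref = pot$ref[i], alt = pot$alt[i],
               depth = st$depth, alt_count = st$alt_count, vaf = st$vaf,
               g_T = post$g_map[["g_T"]], category = verdict$category,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) out <- data.frame()
  out
}

#' Detect and converge one mutation cluster
#'
#' Runs one round (mode `"quick"`) or iterates to convergence (mode
#' `"full"`) of theta estimation, MAP screening and site filtration on the
#' current (masked) data, returning the cluster members in the pass and
#' hold categories together with the refined frequency.
#'
#' @param plasma,germline `pileup_set`s (already masked of previously
#'   detected clusters).
#' @param cfg A [caller_config()].
#' @return A `cluster_result`: list with `theta` (a `theta_estimate` or
#'   `NULL`), `members` (data.frame of pass/hold somatic candidates),
#'   `n_refinement_rounds`, `converged`, `empty`.
#' @export
converge_cluster <- function(plasma, germline, cfg = caller_config()) {
  empty <- list(theta = NULL, members = data.frame(),
                n_refinement_rounds = 0L, converged = TRUE, empty = TRUE)
  class(empty) <- "cluster_result"
  pot <- select_potential_loci(plasma, germline, cfg$selection)
  if (!nrow(pot)) return(empty)
  cand_tab <- candidate_loci(plasma, germline, cfg$selection)
  if (!nrow(cand_tab)) return(empty)

  seed_set <- pot[top_jenks_class(pot$vaf, pot$depth,
                                  sep = cfg$cluster_sep), ]
  seed_ids <- seed_set$locus_id
  est <- estimate_theta(seed_set, plasma, prior = cfg$theta_prior)
  theta <- est$theta
  if (theta < cfg$min_theta) return(empty)

  members <- data.frame()
  converged <- cfg$mode == "quick"
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    cand <- .screen_loci(cand_tab, plasma, germline, theta, cfg)
    members <- if (nrow(cand)) cand[cand$category %in% c("pass", "hold"), ]
               else data.frame()
    if (cfg$mode == "quick" || rounds >= cfg$max_refine_rounds) break
    pass <- if (nrow(members)) members[members$category == "pass", ]
            else data.frame()
    if (!nrow(pass)) break
    # refine theta on the pass candidates that belong to the seeded cluster:
    # anchoring to the round's initial grouping keeps theta on the most
    # frequent cluster instead of drifting onto lower-cluster VAF tails that
    # survive the binomial test
    anchored <- pass[pass$locus_id %in% seed_ids, ]
    if (nrow(anchored)) pass <- anchored
    est2 <- estimate_theta(
      data.table::data.table(locus_id = pass$locus_id, ref = pass$ref,
                             alt = pass$alt),
      plasma, prior = cfg$theta_prior)
    if (abs(est2$theta - theta) < cfg$conv_tol) {
      theta <- est2$theta
      est <- est2
      converged <- TRUE
      break
    }
    theta <- est2$theta
    est <- est2
  }
  structure(list(theta = est, members = members,
                 n_refinement_rounds = rounds, converged = converged,
                 empty = !nrow(members)),
            class = "cluster_result")
}

#' Mask detected cluster loci from a pileup set
#'
#' Removes the member loci (and all their observations) so subsequent
#' iterations cannot re-detect them; masking an empty cluster is a no-op.
#'
#' @param ps A `pileup_set`.
#' @param cluster A `cluster_result`.
#' @return The masked `pileup_set`.
#' @export
mask_detected <- function(ps, cluster) {
  if (cluster$empty) return(ps)
  mask_loci(ps, cluster$members$locus_id)
}

#' Call somatic SNVs from matched plasma / germline pileups
#'
#' The full pipeline: iteratively detect mutation clusters in decreasing
#' frequency order (masking each detected cluster), then apply the
#' misalignment co-occurrence filter (when per-read mismatch positions are
#' available) and the read-level classifier filter to the union of calls,
#' and estimate the tumor fraction from the highest-VAF class of the final
#' call set. Deterministic for fixed inputs and configuration.
#'
#' @param plasma,germline `pileup_set`s over a common locus panel.
#' @param cfg A [caller_config()].
#' @param mm_positions Optional list mapping `read_id` to integer mismatch
#'   positions, enabling the co-occurrence artifact filter.
#' @return List of class `snv_callset`: `calls` (data.frame: chrom, pos,
#'   ref, alt, vaf, depth, alt_count, cluster_index, category,
#'   n_supporting, n_confirmed), `clusters` (list of `cluster_result`s),
#'   `tumor_fraction`, `config`.
#' @export
call_variants <- function(plasma, germline, cfg = caller_config(),
                          mm_positions = NULL) {
  stopifnot(inherits(plasma, "pileup_set"), inherits(germline, "pileup_set"))
  clusters <- list()
  calls <- list()
  pl <- plasma
  gl <- germline
  for (k in seq_len(cfg$max_clusters)) {
    cl <- converge_cluster(pl, gl, cfg)
    if (cl$empty) break
    m <- cl$members
    m$cluster_index <- k
    m$cluster_theta <- cl$theta$theta
    clusters[[k]] <- cl
    calls[[k]] <- m
    pl <- mask_detected(pl, cl)
    gl <- mask_detected(gl, cl)
  }
  calls <- if (length(calls)) do.call(rbind, calls) else data.frame()

  if (nrow(calls) && !is.null(mm_positions)) {
    artifact <- .cooccurrence_flags(calls, plasma, mm_positions)
    calls <- calls[!artifact, ]
  }

  if (nrow(calls)) {
    calls$n_supporting <- NA_integer_
    calls$n_confirmed <- NA_integer_
    ctx_map <- if ("context" %in% names(plasma$loci)) {
      setNames(plasma$loci$context, plasma$loci$locus_id)
    } else NULL
    keep <- rep(TRUE, nrow(calls))
    pobs <- .split_obs(plasma, calls$locus_id)
    for (i in seq_len(nrow(calls))) {
      sup <- pobs[[i]]
      sup <- sup[sup$base == calls$alt[i], , drop = FALSE]
      if (!nrow(sup)) {
        keep[i] <- FALSE
        next
      }
      if (!is.null(cfg$classifier)) {
        sup$context <- if (is.null(ctx_map)) paste0("N", calls$ref[i], "N")
                       else unname(ctx_map[as.character(calls$locus_id[i])])
        sup$variant_base <- calls$alt[i]
        res <- filter_candidate_by_reads(sup, cfg$classifier,
                                         cfg$min_confirmed)
        calls$n_supporting[i] <- res$n_supporting
        calls$n_confirmed[i] <- res$n_confirmed
        keep[i] <- res$keep
      } else {
        calls$n_supporting[i] <- nrow(sup)
        calls$n_confirmed[i] <- nrow(sup)
        keep[i] <- nrow(sup) >= cfg$min_confirmed
      }
    }
    calls <- calls[keep, ]
  }

  tumor_fraction <- NA_real_
  if (nrow(calls)) {
    tf <- estimate_tumor_fraction(calls, plasma, prior = cfg$theta_prior)
    tumor_fraction <- tf$fraction
  }
  structure(list(calls = calls, clusters = clusters,
                 tumor_fraction = tumor_fraction, config = cfg),
            class = "snv_callset")
}

#' @export
print.snv_callset <- function(x, ...) {
  cat(sprintf("<snv_callset> %d calls in %d clusters, tumor fraction %.3f\n",
              nrow(x$calls), length(x$clusters), x$tumor_fraction))
  invisible(x)
}

# apply the co-occurrence artifact filter to a call table given per-read
# mismatch positions (list keyed by read_id)
.cooccurrence_flags <- function(calls, plasma, mm_positions) {
  pobs <- .split_obs(plasma, calls$locus_id)
  var_sets <- list()
  ref_sets <- list()
  for (i in seq_len(nrow(calls))) {
    o <- pobs[[i]]
    is_alt <- o$base == calls$alt[i]
    grabpos <- function(ids) {
      lapply(ids, function(id) {
        p <- mm_positions[[id]]
        if (is.null(p)) integer() else setdiff(p, calls$pos[i])
      })
    }
    var_sets[[i]] <- grabpos(o$read_id[is_alt])
    ref_sets[[i]] <- grabpos(o$read_id[o$base == calls$ref[i]])
  }
  misalignment_cooccurrence_filter(var_sets, ref_sets)
}
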