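# One-dimensional natural-breaks (Jenks) classification, exact dynamic
# program over sorted values. Used to seed mutation clusters from VAFs and to
# pick the highest-VAF class for the tumor-fraction estimate.

#' Jenks natural breaks on a numeric vector
#'
#' Exact optimal partition of sorted values into `k` contiguous classes
#' minimizing the total within-class sum of squared deviations (Fisher's
#' dynamic program, O(n^2 k)). Returns the class assignment in the original
#' order plus the goodness of variance fit
#' `GVF = 1 - SS_within / SS_total` used to judge whether the split is real.
#'
#' @param x Numeric vector (n >= 1).
#' @param k Number of classes (default 2); capped at the number of distinct
#'   values.
#' @return List with `class` (integer vector, 1 = lowest class), `breaks`
#'   (upper value of each class), and `gvf`.
#' @examples
#' jenks_breaks(c(0.24, 0.26, 0.25, 0.05, 0.04), k = 2)$class
#' @export
jenks_breaks <- function(x, k = 2L) {
  stopifnot(length(x) >= 1L, k >= 1L)
  k <- min(k, length(unique(x)))
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)

  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  # ssq(i, j): within-class SS of xs[i..j]
  ssq <- function(i, j) {
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }

  # D[m, j]: minimal SS of partitioning xs[1..j] into m classes
  D <- matrix(Inf, k, n)
  B <- matrix(1L, k, n)  # start index of the last class
  for (j in 1:n) D[1L, j] <- ssq(1L, j)
  if (k > 1L) {
    for (m in 2:k) {
      for (j in m:n) {
        best <- Inf
        bi <- m
        for (i in m:j) {
          v <- D[m - 1L, i - 1L] + ssq(i, j)
          if (v < best) {
            best <- v
            bi <- i
          }
        }
        D[m, j] <- best
        B[m, j] <- bi
      }
    }
  }

  cls_sorted <- integer(n)
  j <- n
  for (m in k:1) {
    i <- B[m, j]
    cls_sorted[i:j] <- m
    j <- i - 1L
    if (j < 1L) break
  }
  cls <- integer(n)
  cls[ord] <- cls_sorted

  total_ss <- ssq(1L, n)
  gvf <- if (total_ss > 0) 1 - D[k, n] / total_ss else 1
  breaks <- vapply(seq_len(k), function(m) max(xs[cls_sorted == m]), 0)
  list(class = cls, breaks = breaks, gvf = gvf, k = k)
}

# Highest-VAF class membership. The class count is scanned upward from 2;
# a split is accepted when the top class (>= 3 members) sits more than
# `sep` times the binomial sampling spread above the class below it. The
# spread of class c is the *expected* binomial standard deviation
# sqrt(v(1-v)/depth) at the class mean -- unlike the empirical sd it does
# not shrink when a single cluster is artificially cut, so the best
# artificial split of a unimodal VAF set scores <= ~1.2 while genuinely
# distinct cluster pairs score >= ~2.0 even after selection bias.
# Without per-locus depths the empirical sd is used instead. If no k
# yields an accepted split, all values form one class.
top_jenks_class <- function(vaf, depth = NULL, k_max = 4L, sep = 1.8) {
  n <- length(vaf)
  if (n < 6L || length(unique(vaf)) < 3L) return(rep(TRUE, n))
  class_spread <- function(idx) {
    if (!is.null(depth)) {
      v <- max(mean(vaf[idx]), 1e-6)
      sqrt(v * (1 - v) / mean(depth[idx]))
    } else if (sum(idx) > 1L) {
      stats::sd(vaf[idx])
    } else 0
  }
  for (k in 2:min(k_max, length(unique(vaf)))) {
    jb <- jenks_breaks(vaf, k = k)
    top <- jb$class == jb$k
    nxt <- jb$class == jb$k - 1L
    if (sum(top) < 3L || sum(nxt) < 1L) next
    gap <- mean(vaf[top]) - mean(vaf[nxt])
    spread <- sep * sqrt(class_spread(top)^2 + class_spread(nxt)^2)
    if (is.na(spread)) spread <- 0
    if (gap > spread) return(top)
  }
  rep(TRUE, n)
}
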