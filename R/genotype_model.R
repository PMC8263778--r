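#' @importFrom stats binom.test fisher.test rbinom rnorm rpois runif setNames
#' @importFrom utils head write.table read.table
NULL

GENOTYPES <- c("AA", "AB", "BB")

# observations with an error probability above this carry no information
UNINFORMATIVE_EPS <- 0.75

#' Combined sequencing-error probability from mapping and base quality
#'
#' The probability that an observed base call is wrong, combining the
#' Phred-scale mapping quality `m` and base quality `q` of the read:
#' \deqn{\epsilon = 1 - (1 - 10^{-m/10})(1 - 10^{-q/10})}
#' Either a misplaced read or a miscalled base makes the observation
#' unreliable, and the two error sources are treated as independent.
#'
#' @param map_qual Phred-scale mapping quality (numeric, >= 0). Vectorized.
#' @param base_qual Phred-scale base quality (numeric, >= 0). Vectorized.
#' @return Error probability in `[0, 1]`, symmetric in the two arguments.
#' @examples
#' error_probability(20, 20)  # 1 - 0.99^2 = 0.0199
#' @export
error_probability <- function(map_qual, base_qual) {
  if (any(map_qual < 0) || any(base_qual < 0)) {
    stop("Phred qualities must be non-negative")
  }
  1 - (1 - 10^(-map_qual / 10)) * (1 - 10^(-base_qual / 10))
}

#' Likelihood of an observed base under a locus genotype
#'
#' Probability of observing base call `base` given a diploid genotype over the
#' locus alleles A (reference) and B (alternate), with sequencing-error
#' probability `eps`. All error directions are equally likely, so a genotype
#' allele is read correctly with probability `1 - eps` and each of the three
#' other bases receives `eps / 3`:
#' \itemize{
#'   \item `P(A | AA) = 1 - eps`, any other base `eps/3`
#'   \item `P(A | AB) = P(B | AB) = (1 - eps)/2 + eps/6`, the two
#'     non-genotype bases `eps/3` each
#'   \item `P(B | BB) = 1 - eps`, any other base `eps/3`
#' }
#' The four base probabilities sum to one for every genotype. `N` calls (or
#' observations with `eps` above the uninformative cutoff 0.75) contribute
#' likelihood 1.
#'
#' @param base Observed base call, one of `A C G T N` (vectorized).
#' @param genotype One of `"AA"`, `"AB"`, `"BB"` (relative to `ref`/`alt`).
#' @param eps Error probability per observation (vectorized with `base`).
#' @param ref,alt The locus reference and alternate alleles. `alt` may be `NA`
#'   when no alternate allele is defined (then only `"AA"` is meaningful).
#' @return Numeric vector of likelihoods.
#' @export
base_likelihood <- function(base, genotype, eps, ref, alt) {
  genotype <- match.arg(genotype, GENOTYPES)
  L <- base_likelihood_matrix(base, eps, ref, alt)
  unname(L[, genotype])
}

# n x 3 matrix of P(base | g) for g in AA, AB, BB; the vectorized workhorse
# behind every likelihood in the package.
base_likelihood_matrix <- function(base, eps, ref, alt) {
  n <- length(base)
  is_ref <- base == ref
  is_alt <- !is.na(alt) & base == alt
  uninf <- base == "N" | eps >= UNINFORMATIVE_EPS
  third <- eps / 3
  het <- 0.5 * (1 - eps) + eps / 6
  L <- cbind(
    AA = ifelse(is_ref, 1 - eps, third),
    AB = ifelse(is_ref | is_alt, het, third),
    BB = ifelse(is_alt, 1 - eps, third)
  )
  L[uninf, ] <- 1
  L
}

#' Joint-genotype prior table
#'
#' Prior over the joint genotype triplet `(g_T, g_N, g_W)` of tumor-derived
#' cfDNA, normal cfDNA and white-blood-cell DNA. Because the overwhelming
#' majority of normal cfDNA originates from white blood cells, the prior is
#' zero whenever `g_W != g_N`; the remaining mass is a table over
#' `(g_N, g_T)` built from a diploid germline prior and a small per-allele
#' somatic transition probability:
#' \itemize{
#'   \item germline: `P(AA) = 1 - 3h/2`, `P(AB) = h`, `P(BB) = h/2` with
#'     heterozygosity `h`
#'   \item somatic transition: each single-allele change costs a factor `s`,
#'     a double change `s^2`, e.g. `P(g_T = AB | g_N = AA) = s`.
#' }
#'
#' @param heterozygosity Germline heterozygosity `h` (default `1e-3`).
#' @param somatic_rate Somatic transition probability `s` per changed allele
#'   (default `1e-5`).
#' @return An object of class `prior_table`: a 3x3 matrix `p[g_N, g_T]`
#'   summing to one, with the two rates kept as attributes.
#' @examples
#' p <- default_prior_table()
#' sum(p)  # 1
#' @export
default_prior_table <- function(heterozygosity = 1e-3, somatic_rate = 1e-5) {
  h <- heterozygosity
  s <- somatic_rate
  g_n <- c(AA = 1 - 1.5 * h, AB = h, BB = 0.5 * h)
  trans <- rbind(
    AA = c(AA = 1 - s - s^2, AB = s,         BB = s^2),
    AB = c(AA = s,           AB = 1 - 2 * s, BB = s),
    BB = c(AA = s^2,         AB = s,         BB = 1 - s - s^2)
  )
  p <- trans * g_n
  p <- p / sum(p)
  structure(p, class = c("prior_table", class(p)),
            heterozygosity = h, somatic_rate = s)
}

#' Potential-locus prior used for cluster-frequency estimation
#'
#' At selected potential mutation loci the germline sample is guaranteed clean
#' (only reference alleles), so `g_W = g_N = AA` is fixed and the prior mass
#' is spread uniformly over the tumor genotype `g_T`. Spreading it uniformly
#' makes the tumor-component read density equal, term by term, to the
#' heterozygous-genotype density, which is the appropriate reference model for
#' candidate somatic sites; a sharper table can be substituted.
#'
#' @return A `prior_table` with all mass on the `g_N = AA` row.
#' @export
theta_prior_table <- function() {
  p <- matrix(0, 3, 3, dimnames = list(GENOTYPES, GENOTYPES))
  p["AA", ] <- 1 / 3
  structure(p, class = c("prior_table", class(p)),
            heterozygosity = 0, somatic_rate = 1 / 3)
}

#' Read a prior table from a TSV or JSON config file
#'
#' TSV layout: columns `g_N`, `g_T`, `p` (9 rows). JSON layout: an object
#' mapping `"g_N,g_T"` to probability. The table must be non-negative and sum
#' to one (tolerance 1e-8).
#'
#' @param path File path (`.tsv`/`.txt` or `.json`).
#' @return A `prior_table`.
#' @export
read_prior_table <- function(path) {
  if (grepl("\\.json$", path)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    keys <- strsplit(names(x), ",", fixed = TRUE)
    df <- data.frame(g_N = vapply(keys, `[`, "", 1L),
                     g_T = vapply(keys, `[`, "", 2L),
                     p = as.numeric(unlist(x)))
  } else {
    df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  p <- matrix(0, 3, 3, dimnames = list(GENOTYPES, GENOTYPES))
  p[cbind(df$g_N, df$g_T)] <- df$p
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("prior table must be non-negative and sum to 1")
  }
  structure(p, class = c("prior_table", class(p)))
}

#' Prior probability of one joint genotype triplet
#'
#' Looks up `P(g_N, g_T)` when `g_W == g_N`, and returns 0 otherwise: the
#' white-blood-cell genotype must agree with the normal-cfDNA genotype.
#'
#' @param g_T,g_N,g_W Genotypes, each one of `"AA"`, `"AB"`, `"BB"`.
#' @param table A `prior_table` (default [default_prior_table()]).
#' @return Prior probability of the triplet.
#' @export
joint_prior <- function(g_T, g_N, g_W, table = default_prior_table()) {
  if (g_W != g_N) return(0)
  unclass(table)[g_N, g_T]
}

#' Two-subpopulation mixture likelihood of one read observation
#'
#' A cfDNA read originates from tumor-derived cfDNA with probability `theta`
#' and from normal cfDNA with probability `1 - theta`, so its likelihood is
#' `theta * P(X | g_T) + (1 - theta) * P(X | g_N)`, with per-genotype terms
#' from [base_likelihood()] at the observation's error probability.
#'
#' @param base Observed base call(s).
#' @param map_qual,base_qual Phred qualities of the observation(s).
#' @param g_T,g_N Tumor-derived and normal cfDNA genotypes.
#' @param theta Mixture fraction in `[0, 1]`.
#' @param ref,alt Locus alleles.
#' @return Likelihood per observation.
#' @export
read_likelihood_mixture <- function(base, map_qual, base_qual, g_T, g_N,
                                    theta, ref, alt) {
  stopifnot(theta >= 0, theta <= 1)
  eps <- error_probability(map_qual, base_qual)
  L <- base_likelihood_matrix(base, eps, ref, alt)
  unname(theta * L[, g_T] + (1 - theta) * L[, g_N])
}

# All prior-valid joint-genotype triplets (g_W == g_N), as a data.frame.
valid_triplets <- function() {
  g <- expand.grid(g_T = GENOTYPES, g_N = GENOTYPES,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$g_W <- g$g_N
  g[, c("g_T", "g_N", "g_W")]
}
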