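# Diversity measures: expected heterozygosity, nucleotide diversity,
# Watterson's theta, and the frequency-independent average substitution
# rate among allele types (final sigma), plus the exhaustive subset oracle.

#' Per-site substitution rate (p-distance) between two sequences
#'
#' The number of mismatching sites divided by the sequence length; the raw
#' p-distance with no multiple-hit correction.
#'
#' @param s1,s2 Nucleotide strings of equal length over `A,C,G,T`.
#' @return A rate in `[0, 1]`.
#' @examples
#' pairwise_substitution_rate("AAT", "AAA")  # 1/3
#' @export
pairwise_substitution_rate <- function(s1, s2) {
  if (nchar(s1) != nchar(s2)) stop("sequences must have equal length", call. = FALSE)
  if (nchar(s1) < 1L) stop("sequences must be non-empty", call. = FALSE)
  x <- strsplit(toupper(s1), "")[[1]]
  y <- strsplit(toupper(s2), "")[[1]]
  mean(x != y)
}

#' Pairwise substitution-rate matrix among sequences
#'
#' Computes all pairwise p-distances via one-hot encoding and matrix
#' products (fast enough for the haplotype sets arising inside the
#' simulation experiments).
#'
#' @param seqs Character vector of equal-length sequences over `A,C,G,T`.
#' @param full_length Optional denominator: when `seqs` hold only the
#'   variable columns of a longer alignment, pass the original number of
#'   sites so rates stay per-site of the full locus.
#' @return A symmetric `length(seqs)` square matrix with zero diagonal.
#' @export
substitution_rate_matrix <- function(seqs, full_length = NULL) {
  m <- length(seqs)
  L <- if (is.null(full_length)) nchar(seqs[1L]) else full_length
  if (m == 0L) return(matrix(numeric(0), 0, 0))
  k <- nchar(seqs[1L])
  if (k == 0L) return(matrix(0, m, m))
  x <- matrix(match(unlist(strsplit(seqs, ""), use.names = FALSE), DNA_BASES),
              nrow = m, ncol = k, byrow = TRUE)
  if (anyNA(x)) stop("sequences contain non-ACGT characters", call. = FALSE)
  shared <- matrix(0, m, m)
  for (b in 1:4) {
    ind <- (x == b) * 1
    shared <- shared + tcrossprod(ind)
  }
  r <- (k - shared) / L
  diag(r) <- 0
  r
}

#' Expected heterozygosity
#'
#' `He = 1 - sum(p_i^2)`: the probability that two alleles drawn by their
#' frequencies are of different types.
#'
#' @param freqs Allele frequencies summing to 1.
#' @return A value in `[0, 1 - 1/m]`.
#' @export
expected_heterozygosity <- function(freqs) {
  check_freqs(freqs)
  1 - sum(freqs^2)
}

check_freqs <- function(freqs) {
  if (any(freqs < 0)) stop("allele frequencies must be non-negative", call. = FALSE)
  if (abs(sum(freqs) - 1) > 1e-8) stop("allele frequencies must sum to 1", call. = FALSE)
  invisible(freqs)
}

#' Unbiased estimator of expected heterozygosity
#'
#' The finite-sample correction `2n/(2n-1) * (1 - sum(p_i^2))`. The factor
#' may be overridden (e.g. `n/(n-1)` for a purely haploid convention).
#'
#' @param freqs Sample allele frequencies summing to 1.
#' @param n Sample size (`>= 1`).
#' @param factor Correction factor; default `2n/(2n-1)`.
#' @return The corrected heterozygosity.
#' @export
expected_heterozygosity_unbiased <- function(freqs, n, factor = NULL) {
  if (n < 1) stop("sample size must be >= 1", call. = FALSE)
  if (is.null(factor)) factor <- 2 * n / (2 * n - 1)
  factor * expected_heterozygosity(freqs)
}

#' Nucleotide diversity from allele frequencies and substitution rates
#'
#' The frequency-weighted mean pairwise per-site substitution rate,
#' `pi = sum_i sum_j p_i p_j pi_ij`. With `corrected = TRUE` the
#' `n/(n-1)` small-sample correction is applied (the estimator commonly
#' written pi-tilde).
#'
#' @param freqs Allele-type frequencies summing to 1.
#' @param rates Symmetric per-site substitution-rate matrix among the same
#'   allele types (zero diagonal).
#' @param corrected Apply the `n/(n-1)` correction?
#' @param n Sample size; required when `corrected = TRUE`.
#' @return The (corrected) nucleotide diversity.
#' @export
nucleotide_diversity <- function(freqs, rates, corrected = FALSE, n = NULL) {
  check_freqs(freqs)
  if (length(freqs) != nrow(rates) || nrow(rates) != ncol(rates)) {
    stop("freqs and rates are not conformable", call. = FALSE)
  }
  pi_hat <- drop(crossprod(freqs, rates %*% freqs))
  if (!corrected) return(pi_hat)
  if (is.null(n)) stop("n is required for the corrected estimator", call. = FALSE)
  if (n < 2) stop("the corrected estimator requires n >= 2", call. = FALSE)
  n / (n - 1) * pi_hat
}

#' Number of segregating sites
#'
#' A column is segregating iff it shows two or more distinct bases among
#' `A,C,G,T` (the alignment must be cleaned first).
#'
#' @param a A cleaned [alignment()].
#' @return Integer count `K`.
#' @export
segregating_sites <- function(a) {
  stopifnot(inherits(a, "alignment"))
  assert_clean(a)
  if (a$length == 0L || a$n < 2L) return(0L)
  m <- seq_char_matrix(a)
  sum(apply(m, 2, function(col) length(unique(col)) > 1L))
}

#' Watterson's theta
#'
#' `theta_w = K / H_{n-1}` with `K` the number of segregating sites and
#' `H_{n-1}` the harmonic number; `per_site = TRUE` divides by the
#' alignment length.
#'
#' @param a A cleaned [alignment()] with `n >= 2`.
#' @param per_site Report the per-site value?
#' @return Watterson's theta (whole-locus or per-site).
#' @export
watterson_theta <- function(a, per_site = FALSE) {
  stopifnot(inherits(a, "alignment"))
  if (a$n < 2L) stop("Watterson's theta requires n >= 2", call. = FALSE)
  k <- segregating_sites(a)
  th <- k / harmonic(a$n - 1L)
  if (per_site) th / a$length else th
}

#' Average substitution rate among allele types (final sigma statistic)
#'
#' The frequency-independent diversity measure: the mean per-site
#' substitution rate over all ordered pairs of distinct allele types,
#' `sum_i sum_j pi_ij / (m (m - 1))`, and 0 for a monomorphic sample
#' (`m = 1`). Unlike nucleotide diversity it ignores allele frequencies,
#' so rare but phylogenetically distant alleles carry full weight.
#'
#' @param alleles An `"allele_set"` from [collapse_alleles()].
#' @param rates Optional substitution-rate matrix over the `m` haplotypes
#'   (computed from the allele set when omitted).
#' @return The statistic, in `[0, 1]`.
#' @examples
#' a <- alignment(c("AAA", "GGG", "TTT"))
#' sigma_tilde(collapse_alleles(a))  # 1
#' @export
sigma_tilde <- function(alleles, rates = NULL) {
  stopifnot(inherits(alleles, "allele_set"))
  m <- alleles$m
  if (m == 1L) return(0)
  if (is.null(rates)) rates <- substitution_rate_matrix(alleles$haplotypes)
  if (nrow(rates) != m) stop("rates must be over the m distinct haplotypes", call. = FALSE)
  sum(rates) / (m * (m - 1))
}

#' Frequency-independent diversity of an alignment
#'
#' Convenience wrapper: collapses to allele types and applies
#' [sigma_tilde()]. On a whole statistical population this is the
#' parameter itself (the average substitution rate among all allele
#' types); on a sample it is the estimator.
#'
#' @param a A cleaned [alignment()].
#' @return The statistic, in `[0, 1]`.
#' @export
sigma_hat <- function(a) {
  sigma_tilde(collapse_alleles(a))
}

#' Exhaustive subset oracle for the maximal average substitution rate
#'
#' For a small population, enumerates every size-`n` subset of sequences
#' and returns the maximum of [sigma_tilde()] over them. This is the
#' auxiliary quantity that spatial sampling targets; it is non-increasing
#' in `n` and equals the population value at `n = N`.
#'
#' @param population An [alignment()] holding the whole population.
#' @param n Subset size, `2 <= n <= N`.
#' @param cap Refuse enumeration when `choose(N, n)` exceeds this guard
#'   (combinatorial explosion).
#' @return The maximal subset statistic.
#' @export
sigma_n_oracle <- function(population, n, cap = 2e5) {
  stopifnot(inherits(population, "alignment"))
  N <- population$n
  if (n < 2 || n > N) stop("n must satisfy 2 <= n <= N", call. = FALSE)
  if (choose(N, n) > cap) {
    stop("choose(N, n) exceeds the enumeration cap (combinatorial explosion)",
         call. = FALSE)
  }
  al <- collapse_alleles(population)
  rh <- substitution_rate_matrix(al$haplotypes)
  best <- 0
  subsets <- utils::combn(N, n)
  for (j in seq_len(ncol(subsets))) {
    hs <- unique(al$index[subsets[, j]])
    k <- length(hs)
    if (k == 1L) next
    val <- sum(rh[hs, hs]) / (k * (k - 1))
    if (val > best) best <- val
  }
  best
}

#' All seven diversity measures of an alignment
#'
#' One pass computing expected heterozygosity, its unbiased estimator,
#' plug-in and corrected nucleotide diversity, whole-locus and per-site
#' Watterson's theta, and the frequency-independent average substitution
#' rate among allele types, together with `n`, `m` and `K`.
#'
#' @param a A cleaned [alignment()] with `n >= 2`.
#' @param per_site_length Denominator for the per-site theta (defaults to
#'   the alignment length).
#' @return An object of class `"diversity_summary"`: a list with elements
#'   `He`, `He_hat`, `pi_hat`, `pi_tilde`, `theta_w`, `theta_w_site`,
#'   `sigma_hat`, `n`, `m`, `K`.
#' @examples
#' calc_diversity(alignment(c("AAA", "GGG", "TTT")))
#' @export
calc_diversity <- function(a, per_site_length = NULL) {
  stopifnot(inherits(a, "alignment"))
  assert_clean(a)
  if (a$n < 2L) stop("diversity summary requires n >= 2", call. = FALSE)
  if (is.null(per_site_length)) per_site_length <- a$length
  al <- collapse_alleles(a)
  rates <- substitution_rate_matrix(al$haplotypes)
  He <- expected_heterozygosity(al$freqs)
  He_hat <- expected_heterozygosity_unbiased(al$freqs, a$n)
  pi_hat <- nucleotide_diversity(al$freqs, rates)
  pi_tilde <- nucleotide_diversity(al$freqs, rates, corrected = TRUE, n = a$n)
  K <- segregating_sites(a)
  theta_w <- K / harmonic(a$n - 1L)
  structure(
    list(He = He, He_hat = He_hat, pi_hat = pi_hat, pi_tilde = pi_tilde,
         theta_w = theta_w, theta_w_site = theta_w / per_site_length,
         sigma_hat = sigma_tilde(al, rates),
         n = a$n, m = al$m, K = K),
    class = "diversity_summary"
  )
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("Diversity summary (n = %d, m = %d, K = %d)\n", x$n, x$m, x$K))
  vals <- c(He = x$He, He_hat = x$He_hat, pi_hat = x$pi_hat,
            pi_tilde = x$pi_tilde, theta_w = x$theta_w,
            theta_w_site = x$theta_w_site, sigma_hat = x$sigma_hat)
  for (nm in names(vals)) cat(sprintf("  %-13s %g\n", nm, vals[[nm]]))
  invisible(x)
}

#' Coerce a diversity summary to a one-row data frame
#' @param x A `"diversity_summary"`.
#' @param ... Unused.
#' @export
as.data.frame.diversity_summary <- function(x, ...) {
  data.frame(He = x$He, He_hat = x$He_hat, pi_hat = x$pi_hat,
             pi_tilde = x$pi_tilde, theta_w = x$theta_w,
             theta_w_site = x$theta_w_site, sigma_hat = x$sigma_hat,
             n = x$n, m = x$m, K = x$K)
}
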