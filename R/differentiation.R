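# Between-deme differentiation: frequency-based Gst and its nucleotide
# analogue Nst, used as diagnostics of the simulated population structure.

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("differentiation requires at least two groups", call. = FALSE)
  }
  lens <- vapply(groups, function(g) {
    stopifnot(inherits(g, "alignment"))
    g$length
  }, integer(1))
  if (length(unique(lens)) > 1L) {
    stop("all groups must share the same sequence length", call. = FALSE)
  }
  invisible(groups)
}

pool_alignments <- function(groups) {
  seqs <- unlist(lapply(groups, `[[`, "seqs"), use.names = FALSE)
  alignment(seqs, ids = paste0("s", seq_along(seqs)))
}

#' Gst: haplotype-frequency differentiation among groups
#'
#' Nei's decomposition `(H_T - H_S)/H_T`, where `H_S` is the sample-size
#' weighted mean within-group expected heterozygosity of haplotype
#' frequencies and `H_T` the expected heterozygosity of the pooled
#' frequencies. Returns 0 (with attribute `undefined = TRUE`) when the
#' pooled population is monomorphic.
#'
#' @param groups A list of cleaned [alignment()]s, one per deme.
#' @return A value in `[0, 1]`.
#' @export
gst <- function(groups) {
  check_groups(groups)
  sizes <- vapply(groups, `[[`, integer(1), "n")
  w <- sizes / sum(sizes)
  hs <- sum(w * vapply(groups, function(g) {
    expected_heterozygosity(collapse_alleles(g)$freqs)
  }, numeric(1)))
  pooled <- collapse_alleles(pool_alignments(groups))
  ht <- expected_heterozygosity(pooled$freqs)
  if (ht == 0) return(structure(0, undefined = TRUE))
  (ht - hs) / ht
}

#' Nst: nucleotide-level differentiation among groups
#'
#' The analogue of [gst()] built on nucleotide diversity:
#' `(v_T - v_S)/v_T` with `v_S` the weighted mean within-group plug-in
#' nucleotide diversity and `v_T` the pooled value. Returns 0 (flagged)
#' when the pooled diversity is zero.
#'
#' @param groups A list of cleaned [alignment()]s, one per deme.
#' @return The differentiation index.
#' @export
nst <- function(groups) {
  check_groups(groups)
  sizes <- vapply(groups, `[[`, integer(1), "n")
  w <- sizes / sum(sizes)
  pi_of <- function(a) {
    al <- collapse_alleles(a)
    nucleotide_diversity(al$freqs, substitution_rate_matrix(al$haplotypes))
  }
  vs <- sum(w * vapply(groups, pi_of, numeric(1)))
  vt <- pi_of(pool_alignments(groups))
  if (vt == 0) return(structure(0, undefined = TRUE))
  (vt - vs) / vt
}
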