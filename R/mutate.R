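# GTR sequence evolution along a genealogy.

#' General time reversible substitution model
#'
#' Builds a GTR rate matrix from six exchangeabilities and four base
#' frequencies, scaled so the expected number of substitutions per site
#' per generation equals `mu`. The default (all exchangeabilities 1,
#' equal frequencies) is the Jukes-Cantor special case of GTR.
#'
#' @param mu Per-site per-generation substitution rate.
#' @param exchangeabilities Six rates for the unordered pairs
#'   AC, AG, AT, CG, CT, GT.
#' @param base_freqs Equilibrium frequencies of A, C, G, T (sum to 1).
#' @return An object of class `"substitution_model"` with the scaled rate
#'   matrix `Q`, its eigendecomposition (for fast transition matrices),
#'   `mu` and `base_freqs`.
#' @export
substitution_model <- function(mu, exchangeabilities = rep(1, 6),
                               base_freqs = rep(0.25, 4)) {
  if (mu < 0) stop("mu must be non-negative", call. = FALSE)
  if (length(exchangeabilities) != 6L || any(exchangeabilities < 0)) {
    stop("exchangeabilities must be six non-negative rates", call. = FALSE)
  }
  if (length(base_freqs) != 4L || any(base_freqs <= 0) ||
      abs(sum(base_freqs) - 1) > 1e-8) {
    stop("base_freqs must be four positive frequencies summing to 1", call. = FALSE)
  }
  s <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  s[upper.tri(s)] <- exchangeabilities
  s <- s + t(s)
  q <- s * rep(base_freqs, each = 4)   # q_ij = s_ij * pi_j
  diag(q) <- -rowSums(q)
  rate <- -sum(base_freqs * diag(q))   # expected substitutions/site/unit time
  if (rate > 0) q <- q * (mu / rate)
  # reversible Q diagonalised via the symmetrising similarity transform
  dhalf <- sqrt(base_freqs)
  b <- q * (dhalf / rep(dhalf, each = 4))  # B = D^1/2 Q D^-1/2 (symmetric)
  eg <- eigen((b + t(b)) / 2, symmetric = TRUE)
  structure(
    list(Q = q, mu = mu, base_freqs = base_freqs,
         eig = list(values = eg$values,
                    right = eg$vectors / dhalf,        # D^-1/2 U
                    left = t(eg$vectors * dhalf))),    # U' D^1/2
    class = "substitution_model"
  )
}

#' Transition probability matrix exp(Q t)
#'
#' @param model A `"substitution_model"`.
#' @param t Elapsed time (generations).
#' @return A 4x4 stochastic matrix.
#' @export
transition_matrix <- function(model, t) {
  e <- model$eig
  p <- e$right %*% (exp(e$values * t) * e$left)
  p[p < 0] <- 0
  p / rowSums(p)
}

#' Evolve sequences along a genealogy
#'
#' Draws the root sequence from the model's base frequencies and evolves
#' each site independently down every branch with the transition matrix
#' `exp(Q t)`; the tip sequences are returned as an alignment (one
#' sequence per individual), tagged with each tip's deme.
#'
#' @param g A `"genealogy"` from [simulate_genealogy()].
#' @param model A `"substitution_model"`.
#' @param length Number of sites (default 1000).
#' @param seed Optional integer seed.
#' @return A cleaned [alignment()] with attribute `demes` (deme index per
#'   sequence, in tip order).
#' @export
mutate_sequences <- function(g, model, length = 1000L, seed = NULL) {
  stopifnot(inherits(g, "genealogy"), inherits(model, "substitution_model"))
  if (length < 1L) stop("sequence length must be >= 1", call. = FALSE)
  tree <- g$tree
  n <- g$n
  n_nodes <- 2L * n - 1L
  L <- as.integer(length)

  with_seed(seed, {
    states <- matrix(0L, n_nodes, L)
    root <- n + 1L
    states[root, ] <- sample.int(4L, L, replace = TRUE, prob = model$base_freqs)

    # preorder: parents before children
    ord <- rev(seq_len(nrow(tree$edge)))
    for (ei in ord) {
      par <- tree$edge[ei, 1L]
      chi <- tree$edge[ei, 2L]
      tlen <- tree$edge.length[ei]
      s <- states[par, ]
      if (tlen > 0 && model$mu > 0) {
        p <- transition_matrix(model, tlen)
        stay <- p[cbind(s, s)]
        u <- stats::runif(L)
        hit <- which(u > stay)
        for (i in hit) {
          probs <- p[s[i], ]
          probs[s[i]] <- 0
          s[i] <- sample.int(4L, 1L, prob = probs)
        }
      }
      states[chi, ] <- s
    }

    seqs <- char_matrix_to_seqs(
      matrix(DNA_BASES[states[seq_len(n), , drop = FALSE]], nrow = n)
    )
    out <- alignment(seqs, ids = tree$tip.label)
    attr(out, "demes") <- g$leaf_demes
    out
  })
}
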