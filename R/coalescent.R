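# Structured coalescent: backward-in-time genealogy of haploid lineages
# distributed over demes, with competing-exponential coalescence and
# migration events.

#' Simulate a structured-coalescent genealogy
#'
#' Traces lineages backward in continuous time. Within deme `d` holding
#' `k_d` lineages of (haploid) size `N_d`, any pair coalesces at rate
#' `choose(k_d, 2) / N_d` per generation; each lineage in deme `i`
#' migrates to deme `j` at the backward rate `m_ij` taken directly from
#' the layout's migration matrix. Events compete as exponentials until the
#' grand MRCA. Branch lengths are in generations.
#'
#' @param layout A `"deme_layout"` with `sizes` set (see [assign_sizes()]),
#'   or a single-deme layout plus `lineages`.
#' @param lineages Optional integer vector: number of sampled lineages per
#'   deme. Defaults to the full deme sizes (whole-population mode).
#' @param seed Optional integer seed.
#' @param event_cap Guard against non-termination (e.g. zero migration
#'   with lineages split across demes): error beyond this many events.
#' @return An object of class `"genealogy"`: list with `tree` (an
#'   [ape::as.phylo] `"phylo"` with branch lengths), `leaf_demes`
#'   (deme index per tip, in tip order), `tmrca` (generations) and
#'   `n_events`.
#' @export
simulate_genealogy <- function(layout, lineages = NULL, seed = NULL,
                               event_cap = 5e6) {
  stopifnot(inherits(layout, "deme_layout"))
  L <- layout$n_demes
  sizes <- layout$sizes
  if (is.null(sizes)) {
    stop("layout has no deme sizes; call assign_sizes() first", call. = FALSE)
  }
  if (is.null(lineages)) lineages <- sizes
  lineages <- as.integer(lineages)
  if (length(lineages) != L) stop("lineages must have one entry per deme", call. = FALSE)
  n <- sum(lineages)
  if (n < 2L) stop("at least two lineages are required", call. = FALSE)
  occupied <- sum(lineages > 0L)
  if (occupied > 1L && sum(layout$migration) == 0) {
    stop("zero migration with lineages in multiple demes: no MRCA exists", call. = FALSE)
  }

  mig <- layout$migration
  mig_out <- rowSums(mig)

  with_seed(seed, {
    # active lineage bookkeeping
    node_deme <- rep.int(seq_len(L), lineages)      # deme of each active node
    node_id <- seq_len(n)                           # node ids of active lineages
    act <- n
    k <- tabulate(node_deme, nbins = L)             # lineages per deme
    node_time <- numeric(2L * n - 1L)
    edge <- matrix(0L, 2L * (n - 1L), 2L)
    edge_len <- numeric(2L * (n - 1L))
    next_node <- n
    e <- 0L
    t <- 0
    n_events <- 0L

    while (act > 1L) {
      coal_rate <- k * (k - 1) / (2 * sizes)
      mig_rate <- k * mig_out
      tot <- sum(coal_rate) + sum(mig_rate)
      if (tot <= 0) stop("no possible events remain before the MRCA", call. = FALSE)
      t <- t + stats::rexp(1L, tot)
      n_events <- n_events + 1L
      if (n_events > event_cap) {
        stop("event cap exceeded before reaching the MRCA (check migration rates)",
             call. = FALSE)
      }
      u <- stats::runif(1L) * tot
      cs <- cumsum(c(coal_rate, mig_rate))
      ev <- which.max(cs >= u)
      if (ev <= L) {
        # coalescence in deme d
        d <- ev
        in_d <- which(node_deme[seq_len(act)] == d)
        pick <- in_d[sample.int(length(in_d), 2L)]
        next_node <- next_node + 1L
        for (child_slot in pick) {
          e <- e + 1L
          edge[e, ] <- c(next_node, node_id[child_slot])
          edge_len[e] <- t - node_time[node_id[child_slot]]
        }
        node_time[next_node] <- t
        keep <- pick[1L]
        drop <- pick[2L]
        node_id[keep] <- next_node
        # remove the dropped slot by swapping in the last active slot
        node_id[drop] <- node_id[act]
        node_deme[drop] <- node_deme[act]
        act <- act - 1L
        k[d] <- k[d] - 1L
      } else {
        # migration out of deme d
        d <- ev - L
        in_d <- which(node_deme[seq_len(act)] == d)
        slot <- in_d[sample.int(length(in_d), 1L)]
        dest <- sample.int(L, 1L, prob = mig[d, ])
        node_deme[slot] <- dest
        k[d] <- k[d] - 1L
        k[dest] <- k[dest] + 1L
      }
    }

    # renumber internal nodes so the root is n + 1 (ape convention):
    # internal creation ids n+1 .. 2n-1 map to 3n - id
    internal <- edge > n
    edge[internal] <- 3L * n - edge[internal]
    leaf_demes <- rep.int(seq_len(L), lineages)
    tip_label <- paste0("d", leaf_demes, "_", sequence(lineages))
    tree <- structure(
      list(edge = edge, edge.length = edge_len,
           tip.label = tip_label, Nnode = n - 1L),
      class = "phylo", order = "postorder"
    )
    structure(
      list(tree = tree, leaf_demes = leaf_demes, tmrca = t,
           n_events = n_events, n = n),
      class = "genealogy"
    )
  })
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("Genealogy: %d tips, TMRCA = %.1f generations (%d events)\n",
              x$n, x$tmrca, x$n_events))
  invisible(x)
}

#' Total branch length of a genealogy (generations)
#'
#' @param g A `"genealogy"`.
#' @return Sum of all branch lengths.
#' @export
total_tree_length <- function(g) {
  sum(g$tree$edge.length)
}

#' Export a genealogy as a Newick string
#'
#' @param g A `"genealogy"`.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when writing to a file.
#' @export
genealogy_newick <- function(g, path = NULL) {
  if (is.null(path)) ape::write.tree(g$tree) else ape::write.tree(g$tree, file = path)
}
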