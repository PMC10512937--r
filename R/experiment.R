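# Simulation experiments: whole-population coalescent + mutation, spatial
# or random sampling, estimator bias (SME) and accuracy (SRMSE) tables.

#' Configure a simulation experiment
#'
#' The five designs: (1) stepping-stone on designed grids (linear, circle,
#' plane, cylinder) with even deme sizes; (2) stepping-stone on linear and
#' plane grids with centre-weighted (truncated-normal) sizes; (3) island
#' model on random coordinates with even sizes; (4) island model with
#' latitude-weighted sizes; (5) a single panmictic population sampled at
#' random. Experiments 1-4 sample spatially: annealing picks k demes, then
#' one individual is drawn per chosen deme.
#'
#' @param id Experiment number, 1-5.
#' @param N Total haploid population size.
#' @param n_demes Number of demes (ignored for id = 5). The cylinder
#'   structure uses the nearest even count, the plane the nearest square.
#' @param mu Per-site per-generation mutation rate.
#' @param seq_length Sites per sequence.
#' @param migration_rates Per-generation migration rates to sweep.
#' @param sample_sizes Sample sizes (spatially realisable sizes, i.e.
#'   `<= n_demes`, are used for the spatial designs).
#' @param replicates Coalescent replicates per migration rate.
#' @param annealing_iterations Annealing proposals for the location choice.
#' @param spacing_km Grid spacing of the designed layouts.
#' @param model Substitution model (default JC-equivalent GTR at `mu`).
#' @return An `"experiment_config"` list.
#' @export
experiment_config <- function(id,
                              N = 10000L,
                              n_demes = 100L,
                              mu = 2e-8,
                              seq_length = 1000L,
                              migration_rates = c(0.001, 0.01, 0.1, 0.5, 0.9),
                              sample_sizes = c(10L, 20L, 30L, 40L, 50L),
                              replicates = 20L,
                              annealing_iterations = 100000L,
                              spacing_km = 10,
                              model = NULL) {
  id <- as.integer(id)
  if (!id %in% 1:5) stop("experiment id must be 1..5", call. = FALSE)
  structures <- switch(id,
    c("linear", "circle", "plane", "cylinder"),
    c("linear", "plane"),
    "island",
    "island",
    "single")
  size_scheme <- switch(id, "even", "truncated_normal", "even", "latitude_normal", NA)
  sampling <- if (id == 5L) "random" else "spatial"
  if (is.null(model)) model <- substitution_model(mu)
  structure(
    list(id = id, structures = structures, size_scheme = size_scheme,
         sampling = sampling, N = as.integer(N), n_demes = as.integer(n_demes),
         mu = mu, seq_length = as.integer(seq_length),
         migration_rates = if (id == 5L) 0 else migration_rates,
         sample_sizes = as.integer(sample_sizes),
         replicates = as.integer(replicates),
         annealing_iterations = as.integer(annealing_iterations),
         spacing_km = spacing_km, model = model),
    class = "experiment_config"
  )
}

#' Desk-scale experiment configuration
#'
#' The reduced study conditions used throughout the package's own
#' verification runs: 1,000 haploids over 25 demes (26 for the cylinder),
#' mutation rate 2e-7 per site, 10 replicates, migration rates
#' 0.001-0.5 and spatial sample sizes 10 and 20 (plus 30 for the random
#' design, where the deme count imposes no ceiling).
#'
#' @param id Experiment number, 1-5.
#' @param ... Overrides passed to [experiment_config()].
#' @return An `"experiment_config"`.
#' @export
scaled_experiment_config <- function(id, ...) {
  defaults <- list(
    id = id, N = 1000L, n_demes = 25L, mu = 2e-7, seq_length = 1000L,
    migration_rates = c(0.001, 0.01, 0.1, 0.5),
    sample_sizes = c(10L, 20L, 30L),
    replicates = 10L, annealing_iterations = 20000L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(experiment_config, args)
}

structure_layout <- function(cfg, structure, rate, layout_seed) {
  if (structure == "single") {
    lay <- build_single_layout(N = cfg$N)
  } else if (structure == "island") {
    lay <- build_island_layout(n_demes = cfg$n_demes, migration_rate = rate,
                               seed = layout_seed)
  } else {
    nd <- cfg$n_demes
    if (structure == "cylinder" && nd %% 2L != 0L) nd <- nd + 1L
    if (structure == "plane") nd <- round(sqrt(nd))^2
    lay <- build_grid_layout(structure, migration_rate = rate, n_demes = nd,
                             spacing_km = cfg$spacing_km)
  }
  if (structure != "single") {
    lay <- assign_sizes(lay, cfg$size_scheme, cfg$N)
  }
  lay
}

scale_migration <- function(layout, from_rate, to_rate) {
  if (from_rate > 0) layout$migration <- layout$migration * (to_rate / from_rate)
  layout
}

#' Diversity parameters of a whole statistical population
#'
#' Computes the statistical parameters every estimator is benchmarked
#' against: plug-in nucleotide diversity, expected heterozygosity and the
#' average substitution rate among all allele types, plus the population
#' per-site Watterson's theta as a secondary reference. Populations with
#' no segregating site are flagged for exclusion.
#'
#' @param population A cleaned [alignment()] of all N sequences.
#' @return A list with `pi`, `He`, `sigma`, `theta_w_site`, `m`, `K`, `N`
#'   and `excluded`.
#' @export
compute_parameters <- function(population) {
  stopifnot(inherits(population, "alignment"))
  al <- collapse_alleles(population)
  K <- segregating_sites(population)
  rates <- substitution_rate_matrix(al$haplotypes)
  pi <- nucleotide_diversity(al$freqs, rates)
  list(
    pi = pi,
    He = expected_heterozygosity(al$freqs),
    sigma = sigma_tilde(al, rates),
    theta_w_site = if (population$n >= 2L) {
      K / harmonic(population$n - 1L) / population$length
    } else {
      0
    },
    m = al$m, K = K, N = population$n,
    excluded = (K == 0L)
  )
}

#' Draw a sample from a simulated population
#'
#' Spatial mode: the chosen demes (from [spatial_sample()], or supplied
#' precomputed) each contribute exactly one uniformly drawn individual.
#' Random mode: k individuals uniformly without replacement.
#'
#' @param population Alignment with a `demes` attribute (spatial mode).
#' @param layout The `"deme_layout"` the population was simulated on.
#' @param mode `"spatial"` or `"random"`.
#' @param k Sample size.
#' @param seed Optional seed for the individual draws.
#' @param chosen_demes Optional precomputed deme indices (length k).
#' @param annealing_iterations Annealing budget when demes must be chosen
#'   here.
#' @return An [alignment()] of the k sampled sequences.
#' @export
draw_sample <- function(population, layout = NULL, mode = c("spatial", "random"),
                        k, seed = NULL, chosen_demes = NULL,
                        annealing_iterations = 100000L) {
  mode <- match.arg(mode)
  stopifnot(inherits(population, "alignment"))
  if (mode == "random") {
    if (k > population$n) stop("k exceeds the population size", call. = FALSE)
    idx <- with_seed(seed, sample.int(population$n, k))
    return(subset_alignment(population, idx))
  }
  demes <- attr(population, "demes")
  if (is.null(demes)) stop("population carries no deme labels", call. = FALSE)
  if (is.null(chosen_demes)) {
    if (is.null(layout)) stop("spatial mode needs a layout or chosen_demes", call. = FALSE)
    if (k > layout$n_demes) stop("k exceeds the number of demes", call. = FALSE)
    chosen_demes <- spatial_sample(layout$coords, k, seed = seed,
                                   iterations = annealing_iterations)$chosen
  }
  idx <- with_seed(seed, vapply(chosen_demes, function(d) {
    members <- which(demes == d)
    if (length(members) == 0L) stop("chosen deme has no individuals", call. = FALSE)
    members[sample.int(length(members), 1L)]
  }, integer(1)))
  subset_alignment(population, idx)
}

#' Run a simulation experiment
#'
#' Full factorial over structure x migration rate x replicate x sample
#' size. Each replicate simulates the whole-population genealogy, mutates
#' sequences, computes the statistical parameters on all N sequences,
#' draws spatial (one individual per annealing-chosen deme) or random
#' samples, and records every estimator against its parameter. Spatial
#' deme choices are made once per (structure, k) since the layout is fixed
#' across replicates. Per-site Watterson's theta is recorded twice: against
#' the population nucleotide diversity (`reference = "pi"`, the headline)
#' and against the population per-site theta (`reference = "theta_pop"`).
#'
#' @param cfg An `"experiment_config"`.
#' @param seed Master seed; every stage derives its own stream from it.
#' @param verbose Print progress?
#' @return A list of class `"experiment_result"`: `replicates` (tidy data
#'   frame of every estimate), `summary` (per-cell SME/SRMSE table from
#'   [summarize_replicates()]), `parameters`, `gst_nst` and `config`.
#' @export
run_experiment <- function(cfg, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  base_rate <- cfg$migration_rates[1]
  rows <- list()
  prow <- list()
  frow <- list()
  seeds_struct <- derive_seeds(seed, length(cfg$structures))

  for (si in seq_along(cfg$structures)) {
    structure <- cfg$structures[si]
    sseed <- seeds_struct[si]
    stage_seeds <- derive_seeds(sseed, 3L)
    layout <- structure_layout(cfg, structure, base_rate, layout_seed = stage_seeds[1])

    if (cfg$sampling == "spatial") {
      ks <- cfg$sample_sizes[cfg$sample_sizes <= layout$n_demes]
      ann_seeds <- derive_seeds(stage_seeds[2], length(ks))
      chosen <- lapply(seq_along(ks), function(i) {
        spatial_sample(layout$coords, ks[i],
                       iterations = cfg$annealing_iterations,
                       seed = ann_seeds[i])$chosen
      })
      names(chosen) <- as.character(ks)
    } else {
      ks <- cfg$sample_sizes[cfg$sample_sizes <= cfg$N]
      chosen <- NULL
    }

    rate_seeds <- derive_seeds(stage_seeds[3], length(cfg$migration_rates))
    for (ri in seq_along(cfg$migration_rates)) {
      rate <- cfg$migration_rates[ri]
      lay_r <- scale_migration(layout, base_rate, rate)
      rep_seeds <- derive_seeds(rate_seeds[ri], cfg$replicates)
      for (rep in seq_len(cfg$replicates)) {
        sub <- derive_seeds(rep_seeds[rep], 2L + length(ks))
        g <- simulate_genealogy(lay_r, seed = sub[1])
        pop <- mutate_sequences(g, cfg$model, length = cfg$seq_length, seed = sub[2])
        par <- compute_parameters(pop)
        prow[[length(prow) + 1L]] <- data.frame(
          experiment = cfg$id, structure = structure, migration = rate,
          replicate = rep, pi = par$pi, He = par$He, sigma = par$sigma,
          theta_w_site = par$theta_w_site, m = par$m, K = par$K,
          excluded = par$excluded
        )
        if (layout$n_demes > 1L && !par$excluded) {
          groups <- lapply(seq_len(layout$n_demes), function(d) {
            subset_alignment(pop, which(attr(pop, "demes") == d))
          })
          groups <- groups[vapply(groups, `[[`, integer(1), "n") > 0L]
          frow[[length(frow) + 1L]] <- data.frame(
            experiment = cfg$id, structure = structure, migration = rate,
            replicate = rep, gst = as.numeric(gst(groups)),
            nst = as.numeric(nst(groups))
          )
        }
        if (par$excluded) next
        for (ki in seq_along(ks)) {
          k <- ks[ki]
          samp <- draw_sample(pop, layout = lay_r, mode = cfg$sampling, k = k,
                              seed = sub[2L + ki],
                              chosen_demes = if (cfg$sampling == "spatial") {
                                chosen[[as.character(k)]]
                              } else {
                                NULL
                              })
          est <- calc_diversity(samp, per_site_length = cfg$seq_length)
          rows[[length(rows) + 1L]] <- data.frame(
            experiment = cfg$id, structure = structure, migration = rate,
            replicate = rep, sample_size = k,
            measure = c("pi_tilde", "He_hat", "sigma_hat",
                        "theta_w_site", "theta_w_site"),
            reference = c("pi", "He", "sigma", "pi", "theta_pop"),
            estimate = c(est$pi_tilde, est$He_hat, est$sigma_hat,
                         est$theta_w_site, est$theta_w_site),
            parameter = c(par$pi, par$He, par$sigma, par$pi, par$theta_w_site)
          )
        }
      }
      if (verbose) {
        message(sprintf("experiment %d %s rate %g done", cfg$id, structure, rate))
      }
    }
  }

  replicates <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(replicates)) {
    replicates$rel_err <- (replicates$estimate - replicates$parameter) /
      replicates$parameter
  }
  structure(
    list(replicates = replicates,
         summary = if (is.null(replicates)) NULL else summarize_replicates(replicates),
         parameters = do.call(rbind, prow),
         gst_nst = if (length(frow)) do.call(rbind, frow) else NULL,
         config = cfg),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment %d: %d estimate rows, %d replicates simulated\n",
              x$config$id,
              if (is.null(x$replicates)) 0L else nrow(x$replicates),
              nrow(x$parameters)))
  invisible(x)
}

#' Per-cell bias and accuracy of the estimators
#'
#' Aggregates replicate-level relative errors into the per-cell scaled
#' mean error `SME = mean((est - param)/param)` and scaled root mean
#' square error `SRMSE = mean(|est - param|/param)`, with their standard
#' deviations, per (experiment, structure, migration, sample size,
#' measure, reference) cell. Excluded replicates never enter the means.
#'
#' @param replicates The tidy replicate data frame from [run_experiment()]
#'   (columns `measure`, `reference`, `rel_err`, plus the cell keys).
#' @return A data frame of class `"bias_accuracy"`.
#' @export
summarize_replicates <- function(replicates) {
  stopifnot(is.data.frame(replicates), "rel_err" %in% names(replicates))
  keys <- replicates[c("experiment", "structure", "migration",
                       "sample_size", "measure", "reference")]
  f <- interaction(keys, drop = TRUE, lex.order = TRUE)
  agg <- lapply(split(seq_len(nrow(replicates)), f), function(idx) {
    e <- replicates$rel_err[idx]
    cbind(keys[idx[1L], , drop = FALSE],
          data.frame(SME = mean(e), SRMSE = mean(abs(e)),
                     SME_sd = stats::sd(e), SRMSE_sd = stats::sd(abs(e)),
                     n_replicates = length(e)))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  class(out) <- c("bias_accuracy", "data.frame")
  out
}

#' Grand means of bias and accuracy per measure
#'
#' Cell means are averaged with equal weight over all cells of the
#' summary (optionally restricted), yielding one grand SME/SRMSE pair per
#' (measure, reference).
#'
#' @param summary A `"bias_accuracy"` table (or rbind of several).
#' @param experiments Optional experiment ids to restrict to.
#' @param abs_sme Also report the grand mean of |cell SME|.
#' @return Data frame with one row per (measure, reference).
#' @export
grand_means <- function(summary, experiments = NULL, abs_sme = TRUE) {
  stopifnot(is.data.frame(summary))
  if (!is.null(experiments)) summary <- summary[summary$experiment %in% experiments, ]
  f <- interaction(summary$measure, summary$reference, drop = TRUE)
  agg <- lapply(split(seq_len(nrow(summary)), f), function(idx) {
    data.frame(measure = summary$measure[idx[1L]],
               reference = summary$reference[idx[1L]],
               SME = mean(summary$SME[idx]),
               abs_SME = mean(abs(summary$SME[idx])),
               SRMSE = mean(summary$SRMSE[idx]),
               n_cells = length(idx))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  if (!abs_sme) out$abs_SME <- NULL
  out
}

#' Run the desk-scale suite of all five experiments
#'
#' Convenience wrapper running [scaled_experiment_config()] designs for
#' the requested experiments under one master seed and binding their
#' summaries.
#'
#' @param seed Master seed.
#' @param experiments Which experiment ids to run (default 1:5).
#' @param ... Overrides forwarded to [scaled_experiment_config()].
#' @param verbose Print progress?
#' @return List with `results` (per-experiment `"experiment_result"`s),
#'   `summary` (combined per-cell table) and `replicates`.
#' @export
scaled_experiment_suite <- function(seed = 1L, experiments = 1:5, ...,
                                    verbose = FALSE) {
  seeds <- derive_seeds(seed, 5L)
  results <- lapply(experiments, function(id) {
    run_experiment(scaled_experiment_config(id, ...), seed = seeds[id],
                   verbose = verbose)
  })
  names(results) <- paste0("experiment_", experiments)
  summary <- do.call(rbind, lapply(results, `[[`, "summary"))
  rownames(summary) <- NULL
  replicates <- do.call(rbind, lapply(results, `[[`, "replicates"))
  list(results = results, summary = summary, replicates = replicates)
}
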