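#' Metaheuristic run configuration
#'
#' Bundles the parameter set that specifies one colony (or classical) run:
#' the algorithm, the target pattern, the initial and final colony size,
#' operator rates, the cooling factor for annealing, and engine settings.
#'
#' @param algorithm `"SGA"` or `"SA"`.
#' @param pattern Target [fitness_pattern()].
#' @param N0 Initial cell count (>= 2).
#' @param Nf Final cell count; the run stops when the colony reaches it.
#' @param m Mutation rate per plasmid per division (SGA; SA default 0).
#' @param c Conjugation rate per donor per generation (SGA crossover /
#'   SA perturbation).
#' @param alpha Temperature decrease factor in (0, 1); SA only. The aTc
#'   field degrades at `lambda = -log(alpha) / T_div`, i.e. by a factor
#'   `alpha` per generation — the colony reading of multiplying the
#'   classical temperature by `alpha` once per iteration.
#' @param detection `"gfp"` (first cell with a matured reporter; default)
#'   or `"genotype"` (first cell whose genotype is optimal).
#' @param engine Engine overrides, see [colony_state()].
#' @param sa Annealing-field settings: `amount` (total aTc bolus),
#'   `K_frac` (conjugation half-max as a fraction of the initial central
#'   aTc concentration), `hill` (Hill coefficient), `D` (aTc diffusion,
#'   um^2/min; 0 for a frozen zone), `grid_n`, `dx`.
#' @param max_generations Safety cap on simulated generations.
#' @param seed Optional integer seed.
#' @return An `mh_config` object.
#' @examples
#' cfg <- mh_config("SGA", "1100", N0 = 200, Nf = 10000, m = 0.01, c = 0.01)
#' @export
mh_config <- function(algorithm = c("SGA", "SA"), pattern,
                      N0 = 200, Nf = 10000,
                      m = if (identical(toupper(algorithm[1]), "SA")) 0 else 0.01,
                      c = 0.01, alpha = 0.25,
                      detection = c("gfp", "genotype"),
                      engine = list(), sa = list(),
                      max_generations = 30, seed = NULL) {
  algorithm <- toupper(match.arg(algorithm))
  detection <- match.arg(detection)
  pattern <- fitness_pattern(pattern)
  if (!(N0 >= 2)) stop("N0 must be at least 2", call. = FALSE)
  if (!(Nf > N0)) stop("Nf must exceed N0", call. = FALSE)
  if (m < 0 || m > 1) stop("mutation rate m must lie in [0, 1]", call. = FALSE)
  if (c < 0 || c > 1) stop("conjugation rate c must lie in [0, 1]", call. = FALSE)
  if (algorithm == "SA" && (alpha <= 0 || alpha >= 1)) {
    stop("alpha must lie strictly inside (0, 1)", call. = FALSE)
  }
  sa_def <- list(amount = 100, K_frac = 0.1, hill = 2, D = 12,
                 grid_n = 129L, dx = 2)
  structure(
    list(algorithm = algorithm, pattern = pattern, N0 = as.integer(N0),
         Nf = as.integer(Nf), m = m, c = c, alpha = alpha,
         detection = detection,
         engine = utils::modifyList(default_engine(), engine),
         sa = utils::modifyList(sa_def, sa),
         max_generations = max_generations,
         seed = if (!is.null(seed)) as.integer(seed)),
    class = "mh_config"
  )
}

#' @export
print.mh_config <- function(x, ...) {
  cat("<mh_config> ", x$algorithm, " on pattern ", unclass(x$pattern),
      "\n  N0=", x$N0, " Nf=", x$Nf, " m=", x$m, " c=", x$c,
      if (x$algorithm == "SA") paste0(" alpha=", x$alpha) else "",
      "  detection=", x$detection, "\n", sep = "")
  invisible(x)
}

#' Initialize a colony from a run configuration
#'
#' Founders follow the same rule as the classical pools — 50% empty, 50%
#' single-plasmid round-robin ([init_population()]) — placed in a dense disc
#' and shuffled over positions. An annealing configuration additionally
#' deposits the central aTc bolus (a Gaussian whose width is the initial
#' colony radius) on a fresh signal field with
#' `lambda = -log(alpha) / T_div`.
#'
#' @param config An [mh_config()].
#' @return A `colony_state`.
#' @export
init_colony <- function(config) {
  stopifnot(inherits(config, "mh_config"))
  L <- pattern_length(config$pattern)
  geno <- init_population_matrix(config$N0, L)
  state <- colony_state(geno, config$pattern, engine = config$engine)
  if (config$algorithm == "SA") {
    eng <- state$engine
    lam <- -log(config$alpha) / eng$T_div
    f <- signal_field(config$sa$grid_n, dx = config$sa$dx,
                      D = config$sa$D, lambda = lam)
    colony_radius <- max(sqrt(state$x^2 + state$y^2)) + eng$r
    f <- sf_deposit_gaussian(f, config$sa$amount, colony_radius)
    state$fields$atc <- f
    mid <- (f$n + 1L) %/% 2L
    # half-max as a fraction of the initial central amplitude; an empty
    # bolus still needs a positive K (H(0) = 0 either way)
    K <- config$sa$K_frac * f$grid[mid, mid]
    state$sa <- list(K = if (K > 0) K else 1, hill = config$sa$hill)
  }
  state
}

#' Saturating aTc response of the conjugation machinery
#'
#' Hill function `H(x) = x^h / (K^h + x^h)` with `H(0) = 0` and
#' `H(Inf) = 1`: the local aTc concentration cancels tetR repression of the
#' conjugative rel protein, so high aTc (high temperature) means frequent
#' conjugation and the cooling field gradually freezes the search.
#'
#' @param x aTc concentration(s).
#' @param K Half-maximal concentration (> 0).
#' @param hill Hill coefficient (default 2).
#' @export
atc_response <- function(x, K, hill = 2) {
  stopifnot(K > 0, hill > 0)
  xp <- pmax(x, 0)^hill
  xp / (K^hill + xp)
}

#' Run a metaheuristic in a growing colony
#'
#' Steps the colony engine in 1-minute ticks: growth and division (with
#' per-division mutation in SGA mode), conjugation (aTc-modulated in SA
#' mode), signal-field updates, and reporter maturation. The run records the
#' colony trajectory and stops once the first optimum is detected and the
#' colony has reached `Nf` cells — or immediately at detection when
#' `stop_at_detection = TRUE` (the default, since the reported quantity is
#' the first-optimum generation).
#'
#' @param config An [mh_config()].
#' @param seed Integer seed (overrides `config$seed`).
#' @param dt Engine step in minutes (<= 1; default 1).
#' @param stop_at_detection Stop stepping once the first optimum is found
#'   (default TRUE).
#' @param keep_state Keep the final `colony_state` in the result (default
#'   FALSE to keep results light).
#' @return A `colony_run` object: `first_optimum_generation` (fractional
#'   generations, `NA` when not found by the time the colony reaches `Nf`),
#'   the per-step `trajectory` tibble, and the configuration.
#' @examples
#' \donttest{
#' res <- run_colony(mh_config("SGA", "10xxx", N0 = 50, Nf = 400), seed = 1)
#' res$first_optimum_generation  # ~0.6: maturation delay of optimal founders
#' }
#' @export
run_colony <- function(config, seed = config$seed, dt = 1,
                       stop_at_detection = TRUE, keep_state = FALSE) {
  stopifnot(inherits(config, "mh_config"), dt > 0, dt <= 1)
  if (!is.null(seed)) set.seed(seed)
  state <- init_colony(config)
  eng <- state$engine
  sa_mode <- config$algorithm == "SA"
  max_time <- config$max_generations * eng$T_div

  first_gen <- NA_real_
  traj <- list()
  record <- function(state) {
    opt <- is_optimal(state$geno, state$pattern)
    tibble::tibble(
      time = state$time,
      generation = colony_generation(state),
      n_cells = length(state$x),
      n_optimal = sum(opt),
      n_gfp = sum(state$gfp),
      conj_events = state$conj_events,
      atc_mass = if (sa_mode) sf_mass(state$fields$atc) else NA_real_
    )
  }
  detected <- function(state) {
    if (config$detection == "gfp") any(state$gfp)
    else any(is_optimal(state$geno, state$pattern))
  }

  traj[[1]] <- record(state)
  if (detected(state)) first_gen <- colony_generation(state)

  while (is.na(first_gen) || !stop_at_detection) {
    if (length(state$x) >= config$Nf || state$time >= max_time) break
    state <- grow_step(state, dt, m = config$m)
    if (sa_mode) {
      # once the field has decayed far below the response threshold the
      # Hill term is numerically zero everywhere: stop paying for it
      cold <- max(state$fields$atc$grid) < 1e-6 * state$sa$K
      if (!cold) {
        conc <- sf_sample(state$fields$atc,
                          cbind(clamp_to_field(state$x, state$fields$atc),
                                clamp_to_field(state$y, state$fields$atc)))
        mod <- atc_response(conc, state$sa$K, state$sa$hill)
        state <- conjugate_step(state, config$c, dt, modulate = mod)
        state$fields$atc <- sf_run(state$fields$atc, dt)
      }
    } else {
      state <- conjugate_step(state, config$c, dt)
    }
    state <- update_reporters(state, dt)
    traj[[length(traj) + 1L]] <- record(state)
    if (is.na(first_gen) && detected(state)) {
      first_gen <- colony_generation(state)
    }
  }

  structure(
    list(
      config = config,
      seed = seed,
      first_optimum_generation = first_gen,
      found = !is.na(first_gen),
      stopped_generation = colony_generation(state),
      final_n = length(state$x),
      trajectory = dplyr::bind_rows(traj),
      state = if (keep_state) state else NULL
    ),
    class = "colony_run"
  )
}

clamp_to_field <- function(v, field) pmin(pmax(v, -field$half), field$half)

#' @export
print.colony_run <- function(x, ...) {
  cat("<colony_run> ", x$config$algorithm, " on pattern ",
      unclass(x$config$pattern), "\n", sep = "")
  if (x$found) {
    cat("  first optimum at generation ",
        format(round(x$first_optimum_generation, 3)), sep = "")
  } else {
    cat("  no optimum found", sep = "")
  }
  cat(" (stopped at generation ", format(round(x$stopped_generation, 3)),
      ", ", x$final_n, " cells)\n", sep = "")
  invisible(x)
}

#' Replicate colony runs over seeds
#'
#' @param config An [mh_config()].
#' @param seeds Integer vector of seeds.
#' @param ... Passed to [run_colony()].
#' @return Tibble: `seed`, `first_optimum` (generations; `NA` = not found),
#'   `found`, `stopped_generation`, `final_n`.
#' @export
replicate_colony <- function(config, seeds, ...) {
  purrr::map_dfr(seeds, function(s) {
    res <- run_colony(config, seed = s, ...)
    tibble::tibble(seed = s,
                   first_optimum = res$first_optimum_generation,
                   found = res$found,
                   stopped_generation = res$stopped_generation,
                   final_n = res$final_n)
  })
}

#' Stop-censored mean of first-optimum generations
#'
#' Runs that never found an optimum are counted at the generation where the
#' run stopped (the colony reached its final size), giving a conservative
#' lower bound on their first-optimum generation.
#'
#' @param runs A tibble from [replicate_colony()] or [replicate_runs()].
#' @export
censored_mean <- function(runs) {
  stopped <- if ("stopped_generation" %in% names(runs)) {
    runs$stopped_generation
  } else {
    rep(max(runs$first_optimum, na.rm = TRUE), nrow(runs))
  }
  mean(ifelse(is.na(runs$first_optimum), stopped, runs$first_optimum))
}
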