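#' Initial solution pool
#'
#' Half the pool holds no plasmids; the other half holds a single plasmid,
#' assigned round-robin over plasmid indices. With `P = 200` and `L = 5`
#' this gives 100 empty genotypes and 20 of each singleton. The same rule
#' seeds both the classical pools and the colony founders.
#'
#' @param P Pool size (>= 2).
#' @param L Number of plasmids (>= 1).
#' @return A tibble with columns `individual` and `genotype` (bit string).
#' @export
init_population <- function(P, L) {
  stopifnot(P >= 2, L >= 1)
  n_empty <- floor(P / 2)
  m <- matrix(0L, P, L)
  singles <- seq_len(P - n_empty)
  plasmid <- ((singles - 1L) %% L) + 1L
  m[cbind(n_empty + singles, plasmid)] <- 1L
  tibble::tibble(individual = seq_len(P), genotype = genotype_string(m))
}

init_population_matrix <- function(P, L) {
  genotype_matrix(init_population(P, L)$genotype, L = L)
}

#' Classical Simple Genetic Algorithm on bit strings
#'
#' The fixed-pool reference version used for head-to-head generation counts
#' against the colony runs. Selection is random; there is no elitism. Each
#' generation applies, in order:
#'
#' 1. **Crossover pass** (in index order): each individual, with probability
#'    `c`, receives a copy of one uniformly chosen *present* plasmid from a
#'    uniformly chosen other individual — conjugation in silico. Nothing
#'    happens when the donor carries no plasmids; a duplicate arrival is a
#'    no-op.
#' 2. **Mutation pass**: every bit of every individual flips independently
#'    with probability `m`.
#' 3. **Evaluation**: if any individual matches the pattern, the generation
#'    index is returned.
#'
#' Evaluation happens after the update pass, so an optimal individual
#' already present at initialization is reported at generation 1, never 0.
#'
#' @param pattern The target [fitness_pattern()].
#' @param P Pool size (default 200).
#' @param c Crossover (conjugation) rate per individual per generation.
#' @param m Mutation rate per bit per generation.
#' @param max_generations Give up after this many generations.
#' @param seed Optional integer seed.
#' @return A `mh_run` result; `first_optimum` is the generation index or
#'   `NA` ("not found").
#' @examples
#' sga_run("10xxx", seed = 1)$first_optimum  # 1: optimal founders exist
#' @export
sga_run <- function(pattern, P = 200, c = 0.01, m = 0.01,
                    max_generations = 500, seed = NULL) {
  pattern <- fitness_pattern(pattern)
  stopifnot(P >= 2, c >= 0, c <= 1, m >= 0, m <= 1, max_generations >= 1)
  if (!is.null(seed)) set.seed(seed)
  L <- pattern_length(pattern)
  pool <- init_population_matrix(P, L)
  for (g in seq_len(max_generations)) {
    # crossover pass, index order: recipients see earlier updates this pass
    receivers <- which(stats::runif(P) < c)
    for (i in receivers) {
      donor <- sample.int(P - 1L, 1L)
      if (donor >= i) donor <- donor + 1L
      present <- which(pool[donor, ] == 1L)
      if (!length(present)) next
      pl <- if (length(present) == 1L) present else sample(present, 1L)
      pool[i, pl] <- 1L
    }
    if (m > 0) {
      hit <- matrix(stats::runif(P * L) < m, P, L)
      pool[hit] <- 1L - pool[hit]
    }
    if (any(is_optimal(pool, pattern))) {
      return(new_mh_run("sga_classic", pattern, g, g,
                        list(P = P, c = c, m = m), seed))
    }
  }
  new_mh_run("sga_classic", pattern, NA_real_, max_generations,
             list(P = P, c = c, m = m), seed)
}

#' Classical Simulated Annealing on a single bit string
#'
#' Starts from a uniformly random genotype. Each iteration proposes a single
#' uniform-random bit flip; the energy is the number of violated constrained
#' pattern positions ("don't care" positions never contribute). The proposal
#' is accepted when `dE <= 0`, otherwise with probability `exp(-dE / T)`.
#' After the move the temperature cools geometrically, `T <- alpha * T`, and
#' the run stops when `T < T_min`. The state is evaluated after each
#' iteration, so a run that starts at an optimum reports iteration 1.
#'
#' @param pattern The target [fitness_pattern()].
#' @param T0 Initial temperature (default 1).
#' @param T_min Stopping temperature (default 1e-3).
#' @param alpha Cooling factor in (0, 1).
#' @param seed Optional integer seed.
#' @param init Optional starting bit string (default: uniform random).
#' @return A `mh_run` result; `first_optimum` is the iteration index or `NA`.
#' @export
sa_run <- function(pattern, T0 = 1, T_min = 1e-3, alpha = 0.25,
                   seed = NULL, init = NULL) {
  pattern <- fitness_pattern(pattern)
  stopifnot(alpha > 0, alpha < 1, T0 > T_min, T_min > 0)
  if (!is.null(seed)) set.seed(seed)
  L <- pattern_length(pattern)
  g <- if (is.null(init)) {
    as.integer(stats::runif(L) < 0.5)
  } else {
    drop(genotype_matrix(init, L = L))
  }
  e <- energy(matrix(g, 1L), pattern)
  temp <- T0
  k <- 0L
  while (temp >= T_min) {
    k <- k + 1L
    flip <- sample.int(L, 1L)
    g2 <- g
    g2[flip] <- 1L - g2[flip]
    e2 <- energy(matrix(g2, 1L), pattern)
    if (metropolis_accept(e2 - e, temp)) {
      g <- g2; e <- e2
    }
    temp <- alpha * temp
    if (e == 0L) {
      return(new_mh_run("sa_classic", pattern, k, k,
                        list(T0 = T0, T_min = T_min, alpha = alpha), seed))
    }
  }
  new_mh_run("sa_classic", pattern, NA_real_, k,
             list(T0 = T0, T_min = T_min, alpha = alpha), seed)
}

# Metropolis rule: always accept improvements or ties, accept a worsening
# move of dE at temperature temp with probability exp(-dE / temp)
metropolis_accept <- function(dE, temp) {
  dE <= 0 || stats::runif(1) < exp(-dE / temp)
}

new_mh_run <- function(algorithm, pattern, first_optimum, stopped_at,
                       params, seed) {
  structure(
    list(algorithm = algorithm, pattern = pattern,
         first_optimum = first_optimum, found = !is.na(first_optimum),
         stopped_at = stopped_at, params = params, seed = seed),
    class = "mh_run"
  )
}

#' @export
print.mh_run <- function(x, ...) {
  cat("<mh_run> ", x$algorithm, " on pattern ", unclass(x$pattern), "\n",
      sep = "")
  if (x$found) {
    cat("  first optimum at generation ", format(x$first_optimum), "\n",
        sep = "")
  } else {
    cat("  no optimum found (stopped at ", format(x$stopped_at), ")\n",
        sep = "")
  }
  invisible(x)
}

#' Replicate a classical run over seeds
#'
#' @param runner One of [sga_run()] / [sa_run()] (or any function returning
#'   an `mh_run` given `seed = `).
#' @param seeds Integer vector of seeds.
#' @param ... Passed to `runner`.
#' @return A tibble with one row per seed: `seed`, `first_optimum`, `found`.
#' @export
replicate_runs <- function(runner, seeds, ...) {
  purrr::map_dfr(seeds, function(s) {
    res <- runner(..., seed = s)
    tibble::tibble(seed = s, first_optimum = as.numeric(res$first_optimum),
                   found = res$found)
  })
}
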