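#' Agent-based growing colony
#'
#' The colony is a collection of circular cells (radius `r`, default 1 um)
#' on a 2D plane. Each cell carries a plasmid-presence genotype, a division
#' clock, and a GFP reporter timer driven by the compiled fitness circuit.
#' Cells grow and divide (clocks drawn from a truncated normal around the
#' 20-minute division time), daughters are mutated per plasmid, overlaps are
#' resolved by iterative pairwise shoving, and conjugation copies one present
#' plasmid from a donor to a touching neighbor. There is no cell death and
#' no plasmid loss: genotype bits change only through mutation, or are
#' gained through conjugation.
#'
#' @name colony_engine
NULL

default_engine <- function() {
  list(
    T_div = 20,        # mean division time, min
    sd_div = 2,        # division-time sd, min
    min_div = 5,       # truncation floor, min
    r = 1,             # cell radius, um
    conj_reach = 2.2,  # neighbor reach for conjugation, in units of r
    tau_gfp = 12,      # GFP maturation delay, min
    relax_tol = 0.05,  # overlap tolerance, fraction of r
    relax_iter = 100,  # max relaxation sweeps (residual-based convergence)
    relax_beta = 1.4,  # over-relaxation factor for the pairwise shove
    mut_mode = "flip", # "flip" or "resample" at division
    init_phase = "uniform"  # founder cell-cycle phase: "uniform" or "full"
  )
}

draw_division_clock <- function(n, eng) {
  pmax(stats::rnorm(n, eng$T_div, eng$sd_div), eng$min_div)
}

#' Create a colony state
#'
#' Places `n` cells in a dense disc around the origin (sunflower spiral then
#' one relaxation pass) and assigns the given genotypes in random order, so
#' empty and singleton founders are spatially well mixed.
#'
#' @param genotypes Character vector of bit strings (one per founder cell)
#'   or 0/1 matrix.
#' @param pattern The [fitness_pattern()] the reporter circuit evaluates.
#' @param engine Named list of engine settings; unspecified entries take the
#'   defaults documented in `default_engine` (division time 20 +/- 2 min
#'   truncated at 5, radius 1 um, conjugation reach 2.2 r, GFP maturation
#'   12 min).
#' @param shuffle Randomize the genotype-to-position assignment (default
#'   TRUE).
#' @return A `colony_state` object.
#' @export
colony_state <- function(genotypes, pattern, engine = list(), shuffle = TRUE) {
  pattern <- fitness_pattern(pattern)
  geno <- genotype_matrix(genotypes, L = pattern_length(pattern))
  n <- nrow(geno)
  stopifnot(n >= 1)
  eng <- utils::modifyList(default_engine(), engine)

  # sunflower layout: nearest-neighbor spacing ~ 2r, then relax residuals
  k <- seq_len(n)
  scale <- 2 * eng$r / sqrt(pi)
  rad <- scale * sqrt(k - 0.5)
  th <- k * pi * (3 - sqrt(5))
  x <- rad * cos(th)
  y <- rad * sin(th)
  rl <- relax_cells_cpp(x, y, eng$r, eng$relax_tol, eng$relax_iter,
                        eng$relax_beta)

  if (shuffle && n > 1L) geno <- geno[sample.int(n), , drop = FALSE]

  # founders start at a uniformly random point of their division cycle
  # (init_phase = "full" gives every founder a whole cycle: deterministic
  # doubling when sd_div = 0, used for growth-law checks)
  full <- draw_division_clock(n, eng)
  clock0 <- if (identical(eng$init_phase, "full")) full else
    stats::runif(n, 0, full)
  state <- structure(
    list(
      x = rl$x, y = rl$y,
      geno = geno,
      clock = clock0,
      timer = rep(NA_real_, n),
      gfp = rep(FALSE, n),
      id = seq_len(n), next_id = n + 1L,
      time = 0,
      pattern = pattern,
      engine = eng,
      fields = list(),
      conj_events = 0L
    ),
    class = "colony_state"
  )
  update_reporters(state, dt = 0)
}

#' @export
print.colony_state <- function(x, ...) {
  cat("<colony_state> ", length(x$x), " cells at t=", x$time, " min (",
      format(round(colony_generation(x), 3)), " generations)\n", sep = "")
  cat("  pattern ", unclass(x$pattern), ", optimal ",
      sum(is_optimal(x$geno, x$pattern)), ", GFP on ", sum(x$gfp), "\n",
      sep = "")
  invisible(x)
}

#' Fractional generation clock of a colony
#'
#' `gen(t) = t / T_div`: elapsed minutes over the mean division time, so
#' fractional generations are meaningful (a 12-minute GFP maturation delay
#' is 0.6 generations at the 20-minute division time).
#'
#' @param state A `colony_state`.
#' @export
colony_generation <- function(state) state$time / state$engine$T_div

#' Snapshot a colony as a tibble
#'
#' @param state A `colony_state`.
#' @return One row per cell: `id`, `x`, `y`, `genotype`, `optimal`, `gfp`.
#' @export
colony_cells <- function(state) {
  tibble::tibble(
    id = state$id,
    x = state$x,
    y = state$y,
    genotype = genotype_string(state$geno),
    optimal = is_optimal(state$geno, state$pattern),
    gfp = state$gfp
  )
}

#' Mutate a genotype at division
#'
#' Promoter mutation: each plasmid bit flips independently with probability
#' `m` per division (`mode = "flip"`, the classical operator). The
#' alternative reading of "an arbitrary change in the state of a protein" —
#' resampling the bit uniformly, i.e. a half-effective flip rate — is
#' available as `mode = "resample"`.
#'
#' @param genotypes Bit strings or 0/1 matrix.
#' @param m Per-plasmid mutation probability in `[0, 1]`.
#' @param mode `"flip"` (default) or `"resample"`.
#' @return A matrix of mutated genotypes (same shape as the input matrix).
#' @export
mutate_at_division <- function(genotypes, m, mode = c("flip", "resample")) {
  mode <- match.arg(mode)
  stopifnot(m >= 0, m <= 1)
  g <- genotype_matrix(genotypes)
  if (m == 0) return(g)
  hit <- matrix(stats::runif(length(g)) < m, nrow(g), ncol(g))
  if (mode == "flip") {
    g[hit] <- 1L - g[hit]
  } else {
    g[hit] <- as.integer(stats::runif(sum(hit)) < 0.5)
  }
  g
}

#' Advance growth and division by one time step
#'
#' Division clocks advance by `dt`; a cell whose clock expires divides into
#' two daughters displaced by +/- r along a uniform random direction, both
#' with freshly drawn clocks and independently mutated genotypes (rate `m`
#' per plasmid per division); mechanical relaxation then resolves overlaps.
#'
#' @param state A `colony_state`.
#' @param dt Step in minutes (at most 1).
#' @param m Mutation rate per plasmid per division.
#' @export
grow_step <- function(state, dt = 1, m = 0) {
  stopifnot(dt > 0, dt <= 1)
  eng <- state$engine
  state$clock <- state$clock - dt
  div <- which(state$clock <= 0)
  if (length(div)) {
    nd <- length(div)
    theta <- stats::runif(nd, 0, 2 * pi)
    dx <- eng$r * cos(theta); dy <- eng$r * sin(theta)
    gm <- state$geno[div, , drop = FALSE]
    d1 <- mutate_at_division(gm, m, eng$mut_mode)
    d2 <- mutate_at_division(gm, m, eng$mut_mode)
    # daughter 1 replaces the mother in place
    state$geno[div, ] <- d1
    state$x[div] <- state$x[div] - dx
    state$y[div] <- state$y[div] - dy
    state$clock[div] <- draw_division_clock(nd, eng)
    # daughter 2 appended; inherits the reporter timer (GFP is partitioned)
    state$x <- c(state$x, state$x[div] + 2 * dx)
    state$y <- c(state$y, state$y[div] + 2 * dy)
    state$geno <- rbind(state$geno, d2)
    state$clock <- c(state$clock, draw_division_clock(nd, eng))
    state$timer <- c(state$timer, state$timer[div])
    state$gfp <- c(state$gfp, state$gfp[div])
    state$id <- c(state$id, seq.int(state$next_id, length.out = nd))
    state$next_id <- state$next_id + nd
    rl <- relax_cells_cpp(state$x, state$y, eng$r, eng$relax_tol,
                          eng$relax_iter, eng$relax_beta)
    state$x <- rl$x; state$y <- rl$y
  }
  state$time <- state$time + dt
  state
}

#' Conjugative plasmid transfer for one time step
#'
#' Each cell attempts conjugation with probability `c * dt / T_div`
#' (optionally scaled per cell by `modulate`, e.g. the aTc temperature
#' response in annealing mode). An attempting donor picks a uniformly random
#' neighbor within `conj_reach * r` and copies one uniformly chosen present
#' plasmid into it (the donor keeps its copy; a recipient that already has
#' the plasmid is unchanged). Donors with no plasmids, or no neighbor in
#' reach, do nothing.
#'
#' @param state A `colony_state`.
#' @param c Conjugation rate per donor per generation.
#' @param dt Step in minutes.
#' @param modulate Optional numeric vector in `[0, 1]`, one per cell,
#'   multiplying each cell's attempt probability.
#' @export
conjugate_step <- function(state, c, dt = 1, modulate = NULL) {
  stopifnot(c >= 0)
  n <- length(state$x)
  if (c == 0 || n < 2) return(state)
  p <- c * dt / state$engine$T_div
  if (!is.null(modulate)) {
    stopifnot(length(modulate) == n)
    p <- p * modulate
  }
  attempting <- which(stats::runif(n) < p)
  if (!length(attempting)) return(state)
  # only donors that carry at least one plasmid can transfer
  donors <- attempting[rowSums(state$geno[attempting, , drop = FALSE]) > 0L]
  if (!length(donors)) return(state)
  reach <- state$engine$conj_reach * state$engine$r
  recip <- pick_neighbors_cpp(state$x, state$y, donors, reach)
  for (k in seq_along(donors)) {
    if (is.na(recip[k])) next
    present <- which(state$geno[donors[k], ] == 1L)
    pl <- if (length(present) == 1L) present else sample(present, 1L)
    state$geno[recip[k], pl] <- 1L
    state$conj_events <- state$conj_events + 1L
  }
  state
}

#' Update the GFP reporter of every cell
#'
#' A cell whose circuit currently evaluates optimal starts (at 0) or
#' continues (+`dt`) its maturation timer; GFP turns on once the timer
#' reaches `tau_gfp` minutes. A cell that stops being optimal resets its
#' timer and goes dark.
#'
#' @param state A `colony_state`.
#' @param dt Minutes elapsed since the previous reporter update.
#' @param tau_gfp Maturation delay in minutes (default from the engine
#'   settings).
#' @export
update_reporters <- function(state, dt = 1, tau_gfp = state$engine$tau_gfp) {
  stopifnot(tau_gfp >= 0)
  ok <- is_optimal(state$geno, state$pattern)
  state$timer <- ifelse(ok, ifelse(is.na(state$timer), 0, state$timer + dt),
                        NA_real_)
  state$gfp <- !is.na(state$timer) & state$timer >= tau_gfp
  state
}

#' Largest pairwise overlap in a colony (um)
#'
#' @param state A `colony_state`.
#' @export
colony_max_overlap <- function(state) {
  max_overlap_cpp(state$x, state$y, state$engine$r)
}
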