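#' Conway's Game of Life on a toroidal grid
#'
#' The reference implementation the colony automaton is compared against:
#' standard B3/S23 rules on the 8-site Moore neighborhood with wrap-around
#' boundaries, computed by vectorized matrix shifts.
#'
#' @param grid A 0/1 matrix (`life_grid` or plain), or a character vector /
#'   single string in plaintext Life format (`.` or `b` dead, `O`/`o`/`*`
#'   live, one row per line).
#' @return A `life_grid` (0/1 integer matrix).
#' @examples
#' blinker <- life_grid(c(".....", ".OOO.", "....."))
#' life_step(blinker)
#' @export
life_grid <- function(grid) {
  if (is.character(grid)) {
    if (length(grid) == 1L && grepl("\n", grid)) {
      grid <- strsplit(grid, "\n", fixed = TRUE)[[1]]
    }
    grid <- grid[nzchar(trimws(grid)) & !startsWith(trimws(grid), "!")]
    rows <- strsplit(grid, "", fixed = TRUE)
    w <- max(lengths(rows))
    m <- t(vapply(rows, function(r) {
      r <- c(r, rep(".", w - length(r)))
      as.integer(r %in% c("O", "o", "*", "1"))
    }, integer(w)))
  } else {
    m <- as.matrix(grid)
    storage.mode(m) <- "integer"
  }
  if (any(is.na(m)) || any(m != 0L & m != 1L)) {
    stop("a life grid must contain only 0 and 1", call. = FALSE)
  }
  structure(m, class = c("life_grid", "matrix", "array"))
}

#' @export
print.life_grid <- function(x, ...) {
  cat("<life_grid> ", nrow(x), "x", ncol(x), ", ", sum(x), " live\n", sep = "")
  chars <- matrix(c(".", "O")[unclass(x) + 1L], nrow(x))
  cat(apply(chars, 1L, paste, collapse = ""), sep = "\n")
  invisible(x)
}

shift_torus <- function(m, dr, dc) {
  n <- nrow(m); k <- ncol(m)
  m[(seq_len(n) - 1L - dr) %% n + 1L, (seq_len(k) - 1L - dc) %% k + 1L,
    drop = FALSE]
}

#' @rdname life_grid
#' @export
life_step <- function(grid) {
  g <- life_grid(grid)
  m <- unclass(g)
  nb <- matrix(0L, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- nb + shift_torus(m, dr, dc)
  }
  out <- (m == 1L & (nb == 2L | nb == 3L)) | (m == 0L & nb == 3L)
  life_grid(matrix(as.integer(out), nrow(m)))
}

#' @rdname life_grid
#' @param steps Number of updates.
#' @return `run_life()`: a list of `life_grid` frames (`steps + 1` long,
#'   first element the initial grid).
#' @export
run_life <- function(grid, steps) {
  g <- life_grid(grid)
  frames <- vector("list", steps + 1L)
  frames[[1L]] <- g
  for (i in seq_len(steps)) {
    g <- life_step(g)
    frames[[i + 1L]] <- g
  }
  frames
}

#' Band-detector state rule
#'
#' The crowding rule of the colony automaton: a cell is live iff the local
#' autoinducer (AHL) concentration lies in the band `[c_low, c_high]`.
#' Under-crowding (too little AHL) and over-crowding (too much) both map to
#' the dead state.
#'
#' @param concentration Numeric vector of AHL concentrations.
#' @param c_low,c_high Band edges, `0 < c_low < c_high`.
#' @return Logical vector: live state.
#' @export
band_rule <- function(concentration, c_low, c_high) {
  stopifnot(c_low > 0, c_high > c_low)
  concentration >= c_low & concentration <= c_high
}

#' Colony cellular-automaton configuration
#'
#' A static (non-growing) lattice of cells plays Game of Life through quorum
#' sensing: live cells emit AHL, every cell senses its local concentration
#' at each update and applies the band rule. The AHL diffusion/degradation
#' pair sets the neighborhood reach (the quorum-sensing stand-in for the
#' Moore neighborhood), and the thresholds are calibrated from computed
#' steady fields, not guessed (see [calibrate_ca()]).
#'
#' @param layout `"lattice"` (square lattice at pitch `2 r`, default) or
#'   `"disc"` (disordered dense disc).
#' @param side Lattice side length in cells (layout `"lattice"`).
#' @param n_cells Number of cells (layout `"disc"`).
#' @param emission AHL emission per live cell, units/min.
#' @param D,lambda AHL diffusion (um^2/min) and degradation (1/min).
#' @param c_low,c_high Band edges; `NULL` to calibrate via [calibrate_ca()].
#' @param update_every Minutes between synchronous rule applications.
#' @param seed_live Logical matrix/vector marking the bootstrap (GFP) seed
#'   cells, or `"random"` with `seed_frac`.
#' @param seed_frac Fraction of cells seeded when `seed_live = "random"`.
#' @param atc_amount Initial aTc bolus that arms the bootstrap override.
#' @param atc_threshold Bootstrap lapses when central aTc falls below this.
#' @param r Cell radius, um.
#' @param dx,grid_n AHL field geometry.
#' @return A `ca_config` object.
#' @export
ca_config <- function(layout = c("lattice", "disc"), side = 20, n_cells = 400,
                      emission = 1, D = 16, lambda = 0.08,
                      c_low = NULL, c_high = NULL, update_every = 20,
                      seed_live = "random", seed_frac = 0.35,
                      atc_amount = 50, atc_threshold = 1,
                      r = 1, dx = 2, grid_n = NULL) {
  layout <- match.arg(layout)
  stopifnot(update_every > 0, emission > 0, D > 0, lambda > 0)
  if (!is.null(c_low) && !is.null(c_high) && !(c_low < c_high)) {
    stop("need c_low < c_high", call. = FALSE)
  }
  structure(
    list(layout = layout, side = as.integer(side),
         n_cells = as.integer(n_cells),
         emission = emission, D = D, lambda = lambda,
         c_low = c_low, c_high = c_high, update_every = update_every,
         seed_live = seed_live, seed_frac = seed_frac,
         atc_amount = atc_amount, atc_threshold = atc_threshold,
         r = r, dx = dx, grid_n = grid_n),
    class = "ca_config"
  )
}

ca_positions <- function(config) {
  pitch <- 2 * config$r
  if (config$layout == "lattice") {
    s <- config$side
    idx <- expand.grid(row = seq_len(s), col = seq_len(s))
    x <- (idx$col - (s + 1) / 2) * pitch
    y <- ((s + 1) / 2 - idx$row) * pitch
    tibble::tibble(cell = seq_len(s * s), row = idx$row, col = idx$col,
                   x = x, y = y)
  } else {
    k <- seq_len(config$n_cells)
    scale <- pitch / sqrt(pi)
    rad <- scale * sqrt(k - 0.5)
    th <- k * pi * (3 - sqrt(5))
    tibble::tibble(cell = k, row = NA_integer_, col = NA_integer_,
                   x = rad * cos(th), y = rad * sin(th))
  }
}

#' Calibrate the quorum-sensing neighborhood and band thresholds
#'
#' Checks that the steady reach of a single emitting cell (the radius where
#' its steady field falls to a reference fraction of the nearest-neighbor
#' concentration) covers the 8 Moore neighbors but not the next ring —
#' about 1.5 lattice pitches — and derives the band edges from computed
#' steady fields: the concentration a cell senses with 2 and with 4 of its
#' 8 neighbors emitting. The resulting band approximates "survive with 2-3
#' live neighbors"; exact B3/S23 equivalence is not achievable through a
#' continuous field and is not attempted.
#'
#' @param config A [ca_config()].
#' @return The config with `c_low`, `c_high` filled in and a `calibration`
#'   attribute (tibble of sensed concentrations per live-neighbor count and
#'   the single-cell reach).
#' @export
calibrate_ca <- function(config) {
  stopifnot(inherits(config, "ca_config"))
  pitch <- 2 * config$r
  # steady field of one emitting cell, sampled at ring distances
  n <- 41L
  f <- signal_field(n, dx = config$dx, D = config$D, lambda = config$lambda)
  f <- steady_point_source(f, config$emission)
  at <- function(d) sf_sample(f, c(d, 0))
  # sensed concentration with k of the 8 Moore neighbors emitting:
  # 4 edge neighbors at 1 pitch, 4 diagonal at sqrt(2) pitches; averaging
  # over which neighbors are live gives the mean per-neighbor contribution
  per_nb <- (4 * at(pitch) + 4 * at(sqrt(2) * pitch)) / 8
  sensed <- function(k) k * per_nb       # dead focal cell: no self term
  conc <- tibble::tibble(live_neighbors = 0:8, sensed = sensed(0:8))
  config$c_low <- sensed(2)              # steady field of 2 emitting neighbors
  config$c_high <- sensed(4)             # steady field of 4 emitting neighbors
  reach <- steady_reach(config$D, config$lambda, config$emission,
                        threshold = config$c_low / 2,
                        dx = config$dx, n = n)
  attr(config, "calibration") <- list(per_neighbor = per_nb,
                                      sensed = conc, reach = reach,
                                      target_reach = 1.5 * pitch)
  config
}

#' Run the quorum-sensing colony automaton
#'
#' Bootstrap phase: while the central aTc concentration stays above the
#' threshold, the seed cells are clamped live (marked GFP) and emit AHL —
#' aTc cancels tetR repression, kick-starting the autoinducer field in an
#' environment that contains none. Main phase: every `update_every`
#' minutes each cell samples its local AHL and applies the band rule; live
#' cells (RFP) emit continuously, dead cells do not. The aTc bolus only
#' degrades, so the override lapses on its own.
#'
#' @param config A [ca_config()]; calibrated automatically when thresholds
#'   are missing.
#' @param steps Number of rule updates to simulate.
#' @param seed Optional integer seed (for random seeding layouts).
#' @return A `ca_run`: list with `frames` (live/dead logical vectors per
#'   update), `cells` (position tibble), `config`, and `gfp_seed` (the
#'   bootstrap cells).
#' @export
run_colony_ca <- function(config, steps, seed = NULL) {
  stopifnot(inherits(config, "ca_config"), steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(config$c_low) || is.null(config$c_high)) {
    config <- calibrate_ca(config)
  }
  cells <- ca_positions(config)
  n <- nrow(cells)

  seed_live <- config$seed_live
  if (identical(seed_live, "random")) {
    seed_live <- seq_len(n) %in% sample.int(n, max(1L, round(config$seed_frac * n)))
  } else if (is.matrix(seed_live)) {
    stopifnot(config$layout == "lattice",
              nrow(seed_live) == config$side, ncol(seed_live) == config$side)
    seed_live <- as.logical(seed_live[cbind(cells$row, cells$col)])
  } else {
    seed_live <- as.logical(seed_live)
    stopifnot(length(seed_live) == n)
  }

  extent <- 2 * (max(abs(c(cells$x, cells$y))) + 4 * config$dx)
  gn <- config$grid_n %||% (2L * ceiling(extent / (2 * config$dx)) + 1L)
  ahl <- signal_field(gn, dx = config$dx, D = config$D,
                      lambda = config$lambda)
  atc <- config$atc_amount   # spatially uniform bolus amplitude, decay only

  pos <- cbind(cells$x, cells$y)
  alive <- rep(FALSE, n)
  frames <- vector("list", steps + 1L)
  frames[[1L]] <- alive

  emit_idx <- function(live_vec) which(live_vec)
  for (s in seq_len(steps)) {
    boot <- atc > config$atc_threshold
    emitting <- if (boot) (alive | seed_live) else alive
    # continuous emission integrated over the update interval, substepped
    # for stability; per-substep deposits are accumulated on one stencil
    dt_max <- min(sf_stable_dt(ahl), 0.5 / config$lambda, 1)
    k <- max(1L, ceiling(config$update_every / dt_max))
    dt <- config$update_every / k
    em <- emit_idx(emitting)
    stencil <- matrix(0, ahl$n, ahl$n)
    for (j in em) {
      rc <- round((c(pos[j, 2], pos[j, 1]) + ahl$half) / ahl$dx) + 1L
      stencil[rc[1], rc[2]] <- stencil[rc[1], rc[2]] + config$emission * dt
    }
    for (i in seq_len(k)) {
      ahl$grid <- ahl$grid + stencil
      ahl <- sf_step(ahl, dt)
    }
    atc <- atc * exp(-config$lambda * config$update_every)
    conc <- sf_sample(ahl, pos)
    alive <- band_rule(conc, config$c_low, config$c_high)
    if (boot) alive <- alive | seed_live
    frames[[s + 1L]] <- alive
  }

  structure(
    list(frames = frames, cells = cells, config = config,
         gfp_seed = seed_live),
    class = "ca_run"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rasterize a colony CA frame onto the reference grid
#'
#' @param run A `ca_run` (lattice layout).
#' @param frame Frame index (1 = initial state).
#' @return A `life_grid`.
#' @export
ca_frame_grid <- function(run, frame) {
  stopifnot(inherits(run, "ca_run"), run$config$layout == "lattice")
  s <- run$config$side
  m <- matrix(0L, s, s)
  live <- run$frames[[frame]]
  m[cbind(run$cells$row, run$cells$col)] <- as.integer(live)
  life_grid(m)
}

#' Jaccard similarity between colony and grid Life patterns
#'
#' Rasterizes the colony frame onto the reference grid (one lattice cell per
#' grid site) and returns the Jaccard index of the live sets:
#' `|A & B| / |A | B|`, defined as 1 when both patterns are empty.
#'
#' @param colony_frame A `life_grid` (e.g. from [ca_frame_grid()]) or a
#'   `ca_run` plus `frame`.
#' @param grid_frame A `life_grid` of identical dimensions.
#' @param frame Frame index when `colony_frame` is a `ca_run`.
#' @return Similarity score in `[0, 1]`.
#' @export
compare_patterns <- function(colony_frame, grid_frame, frame = NULL) {
  if (inherits(colony_frame, "ca_run")) {
    colony_frame <- ca_frame_grid(colony_frame, frame)
  }
  a <- unclass(life_grid(colony_frame)) == 1L
  b <- unclass(life_grid(grid_frame)) == 1L
  if (!identical(dim(a), dim(b))) {
    stop("patterns must share the same raster dimensions", call. = FALSE)
  }
  un <- sum(a | b)
  if (un == 0L) return(1)
  sum(a & b) / un
}
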