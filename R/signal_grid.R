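#' 2D reaction-diffusion signal fields
#'
#' Environmental (aTc) and intercellular (AHL) signals live on a square
#' lattice with spacing `dx` (um), diffusion coefficient `D` (um^2/min) and
#' first-order degradation rate `lambda` (1/min), with no-flux boundaries.
#' The grid is centered on the origin so colony coordinates map directly
#' onto field positions. Concentrations are in arbitrary units; "mass" is
#' the plain sum of node values, which the flux-form Laplacian conserves
#' exactly when `lambda = 0` and nothing is emitted.
#'
#' @param n Number of nodes per side (the grid is n x n).
#' @param dx Node spacing in um (default 2, about one cell diameter).
#' @param D Diffusion coefficient, um^2/min.
#' @param lambda Degradation rate, 1/min.
#' @return A `signal_field` object.
#' @examples
#' f <- signal_field(41, D = 12, lambda = 0.05)
#' f <- sf_deposit(f, c(0, 0), 10)
#' f <- sf_step(f, dt = 1)
#' sf_sample(f, c(1, 0))
#' @export
signal_field <- function(n, dx = 2, D = 12, lambda = 0.05) {
  stopifnot(n >= 3, dx > 0, D >= 0, lambda >= 0)
  structure(
    list(grid = matrix(0, n, n), n = as.integer(n), dx = dx,
         D = D, lambda = lambda,
         half = (n - 1) / 2 * dx),   # grid spans [-half, half] on both axes
    class = "signal_field"
  )
}

#' @export
print.signal_field <- function(x, ...) {
  cat("<signal_field> ", x$n, "x", x$n, " nodes, dx=", x$dx, " um, D=", x$D,
      " um^2/min, lambda=", x$lambda, " /min\n", sep = "")
  cat("  extent [", -x$half, ", ", x$half, "] um, total mass ",
      format(sf_mass(x)), "\n", sep = "")
  invisible(x)
}

#' @rdname signal_field
#' @param field A `signal_field`.
#' @export
sf_mass <- function(field) sum(field$grid)

#' Largest explicit-scheme stable step for a field
#'
#' The forward scheme requires `D * dt / dx^2 <= 0.25`.
#'
#' @param field A `signal_field`.
#' @return dt in minutes (Inf when D = 0).
#' @export
sf_stable_dt <- function(field) {
  if (field$D == 0) return(Inf)
  0.25 * field$dx^2 / field$D
}

#' Advance a signal field by one time step
#'
#' One forward step of the flux-form five-point Laplacian (no-flux
#' boundaries) followed by exponential degradation `exp(-lambda * dt)`.
#' Longer intervals are taken with [sf_run()], which substeps automatically.
#'
#' @param field A `signal_field`.
#' @param dt Step in minutes; must satisfy `D * dt / dx^2 <= 0.25`.
#' @return The updated field.
#' @export
sf_step <- function(field, dt) {
  stopifnot(inherits(field, "signal_field"), dt > 0)
  r <- field$D * dt / field$dx^2
  if (r > 0.25 + 1e-12) {
    stop("explicit scheme unstable: D*dt/dx^2 = ", signif(r, 4),
         " exceeds the stability bound 0.25; reduce dt below ",
         signif(sf_stable_dt(field), 4), " min", call. = FALSE)
  }
  g <- field$grid
  if (r > 0) {
    n <- field$n
    up    <- g[c(1L, seq_len(n - 1L)), , drop = FALSE]
    down  <- g[c(seq_len(n - 1L) + 1L, n), , drop = FALSE]
    left  <- g[, c(1L, seq_len(n - 1L)), drop = FALSE]
    right <- g[, c(seq_len(n - 1L) + 1L, n), drop = FALSE]
    # replicated edge rows/cols give zero flux across the boundary
    g <- g + r * (up + down + left + right - 4 * g)
  }
  if (field$lambda > 0) g <- g * exp(-field$lambda * dt)
  field$grid <- g
  field
}

#' Run a field forward over an interval, substepping for stability
#'
#' @param field A `signal_field`.
#' @param total Interval in minutes.
#' @param emit Optional function `(field) -> field` applied before each
#'   substep (used for continuous point sources).
#' @export
sf_run <- function(field, total, emit = NULL) {
  stopifnot(total >= 0)
  if (total == 0) return(field)
  dt_max <- sf_stable_dt(field)
  k <- max(1L, ceiling(total / min(dt_max, total)))
  dt <- total / k
  for (i in seq_len(k)) {
    if (!is.null(emit)) field <- emit(field)
    field <- sf_step(field, dt)
  }
  field
}

node_index <- function(field, position) {
  position <- as.numeric(position)
  if (length(position) != 2L || anyNA(position)) {
    stop("position must be an (x, y) pair", call. = FALSE)
  }
  if (any(abs(position) > field$half + 1e-9)) {
    stop("position (", position[1], ", ", position[2],
         ") lies outside the field extent [", -field$half, ", ",
         field$half, "]", call. = FALSE)
  }
  # column index ~ x, row index ~ y
  c(row = round((position[2] + field$half) / field$dx) + 1L,
    col = round((position[1] + field$half) / field$dx) + 1L)
}

#' Deposit signal at a position
#'
#' Adds `amount` to the node nearest to `position` (mass-conserving).
#'
#' @param field A `signal_field`.
#' @param position `(x, y)` in um; must lie within the field extent.
#' @param amount Signal amount (arbitrary units).
#' @export
sf_deposit <- function(field, position, amount) {
  idx <- node_index(field, position)
  field$grid[idx["row"], idx["col"]] <- field$grid[idx["row"], idx["col"]] + amount
  field
}

#' Deposit a Gaussian bolus centered at the origin
#'
#' Used for the annealing temperature: a single central aTc deposit of the
#' given total mass and width (standard deviation, um), then left to degrade.
#'
#' @param field A `signal_field`.
#' @param mass Total signal amount to spread over the grid.
#' @param width Gaussian standard deviation in um.
#' @export
sf_deposit_gaussian <- function(field, mass, width) {
  stopifnot(mass >= 0, width > 0)
  ax <- seq(-field$half, field$half, by = field$dx)
  w <- exp(-outer(ax^2, ax^2, "+") / (2 * width^2))
  field$grid <- field$grid + mass * w / sum(w)
  field
}

#' Sample a field at a continuous position (bilinear interpolation)
#'
#' @param field A `signal_field`.
#' @param position `(x, y)` in um, or a two-column matrix of positions.
#' @return Concentration(s) at the position(s).
#' @export
sf_sample <- function(field, position) {
  if (!is.matrix(position)) position <- matrix(as.numeric(position), nrow = 1L)
  if (any(abs(position) > field$half + 1e-9)) {
    stop("position outside field extent", call. = FALSE)
  }
  fx <- (position[, 1] + field$half) / field$dx   # 0-based continuous col
  fy <- (position[, 2] + field$half) / field$dx   # 0-based continuous row
  n <- field$n
  c0 <- pmin(pmax(floor(fx), 0), n - 1L); c1 <- pmin(c0 + 1L, n - 1L)
  r0 <- pmin(pmax(floor(fy), 0), n - 1L); r1 <- pmin(r0 + 1L, n - 1L)
  tx <- fx - c0; ty <- fy - r0
  g <- field$grid
  at <- function(rr, cc) g[cbind(rr + 1L, cc + 1L)]
  out <- (1 - ty) * ((1 - tx) * at(r0, c0) + tx * at(r0, c1)) +
              ty  * ((1 - tx) * at(r1, c0) + tx * at(r1, c1))
  unname(out)
}

#' Steady-state reach of a continuously emitting point source
#'
#' Emits `emission` units/min at the central node, iterates the field to its
#' numerical steady state (max per-substep change below `tol` relative to the
#' source-node concentration), then returns the radius at which the radial
#' concentration profile first falls to `threshold`, by linear interpolation
#' along a grid axis. Used to calibrate the quorum-sensing approximation of
#' the Moore neighborhood: D, lambda and emission are chosen so this reach
#' covers the 8 adjacent cells but not the next ring.
#'
#' @param D,lambda Diffusion (um^2/min) and degradation (1/min), both > 0.
#' @param emission Source strength, units/min (> 0).
#' @param threshold Concentration defining the edge of the neighborhood.
#' @param dx Grid spacing, um.
#' @param n Grid size per side (odd; default 41).
#' @param tol Relative convergence tolerance (default 1e-8).
#' @param max_minutes Cap on simulated time (default 2e4).
#' @return Radius in um, or `NA_real_` ("no reach") when the threshold
#'   exceeds the steady source-node concentration.
#' @export
steady_reach <- function(D, lambda, emission, threshold,
                         dx = 2, n = 41L, tol = 1e-8, max_minutes = 2e4) {
  stopifnot(D > 0, lambda > 0, emission > 0, threshold > 0)
  if (n %% 2L == 0L) n <- n + 1L
  field <- signal_field(n, dx = dx, D = D, lambda = lambda)
  f <- steady_point_source(field, emission, tol = tol,
                           max_minutes = max_minutes)
  mid <- (n + 1L) / 2L
  prof <- f$grid[mid, mid:n]           # radial profile along +x
  radii <- (seq_along(prof) - 1L) * dx
  if (threshold > prof[1]) return(NA_real_)
  below <- which(prof <= threshold)
  below <- below[below > 1L]
  if (length(below) == 0L) return(radii[length(radii)])  # reaches grid edge
  j <- below[1L]
  # linear interpolation between nodes j-1 and j
  r0 <- radii[j - 1L]; c0 <- prof[j - 1L]; c1 <- prof[j]
  if (c0 == c1) return(r0)
  r0 + dx * (c0 - threshold) / (c0 - c1)
}

#' Steady state of a field under a continuous central source
#'
#' Solves the discrete steady-state balance `(D / dx^2) L c - lambda c +
#' E = 0` (L the no-flux five-point Laplacian, E the emission rate at the
#' central node) exactly as a sparse linear system (`method = "solve"`,
#' the default), or by forward iteration of [sf_step()] with per-substep
#' deposits until the max per-step change falls below `tol` relative to
#' the source-node concentration (`method = "iterate"`). The two agree in
#' the small-step limit; the direct solve has no time-stepping artifact.
#'
#' @param field A `signal_field`.
#' @param emission Units/min at the central node.
#' @param method `"solve"` or `"iterate"`.
#' @inheritParams steady_reach
#' @return The field holding the steady concentrations.
#' @export
steady_point_source <- function(field, emission,
                                method = c("solve", "iterate"),
                                tol = 1e-8, max_minutes = 2e4) {
  method <- match.arg(method)
  stopifnot(field$lambda > 0, emission > 0)
  n <- field$n
  mid <- (n + 1L) %/% 2L
  if (method == "solve") {
    N <- n * n
    idx <- function(r, c) (c - 1L) * n + r       # column-major node index
    rr <- rep(seq_len(n), times = n)
    cc <- rep(seq_len(n), each = n)
    # neighbor pairs (right and down; symmetric counterpart added below)
    horiz <- cc < n
    vert <- rr < n
    from <- c(idx(rr[horiz], cc[horiz]), idx(rr[vert], cc[vert]))
    to   <- c(idx(rr[horiz], cc[horiz] + 1L), idx(rr[vert] + 1L, cc[vert]))
    k <- field$D / field$dx^2
    A <- Matrix::sparseMatrix(
      i = c(seq_len(N), from, to),
      j = c(seq_len(N), to, from),
      x = c(rep(field$lambda, N), rep(-k, 2L * length(from))),
      dims = c(N, N)
    )
    # diagonal: lambda + k * (number of neighbors), flux-form no-flux
    deg <- (cc > 1L) + (cc < n) + (rr > 1L) + (rr < n)
    Matrix::diag(A) <- field$lambda + k * deg
    s <- numeric(N)
    s[idx(mid, mid)] <- emission
    field$grid <- matrix(as.numeric(Matrix::solve(A, s)), n, n)
    return(field)
  }
  dt <- min(0.2 * sf_stable_dt(field), 0.5 / field$lambda, 1)
  t <- 0
  repeat {
    prev <- field$grid
    field$grid[mid, mid] <- field$grid[mid, mid] + emission * dt
    field <- sf_step(field, dt)
    t <- t + dt
    ref <- max(field$grid[mid, mid], .Machine$double.eps)
    if (max(abs(field$grid - prev)) / ref < tol || t >= max_minutes) break
  }
  field
}
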