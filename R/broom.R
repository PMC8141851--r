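#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a colony run
#'
#' @param x A `colony_run` from [run_colony()].
#' @param ... Unused.
#' @return The per-step trajectory tibble: `time`, `generation`, `n_cells`,
#'   `n_optimal`, `n_gfp`, `conj_events`, and `atc_mass` in annealing mode.
#' @export
tidy.colony_run <- function(x, ...) x$trajectory

#' @rdname tidy.colony_run
#' @return `glance()`: a one-row tibble with the run outcome.
#' @export
glance.colony_run <- function(x, ...) {
  tibble::tibble(
    algorithm = x$config$algorithm,
    pattern = unclass(x$config$pattern),
    N0 = x$config$N0, Nf = x$config$Nf,
    m = x$config$m, c = x$config$c,
    alpha = if (x$config$algorithm == "SA") x$config$alpha else NA_real_,
    seed = x$seed %||% NA_integer_,
    found = x$found,
    first_optimum_generation = x$first_optimum_generation,
    stopped_generation = x$stopped_generation,
    final_n = x$final_n
  )
}

#' Tidy a classical run
#'
#' @param x An `mh_run` from [sga_run()] or [sa_run()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.mh_run <- function(x, ...) glance.mh_run(x)

#' @rdname tidy.mh_run
#' @export
glance.mh_run <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    pattern = unclass(x$pattern),
    seed = x$seed %||% NA_integer_,
    found = x$found,
    first_optimum = as.numeric(x$first_optimum),
    stopped_at = as.numeric(x$stopped_at)
  )
}
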