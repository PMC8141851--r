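#' Parse a flat parameter file into a run configuration
#'
#' The interpreter front end: reads the documented flat key-value format
#' (YAML-compatible) holding the fundamental algorithm parameters — number
#' of proteins is implied by the pattern length; protein presence is the
#' `{1,0,x}` pattern; initial/final cell counts; mutation, conjugation and
#' temperature-decrease rates — validates them, and fills documented
#' defaults. Every field that fell back to its default is recorded in the
#' `defaulted` attribute.
#'
#' Recognized keys: `algorithm` (SGA/SA, required), `pattern` (required),
#' `N0` (required), `Nf` (required), `m`, `c`, `alpha`, `detection`,
#' `T_div`, `tau_gfp`, `seed`, `max_generations`.
#'
#' @param text A string (or character vector of lines) in the key-value
#'   format, or the path of a file containing it.
#' @return An [mh_config()] with attribute `defaulted` naming defaulted
#'   fields.
#' @examples
#' cfg <- parse_mh_config("
#'   algorithm: SGA
#'   pattern: '1100'
#'   N0: 200
#'   Nf: 10000
#'   m: 0.01
#'   c: 0.01
#' ")
#' attr(cfg, "defaulted")
#' @export
parse_mh_config <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  } else if (length(text) > 1L) {
    text <- paste(text, collapse = "\n")
  }
  vals <- yaml::yaml.load(text)
  if (!is.list(vals)) stop("could not parse key-value config", call. = FALSE)

  required <- c("algorithm", "pattern", "N0", "Nf")
  missing <- setdiff(required, names(vals))
  if (length(missing)) {
    stop("missing required config field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  # yaml turns a bare 1100 into a number (and 10xxx into a string): normalize
  pattern_str <- gsub("[.,]", "", format(vals$pattern, scientific = FALSE))
  optional <- list(m = NULL, c = 0.01, alpha = 0.25,
                   detection = "gfp", T_div = 20, tau_gfp = 12,
                   seed = NULL, max_generations = 30)
  defaulted <- setdiff(names(optional), names(vals))
  algorithm <- toupper(as.character(vals$algorithm))
  if (!algorithm %in% c("SGA", "SA")) {
    stop("algorithm must be SGA or SA, got \"", vals$algorithm, "\"",
         call. = FALSE)
  }
  get <- function(key) if (key %in% names(vals)) vals[[key]] else optional[[key]]
  m <- get("m")
  if (is.null(m)) m <- if (algorithm == "SA") 0 else 0.01
  cfg <- mh_config(
    algorithm = algorithm,
    pattern = pattern_str,
    N0 = vals$N0, Nf = vals$Nf,
    m = m, c = get("c"), alpha = get("alpha"),
    detection = get("detection"),
    engine = list(T_div = get("T_div"), tau_gfp = get("tau_gfp")),
    max_generations = get("max_generations"),
    seed = get("seed")
  )
  attr(cfg, "defaulted") <- defaulted
  cfg
}

#' Emit a gro-style skeleton specification for a configuration
#'
#' Serializes the configuration into the package's documented skeleton
#' dialect — a deterministic, human-readable text block styled after gro
#' specifications (signals, plasmids, the compiled fitness circuit, and one
#' program block per operator). Annealing configurations declare the aTc
#' signal with `lambda = -log(alpha) / T_div`, the degradation rate that
#' shrinks the temperature field by a factor `alpha` per generation.
#' `parse_skeleton()` inverts the serialization field by field.
#'
#' @param config An [mh_config()].
#' @return A character scalar (the skeleton text).
#' @export
emit_skeleton <- function(config) {
  stopifnot(inherits(config, "mh_config"))
  L <- pattern_length(config$pattern)
  num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  lines <- c(
    "skeleton colonymh/1",
    paste0("algorithm ", config$algorithm),
    paste0("seed ", if (is.null(config$seed)) "none" else config$seed),
    paste0("pattern ", unclass(config$pattern)),
    paste0("population initial=", config$N0, " final=", config$Nf),
    paste0("engine T_div=", num(config$engine$T_div),
           " tau_gfp=", num(config$engine$tau_gfp)),
    paste0("detection ", config$detection)
  )
  if (config$algorithm == "SA") {
    lam <- -log(config$alpha) / config$engine$T_div
    lines <- c(lines,
      paste0("signal atc D=", num(config$sa$D), " lambda=", num(lam),
             " alpha=", num(config$alpha), " amount=", num(config$sa$amount)))
  }
  lines <- c(lines,
    vapply(seq_len(L), function(i)
      paste0("plasmid p", i, " conjugative protein=p", i), character(1)),
    strsplit(format_circuit(compile_pattern(config$pattern)), "\n")[[1]],
    paste0("program conjugation rate=", num(config$c),
           " reach=", num(config$engine$conj_reach)),
    paste0("program mutation rate=", num(config$m), " at=division"),
    paste0("program reporter gfp maturation=",
           num(config$engine$tau_gfp)),
    if (config$algorithm == "SA")
      "program temperature sensor=atc target=conjugation",
    paste0("stop final_count=", config$Nf,
           " max_generations=", num(config$max_generations)),
    "end"
  )
  paste(lines, collapse = "\n")
}

#' @rdname emit_skeleton
#' @param text Skeleton text from `emit_skeleton()`.
#' @export
parse_skeleton <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (!startsWith(lines[1], "skeleton colonymh/")) {
    stop("not a colonymh skeleton", call. = FALSE)
  }
  word <- function(prefix) {
    ln <- grep(paste0("^", prefix, " "), lines, value = TRUE)[1]
    sub(paste0("^", prefix, " "), "", ln)
  }
  kv <- function(line, key) {
    m <- regmatches(line, regexec(paste0(key, "=([^ ]+)"), line))[[1]]
    if (length(m) < 2L) NA_character_ else m[2]
  }
  pop <- word("population")
  eng <- word("engine")
  conj <- grep("^program conjugation", lines, value = TRUE)[1]
  mut <- grep("^program mutation", lines, value = TRUE)[1]
  stopline <- grep("^stop", lines, value = TRUE)[1]
  seed <- word("seed")
  algorithm <- word("algorithm")
  alpha <- 0.25
  if (algorithm == "SA") {
    sig <- grep("^signal atc", lines, value = TRUE)[1]
    alpha <- as.numeric(kv(sig, "alpha"))
  }
  mh_config(
    algorithm = algorithm,
    pattern = word("pattern"),
    N0 = as.integer(kv(pop, "initial")),
    Nf = as.integer(kv(pop, "final")),
    m = as.numeric(kv(mut, "rate")),
    c = as.numeric(kv(conj, "rate")),
    alpha = alpha,
    detection = word("detection"),
    engine = list(T_div = as.numeric(kv(eng, "T_div")),
                  tau_gfp = as.numeric(kv(eng, "tau_gfp"))),
    max_generations = as.numeric(kv(stopline, "max_generations")),
    seed = if (seed == "none") NULL else as.integer(seed)
  )
}

## ---- sweeps ----------------------------------------------------------------

sweep_grids <- function() {
  base <- list(pattern = "1100", P = 200, c = 0.01, m = 0.01, alpha = 0.25)
  list(
    T2 = list(algorithm = "SGA", vary = "pattern",
              values = c("11111", "11000", "1100", "10xxx"), base = base),
    T3 = list(algorithm = "SGA", vary = "m",
              values = c(0, 0.01, 0.05, 0.10), base = base),
    T4 = list(algorithm = "SGA", vary = "c",
              values = c(0.025, 0.05, 0.075, 0.10), base = base),
    T5 = list(algorithm = "SGA", vary = "P",
              values = c(200, 400, 10000), base = base),
    T6 = list(algorithm = "SA", vary = "pattern",
              values = c("11111", "11000", "1100", "10xxx"), base = base),
    T7 = list(algorithm = "SA", vary = "alpha",
              values = c(0.25, 0.5, 0.75, 0.9), base = base)
  )
}

#' Run one of the published parameter sweeps
#'
#' Reproduces the parameter grids of the six reported tables: fitness
#' function (T2 for the genetic algorithm, T6 for annealing), mutation rate
#' (T3), crossover/conjugation rate (T4), initial population size (T5) and
#' temperature decrease rate (T7), each around the baseline configuration
#' (pattern 1100, 1% conjugation, 1% mutation, 200 initial cells, stop at
#' 10,000; annealing baseline alpha 0.25). Every grid point is run for
#' `replicates` seeded repeats (`seed0`, `seed0 + 1`, ...) with matched
#' seeds across grid points, for the classical fixed-pool implementation,
#' the colony implementation, or both.
#'
#' @param table_id One of `"T2" ... "T7"`.
#' @param replicates Number of seeded repeats per grid point (>= 1).
#' @param seed0 First seed.
#' @param implementation Subset of `c("classic", "colony")`.
#' @param Nf Colony stop size (default 10000; raised to `2 * N0` when the
#'   initial population is larger).
#' @param max_generations Classical generation cap / colony safety cap.
#' @return A list with `runs` (one row per run) and `summary` (one row per
#'   grid point and implementation: replicate count, number of runs that
#'   found an optimum, mean over found runs, stop-censored mean, sd).
#' @export
run_sweep <- function(table_id, replicates = 30, seed0 = 1,
                      implementation = c("classic", "colony"),
                      Nf = 10000, max_generations = 100) {
  grids <- sweep_grids()
  if (!table_id %in% names(grids)) {
    stop("unknown table_id \"", table_id, "\"; use one of ",
         paste(names(grids), collapse = ", "), call. = FALSE)
  }
  stopifnot(replicates >= 1)
  implementation <- match.arg(implementation, several.ok = TRUE)
  g <- grids[[table_id]]
  seeds <- seq.int(seed0, length.out = replicates)

  runs <- purrr::map_dfr(g$values, function(v) {
    p <- g$base
    p[[g$vary]] <- v
    point <- purrr::map_dfr(implementation, function(impl) {
      if (impl == "classic") {
        tb <- if (g$algorithm == "SGA") {
          replicate_runs(sga_run, seeds, pattern = p$pattern, P = p$P,
                         c = p$c, m = p$m, max_generations = max_generations)
        } else {
          replicate_runs(sa_run, seeds, pattern = p$pattern, alpha = p$alpha)
        }
        tb$stopped_generation <- NA_real_
      } else {
        cfg <- mh_config(g$algorithm, p$pattern, N0 = p$P,
                         Nf = max(Nf, 2L * p$P),
                         m = if (g$algorithm == "SA") 0 else p$m,
                         c = p$c, alpha = p$alpha,
                         max_generations = max_generations)
        tb <- replicate_colony(cfg, seeds)
        tb$final_n <- NULL
      }
      tb$implementation <- impl
      tb
    })
    point$table <- table_id
    point$varied <- g$vary
    point$value <- as.character(v)
    point
  })

  summary <- runs |>
    dplyr::group_by(.data$table, .data$varied, .data$value,
                    .data$implementation) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_found = sum(.data$found),
      mean_found = mean(.data$first_optimum[.data$found]),
      mean_censored = mean(ifelse(.data$found, .data$first_optimum,
                                  .data$stopped_generation)),
      sd_found = stats::sd(.data$first_optimum[.data$found]),
      .groups = "drop"
    )
  list(runs = runs, summary = summary)
}

## ---- fixtures --------------------------------------------------------------

#' Generate a reproducible random pattern and a clause formula realizing it
#'
#' Draws a pattern uniformly over `{1, 0, x}` per position and builds a
#' one-literal-per-clause formula together with an explicit truth
#' assignment such that clause i evaluates true exactly when pattern
#' position i is `1` (don't-care positions get a random clause value).
#' Every generated pattern is satisfiable by construction.
#'
#' @param L Number of plasmids/clauses (>= 1).
#' @param seed Integer seed.
#' @return A list: `pattern`, `formula` (a [clause_formula()]),
#'   `assignment` (logical), and `genotype` (the encoded bit string, which
#'   satisfies the pattern's `1` positions).
#' @export
make_fixture <- function(L, seed) {
  stopifnot(L >= 1)
  set.seed(seed)
  pattern <- fitness_pattern(
    paste(sample(c("1", "0", "x"), L, replace = TRUE), collapse = ""))
  assignment <- stats::runif(L) < 0.5
  sym <- pattern_symbols(pattern)
  want_true <- ifelse(sym == "x", stats::runif(L) < 0.5, sym == "1")
  clauses <- lapply(seq_len(L), function(i) {
    # single literal over variable i whose value matches want_true[i]
    if (want_true[i] == assignment[i]) i else -i
  })
  list(pattern = pattern, formula = clause_formula(clauses),
       assignment = assignment,
       genotype = paste(as.integer(want_true), collapse = ""))
}
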