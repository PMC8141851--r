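#' Compile a fitness pattern into a three-tier repressor circuit
#'
#' The fitness function is realized as transcriptional logic in three tiers:
#'
#' * **Tier 1 (inputs):** one conjugative plasmid per constrained pattern
#'   position, expressing input protein `p<i>`. "Don't care" positions are
#'   omitted entirely.
#' * **Tier 2 (transduction):** forbidden-set inputs (`0` positions) each
#'   activate `araC` (an OR gate — any forbidden protein present turns araC
#'   on). Required-set inputs (`1` positions) jointly repress `trpR`
#'   (an AND gate — trpR stays on unless *all* required proteins are
#'   present).
#' * **Tier 3 (evaluation):** `trpR` represses `lacI`; `cI` is driven by two
#'   promoters, one activated by `araC` and one constitutive but repressed by
#'   `lacI`; `cI` represses `GFP`. The net effect: GFP is on iff no forbidden
#'   plasmid is present and every required plasmid is.
#'
#' The compiled object stores the regulatory wiring as promoters (each with
#' activator and repressor sets), and [eval_circuit()] evaluates its Boolean
#' steady state by a topological pass — it never consults the pattern
#' directly, which is what makes the equivalence with [is_optimal()] a real
#' cross-check.
#'
#' @param pattern A [fitness_pattern()].
#' @return A `circuit_spec` object.
#' @examples
#' cs <- compile_pattern("1100")
#' eval_circuit(cs, "1100")  # TRUE: exact match
#' eval_circuit(cs, "1110")  # FALSE: forbidden plasmid 3 present
#' @export
compile_pattern <- function(pattern) {
  pattern <- fitness_pattern(pattern)
  req  <- required_set(pattern)
  forb <- forbidden_set(pattern)
  idx <- sort(c(req, forb))
  inputs <- if (length(idx)) paste0("p", idx) else character(0)

  promoters <- list()
  add <- function(target, activators = character(), repressors = character(),
                  repression = c("any", "all")) {
    repression <- match.arg(repression)
    promoters[[length(promoters) + 1L]] <<- list(
      target = target, activators = activators,
      repressors = repressors, repression = repression
    )
  }
  # tier 2: OR gate over the forbidden set -> araC
  for (i in forb) add("araC", activators = paste0("p", i))
  # tier 2: AND gate over the required set -> trpR stays on unless all present
  if (length(req)) {
    add("trpR", repressors = paste0("p", req), repression = "all")
  }
  # tier 3: inverter chain and the P_lambda OR node
  add("lacI", repressors = "trpR")
  add("cI", activators = "araC")            # P_BAD branch
  add("cI", repressors = "lacI")            # P_lambda branch (constitutive)
  add("GFP", repressors = "cI")

  structure(
    list(
      pattern = pattern,
      tiers = list(
        input = inputs,
        transduction = c("araC", "trpR"),
        evaluation = c("lacI", "cI", "GFP")
      ),
      inputs = inputs,
      input_index = idx,
      promoters = promoters
    ),
    class = "circuit_spec"
  )
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat("<circuit_spec> three-tier evaluator for pattern ",
      unclass(x$pattern), "\n", sep = "")
  cat("  inputs: ",
      if (length(x$inputs)) paste(x$inputs, collapse = ", ") else "(none)",
      "\n", sep = "")
  cat("  promoters: ", length(x$promoters), " (",
      nrow(circuit_edges(x)), " regulatory edges)\n", sep = "")
  invisible(x)
}

#' Evaluate the Boolean steady state of a compiled circuit
#'
#' Species are digital (on/off). A promoter fires iff all of its activators
#' are on (a promoter with no activators is constitutive) and it is not
#' silenced; silencing needs any repressor on (`repression = "any"`) or all
#' of them on (`repression = "all"`, the cooperative AND-gate promoter).
#' A species is on iff any of its promoters fires. Inputs are clamped to the
#' genotype and the remaining tiers are resolved in topological order
#' (araC/trpR, then lacI, cI, GFP).
#'
#' @param circuit A `circuit_spec` from [compile_pattern()].
#' @param genotypes Bit strings or 0/1 matrix; length must match the
#'   circuit's pattern.
#' @return Logical vector: GFP state per genotype.
#' @export
eval_circuit <- function(circuit, genotypes) {
  stopifnot(inherits(circuit, "circuit_spec"))
  L <- pattern_length(circuit$pattern)
  m <- genotype_matrix(genotypes, L = L)
  order <- c("araC", "trpR", "lacI", "cI", "GFP")
  vapply(seq_len(nrow(m)), function(r) {
    state <- as.list(stats::setNames(m[r, circuit$input_index] == 1L,
                                     circuit$inputs))
    for (species in order) {
      proms <- Filter(function(p) p$target == species, circuit$promoters)
      on <- FALSE
      for (p in proms) {
        act_ok <- all(vapply(p$activators, function(a) isTRUE(state[[a]]),
                             logical(1)))
        rep_on <- vapply(p$repressors, function(a) isTRUE(state[[a]]),
                         logical(1))
        silenced <- if (p$repression == "all") {
          length(rep_on) > 0L && all(rep_on)
        } else {
          any(rep_on)
        }
        if (act_ok && !silenced) { on <- TRUE; break }
      }
      state[[species]] <- on
    }
    isTRUE(state[["GFP"]])
  }, logical(1))
}

#' Regulatory edge list of a compiled circuit
#'
#' @param circuit A `circuit_spec`.
#' @return A tibble with columns `from`, `to`, `type` (activation/repression)
#'   and `gate` (how repressors combine at the target promoter).
#' @export
circuit_edges <- function(circuit) {
  stopifnot(inherits(circuit, "circuit_spec"))
  rows <- purrr::map_dfr(circuit$promoters, function(p) {
    dplyr::bind_rows(
      if (length(p$activators)) {
        tibble::tibble(from = p$activators, to = p$target,
                       type = "activation", gate = "any")
      },
      if (length(p$repressors)) {
        tibble::tibble(from = p$repressors, to = p$target,
                       type = "repression", gate = p$repression)
      }
    )
  })
  rows
}

#' Render a circuit as the text block used in skeleton files
#'
#' @param circuit A `circuit_spec`.
#' @return A character scalar (multi-line).
#' @export
format_circuit <- function(circuit) {
  stopifnot(inherits(circuit, "circuit_spec"))
  e <- circuit_edges(circuit)
  lines <- c(
    paste0("circuit pattern=", unclass(circuit$pattern)),
    paste0("  inputs ", if (length(circuit$inputs))
      paste(circuit$inputs, collapse = " ") else "-"),
    vapply(seq_len(nrow(e)), function(i) {
      sprintf("  %s %s -> %s [%s]", e$type[i], e$from[i], e$to[i], e$gate[i])
    }, character(1))
  )
  paste(lines, collapse = "\n")
}
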