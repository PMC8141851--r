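#' Protein-presence fitness patterns
#'
#' A fitness pattern is a string over the alphabet `{1, 0, x}` with one symbol
#' per plasmid: `1` means the plasmid (and hence its protein) must be present
#' in an optimal solution, `0` means it must be absent, and `x` marks a
#' "don't care" position that never affects fitness. Candidate solutions are
#' plasmid-presence bit strings of the same length (bit i is 1 iff plasmid i
#' is carried by the cell), so the pattern is the whole fitness function:
#' a genotype is optimal iff it satisfies every constrained position.
#'
#' @param x A single string over `{1, 0, x}`, e.g. `"1100"` or `"10xxx"`.
#' @return A `fitness_pattern` object (a validated character scalar).
#' @examples
#' p <- fitness_pattern("10xxx")
#' is_optimal("10000", p)
#' count_optimal(p)
#' @export
fitness_pattern <- function(x) {
  if (inherits(x, "fitness_pattern")) return(x)
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("a fitness pattern must be a single character string", call. = FALSE)
  }
  if (nchar(x) < 1L) {
    stop("a fitness pattern must have length >= 1", call. = FALSE)
  }
  if (grepl("[^10x]", x)) {
    stop("fitness pattern may contain only '1', '0' and 'x': got \"", x, "\"",
         call. = FALSE)
  }
  structure(x, class = "fitness_pattern")
}

#' @export
print.fitness_pattern <- function(x, ...) {
  sym <- pattern_symbols(x)
  cat("<fitness_pattern> ", unclass(x), "\n", sep = "")
  cat("  plasmids: ", length(sym),
      "  required: ", sum(sym == "1"),
      "  forbidden: ", sum(sym == "0"),
      "  don't care: ", sum(sym == "x"), "\n", sep = "")
  invisible(x)
}

pattern_symbols <- function(pattern) {
  strsplit(unclass(fitness_pattern(pattern)), "", fixed = TRUE)[[1]]
}

#' @rdname fitness_pattern
#' @export
pattern_length <- function(x) nchar(unclass(fitness_pattern(x)))

#' Required / forbidden plasmid indices of a pattern
#'
#' @param pattern A [fitness_pattern()] (or string coercible to one).
#' @return An integer vector of 1-based plasmid indices.
#' @export
required_set <- function(pattern) which(pattern_symbols(pattern) == "1")

#' @rdname required_set
#' @export
forbidden_set <- function(pattern) which(pattern_symbols(pattern) == "0")

## ---- genotypes -------------------------------------------------------------

#' Convert genotype bit strings to a presence matrix
#'
#' Genotypes are displayed as bit strings read left to right ("10010"), with
#' bit i = 1 iff plasmid i is present. Internally operations are vectorized
#' over a 0/1 integer matrix with one row per genotype.
#'
#' @param genotypes Character vector of bit strings, or a 0/1 matrix/vector.
#' @param L Expected number of plasmids (optional check).
#' @return Integer matrix, one row per genotype, one column per plasmid.
#' @export
genotype_matrix <- function(genotypes, L = NULL) {
  if (is.matrix(genotypes)) {
    m <- genotypes
    storage.mode(m) <- "integer"
  } else if (is.numeric(genotypes)) {
    m <- matrix(as.integer(genotypes), nrow = 1L)
  } else {
    if (!is.character(genotypes)) {
      stop("genotypes must be bit strings or a 0/1 matrix", call. = FALSE)
    }
    if (length(genotypes) == 0L) {
      stop("no genotypes supplied", call. = FALSE)
    }
    if (any(grepl("[^01]", genotypes))) {
      stop("genotype bit strings may contain only '0' and '1'", call. = FALSE)
    }
    n <- nchar(genotypes)
    if (length(unique(n)) != 1L) {
      stop("all genotypes must have the same length", call. = FALSE)
    }
    m <- matrix(
      as.integer(unlist(strsplit(genotypes, "", fixed = TRUE), use.names = FALSE)),
      nrow = length(genotypes), ncol = n[1L], byrow = TRUE
    )
  }
  if (any(is.na(m)) || any(m != 0L & m != 1L)) {
    stop("genotype entries must be 0 or 1", call. = FALSE)
  }
  if (!is.null(L) && ncol(m) != L) {
    stop("genotype length ", ncol(m), " does not match pattern length ", L,
         call. = FALSE)
  }
  m
}

#' @rdname genotype_matrix
#' @export
genotype_string <- function(m) {
  m <- genotype_matrix(m)
  apply(m, 1L, paste, collapse = "")
}

#' Evaluate genotypes against a fitness pattern
#'
#' A genotype is optimal iff every `1` position of the pattern carries the
#' plasmid and every `0` position does not; `x` positions are ignored. This is
#' the direct, definitional evaluation; [eval_circuit()] reaches the same
#' answer through the compiled repressor cascade.
#'
#' @param genotypes Bit strings (character vector) or a 0/1 matrix.
#' @inheritParams required_set
#' @return Logical vector, one element per genotype.
#' @export
is_optimal <- function(genotypes, pattern) {
  pattern <- fitness_pattern(pattern)
  L <- pattern_length(pattern)
  m <- genotype_matrix(genotypes, L = L)
  req <- required_set(pattern)
  forb <- forbidden_set(pattern)
  ok <- rep(TRUE, nrow(m))
  if (length(req))  ok <- ok & rowSums(m[, req,  drop = FALSE] == 0L) == 0L
  if (length(forb)) ok <- ok & rowSums(m[, forb, drop = FALSE] == 1L) == 0L
  ok
}

#' Number of constrained positions a genotype violates
#'
#' The annealing energy: the count of pattern positions marked `1` whose
#' plasmid is absent plus positions marked `0` whose plasmid is present.
#' Zero iff the genotype is optimal.
#'
#' @inheritParams is_optimal
#' @return Non-negative integer vector.
#' @export
energy <- function(genotypes, pattern) {
  pattern <- fitness_pattern(pattern)
  m <- genotype_matrix(genotypes, L = pattern_length(pattern))
  req <- required_set(pattern)
  forb <- forbidden_set(pattern)
  e <- integer(nrow(m))
  if (length(req))  e <- e + rowSums(m[, req,  drop = FALSE] == 0L)
  if (length(forb)) e <- e + rowSums(m[, forb, drop = FALSE] == 1L)
  as.integer(e)
}

#' Enumerate all genotypes of a given length
#'
#' @param L Number of plasmids (L <= 20 to keep 2^L enumerable).
#' @return Integer matrix with 2^L rows in lexicographic order.
#' @export
enumerate_genotypes <- function(L) {
  stopifnot(L >= 1, L <= 20)
  g <- as.matrix(expand.grid(rep(list(0:1), L), KEEP.OUT.ATTRS = FALSE))[,
    L:1, drop = FALSE]
  dimnames(g) <- NULL
  storage.mode(g) <- "integer"
  g
}

#' Count genotypes satisfying a pattern
#'
#' Equal to 2^(number of `x` symbols): constrained positions are forced.
#'
#' @inheritParams required_set
#' @return A non-negative count.
#' @export
count_optimal <- function(pattern) {
  pattern <- fitness_pattern(pattern)
  2^sum(pattern_symbols(pattern) == "x")
}

## ---- clause formulas -------------------------------------------------------

#' Clause formulas and their plasmid encoding
#'
#' A propositional formula in conjunctive form: an ordered list of disjunctive
#' clauses, each a vector of signed variable indices (DIMACS convention:
#' `3` means variable 3, `-3` its negation). In the plasmid encoding each
#' clause becomes one protein on its own conjugative plasmid whose presence
#' stands for the clause evaluating true under a given truth assignment, so
#' satisfying the full formula corresponds to the all-`1` pattern over the
#' clause plasmids.
#'
#' @param clauses A list of integer vectors (one clause each, no zeros), or a
#'   single string/character vector in DIMACS-like form: one clause per line
#'   of whitespace-separated signed integers (an optional trailing 0 per line
#'   and `c`/`p` header lines are tolerated).
#' @return A `clause_formula` object: list with `clauses` and `n_vars`.
#' @examples
#' f <- clause_formula(list(c(1, -2), c(2, 3)))
#' formula_to_plasmids(f, assignment = c(TRUE, FALSE, TRUE))
#' @export
clause_formula <- function(clauses) {
  if (inherits(clauses, "clause_formula")) return(clauses)
  if (is.character(clauses)) clauses <- parse_dimacs(clauses)
  if (!is.list(clauses) || length(clauses) == 0L) {
    stop("a clause formula needs at least one clause", call. = FALSE)
  }
  clauses <- lapply(clauses, function(cl) {
    cl <- as.integer(cl)
    if (length(cl) == 0L || any(is.na(cl)) || any(cl == 0L)) {
      stop("each clause needs at least one nonzero signed literal",
           call. = FALSE)
    }
    cl
  })
  structure(
    list(clauses = clauses, n_vars = max(abs(unlist(clauses)))),
    class = "clause_formula"
  )
}

parse_dimacs <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^[cp]", lines)]
  if (length(lines) == 0L) stop("no clauses found", call. = FALSE)
  lapply(lines, function(ln) {
    lits <- as.integer(strsplit(ln, "[[:space:]]+")[[1]])
    if (anyNA(lits)) stop("malformed clause line: \"", ln, "\"", call. = FALSE)
    if (length(lits) > 1L && lits[length(lits)] == 0L) {
      lits <- lits[-length(lits)]
    }
    lits
  })
}

#' @export
print.clause_formula <- function(x, ...) {
  cat("<clause_formula> ", length(x$clauses), " clauses over ", x$n_vars,
      " variables\n", sep = "")
  invisible(x)
}

#' Encode a clause formula as plasmids under a truth assignment
#'
#' One plasmid per clause: plasmid i is present iff clause i evaluates true
#' under `assignment`. The target pattern for formula satisfaction is all-`1`
#' over the clause plasmids (the formula is the conjunction of its clauses).
#'
#' @param formula A [clause_formula()].
#' @param assignment Logical vector of truth values, one per variable.
#' @return A tibble with one row per clause: `plasmid`, `clause` (printed
#'   form), `true` (clause value), plus attributes via columns `pattern`
#'   (the all-ones target pattern) and `genotype` (the encoded bit string)
#'   repeated for convenience when the caller wants a single-row summary via
#'   [dplyr::distinct()].
#' @export
formula_to_plasmids <- function(formula, assignment) {
  formula <- clause_formula(formula)
  assignment <- as.logical(assignment)
  if (length(assignment) < formula$n_vars || anyNA(assignment)) {
    stop("assignment must give a truth value for every variable (need ",
         formula$n_vars, ")", call. = FALSE)
  }
  vals <- vapply(formula$clauses, function(cl) {
    any(vapply(cl, function(lit) {
      if (lit > 0L) assignment[lit] else !assignment[-lit]
    }, logical(1)))
  }, logical(1))
  n <- length(formula$clauses)
  tibble::tibble(
    plasmid  = seq_len(n),
    clause   = vapply(formula$clauses, paste, character(1), collapse = " "),
    true     = vals,
    pattern  = strrep("1", n),
    genotype = paste(as.integer(vals), collapse = "")
  )
}
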