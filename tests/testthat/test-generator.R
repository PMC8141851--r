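baseline_text <- "
algorithm: SGA
pattern: '1100'
N0: 200
Nf: 10000
m: 0.01
c: 0.01
"

test_that("the baseline parameter file parses into a valid configuration", {
  cfg <- parse_mh_config(baseline_text)
  expect_s3_class(cfg, "mh_config")
  expect_equal(unclass(cfg$pattern), "1100")
  expect_equal(cfg$N0, 200L)
  expect_equal(cfg$Nf, 10000L)
  expect_equal(cfg$m, 0.01)
  expect_equal(cfg$c, 0.01)
  # a bare unquoted 1100 (read as the number 1,100) still parses as the
  # four-symbol pattern
  cfg2 <- parse_mh_config("algorithm: SGA\npattern: 1100\nN0: 20\nNf: 100")
  expect_equal(unclass(cfg2$pattern), "1100")
})

test_that("missing and out-of-range fields fail with named errors", {
  expect_error(parse_mh_config("algorithm: SGA\npattern: '1100'\nN0: 10"),
               "Nf")
  expect_error(parse_mh_config("pattern: '1100'\nN0: 10\nNf: 100"),
               "algorithm")
  expect_error(parse_mh_config(
    "algorithm: SA\npattern: '1100'\nN0: 10\nNf: 100\nalpha: 1.2"),
    "alpha")
  expect_error(parse_mh_config(
    "algorithm: SGA\npattern: '1100'\nN0: 10\nNf: 100\nm: 3"),
    "m must lie")
})

test_that("defaulted fields are recorded", {
  cfg <- parse_mh_config(baseline_text)
  expect_true("tau_gfp" %in% attr(cfg, "defaulted"))
  expect_true("T_div" %in% attr(cfg, "defaulted"))
  expect_false("m" %in% attr(cfg, "defaulted"))
  expect_equal(cfg$engine$tau_gfp, 12)
})

test_that("annealing skeletons declare the alpha-derived degradation rate", {
  cfg <- mh_config("SA", "1100", N0 = 200, Nf = 10000, alpha = 0.25)
  txt <- emit_skeleton(cfg)
  lam <- as.numeric(sub(".*lambda=([0-9.e-]+).*", "\\1",
                        grep("^signal atc", strsplit(txt, "\n")[[1]],
                             value = TRUE)))
  expect_equal(lam, log(4) / 20, tolerance = 1e-12)
  expect_match(txt, "program temperature")
})

test_that("emission is deterministic and parse inverts it field by field", {
  cfg <- mh_config("SGA", "10xxx", N0 = 100, Nf = 900, m = 0.02, c = 0.05,
                   seed = 7)
  expect_identical(emit_skeleton(cfg), emit_skeleton(cfg))
  back <- parse_skeleton(emit_skeleton(cfg))
  for (f in c("algorithm", "N0", "Nf", "m", "c", "detection", "seed")) {
    expect_identical(back[[f]], cfg[[f]], info = f)
  }
  expect_identical(unclass(back$pattern), unclass(cfg$pattern))
})

test_that("round-trip identity holds over many random configurations", {
  set.seed(18)
  for (i in 1:300) {
    alg <- sample(c("SGA", "SA"), 1)
    L <- sample(1:8, 1)
    N0 <- sample(2:500, 1)
    cfg <- mh_config(
      alg,
      paste(sample(c("1", "0", "x"), L, replace = TRUE), collapse = ""),
      N0 = N0, Nf = N0 + sample(1:20000, 1),
      m = round(stats::runif(1), 4), c = round(stats::runif(1), 4),
      alpha = round(stats::runif(1, 0.01, 0.99), 4),
      detection = sample(c("gfp", "genotype"), 1),
      engine = list(T_div = sample(5:40, 1), tau_gfp = sample(0:30, 1)),
      seed = sample(c(NA, 1:1000), 1)
    )
    if (is.na(cfg$seed)) cfg$seed <- NULL
    back <- parse_skeleton(emit_skeleton(cfg))
    for (f in c("algorithm", "N0", "Nf", "m", "c", "detection", "seed",
                "max_generations")) {
      expect_identical(back[[f]], cfg[[f]],
                       info = paste(f, emit_skeleton(cfg)))
    }
    expect_identical(unclass(back$pattern), unclass(cfg$pattern))
    expect_equal(back$engine$T_div, cfg$engine$T_div)
    expect_equal(back$engine$tau_gfp, cfg$engine$tau_gfp)
    if (alg == "SA") expect_equal(back$alpha, cfg$alpha, tolerance = 1e-12)
  }
})

test_that("every declared protein is referenced by the circuit or an operator", {
  cfg <- mh_config("SGA", "10x", N0 = 10, Nf = 50)
  lines <- strsplit(emit_skeleton(cfg), "\n")[[1]]
  declared <- sub("^plasmid (p[0-9]+) .*", "\\1",
                  grep("^plasmid", lines, value = TRUE))
  body <- paste(grep("^plasmid", lines, value = TRUE, invert = TRUE),
                collapse = " ")
  conjugative <- grepl("program conjugation", body)
  for (p in declared) {
    referenced <- grepl(paste0("\\b", p, "\\b"), body) || conjugative
    expect_true(referenced, info = p)
  }
})

test_that("sweep output has one row per grid point, seed and implementation", {
  sw <- run_sweep("T3", replicates = 2, seed0 = 1,
                  implementation = "classic")
  expect_equal(nrow(sw$runs), 4 * 2)
  expect_equal(nrow(sw$summary), 4)
  expect_true(all(sw$summary$n == 2))
  # grid values match the published mutation sweep
  expect_setequal(sw$summary$value, c("0", "0.01", "0.05", "0.1"))
  # summary means recomputed from the run rows
  for (v in sw$summary$value) {
    rows <- sw$runs[sw$runs$value == v & sw$runs$found, ]
    expect_equal(sw$summary$mean_found[sw$summary$value == v],
                 mean(rows$first_optimum), tolerance = 1e-12)
  }
  expect_error(run_sweep("T9", 1, 1), "unknown table_id")
  # annealing sweep grid: the published alpha values
  sw7 <- run_sweep("T7", replicates = 1, seed0 = 3,
                   implementation = "classic")
  expect_setequal(sw7$summary$value, c("0.25", "0.5", "0.75", "0.9"))
})

test_that("fixtures are reproducible, satisfiable and self-consistent", {
  f1 <- make_fixture(5, seed = 99)
  f2 <- make_fixture(5, seed = 99)
  expect_identical(f1$pattern, f2$pattern)
  expect_identical(f1$formula$clauses, f2$formula$clauses)
  expect_equal(pattern_length(f1$pattern), 5)
  expect_gte(count_optimal(f1$pattern), 1)
  # the encoded genotype realizes the clause truth values and satisfies
  # the constrained pattern positions
  tb <- formula_to_plasmids(f1$formula, f1$assignment)
  expect_equal(tb$genotype[1], f1$genotype)
  sym <- strsplit(unclass(f1$pattern), "")[[1]]
  bits <- strsplit(f1$genotype, "")[[1]]
  expect_true(all(bits[sym == "1"] == "1"))
  expect_true(all(bits[sym == "0"] == "0"))
  # different seeds give different fixtures (overwhelmingly)
  f3 <- make_fixture(8, seed = 100)
  f4 <- make_fixture(8, seed = 101)
  expect_false(identical(f3$pattern, f4$pattern) &&
                 identical(f3$assignment, f4$assignment))
})
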