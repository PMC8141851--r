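test_that("configuration validation enforces the parameter invariants", {
  expect_error(mh_config("SGA", "1100", N0 = 1, Nf = 100), "N0")
  expect_error(mh_config("SGA", "1100", N0 = 200, Nf = 200), "Nf")
  expect_error(mh_config("SGA", "1100", m = 1.5), "m must lie")
  expect_error(mh_config("SGA", "1100", c = -0.1), "c must lie")
  expect_error(mh_config("SA", "1100", alpha = 1.2), "alpha")
  expect_error(mh_config("SA", "1100", alpha = 0), "alpha")
  # SA defaults to pure conjugative perturbation (no mutation)
  expect_equal(mh_config("SA", "1100")$m, 0)
  expect_equal(mh_config("SGA", "1100")$m, 0.01)
})

test_that("colony founders follow the half-empty half-singleton rule", {
  set.seed(12)
  st <- init_colony(mh_config("SGA", "1100", N0 = 200, Nf = 1000))
  m <- st$geno
  expect_equal(sum(rowSums(m) == 0), 100)
  expect_equal(unname(colSums(m)), rep(25, 4))
  # dense disc: all founders within the close-packing radius bound
  rad <- sqrt(st$x^2 + st$y^2)
  expect_lt(max(rad), st$engine$r * sqrt(200) * 1.6)
})

test_that("the annealing bolus carries the configured aTc mass", {
  set.seed(13)
  cfg <- mh_config("SA", "1100", N0 = 100, Nf = 500,
                   sa = list(amount = 42, grid_n = 65))
  st <- init_colony(cfg)
  expect_equal(sf_mass(st$fields$atc), 42, tolerance = 1e-9)
  # degradation rate implements the per-generation cooling factor alpha
  f <- sf_run(st$fields$atc, st$engine$T_div)
  expect_equal(sf_mass(f) / 42, cfg$alpha, tolerance = 1e-6)
})

test_that("optimal founders report GFP one maturation delay after start", {
  res <- run_colony(mh_config("SGA", "10xxx", N0 = 50, Nf = 400), seed = 31)
  expect_true(res$found)
  expect_equal(res$first_optimum_generation, 12 / 20)
  # genotype-level detection sees the same founders immediately
  res0 <- run_colony(mh_config("SGA", "10xxx", N0 = 50, Nf = 400,
                               detection = "genotype"), seed = 31)
  expect_equal(res0$first_optimum_generation, 0)
})

test_that("frozen colonies stop at the final count without an optimum", {
  res <- run_colony(mh_config("SGA", "1100", N0 = 50, Nf = 400,
                              m = 0, c = 0), seed = 32)
  expect_false(res$found)
  # stop criterion honored within one division round
  expect_lt(res$final_n, 2 * 400)
  expect_gte(res$final_n, 400)
})

test_that("without aTc the annealing colony never conjugates", {
  cfg <- mh_config("SA", "1100", N0 = 60, Nf = 300, c = 1,
                   sa = list(amount = 0, grid_n = 65))
  res <- run_colony(cfg, seed = 33, stop_at_detection = FALSE)
  expect_equal(max(tidy(res)$conj_events), 0)
  expect_false(res$found)
})

test_that("edge cells feel less aTc than center cells as the colony grows", {
  set.seed(34)
  cfg <- mh_config("SA", "xxxx", N0 = 150, Nf = 1200)
  st <- init_colony(cfg)
  for (t in 1:40) {
    st <- grow_step(st, 1, m = 0)
    st$fields$atc <- sf_run(st$fields$atc, 1)
  }
  rad <- sqrt(st$x^2 + st$y^2)
  conc <- sf_sample(st$fields$atc, cbind(st$x, st$y))
  inner <- conc[rad < stats::quantile(rad, 0.2)]
  outer <- conc[rad > stats::quantile(rad, 0.8)]
  expect_gt(mean(inner), mean(outer))
})

test_that("annealing conjugation activity cools down over the run", {
  cfg <- mh_config("SA", "11111", N0 = 200, Nf = 3000, c = 0.5)
  res <- run_colony(cfg, seed = 35, stop_at_detection = FALSE)
  tr <- tidy(res)
  # per-cell conjugation hazard in the first generation vs afterwards
  gen1 <- max(tr$conj_events[tr$generation <= 1])
  later <- max(tr$conj_events) - gen1
  cells_gen1 <- mean(tr$n_cells[tr$generation <= 1])
  cells_later <- mean(tr$n_cells[tr$generation > 1])
  span_later <- max(tr$generation) - 1
  expect_gt(gen1 / cells_gen1, (later / cells_later) / span_later)
})

test_that("tidy and glance expose the run record", {
  res <- run_colony(mh_config("SGA", "10xxx", N0 = 20, Nf = 100), seed = 36)
  tr <- tidy(res)
  expect_true(all(c("generation", "n_cells", "n_optimal", "n_gfp")
                  %in% names(tr)))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$first_optimum_generation, res$first_optimum_generation)
  expect_equal(gl$pattern, "10xxx")
})

test_that("the saturating aTc response has the right limits", {
  expect_equal(atc_response(0, K = 1), 0)
  expect_equal(atc_response(1, K = 1), 0.5)
  expect_gt(atc_response(100, K = 1), 0.999)
  expect_true(all(diff(atc_response(seq(0, 5, 0.1), K = 1)) > 0))
})
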