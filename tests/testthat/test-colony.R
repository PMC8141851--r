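test_that("a deterministic clock doubles the colony every division time", {
  set.seed(1)
  st <- colony_state("0", "x",
                     engine = list(sd_div = 0, init_phase = "full"))
  expect_equal(length(st$x), 1L)
  for (t in 1:60) st <- grow_step(st, dt = 1, m = 0)
  expect_equal(length(st$x), 8L)   # 2^3 after three 20-min cycles
  expect_equal(colony_generation(st), 3)
})

test_that("growth reaches 10,000 cells from 200 in about six generations", {
  set.seed(42)
  st <- colony_state(init_population(200, 4)$genotype, "xxxx")
  while (length(st$x) < 10000) st <- grow_step(st, dt = 1, m = 0)
  g <- colony_generation(st)
  expect_gt(g, log2(10000 / 200) - 1.2)   # 5.64 +/- about one generation
  expect_lt(g, log2(10000 / 200) + 1.2)
})

test_that("effective division time matches the configured value", {
  set.seed(5)
  st <- colony_state(init_population(100, 2)$genotype, "xx")
  ns <- integer(0); ts <- numeric(0)
  for (t in 1:80) {
    st <- grow_step(st, dt = 1, m = 0)
    ns <- c(ns, length(st$x)); ts <- c(ts, st$time)
  }
  # discard the first generation: founder ages are uniform, so early growth
  # is linear before the age distribution settles
  keep <- ts > 20
  fit <- stats::lm(log(ns[keep]) ~ ts[keep])
  T_eff <- log(2) / stats::coef(fit)[2]
  expect_equal(unname(T_eff), 20, tolerance = 0.05)
})

test_that("relaxation keeps overlaps within tolerance and the colony centered", {
  set.seed(9)
  st <- colony_state(init_population(150, 2)$genotype, "xx")
  for (t in 1:40) {
    st <- grow_step(st, dt = 1, m = 0)
    expect_lte(colony_max_overlap(st), 0.05 * st$engine$r + 1e-9)
  }
  com <- c(mean(st$x), mean(st$y))
  expect_lt(sqrt(sum(com^2)), 2 * st$engine$r)
})

test_that("division mutation flips bits at the configured frequency", {
  set.seed(2)
  g <- matrix(0L, 20000, 5)
  m1 <- mutate_at_division(g, 0)
  expect_identical(m1, g)                      # m = 0: unchanged
  m2 <- mutate_at_division(g, 1)
  expect_true(all(m2 == 1L))                   # m = 1: every bit flipped
  m3 <- mutate_at_division(g, 0.05)
  expect_equal(mean(m3), 0.05, tolerance = 0.1)  # 1e5 draws, +/-10%
  # resample mode is a half-effective flip
  m4 <- mutate_at_division(g, 0.05, mode = "resample")
  expect_equal(mean(m4), 0.025, tolerance = 0.15)
})

test_that("conjugation copies plasmids at the configured per-generation rate", {
  set.seed(4)
  st <- colony_state(matrix(1L, 2000, 3), "xxx")
  for (t in 1:20) st <- conjugate_step(st, c = 0.1, dt = 1)
  # one generation at c = 0.1 in a dense all-donor colony
  rate <- st$conj_events / 2000
  expect_equal(rate, 0.1, tolerance = 0.1)
  # all-zero donors never transfer
  st0 <- colony_state(matrix(0L, 100, 3), "xxx")
  st0 <- conjugate_step(st0, c = 1, dt = 20)
  expect_equal(st0$conj_events, 0L)
  expect_true(all(st0$geno == 0L))
})

test_that("a transferred plasmid the recipient already has changes nothing", {
  set.seed(6)
  st <- colony_state(matrix(1L, 50, 2), "xx")
  before <- st$geno
  st <- conjugate_step(st, c = 1, dt = 20)
  expect_gt(st$conj_events, 0L)
  expect_identical(st$geno, before)
})

test_that("reporter maturation delays GFP by tau_gfp minutes", {
  set.seed(8)
  # optimal from t = 0 with tau = 12: first GFP at generation 12/20 = 0.6
  st <- colony_state("10", "10", engine = list(tau_gfp = 12))
  expect_false(any(st$gfp))
  t_on <- NA
  for (t in 1:20) {
    st <- grow_step(st, dt = 1, m = 0)
    st <- update_reporters(st, dt = 1)
    if (is.na(t_on) && any(st$gfp)) t_on <- st$time
  }
  expect_equal(t_on / 20, 0.6)
  # tau = 0: immediately on
  st0 <- colony_state("10", "10", engine = list(tau_gfp = 0))
  expect_true(all(st0$gfp))
  # never-optimal genotype: never on
  stn <- colony_state("01", "10", engine = list(tau_gfp = 0))
  for (t in 1:30) stn <- update_reporters(grow_step(stn, 1, m = 0), 1)
  expect_false(any(stn$gfp))
})

test_that("without mutation or conjugation no new genotype ever appears", {
  set.seed(10)
  st <- colony_state(init_population(60, 4)$genotype, "1100")
  seen0 <- unique(genotype_string(st$geno))
  for (t in 1:60) {
    st <- grow_step(st, dt = 1, m = 0)
    st <- conjugate_step(st, c = 0, dt = 1)
  }
  expect_true(all(unique(genotype_string(st$geno)) %in% seen0))
})
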