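test_that("canonical still lifes and oscillators behave on the grid", {
  block <- life_grid(c("....", ".OO.", ".OO.", "...."))
  expect_identical(unclass(life_step(block)), unclass(block))
  blinker <- life_grid(c(".....", ".....", ".OOO.", ".....", "....."))
  b1 <- life_step(blinker)
  expect_equal(sum(b1), 3)
  expect_false(identical(unclass(b1), unclass(blinker)))   # now vertical
  expect_identical(unclass(life_step(b1)), unclass(blinker))  # period 2
  empty <- life_grid(matrix(0L, 5, 5))
  expect_identical(unclass(life_step(empty)), unclass(empty))
})

test_that("a glider translates itself across the torus every four steps", {
  g0 <- matrix(0L, 20, 20)
  # glider heading down-right
  g0[cbind(c(1, 2, 3, 3, 3), c(2, 3, 1, 2, 3))] <- 1L
  g <- life_grid(g0)
  shift_by <- function(m, di, dj) {
    m[(seq_len(20) - 1L - di) %% 20 + 1L, (seq_len(20) - 1L - dj) %% 20 + 1L]
  }
  # find the per-cycle translation after the first 4 steps ...
  for (s in 1:4) g <- life_step(g)
  moves <- expand.grid(di = -1:1, dj = -1:1)
  hit <- which(vapply(seq_len(nrow(moves)), function(k) {
    identical(shift_by(g0, moves$di[k], moves$dj[k]), unclass(g))
  }, logical(1)))
  expect_length(hit, 1)
  di <- moves$di[hit]; dj <- moves$dj[hit]
  expect_false(di == 0 && dj == 0)   # it translates, not oscillates
  # ... and confirm the same translation every 4 steps, wrapping the torus
  for (cycle in 2:13) {   # 52 steps in total
    for (s in 1:4) g <- life_step(g)
    expect_identical(unclass(g), shift_by(g0, cycle * di, cycle * dj),
                     info = paste("cycle", cycle))
  }
})

test_that("grid updates agree exactly with a naive two-loop oracle", {
  set.seed(14)
  for (board in 1:100) {
    m <- matrix(rbinom(400, 1, 0.35), 20, 20)
    g <- life_grid(m)
    for (s in 1:50) {
      m <- naive_life_step(m)
      g <- life_step(g)
    }
    expect_identical(unclass(g), m, info = paste("board", board))
  }
})

test_that("the band rule kills under- and over-crowded cells", {
  expect_false(band_rule(0, 1, 2))            # under-crowding
  expect_true(band_rule(1.5, 1, 2))           # mid-level
  expect_false(band_rule(4, 1, 2))            # over-crowding
  expect_equal(band_rule(c(0.5, 1, 1.5, 2, 2.5), 1, 2),
               c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_error(band_rule(1, 2, 1), "c_high")
})

test_that("calibration derives the band from computed steady fields", {
  cfg <- calibrate_ca(ca_config())
  cal <- attr(cfg, "calibration")
  expect_equal(cfg$c_low, 2 * cal$per_neighbor)
  expect_equal(cfg$c_high, 4 * cal$per_neighbor)
  expect_true(cfg$c_low < cfg$c_high)
  # the calibration keeps an isolated cell below its own survival band:
  # its steady self-field is under the two-neighbor threshold
  f <- steady_point_source(
    signal_field(41, dx = cfg$dx, D = cfg$D, lambda = cfg$lambda),
    cfg$emission)
  expect_lt(sf_sample(f, c(0, 0)), cfg$c_low)
})

test_that("an unseeded colony with no ambient signal stays dead forever", {
  cfg <- ca_config(side = 8, seed_live = rep(FALSE, 64))
  run <- run_colony_ca(cfg, steps = 6)
  expect_true(all(vapply(run$frames, sum, numeric(1)) == 0))
})

test_that("a single isolated live cell dies once the bootstrap lapses", {
  m <- matrix(0L, 9, 9); m[5, 5] <- 1L
  run <- run_colony_ca(ca_config(side = 9, seed_live = m), steps = 8)
  live <- vapply(run$frames, sum, numeric(1))
  expect_equal(live[2], 1)          # clamped alive while aTc is high
  expect_equal(live[length(live)], 0)  # self-field below c_low: dies
})

test_that("an impossible band extinguishes the colony after bootstrap", {
  cfg <- ca_config(side = 8, seed_frac = 0.5, c_low = 1e6, c_high = 2e6)
  run <- run_colony_ca(cfg, steps = 8, seed = 15)
  live <- vapply(run$frames, sum, numeric(1))
  expect_gt(live[2], 0)             # bootstrap clamps the seeds on
  expect_equal(live[length(live)], 0)
})

test_that("emission far above the band causes mass extinction on update", {
  # every cell live and emitting, with a band far below the resulting field
  cfg <- ca_config(side = 8, seed_live = rep(TRUE, 64),
                   c_low = 1e-9, c_high = 2e-9, atc_amount = 50)
  run <- run_colony_ca(cfg, steps = 6, seed = 16)
  live <- vapply(run$frames, sum, numeric(1))
  boot_updates <- sum(50 * exp(-cfg$lambda * cfg$update_every *
                                 (0:5)) > cfg$atc_threshold)
  expect_equal(live[boot_updates + 2], 0)  # first unclamped update: all dead
})

test_that("pattern similarity is the Jaccard index of live sets", {
  a <- life_grid(c("OO..", "....", "..O.", "...."))
  expect_equal(compare_patterns(a, a), 1)
  b <- life_grid(c("..OO", "....", "....", "O..."))
  expect_equal(compare_patterns(a, b), 0)
  empty <- life_grid(matrix(0L, 4, 4))
  expect_equal(compare_patterns(empty, empty), 1)   # both empty: defined as 1
  expect_error(compare_patterns(a, life_grid(matrix(0L, 3, 3))), "dimensions")
})

test_that("colony frames rasterize onto the reference grid for comparison", {
  set.seed(17)
  m <- matrix(rbinom(100, 1, 0.3), 10, 10)
  run <- run_colony_ca(ca_config(side = 10, seed_live = m), steps = 4)
  # during bootstrap the colony shows exactly the seeded pattern
  expect_equal(compare_patterns(run, life_grid(m), frame = 2), 1)
  # matched-start comparison with grid Life: a similarity score in [0, 1],
  # reported, not asserted to be high (the neighborhoods differ by design)
  grid_frames <- run_life(life_grid(m), 4)
  scores <- vapply(seq_along(run$frames), function(i) {
    compare_patterns(run, grid_frames[[i]], frame = i)
  }, numeric(1))
  expect_true(all(scores >= 0 & scores <= 1))
})
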