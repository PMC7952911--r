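test_that("network construction follows the delay rule", {
  topo <- build_symmetry_network(8, 8, "manhattan", k = 1, base = 2)
  expect_equal(n_delay_lines(topo), 4096)
  expect_equal(max(topo$delays), 16)  # 14 px max Manhattan distance + base
  expect_true(all(topo$delays >= topo$base))
  # symmetric in grid positions when input and output grids coincide
  expect_equal(topo$delays, t(topo$delays))

  tiny <- build_symmetry_network(1, 1)
  expect_equal(n_delay_lines(tiny), 1)
  expect_equal(as.vector(tiny$delays), tiny$base)

  expect_error(build_symmetry_network(0, 4), class = "symspike_invalid_input")
})

test_that("latency is the longest line plus the accumulation stages", {
  topo <- build_symmetry_network(8, 8, "manhattan", k = 1, base = 2)
  expect_equal(latency(topo), 18)
  expect_equal(latency(build_symmetry_network(1, 1)), 4)
  # non-decreasing under grid enlargement
  for (s in 2:6) {
    expect_gte(latency(build_symmetry_network(s, s)),
               latency(build_symmetry_network(s - 1, s - 1)))
  }
})

test_that("the LIF update rule implements a one-cycle coincidence window", {
  topo <- build_symmetry_network(3, 1, "manhattan", k = 1, base = 2)
  st <- new_sim_state(topo, lif_params())

  # quiescent step: nothing changes but the cycle counter
  st1 <- step(st)
  expect_equal(st1$acc, c(0, 0, 0))
  expect_false(any(st1$fires))
  expect_equal(st1$cycle, 1L)

  # two pulses in the same cycle at theta = 1.5, leak = 0.5: fire and reset
  two <- data.frame(x = c(0, 2), y = c(0, 0))  # both at distance 1 from center
  st2 <- new_sim_state(topo, lif_params())
  st2 <- step(st2, two)           # pulses in flight (delay 1 + base 2 = 3)
  st2 <- step(st2); st2 <- step(st2)
  expect_equal(st2$arrivals[2], 2L)
  expect_true(st2$fires[2])
  expect_equal(st2$acc[2], 0)     # reset on fire

  # pulses two cycles apart never fire a pairwise detector
  topo2 <- build_symmetry_network(4, 1, "manhattan", k = 1, base = 2)
  pair <- data.frame(x = c(0, 3), y = c(0, 0))
  tr <- run_symmetry(pair, topo2)
  o <- 2L  # x = 1: distances 1 and 2, arrivals 2 cycles apart...
  # distances are 1 and 2 -> delays 3 and 4: one cycle apart; use x=0 (0 and 3)
  o0 <- 1L # distances 0 and 3 -> delays 2 and 5, three cycles apart
  expect_false(any(tr$fires[, o0]))
})

test_that("shift-register and countdown delay lines are observationally equal", {
  withr::local_seed(21)
  for (rep in 1:6) {
    w <- sample(3:7, 1); h <- sample(3:7, 1)
    metric <- sample(c("manhattan", "euclidean"), 1)
    topo <- build_symmetry_network(w, h, metric)
    pts <- random_points(sample(2:6, 1), w, h)
    a <- run_symmetry(pts, topo, representation = "countdown")
    b <- run_symmetry(pts, topo, representation = "shift_register")
    expect_identical(a$arrivals, b$arrivals)
    expect_equal(a$acc, b$acc)
    expect_identical(a$fires, b$fires)
  }
})

test_that("coincidence detection reproduces the distance-histogram density", {
  withr::local_seed(31)
  for (rep in 1:10) {
    w <- sample(4:12, 1); h <- sample(4:12, 1)
    metric <- sample(c("manhattan", "euclidean"), 1)
    topo <- build_symmetry_network(w, h, metric)
    pts <- random_points(sample(2:10, 1), w, h)
    snn_map <- detect_symmetry(run_symmetry(pts, topo))
    alg_map <- symmetry_density(pts, w, h,
                                density_config(metric = metric, decimals = 0))
    expect_equal(snn_map$value, alg_map$value, ignore_attr = TRUE)
  }
})

test_that("firing outputs for a two-point line are exactly the equidistant set", {
  topo <- build_symmetry_network(8, 8, "manhattan")
  withr::local_seed(41)
  for (rep in 1:10) {
    pts <- random_points(2, 8, 8)
    tr <- run_symmetry(pts, topo)
    fired <- fired_points(tr)
    eq <- brute_equidistant(c(pts$x[1], pts$y[1]), c(pts$x[2], pts$y[2]), 8, 8,
                            "manhattan")
    expect_setequal(paste(fired$x, fired$y), paste(eq$x, eq$y))
  }
})

test_that("a single active input never fires the output layer", {
  topo <- build_symmetry_network(6, 6)
  tr <- run_symmetry(data.frame(x = 2, y = 3), topo)
  expect_false(any(tr$fires))
  expect_true(all(detect_symmetry(tr)$value == 1))
})

test_that("spikes respect causality within the delay bounds", {
  topo <- build_symmetry_network(7, 7, "euclidean")
  pts <- data.frame(x = c(1, 5), y = c(3, 3))
  tr <- run_symmetry(pts, topo)
  arrive_cycles <- which(rowSums(tr$arrivals) > 0)
  expect_gte(min(arrive_cycles), min(topo$delays))
  expect_lte(max(arrive_cycles), max(topo$delays))
  fire_cycles <- which(apply(tr$fires, 1, any))
  expect_gte(min(fire_cycles), min(topo$delays))
})

test_that("an all-quiet trace detects an all-zero map", {
  topo <- build_symmetry_network(4, 4)
  tr <- run_symmetry(data.frame(x = integer(), y = integer()), topo)
  expect_true(all(detect_symmetry(tr)$value == 0))
})

test_that("delay noise is seeded, clamped at base, and absent at sd = 0", {
  topo <- build_symmetry_network(6, 6)
  expect_identical(add_delay_noise(topo, 0, seed = 3)$delays, topo$delays)
  n1 <- add_delay_noise(topo, 2, seed = 3)
  n2 <- add_delay_noise(topo, 2, seed = 3)
  n3 <- add_delay_noise(topo, 2, seed = 4)
  expect_identical(n1$delays, n2$delays)
  expect_false(identical(n1$delays, n3$delays))
  expect_true(all(n1$delays >= topo$base))
  expect_error(add_delay_noise(topo, -1), class = "symspike_invalid_input")
})

test_that("a too-short horizon is rejected", {
  topo <- build_symmetry_network(5, 5)
  expect_error(run_symmetry(data.frame(x = 0, y = 0), topo, cycles = 3),
               class = "symspike_insufficient_horizon")
})

test_that("trace event logs carry inject, arrive and fire events", {
  topo <- build_symmetry_network(5, 5)
  pts <- data.frame(x = c(1, 3), y = c(2, 2))
  tr <- run_symmetry(pts, topo)
  log <- tidy(tr)
  expect_setequal(unique(log$event), c("inject", "arrive", "fire"))
  expect_equal(sum(log$event == "inject"), 2)
  g <- glance(tr)
  expect_equal(g$max_coincidence, 2L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  expect_true(file.exists(path))
})
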