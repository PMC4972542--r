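test_that("the input sigmoid has the right midpoint, limits and ordering", {
  expect_equal(input_drive(500, mc_sigmoid()), 50)
  expect_equal(input_drive(350, tc_sigmoid()), 50)
  expect_equal(input_drive(1e7, tc_sigmoid()), 100)
  expect_equal(input_drive(-1e7, tc_sigmoid()), 0)
  # closed forms at 350: the tufted drive sits at its midpoint, the mitral
  # drive well below its own
  expect_equal(input_drive(350, mc_sigmoid()), 100 / (1 + exp(0.007 * 150)))
  expect_gt(input_drive(350, tc_sigmoid()), input_drive(350, mc_sigmoid()))
  x <- input_drive(seq(0, 1000, by = 50), tc_sigmoid())
  expect_true(all(diff(x) > 0))
})

test_that("inhibition terms implement the four models", {
  tc <- tc_adli(gi = 0.01)
  expect_equal(inhibition_term(10, 500, tc), 0.01 * 500)
  # Gaussian gate falls to ~1% of its center value 40 Hz away for the
  # tufted parameters
  ratio <- inhibition_term(50, 500, tc) / inhibition_term(10, 500, tc)
  expect_equal(ratio, exp(-(50 - 10)^2 / 350))
  expect_equal(inhibition_term(50, 0, tc), 0)
  sub <- inhibition_params("subtractive", gi = 0.02)
  expect_equal(inhibition_term(77, 100, sub), 2)
  expect_equal(inhibition_term(77, 0, sub), 0)
  div <- inhibition_params("divisive", gi = 0.1)
  expect_equal(inhibition_term(40, 9999, div), 4) # printed form ignores u
  div_uv <- inhibition_params("divisive", gi = 0.001, network_divisive = TRUE)
  expect_equal(inhibition_term(40, 100, div_uv), 4)
  none <- inhibition_params("none")
  expect_equal(inhibition_term(40, 100, none), 0)
})

test_that("a drive balancing the leak is a fixed point of the Euler step", {
  cfg <- bulb_config("none", n_glomeruli = 10, connectivity_seed = 1)
  v <- seq(5, 50, length.out = 10)
  drives <- cfg$dynamics$gl * (v - cfg$dynamics$El)
  out <- step_population(list(v = v), drives, cfg, dt = 0.2)
  expect_equal(out$v, v)
})

test_that("without inhibition the steady state is the closed-form balance", {
  cfg <- bulb_config("none", n_glomeruli = 12, connectivity_seed = 2)
  x <- seq(0, 1000, length.out = 12)
  res <- simulate_trials(x, cfg, tol = 1e-8)
  expect_true(res$converged)
  expected <- input_drive(x, common_sigmoid()) / cfg$dynamics$gl +
    cfg$dynamics$El
  expect_equal(drop(res$rates), expected, tolerance = 1e-6)
})

test_that("a two-unit subtractive network matches the linear-algebra oracle", {
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  cfg <- population_config(
    cell_type = c("G", "G"), glomerulus = 1:2,
    sigmoid = list(G = common_sigmoid()),
    inhibition = list(G = inhibition_params("subtractive", gi = 0.1)),
    connectivity = A
  )
  # steady state solves (I + gi * A) v = stim
  stim <- c(60, 40)
  intens <- common_sigmoid()$midpoint -
    log(100 / stim - 1) / common_sigmoid()$slope # invert the sigmoid
  oracle <- solve(diag(2) + 0.1 * A, stim)
  res <- simulate_trials(intens, cfg, tol = 1e-9)
  expect_equal(drop(res$rates), oracle, tolerance = 1e-6)
})

test_that("Euler relaxation agrees with a Newton oracle on a small ADLI net", {
  set.seed(99)
  n <- 8
  A <- matrix(as.numeric(matrix(runif(n * n), n) < 0.6), n)
  diag(A) <- 0
  cfg <- population_config(
    cell_type = rep("TC", n), glomerulus = 1:n,
    sigmoid = list(TC = tc_sigmoid()),
    inhibition = list(TC = tc_adli(gi = 0.02)),
    connectivity = A
  )
  intens <- seq(200, 900, length.out = n)
  res <- simulate_trials(intens, cfg, tol = 1e-10, max_steps = 20000)
  expect_true(res$converged)
  oracle <- newton_steady_state(
    input_drive(intens, tc_sigmoid()), cfg)
  expect_true(all(oracle > 0)) # interior fixed point, clipping inactive
  expect_lt(max(abs(drop(res$rates) - oracle)), 1e-6)
})

test_that("steady states do not depend on the initial condition", {
  cfg <- bulb_config("TC", connectivity_seed = 3)
  base <- make_base_odor(grid_spec(), 400, seed = 61)
  x <- sample_trials(derive_similar_odors(base, 2, seed = 62), c(1L, 2L),
                     seed = 63)
  a <- simulate_trials(x, cfg, tol = 1e-6, v0 = 0)
  b <- simulate_trials(x, cfg, tol = 1e-6, v0 = 100)
  expect_true(a$converged && b$converged)
  expect_lt(max(abs(a$rates - b$rates)), 10 * 1e-6)
})

test_that("rates stay within physical bounds during integration", {
  for (nm in c("TC", "MC", "none", "subtractive", "divisive")) {
    cfg <- bulb_config(nm, connectivity_seed = 4)
    x <- matrix(runif(150 * 20, 0, 1000), 150, 20)
    res <- simulate_trials(x, cfg)
    expect_true(all(res$rates >= 0))
    expect_true(all(res$rates <= 100 / cfg$dynamics$gl + abs(cfg$dynamics$El)))
  }
})

test_that("ADLI suppression is selective for rates near the gate center", {
  # sweep input intensity across units and compare inhibited vs uninhibited
  # steady states: the largest rate decrease must occur in the gate's band
  intens <- seq(0, 1000, length.out = 150)
  for (nm in c("TC", "MC")) {
    on <- bulb_config(nm, connectivity_seed = 5)
    off <- bulb_config(nm, inhibition_kind = "none", connectivity_seed = 5)
    v_on <- drop(simulate_trials(intens, on, tol = 1e-6)$rates)
    v_off <- drop(simulate_trials(intens, off, tol = 1e-6)$rates)
    drop_hz <- v_off - v_on
    center <- on$mu[1]
    v_at_max <- v_off[which.max(drop_hz)]
    expect_gt(max(drop_hz), 5)
    expect_gt(v_at_max, center - 10)
    expect_lt(v_at_max, center + 25)
    # far above the band the decrease is negligible
    expect_lt(max(drop_hz[v_off > center + 45]), 1.5)
  }
})

test_that("subtractive and divisive inhibition reduce rates at every level", {
  intens <- seq(50, 1000, length.out = 150)
  off <- bulb_config("none", connectivity_seed = 6)
  v_off <- drop(simulate_trials(intens, off, tol = 1e-6)$rates)
  for (nm in c("subtractive", "divisive")) {
    on <- bulb_config(nm, connectivity_seed = 6)
    v_on <- drop(simulate_trials(intens, on, tol = 1e-6)$rates)
    active <- v_off > 1
    expect_true(all(v_on[active] < v_off[active]))
  }
})

test_that("connectivity honors fractions, self-exclusion and determinism", {
  A <- make_connectivity(rep("MC", 200), 1:200, c(MC = 0.75), seed = 7)
  expect_true(all(diag(A) == 0))
  in_deg <- rowSums(A)
  expect_lt(abs(mean(in_deg) - 0.75 * 199), 3 * sqrt(199 * 0.75 * 0.25 / 200))
  expect_identical(A, make_connectivity(rep("MC", 200), 1:200, c(MC = 0.75),
                                        seed = 7))
})

test_that("dual-output configurations enforce the wiring constraints", {
  for (nm in c("MC-MC", "TC-TC", "MC-TC")) {
    cfg <- bulb_config(nm, n_glomeruli = 50, connectivity_seed = 8)
    expect_identical(cfg$n_units, 100L)
    A <- cfg$adjacency
    # sister units on one glomerulus never inhibit one another
    for (g in 1:50) {
      pair <- which(cfg$glomerulus == g)
      expect_equal(A[pair[1], pair[2]], 0)
      expect_equal(A[pair[2], pair[1]], 0)
    }
    # inhibition stays segregated by cell type
    cross <- outer(cfg$cell_type, cfg$cell_type, `!=`)
    expect_true(all(A[cross] == 0))
    if (nm == "MC-TC") expect_true(any(cross))
  }
})

test_that("calibrated gains put the gate-center inhibition in the 10-20 Hz band", {
  base <- make_base_odor(grid_spec(), 500, seed = 71)
  x <- sample_trials(derive_similar_odors(base, 4, seed = 72),
                     rep(1:4, each = 25), seed = 73)
  for (nm in c("TC", "MC")) {
    cfg <- bulb_config(nm, connectivity_seed = 9)
    sim <- simulate_trials(x, cfg)
    u <- cfg$adjacency %*% sim$rates
    center_inhib <- mean(cfg$gi[1] * u)
    expect_gt(center_inhib, 10)
    expect_lt(center_inhib, 20)
  }
})
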