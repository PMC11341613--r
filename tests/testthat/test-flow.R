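test_that("strain invariant vanishes for rigid motions and matches simple shear", {
  m <- build_mesh(channel_case(h = 5e-4))
  # rigid translation
  J2 <- strain_invariant(rep(0.3, m$n_cells), rep(-0.1, m$n_cells), m)
  expect_lt(max(abs(J2)), 1e-20)
  # rigid rotation u = (-w y, w x): antisymmetric gradient
  w <- 3
  J2r <- strain_invariant(-w * m$cc_y, w * m$cc_x, m,
                          bu = -w * m$bcy, bv = w * m$bcx)
  expect_lt(max(abs(J2r)), 1e-18)
  # simple shear u = (gd * y, 0), gd = 2 -> J2 = 1 in interior cells
  gd <- 2
  J2s <- strain_invariant(gd * m$cc_y, numeric(m$n_cells), m,
                          bu = gd * m$bcy, bv = numeric(length(m$bo)))
  interior <- !(seq_len(m$n_cells) %in% m$bo)
  expect_lt(max(abs(J2s[interior] - 1)), 1e-6)
})

test_that("rest is a fixed point under zero inflow", {
  m <- build_mesh(toy_case())
  solver <- flow_solver(m, solver_config())
  st <- flow_state_rest(m)
  bc <- boundary_velocity(m, 0.1, 1) # closed phase: Q = 0
  expect_equal(bc$Q, 0)
  for (i in 1:3) st <- advance_flow(st, solver, rheology_params(), bc, 0.01)
  expect_equal(max(abs(st$u), abs(st$v)), 0)
  expect_equal(max(abs(st$p)), 0)
})

test_that("every accepted step is divergence-free and mass-balanced", {
  cfg <- toy_case()
  m <- build_mesh(cfg)
  solver <- flow_solver(m, solver_config())
  st <- flow_state_rest(m)
  rh <- rheology_params()
  # step through the valve opening, where the flow is strongest
  for (t in seq(0.45, 0.6, by = 0.01)) {
    st <- advance_flow(st, solver, rh, boundary_velocity(m, t, 1.3), 0.01)
    expect_lt(st$div_max, solver$config$div_tol)
    imbalance <- abs(sum(st$phi_b))
    expect_lt(imbalance, 1e-12 * max(abs(st$phi_b)))
  }
  expect_gt(max(abs(st$u), abs(st$v)), 0)
})

test_that("snapshot schedule yields round(T / dt) snapshots per cycle", {
  cfg <- case_config(period = 1.07, dt_max = 0.01)
  expect_equal(round(cfg$period / cfg$dt_max), 107)
  # exercised end-to-end on a coarse schedule
  cfg2 <- toy_case(n_cycles = 1)
  series <- run_cycles(cfg2, rheology_params(),
                       solver_config(dt_snap = 1.07 / 10), f = 1)
  expect_equal(ncol(series$U), 10)
  expect_equal(series$times, 1.07 / 10 * (1:10))
})

test_that("final-cycle periodicity residual shrinks with more cycles", {
  cfg1 <- toy_case(n_cycles = 1)
  cfg3 <- toy_case(n_cycles = 3)
  scfg <- solver_config(dt_snap = 1.07 / 10)
  ke <- function(s) colSums(s$U^2 + s$V^2)
  # drift: kinetic-energy gap between cycle start and end
  drift <- function(cfg) {
    s <- run_cycles(cfg, rheology_params(), scfg, f = 1)
    k <- ke(s)
    abs(k[length(k)] - k[1]) / max(k)
  }
  expect_lt(drift(cfg3), drift(cfg1))
})

test_that("velocity error converges at second order on the channel fixture", {
  poise_err <- function(h) {
    cfg <- channel_case(length = 0.02, height = 0.01, h = h)
    m <- build_mesh(cfg)
    H <- 0.01; ub <- 0.003
    uex <- function(y) 6 * ub * (y / H) * (1 - y / H)
    bu <- ifelse(m$bpatch == "inlet1", uex(m$bcy),
                 ifelse(m$bpatch == "outlet", NA, 0))
    bv <- ifelse(m$bpatch == "outlet", NA_real_, 0)
    st <- run_steady(m, rheology_params("newtonian"), list(u = bu, v = bv),
                     dt = 0.05, max_steps = 600, tol = 1e-9)
    sel <- m$cc_x > 0.005 & m$cc_x < 0.018
    sqrt(mean((st$u[sel] - uex(m$cc_y[sel]))^2)) / (1.5 * ub)
  }
  ratio <- poise_err(1e-3) / poise_err(5e-4)
  expect_gt(ratio, 3) # ~4 expected for a second-order scheme
})
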