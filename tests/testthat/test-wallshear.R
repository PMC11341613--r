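test_that("wall shear stress vanishes with the velocity and respects rheology consistency", {
  m <- build_mesh(toy_case())
  rh <- rheology_params("newtonian")
  ws0 <- wall_shear_stress(numeric(m$n_cells), numeric(m$n_cells), m, rh)
  expect_equal(max(abs(ws0)), 0)
  # Casson at H = 0 equals Newtonian with mu = eta
  u <- sin(m$cc_x / 0.02 * pi) * 0.01
  v <- cos(m$cc_y / 0.01 * pi) * 0.005
  wsN <- wall_shear_stress(u, v, m, rheology_params("newtonian",
                                                    mu_const = 2e-3))
  wsC <- wall_shear_stress(u, v, m, rheology_params("casson", eta = 2e-3,
                                                    H = 0))
  expect_equal(wsC, wsN, tolerance = 1e-12)
})

test_that("quadratic wall gradient is exact for an analytic parabolic profile", {
  cfg <- channel_case(length = 0.02, height = 0.01, h = 5e-4)
  m <- build_mesh(cfg)
  H <- 0.01; ub <- 0.003
  u <- 6 * ub * (m$cc_y / H) * (1 - m$cc_y / H)
  rh <- rheology_params("newtonian")
  ws <- wall_shear_stress(u, numeric(m$n_cells), m, rh,
                          gradient = "quadratic")
  w <- which(m$bpatch == "wall")
  horiz <- abs(m$bny[w]) == 1
  tau <- sqrt(ws[horiz, 1]^2 + ws[horiz, 2]^2)
  expect_equal(tau, rep(6 * rh$mu_const * ub / H, sum(horiz)),
               tolerance = 1e-10)
})

test_that("TAWSS reproduces hand-quadrature values and homogeneity", {
  # two equal sub-intervals, magnitudes 1 Pa then 3 Pa -> mean 2 Pa
  times <- seq(0.125, 0.875, by = 0.25) # midpoints of 4 equal slabs
  x <- matrix(c(1, 1, 3, 3), 1)
  y <- matrix(0, 1, 4)
  s <- wall_stress_series(x, y, times)
  expect_equal(tawss(s, method = "midpoint")$value, 2)
  # constant magnitude c -> TAWSS = c under either rule
  sc <- wall_stress_series(matrix(1.7, 1, 9), matrix(0, 1, 9),
                           seq(0.1, 0.9, by = 0.1))
  expect_equal(tawss(sc)$value, 1.7)
  expect_equal(tawss(sc, method = "midpoint")$value, 1.7)
  # homogeneity: scaling WSS by lambda scales TAWSS, leaves OSI unchanged
  set.seed(7)
  X <- matrix(rnorm(5 * 21), 5); Y <- matrix(rnorm(5 * 21), 5)
  tt <- seq(0.05, 1.05, by = 0.05)
  s1 <- wall_stress_series(X, Y, tt)
  s2 <- wall_stress_series(3.7 * X, 3.7 * Y, tt)
  expect_equal(tawss(s2)$value, 3.7 * tawss(s1)$value, tolerance = 1e-12)
  expect_equal(osi(s2)$value, osi(s1)$value, tolerance = 1e-12)
})

test_that("OSI spans its analytic limits and stays within [0, 0.5]", {
  times <- seq(0.05, 0.95, by = 0.1) # 10 midpoint samples, unit period
  # constant direction, arbitrary positive magnitudes -> OSI = 0
  mag <- c(0.2, 1.1, 0.5, 2, 3, 0.1, 0.9, 1.4, 0.6, 0.3)
  dir <- c(0.6, 0.8)
  s_uni <- wall_stress_series(matrix(mag * dir[1], 1),
                              matrix(mag * dir[2], 1), times)
  expect_equal(osi(s_uni, method = "midpoint")$value, 0)
  # +s then -s over equal halves -> OSI = 0.5
  sgn <- rep(c(1, -1), each = 5)
  s_rev <- wall_stress_series(matrix(2.3 * sgn, 1), matrix(-1.1 * sgn, 1),
                              times)
  expect_equal(osi(s_rev, method = "midpoint")$value, 0.5)
  # identically zero shear -> defined as 0
  s0 <- wall_stress_series(matrix(0, 1, 10), matrix(0, 1, 10), times)
  expect_equal(osi(s0)$value, 0)
  # random series stay in [0, 0.5]
  set.seed(11)
  for (i in 1:20) {
    s <- wall_stress_series(matrix(rnorm(15), 1), matrix(rnorm(15), 1),
                            seq_len(15) / 15)
    expect_gte(osi(s)$value, 0)
    expect_lte(osi(s)$value, 0.5)
  }
})

test_that("trapezoidal indices agree with dense brute-force quadrature", {
  # analytic rotating WSS with drift, densely sampled
  tt <- seq(0, 1.07, length.out = 20001)
  X <- rbind(0.5 + cos(2 * pi * tt / 1.07))
  Y <- rbind(sin(2 * pi * tt / 1.07) * 0.8)
  s <- wall_stress_series(X, Y, tt)
  # independent brute-force trapezoid
  trap <- function(f) sum(diff(tt) * (utils::head(f, -1) + f[-1]) / 2)
  mag <- sqrt(X[1, ]^2 + Y[1, ]^2)
  tawss_bf <- trap(mag) / (max(tt) - min(tt))
  osi_bf <- 0.5 * (1 - sqrt(trap(X[1, ])^2 + trap(Y[1, ])^2) / trap(mag))
  expect_equal(tawss(s)$value, tawss_bf, tolerance = 1e-10)
  expect_equal(osi(s)$value, osi_bf, tolerance = 1e-10)
})

test_that("channel wall shear matches the Poiseuille closed form", {
  cfg <- channel_case(length = 0.03, height = 0.01, h = 5e-4)
  m <- build_mesh(cfg)
  rh <- rheology_params("newtonian")
  ub <- 0.003
  bc <- list(u = ifelse(m$bpatch == "inlet1", ub,
                        ifelse(m$bpatch == "outlet", NA, 0)),
             v = ifelse(m$bpatch == "outlet", NA_real_, 0))
  st <- run_steady(m, rh, bc, dt = 0.05, max_steps = 400, tol = 1e-7)
  ws <- wall_shear_stress(st$u, st$v, m, rh)
  w <- which(m$bpatch == "wall")
  sel <- m$bcx[w] > 0.015 & m$bcx[w] < 0.028 # fully developed region
  tau <- sqrt(ws[sel, 1]^2 + ws[sel, 2]^2)
  expect_lt(max(abs(tau - 6 * rh$mu_const * ub / 0.01)) /
              (6 * rh$mu_const * ub / 0.01), 0.03)
})
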