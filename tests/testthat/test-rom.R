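test_that("uniform design covers the closed range with equal spacing", {
  d <- sample_uniform(0.5, 1.5, 20)
  expect_equal(nrow(d), 20)
  expect_equal(d$f[1], 0.5)
  expect_equal(d$f[20], 1.5)
  expect_equal(unique(round(diff(d$f), 12)), round(1 / 19, 12))
  expect_equal(sample_uniform(0.5, 1.5, 2)$f, c(0.5, 1.5))
  expect_true(all(d$f >= 0.5 & d$f <= 1.5))
  expect_error(sample_uniform(0, 1, 1), "n >= 2")
})

test_that("Latin hypercube design is stratified and seed-deterministic", {
  rng <- list(f = c(0.5, 1.5), eta = c(1.5e-3, 1.7e-3), H = c(35, 50))
  d <- sample_lhs(rng, 30, seed = 4)
  expect_equal(dim(d), c(30L, 3L))
  for (k in names(rng)) {
    lo <- rng[[k]][1]; hi <- rng[[k]][2]
    expect_true(all(d[[k]] >= lo & d[[k]] <= hi))
    # exactly one point per equal-probability stratum
    strata <- floor((d[[k]] - lo) / (hi - lo) * 30)
    expect_setequal(pmin(strata, 29), 0:29)
  }
  expect_identical(sample_lhs(rng, 30, seed = 4), d)
  expect_false(identical(sample_lhs(rng, 30, seed = 5), d))
})

test_that("snapshot assembly orders columns parameter-outer, time-inner", {
  times <- (1:4) / 10
  samples <- sample_uniform(0.5, 1.5, 3)
  fields <- lapply(1:3, function(j) matrix(j * 100 + rep(1:4, each = 2),
                                           2, 4, byrow = FALSE))
  S <- assemble_snapshots(fields, samples, times, tag = "m1")
  expect_equal(ncol(S$S), 12)
  # column (j, i) equals the stored field of sample j at time i
  for (j in 1:3) for (i in 1:4) {
    expect_identical(S$S[, (j - 1) * 4 + i], fields[[j]][, i])
  }
  # steady variables: one column per sample
  Ss <- assemble_snapshots(lapply(1:3, function(j) c(j, j)), samples,
                           times = NULL, tag = "TAWSS")
  expect_equal(dim(Ss$S), c(2L, 3L))
  # ragged input names the offending sample
  bad <- fields; bad[[2]] <- bad[[2]][, 1:3]
  expect_error(assemble_snapshots(bad, samples, times), "sample 2")
  nf <- fields; nf[[3]][1, 1] <- NaN
  expect_error(assemble_snapshots(nf, samples, times), "sample 3")
})

test_that("POD satisfies orthonormality, the energy criterion and Eckart-Young", {
  set.seed(21)
  S <- matrix(rnorm(120 * 40), 120) %*% diag(2^seq(3, -16.5, by = -0.5))
  for (eps in c(0.90, 0.99, 0.9999)) {
    b <- pod(S, eps)
    expect_lt(max(abs(crossprod(b$modes) - diag(b$L))), 1e-10)
    # smallest L meeting the threshold
    expect_gte(b$energy[b$L], eps)
    if (b$L > 1) expect_lt(b$energy[b$L - 1], eps)
    # Eckart-Young: training reconstruction error^2 = sum of trailing sv^2
    recon <- b$modes %*% project_coefficients(S, b)
    tail2 <- sqrt(sum(b$sv[seq_len(b$rank) > b$L]^2))
    expect_equal(norm(S - recon, "F"), tail2, tolerance = 1e-8)
  }
  # rank-1 matrix: one mode, exact reconstruction at any eps
  S1 <- outer(1:50, seq(0.1, 1, by = 0.1))
  b1 <- pod(S1, 0.5)
  expect_equal(b1$L, 1L)
  expect_lt(norm(S1 - b1$modes %*% project_coefficients(S1, b1), "F"),
            1e-10)
  expect_error(pod(matrix(0, 5, 3)), "zero")
})

test_that("projection is optimal and respects orthonormal coordinates", {
  set.seed(22)
  S <- matrix(rnorm(60 * 15), 60)
  b <- pod(S, 0.9)
  a <- project_coefficients(S, b)
  base_err <- norm(S - b$modes %*% a, "F")
  for (i in 1:10) {
    beta <- a + matrix(rnorm(length(a), sd = 0.05), nrow(a))
    expect_gte(norm(S - b$modes %*% beta, "F"), base_err)
  }
  # a snapshot equal to c * mode_1 has coefficients (c, 0, ..., 0)
  a1 <- project_coefficients(3.3 * b$modes[, 1, drop = FALSE], b)
  expect_equal(as.numeric(a1), c(3.3, rep(0, b$L - 1)), tolerance = 1e-12)
  expect_equal(as.numeric(project_coefficients(matrix(0, 60, 1), b)),
               rep(0, b$L))
  expect_error(project_coefficients(matrix(1, 10, 2), b), "mismatch")
})

test_that("constrained RBF interpolates exactly and absorbs linear data", {
  set.seed(23)
  x <- cbind(runif(25), runif(25, 1, 2), runif(25, 10, 50))
  y <- cbind(sin(x[, 1] * 3) + x[, 2], cos(x[, 3] / 10))
  for (kern in c("tps", "gaussian", "multiquadric")) {
    mod <- fit_rbf(x, y, kernel = kern, shape = 2)
    pred <- predict(mod, x)
    expect_lt(max(abs(pred - y)) / max(abs(y)), 1e-8)
    expect_lt(abs(sum(mod$w[, 1])), 1e-8)
    expect_lt(max(abs(crossprod(mod$nodes, mod$w))), 1e-8)
  }
  # exactly linear data: polynomial tail takes it all, weights ~ 0
  ylin <- cbind(2 + 3 * x[, 1] - 0.5 * x[, 2] + 0.01 * x[, 3])
  modl <- fit_rbf(x, ylin)
  expect_lt(max(abs(modl$w)), 1e-8)
  # interior queries (inside the training box, so no extrapolation)
  qs <- seq(0.2, 0.8, length.out = 7)
  xq <- cbind(quantile(x[, 1], qs), quantile(x[, 2], qs),
              quantile(x[, 3], qs))
  expect_equal(as.numeric(predict(modl, xq)),
               unname(2 + 3 * xq[, 1] - 0.5 * xq[, 2] + 0.01 * xq[, 3]),
               tolerance = 1e-8)
  # duplicate nodes rejected; too few nodes rejected
  expect_error(fit_rbf(x[c(1, 1, 2, 3, 4), ], y[1:5, , drop = FALSE]),
               "duplicate")
  expect_error(fit_rbf(x[1:3, ], y[1:3, , drop = FALSE]), "nodes")
  expect_warning(predict(modl, cbind(5, 5, 500)), "extrapolating")
})

test_that("ROM prediction reproduces projections and full-rank snapshots", {
  set.seed(24)
  times <- (1:12) / 12
  samples <- sample_uniform(0.5, 1.5, 5)
  fields <- manufactured_snapshots(80, times, samples, period = 1,
                                   tail = FALSE)
  S <- assemble_snapshots(fields, samples, times)
  nodes <- unsteady_nodes(samples["f"], times)
  # truncated basis: training query returns the POD projection
  b <- pod(S, 0.95)
  a <- project_coefficients(S, b)
  mod <- fit_rbf(nodes, t(a))
  pred <- rom_predict(b, mod, nodes[13, , drop = FALSE]) # sample 2, t 1
  proj <- b$modes %*% a[, 13]
  expect_equal(as.numeric(pred), as.numeric(proj), tolerance = 1e-8)
  # full basis: training query returns the original snapshot
  bf <- pod(S, 1)
  af <- project_coefficients(S, bf)
  modf <- fit_rbf(nodes, t(af))
  predf <- rom_predict(bf, modf, nodes[13, , drop = FALSE])
  expect_equal(as.numeric(predf), S$S[, 13],
               tolerance = 1e-8 * max(abs(S$S)))
  expect_error(rom_predict(b, modf, nodes[1, , drop = FALSE]), "mismatch")
})

test_that("relative error matches hand-computed Frobenius ratios", {
  expect_equal(relative_error(cbind(c(1, 2)), cbind(c(1, 2)))$error, 0)
  expect_equal(relative_error(cbind(c(3, 4)), cbind(c(0, 0)))$error, 1)
  expect_equal(relative_error(cbind(c(3, 4)), cbind(c(3, 0)))$error, 4 / 5)
  r <- relative_error(matrix(1:6, 2), matrix(0, 2, 3), times = (1:3) / 10)
  expect_equal(r$error, rep(1, 3))
  expect_equal(attr(r, "mean"), 1)
  expect_error(relative_error(cbind(c(0, 0)), cbind(c(1, 0))), "zero-norm")
  expect_error(relative_error(matrix(1, 2, 2), matrix(1, 3, 2)), "shapes")
})

test_that("held-out error shrinks as the training design is refined", {
  times <- seq(0.01, 1.07, by = 0.02)
  te <- tibble::tibble(f = 0.9, eta = 1.62e-3, H = 42)
  err_for <- function(n) {
    tr <- casson_design(n, seed = 11)
    S <- assemble_snapshots(manufactured_snapshots(120, times, tr,
                                                   tail = FALSE),
                            tr, times)
    b <- pod(S, 0.9999)
    mod <- fit_rbf(unsteady_nodes(tr, times),
                   t(project_coefficients(S, b)))
    truth <- manufactured_snapshots(120, times, te, tail = FALSE)[[1]]
    pred <- rom_predict(b, mod,
                        cbind(t = times, f = te$f, eta = te$eta, H = te$H))
    attr(relative_error(truth, pred, times), "mean")
  }
  e_coarse <- err_for(8)
  e_fine <- err_for(16)
  expect_lt(e_fine, 0.5 * e_coarse)
})

test_that("energy sweep grows L monotonically while the error plateaus", {
  times <- seq(0.01, 1.07, by = 0.02)
  tr <- casson_design(8, seed = 11)
  te <- tibble::tibble(f = 0.9, eta = 1.62e-3, H = 42)
  S <- assemble_snapshots(manufactured_snapshots(120, times, tr), tr, times)
  truth <- manufactured_snapshots(120, times, te)[[1]]
  sw <- mode_energy_sweep(S, unsteady_nodes(tr, times),
                          cbind(t = times, f = te$f, eta = te$eta,
                                H = te$H), truth)
  expect_equal(sw$eps, c(0.90, 0.95, 0.99, 0.999))
  expect_true(all(diff(sw$L) >= 0))
  expect_gt(sw$L[4], sw$L[1])
  expect_true(all(diff(sw$train_error) <= 1e-12))
  # held-out error saturates at high threshold instead of tracking L
  expect_lt(abs(sw$test_error[4] - sw$test_error[3]),
            0.5 * (sw$test_error[1] - sw$test_error[3]) + 1e-9)
})
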