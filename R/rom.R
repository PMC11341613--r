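#' Uniform parameter design
#'
#' `n` equispaced points covering a closed range, endpoints included -- the
#' design used for the single-parameter (cardiac-output scaling) case.
#'
#' @param lower,upper Range bounds.
#' @param n Number of points (>= 2).
#' @param name Column name for the parameter.
#' @return A tibble with one column of `n` design points.
#' @export
sample_uniform <- function(lower, upper, n, name = "f") {
  if (n < 2) stop("uniform design needs n >= 2", call. = FALSE)
  out <- tibble::tibble(seq(lower, upper, length.out = n))
  names(out) <- name
  out
}

#' Latin hypercube parameter design
#'
#' One point per equal-probability stratum in every coordinate, scaled to the
#' requested ranges -- the design used for the three-parameter
#' (scaling factor, plasma viscosity, hematocrit) case.
#'
#' @param ranges Named list of `c(lower, upper)` ranges.
#' @param n Number of points.
#' @param seed Integer seed fixing the design.
#' @return A tibble with `n` rows and one column per range.
#' @export
sample_lhs <- function(ranges, n, seed = 1L) {
  stopifnot(n >= 1, length(ranges) >= 1)
  d <- length(ranges)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  u <- lhs::randomLHS(n, d)
  out <- lapply(seq_len(d), function(k) {
    r <- ranges[[k]]
    r[1] + u[, k] * (r[2] - r[1])
  })
  names(out) <- names(ranges)
  tibble::as_tibble(out)
}

#' Assemble fields into a snapshot matrix
#'
#' Time-dependent variables: one column per (parameter, time) pair, ordered
#' parameter-outer / time-inner. Steady variables (TAWSS, OSI): one column
#' per parameter point.
#'
#' @param fields A list, one entry per design point: an `N_h x N_t` matrix
#'   (time-dependent) or a length-`N_h` vector (steady).
#' @param samples Tibble of design points (one row per entry of `fields`).
#' @param times Snapshot times for time-dependent variables; `NULL` for
#'   steady ones.
#' @param tag Variable tag (e.g. `"m1"`, `"washout"`, `"TAWSS"`).
#' @return An object of class `snapshot_matrix`.
#' @export
assemble_snapshots <- function(fields, samples, times = NULL, tag = "field") {
  stopifnot(length(fields) == nrow(samples))
  steady <- is.null(times)
  fields <- lapply(fields, function(f) if (steady) cbind(f) else f)
  nh <- nrow(fields[[1]])
  ntime <- if (steady) 1L else length(times)
  for (j in seq_along(fields)) {
    f <- fields[[j]]
    if (nrow(f) != nh || ncol(f) != ntime) {
      stop(sprintf("ragged snapshot input at sample %d: got %d x %d, expected %d x %d",
                   j, nrow(f), ncol(f), nh, ntime), call. = FALSE)
    }
    if (any(!is.finite(f))) {
      stop(sprintf("non-finite snapshot values at sample %d", j),
           call. = FALSE)
    }
  }
  S <- do.call(cbind, fields)
  structure(list(S = S, tag = tag, times = times, samples = samples,
                 n_h = nh, n_t = if (steady) NA_integer_ else ntime,
                 n_p = nrow(samples), steady = steady),
            class = "snapshot_matrix")
}

#' @export
print.snapshot_matrix <- function(x, ...) {
  cat(sprintf("<snapshot_matrix> %s: %d cells x %d columns (%s, N_p = %d)\n",
              x$tag, x$n_h, ncol(x$S),
              if (x$steady) "steady" else sprintf("N_t = %d", x$n_t), x$n_p))
  invisible(x)
}

#' Proper orthogonal decomposition of a snapshot matrix
#'
#' Thin SVD of the raw snapshot matrix (no mean subtraction). The retained
#' dimension `L` is the smallest integer whose cumulative squared singular
#' values reach the energy threshold `eps`.
#'
#' @param S A `snapshot_matrix` or plain matrix.
#' @param eps Cumulative energy threshold in (0, 1]; default 0.99.
#' @return An object of class `pod_basis`: orthonormal `modes`
#'   (`N_h x L`), all nonzero singular values `sv`, numerical rank `R`,
#'   threshold `eps`, retained count `L`.
#' @export
pod <- function(S, eps = 0.99) {
  stopifnot(eps > 0, eps <= 1)
  M <- if (inherits(S, "snapshot_matrix")) S$S else as.matrix(S)
  if (length(M) == 0) stop("empty snapshot matrix", call. = FALSE)
  sv <- svd(M)
  tol <- max(dim(M)) * .Machine$double.eps * sv$d[1]
  R <- sum(sv$d > tol)
  if (R == 0) stop("snapshot matrix is identically zero: no basis",
                   call. = FALSE)
  d <- sv$d[seq_len(R)]
  energy <- cumsum(d^2) / sum(d^2)
  L <- which(energy >= eps)[1]
  structure(list(modes = sv$u[, seq_len(L), drop = FALSE],
                 sv = d, rank = R, eps = eps, L = L, energy = energy),
            class = "pod_basis")
}

#' @export
print.pod_basis <- function(x, ...) {
  cat(sprintf("<pod_basis> L = %d of rank %d (eps = %g, captured %.6f)\n",
              x$L, x$rank, x$eps, x$energy[x$L]))
  invisible(x)
}

#' Project snapshots onto a POD basis
#'
#' Modal coefficients `alpha = B^T S`; the reconstruction `B alpha` is the
#' orthogonal projection of the snapshots onto the reduced space.
#'
#' @param S A `snapshot_matrix` or matrix.
#' @param basis A [pod()] result.
#' @return `L x N_s` coefficient matrix.
#' @export
project_coefficients <- function(S, basis) {
  M <- if (inherits(S, "snapshot_matrix")) S$S else as.matrix(S)
  if (nrow(M) != nrow(basis$modes)) {
    stop("snapshot/basis shape mismatch: ", nrow(M), " vs ",
         nrow(basis$modes), " cells", call. = FALSE)
  }
  crossprod(basis$modes, M)
}

rbf_kernel <- function(kernel, shape) {
  switch(kernel,
    tps = function(r) ifelse(r > 0, r^2 * log(r), 0),
    gaussian = function(r) exp(-(shape * r)^2),
    multiquadric = function(r) sqrt(1 + (shape * r)^2),
    stop("unknown RBF kernel: ", kernel, call. = FALSE))
}

#' Fit a constrained RBF interpolant of modal coefficients
#'
#' `F(x) = sum_j w_j psi(||x - x_j||) + P(x)` with a degree-1 polynomial tail
#' `P`, subject to exact interpolation at the nodes and the moment conditions
#' `sum_j w_j = 0`, `sum_j w_j x_j = 0`, which determine `w` and `P`
#' uniquely. Node coordinates are affinely normalized to `[0, 1]` per
#' dimension before kernel evaluation (mixed units -- seconds, Pa s,
#' percent -- would otherwise ill-condition the system).
#'
#' @param x Node coordinates, `N x d` matrix (or data frame): `(t, mu)` for
#'   time-dependent variables, `(mu)` for steady ones.
#' @param y Outputs at the nodes, `N x L` (one column per modal coefficient).
#' @param kernel `"tps"` (thin-plate spline, default), `"gaussian"` or
#'   `"multiquadric"`.
#' @param shape Shape parameter for the scaled kernels.
#' @return An object of class `rbf_model`.
#' @export
fit_rbf <- function(x, y, kernel = c("tps", "gaussian", "multiquadric"),
                    shape = 1) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x); y <- as.matrix(y)
  storage.mode(x) <- "double"
  n <- nrow(x); d <- ncol(x)
  if (n != nrow(y)) stop("x and y row counts differ", call. = FALSE)
  if (n < d + 2) stop("need at least d + 2 nodes for a degree-1 tail",
                      call. = FALSE)
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  wid <- ifelse(hi > lo, hi - lo, 1)
  xn <- sweep(sweep(x, 2, lo), 2, wid, "/")
  if (anyDuplicated(xn)) stop("duplicate RBF nodes", call. = FALSE)
  psi <- rbf_kernel(kernel, shape)
  D <- as.matrix(stats::dist(xn))
  Phi <- psi(D)
  P <- cbind(1, xn)
  A <- rbind(cbind(Phi, P), cbind(t(P), matrix(0, d + 1, d + 1)))
  rhs <- rbind(y, matrix(0, d + 1, ncol(y)))
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    stop(sprintf("singular RBF system (kernel %s, shape %g): %s",
                 kernel, shape, conditionMessage(e)), call. = FALSE)
  })
  structure(list(w = sol[seq_len(n), , drop = FALSE],
                 poly = sol[(n + 1):(n + d + 1), , drop = FALSE],
                 nodes = xn, lo = lo, wid = wid,
                 kernel = kernel, shape = shape, d = d,
                 L = ncol(y)),
            class = "rbf_model")
}

#' Evaluate an RBF interpolant
#'
#' @param object An [fit_rbf()] model.
#' @param newdata Query coordinates, `m x d` (raw units; normalized
#'   internally). Queries outside the training box trigger an extrapolation
#'   warning.
#' @param ... Unused.
#' @return `m x L` matrix of interpolated outputs.
#' @export
predict.rbf_model <- function(object, newdata, ...) {
  q <- as.matrix(newdata)
  if (ncol(q) != object$d) {
    stop("query dimension ", ncol(q), " does not match model dimension ",
         object$d, call. = FALSE)
  }
  storage.mode(q) <- "double"
  qn <- sweep(sweep(q, 2, object$lo), 2, object$wid, "/")
  if (any(qn < -1e-9) || any(qn > 1 + 1e-9)) {
    warning("RBF query outside the training box: extrapolating")
  }
  psi <- rbf_kernel(object$kernel, object$shape)
  # cross-distance matrix queries x nodes
  D <- sqrt(pmax(outer(rowSums(qn^2), rowSums(object$nodes^2), "+") -
                   2 * tcrossprod(qn, object$nodes), 0))
  psi(D) %*% object$w + cbind(1, qn) %*% object$poly
}

#' Reconstruct a full field from the reduced model
#'
#' `Phi_rb = sum_l alpha_l(query) * mode_l`: evaluates the RBF map at the
#' query coordinates and expands through the POD basis. Runtime is
#' independent of the snapshot count beyond the RBF node sum.
#'
#' @param basis A [pod()] basis.
#' @param model An [fit_rbf()] model trained on that basis' coefficients.
#' @param query Query coordinates, `m x d`.
#' @return `N_h x m` matrix of reconstructed fields (one column per query).
#' @export
rom_predict <- function(basis, model, query) {
  if (model$L != basis$L) {
    stop("basis/model mismatch: basis has L = ", basis$L,
         " modes, model maps to L = ", model$L, call. = FALSE)
  }
  alpha <- predict(model, query)
  basis$modes %*% t(alpha)
}

#' Relative reconstruction error
#'
#' Frobenius-norm relative error per snapshot column (time-resolved for
#' time-dependent variables, a single value for steady ones), plus a
#' time-averaged summary.
#'
#' @param truth,pred Matrices (cells x columns) or vectors of matching shape.
#' @param times Optional column times for labelling.
#' @return A tibble of class `error_report` with columns `time` (if given)
#'   and `error`; attribute `"mean"` carries the time-averaged error.
#' @export
relative_error <- function(truth, pred, times = NULL) {
  truth <- cbind(truth); pred <- cbind(pred)
  if (!all(dim(truth) == dim(pred))) {
    stop("truth/prediction shapes differ", call. = FALSE)
  }
  denom <- sqrt(colSums(truth^2))
  if (any(denom == 0)) stop("zero-norm truth column: relative error undefined",
                            call. = FALSE)
  e <- sqrt(colSums((truth - pred)^2)) / denom
  out <- if (is.null(times)) tibble::tibble(error = e) else
    tibble::tibble(time = times, error = e)
  attr(out, "mean") <- mean(e)
  class(out) <- c("error_report", class(out))
  out
}

#' Sweep the POD energy threshold
#'
#' For each threshold, retains `L(eps)` modes, refits the RBF map on the
#' training nodes and reports training and held-out reconstruction errors --
#' the standard accuracy/cost trade-off curve (error plateaus while `L`
#' grows at high thresholds).
#'
#' @param S Training `snapshot_matrix` (or matrix).
#' @param x_train Node coordinates matching the snapshot columns.
#' @param x_test,truth_test Held-out query coordinates and their true fields
#'   (optional; test error reported when supplied).
#' @param eps_list Thresholds; default `c(0.90, 0.95, 0.99, 0.999)`.
#' @param kernel,shape RBF settings, as in [fit_rbf()].
#' @return Tibble with `eps`, `L`, `train_error`, `test_error`.
#' @export
mode_energy_sweep <- function(S, x_train, x_test = NULL, truth_test = NULL,
                              eps_list = c(0.90, 0.95, 0.99, 0.999),
                              kernel = "tps", shape = 1) {
  stopifnot(all(eps_list > 0), all(eps_list <= 1))
  M <- if (inherits(S, "snapshot_matrix")) S$S else as.matrix(S)
  res <- lapply(eps_list, function(eps) {
    basis <- pod(M, eps)
    alpha <- project_coefficients(M, basis)
    model <- fit_rbf(x_train, t(alpha), kernel = kernel, shape = shape)
    train_pred <- rom_predict(basis, model, x_train)
    tr <- attr(relative_error(M, train_pred), "mean")
    te <- NA_real_
    if (!is.null(x_test)) {
      pred <- rom_predict(basis, model, x_test)
      te <- attr(relative_error(truth_test, pred), "mean")
    }
    tibble::tibble(eps = eps, L = basis$L, train_error = tr, test_error = te)
  })
  do.call(rbind, res)
}
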