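#' Offline phase: full-order runs, POD and RBF fits for all stasis indices
#'
#' Executes the complete offline pipeline on a case: draws the parameter
#' design (uniform in the cardiac-output factor f for Newtonian runs; Latin
#' hypercube over (f, eta, H) for Casson runs), runs the flow solver and the
#' segregated scalar transports for every design point, computes the wall
#' indices, assembles one snapshot matrix per variable
#' (m1, m2, washout, TAWSS, OSI), extracts the POD basis at the energy
#' threshold, and fits the constrained RBF map from `(t, mu)` (or `mu` for
#' the steady indices) to the modal coefficients. Held-out design points are
#' excluded from training and kept as validation truth.
#'
#' @param config A list with `case`, `solver`, `rom` entries (see
#'   [read_run_config()]) or a path to a key/value config file. `rom` keys
#'   (all optional): `n_samples`, `seed`, `eps`, `kernel`, `shape`,
#'   `test_idx`, `f_min`, `f_max`, `eta_min`, `eta_max`, `H_min`, `H_max`,
#'   `n_loops`.
#' @param out_dir Directory for persisted artifacts (`artifacts.rds` +
#'   `manifest.json`); `NULL` to skip persistence.
#' @param seed Master seed (drives the design sampling).
#' @param verbose Progress messages.
#' @return An object of class `rom_offline`: per-variable `pod_basis` and
#'   `rbf_model`, train/test truth, design, mesh, manifest.
#' @export
run_offline <- function(config, out_dir = NULL, seed = 1L, verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  case <- config$case
  solver <- config$solver %||% solver_config(dt_max = case$dt_max)
  rom <- config$rom %||% list()
  newton <- case$rheology == "newtonian"
  n_samples <- rom$n_samples %||% if (newton) 20L else 30L
  eps <- rom$eps %||% 0.99
  kernel <- rom$kernel %||% "tps"
  shape <- rom$shape %||% 1
  test_idx <- as.integer(rom$test_idx %||% if (newton) c(3L, 7L) else
    c(1L, 14L))
  test_idx <- test_idx[test_idx <= n_samples]
  n_loops <- rom$n_loops %||% case$n_cycles

  t_start <- proc.time()[["elapsed"]]
  if (newton) {
    samples <- sample_uniform(rom$f_min %||% 0.5, rom$f_max %||% 1.5,
                              n_samples, name = "f")
  } else {
    samples <- sample_lhs(list(f = c(rom$f_min %||% 0.5,
                                     rom$f_max %||% 1.5),
                               eta = c(rom$eta_min %||% 1.5e-3,
                                       rom$eta_max %||% 1.7e-3),
                               H = c(rom$H_min %||% 35,
                                     rom$H_max %||% 50)),
                          n_samples, seed = seed)
  }

  mesh <- build_mesh(case)
  unsteady_vars <- c("m1", "m2", "washout")
  steady_vars <- c("TAWSS", "OSI")
  fields <- stats::setNames(vector("list", 5),
                            c(unsteady_vars, steady_vars))
  for (v in names(fields)) fields[[v]] <- vector("list", n_samples)
  times <- NULL
  t_fom <- 0
  for (j in seq_len(n_samples)) {
    t0 <- proc.time()[["elapsed"]]
    rheo <- if (newton) rheology_params("newtonian") else
      rheology_params("casson", eta = samples$eta[j], H = samples$H[j])
    series <- tryCatch(
      run_cycles(case, rheo, solver, f = samples$f[j], mesh = mesh),
      error = function(e) stop("offline stage 'flow' failed at sample ", j,
                               ": ", conditionMessage(e), call. = FALSE))
    scalars <- tryCatch(
      run_transport(series, n_loops = n_loops),
      error = function(e) stop("offline stage 'transport' failed at sample ",
                               j, ": ", conditionMessage(e), call. = FALSE))
    wss <- wss_series(series, rheo)
    times <- series$times
    fields$m1[[j]] <- scalars$m1
    fields$m2[[j]] <- scalars$m2
    fields$washout[[j]] <- scalars$washout
    fields$TAWSS[[j]] <- tawss(wss)$value
    fields$OSI[[j]] <- osi(wss)$value
    t_fom <- t_fom + (proc.time()[["elapsed"]] - t0)
    if (verbose) message(sprintf("sample %d/%d done (f = %.3f)",
                                 j, n_samples, samples$f[j]))
  }

  train_idx <- setdiff(seq_len(n_samples), test_idx)
  mu_cols <- if (newton) "f" else c("f", "eta", "H")
  mu_mat <- as.matrix(samples[mu_cols])
  node_unsteady <- function(idx) {
    do.call(rbind, lapply(idx, function(j) {
      cbind(t = times, mu_mat[rep(j, length(times)), , drop = FALSE])
    }))
  }

  t0 <- proc.time()[["elapsed"]]
  variables <- list()
  for (v in names(fields)) {
    steady <- v %in% steady_vars
    S_train <- assemble_snapshots(fields[[v]][train_idx],
                                  samples[train_idx, ],
                                  times = if (steady) NULL else times,
                                  tag = v)
    basis <- pod(S_train, eps)
    alpha <- project_coefficients(S_train, basis)
    x_train <- if (steady) mu_mat[train_idx, , drop = FALSE] else
      node_unsteady(train_idx)
    t_pod <- proc.time()[["elapsed"]]
    model <- fit_rbf(x_train, t(alpha), kernel = kernel, shape = shape)
    variables[[v]] <- list(
      tag = v, steady = steady, basis = basis, model = model,
      S_train = S_train, x_train = x_train,
      test_fields = fields[[v]][test_idx]
    )
  }
  t_rom <- proc.time()[["elapsed"]] - t0

  manifest <- list(
    rheology = case$rheology,
    seed = seed,
    n_h = mesh$n_cells,
    n_wall = sum(mesh$bpatch == "wall"),
    n_t = length(times),
    n_p = n_samples,
    n_train = length(train_idx),
    n_s = stats::setNames(
      lapply(variables, function(v) ncol(v$S_train$S)), names(variables)),
    L = stats::setNames(lapply(variables, function(v) v$basis$L),
                        names(variables)),
    eps = eps, kernel = kernel, shape = shape,
    test_idx = test_idx,
    timing = list(offline_fom_s = t_fom, pod_rbf_s = t_rom,
                  total_s = proc.time()[["elapsed"]] - t_start)
  )

  out <- structure(list(variables = variables, samples = samples,
                        train_idx = train_idx, test_idx = test_idx,
                        times = times, mesh = mesh, case = case,
                        solver = solver, mu_cols = mu_cols,
                        manifest = manifest),
                   class = "rom_offline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(out, file.path(out_dir, "artifacts.rds"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rom_offline <- function(x, ...) {
  cat("<rom_offline>", x$manifest$rheology, "case:",
      x$manifest$n_p, "design points (", x$manifest$n_train, "training ),",
      x$manifest$n_h, "cells,", x$manifest$n_t, "snapshots/cycle\n")
  for (v in names(x$variables)) {
    cat(sprintf("  %-8s L = %d, N_s = %d\n", v, x$manifest$L[[v]],
                x$manifest$n_s[[v]]))
  }
  invisible(x)
}

#' Online phase: evaluate the reduced model at new parameters
#'
#' Evaluates the POD-RBF surrogate for the requested variables at a query
#' parameter point (and times, for the time-dependent variables). When the
#' query matches a stored held-out design point, the validation truth is
#' used to emit a relative-error report.
#'
#' @param offline A `rom_offline` object or the directory it was persisted
#'   to.
#' @param query Named list / one-row data frame with `f` (and `eta`, `H` for
#'   Casson cases).
#' @param times Times at which to evaluate the time-dependent variables;
#'   defaults to the snapshot schedule. Must be omitted (`NULL`) when only
#'   steady variables are requested.
#' @param variables Variables to evaluate (default: all five).
#' @param truth Optional named list of truth fields for error reporting.
#' @return A list with `predictions` (named list of field matrices/vectors),
#'   `errors` (named list of `error_report`s, where truth is available) and
#'   the echoed `query`.
#' @export
run_online <- function(offline, query, times = NULL, variables = NULL,
                       truth = NULL) {
  if (is.character(offline)) {
    path <- file.path(offline, "artifacts.rds")
    if (!file.exists(path)) stop("missing artifacts at ", path,
                                 call. = FALSE)
    offline <- readRDS(path)
  }
  stopifnot(inherits(offline, "rom_offline"))
  variables <- variables %||% names(offline$variables)
  unknown <- setdiff(variables, names(offline$variables))
  if (length(unknown)) stop("unknown variable(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  q <- as.data.frame(query)[offline$mu_cols]
  if (nrow(q) != 1) stop("one query point at a time", call. = FALSE)
  qv <- as.numeric(q[1, ])

  all_steady <- all(vapply(offline$variables[variables],
                           function(v) v$steady, logical(1)))
  if (all_steady && !is.null(times)) {
    stop("steady variables accept no time argument", call. = FALSE)
  }
  tq <- times %||% offline$times

  # does the query match a stored held-out sample?
  test_match <- NULL
  if (length(offline$test_idx)) {
    tm <- as.matrix(offline$samples[offline$test_idx, offline$mu_cols])
    hit <- which(apply(tm, 1, function(r) isTRUE(all.equal(r, qv,
                                                           tolerance = 1e-12,
                                                           check.attributes = FALSE))))
    if (length(hit)) test_match <- hit[1]
  }

  predictions <- list(); errors <- list()
  for (v in variables) {
    var <- offline$variables[[v]]
    if (var$steady) {
      xq <- matrix(qv, nrow = 1,
                   dimnames = list(NULL, offline$mu_cols))
      pred <- rom_predict(var$basis, var$model, xq)[, 1]
    } else {
      xq <- cbind(t = tq,
                  matrix(rep(qv, each = length(tq)), ncol = length(qv),
                         dimnames = list(NULL, offline$mu_cols)))
      pred <- rom_predict(var$basis, var$model, xq)
    }
    predictions[[v]] <- pred
    tru <- truth[[v]]
    if (is.null(tru) && !is.null(test_match)) {
      tru <- var$test_fields[[test_match]]
      if (!var$steady && !is.null(times)) tru <- NULL # schedule mismatch
    }
    if (!is.null(tru)) {
      errors[[v]] <- relative_error(tru, pred,
                                    times = if (var$steady) NULL else tq)
    }
  }
  list(predictions = predictions, errors = errors, query = q)
}

#' Energy-threshold sweep over all variables of an offline result
#'
#' Re-selects the POD dimension and refits the RBF map at each threshold,
#' reporting training and held-out errors per variable.
#'
#' @param offline A `rom_offline` object (or artifact directory).
#' @param eps_list Energy thresholds; default `c(0.90, 0.95, 0.99, 0.999)`.
#' @return Tibble with `variable`, `eps`, `L`, `train_error`, `test_error`.
#' @export
sweep_epsilon <- function(offline, eps_list = c(0.90, 0.95, 0.99, 0.999)) {
  if (is.character(offline)) {
    offline <- readRDS(file.path(offline, "artifacts.rds"))
  }
  res <- lapply(names(offline$variables), function(v) {
    var <- offline$variables[[v]]
    has_test <- length(offline$test_idx) > 0
    if (has_test) {
      mu_mat <- as.matrix(offline$samples[offline$mu_cols])
      if (var$steady) {
        x_test <- mu_mat[offline$test_idx, , drop = FALSE]
        truth <- do.call(cbind, var$test_fields)
      } else {
        x_test <- do.call(rbind, lapply(offline$test_idx, function(j) {
          cbind(t = offline$times,
                mu_mat[rep(j, length(offline$times)), , drop = FALSE])
        }))
        truth <- do.call(cbind, var$test_fields)
      }
    } else {
      x_test <- NULL; truth <- NULL
    }
    sw <- mode_energy_sweep(var$S_train, var$x_train, x_test, truth,
                            eps_list = eps_list,
                            kernel = var$model$kernel,
                            shape = var$model$shape)
    tibble::tibble(variable = v, sw)
  })
  do.call(rbind, res)
}

#' Verify manifest/artifact consistency
#'
#' @param offline A `rom_offline` object.
#' @return Invisibly `TRUE`; stops on an inconsistency.
#' @export
check_manifest <- function(offline) {
  m <- offline$manifest
  for (v in names(offline$variables)) {
    var <- offline$variables[[v]]
    if (ncol(var$S_train$S) != m$n_s[[v]]) {
      stop("manifest N_s mismatch for ", v, call. = FALSE)
    }
    if (var$basis$L != m$L[[v]]) stop("manifest L mismatch for ", v,
                                      call. = FALSE)
    nh_expect <- if (var$steady) m$n_wall else m$n_h
    if (nrow(var$S_train$S) != nh_expect) {
      stop("manifest N_h mismatch for ", v, call. = FALSE)
    }
  }
  if (m$n_p != nrow(offline$samples)) stop("manifest N_p mismatch",
                                           call. = FALSE)
  invisible(TRUE)
}
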