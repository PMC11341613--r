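#' Flow solver configuration
#'
#' @param dt_max Maximum time step (s). Default 0.01.
#' @param courant_max Maximum cell Courant number used when adapting the step
#'   (default 0.8). The implicit scheme is stable beyond it; the cap protects
#'   accuracy during the pulse.
#' @param convection Convection scheme for momentum: `"linear_upwind"`
#'   (second-order upwind-biased via deferred correction, default) or
#'   `"upwind"` (first-order fallback).
#' @param scalar_convection Convection scheme for the passive scalars;
#'   first-order upwind by default to keep the washout bounded in `[0, 1]`.
#' @param div_tol Acceptable post-projection divergence (1/s).
#' @param dt_snap Snapshot spacing (s); `NULL` means `dt_max`.
#' @param p_ref Reference pressure at the outlet (Pa).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(dt_max = 0.01, courant_max = 0.8,
                          convection = c("linear_upwind", "upwind"),
                          scalar_convection = c("upwind", "linear_upwind"),
                          div_tol = 1e-7, dt_snap = NULL, p_ref = 0) {
  convection <- match.arg(convection)
  scalar_convection <- match.arg(scalar_convection)
  stopifnot(dt_max > 0, courant_max > 0, courant_max <= 1, div_tol > 0)
  structure(list(dt_max = dt_max, courant_max = courant_max,
                 convection = convection,
                 scalar_convection = scalar_convection,
                 div_tol = div_tol, dt_snap = dt_snap, p_ref = p_ref),
            class = "solver_config")
}

#' Second invariant of the strain-rate tensor
#'
#' `J2 = (D : D) / 2` with `D = (grad v + grad v^T) / 2`, so the scalar shear
#' rate is `2 * sqrt(J2)`. Gradients are Green-Gauss; boundary face values
#' default to the owner cell (zero-gradient) unless supplied.
#'
#' @param u,v Cell velocity components (m/s).
#' @param mesh An `fv_mesh`.
#' @param bu,bv Optional boundary-face velocity values (NA = zero-gradient).
#' @return J2 per cell (s^-2), non-negative.
#' @export
strain_invariant <- function(u, v, mesh, bu = NULL, bv = NULL) {
  if (is.null(bu)) bu <- rep(NA_real_, length(mesh$bo))
  if (is.null(bv)) bv <- rep(NA_real_, length(mesh$bo))
  bu <- fv_resolve_bc(mesh, u, bu)
  bv <- fv_resolve_bc(mesh, v, bv)
  gu <- fv_gradient(mesh, u, bu)
  gv <- fv_gradient(mesh, v, bv)
  dxx <- gu$x
  dyy <- gv$y
  dxy <- 0.5 * (gu$y + gv$x)
  0.5 * (dxx^2 + dyy^2 + 2 * dxy^2)
}

#' Snapshot schedule for a case
#'
#' The uniform schedule `t_i = i * dt_snap`, `i = 1, ..., round(T /
#' dt_snap)`, on which [run_cycles()] collects the final-cycle fields. With
#' the defaults (T = 1.07 s, dt = 0.01 s) one cycle yields 107 snapshots.
#'
#' @param config A [case_config()].
#' @param dt_snap Snapshot spacing (s); defaults to the case's `dt_max`.
#' @return Vector of within-cycle snapshot times (s).
#' @export
snapshot_times <- function(config, dt_snap = NULL) {
  dt <- dt_snap %||% config$dt_max
  dt * seq_len(as.integer(round(config$period / dt)))
}

#' Initial flow state (rest)
#'
#' @param mesh An `fv_mesh`.
#' @param t0 Initial time (s).
#' @return A `flow_state`: cell velocity and pressure, face fluxes, time.
#' @export
flow_state_rest <- function(mesh, t0 = 0) {
  structure(list(u = numeric(mesh$n_cells), v = numeric(mesh$n_cells),
                 p = numeric(mesh$n_cells),
                 phi_int = numeric(length(mesh$fo)),
                 phi_b = numeric(length(mesh$bo)),
                 t = t0, div_max = 0),
            class = "flow_state")
}

#' Prepare a reusable flow solver for a mesh
#'
#' Assembles and factorizes the (constant-coefficient) pressure-projection
#' operator once, with a fixed reference pressure on the outlet patch and
#' homogeneous Neumann conditions elsewhere.
#'
#' @param mesh An `fv_mesh`.
#' @param config A [solver_config()].
#' @return A `flow_solver` object to pass to [advance_flow()].
#' @export
flow_solver <- function(mesh, config = solver_config()) {
  n <- mesh$n_cells
  a_int <- mesh$farea / mesh$fd
  out <- mesh$bpatch == "outlet"
  if (!any(out)) stop("mesh has no outlet patch; pressure level undefined",
                      call. = FALSE)
  a_out <- mesh$barea[out] / mesh$bd[out]
  i <- c(mesh$fo, mesh$fn, mesh$fo, mesh$fn, mesh$bo[out])
  j <- c(mesh$fo, mesh$fn, mesh$fn, mesh$fo, mesh$bo[out])
  x <- c(a_int, a_int, -a_int, -a_int, a_out)
  M <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  chol <- Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE)
  structure(list(mesh = mesh, config = config, chol = chol,
                 outlet = which(out)),
            class = "flow_solver")
}

# assemble the scalar advection-diffusion-reaction matrix and rhs shared by
# momentum components and passive scalars (implicit Euler, implicit upwind
# convection, two-point diffusion). Returns triplets + rhs pieces.
fv_transport_system <- function(mesh, rho, dt, phi_int, phi_b, mu_face,
                                mu_bface, dirichlet, bval) {
  n <- mesh$n_cells
  Fm <- rho * phi_int
  Dm <- mu_face * mesh$farea / mesh$fd
  i <- c(mesh$fo, mesh$fo, mesh$fn, mesh$fn)
  j <- c(mesh$fo, mesh$fn, mesh$fn, mesh$fo)
  x <- c(pmax(Fm, 0) + Dm, pmin(Fm, 0) - Dm,
         -pmin(Fm, 0) + Dm, -pmax(Fm, 0) - Dm)
  diag_extra <- numeric(n)
  rhs <- numeric(n)
  Fb <- rho * phi_b
  # Dirichlet boundary faces: known face value enters convection and diffusion
  if (any(dirichlet)) {
    bo <- mesh$bo[dirichlet]
    Db <- mu_bface[dirichlet] * mesh$barea[dirichlet] / mesh$bd[dirichlet]
    rhs <- rhs + fv_accum(n, bo, -Fb[dirichlet] * bval[dirichlet] +
                            Db * bval[dirichlet])
    diag_extra <- diag_extra + fv_accum(n, bo, Db)
  }
  # zero-gradient faces: face value = owner value, convection only
  zg <- !dirichlet
  if (any(zg)) {
    diag_extra <- diag_extra + fv_accum(n, mesh$bo[zg], Fb[zg])
  }
  # time term
  diag_extra <- diag_extra + rho * mesh$vol / dt
  list(i = c(i, seq_len(n)), j = c(j, seq_len(n)), x = c(x, diag_extra),
       rhs = rhs, Fm = Fm)
}

# deferred linear-upwind correction to the rhs of a transported quantity
fv_linear_upwind_corr <- function(mesh, Fm, field, bvals) {
  g <- fv_gradient(mesh, field, bvals)
  up <- ifelse(Fm >= 0, mesh$fo, mesh$fn)
  sgn <- ifelse(Fm >= 0, 1, -1)
  corr <- (g$x[up] * mesh$fnx + g$y[up] * mesh$fny) * (mesh$h / 2) * sgn
  fv_accum(mesh$n_cells, mesh$fo, -Fm * corr) +
    fv_accum(mesh$n_cells, mesh$fn, Fm * corr)
}

#' Advance the incompressible flow by one implicit time step
#'
#' Incremental pressure projection with implicit Euler time discretization:
#' an implicit momentum predictor (upwind-biased convection with deferred
#' second-order correction, lagged mass fluxes, one Picard update of the
#' effective viscosity), Rhie-Chow face-flux interpolation, and a pressure
#' correction that renders the face fluxes discretely divergence-free.
#'
#' @param state A `flow_state` at time t.
#' @param solver A [flow_solver()].
#' @param rheology A [rheology_params()].
#' @param bc Boundary data at t + dt, as from [boundary_velocity()].
#' @param dt Time step (s).
#' @return A `flow_state` at t + dt with `div_max`, the maximum cell
#'   divergence (1/s) after projection.
#' @export
advance_flow <- function(state, solver, rheology, bc, dt) {
  mesh <- solver$mesh
  config <- solver$config
  n <- mesh$n_cells
  rho <- rheology$rho

  bu <- fv_resolve_bc(mesh, state$u, bc$u)
  bv <- fv_resolve_bc(mesh, state$v, bc$v)

  # effective viscosity (Picard-lagged on the current velocity)
  if (rheology$model == "newtonian") {
    mu_cell <- rep(rheology$mu_const, n)
  } else {
    J2 <- strain_invariant(state$u, state$v, mesh, bu, bv)
    mu_cell <- effective_viscosity(J2, rheology)
  }
  mu_face <- 0.5 * (mu_cell[mesh$fo] + mu_cell[mesh$fn])
  mu_bface <- mu_cell[mesh$bo]

  dirichlet <- mesh$bpatch != "outlet"
  # boundary mass fluxes at the new time: Dirichlet faces exact, outlet lagged
  phi_b_new <- state$phi_b
  phi_b_new[dirichlet] <- (bu[dirichlet] * mesh$bnx[dirichlet] +
                             bv[dirichlet] * mesh$bny[dirichlet]) *
    mesh$barea[dirichlet]

  # pressure gradient (Neumann walls/inlets, fixed value at outlet)
  bp <- state$p[mesh$bo]
  bp[!dirichlet] <- config$p_ref
  gp <- fv_gradient(mesh, state$p, bp)

  sys_u <- fv_transport_system(mesh, rho, dt, state$phi_int, phi_b_new,
                               mu_face, mu_bface, dirichlet, bu)
  A <- Matrix::sparseMatrix(i = sys_u$i, j = sys_u$j, x = sys_u$x,
                            dims = c(n, n))
  rhs_u <- sys_u$rhs + rho * mesh$vol / dt * state$u - mesh$vol * gp$x
  # v shares the matrix; only Dirichlet rhs differs
  sys_v <- fv_transport_system(mesh, rho, dt, state$phi_int, phi_b_new,
                               mu_face, mu_bface, dirichlet, bv)
  rhs_v <- sys_v$rhs + rho * mesh$vol / dt * state$v - mesh$vol * gp$y

  if (config$convection == "linear_upwind") {
    rhs_u <- rhs_u + fv_linear_upwind_corr(mesh, sys_u$Fm, state$u, bu)
    rhs_v <- rhs_v + fv_linear_upwind_corr(mesh, sys_v$Fm, state$v, bv)
  }
  {
    # explicit transpose-viscosity term div(mu grad(v)^T); vanishes
    # analytically for constant viscosity and divergence-free fields, kept
    # discretely for both rheologies so they share one momentum operator
    gu <- fv_gradient(mesh, state$u, bu)
    gv <- fv_gradient(mesh, state$v, bv)
    tdiv <- function(ax, ay) {
      axf <- 0.5 * (ax[mesh$fo] + ax[mesh$fn])
      ayf <- 0.5 * (ay[mesh$fo] + ay[mesh$fn])
      fv_divergence(mesh, (axf * mesh$fnx + ayf * mesh$fny) * mesh$farea,
                    (ax[mesh$bo] * mesh$bnx + ay[mesh$bo] * mesh$bny) *
                      mesh$barea)
    }
    rhs_u <- rhs_u + tdiv(mu_cell * gu$x, mu_cell * gv$x)
    rhs_v <- rhs_v + tdiv(mu_cell * gu$y, mu_cell * gv$y)
  }

  sol <- Matrix::solve(A, cbind(rhs_u, rhs_v))
  us <- as.numeric(sol[, 1]); vs <- as.numeric(sol[, 2])
  if (any(!is.finite(us)) || any(!is.finite(vs))) {
    stop("flow solver produced non-finite velocities (momentum predictor)",
         call. = FALSE)
  }

  # Rhie-Chow predictor fluxes
  c_ <- dt / rho
  uf <- 0.5 * (us[mesh$fo] + us[mesh$fn])
  vf <- 0.5 * (vs[mesh$fo] + vs[mesh$fn])
  gpxf <- 0.5 * (gp$x[mesh$fo] + gp$x[mesh$fn])
  gpyf <- 0.5 * (gp$y[mesh$fo] + gp$y[mesh$fn])
  dpdn <- (state$p[mesh$fn] - state$p[mesh$fo]) / mesh$fd
  phi_star <- (uf * mesh$fnx + vf * mesh$fny +
                 c_ * (gpxf * mesh$fnx + gpyf * mesh$fny - dpdn)) * mesh$farea
  phib_star <- phi_b_new
  ot <- !dirichlet
  dpdn_b <- (config$p_ref - state$p[mesh$bo[ot]]) / mesh$bd[ot]
  phib_star[ot] <- (us[mesh$bo[ot]] * mesh$bnx[ot] +
                      vs[mesh$bo[ot]] * mesh$bny[ot] +
                      c_ * (gp$x[mesh$bo[ot]] * mesh$bnx[ot] +
                              gp$y[mesh$bo[ot]] * mesh$bny[ot] - dpdn_b)) *
    mesh$barea[ot]

  # pressure correction
  div <- fv_divergence(mesh, phi_star, phib_star)
  pc <- -as.numeric(Matrix::solve(solver$chol, div)) / c_
  if (any(!is.finite(pc))) {
    stop("flow solver produced non-finite pressure correction", call. = FALSE)
  }

  phi_int <- phi_star - c_ * (pc[mesh$fn] - pc[mesh$fo]) / mesh$fd * mesh$farea
  phi_b <- phib_star
  phi_b[ot] <- phib_star[ot] - c_ * (0 - pc[mesh$bo[ot]]) / mesh$bd[ot] *
    mesh$barea[ot]

  bpc <- pc[mesh$bo]
  bpc[ot] <- 0
  gpc <- fv_gradient(mesh, pc, bpc)
  u_new <- us - c_ * gpc$x
  v_new <- vs - c_ * gpc$y
  p_new <- state$p + pc

  div_new <- fv_divergence(mesh, phi_int, phi_b) / mesh$vol
  div_max <- max(abs(div_new))
  if (!is.finite(div_max) || div_max > config$div_tol) {
    stop(sprintf("projection failed: max divergence %.3e exceeds %.3e",
                 div_max, config$div_tol), call. = FALSE)
  }

  structure(list(u = u_new, v = v_new, p = p_new,
                 phi_int = phi_int, phi_b = phi_b,
                 t = state$t + dt, div_max = div_max),
            class = "flow_state")
}

#' Integrate cardiac cycles from rest and collect the final cycle
#'
#' Starts from `v = 0`, integrates `n_cycles` periods of the pulsatile
#' waveform with Courant-limited subcycling, and records velocity, pressure
#' and face fluxes on the uniform snapshot schedule `t_i = i * dt_snap`,
#' `i = 1, ..., round(T / dt_snap)`, of the final cycle.
#'
#' @param config A [case_config()].
#' @param rheology A [rheology_params()]; defaults follow the case's rheology
#'   selector.
#' @param solver_cfg A [solver_config()].
#' @param f Cardiac-output scaling factor.
#' @param mesh Optional pre-built mesh (rebuilt from `config` otherwise).
#' @param verbose Print per-cycle progress.
#' @return A `cycle_series`: snapshot `times` (s, within-cycle), matrices
#'   `U`, `V`, `P` (cells x snapshots), face-flux matrices `PHI`, `PHB`,
#'   outlet rates `Q`, the mesh and run metadata.
#' @export
run_cycles <- function(config, rheology = NULL,
                       solver_cfg = solver_config(dt_max = config$dt_max),
                       f = 1, mesh = NULL, verbose = FALSE) {
  if (is.null(rheology)) rheology <- rheology_params(config$rheology)
  if (is.null(mesh)) mesh <- build_mesh(config)
  times <- snapshot_times(config, solver_cfg$dt_snap %||% solver_cfg$dt_max)
  dt_snap <- times[1]
  n_snap <- length(times)
  solver <- flow_solver(mesh, solver_cfg)
  state <- flow_state_rest(mesh)

  n <- mesh$n_cells
  U <- matrix(0, n, n_snap); V <- matrix(0, n, n_snap)
  P <- matrix(0, n, n_snap)
  PHI <- matrix(0, length(mesh$fo), n_snap)
  PHB <- matrix(0, length(mesh$bo), n_snap)
  Q <- numeric(n_snap)

  for (cyc in seq_len(config$n_cycles)) {
    for (i in seq_len(n_snap)) {
      target <- (cyc - 1) * config$period + i * dt_snap
      while (state$t < target - 1e-12) {
        umax <- max(abs(state$u), abs(state$v), 1e-12)
        bc_probe <- boundary_velocity(mesh, target, f)
        umax <- max(umax, abs(bc_probe$u), abs(bc_probe$v), na.rm = TRUE)
        dt <- min(solver_cfg$dt_max,
                  solver_cfg$courant_max * mesh$h / umax,
                  target - state$t)
        bc <- boundary_velocity(mesh, state$t + dt, f)
        state <- advance_flow(state, solver, rheology, bc, dt)
      }
      if (cyc == config$n_cycles) {
        U[, i] <- state$u; V[, i] <- state$v; P[, i] <- state$p
        PHI[, i] <- state$phi_int; PHB[, i] <- state$phi_b
        Q[i] <- mv_waveform(state$t, f, config)
      }
    }
    if (verbose) {
      message(sprintf("cycle %d/%d done (t = %.3f s, max |v| = %.3e m/s)",
                      cyc, config$n_cycles, state$t,
                      max(abs(state$u), abs(state$v))))
    }
  }
  structure(list(times = times, U = U, V = V, P = P, PHI = PHI, PHB = PHB,
                 Q = Q, mesh = mesh, f = f, rheology = rheology,
                 config = config, solver_cfg = solver_cfg),
            class = "cycle_series")
}

#' March the flow to a steady state under fixed boundary data
#'
#' Repeats [advance_flow()] with constant boundary conditions until the
#' velocity increment stalls. Intended for steady fixtures (e.g. channel
#' flow); the implicit scheme permits steps beyond the Courant limit here.
#'
#' @param mesh An `fv_mesh`.
#' @param rheology A [rheology_params()].
#' @param bc Fixed boundary data, as from [boundary_velocity()] or built
#'   manually (`u`, `v` per boundary face, NA = zero-gradient).
#' @param dt Pseudo-time step (s).
#' @param solver_cfg A [solver_config()].
#' @param max_steps Iteration cap.
#' @param tol Relative stall tolerance on `max |du|`.
#' @return A `flow_state` with attributes `steps` and `converged`.
#' @export
run_steady <- function(mesh, rheology, bc, dt = 0.05,
                       solver_cfg = solver_config(dt_max = dt),
                       max_steps = 1000L, tol = 1e-8) {
  solver <- flow_solver(mesh, solver_cfg)
  state <- flow_state_rest(mesh)
  converged <- FALSE
  step <- 0L
  while (step < max_steps) {
    step <- step + 1L
    new <- advance_flow(state, solver, rheology, bc, dt)
    du <- max(abs(new$u - state$u), abs(new$v - state$v))
    uref <- max(abs(new$u), abs(new$v), 1e-30)
    state <- new
    if (du <= tol * uref) { converged <- TRUE; break }
  }
  attr(state, "steps") <- step
  attr(state, "converged") <- converged
  state
}
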