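#' Passive-scalar transport configuration
#'
#' Settings for the blood-age moments m1, m2 and the washout scalar phi:
#' tiny mass diffusivities (1e-10 kg/(m s), advection-dominated), Dirichlet
#' zero at the inlets, zero normal gradient everywhere else; initial values
#' m_k = 0 and phi = 1, with the zeroth moment identically 1.
#'
#' @param mu_m1,mu_m2,mu_phi Mass diffusivities (kg/(m s)).
#' @return An object of class `transport_config`.
#' @export
transport_config <- function(mu_m1 = 1e-10, mu_m2 = 1e-10, mu_phi = 1e-10) {
  stopifnot(mu_m1 >= 0, mu_m2 >= 0, mu_phi >= 0)
  structure(list(mu_m1 = mu_m1, mu_m2 = mu_m2, mu_phi = mu_phi),
            class = "transport_config")
}

# one implicit-Euler advection-diffusion step for a passive scalar.
# source_cell: volumetric source density rho * k * m_{k-1} (0 for washout).
fv_scalar_step <- function(field, mesh, rho, dt, phi_int, phi_b, mu,
                           source_cell, scheme = "upwind") {
  n <- mesh$n_cells
  dirichlet <- mesh$bpatch %in% mesh$inlet_patches
  bval <- numeric(length(mesh$bo)) # Dirichlet 0 on inlets
  sys <- fv_transport_system(mesh, rho, dt, phi_int, phi_b,
                             rep(mu, length(mesh$fo)),
                             rep(mu, length(mesh$bo)), dirichlet, bval)
  A <- Matrix::sparseMatrix(i = sys$i, j = sys$j, x = sys$x, dims = c(n, n))
  rhs <- sys$rhs + rho * mesh$vol / dt * field + source_cell * mesh$vol
  if (scheme == "linear_upwind") {
    bres <- rep(NA_real_, length(mesh$bo))
    bres[dirichlet] <- 0
    bres <- fv_resolve_bc(mesh, field, bres)
    rhs <- rhs + fv_linear_upwind_corr(mesh, sys$Fm, field, bres)
  }
  out <- as.numeric(Matrix::solve(A, rhs))
  if (any(!is.finite(out))) stop("scalar transport produced non-finite values",
                                 call. = FALSE)
  out
}

# note: zero-gradient faces in fv_transport_system see the *mass flux* sign;
# at inflow through a zero-gradient face the scheme still uses the owner
# value, which is the standard (and bounded) first-order treatment.

#' Advance an age moment by one time step
#'
#' Implicit-Euler finite-volume update of
#' `rho dm_k/dt + rho div(v m_k) = div(mu grad m_k) + rho k m_{k-1}`,
#' with `m_0 = 1`: the first moment grows at unit rate where blood is
#' stagnant, the second feeds on the first. Dirichlet 0 on the inlets (fresh
#' blood has zero age), zero normal gradient elsewhere. Solved after the flow
#' system against stored face fluxes (segregated).
#'
#' @param k Moment order, 1 or 2.
#' @param m Current moment field (cells).
#' @param m_prev The order-(k-1) moment at the same step; ignored for `k = 1`
#'   (identically 1). Required for `k = 2`.
#' @param mesh An `fv_mesh`.
#' @param phi_int,phi_b Face fluxes at the target time (m^2/s).
#' @param rho Density (kg/m^3).
#' @param dt Time step (s).
#' @param config A [transport_config()].
#' @param scheme `"upwind"` (default, bounded) or `"linear_upwind"`.
#' @return Updated moment field.
#' @export
advance_moment <- function(k, m, m_prev = NULL, mesh, phi_int, phi_b,
                           rho = 1050, dt, config = transport_config(),
                           scheme = "upwind") {
  if (!k %in% c(1, 2)) stop("moment order k must be 1 or 2", call. = FALSE)
  if (k == 2 && is.null(m_prev)) {
    stop("advance_moment(k = 2) requires the first moment m_prev",
         call. = FALSE)
  }
  src <- if (k == 1) rho * rep(1, mesh$n_cells) else 2 * rho * m_prev
  mu <- if (k == 1) config$mu_m1 else config$mu_m2
  fv_scalar_step(m, mesh, rho, dt, phi_int, phi_b, mu, src, scheme)
}

#' Advance the washout scalar by one time step
#'
#' Same discretization as [advance_moment()] with zero source; initialized at
#' 1, flushed to 0 by inflowing fresh blood. First-order upwind convection
#' keeps it in `[0, 1]`.
#'
#' @inheritParams advance_moment
#' @param phi Current washout field.
#' @return Updated washout field.
#' @export
advance_washout <- function(phi, mesh, phi_int, phi_b, rho = 1050, dt,
                            config = transport_config(), scheme = "upwind") {
  fv_scalar_step(phi, mesh, rho, dt, phi_int, phi_b, config$mu_phi,
                 numeric(mesh$n_cells), scheme)
}

#' Run the age-moment and washout transports over stored velocity snapshots
#'
#' Replays the stored (final-cycle) face-flux series `n_loops` times --
#' the flow is periodic downstream of its transient -- advancing m1, m2 and
#' the washout from their initial data, and records the fields of the last
#' replay loop on the snapshot schedule.
#'
#' @param series A `cycle_series` from [run_cycles()].
#' @param config A [transport_config()].
#' @param n_loops Number of cycle replays (defaults to the case's `n_cycles`).
#' @param scheme Convection scheme for the scalars.
#' @return A `scalar_series`: matrices `m1`, `m2`, `washout`
#'   (cells x snapshots) for the final loop, plus `times` and the mesh.
#' @export
run_transport <- function(series, config = transport_config(),
                          n_loops = series$config$n_cycles,
                          scheme = series$solver_cfg$scalar_convection) {
  mesh <- series$mesh
  rho <- series$rheology$rho
  nt <- length(series$times)
  dt <- series$times[2] - series$times[1]
  m1 <- numeric(mesh$n_cells)
  m2 <- numeric(mesh$n_cells)
  wo <- rep(1, mesh$n_cells)
  M1 <- matrix(0, mesh$n_cells, nt)
  M2 <- matrix(0, mesh$n_cells, nt)
  WO <- matrix(0, mesh$n_cells, nt)
  for (loop in seq_len(n_loops)) {
    for (i in seq_len(nt)) {
      fi <- series$PHI[, i]; fb <- series$PHB[, i]
      m1 <- advance_moment(1, m1, NULL, mesh, fi, fb, rho, dt, config, scheme)
      m2 <- advance_moment(2, m2, m1, mesh, fi, fb, rho, dt, config, scheme)
      wo <- advance_washout(wo, mesh, fi, fb, rho, dt, config, scheme)
      if (loop == n_loops) {
        M1[, i] <- m1; M2[, i] <- m2; WO[, i] <- wo
      }
    }
  }
  structure(list(m1 = M1, m2 = M2, washout = WO, times = series$times,
                 mesh = mesh, config = config),
            class = "scalar_series")
}
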