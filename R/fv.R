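# Internal finite-volume primitives shared by the flow and transport solvers.
# All meshes are orthogonal Cartesian (axis-aligned square cells), so linear
# face interpolation uses weight 1/2 and two-point normal gradients are exact.

# scatter-add vals into a length-n accumulator at positions idx
fv_accum <- function(n, idx, vals) {
  out <- numeric(n)
  if (length(idx)) {
    s <- rowsum(vals, idx)
    out[as.integer(rownames(s))] <- s
  }
  out
}

# Green-Gauss cell gradient of a cell field given boundary-face values
fv_gradient <- function(mesh, phi, bvals) {
  fv <- 0.5 * (phi[mesh$fo] + phi[mesh$fn])
  gx <- fv_accum(mesh$n_cells, mesh$fo, fv * mesh$fnx * mesh$farea) -
    fv_accum(mesh$n_cells, mesh$fn, fv * mesh$fnx * mesh$farea) +
    fv_accum(mesh$n_cells, mesh$bo, bvals * mesh$bnx * mesh$barea)
  gy <- fv_accum(mesh$n_cells, mesh$fo, fv * mesh$fny * mesh$farea) -
    fv_accum(mesh$n_cells, mesh$fn, fv * mesh$fny * mesh$farea) +
    fv_accum(mesh$n_cells, mesh$bo, bvals * mesh$bny * mesh$barea)
  list(x = gx / mesh$vol, y = gy / mesh$vol)
}

# divergence (per cell, NOT volume-scaled) of face fluxes
fv_divergence <- function(mesh, phi_int, phi_b) {
  fv_accum(mesh$n_cells, mesh$fo, phi_int) -
    fv_accum(mesh$n_cells, mesh$fn, phi_int) +
    fv_accum(mesh$n_cells, mesh$bo, phi_b)
}

#' Boundary velocity values for a case at a given instant
#'
#' Inlet patches receive a uniform (plug) inflow profile directed along the
#' inward normal, with speed set by the equal split of the instantaneous
#' outlet waveform across the inlets; walls are no-slip; the outlet is
#' zero-gradient (`NA` here, resolved against the owner cell by the solvers).
#'
#' @param mesh An `fv_mesh`.
#' @param t Time (s).
#' @param f Cardiac-output scaling factor.
#' @return List with per-boundary-face `u`, `v` (NA on zero-gradient faces)
#'   and the instantaneous total rate `Q`.
#' @export
boundary_velocity <- function(mesh, t, f = 1) {
  config <- mesh$config
  Q <- mv_waveform(t, f, config)
  ub <- numeric(length(mesh$bo))
  vb <- numeric(length(mesh$bo))
  if (Q != 0) {
    split <- inlet_split(Q, mesh)
    for (k in seq_len(nrow(split))) {
      sel <- mesh$bpatch == split$patch[k]
      ub[sel] <- -mesh$bnx[sel] * split$speed[k]
      vb[sel] <- -mesh$bny[sel] * split$speed[k]
    }
  }
  out <- mesh$bpatch == "outlet"
  ub[out] <- NA_real_
  vb[out] <- NA_real_
  list(u = ub, v = vb, Q = Q)
}

# resolve NA (zero-gradient) boundary values against owner cells
fv_resolve_bc <- function(mesh, field, bvals) {
  na <- is.na(bvals)
  bvals[na] <- field[mesh$bo[na]]
  bvals
}

# face fluxes (m^2/s per unit depth) from cell velocities and boundary values
fv_face_fluxes <- function(mesh, u, v, bu, bv) {
  uf <- 0.5 * (u[mesh$fo] + u[mesh$fn])
  vf <- 0.5 * (v[mesh$fo] + v[mesh$fn])
  phi_int <- (uf * mesh$fnx + vf * mesh$fny) * mesh$farea
  bu <- fv_resolve_bc(mesh, u, bu)
  bv <- fv_resolve_bc(mesh, v, bv)
  phi_b <- (bu * mesh$bnx + bv * mesh$bny) * mesh$barea
  list(int = phi_int, b = phi_b)
}
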