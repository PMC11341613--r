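# Shared fixtures, all generated in code.

# plain channel (no pocket): inlet on the left, outlet on the right
channel_case <- function(length = 0.03, height = 0.01, h = 5e-4) {
  case_config(chamber_length = length, chamber_height = height,
              pocket_length = NA, pocket_width = NA, h = h,
              n_inlets = 1, inlet_side = "left", outlet_side = "right",
              inlet_frac = 1, outlet_frac = 1)
}

# quasi-1-D channel for the plug-flow transport oracles
plug_fixture <- function(L = 0.1, h = 1e-3, u = 0.05) {
  cfg <- channel_case(length = L, height = h, h = h)
  mesh <- build_mesh(cfg)
  uc <- rep(u, mesh$n_cells)
  vc <- numeric(mesh$n_cells)
  bu <- ifelse(mesh$bpatch == "inlet1", u,
               ifelse(mesh$bpatch == "outlet", NA, 0))
  bv <- ifelse(mesh$bpatch == "outlet", NA_real_, 0)
  fl <- hemorom:::fv_face_fluxes(mesh, uc, vc, bu, bv)
  list(mesh = mesh, u = u, L = L, flux = fl)
}

# small pulsatile atrium-with-pocket case for solver-level tests
toy_case <- function(n_cycles = 2) {
  case_config(chamber_length = 0.02, chamber_height = 0.01,
              pocket_length = 0.004, pocket_width = 0.003, h = 0.001,
              n_inlets = 2, n_cycles = n_cycles, stroke_volume = 1e-5)
}

# LHS design over the full Casson parameter box
casson_design <- function(n, seed) {
  sample_lhs(list(f = c(0.5, 1.5), eta = c(1.5e-3, 1.7e-3), H = c(35, 50)),
             n, seed = seed)
}

# (t, mu) node block for a design, parameter-outer / time-inner
unsteady_nodes <- function(samples, times) {
  do.call(rbind, lapply(seq_len(nrow(samples)), function(j) {
    cbind(t = times,
          as.matrix(samples[rep(j, length(times)), , drop = FALSE]))
  }))
}
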