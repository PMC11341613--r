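#' Case configuration for the idealized atrium-with-appendage geometry
#'
#' Describes a two-dimensional rectangular chamber (the "atrium") with a blind
#' rectangular side pocket (the "appendage") attached to the right wall, the
#' pulsatile boundary setup -- `n_inlets` equal-flow inlet patches (the
#' "pulmonary veins") and one outlet patch (the "mitral valve") -- and the
#' cardiac timing. All units SI; 2-D flow rates are per unit depth (m^2/s).
#'
#' @param chamber_length,chamber_height Chamber dimensions (m).
#' @param pocket_length,pocket_width Pocket (appendage) dimensions (m). The
#'   pocket protrudes from the right wall; its mouth spans `pocket_width` of
#'   that wall. Use `NA` for both to build a plain channel without a pocket.
#' @param h Mesh spacing (m); must divide every dimension to within one cell.
#' @param n_inlets Number of equal-flow inlet patches (>= 1).
#' @param period Cardiac period T (s). Default 1.07.
#' @param dt_max Maximum flow time step (s). Default 0.01; also the snapshot
#'   spacing, so one cycle yields `round(period / dt_max)` snapshots.
#' @param n_cycles Number of cardiac cycles integrated from rest; fields of the
#'   final cycle are collected.
#' @param rheology `"newtonian"` or `"casson"`.
#' @param stroke_volume Volume (per unit depth, m^2) expelled through the
#'   outlet over one cycle at scaling factor f = 1.
#' @param t_open_frac Fraction of the cycle at which the outlet valve opens
#'   (default 0.4: closed phase for t < 0.4 T, smooth pulse afterwards).
#' @param inlet_side,outlet_side Chamber side carrying the inlet/outlet
#'   patches: one of `"top"`, `"bottom"`, `"left"`, `"right"`.
#' @param inlet_frac Fraction of the inlet side covered by inlet patches
#'   (split evenly among `n_inlets` segments).
#' @param outlet_frac Fraction of the outlet side covered by the outlet patch.
#' @param pocket_y0 Lower y-coordinate of the pocket mouth (m); `NULL` centres
#'   the mouth at 70% of the chamber height (near the inlets, where the real
#'   appendage sits), snapped to the grid.
#'
#' @return An object of class `case_config` (a validated list).
#' @export
case_config <- function(chamber_length = 0.04,
                        chamber_height = 0.02,
                        pocket_length = 0.01,
                        pocket_width = 0.004,
                        h = 0.001,
                        n_inlets = 4L,
                        period = 1.07,
                        dt_max = 0.01,
                        n_cycles = 4L,
                        rheology = c("newtonian", "casson"),
                        stroke_volume = 2e-5,
                        t_open_frac = 0.4,
                        inlet_side = "top",
                        outlet_side = "bottom",
                        inlet_frac = 0.5,
                        outlet_frac = 0.3,
                        pocket_y0 = NULL) {
  rheology <- match.arg(rheology)
  sides <- c("top", "bottom", "left", "right")
  stopifnot(inlet_side %in% sides, outlet_side %in% sides)

  has_pocket <- !(is.na(pocket_length) && is.na(pocket_width))
  if (has_pocket) {
    if (is.na(pocket_length) || is.na(pocket_width) ||
        pocket_length <= 0 || pocket_width <= 0) {
      stop("configuration error: pocket dimensions must both be positive ",
           "(or both NA for no pocket)", call. = FALSE)
    }
    if (pocket_width >= chamber_height) {
      stop("configuration error: pocket wider than the chamber wall",
           call. = FALSE)
    }
  }
  if (h <= 0) stop("configuration error: mesh spacing must be positive",
                   call. = FALSE)
  if (chamber_length <= 0 || chamber_height <= 0) {
    stop("configuration error: chamber dimensions must be positive",
         call. = FALSE)
  }
  if (period <= 0) stop("configuration error: period must be positive",
                        call. = FALSE)
  if (dt_max <= 0 || dt_max > period) {
    stop("configuration error: need 0 < dt_max <= period", call. = FALSE)
  }
  n_inlets <- as.integer(n_inlets)
  if (n_inlets < 1L) stop("configuration error: n_inlets >= 1", call. = FALSE)
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) stop("configuration error: n_cycles >= 1", call. = FALSE)

  # h must tile each dimension to within one cell
  check_div <- function(L, nm) {
    n <- round(L / h)
    if (n < 1L || abs(n * h - L) > 1e-6 * max(L, h)) {
      stop("configuration error: h does not divide ", nm, call. = FALSE)
    }
    as.integer(n)
  }
  nx <- check_div(chamber_length, "chamber_length")
  ny <- check_div(chamber_height, "chamber_height")
  npx <- if (has_pocket) check_div(pocket_length, "pocket_length") else 0L
  npy <- if (has_pocket) check_div(pocket_width, "pocket_width") else 0L

  structure(list(
    chamber_length = chamber_length, chamber_height = chamber_height,
    pocket_length = if (has_pocket) pocket_length else NA_real_,
    pocket_width = if (has_pocket) pocket_width else NA_real_,
    has_pocket = has_pocket,
    h = h, nx = nx, ny = ny, npx = npx, npy = npy,
    n_inlets = n_inlets, period = period, dt_max = dt_max,
    n_cycles = n_cycles, rheology = rheology,
    stroke_volume = stroke_volume, t_open_frac = t_open_frac,
    inlet_side = inlet_side, outlet_side = outlet_side,
    inlet_frac = inlet_frac, outlet_frac = outlet_frac,
    pocket_y0 = pocket_y0
  ), class = "case_config")
}

#' @export
print.case_config <- function(x, ...) {
  cat("<case_config>\n")
  cat(sprintf("  chamber %g x %g m, h = %g m (%d x %d cells)\n",
              x$chamber_length, x$chamber_height, x$h, x$nx, x$ny))
  if (x$has_pocket) {
    cat(sprintf("  pocket  %g x %g m (%d x %d cells)\n",
                x$pocket_length, x$pocket_width, x$npx, x$npy))
  } else cat("  no pocket (plain channel)\n")
  cat(sprintf("  %d inlet(s) on %s, outlet on %s\n",
              x$n_inlets, x$inlet_side, x$outlet_side))
  cat(sprintf("  T = %g s, dt_max = %g s, %d cycle(s), rheology = %s\n",
              x$period, x$dt_max, x$n_cycles, x$rheology))
  invisible(x)
}

#' Pulsatile outlet (mitral valve) flow-rate waveform
#'
#' An analytic stand-in for the echo-Doppler mitral waveform: zero flow during
#' the closed phase (`t < t_open_frac * T`) and a smooth `sin^2` pulse over the
#' open phase, so the waveform is periodic and C^1. The waveform scales
#' linearly and exactly with the cardiac-output factor `f`; its integral over
#' one period at `f = 1` equals `stroke_volume`.
#'
#' @param t Time(s) (s); wrapped modulo the period.
#' @param f Cardiac-output scaling factor; values outside `[0.5, 1.5]` trigger
#'   a warning (the calibrated parameter range), not an error.
#' @param config A [case_config()].
#' @return Volumetric flow rate out of the chamber (m^2/s per unit depth),
#'   vectorized over `t`.
#' @export
mv_waveform <- function(t, f = 1, config = case_config()) {
  if (any(f < 0.5 | f > 1.5)) {
    warning("scaling factor f outside the calibrated range [0.5, 1.5]")
  }
  T_ <- config$period
  t0 <- config$t_open_frac * T_
  tt <- t %% T_
  amp <- 2 * config$stroke_volume / (T_ - t0)
  q <- ifelse(tt >= t0, amp * sin(pi * (tt - t0) / (T_ - t0))^2, 0)
  f * q
}

#' Split a total inflow rate equally across the inlet patches
#'
#' Each inlet ("pulmonary vein") carries the same flow rate; together they
#' balance the outlet each instant (rigid walls, incompressible flow).
#'
#' @param total Total inflow rate (m^2/s per unit depth).
#' @param mesh A [build_mesh()] result.
#' @return Tibble with one row per inlet patch: `patch`, `area`, `rate`,
#'   `speed` (plug inflow speed, rate / patch area).
#' @export
inlet_split <- function(total, mesh) {
  patches <- mesh$inlet_patches
  areas <- vapply(patches, function(p) sum(mesh$barea[mesh$bpatch == p]),
                  numeric(1))
  if (any(areas <= 0)) {
    stop("zero-area inlet patch: ", paste(patches[areas <= 0], collapse = ", "),
         call. = FALSE)
  }
  rate <- total / length(patches)
  tibble::tibble(patch = patches, area = areas, rate = rate,
                 speed = rate / areas)
}
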