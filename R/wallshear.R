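#' Wall shear stress on the wall patch at one instant
#'
#' `WSS = T_d . n` per wall face, with the deviatoric stress evaluated from
#' the wall-normal velocity gradient. At a no-slip wall the velocity varies
#' only along the wall normal. Two gradient reconstructions are available:
#' `"consistent"` (default) uses the same two-point flux as the flow
#' solver's wall diffusion -- discretely conservative, so at steady state the
#' integrated wall shear balances the driving pressure exactly;
#' `"quadratic"` fits the wall value (0) and the first two interior cells,
#' exact for analytically prescribed parabolic profiles. The viscosity is
#' the effective (rheology-consistent) viscosity at the wall strain rate.
#'
#' @param u,v Cell velocities (m/s).
#' @param mesh An `fv_mesh`.
#' @param rheology A [rheology_params()].
#' @param gradient Wall-gradient reconstruction, `"consistent"` or
#'   `"quadratic"`.
#' @return Matrix `n_wall x 2` of WSS vectors (Pa); rows follow
#'   `which(mesh$bpatch == "wall")`.
#' @export
wall_shear_stress <- function(u, v, mesh, rheology,
                              gradient = c("consistent", "quadratic")) {
  gradient <- match.arg(gradient)
  w <- which(mesh$bpatch == "wall")
  own <- mesh$bo[w]
  sec <- mesh$bsecond[w]
  h <- mesh$h
  # one-sided normal derivative of each component, inward coordinate s
  dgrad <- function(f) {
    if (gradient == "consistent") return(f[own] / (h / 2))
    ifelse(sec > 0, (9 * f[own] - f[sec]) / (3 * h), f[own] / (h / 2))
  }
  gu <- dgrad(u)
  gv <- dgrad(v)
  nx <- mesh$bnx[w]; ny <- mesh$bny[w]
  # grad v = g (x) s_hat with s_hat = -n; WSS_i = mu * (-(g_i) - n_i (g.n))
  gdotn <- gu * nx + gv * ny
  # wall strain-rate invariant from the same gradient: D = sym(g (x) s_hat)
  dxx <- gu * (-nx); dyy <- gv * (-ny)
  dxy <- 0.5 * (gu * (-ny) + gv * (-nx))
  J2 <- 0.5 * (dxx^2 + dyy^2 + 2 * dxy^2)
  mu <- effective_viscosity(J2, rheology)
  cbind(x = mu * (-gu - nx * gdotn), y = mu * (-gv - ny * gdotn))
}

#' Wall shear stress series over stored snapshots
#'
#' @param series A `cycle_series` from [run_cycles()].
#' @param rheology A [rheology_params()]; defaults to the series' rheology.
#' @param gradient Wall-gradient reconstruction (see [wall_shear_stress()]).
#' @return A `wall_stress_series`: matrices `x`, `y` (wall faces x snapshots),
#'   snapshot `times`, wall-face indices and the mesh.
#' @export
wss_series <- function(series, rheology = series$rheology,
                       gradient = "consistent") {
  nt <- length(series$times)
  w <- which(series$mesh$bpatch == "wall")
  X <- matrix(0, length(w), nt)
  Y <- matrix(0, length(w), nt)
  for (i in seq_len(nt)) {
    ws <- wall_shear_stress(series$U[, i], series$V[, i], series$mesh,
                            rheology, gradient)
    X[, i] <- ws[, 1]; Y[, i] <- ws[, 2]
  }
  wall_stress_series(X, Y, series$times, faces = w, mesh = series$mesh)
}

#' Construct a wall stress series from components
#'
#' @param x,y Matrices (faces x times) of WSS components (Pa).
#' @param times Sample times (s), uniform schedule over one period.
#' @param faces Optional boundary-face indices.
#' @param mesh Optional mesh.
#' @return A `wall_stress_series`.
#' @export
wall_stress_series <- function(x, y, times, faces = NULL, mesh = NULL) {
  x <- rbind(x); y <- rbind(y)
  stopifnot(all(dim(x) == dim(y)), ncol(x) == length(times))
  if (ncol(x) == 0) stop("empty wall stress series", call. = FALSE)
  structure(list(x = x, y = y, times = times, faces = faces, mesh = mesh),
            class = "wall_stress_series")
}

# quadrature over the sample schedule: trapezoid on [t1, tN], or midpoint
# (uniform-width rectangles, the natural rule for periodic samples / exact
# for piecewise-constant signals sampled at interval midpoints)
ws_integrate <- function(M, times, method) {
  if (method == "trapezoid") {
    dt <- diff(times)
    wts <- c(dt / 2, 0) + c(0, dt / 2)
    span <- times[length(times)] - times[1]
  } else {
    wts <- rep(mean(diff(times)), length(times))
    span <- sum(wts)
  }
  list(int = as.numeric(M %*% wts), span = span)
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' `TAWSS = (1/T) integral ||WSS|| dt` per wall face.
#'
#' @param series A `wall_stress_series` covering one period on a uniform
#'   schedule.
#' @param method Quadrature: `"trapezoid"` (default) or `"midpoint"`
#'   (uniform rectangles; exact for piecewise-constant signals sampled at
#'   subinterval midpoints, and the natural rule for periodic samples).
#' @return A tibble (class `steady_index_field`) with `face` and `value`
#'   (Pa); attribute `tag = "TAWSS"`.
#' @export
tawss <- function(series, method = c("trapezoid", "midpoint")) {
  method <- match.arg(method)
  stopifnot(inherits(series, "wall_stress_series"))
  mag <- sqrt(series$x^2 + series$y^2)
  q <- ws_integrate(mag, series$times, method)
  steady_index_field(q$int / q$span, series, "TAWSS")
}

#' Oscillatory shear index (OSI)
#'
#' `OSI = 1/2 * [1 - ||integral WSS dt|| / integral ||WSS|| dt]` per wall
#' face: 0 for unidirectional shear, 0.5 for fully reversed zero-mean shear.
#' Faces whose shear is identically zero are assigned OSI = 0.
#'
#' @inheritParams tawss
#' @return A tibble (class `steady_index_field`) with `face` and `value`
#'   (dimensionless in `[0, 0.5]`); attribute `tag = "OSI"`.
#' @export
osi <- function(series, method = c("trapezoid", "midpoint")) {
  method <- match.arg(method)
  stopifnot(inherits(series, "wall_stress_series"))
  qx <- ws_integrate(series$x, series$times, method)
  qy <- ws_integrate(series$y, series$times, method)
  qm <- ws_integrate(sqrt(series$x^2 + series$y^2), series$times, method)
  val <- ifelse(qm$int > 0,
                0.5 * (1 - sqrt(qx$int^2 + qy$int^2) / qm$int),
                0)
  # the triangle inequality guarantees [0, 0.5]; clip roundoff only
  steady_index_field(pmin(pmax(val, 0), 0.5), series, "OSI")
}

steady_index_field <- function(value, series, tag) {
  out <- tibble::tibble(
    face = if (is.null(series$faces)) seq_along(value) else series$faces,
    value = value
  )
  attr(out, "tag") <- tag
  class(out) <- c("steady_index_field", class(out))
  out
}
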