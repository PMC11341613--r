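#' Blood rheology parameters
#'
#' Newtonian blood uses a constant dynamic viscosity. The Casson model is a
#' yield-stress, shear-thinning law driven by the plasma viscosity `eta` and
#' the hematocrit `H`: the mixture viscosity scale is
#' `eta_bar = eta / (1 - H/100)^2.5` and the yield stress is
#' `tau_y = (a1 + a2 * H/100)^3` with `a1 = 0`, `a2 = 0.290` Pa^(1/3) for
#' blood. `H` is stored as a percent, as conventionally printed.
#'
#' @param model `"newtonian"` or `"casson"`.
#' @param rho Density (kg/m^3), 1050 for blood.
#' @param mu_const Constant dynamic viscosity (Pa s), Newtonian only.
#' @param eta Plasma viscosity (Pa s), Casson only.
#' @param H Hematocrit in percent (0 <= H < 100), Casson only.
#' @param J2_min Regularization floor (s^-2) for the strain-rate invariant:
#'   the Casson viscosity diverges as J2 -> 0 and is evaluated at
#'   `max(J2, J2_min)`.
#' @param strict_paper If `TRUE`, use the outer exponent 1/2 on the bracketed
#'   Casson term instead of 2. Under that variant the zero-yield-stress limit
#'   does not reduce to a constant viscosity; the default (exponent 2) is the
#'   standard Casson law and recovers `mu = eta_bar` as `tau_y -> 0`.
#' @return An object of class `rheology_params`.
#' @export
rheology_params <- function(model = c("newtonian", "casson"),
                            rho = 1050,
                            mu_const = 0.0035,
                            eta = 1.6e-3,
                            H = 45,
                            J2_min = 1e-12,
                            strict_paper = FALSE) {
  model <- match.arg(model)
  stopifnot(rho > 0, mu_const > 0, eta > 0, H >= 0, H < 100, J2_min > 0)
  a1 <- 0; a2 <- 0.290
  Hfrac <- H / 100
  eta_bar <- eta / (1 - Hfrac)^2.5
  tau_y <- (a1 + a2 * Hfrac)^3
  structure(list(model = model, rho = rho, mu_const = mu_const,
                 eta = eta, H = H, a1 = a1, a2 = a2,
                 eta_bar = eta_bar, tau_y = tau_y,
                 J2_min = J2_min, strict_paper = strict_paper),
            class = "rheology_params")
}

#' @export
print.rheology_params <- function(x, ...) {
  cat("<rheology_params>", x$model, "\n")
  if (x$model == "newtonian") {
    cat(sprintf("  rho = %g kg/m^3, mu = %g Pa s\n", x$rho, x$mu_const))
  } else {
    cat(sprintf("  rho = %g kg/m^3, eta = %g Pa s, H = %g%%\n",
                x$rho, x$eta, x$H))
    cat(sprintf("  eta_bar = %g Pa s, tau_y = %g Pa\n", x$eta_bar, x$tau_y))
  }
  invisible(x)
}

#' Casson yield stress
#'
#' `tau_y = (a1 + a2 * H/100)^3` with `a1 = 0`, `a2 = 0.290` Pa^(1/3).
#'
#' @param rheology A [rheology_params()].
#' @return Yield stress (Pa).
#' @export
yield_stress <- function(rheology) {
  stopifnot(inherits(rheology, "rheology_params"))
  rheology$tau_y
}

#' Effective dynamic viscosity
#'
#' Newtonian: the constant `mu_const`. Casson (default form):
#' `mu(J2) = [ (eta_bar^2 J2)^{1/4} + (tau_y/2)^{1/2} ]^2 * J2^{-1/2}`,
#' evaluated at `max(J2, J2_min)`, which is shear-thinning and tends to
#' `eta_bar` for large J2 and to the Newtonian limit `eta` when `H = 0`.
#'
#' @param J2 Second invariant of the strain-rate tensor (s^-2), `>= 0`;
#'   the shear rate is `2 * sqrt(J2)`.
#' @param rheology A [rheology_params()].
#' @return Dynamic viscosity (Pa s), vectorized over `J2`.
#' @export
effective_viscosity <- function(J2, rheology) {
  stopifnot(inherits(rheology, "rheology_params"))
  if (any(J2 < 0)) stop("J2 must be non-negative", call. = FALSE)
  if (rheology$model == "newtonian") {
    return(rep(rheology$mu_const, length(J2)))
  }
  J2r <- pmax(J2, rheology$J2_min)
  bracket <- (rheology$eta_bar^2 * J2r)^0.25 + sqrt(rheology$tau_y / 2)
  expo <- if (rheology$strict_paper) 0.5 else 2
  bracket^expo / sqrt(J2r)
}
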