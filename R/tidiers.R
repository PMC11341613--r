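#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a POD basis: one row per singular value
#'
#' @param x A `pod_basis`.
#' @param ... Unused.
#' @return Tibble with `mode`, `sv`, `energy` (fraction) and `cumulative`
#'   energy; `retained` flags the modes kept at the fitted threshold.
#' @method tidy pod_basis
#' @export
tidy.pod_basis <- function(x, ...) {
  frac <- x$sv^2 / sum(x$sv^2)
  tibble::tibble(mode = seq_along(x$sv), sv = x$sv, energy = frac,
                 cumulative = cumsum(frac),
                 retained = seq_along(x$sv) <= x$L)
}

#' One-row summary of a POD basis
#'
#' @param x A `pod_basis`.
#' @param ... Unused.
#' @return Tibble with `L`, `rank`, `eps` and the energy actually captured.
#' @method glance pod_basis
#' @export
glance.pod_basis <- function(x, ...) {
  tibble::tibble(L = x$L, rank = x$rank, eps = x$eps,
                 captured = x$energy[x$L])
}

#' Tidy an RBF model: one row per modal coefficient output
#'
#' @param x An `rbf_model`.
#' @param ... Unused.
#' @return Tibble with the weight norm and the moment-constraint residuals
#'   per output (both should be ~0 by construction).
#' @method tidy rbf_model
#' @export
tidy.rbf_model <- function(x, ...) {
  sum_w <- colSums(x$w)
  sum_wx <- crossprod(x$nodes, x$w) # d x L
  tibble::tibble(coefficient = seq_len(x$L),
                 weight_norm = sqrt(colSums(x$w^2)),
                 constraint_sum = abs(sum_w),
                 constraint_moment = apply(abs(sum_wx), 2, max))
}

#' One-row summary of an RBF model
#'
#' @param x An `rbf_model`.
#' @param ... Unused.
#' @return Tibble with node count, input dimension, kernel and shape.
#' @method glance rbf_model
#' @export
glance.rbf_model <- function(x, ...) {
  tibble::tibble(nodes = nrow(x$nodes), dim = x$d, outputs = x$L,
                 kernel = x$kernel, shape = x$shape)
}

#' Scree/energy plot for a POD basis
#'
#' @param object A `pod_basis`.
#' @param ... Unused.
#' @return A ggplot: singular-value spectrum with the retained modes marked.
#' @method autoplot pod_basis
#' @export
autoplot.pod_basis <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mode, y = .data$sv,
                                  colour = .data$retained)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mode", y = "singular value",
                  colour = sprintf("retained (eps = %g)", object$eps)) +
    ggplot2::theme_minimal()
}

#' Relative-error trace plot
#'
#' @param object An `error_report`.
#' @param ... Unused.
#' @return A ggplot of the relative error over the cycle (or a point for
#'   steady variables), with the time-averaged level as a reference line.
#' @method autoplot error_report
#' @export
autoplot.error_report <- function(object, ...) {
  m <- attr(object, "mean")
  if ("time" %in% names(object)) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$error)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = m, linetype = 2) +
      ggplot2::labs(x = "time (s)", y = "relative error") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = seq_len(nrow(object)),
                                         y = .data$error)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "case", y = "relative error") +
      ggplot2::theme_minimal()
  }
}

#' Plot a cell field on the mesh
#'
#' @param mesh An `fv_mesh`.
#' @param values Per-cell values.
#' @param name Legend title.
#' @return A ggplot raster of the chamber-and-pocket field.
#' @export
plot_field <- function(mesh, values, name = "value") {
  d <- tibble::tibble(x = mesh$cc_x, y = mesh$cc_y, value = values)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = name) +
    ggplot2::theme_minimal()
}

#' Plot the outlet waveform across scaling factors
#'
#' @param config A [case_config()].
#' @param f Scaling factors to overlay.
#' @return A ggplot of `Q(t; f)` over one period.
#' @export
plot_waveform <- function(config = case_config(), f = c(0.5, 1, 1.5)) {
  tt <- seq(0, config$period, length.out = 300)
  d <- do.call(rbind, lapply(f, function(fk) {
    tibble::tibble(t = tt, Q = mv_waveform(tt, fk, config), f = factor(fk))
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$Q,
                                  colour = .data$f)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "outlet flow rate (m²/s)",
                  colour = "f") +
    ggplot2::theme_minimal()
}
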