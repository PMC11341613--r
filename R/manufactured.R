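#' Manufactured smooth snapshot family
#'
#' A synthetic field family with known, smooth dependence on time and on the
#' physical parameters (scaling factor f, plasma viscosity eta, hematocrit
#' H): a small sum of fixed spatial modes whose coefficients vary smoothly
#' with `(t, mu)`. Used to exercise the POD-RBF pipeline end-to-end where the
#' exact parametric structure is known -- held-out-parameter error must
#' shrink as the training design is refined.
#'
#' @param n_h Number of spatial degrees of freedom.
#' @param times Snapshot times (s); use `NULL` for a steady family.
#' @param samples Tibble of design points with column `f` and optionally
#'   `eta`, `H`.
#' @param tail If `TRUE` (default), superimpose a slowly decaying series of
#'   fine spatial modes, giving the snapshot spectrum the gradual roll-off
#'   of genuine flow fields (the retained dimension then keeps growing at
#'   high energy thresholds). `FALSE` keeps only the four smooth core modes,
#'   the right target for convergence studies.
#' @param period Period used to phase the temporal factors (s).
#' @return A list of fields, one per design row: `n_h x length(times)`
#'   matrices, or length-`n_h` vectors if `times` is `NULL`.
#' @export
manufactured_snapshots <- function(n_h, times, samples, period = 1.07,
                                   tail = TRUE) {
  s <- seq(0, 1, length.out = n_h)
  g1 <- sin(pi * s)
  g2 <- cos(2 * pi * s)
  g3 <- s * (1 - s)
  g4 <- sin(3 * pi * s) * s
  lapply(seq_len(nrow(samples)), function(j) {
    f <- samples$f[j]
    et <- if ("eta" %in% names(samples)) samples$eta[j] / 1.6e-3 else 1
    H <- if ("H" %in% names(samples)) samples$H[j] / 45 else 1
    if (is.null(times)) {
      c1 <- f; c2 <- 0.4 * f^2 * H; c3 <- 0.6 * et * sqrt(f)
      c4 <- 0.2 * sin(2 * f) * H
      return(c1 * g1 + c2 * g2 + c3 * g3 + c4 * g4)
    }
    tt <- times / period
    out <- matrix(0, n_h, length(times))
    for (i in seq_along(tt)) {
      c1 <- f * (1 + 0.5 * sin(2 * pi * tt[i]))
      c2 <- 0.4 * f^2 * H * cos(2 * pi * tt[i])
      c3 <- 0.6 * et * tt[i]
      c4 <- 0.2 * sin(2 * f) * H * tt[i]^2
      out[, i] <- c1 * g1 + c2 * g2 + c3 * g3 + c4 * g4
      if (tail) {
        for (k in 5:12) {
          ck <- 0.3 / k * sin(2 * pi * k * tt[i] + k * f) * (0.5 + 0.5 * H)
          out[, i] <- out[, i] + ck * sin(k * pi * s)
        }
      }
    }
    out
  })
}
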