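#' Build the structured finite-volume mesh for a case
#'
#' Meshes the chamber-with-pocket geometry with a uniform Cartesian grid of
#' spacing `h`. Cells are squares (volume `h^2` per unit depth); faces are
#' axis-aligned, so the mesh is orthogonal and two-point flux approximations
#' are exact. The boundary is partitioned into patches: `n_inlets` inlet
#' segments, one outlet segment, and walls (everything else, including the
#' whole pocket rim). Pocket cells carry a region tag.
#'
#' @param config A [case_config()].
#' @return An object of class `fv_mesh`: cell centres/volumes/region tags,
#'   interior faces (owner, neighbour, unit normal owner -> neighbour, area,
#'   centre distance) and boundary faces (owner, outward unit normal, area,
#'   patch label, face centre, the second cell inward for one-sided wall
#'   gradients).
#' @export
build_mesh <- function(config) {
  stopifnot(inherits(config, "case_config"))
  h <- config$h
  nx <- config$nx; ny <- config$ny
  npx <- config$npx; npy <- config$npy
  ni <- nx + npx

  if (config$has_pocket) {
    j0 <- if (is.null(config$pocket_y0)) {
      round(0.7 * ny - npy / 2)
    } else round(config$pocket_y0 / h)
    j0 <- as.integer(j0)
    if (j0 < 0L || j0 + npy > ny) {
      stop("configuration error: pocket does not fit on the chamber wall",
           call. = FALSE)
    }
    if (config$inlet_side == "right" || config$outlet_side == "right") {
      stop("configuration error: right wall carries the pocket; place ",
           "inlet/outlet elsewhere", call. = FALSE)
    }
  } else j0 <- 0L

  # super-grid cell map: 0 = no cell
  cid <- matrix(0L, nrow = ni, ncol = ny)
  present <- function(i, j) {
    if (i < 1L || j < 1L || i > ni || j > ny) return(FALSE)
    cid[i, j] > 0L
  }
  k <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    k <- k + 1L; cid[i, j] <- k
  }
  if (npx > 0L) {
    for (j in (j0 + 1L):(j0 + npy)) for (i in (nx + 1L):(nx + npx)) {
      k <- k + 1L; cid[i, j] <- k
    }
  }
  n_cells <- k

  idx <- which(cid > 0L, arr.ind = TRUE)
  ord <- order(cid[cid > 0L])
  ii <- idx[ord, 1L]; jj <- idx[ord, 2L]
  cc_x <- (ii - 0.5) * h
  cc_y <- (jj - 0.5) * h
  region <- ifelse(ii > nx, "pocket", "chamber")

  # interior faces
  fo <- integer(0); fn <- integer(0); fnx <- numeric(0); fny <- numeric(0)
  # x-faces
  for (j in seq_len(ny)) for (i in seq_len(ni - 1L)) {
    if (cid[i, j] > 0L && cid[i + 1L, j] > 0L) {
      fo <- c(fo, cid[i, j]); fn <- c(fn, cid[i + 1L, j])
      fnx <- c(fnx, 1); fny <- c(fny, 0)
    }
  }
  # y-faces
  for (j in seq_len(ny - 1L)) for (i in seq_len(ni)) {
    if (cid[i, j] > 0L && cid[i, j + 1L] > 0L) {
      fo <- c(fo, cid[i, j]); fn <- c(fn, cid[i, j + 1L])
      fnx <- c(fnx, 0); fny <- c(fny, 1)
    }
  }

  # boundary faces
  bo <- integer(0); bnx <- numeric(0); bny <- numeric(0)
  bcx <- numeric(0); bcy <- numeric(0); bsec <- integer(0)
  dirs <- cbind(c(1, -1, 0, 0), c(0, 0, 1, -1))
  for (c_ in seq_len(n_cells)) {
    i <- ii[c_]; j <- jj[c_]
    for (d in 1:4) {
      di <- dirs[d, 1L]; dj <- dirs[d, 2L]
      if (!present(i + di, j + dj)) {
        bo <- c(bo, c_)
        bnx <- c(bnx, di); bny <- c(bny, dj)
        bcx <- c(bcx, cc_x[c_] + di * h / 2)
        bcy <- c(bcy, cc_y[c_] + dj * h / 2)
        bsec <- c(bsec, if (present(i - di, j - dj)) cid[i - di, j - dj] else 0L)
      }
    }
  }

  bpatch <- rep("wall", length(bo))
  assign_side <- function(side, frac, n_seg, labels) {
    # indices of boundary faces lying on the given chamber side
    onside <- switch(side,
      top    = which(bny == 1 & jj[bo] == ny & ii[bo] <= nx),
      bottom = which(bny == -1 & jj[bo] == 1L & ii[bo] <= nx),
      left   = which(bnx == -1 & ii[bo] == 1L),
      right  = which(bnx == 1 & ii[bo] == nx)
    )
    pos <- if (side %in% c("top", "bottom")) ii[bo[onside]] else jj[bo[onside]]
    onside <- onside[order(pos)]
    n_side <- length(onside)
    m <- max(1L, min(as.integer(round(frac * n_side / n_seg)),
                     n_side %/% n_seg))
    for (b in seq_len(n_seg)) {
      lo <- round((b - 1) * n_side / n_seg)
      hi <- round(b * n_side / n_seg)
      off <- (hi - lo - m) %/% 2
      sel <- onside[(lo + off + 1L):(lo + off + m)]
      bpatch[sel] <<- labels[b]
    }
  }
  inlet_patches <- paste0("inlet", seq_len(config$n_inlets))
  assign_side(config$inlet_side, config$inlet_frac, config$n_inlets,
              inlet_patches)
  assign_side(config$outlet_side, config$outlet_frac, 1L, "outlet")

  structure(list(
    n_cells = n_cells, h = h,
    cc_x = cc_x, cc_y = cc_y, vol = rep(h * h, n_cells),
    region = region, ci = ii, cj = jj, cid = cid, ni = ni, nj = ny,
    fo = fo, fn = fn, fnx = fnx, fny = fny,
    farea = rep(h, length(fo)), fd = rep(h, length(fo)),
    bo = bo, bnx = bnx, bny = bny, barea = rep(h, length(bo)),
    bpatch = bpatch, bcx = bcx, bcy = bcy, bsecond = bsec,
    bd = rep(h / 2, length(bo)),
    inlet_patches = inlet_patches,
    config = config
  ), class = "fv_mesh")
}

#' @export
print.fv_mesh <- function(x, ...) {
  cat("<fv_mesh>", x$n_cells, "cells (",
      sum(x$region == "pocket"), "in pocket ),",
      length(x$fo), "interior faces,", length(x$bo), "boundary faces\n")
  cat("  patches:", paste(sprintf("%s(%d)", names(table(x$bpatch)),
                                  table(x$bpatch)), collapse = " "), "\n")
  invisible(x)
}

#' Mesh integrity checks
#'
#' Verifies the closed-surface identity (outward boundary area vectors sum to
#' zero), unit normals, and that the patches partition the boundary.
#'
#' @param mesh An `fv_mesh`.
#' @return Invisibly `TRUE`; stops on violation.
#' @export
check_mesh <- function(mesh) {
  sx <- sum(mesh$bnx * mesh$barea)
  sy <- sum(mesh$bny * mesh$barea)
  if (max(abs(c(sx, sy))) > 1e-10) stop("mesh boundary is not closed")
  nrm2 <- mesh$bnx^2 + mesh$bny^2
  if (max(abs(nrm2 - 1)) > 1e-12) stop("boundary normals are not unit")
  nrm2i <- mesh$fnx^2 + mesh$fny^2
  if (max(abs(nrm2i - 1)) > 1e-12) stop("interior normals are not unit")
  known <- c(mesh$inlet_patches, "outlet", "wall")
  if (!all(mesh$bpatch %in% known)) stop("unknown patch label on boundary")
  invisible(TRUE)
}
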