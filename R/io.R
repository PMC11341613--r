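#' Read a plain-text key/value run configuration
#'
#' Lines of `key = value` (`#` comments allowed). Geometry/timing keys feed
#' [case_config()], solver keys feed [solver_config()], and the remaining
#' keys describe the parameter design and ROM settings. Unknown keys error.
#'
#' @param path Config file path.
#' @return A list with `case` (a `case_config`), `solver` (a
#'   `solver_config`) and `rom` (design + ROM settings).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, `[[`, "", 2))
  if (anyDuplicated(keys)) stop("duplicate config key: ",
                                keys[duplicated(keys)][1], call. = FALSE)
  parse_val <- function(v) {
    if (grepl(",", v)) return(as.numeric(strsplit(v, ",")[[1]]))
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  }
  cfg <- stats::setNames(lapply(vals, parse_val), keys)

  case_keys <- names(formals(case_config))
  solver_keys <- names(formals(solver_config))
  rom_keys <- c("n_samples", "seed", "eps", "kernel", "shape", "test_idx",
                "f_min", "f_max", "eta_min", "eta_max", "H_min", "H_max",
                "n_loops")
  unknown <- setdiff(names(cfg), c(case_keys, solver_keys, rom_keys))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  case <- do.call(case_config, cfg[intersect(names(cfg), case_keys)])
  solver <- do.call(solver_config, cfg[intersect(names(cfg), solver_keys)])
  rom <- cfg[intersect(names(cfg), rom_keys)]
  list(case = case, solver = solver, rom = rom)
}

#' Write a run configuration as plain text
#'
#' @param config A named list (flat keys) to serialize as `key = value`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  fmt <- vapply(config, function(v) paste(format(v, scientific = TRUE,
                                                 trim = TRUE),
                                          collapse = ","), "")
  writeLines(paste(names(config), "=", fmt), path)
  invisible(path)
}

#' Write cell fields to a legacy-ASCII VTK unstructured-grid file
#'
#' Quadrilateral cells from the structured mesh, with one `CELL_DATA` scalar
#' array per supplied field; readable by ParaView/VisIt-class viewers.
#'
#' @param path Output path (`.vtk`).
#' @param mesh An `fv_mesh`.
#' @param celldata Named list of per-cell numeric vectors.
#' @return Invisibly, `path`.
#' @export
write_vtk <- function(path, mesh, celldata = list()) {
  for (nm in names(celldata)) {
    if (length(celldata[[nm]]) != mesh$n_cells) {
      stop("field '", nm, "' length does not match the cell count",
           call. = FALSE)
    }
  }
  h <- mesh$h
  npx <- mesh$ni + 1L
  node_id <- function(i, j) (j - 1L) * npx + i # 1-based on (ni+1)x(nj+1)
  con <- matrix(0L, mesh$n_cells, 4L)
  for (c_ in seq_len(mesh$n_cells)) {
    i <- mesh$ci[c_]; j <- mesh$cj[c_]
    con[c_, ] <- c(node_id(i, j), node_id(i + 1L, j),
                   node_id(i + 1L, j + 1L), node_id(i, j + 1L))
  }
  n_nodes <- npx * (mesh$nj + 1L)
  xs <- rep((0:mesh$ni) * h, times = mesh$nj + 1L)
  ys <- rep((0:mesh$nj) * h, each = npx)
  num <- function(x) formatC(x, format = "g", digits = 9)
  out <- c(
    "# vtk DataFile Version 3.0",
    "hemorom fields", "ASCII", "DATASET UNSTRUCTURED_GRID",
    paste("POINTS", n_nodes, "double"),
    paste(num(xs), num(ys), "0"),
    paste("CELLS", mesh$n_cells, mesh$n_cells * 5L),
    paste(4L, con[, 1] - 1L, con[, 2] - 1L, con[, 3] - 1L, con[, 4] - 1L),
    paste("CELL_TYPES", mesh$n_cells),
    rep("9", mesh$n_cells)
  )
  if (length(celldata)) {
    out <- c(out, paste("CELL_DATA", mesh$n_cells))
    for (nm in names(celldata)) {
      out <- c(out,
               paste("SCALARS", nm, "double 1"),
               "LOOKUP_TABLE default",
               formatC(celldata[[nm]], format = "g", digits = 17))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read back CELL_DATA scalars from a legacy-ASCII VTK file
#'
#' Companion reader for [write_vtk()] output (round-trip checks and
#' post-processing).
#'
#' @param path A `.vtk` file written by [write_vtk()].
#' @return Named list of per-cell numeric vectors.
#' @export
read_vtk_celldata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cd <- grep("^CELL_DATA", lines)
  if (!length(cd)) return(list())
  n <- as.integer(strsplit(lines[cd], " ")[[1]][2])
  out <- list()
  i <- cd + 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], "SCALARS")) {
      nm <- strsplit(lines[i], " ")[[1]][2]
      vals <- as.numeric(lines[(i + 2L):(i + 1L + n)])
      out[[nm]] <- vals
      i <- i + 2L + n
    } else i <- i + 1L
  }
  out
}

#' Export snapshot fields and wall-index tables
#'
#' Writes each time-dependent field as one VTK file per snapshot
#' (`<prefix>_<var>_s<sample>_t<index>.vtk`), steady fields as a single
#' file, and any wall indices as tab-separated tables with one row per wall
#' face.
#'
#' @param fields Named list: matrices (cells x times) or vectors per cell.
#' @param mesh An `fv_mesh`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @param sample Sample index used in file names.
#' @param wall_indices Optional named list of `steady_index_field` tibbles.
#' @return Invisibly, the vector of paths written.
#' @export
export_fields <- function(fields, mesh, dir, prefix = "case", sample = 1L,
                          wall_indices = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (is.matrix(f) && ncol(f) > 1) {
      for (i in seq_len(ncol(f))) {
        p <- file.path(dir, sprintf("%s_%s_s%02d_t%03d.vtk",
                                    prefix, nm, sample, i))
        write_vtk(p, mesh, stats::setNames(list(f[, i]), nm))
        paths <- c(paths, p)
      }
    } else {
      p <- file.path(dir, sprintf("%s_%s_s%02d.vtk", prefix, nm, sample))
      write_vtk(p, mesh, stats::setNames(list(as.numeric(f)), nm))
      paths <- c(paths, p)
    }
  }
  for (nm in names(wall_indices)) {
    idx <- wall_indices[[nm]]
    p <- file.path(dir, sprintf("%s_%s_s%02d.tsv", prefix, nm, sample))
    tab <- data.frame(face = idx$face,
                      x = mesh$bcx[idx$face], y = mesh$bcy[idx$face],
                      value = idx$value)
    utils::write.table(tab, p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
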