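## File interfaces: YAML run configuration, legacy-VTK structured-points
## export of phantoms and solved fields, NIfTI-style voxel volumes
## (via RNifti when available), and CSV trial logs.

#' Read / write a phantom-and-montage configuration
#'
#' The YAML configuration carries explicit units (mm, S/m, A) and the
#' arguments of [build_layered_head()], [embed_eyes()], [attach_torso()]
#' and [place_montage()].
#'
#' @param path YAML file path.
#' @return for the reader: the configuration list.
#' @export
read_phantom_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(is.list(cfg))
  cfg
}

#' @rdname read_phantom_config
#' @param config configuration list.
#' @export
write_phantom_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build a phantom (and montage) from a configuration list
#'
#' @param config list as returned by [read_phantom_config()]; recognised
#'   blocks: `head` (radii_mm, tissues, spacing_mm), `eyes` (logical or
#'   argument list), `torso` (logical or argument list), `montage`
#'   (name, mode, current_A, ...).
#' @return a [voxel_phantom()].
#' @export
phantom_from_config <- function(config) {
  hd <- config$head
  if (is.null(hd)) stop("config has no 'head' block")
  ph <- do.call(build_layered_head, hd)
  if (!is.null(config$eyes) && !identical(config$eyes, FALSE)) {
    args <- if (is.list(config$eyes)) config$eyes else list()
    ph <- do.call(embed_eyes, c(list(ph), args))
  }
  if (!is.null(config$torso) && !identical(config$torso, FALSE)) {
    args <- if (is.list(config$torso)) config$torso else list()
    ph <- do.call(attach_torso, c(list(ph), args))
  }
  if (!is.null(config$montage)) {
    args <- config$montage
    nm <- args$name
    args$name <- NULL
    ph <- do.call(place_montage, c(list(ph, nm), args))
  }
  ph
}

#' Export a phantom or solution as a legacy VTK structured-points file
#'
#' Writes ASCII legacy VTK (STRUCTURED_POINTS). For a phantom, the tissue
#' labels are written as cell data. For a solution, the potential is written
#' as point data and the current-density vector and magnitude as cell data
#' (J in mA/m^2).
#'
#' @param x a [voxel_phantom()] or [simulate_montage()] result.
#' @param path output `.vtk` path.
#' @return invisibly, `path`.
#' @export
write_vtk <- function(x, path) {
  if (inherits(x, "tes_solution")) return(write_vtk_solution(x, path))
  if (!inherits(x, "voxel_phantom")) stop("unsupported object")
  d <- dim(x$labels)
  h <- x$spacing_mm
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "phosfem phantom", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1] + 1L, d[2] + 1L, d[3] + 1L),
               sprintf("ORIGIN %g %g %g", x$origin_mm[1], x$origin_mm[2],
                       x$origin_mm[3]),
               sprintf("SPACING %g %g %g", h, h, h),
               sprintf("CELL_DATA %d", prod(d)),
               "SCALARS tissue int 1", "LOOKUP_TABLE default"), con)
  writeLines(format_rows(as.vector(x$labels)), con)
  invisible(path)
}

format_rows <- function(v, per = 9L) {
  n <- length(v)
  idx <- split(seq_len(n), (seq_len(n) - 1L) %/% per)
  vapply(idx, function(i) paste(format(v[i], trim = TRUE), collapse = " "), "")
}

write_vtk_solution <- function(sol, path) {
  ph <- sol$system$phantom
  d <- dim(ph$labels)
  nd <- d + 1L
  h <- ph$spacing_mm
  phi <- numeric(prod(nd))
  act <- sol$system$node_index > 0L
  phi[act] <- sol$potential$node_potentials[sol$system$node_index[act]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "phosfem solution", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", nd[1], nd[2], nd[3]),
               sprintf("ORIGIN %g %g %g", ph$origin_mm[1], ph$origin_mm[2],
                       ph$origin_mm[3]),
               sprintf("SPACING %g %g %g", h, h, h),
               sprintf("POINT_DATA %d", prod(nd)),
               "SCALARS potential_V float 1", "LOOKUP_TABLE default"), con)
  writeLines(format_rows(signif(phi, 7)), con)
  writeLines(c(sprintf("CELL_DATA %d", prod(d)),
               "SCALARS Jmag_mA_m2 float 1", "LOOKUP_TABLE default"), con)
  writeLines(format_rows(signif(1000 * field_as_array(sol$field), 7)), con)
  writeLines("VECTORS J_mA_m2 float", con)
  jx <- 1000 * field_as_array(sol$field, "jx")
  jy <- 1000 * field_as_array(sol$field, "jy")
  jz <- 1000 * field_as_array(sol$field, "jz")
  m <- cbind(as.vector(jx), as.vector(jy), as.vector(jz))
  writeLines(apply(signif(m, 7), 1, paste, collapse = " "), con)
  invisible(path)
}

#' Write / read a phantom as a NIfTI voxel volume
#'
#' Uses the RNifti package (suggested dependency) with the voxel spacing in
#' the header; tissue names are not stored in the NIfTI and must be
#' supplied on reading.
#'
#' @param phantom a [voxel_phantom()].
#' @param path `.nii` / `.nii.gz` path.
#' @return invisibly `path` (writer); a [voxel_phantom()] (reader).
#' @export
write_phantom_nifti <- function(phantom, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("write_phantom_nifti() needs the RNifti package")
  img <- RNifti::asNifti(phantom$labels)
  RNifti::pixdim(img) <- rep(phantom$spacing_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_phantom_nifti
#' @param tissue_names tissue-name table of the stored labels.
#' @export
read_phantom_nifti <- function(path, tissue_names) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("read_phantom_nifti() needs the RNifti package")
  img <- RNifti::readNifti(path)
  h <- RNifti::pixdim(img)[1]
  arr <- array(as.integer(img), dim(img))
  voxel_phantom(arr, h, -dim(arr) / 2 * h, tissue_names)
}

#' Write staircase trial logs as CSV
#'
#' @param study a [simulate_study()] result run with `keep_logs = TRUE`.
#' @param path output CSV path.
#' @return invisibly `path`.
#' @export
write_trial_logs <- function(study, path) {
  if (is.null(study$logs)) stop("study was run without keep_logs = TRUE")
  rows <- list()
  for (i in seq_along(study$logs))
    for (mt in names(study$logs[[i]])) {
      lg <- study$logs[[i]][[mt]]
      lg$subject <- i
      lg$montage <- mt
      rows[[length(rows) + 1L]] <- lg
    }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
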