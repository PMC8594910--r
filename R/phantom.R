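#' Voxelized volume-conductor phantom
#'
#' A `voxel_phantom` is a labeled 3-D voxel grid with isotropic physical
#' spacing, the basic geometric container of the package. Label 0 is
#' non-conducting air; every nonzero label has a tissue name. Coordinates
#' follow the RAS convention (x right, y anterior, z superior), voxel
#' ownership is by center point, and grids built by [build_layered_head()]
#' are symmetric about the origin so that mirror-symmetric configurations
#' produce voxelwise mirror-symmetric phantoms.
#'
#' @param labels integer 3-D array of tissue ids (0 = air).
#' @param spacing_mm positive isotropic voxel edge length in mm.
#' @param origin_mm coordinates (mm) of the node at grid index (0,0,0),
#'   i.e. the outer corner of voxel (1,1,1).
#' @param tissue_names character vector of tissue names; `tissue_names[i]`
#'   names label id `i`.
#' @return An object of class `voxel_phantom`: a list with fields `labels`,
#'   `spacing_mm`, `origin_mm`, `tissue_names`, plus optional `landmarks`,
#'   `head_radius_mm`, `torso` and `montage` fields filled by the builder
#'   functions.
#' @export
voxel_phantom <- function(labels, spacing_mm, origin_mm, tissue_names) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0)
    stop("spacing_mm must be a positive scalar")
  if (length(origin_mm) != 3L) stop("origin_mm must be a 3-vector")
  ids <- sort(unique(as.integer(labels)))
  ids <- ids[ids > 0L]
  if (length(ids) && max(ids) > length(tissue_names))
    stop("label id ", max(ids), " has no tissue name")
  structure(
    list(labels = labels, spacing_mm = spacing_mm,
         origin_mm = as.numeric(origin_mm), tissue_names = tissue_names),
    class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat("voxel_phantom: ", paste(d, collapse = " x "),
      " voxels @ ", x$spacing_mm, " mm\n", sep = "")
  tab <- table(factor(x$labels[x$labels > 0L],
                      levels = seq_along(x$tissue_names),
                      labels = x$tissue_names))
  tab <- tab[tab > 0L]
  for (nm in names(tab))
    cat(sprintf("  %-14s %8d voxels\n", nm, tab[[nm]]))
  if (!is.null(x$montage))
    cat("  montage:", x$montage$name, sprintf("(%s)\n", x$montage$mode))
  invisible(x)
}

## --- small internal geometry helpers --------------------------------------

tissue_id <- function(phantom, name) {
  id <- match(name, phantom$tissue_names)
  if (is.na(id)) stop("phantom has no tissue named '", name, "'")
  id
}

ensure_tissue <- function(phantom, name) {
  id <- match(name, phantom$tissue_names)
  if (is.na(id)) {
    phantom$tissue_names <- c(phantom$tissue_names, name)
    id <- length(phantom$tissue_names)
  }
  list(phantom = phantom, id = as.integer(id))
}

axis_centers <- function(phantom) {
  d <- dim(phantom$labels)
  h <- phantom$spacing_mm
  o <- phantom$origin_mm
  list(x = o[1] + (seq_len(d[1]) - 0.5) * h,
       y = o[2] + (seq_len(d[2]) - 0.5) * h,
       z = o[3] + (seq_len(d[3]) - 0.5) * h)
}

## squared distance of every voxel center to a point, as an array
center_dist2 <- function(phantom, p) {
  ax <- axis_centers(phantom)
  dx2 <- (ax$x - p[1])^2
  dy2 <- (ax$y - p[2])^2
  dz2 <- (ax$z - p[3])^2
  d <- dim(phantom$labels)
  outer(outer(dx2, dy2, "+"), dz2, "+")
}

## shift a logical/integer array by one voxel along axis, padding with `fill`
shift_array <- function(a, axis, by, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  n <- d[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) { dst[[axis]] <- (1 + by):n; src[[axis]] <- 1:(n - by) }
  else if (by < 0) { dst[[axis]] <- 1:(n + by); src[[axis]] <- (1 - by):n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

## TRUE where `mask` has at least one face neighbor outside `mask`
## (neighbors beyond the grid count as outside)
boundary_of <- function(mask) {
  inside <- mask
  for (ax in 1:3) for (by in c(-1L, 1L))
    inside <- inside & shift_array(mask, ax, by, fill = FALSE)
  mask & !inside
}

## 6-connected flood fill over `mask` starting from `seed` (logical arrays)
flood_fill6 <- function(mask, seed) {
  reach <- seed & mask
  repeat {
    grown <- reach
    for (ax in 1:3) for (by in c(-1L, 1L))
      grown <- grown | shift_array(reach, ax, by, fill = FALSE)
    grown <- grown & mask
    if (!any(grown & !reach)) return(reach)
    reach <- grown
  }
}

## --- conductivity tables ----------------------------------------------------

#' Tissue conductivity tables
#'
#' Returns a named vector of isotropic tissue conductivities (S/m). Two
#' presets are shipped, matching the two volume-conductor parameterizations
#' evaluated by the pipeline: `"model1"` (the coarse "brain model": single
#' homogeneous eye compartment including the optic nerve, complete electrode
#' model with a 5 mm electrolyte layer of 1.5 S/m) and `"model2"` (the
#' detailed "retina model": separate vitreous/lens/aqueous/retina/sclera/
#' cornea/optic-nerve eye compartments and a 4 mm electrolyte layer of
#' 1.4 S/m, current injected as point loads on the outer electrode nodes).
#'
#' @param preset `"model1"` or `"model2"`.
#' @return Named numeric vector (S/m) of class `conductivity_table`.
#' @export
conductivity_preset <- function(preset = c("model2", "model1")) {
  preset <- match.arg(preset)
  sig <- switch(preset,
    model1 = c(scalp = 0.43, csf = 1.79, brain = 0.33, skull = 0.01,
               electrode = 1.5, eye = 0.4),
    model2 = c(white_matter = 0.14, gray_matter = 0.33, csf = 1.79,
               skull = 0.014, scalp = 0.33, vitreous = 1.55, lens = 0.32,
               aqueous = 1.8, retina = 0.7, sclera = 0.56, cornea = 0.5,
               optic_nerve = 0.03, muscle = 0.35, fat = 0.04,
               electrode = 1.4))
  structure(sig, class = c("conductivity_table", "numeric"))
}

#' Look up per-voxel conductivities
#'
#' @param phantom a [voxel_phantom()].
#' @param conductivities named numeric vector (S/m), e.g. from
#'   [conductivity_preset()]. Every labeled tissue present in the phantom
#'   must have an entry; all values must be positive.
#' @return numeric vector of conductivities for the labels `1..n_tissues`.
#' @keywords internal
tissue_sigma <- function(phantom, conductivities) {
  if (any(conductivities <= 0)) stop("all conductivities must be > 0")
  present <- sort(unique(as.integer(phantom$labels)))
  present <- present[present > 0L]
  sig <- rep(NA_real_, length(phantom$tissue_names))
  hit <- match(phantom$tissue_names, names(conductivities))
  sig[!is.na(hit)] <- conductivities[hit[!is.na(hit)]]
  missing <- present[is.na(sig[present])]
  if (length(missing))
    stop("no conductivity for tissue label(s): ",
         paste(phantom$tissue_names[missing], collapse = ", "))
  sig
}

## --- layered head -----------------------------------------------------------

#' Build a concentric-sphere layered head phantom
#'
#' Voxelizes concentric spherical shells (outer to inner) on a grid that is
#' symmetric about the origin. Voxels are assigned by center-point
#' membership: a voxel belongs to the outermost shell whose outer radius is
#' at least the distance of its center from the origin.
#'
#' @param radii_mm strictly decreasing outer radii of the shells (mm). The
#'   last entry bounds the innermost (solid) compartment.
#' @param tissues character vector of tissue names, one per shell,
#'   outer to inner (default scalp, skull, CSF, brain).
#' @param spacing_mm isotropic voxel size (mm); must not exceed the thinnest
#'   shell.
#' @param pad_mm air padding around the outer radius (room for electrode
#'   electrolyte layers).
#' @return a [voxel_phantom()] with `head_radius_mm` set.
#' @examples
#' ph <- build_layered_head(c(46, 43, 40), c("scalp", "skull", "brain"), 2)
#' @export
build_layered_head <- function(radii_mm,
                               tissues = c("scalp", "skull", "csf", "brain"),
                               spacing_mm = 2, pad_mm = 10) {
  if (any(diff(radii_mm) >= 0)) stop("radii must be strictly decreasing")
  if (length(radii_mm) != length(tissues))
    stop("need one tissue name per radius")
  thick <- -diff(radii_mm)
  if (length(thick) && any(thick < spacing_mm)) {
    bad <- which(thick < spacing_mm)[1]
    stop(sprintf(
      "shell '%s' (%.3g mm) is thinner than one voxel (%.3g mm)",
      tissues[bad], thick[bad], spacing_mm))
  }
  R <- radii_mm[1]
  half <- ceiling((R + pad_mm) / spacing_mm)
  n <- 2L * half
  origin <- rep(-half * spacing_mm, 3)
  ph <- voxel_phantom(array(0L, c(n, n, n)), spacing_mm, origin, tissues)
  d2 <- center_dist2(ph, c(0, 0, 0))
  lab <- array(0L, c(n, n, n))
  ## outermost first so inner shells overwrite
  for (i in seq_along(radii_mm))
    lab[d2 <= radii_mm[i]^2] <- i
  ph$labels <- lab
  ph$head_radius_mm <- R
  ph
}

## --- eyes -------------------------------------------------------------------

#' Embed spherical eyes into a head phantom
#'
#' Places mirror-symmetric spherical eyeballs about the midsagittal plane.
#' With `compartments = "model2"` each eye gets an outer shell split into
#' sclera (anterior), cornea (a cap around the optic axis) and retina (the
#' outer element layer of the posterior semi-shell, behind the equatorial
#' plane normal to the optic axis), a vitreous interior, an anterior
#' aqueous gap, a lens, and an optic-nerve cylinder running from the
#' posterior pole toward the brain center. With `compartments = "model1"`
#' the whole eyeball and the optic nerve are a single homogeneous `"eye"`
#' tissue.
#'
#' Skull voxels within `orbit_margin_mm` of the eyeball are relabeled to a
#' periorbital tissue (fat for model 2, scalp for model 1) so that the eye
#' is enclosed by conducting scalp-or-orbit tissue; set
#' `carve_orbit = FALSE` to instead treat an eye/skull overlap as an error.
#'
#' @param phantom head phantom from [build_layered_head()].
#' @param eye_center_mm center of the *right* eye (mm); the left eye is its
#'   mirror image. Default scales `(30.6, 65.6, -19.4)` with the head
#'   radius: 75 mm from the center, 15 degrees below the 10/20 equator so
#'   that Fp2 sits above the orbit and So below it (interpupillary distance
#'   61 mm on a 92 mm head).
#' @param eye_radius_mm eyeball radius (mm), default 12 scaled likewise.
#' @param compartments `"model2"` (full compartments) or `"model1"`.
#' @param optic_axis unit vector of the optic axis (default anterior).
#' @param carve_orbit relabel skull near the eye to periorbital tissue.
#' @param orbit_margin_mm carving margin beyond the eyeball surface.
#' @param orbit_depth_mm radial depth of the retrobulbar fat cone behind the
#'   eyeball (detailed-compartment mode only).
#' @param nerve_radius_mm,nerve_length_mm optic-nerve cylinder geometry.
#' @return the phantom with eye compartments added and field `eyes`
#'   recording centers, radius and axis.
#' @export
embed_eyes <- function(phantom, eye_center_mm = NULL, eye_radius_mm = NULL,
                       compartments = c("model2", "model1"),
                       optic_axis = c(0, 1, 0),
                       carve_orbit = TRUE, orbit_margin_mm = 3,
                       orbit_depth_mm = 10,
                       nerve_radius_mm = 2, nerve_length_mm = 25) {
  compartments <- match.arg(compartments)
  R <- phantom$head_radius_mm
  if (is.null(R)) stop("phantom has no head radius; build it with build_layered_head()")
  sc <- R / 92
  ## default right-eye center: 25 deg lateral azimuth, 15 deg below the
  ## 10/20 equator (the forehead Fp2 patch sits above the orbit, So below),
  ## 75 mm from the head center: interpupillary distance ~61 mm
  if (is.null(eye_center_mm)) eye_center_mm <- sc * c(30.6, 65.6, -19.4)
  if (is.null(eye_radius_mm)) eye_radius_mm <- sc * 12
  r <- eye_radius_mm
  a <- optic_axis / sqrt(sum(optic_axis^2))
  if (!all(is.finite(a))) stop("degenerate optic axis")
  cr <- as.numeric(eye_center_mm)
  if (sqrt(sum(cr^2)) + r > R)
    stop("eye sphere does not fit inside the scalp surface")

  h <- phantom$spacing_mm
  skull <- match("skull", phantom$tissue_names)
  names_needed <- if (compartments == "model2")
    c("sclera", "retina", "cornea", "vitreous", "aqueous", "lens",
      "optic_nerve", "fat") else c("eye", "scalp")
  for (nm in names_needed) {
    tmp <- ensure_tissue(phantom, nm); phantom <- tmp$phantom
  }
  id <- function(nm) match(nm, phantom$tissue_names)

  skull_safe <- if (is.na(skull)) -1L else skull
  place_one <- function(ph, ctr) {
    d2 <- center_dist2(ph, ctr)
    eye <- d2 <= r^2
    if (!is.na(skull)) {
      if (any(eye & ph$labels == skull)) {
        if (!carve_orbit) stop("eye sphere intersects the skull shell")
      }
      if (carve_orbit) {
        orbit <- d2 <= (r + orbit_margin_mm)^2 & ph$labels == skull
        ph$labels[orbit] <- if (compartments == "model2")
          id("fat") else id("scalp")
        if (any(eye & ph$labels == skull))
          stop("eye sphere intersects the skull shell")
      }
    }
    ax <- axis_centers(ph)
    d <- dim(ph$labels)
    ## signed distance of voxel centers along the optic axis, from eye center
    qa <- outer(outer((ax$x - ctr[1]) * a[1], (ax$y - ctr[2]) * a[2], "+"),
                (ax$z - ctr[3]) * a[3], "+")
    if (compartments == "model1") {
      ph$labels[eye] <- id("eye")
    } else {
      outer_layer <- boundary_of(eye)
      interior <- eye & !outer_layer
      ## outer layer: cornea cap (<= 40 deg of optic axis), retina on the
      ## posterior semi-shell, sclera on the remaining anterior half
      cosang <- qa / sqrt(pmax(d2, .Machine$double.eps))
      post <- qa < 0
      ph$labels[outer_layer & post] <- id("retina")
      ph$labels[outer_layer & !post & cosang >= cos(40 * pi / 180)] <- id("cornea")
      ph$labels[outer_layer & !post & cosang < cos(40 * pi / 180)] <- id("sclera")
      ## interior: lens ball ahead of center, aqueous gap behind the cornea,
      ## vitreous fills the rest (the whole posterior interior)
      lens <- center_dist2(ph, ctr + 5 * a) <= 4.5^2
      ph$labels[interior] <- id("vitreous")
      ph$labels[interior & qa >= 6.5] <- id("aqueous")
      ph$labels[interior & lens] <- id("lens")
      ## retrobulbar orbital fat: the low-conductivity cone that embeds the
      ## eyeball and optic nerve in the bony orbit; it insulates the
      ## posterior globe so that orbit-entering current leaves through the
      ## retina/sclera rather than diffusely into the brain compartment
      behind <- d2 > r^2 & d2 <= (r + orbit_depth_mm)^2 & qa < 0 &
        ph$labels > 0L & ph$labels != skull_safe
      ph$labels[behind] <- id("fat")
    }
    ## optic nerve: cylinder from the posterior pole toward the head center
    pole <- ctr - r * a
    ndir <- -pole / sqrt(sum(pole^2))
    px <- outer(outer((ax$x - pole[1]) * ndir[1],
                      (ax$y - pole[2]) * ndir[2], "+"),
                (ax$z - pole[3]) * ndir[3], "+")
    dp2 <- center_dist2(ph, pole)
    rad2 <- dp2 - px^2
    nerve <- px >= -h / 2 & px <= nerve_length_mm &
      rad2 <= nerve_radius_mm^2 & ph$labels > 0L
    ph$labels[nerve] <- if (compartments == "model1") id("eye") else id("optic_nerve")
    ph
  }

  phantom <- place_one(phantom, cr)
  phantom <- place_one(phantom, c(-cr[1], cr[2], cr[3]))

  ## enclosure invariant: no eye-compartment voxel may touch air
  eye_ids <- stats::na.omit(match(setdiff(names_needed, c("fat", "scalp")),
                                  phantom$tissue_names))
  eyemask <- array(phantom$labels %in% eye_ids, dim(phantom$labels))
  airnb <- array(FALSE, dim(phantom$labels))
  air <- phantom$labels == 0L
  for (axi in 1:3) for (by in c(-1L, 1L))
    airnb <- airnb | shift_array(air, axi, by, fill = TRUE)
  if (any(eyemask & airnb))
    stop("eye compartment touches air; increase scalp cover or head radius")

  phantom$eyes <- list(center_right = cr,
                       center_left = c(-cr[1], cr[2], cr[3]),
                       radius_mm = r, axis = a, compartments = compartments)
  phantom
}

## --- torso ------------------------------------------------------------------

#' Attach a cylindrical torso below the head
#'
#' Adds a neck and a homogeneous torso cylinder (labeled with the
#' scalp-conductivity tissue, following the convention that the trunk is
#' modeled as skin) so that a shoulder electrode can be placed. The grid is
#' grown as needed; symmetry about the midsagittal plane is preserved.
#' `length_mm = 0` returns the phantom unchanged.
#'
#' @param phantom head phantom.
#' @param length_mm torso cylinder length (mm).
#' @param radius_mm torso cylinder radius (mm).
#' @param neck_radius_mm,neck_length_mm neck cylinder geometry.
#' @param tissue tissue name used for neck and torso (default `"scalp"`).
#' @return phantom with `torso` metadata and an `rS` (right shoulder)
#'   landmark.
#' @export
attach_torso <- function(phantom, length_mm = 140, radius_mm = 70,
                         neck_radius_mm = 25, neck_length_mm = 15,
                         tissue = "scalp") {
  if (length_mm == 0) return(phantom)
  R <- phantom$head_radius_mm
  if (is.null(R)) stop("phantom has no head radius")
  h <- phantom$spacing_mm
  tmp <- ensure_tissue(phantom, tissue); phantom <- tmp$phantom
  tid <- tmp$id

  z_neck_top <- -0.8 * R            # inside the head ball: overlap guaranteed
  z_torso_top <- -(R + neck_length_mm)
  z_bottom <- z_torso_top - length_mm

  ## grow grid: downward in z, symmetric in x/y if the torso is wider
  d <- dim(phantom$labels)
  o <- phantom$origin_mm
  pad <- 4 * h
  need_half <- ceiling((radius_mm + pad) / h)
  half_x <- d[1] / 2
  new_half <- max(half_x, need_half)
  nz_extra <- max(0L, ceiling((o[3] - (z_bottom - pad)) / h))
  nxy <- 2L * new_half
  newd <- c(nxy, nxy, d[3] + nz_extra)
  lab <- array(0L, newd)
  offxy <- new_half - half_x
  lab[(offxy + 1):(offxy + d[1]), (offxy + 1):(offxy + d[2]),
      (nz_extra + 1):(nz_extra + d[3])] <- phantom$labels
  phantom$labels <- lab
  phantom$origin_mm <- c(-new_half * h, -new_half * h, o[3] - nz_extra * h)

  ax <- axis_centers(phantom)
  rho2 <- outer(ax$x^2, ax$y^2, "+")
  for (k in seq_along(ax$z)) {
    z <- ax$z[k]
    sl <- phantom$labels[, , k]
    if (z <= z_neck_top && z > z_torso_top)
      sl[rho2 <= neck_radius_mm^2 & sl == 0L] <- tid
    if (z <= z_torso_top && z >= z_bottom)
      sl[rho2 <= radius_mm^2 & sl == 0L] <- tid
    phantom$labels[, , k] <- sl
  }

  ## connectivity check: everything conducting must be one component
  cond <- phantom$labels > 0L
  seed <- array(FALSE, dim(cond))
  ctr <- round(dim(cond) / 2)
  seed[ctr[1], ctr[2], which.min(abs(ax$z))] <- TRUE
  seed <- seed & cond
  if (!any(seed)) stop("no conducting voxel at head center")
  reach <- flood_fill6(cond, seed)
  if (any(cond & !reach))
    stop("torso is disconnected from the head")

  phantom$torso <- list(radius_mm = radius_mm, length_mm = length_mm,
                        z_top = z_torso_top, z_bottom = z_bottom,
                        tissue = tissue)
  if (is.null(phantom$landmarks)) phantom$landmarks <- list()
  ## anchor low enough that a 30 mm patch stays on the lateral surface
  phantom$landmarks$rS <- c(radius_mm, 0, z_torso_top - 18)
  phantom
}
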