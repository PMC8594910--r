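## Regions of interest over the phantom and current-density summaries:
## eye-surface and retina ROIs, geometric stand-ins for the occipital
## cortex (posterior brain cap) and the lateral geniculate nucleus (small
## central-posterior ball), retinal topographic sector maps, and
## electrode-to-target distances.

#' Build the standard ROI set of a phantom
#'
#' ROIs (element/voxel id sets): right/left eye surface (outer element layer
#' of each eyeball, optic nerve excluded), right/left retina (the
#' retina-labeled posterior semi-shell for the detailed eye model; for the
#' homogeneous eye, the posterior half of the eye-surface layer), right/left
#' occipital cortex (brain voxels in a posterior spherical cap, default 30
#' degree half-angle, outer 25% of the brain radius) and right/left LGN
#' (5 mm ball at +/-12 mm lateral, central-posterior). The anatomical ROIs
#' of a real head cannot be transferred to a sphere phantom; these geometric
#' stand-ins are fixed, documented rules.
#'
#' @param phantom phantom with embedded eyes ([embed_eyes()]).
#' @param oc_half_angle_deg half-angle of the occipital cap.
#' @param lgn_center_mm center of the right LGN ball (left is mirrored).
#' @param lgn_radius_mm LGN ball radius.
#' @return object of class `roi_set`: named list of voxel-id vectors with a
#'   `provenance` attribute describing the geometric rules.
#' @export
build_rois <- function(phantom, oc_half_angle_deg = 30,
                       lgn_center_mm = c(12, -15, 0), lgn_radius_mm = 5) {
  if (is.null(phantom$eyes)) stop("phantom has no eyes; call embed_eyes()")
  lab <- phantom$labels
  nm <- phantom$tissue_names
  brain_ids <- stats::na.omit(match(c("brain", "gray_matter", "white_matter"), nm))
  if (!length(brain_ids)) stop("phantom has no brain tissue")
  eye <- phantom$eyes
  model2 <- eye$compartments == "model2"
  eye_tissues <- if (model2)
    c("sclera", "retina", "cornea", "vitreous", "aqueous", "lens")
  else "eye"
  eye_ids <- stats::na.omit(match(eye_tissues, nm))
  if (!length(eye_ids)) stop("phantom has no eye tissue")
  nerve_id <- match(if (model2) "optic_nerve" else "eye", nm)

  d <- dim(lab)
  ax <- axis_centers(phantom)

  eyeball_mask <- function(ctr) {
    ## eyeball proper: eye-tissue voxels within the eye sphere (excludes the
    ## optic nerve, which extends beyond it; for model 1 the nerve shares the
    ## eye label, so the sphere cut is what separates them)
    d2 <- center_dist2(phantom, ctr)
    array(lab %in% eye_ids, d) & d2 <= (eye$radius_mm + 1e-9)^2
  }
  side <- function(suffix, ctr) {
    ball <- eyeball_mask(ctr)
    surf <- boundary_of(ball)
    ## posterior semi-shell: behind the equatorial plane normal to the axis
    qa <- outer(outer((ax$x - ctr[1]) * eye$axis[1],
                      (ax$y - ctr[2]) * eye$axis[2], "+"),
                (ax$z - ctr[3]) * eye$axis[3], "+")
    post <- surf & qa < 0
    retina <- if (model2) which(post & lab == match("retina", nm)) else which(post)
    out <- list(which(surf), retina)
    names(out) <- paste0(c("eye_surface_", "retina_"), suffix)
    out
  }
  rois <- c(side("right", eye$center_right), side("left", eye$center_left))

  ## occipital cap: brain voxels within the cone about the occipital pole
  ## (posterior, -y) and in the outer quarter of the brain radius
  brain <- array(lab %in% brain_ids, d)
  r2 <- center_dist2(phantom, c(0, 0, 0))
  rmax <- sqrt(max(r2[brain]))
  yy <- array(rep(ax$y, each = d[1]), d)
  xx <- array(ax$x, d)
  cosoc <- -yy / sqrt(pmax(r2, .Machine$double.eps))
  cap <- brain & cosoc >= cos(oc_half_angle_deg * pi / 180) &
    sqrt(r2) >= 0.75 * rmax
  rois$oc_right <- which(cap & xx > 0)
  rois$oc_left <- which(cap & xx <= 0)

  lgnc <- as.numeric(lgn_center_mm)
  rois$lgn_right <- which(brain & center_dist2(phantom, lgnc) <= lgn_radius_mm^2)
  rois$lgn_left <- which(brain &
    center_dist2(phantom, c(-lgnc[1], lgnc[2], lgnc[3])) <= lgn_radius_mm^2)

  empty <- names(rois)[vapply(rois, length, 1L) == 0L]
  if (length(empty))
    stop("empty ROI(s): ", paste(empty, collapse = ", "),
         " (resolution too coarse?)")
  structure(rois, class = "roi_set", provenance = c(
    eye_surface = "outer element layer of the eyeball (optic nerve excluded)",
    retina = "outer element layer of the posterior semi-shell",
    oc = sprintf("brain voxels in a posterior cap (%g deg half-angle, outer 25%% radius)",
                 oc_half_angle_deg),
    lgn = sprintf("%g mm ball at (+/-%g, %g, %g) mm", lgn_radius_mm,
                  lgnc[1], lgnc[2], lgnc[3])))
}

#' Mean current-density magnitude over an ROI
#'
#' Volume-weighted mean of the element |J| over the ROI; with uniform cubic
#' voxels this is the arithmetic mean. Reported in mA/m^2.
#'
#' @param field a [current_density()] result.
#' @param roi vector of voxel ids (one entry of a [build_rois()] set).
#' @return mean |J| in mA/m^2.
#' @export
mean_current_density <- function(field, roi) {
  if (!length(roi)) stop("empty ROI")
  idx <- match(roi, field$voxels)
  if (anyNA(idx)) stop("ROI contains non-conducting voxels")
  1000 * mean(field$magnitude[idx])
}

#' Retinal topographic sector map
#'
#' Bins the retina ROI into 4 quadrants (about the optic axis, using the
#' head's superior and right directions) x 2 eccentricity rings (central:
#' polar angle from the posterior pole <= `central_deg`; peripheral
#' otherwise) and averages |J| per sector. The visual-field convention
#' flips both quadrant axes (the retinal lower-left quadrant maps to the
#' upper-right visual field).
#'
#' @param field a [current_density()] result.
#' @param phantom the phantom the field was solved on.
#' @param retina_roi voxel ids of one retina ROI.
#' @param eye_center_mm center of that eye.
#' @param optic_axis optic axis (defaults to the phantom's).
#' @param central_deg central/peripheral boundary (degrees from the
#'   posterior pole).
#' @param convention `"retinal"` or `"visual_field"`.
#' @return object of class `retinal_map`: `mean` and `n` matrices
#'   (2 eccentricity rows x 4 quadrant columns, mA/m^2), `convention`.
#' @export
retinal_topographic_map <- function(field, phantom, retina_roi,
                                    eye_center_mm = phantom$eyes$center_right,
                                    optic_axis = phantom$eyes$axis,
                                    central_deg = 30,
                                    convention = c("retinal", "visual_field")) {
  convention <- match.arg(convention)
  a <- optic_axis / sqrt(sum(optic_axis^2))
  if (!all(is.finite(a))) stop("degenerate optic axis")
  if (!length(retina_roi)) stop("empty retina ROI")
  idx <- match(retina_roi, field$voxels)
  if (anyNA(idx)) stop("retina ROI not covered by the field")
  mag <- 1000 * field$magnitude[idx]

  d <- dim(phantom$labels)
  v0 <- retina_roi - 1L
  ax <- axis_centers(phantom)
  p <- cbind(ax$x[v0 %% d[1] + 1L],
             ax$y[(v0 %/% d[1]) %% d[2] + 1L],
             ax$z[v0 %/% (d[1] * d[2]) + 1L])
  q <- sweep(p, 2, eye_center_mm)
  ## polar angle from the posterior pole direction (-a)
  qn <- sqrt(rowSums(q^2))
  cospol <- as.vector(q %*% (-a)) / qn
  polar <- acos(pmin(1, pmax(-1, cospol))) * 180 / pi
  ring <- ifelse(polar <= central_deg, "central", "peripheral")
  ## quadrants in the plane normal to the axis, head axes: x right, z up
  right <- c(1, 0, 0) - sum(c(1, 0, 0) * a) * a
  up <- c(0, 0, 1) - sum(c(0, 0, 1) * a) * a
  xr <- as.vector(q %*% right)
  zu <- as.vector(q %*% up)
  quad <- ifelse(zu >= 0,
                 ifelse(xr >= 0, "upper_right", "upper_left"),
                 ifelse(xr >= 0, "lower_right", "lower_left"))
  if (convention == "visual_field") {
    flip <- c(upper_right = "lower_left", upper_left = "lower_right",
              lower_right = "upper_left", lower_left = "upper_right")
    quad <- flip[quad]
  }
  rings <- c("central", "peripheral")
  quads <- c("upper_left", "upper_right", "lower_left", "lower_right")
  mn <- matrix(NA_real_, 2, 4, dimnames = list(rings, quads))
  cnt <- matrix(0L, 2, 4, dimnames = list(rings, quads))
  for (r in rings) for (qd in quads) {
    sel <- ring == r & quad == qd
    cnt[r, qd] <- sum(sel)
    if (any(sel)) mn[r, qd] <- mean(mag[sel])
  }
  structure(list(mean = mn, n = cnt, convention = convention,
                 central_deg = central_deg), class = "retinal_map")
}

#' @export
print.retinal_map <- function(x, ...) {
  cat("retinal_map (", x$convention, " convention, mA/m^2):\n", sep = "")
  print(round(x$mean, 2))
  invisible(x)
}

#' Average electrode distance to the eye and the occipital cortex
#'
#' Mean of the two electrode-patch centroid Euclidean distances to the
#' right-eye center and to the occipital-cortex ROI centroid, in cm (the
#' montage-level surrogate used by the distance analysis).
#'
#' @param phantom phantom with a placed montage and eyes.
#' @param montage montage spec (default: the phantom's).
#' @param rois optional [build_rois()] result (for the OC centroid).
#' @return named vector `c(eye_cm =, oc_cm =)`.
#' @export
electrode_eye_distances <- function(phantom, montage = phantom$montage,
                                    rois = NULL) {
  if (is.null(montage)) stop("no montage placed")
  if (is.null(phantom$eyes)) stop("phantom has no eyes")
  if (is.null(rois)) rois <- build_rois(phantom)
  d <- dim(phantom$labels)
  ax <- axis_centers(phantom)
  centroid <- function(vox) {
    v0 <- vox - 1L
    c(mean(ax$x[v0 %% d[1] + 1L]),
      mean(ax$y[(v0 %/% d[1]) %% d[2] + 1L]),
      mean(ax$z[v0 %/% (d[1] * d[2]) + 1L]))
  }
  oc_centroid <- centroid(c(rois$oc_right, rois$oc_left))
  eye_ctr <- phantom$eyes$center_right
  pdist <- vapply(montage$patches, function(p) {
    pc <- centroid(p$footprint_voxels)
    c(eye = sqrt(sum((pc - eye_ctr)^2)), oc = sqrt(sum((pc - oc_centroid)^2)))
  }, c(eye = 0, oc = 0))
  c(eye_cm = mean(pdist["eye", ]) / 10, oc_cm = mean(pdist["oc", ]) / 10)
}

#' Montage x ROI current-density summary table
#'
#' @param solutions named list of [simulate_montage()] results (one per
#'   montage).
#' @param rois a [build_rois()] set (same phantom geometry for all).
#' @return data.frame: montage, ROI means in mA/m^2 and mA/m^2 per mA.
#' @export
roi_summary_table <- function(solutions, rois) {
  rows <- lapply(names(solutions), function(nm) {
    sol <- solutions[[nm]]
    means <- vapply(rois, function(r) mean_current_density(sol$field, r), 0)
    I_mA <- 1000 * sol$montage$current_A
    out <- data.frame(montage = nm, roi = names(rois),
                      mean_mA_m2 = as.numeric(means),
                      mean_mA_m2_per_mA = as.numeric(means) / I_mA)
    out
  })
  do.call(rbind, rows)
}
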