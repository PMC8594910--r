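#' 10/20-style electrode positions used by the package
#'
#' Fixed spherical angles (degrees) for the supported scalp positions:
#' `inclination` is measured from the vertex (Cz), `azimuth` from the
#' anterior midline, positive toward the right. The circumferential ring
#' electrodes sit at 90 deg inclination with the standard 10/20 spacing
#' (Fp2 at 18 deg, F8 at 54 deg, O2 at 162 deg, mirrored on the left).
#' `So` (suborbital right) sits 25 deg below the Fp2 meridian point; `rS`
#' (right shoulder) is a landmark on the torso and needs [attach_torso()].
#'
#' @return data.frame with columns `label`, `inclination_deg`, `azimuth_deg`.
#' @export
montage_positions <- function() {
  data.frame(
    label = c("Cz", "Fpz", "Fp1", "Fp2", "F7", "F8", "T7", "T8",
              "O1", "O2", "Oz", "So"),
    inclination_deg = c(0, 90, 90, 90, 90, 90, 90, 90, 90, 90, 90, 115),
    azimuth_deg = c(0, 0, -18, 18, -54, 54, -90, 90, -162, 162, 180, 18),
    stringsAsFactors = FALSE)
}

position_direction <- function(label) {
  tab <- montage_positions()
  i <- match(label, tab$label)
  if (is.na(i)) stop("unknown 10/20 position label '", label, "'")
  inc <- tab$inclination_deg[i] * pi / 180
  az <- tab$azimuth_deg[i] * pi / 180
  c(sin(inc) * sin(az), sin(inc) * cos(az), cos(inc))
}

## node-grid indexing: node (i,j,k) is 0-based; voxel (vi,vj,vk) is 1-based
node_dims <- function(phantom) dim(phantom$labels) + 1L

node_lin_id <- function(nd, i, j, k) 1L + i + nd[1] * (j + nd[2] * k)

#' Coordinates of mesh nodes (mm)
#' @param phantom a voxel phantom
#' @param ids node linear ids (1-based, column-major over the node grid)
#' @return matrix `length(ids)` x 3 of node coordinates in mm
#' @export
node_coords <- function(phantom, ids) {
  nd <- node_dims(phantom)
  id0 <- ids - 1L
  i <- id0 %% nd[1]
  j <- (id0 %/% nd[1]) %% nd[2]
  k <- id0 %/% (nd[1] * nd[2])
  h <- phantom$spacing_mm
  cbind(phantom$origin_mm[1] + i * h,
        phantom$origin_mm[2] + j * h,
        phantom$origin_mm[3] + k * h)
}

## node ids of one face (perpendicular to `axis`, on side `side` in 0/1)
## of voxel linear ids `vox`
voxel_face_nodes <- function(phantom, vox, axis, side) {
  d <- dim(phantom$labels)
  nd <- node_dims(phantom)
  v0 <- vox - 1L
  vi <- v0 %% d[1]
  vj <- (v0 %/% d[1]) %% d[2]
  vk <- v0 %/% (d[1] * d[2])
  corners <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  out <- matrix(0L, length(vox), 4L)
  for (ci in seq_along(corners)) {
    dd <- corners[[ci]]
    off <- switch(axis,
                  cbind(side, dd[1], dd[2]),
                  cbind(dd[1], side, dd[2]),
                  cbind(dd[1], dd[2], side))
    out[, ci] <- node_lin_id(nd, vi + off[, 1], vj + off[, 2], vk + off[, 3])
  }
  out
}

## exposed faces of the voxels in `mask` (faces adjacent to air / grid edge):
## returns list(vox =, axis =, side =, normal_sign =)
exposed_faces <- function(phantom, mask) {
  air <- phantom$labels == 0L
  res <- list(vox = integer(0), axis = integer(0), side = integer(0))
  for (axi in 1:3) for (by in c(-1L, 1L)) {
    nb_air <- shift_array(air, axi, -by, fill = TRUE)   # neighbor at +by is air
    hit <- which(mask & nb_air)
    if (length(hit)) {
      res$vox <- c(res$vox, hit)
      res$axis <- c(res$axis, rep(axi, length(hit)))
      res$side <- c(res$side, rep(if (by > 0) 1L else 0L, length(hit)))
    }
  }
  res
}

## geodesic square footprint selection on the head sphere
geodesic_uv <- function(points, direction, radius) {
  d <- direction
  up <- c(0, 0, 1)
  e1 <- up - sum(up * d) * d
  if (sqrt(sum(e1^2)) < 1e-6) e1 <- c(0, 1, 0) - sum(c(0, 1, 0) * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  nrm <- sqrt(rowSums(points^2))
  ph <- points / nrm
  cosg <- pmin(1, pmax(-1, ph %*% d))
  gam <- acos(cosg)
  t <- ph - as.vector(cosg) %*% t(d)
  tn <- sqrt(rowSums(t^2))
  tn[tn < 1e-12] <- 1
  t <- t / tn
  u <- radius * gam * (t %*% e1)
  v <- radius * gam * (t %*% e2)
  cbind(as.vector(u), as.vector(v))
}

#' Place a two-electrode montage on a phantom
#'
#' Selects a geodesic square patch (about 30 x 30 mm by default) of surface
#' voxels around each electrode position, adds an electrolyte layer of the
#' mode's default thickness on top of the surface (labeled `"electrode"`),
#' and records the patch contact nodes. Named montages follow the study
#' montage list (`"Fp2-So"`, `"Fp2-rS"`, `"Fp2-Cz"`, `"Fp2-O2"`, `"So-rS"`,
#' `"Cz-F8"`, `"F7-F8"`); any `"A-B"` pair of known position labels works.
#'
#' The montage (an object of class `montage_spec`) is stored in the returned
#' phantom as `$montage`; the first patch is the current source, the second
#' the sink.
#'
#' @param phantom a [voxel_phantom()] (with torso when `rS` is used).
#' @param montage montage name, `"A-B"`.
#' @param mode `"neumann"` (point loads equally distributed over the outer
#'   electrode nodes) or `"complete_electrode"` (contact impedance layer and
#'   one auxiliary potential per electrode).
#' @param current_A injected current (amperes); source = first patch.
#' @param thickness_mm electrolyte thickness; defaults to 4 mm for
#'   `"neumann"` and 5 mm for `"complete_electrode"`.
#' @param halfwidth_mm half edge length of the geodesic square patch (mm).
#' @param contact_impedance_ohm lumped electrode impedance (ohm), used in
#'   complete-electrode mode; the surface impedance is
#'   `contact_impedance_ohm * patch area`.
#' @return the phantom with electrolyte voxels added and `$montage` set.
#' @export
place_montage <- function(phantom, montage, mode = c("neumann", "complete_electrode"),
                          current_A = 1e-3, thickness_mm = NULL,
                          halfwidth_mm = 15, contact_impedance_ohm = 1e4) {
  mode <- match.arg(mode)
  if (!is.null(phantom$montage))
    stop("phantom already carries a montage")
  if (is.null(thickness_mm))
    thickness_mm <- if (mode == "neumann") 4 else 5
  labels <- strsplit(montage, "-", fixed = TRUE)[[1]]
  if (length(labels) != 2L) stop("montage must be of the form 'A-B'")

  tmp <- ensure_tissue(phantom, "electrode"); phantom <- tmp$phantom
  elec_id <- tmp$id

  cond <- phantom$labels > 0L
  surf <- boundary_of(cond)
  surf_ids <- which(surf)
  ax <- axis_centers(phantom)
  d <- dim(phantom$labels)
  v0 <- surf_ids - 1L
  surf_xyz <- cbind(ax$x[v0 %% d[1] + 1L],
                    ax$y[(v0 %/% d[1]) %% d[2] + 1L],
                    ax$z[v0 %/% (d[1] * d[2]) + 1L])
  air_ids <- which(phantom$labels == 0L)
  a0 <- air_ids - 1L
  air_xyz <- cbind(ax$x[a0 %% d[1] + 1L],
                   ax$y[(a0 %/% d[1]) %% d[2] + 1L],
                   ax$z[a0 %/% (d[1] * d[2]) + 1L])

  build_patch <- function(label) {
    if (label == "rS") {
      if (is.null(phantom$torso))
        stop("position 'rS' needs a torso; call attach_torso() first")
      tr <- phantom$torso$radius_mm
      anchor <- phantom$landmarks$rS
      on_torso <- surf_xyz[, 3] <= phantom$torso$z_top &
        surf_xyz[, 3] >= phantom$torso$z_bottom
      uu <- tr * atan2(surf_xyz[, 2], surf_xyz[, 1])        # azimuth from +x
      vv <- surf_xyz[, 3] - anchor[3]
      sel <- on_torso & abs(uu) <= halfwidth_mm & abs(vv) <= halfwidth_mm
      foot <- surf_ids[sel]
      rho_air <- sqrt(air_xyz[, 1]^2 + air_xyz[, 2]^2)
      ua <- tr * atan2(air_xyz[, 2], air_xyz[, 1])
      esel <- air_xyz[, 3] <= phantom$torso$z_top + 1e-9 &
        air_xyz[, 3] >= phantom$torso$z_bottom - 1e-9 &
        abs(ua) <= halfwidth_mm &
        abs(air_xyz[, 3] - anchor[3]) <= halfwidth_mm &
        rho_air <= tr + thickness_mm
      gel <- air_ids[esel]
      radial <- function(p) {
        rr <- sqrt(p[, 1]^2 + p[, 2]^2)
        cbind(p[, 1] / rr, p[, 2] / rr, 0)
      }
      list(label = label, anchor = anchor, foot = foot, gel = gel,
           radial = radial)
    } else {
      dvec <- position_direction(label)
      R0 <- phantom$head_radius_mm
      anchor <- R0 * dvec
      ## restrict to head-sphere surface (not torso/neck)
      rad <- sqrt(rowSums(surf_xyz^2))
      on_head <- rad <= R0 + 1e-9 &
        (is.null(phantom$torso) | surf_xyz[, 3] > -0.8 * R0 + 1e-9)
      uv <- geodesic_uv(surf_xyz, dvec, R0)
      sel <- on_head & abs(uv[, 1]) <= halfwidth_mm & abs(uv[, 2]) <= halfwidth_mm
      foot <- surf_ids[sel]
      ra <- sqrt(rowSums(air_xyz^2))
      uva <- geodesic_uv(air_xyz, dvec, R0)
      esel <- ra <= R0 + thickness_mm &
        abs(uva[, 1]) <= halfwidth_mm & abs(uva[, 2]) <= halfwidth_mm
      if (!is.null(phantom$torso)) esel <- esel & air_xyz[, 3] > -0.8 * R0
      gel <- air_ids[esel]
      radial <- function(p) p / sqrt(rowSums(p^2))
      list(label = label, anchor = anchor, foot = foot, gel = gel,
           radial = radial)
    }
  }

  finish_patch <- function(ph, pp) {
    if (!length(pp$foot)) stop("no surface voxels found for '", pp$label, "'")
    h <- ph$spacing_mm
    ## geodesic patch area estimate: exposed footprint faces projected onto
    ## the local tangent plane (before electrolyte is added)
    mask <- array(FALSE, dim(ph$labels)); mask[pp$foot] <- TRUE
    ef <- exposed_faces(ph, mask)
    area <- 0
    if (length(ef$vox)) {
      fv0 <- ef$vox - 1L
      fxyz <- cbind(ax$x[fv0 %% d[1] + 1L],
                    ax$y[(fv0 %/% d[1]) %% d[2] + 1L],
                    ax$z[fv0 %/% (d[1] * d[2]) + 1L])
      rhat <- pp$radial(fxyz)
      area <- sum(h^2 * abs(rhat[cbind(seq_along(ef$vox), ef$axis)]))
    }
    ## label electrolyte; with thickness 0 (point-like validation patches)
    ## the contact sits directly on the outward faces of the footprint
    ph$labels[pp$gel] <- elec_id
    gmask <- array(FALSE, dim(ph$labels))
    gmask[if (length(pp$gel)) pp$gel else pp$foot] <- TRUE
    gf <- exposed_faces(ph, gmask)
    node_area <- numeric(0)
    nodes <- integer(0)
    if (length(gf$vox)) {
      gv0 <- gf$vox - 1L
      gxyz <- cbind(ax$x[gv0 %% d[1] + 1L],
                    ax$y[(gv0 %/% d[1]) %% d[2] + 1L],
                    ax$z[gv0 %/% (d[1] * d[2]) + 1L])
      rhat <- pp$radial(gxyz)
      comp <- rhat[cbind(seq_along(gf$vox), gf$axis)]
      sgn <- ifelse(gf$side == 1L, 1, -1)
      keep <- comp * sgn > 0.5                    # outward, radial-ish faces
      if (any(keep)) {
        kv <- which(keep)
        all_nodes <- integer(0)
        for (axi in 1:3) {
          sel <- kv[gf$axis[kv] == axi]
          if (!length(sel)) next
          for (sd in c(0L, 1L)) {
            s2 <- sel[gf$side[sel] == sd]
            if (!length(s2)) next
            fn <- voxel_face_nodes(ph, gf$vox[s2], axi, sd)
            all_nodes <- c(all_nodes, as.vector(fn))
          }
        }
        tab <- table(all_nodes)
        nodes <- as.integer(names(tab))
        node_area <- as.numeric(tab) * h^2 / 4
      }
    }
    if (!length(nodes)) stop("electrode patch '", pp$label, "' has no contact nodes")
    list(ph = ph,
         patch = structure(list(
           position_label = pp$label, anchor_mm = pp$anchor,
           footprint_voxels = pp$foot, electrolyte_voxels = pp$gel,
           contact_nodes = nodes, contact_node_area_mm2 = node_area,
           area_mm2 = area, thickness_mm = thickness_mm),
           class = "electrode_patch"))
  }

  pA <- build_patch(labels[1])
  pB <- build_patch(labels[2])
  if (length(intersect(pA$foot, pB$foot)) || length(intersect(pA$gel, pB$gel)))
    stop("electrode patches overlap")
  fA <- finish_patch(phantom, pA); phantom <- fA$ph
  fB <- finish_patch(phantom, pB); phantom <- fB$ph
  if (length(intersect(fA$patch$contact_nodes, fB$patch$contact_nodes)))
    stop("electrode patches overlap (shared contact nodes)")

  phantom$montage <- structure(list(
    name = montage, mode = mode, current_A = current_A,
    contact_impedance_ohm = contact_impedance_ohm,
    patches = list(fA$patch, fB$patch)), class = "montage_spec")
  phantom
}

#' @export
print.montage_spec <- function(x, ...) {
  cat("montage_spec:", x$name, sprintf("(%s, %g mA)\n", x$mode, 1e3 * x$current_A))
  for (p in x$patches)
    cat(sprintf("  %-4s area %.0f mm^2, %d contact nodes, gel %d voxels\n",
                p$position_label, p$area_mm2, length(p$contact_nodes),
                length(p$electrolyte_voxels)))
  invisible(x)
}

#' Convenience builder for the default study phantom
#'
#' Layered spherical head (92 mm default outer radius) with embedded eyes
#' and an attached torso, ready for montage placement. `model = "model1"`
#' builds the scalp/skull/CSF/brain stack with a homogeneous eye;
#' `model = "model2"` splits the brain into gray and white matter and uses
#' the full eye compartments.
#'
#' @param model `"model2"` or `"model1"` tissue stack.
#' @param spacing_mm voxel size (mm).
#' @param radius_mm outer scalp radius (mm).
#' @param torso attach a torso (needed for `rS` montages).
#' @return a [voxel_phantom()].
#' @export
default_head_phantom <- function(model = c("model2", "model1"),
                                 spacing_mm = 2, radius_mm = 92,
                                 torso = TRUE) {
  model <- match.arg(model)
  sc <- radius_mm / 92
  if (model == "model1") {
    ph <- build_layered_head(sc * c(92, 86, 80, 76),
                             c("scalp", "skull", "csf", "brain"),
                             spacing_mm)
  } else {
    ph <- build_layered_head(sc * c(92, 86, 80, 76, 64),
                             c("scalp", "skull", "csf", "gray_matter",
                               "white_matter"), spacing_mm)
  }
  ph <- embed_eyes(ph, compartments = model)
  if (torso)
    ph <- attach_torso(ph, length_mm = sc * 140, radius_mm = sc * 70)
  ph
}
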