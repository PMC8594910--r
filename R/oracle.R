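## Closed-form potentials for two point electrodes injecting current on the
## outer surface of homogeneous and N-layer concentric spheres. These serve
## as ground truth for the hexahedral solver.

#' Specification of a layered-sphere validation geometry
#'
#' @param radii_mm strictly decreasing layer outer radii (mm); the first is
#'   the sphere surface.
#' @param sigma layer conductivities (S/m), outer to inner.
#' @param electrode_A,electrode_B unit direction vectors of the source and
#'   sink point electrodes on the outer surface.
#' @param current_A injected current (amperes).
#' @param L Legendre series truncation order.
#' @return list of class `layered_sphere_spec`.
#' @export
layered_sphere_spec <- function(radii_mm, sigma, electrode_A, electrode_B,
                                current_A = 1e-3, L = 120L) {
  if (any(diff(radii_mm) >= 0)) stop("radii must be strictly decreasing")
  if (length(radii_mm) != length(sigma))
    stop("need one conductivity per layer")
  if (any(sigma <= 0)) stop("conductivities must be positive")
  if (L < 1L) stop("L must be >= 1")
  norm <- function(v) v / sqrt(sum(v^2))
  structure(list(radii_mm = radii_mm, sigma = sigma,
                 electrode_A = norm(electrode_A),
                 electrode_B = norm(electrode_B),
                 current_A = current_A, L = as.integer(L)),
            class = "layered_sphere_spec")
}

## radial coefficients (A_m, B_m) per layer and degree, normalized radius
## t = r / R. Solves the small interface system per degree directly.
layer_coefficients <- function(spec) {
  R <- spec$radii_mm[1]
  tif <- spec$radii_mm[-1] / R          # interface radii (outer bdry of inner layers)
  N <- length(spec$sigma)
  L <- spec$L
  sig <- spec$sigma
  A <- matrix(0, N, L); B <- matrix(0, N, L)
  for (l in seq_len(L)) {
    if (N == 1L) {
      A[1, l] <- spec$current_A * (2 * l + 1) /
        (4 * pi * sig[1] * (R / 1000) * l)
      next
    }
    nunk <- 2L * N - 1L                  # A_1,B_1,...,A_{N-1},B_{N-1},A_N
    M <- matrix(0, nunk, nunk)
    rhs <- numeric(nunk)
    colA <- function(m) if (m < N) 2L * m - 1L else nunk
    colB <- function(m) 2L * m        # only m < N
    row <- 1L
    for (m in seq_len(N - 1L)) {
      t <- tif[m]
      ## potential continuity at interface m (between layer m and m+1)
      M[row, colA(m)] <- t^l
      M[row, colB(m)] <- t^(-(l + 1))
      M[row, colA(m + 1L)] <- -t^l
      if (m + 1L < N) M[row, colB(m + 1L)] <- -t^(-(l + 1))
      row <- row + 1L
      ## radial current continuity
      M[row, colA(m)] <- sig[m] * l * t^(l - 1)
      M[row, colB(m)] <- -sig[m] * (l + 1) * t^(-(l + 2))
      M[row, colA(m + 1L)] <- -sig[m + 1L] * l * t^(l - 1)
      if (m + 1L < N)
        M[row, colB(m + 1L)] <- sig[m + 1L] * (l + 1) * t^(-(l + 2))
      row <- row + 1L
    }
    ## outer Neumann source: sigma_1 (A_1 l - B_1 (l+1)) = I (2l+1)/(4 pi R)
    M[row, colA(1L)] <- sig[1] * l
    M[row, colB(1L)] <- -sig[1] * (l + 1)
    rhs[row] <- spec$current_A * (2 * l + 1) / (4 * pi * (R / 1000))
    ## per-layer normalized radial basis (column scaling): keeps the mixed
    ## t^l / t^(-l-1) system well conditioned at high degree
    tout <- c(1, tif)               # outer normalized radius of each layer
    cs <- numeric(nunk)
    for (m in seq_len(N)) cs[colA(m)] <- tout[m]^(-l)
    for (m in seq_len(N - 1L)) cs[colB(m)] <- tif[m]^(l + 1)
    Ms <- sweep(M, 2, cs, "*")
    sol <- tryCatch(cs * solve(Ms, rhs), error = function(e)
      stop("singular transfer system (degenerate radii?)"))
    for (m in seq_len(N)) {
      A[m, l] <- sol[colA(m)]
      if (m < N) B[m, l] <- sol[colB(m)]
    }
  }
  list(A = A, B = B)
}

eval_sphere_series <- function(spec, points_mm, coeff) {
  R <- spec$radii_mm[1]
  pts <- as.matrix(points_mm)
  if (ncol(pts) != 3L) stop("points must be an n x 3 matrix (mm)")
  r <- sqrt(rowSums(pts^2))
  if (any(r > R * (1 + 1e-9))) stop("evaluation point outside the sphere")
  t <- pmin(r / R, 1)
  ph <- pts / pmax(r, .Machine$double.eps)
  cosA <- pmin(1, pmax(-1, ph %*% spec$electrode_A))
  cosB <- pmin(1, pmax(-1, ph %*% spec$electrode_B))
  at_elec <- (cosA > 1 - 1e-12 | cosB > 1 - 1e-12) & t > 1 - 1e-9
  if (any(at_elec)) stop("evaluation point coincides with an electrode")
  ## layer of each point: layer m spans (radii[m+1], radii[m]]
  edges <- c(spec$radii_mm[-1], -Inf)
  layer <- rep(length(spec$sigma), length(r))
  for (m in seq_along(edges)) layer[r <= c(spec$radii_mm)[m] & r > edges[m]] <- m
  layer[r == 0] <- length(spec$sigma)
  L <- spec$L
  ## rolling Legendre recursion and radial powers: O(n) memory at any L
  xA <- as.vector(cosA); xB <- as.vector(cosB)
  pa0 <- rep(1, length(r)); pa1 <- xA
  pb0 <- rep(1, length(r)); pb1 <- xB
  tl <- t
  tinv <- 1 / pmax(t, .Machine$double.xmin)
  tpw <- tinv^2                       # t^(-(l+1)) at l = 1
  phi <- numeric(length(r))
  for (l in seq_len(L)) {
    radial <- coeff$A[cbind(layer, l)] * tl
    bb <- coeff$B[cbind(layer, l)]
    nz <- which(bb != 0)
    if (length(nz)) radial[nz] <- radial[nz] + bb[nz] * tpw[nz]
    phi <- phi + radial * (pa1 - pb1)
    tl <- tl * t
    tpw <- tpw * tinv
    pa2 <- ((2 * l + 1) * xA * pa1 - l * pa0) / (l + 1)
    pa0 <- pa1; pa1 <- pa2
    pb2 <- ((2 * l + 1) * xB * pb1 - l * pb0) / (l + 1)
    pb0 <- pb1; pb1 <- pb2
  }
  phi
}

#' Potential of two point electrodes on a homogeneous sphere
#'
#' Classical Legendre series for current `I` injected at one surface point
#' and extracted at another, insulating boundary elsewhere:
#' `phi(r, gamma) = I / (4 pi sigma R) * sum_l ((2l+1)/l) (r/R)^l
#' (P_l(cos gamma_A) - P_l(cos gamma_B))`, truncated at `L`.
#'
#' @param spec a [layered_sphere_spec()] with a single layer.
#' @param points_mm n x 3 matrix of evaluation points (mm, sphere-centered).
#' @return potentials in volts (zero-mean gauge is *not* applied; the series
#'   has no monopole term).
#' @export
homogeneous_sphere_potential <- function(spec, points_mm) {
  if (length(spec$sigma) != 1L)
    stop("spec must have exactly one layer; see nlayer_sphere_potential()")
  eval_sphere_series(spec, points_mm, layer_coefficients(spec))
}

#' Potential of two point electrodes on an N-layer concentric sphere
#'
#' Per-degree radial solutions `A_m r^l + B_m r^(-l-1)` in each layer, with
#' coefficients determined by continuity of potential and radial current
#' density at the interfaces, a regular core (`B_N = 0`) and the surface
#' Neumann source. With one layer this reduces exactly to
#' [homogeneous_sphere_potential()].
#'
#' @inheritParams homogeneous_sphere_potential
#' @return potentials in volts.
#' @export
nlayer_sphere_potential <- function(spec, points_mm) {
  eval_sphere_series(spec, points_mm, layer_coefficients(spec))
}

#' Solver validation against the layered-sphere oracle
#'
#' Builds a concentric-sphere phantom, injects current through two
#' point-like surface electrodes (single node clusters, no electrolyte
#' layer), solves with the hexahedral FEM and compares the potential
#' against the closed-form series. The relative L2 error is the
#' midpoint-quadrature volume norm over all conducting elements outside an
#' exclusion zone around each electrode (which removes the patch/point
#' modeling mismatch from the metric); both fields are aligned to zero mean
#' over the evaluation set.
#'
#' @param radii_mm,sigma layer geometry and conductivities (outer to inner).
#' @param spacing_mm voxel size.
#' @param montage two position labels, e.g. `"Cz-T8"` (the default 90
#'   degree separation keeps the evaluation region well away from both
#'   injection sites).
#' @param current_A injected current.
#' @param exclusion_mm radius of the per-electrode exclusion zone.
#' @param tol CG tolerance.
#' @param L oracle truncation order.
#' @return list: `rel_l2`, `n_eval`, `iterations`, `spacing_mm`.
#' @export
oracle_comparison <- function(radii_mm = c(92, 86, 80),
                              sigma = c(0.43, 0.01, 0.33),
                              spacing_mm = 2, montage = "Cz-T8",
                              current_A = 1e-3, exclusion_mm = 10,
                              tol = 1e-8, L = 200L) {
  tissues <- paste0("layer", seq_along(radii_mm))
  ph <- build_layered_head(radii_mm, tissues, spacing_mm)
  ph <- place_montage(ph, montage, mode = "neumann", current_A = current_A,
                      thickness_mm = 0, halfwidth_mm = spacing_mm)
  cond <- stats::setNames(c(sigma, sigma[1]), c(tissues, "electrode"))
  sys <- assemble_stiffness(ph, cond)
  pot <- solve_potential(sys, build_rhs_neumann(sys), tol = tol)
  ctr <- lapply(ph$montage$patches, function(p)
    colMeans(node_coords(ph, p$contact_nodes)))
  eA <- ctr[[1]] / sqrt(sum(ctr[[1]]^2))
  eB <- ctr[[2]] / sqrt(sum(ctr[[2]]^2))
  d <- dim(ph$labels)
  axc <- axis_centers(ph)
  v0 <- sys$active_voxels - 1L
  exyz <- cbind(axc$x[v0 %% d[1] + 1L],
                axc$y[(v0 %/% d[1]) %% d[2] + 1L],
                axc$z[v0 %/% (d[1] * d[2]) + 1L])
  phi_e <- rowMeans(matrix(pot$node_potentials[sys$voxel_nodes], ncol = 8L))
  dA <- sqrt(rowSums(sweep(exyz, 2, ctr[[1]])^2))
  dB <- sqrt(rowSums(sweep(exyz, 2, ctr[[2]])^2))
  keep <- dA > exclusion_mm & dB > exclusion_mm
  spec <- layered_sphere_spec(radii_mm, sigma, eA, eB, current_A, L = L)
  phi_o <- nlayer_sphere_potential(spec, exyz[keep, , drop = FALSE])
  a <- phi_e[keep] - mean(phi_e[keep])
  b <- phi_o - mean(phi_o)
  list(rel_l2 = sqrt(sum((a - b)^2) / sum(b^2)), n_eval = sum(keep),
       iterations = pot$report$iterations, spacing_mm = spacing_mm)
}
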