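## Quasi-static current-injection solver on hexahedral (voxel) meshes.
##
## The potential phi solves div(sigma grad phi) = 0 with current injected
## either as nodal point loads (pure Neumann, "equally distributed across
## the outer nodes of the electrodes") or through the complete electrode
## model (contact impedance layer + one floating potential per electrode).
## Elements are trilinear 8-node hexahedra; all voxels are cubes, so the
## element stiffness is sigma * h * K_ref with a single reference matrix.

## reference stiffness of a trilinear unit-cube element with sigma = 1,
## by 2 x 2 x 2 Gauss quadrature
hex_reference_stiffness <- function() {
  g <- 0.5 + c(-1, 1) / (2 * sqrt(3))
  K <- matrix(0, 8, 8)
  corners <- as.matrix(expand.grid(di = 0:1, dj = 0:1, dk = 0:1))
  shape_grad <- function(x, y, z) {
    ## d/dx, d/dy, d/dz of N_a = prod over axes of (1-t) or t
    G <- matrix(0, 8, 3)
    for (a in 1:8) {
      cc <- corners[a, ]
      fx <- if (cc[1] == 1) x else 1 - x
      fy <- if (cc[2] == 1) y else 1 - y
      fz <- if (cc[3] == 1) z else 1 - z
      dx <- if (cc[1] == 1) 1 else -1
      dy <- if (cc[2] == 1) 1 else -1
      dz <- if (cc[3] == 1) 1 else -1
      G[a, ] <- c(dx * fy * fz, fx * dy * fz, fx * fy * dz)
    }
    G
  }
  for (x in g) for (y in g) for (z in g) {
    G <- shape_grad(x, y, z)
    K <- K + (G %*% t(G)) / 8
  }
  K
}

#' Assemble the stiffness system for a phantom
#'
#' Builds the sparse symmetric positive semi-definite stiffness matrix of
#' the quasi-static problem over all conducting voxels (trilinear hexahedra,
#' one cube per voxel). Row sums are zero: with pure Neumann boundaries the
#' constant potential is in the nullspace and the potential is determined up
#' to a gauge.
#'
#' @param phantom a [voxel_phantom()] (typically with a montage placed).
#' @param conductivities named vector of tissue conductivities (S/m); every
#'   tissue present in the phantom must have an entry.
#' @return An object of class `fem_system`: sparse matrix `K` (SI units,
#'   siemens), the compact node numbering, per-voxel conductivities and a
#'   reference to the phantom.
#' @export
assemble_stiffness <- function(phantom, conductivities) {
  sig_by_label <- tissue_sigma(phantom, conductivities)
  d <- dim(phantom$labels)
  nd <- d + 1L
  act <- which(phantom$labels > 0L)
  if (!length(act)) stop("phantom has no conducting voxel")
  sigma <- sig_by_label[phantom$labels[act]]
  h <- phantom$spacing_mm / 1000           # meters

  v0 <- act - 1L
  vi <- v0 %% d[1]
  vj <- (v0 %/% d[1]) %% d[2]
  vk <- v0 %/% (d[1] * d[2])
  corners <- as.matrix(expand.grid(di = 0:1, dj = 0:1, dk = 0:1))
  ## node ids (full grid) per voxel corner, local order a = 1..8
  vn <- matrix(0L, length(act), 8L)
  for (a in 1:8)
    vn[, a] <- node_lin_id(nd, vi + corners[a, 1], vj + corners[a, 2],
                           vk + corners[a, 3])

  ## compact numbering of active nodes
  used <- logical(prod(nd))
  used[as.vector(vn)] <- TRUE
  node_index <- integer(prod(nd))
  node_index[used] <- seq_len(sum(used))
  nn <- sum(used)
  cvn <- matrix(node_index[vn], ncol = 8L)

  Kref <- hex_reference_stiffness()
  w <- sigma * h
  nv <- length(act)
  ii <- integer(64 * nv); jj <- integer(64 * nv); xx <- numeric(64 * nv)
  pos <- 0L
  for (a in 1:8) for (b in 1:8) {
    idx <- pos + seq_len(nv)
    ii[idx] <- cvn[, a]
    jj[idx] <- cvn[, b]
    xx[idx] <- w * Kref[a, b]
    pos <- pos + nv
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nn, nn))

  structure(list(K = K, nn = nn, n_aux = 0L,
                 node_index = node_index, active_voxels = act,
                 voxel_nodes = cvn, sigma = sigma, phantom = phantom),
            class = "fem_system")
}

#' @export
print.fem_system <- function(x, ...) {
  cat("fem_system:", x$nn, "potential nodes,",
      length(x$active_voxels), "conducting voxels")
  if (x$n_aux) cat(",", x$n_aux, "electrode unknowns (complete electrode model)")
  cat("\n")
  invisible(x)
}

#' Pure-Neumann load vector for a montage
#'
#' The injected current is equally distributed across the outer contact
#' nodes of each electrode: `+I/n_A` on the source patch nodes, `-I/n_B` on
#' the sink patch nodes, so the load sums to zero.
#'
#' @param system a [assemble_stiffness()] result.
#' @param montage montage spec; defaults to the one stored in the phantom.
#' @return numeric load vector (amperes) over the system unknowns.
#' @export
build_rhs_neumann <- function(system, montage = system$phantom$montage) {
  if (is.null(montage)) stop("no montage available")
  if (montage$mode != "neumann")
    stop("montage mode is not 'neumann'")
  f <- numeric(system$nn + system$n_aux)
  sgn <- c(1, -1)
  for (e in 1:2) {
    nodes <- system$node_index[montage$patches[[e]]$contact_nodes]
    if (!length(nodes) || any(nodes == 0L))
      stop("electrode patch ", e, " has no active contact nodes")
    f[nodes] <- f[nodes] + sgn[e] * montage$current_A / length(nodes)
  }
  f
}

#' Augment a system with the complete electrode model
#'
#' Adds one floating potential unknown per electrode, coupled to the contact
#' nodes through the surface impedance `z = contact_impedance_ohm * A_patch`
#' (ohm m^2), so that the lumped resistance of each electrode equals the
#' configured contact impedance. The total current through each electrode is
#' constrained to +I / -I via the load vector stored in the returned system
#' (`$rhs`). The augmented matrix stays symmetric positive semi-definite
#' with the all-ones nullspace.
#'
#' @param system a [assemble_stiffness()] result.
#' @param montage montage spec with `mode = "complete_electrode"`.
#' @return augmented `fem_system` with `n_aux = 2` and `$rhs`.
#' @export
apply_complete_electrode <- function(system, montage = system$phantom$montage) {
  if (is.null(montage)) stop("no montage available")
  if (montage$mode != "complete_electrode")
    stop("montage mode is not 'complete_electrode'")
  if (!is.numeric(montage$contact_impedance_ohm) ||
      montage$contact_impedance_ohm <= 0)
    stop("contact impedance must be positive")
  nn <- system$nn
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  elec_info <- list()
  for (e in 1:2) {
    p <- montage$patches[[e]]
    nodes <- system$node_index[p$contact_nodes]
    if (!length(nodes) || any(nodes == 0L))
      stop("electrode patch ", e, " has no active contact nodes")
    a_m2 <- p$contact_node_area_mm2 * 1e-6
    A_e <- sum(a_m2)
    z <- montage$contact_impedance_ohm * A_e       # ohm m^2
    ue <- nn + e
    ii <- c(ii, nodes, nodes, rep(ue, length(nodes)), ue)
    jj <- c(jj, nodes, rep(ue, length(nodes)), nodes, ue)
    xx <- c(xx, a_m2 / z, -a_m2 / z, -a_m2 / z, A_e / z)
    elec_info[[e]] <- list(nodes = nodes, area_m2 = a_m2, A_e = A_e, z = z)
  }
  Kc <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nn + 2L, nn + 2L))
  K <- Matrix::bdiag(system$K, Matrix::Matrix(0, 2, 2, sparse = TRUE)) + Kc
  out <- system
  out$K <- methods::as(K, "CsparseMatrix")
  out$n_aux <- 2L
  out$electrodes <- elec_info
  out$rhs <- c(numeric(nn), montage$current_A, -montage$current_A)
  out
}

#' Solve for the electric potential
#'
#' Preconditioned conjugate gradients (Jacobi preconditioner) on the
#' singular pure-Neumann system, with the constant nullspace projected out
#' of the residual each iteration. The load must be compatible (zero total
#' current per conducting component).
#'
#' @param system `fem_system` (plain or complete-electrode augmented).
#' @param rhs load vector; defaults to the system's stored CEM load or the
#'   Neumann load of the phantom's montage.
#' @param tol relative residual tolerance.
#' @param gauge `"zero_mean"` (default) or `"pin"` (first node at 0 V).
#' @param maxit iteration cap.
#' @return list of class `potential_field`: `node_potentials` (volts, over
#'   compact node ids; the last `n_aux` entries are electrode potentials),
#'   `gauge`, and `report` (iterations, relative residual, injected/
#'   extracted current and imbalance).
#' @export
solve_potential <- function(system, rhs = NULL, tol = 1e-8,
                            gauge = c("zero_mean", "pin"), maxit = 10000L) {
  gauge <- match.arg(gauge)
  if (is.null(rhs))
    rhs <- if (system$n_aux > 0L) system$rhs else build_rhs_neumann(system)
  n <- system$nn + system$n_aux
  if (length(rhs) != n) stop("rhs has wrong length")
  inj <- sum(rhs[rhs > 0]); ext <- -sum(rhs[rhs < 0])
  if (max(inj, ext) > 0 && abs(sum(rhs)) > 1e-10 * max(inj, ext))
    stop("incompatible load: total injected current is not zero")
  check_patch_connectivity(system, rhs)

  K <- system$K
  dg <- Matrix::diag(K)
  if (any(dg <= 0)) stop("non-positive diagonal in stiffness matrix")
  Minv <- 1 / dg
  proj <- function(v) v - mean(v)
  b <- proj(rhs)
  x <- numeric(n)
  r <- b
  z <- proj(Minv * r)
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) {
    return(structure(list(node_potentials = x, gauge = gauge,
                          report = solve_report(0L, 0, inj, ext, 0)),
                     class = "potential_field"))
  }
  hist <- numeric(0)
  it <- 0L
  relres <- 1
  while (it < maxit) {
    it <- it + 1L
    Kp <- as.numeric(K %*% p)
    alpha <- rz / sum(p * Kp)
    x <- x + alpha * p
    r <- r - alpha * Kp
    r <- proj(r)
    relres <- sqrt(sum(r * r)) / bnorm
    hist <- c(hist, relres)
    if (relres <= tol) break
    z <- proj(Minv * r)
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  if (relres > tol)
    stop(sprintf(
      "conjugate gradients did not converge in %d iterations (relative residual %.3e; last residuals: %s)",
      maxit, relres,
      paste(sprintf("%.3e", utils::tail(hist, 5)), collapse = ", ")))
  if (gauge == "zero_mean") {
    x <- x - mean(x[seq_len(system$nn)])
  } else {
    x <- x - x[1]
  }
  imb <- electrode_current_imbalance(system, x, rhs)
  structure(list(node_potentials = x, gauge = gauge,
                 report = solve_report(it, relres, inj, ext, imb)),
            class = "potential_field")
}

solve_report <- function(iterations, relres, injected, extracted, imbalance) {
  list(iterations = iterations, relative_residual = relres,
       injected_A = injected, extracted_A = extracted,
       imbalance_A = imbalance)
}

## verify that source and sink loads sit on one conducting component
check_patch_connectivity <- function(system, rhs) {
  pos_nodes <- which(rhs[seq_len(system$nn)] > 0)
  neg_nodes <- which(rhs[seq_len(system$nn)] < 0)
  if (!length(pos_nodes) || !length(neg_nodes)) return(invisible(TRUE))
  d <- dim(system$phantom$labels)
  cond <- system$phantom$labels > 0L
  touch <- function(cnodes) {
    hit <- rowSums(matrix(system$voxel_nodes %in% cnodes,
                          nrow = nrow(system$voxel_nodes))) > 0
    m <- array(FALSE, d)
    m[system$active_voxels[hit]] <- TRUE
    m
  }
  seed <- touch(pos_nodes)
  reach <- flood_fill6(cond, seed)
  target <- touch(neg_nodes)
  if (!any(reach & target))
    stop("montage patches lie on disconnected conducting components")
  invisible(TRUE)
}

electrode_current_imbalance <- function(system, x, rhs) {
  if (system$n_aux == 0L) return(abs(sum(rhs)))
  I <- rhs[system$nn + 1L]
  err <- 0
  for (e in 1:2) {
    el <- system$electrodes[[e]]
    Ie <- (el$A_e * x[system$nn + e] - sum(el$area_m2 * x[el$nodes])) / el$z
    err <- max(err, abs(Ie - rhs[system$nn + e]))
  }
  err
}

#' Per-element current density
#'
#' Evaluates `J = -sigma grad(phi)` at each element center from the
#' trilinear shape-function gradients. Units are stored in A/m^2; the
#' conventional reporting unit of the summaries is mA/m^2.
#'
#' @param system `fem_system`.
#' @param potential a [solve_potential()] result.
#' @return object of class `current_density_field` with `vectors`
#'   (n_voxels x 3, A/m^2), `magnitude` (A/m^2), and the active voxel ids.
#'   Non-conducting voxels carry no element and hence zero current density
#'   (see [field_as_array()]).
#' @export
current_density <- function(system, potential) {
  phi <- potential$node_potentials[seq_len(system$nn)]
  h <- system$phantom$spacing_mm / 1000
  v <- system$voxel_nodes
  p <- matrix(phi[v], ncol = 8L)
  ## local node order a = 1 + di + 2 dj + 4 dk
  gx <- ((p[, 2] - p[, 1]) + (p[, 4] - p[, 3]) +
           (p[, 6] - p[, 5]) + (p[, 8] - p[, 7])) / (4 * h)
  gy <- ((p[, 3] - p[, 1]) + (p[, 4] - p[, 2]) +
           (p[, 7] - p[, 5]) + (p[, 8] - p[, 6])) / (4 * h)
  gz <- ((p[, 5] - p[, 1]) + (p[, 6] - p[, 2]) +
           (p[, 7] - p[, 3]) + (p[, 8] - p[, 4])) / (4 * h)
  J <- -system$sigma * cbind(gx, gy, gz)
  structure(list(vectors = J, magnitude = sqrt(rowSums(J^2)),
                 voxels = system$active_voxels,
                 dim = dim(system$phantom$labels), unit = "A/m^2"),
            class = "current_density_field")
}

#' Expand a current-density field to a full grid array
#' @param field a [current_density()] result.
#' @param what `"magnitude"` or one of `"jx"`, `"jy"`, `"jz"`.
#' @return 3-D array over the phantom grid (zero in non-conducting voxels).
#' @export
field_as_array <- function(field, what = c("magnitude", "jx", "jy", "jz")) {
  what <- match.arg(what)
  a <- array(0, field$dim)
  a[field$voxels] <- switch(what, magnitude = field$magnitude,
                            jx = field$vectors[, 1], jy = field$vectors[, 2],
                            jz = field$vectors[, 3])
  a
}

#' Discrete current flux out of a voxel region
#'
#' Computes the net current (amperes) flowing out of the element set
#' `inside` in the discretely conserved sense: the stiffness contributions
#' of the inside elements are applied to the solved potential and summed
#' over the interface nodes. For a converged solve, a closed surface
#' separating the two electrodes carries the full injected current and a
#' surface enclosing neither electrode carries zero net current (up to the
#' solver residual).
#'
#' @param system `fem_system`.
#' @param potential a [solve_potential()] result.
#' @param inside logical array over the voxel grid selecting the enclosed
#'   region (element-wise; only conducting voxels matter).
#' @return net outward flux in amperes.
#' @export
check_conservation <- function(system, potential, inside) {
  if (!identical(dim(inside), dim(system$phantom$labels)))
    stop("'inside' must be a logical array over the voxel grid")
  sel <- inside[system$active_voxels]
  if (!any(sel)) stop("no conducting voxels inside the surface")
  if (all(sel)) stop("surface must exclude part of the conducting domain")
  h <- system$phantom$spacing_mm / 1000
  Kref <- hex_reference_stiffness()
  cvn <- system$voxel_nodes[sel, , drop = FALSE]
  w <- system$sigma[sel] * h
  nv <- nrow(cvn)
  ii <- integer(64 * nv); jj <- integer(64 * nv); xx <- numeric(64 * nv)
  pos <- 0L
  for (a in 1:8) for (b in 1:8) {
    idx <- pos + seq_len(nv)
    ii[idx] <- cvn[, a]; jj[idx] <- cvn[, b]; xx[idx] <- w * Kref[a, b]
    pos <- pos + nv
  }
  Kin <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = c(system$nn, system$nn))
  wvec <- as.numeric(Kin %*% potential$node_potentials[seq_len(system$nn)])
  in_nodes <- unique(as.vector(cvn))
  out_nodes <- unique(as.vector(system$voxel_nodes[!sel, , drop = FALSE]))
  boundary <- intersect(in_nodes, out_nodes)
  -sum(wvec[boundary])
}

#' One-call forward simulation of a montage
#'
#' Assembles, solves and differentiates in one step.
#'
#' @param phantom phantom with a montage placed ([place_montage()]).
#' @param conductivities named conductivity vector.
#' @param tol,gauge,maxit passed to [solve_potential()].
#' @return object of class `tes_solution`: `system`, `potential`, `field`,
#'   `montage`, `report`.
#' @export
simulate_montage <- function(phantom, conductivities, tol = 1e-8,
                             gauge = "zero_mean", maxit = 10000L) {
  if (is.null(phantom$montage)) stop("phantom has no montage")
  system <- assemble_stiffness(phantom, conductivities)
  if (phantom$montage$mode == "complete_electrode") {
    system <- apply_complete_electrode(system)
    pot <- solve_potential(system, tol = tol, gauge = gauge, maxit = maxit)
  } else {
    pot <- solve_potential(system, build_rhs_neumann(system), tol = tol,
                           gauge = gauge, maxit = maxit)
  }
  field <- current_density(system, pot)
  structure(list(system = system, potential = pot, field = field,
                 montage = phantom$montage, report = pot$report),
            class = "tes_solution")
}

#' @export
print.tes_solution <- function(x, ...) {
  cat("tes_solution:", x$montage$name,
      sprintf("(%s, %g mA)\n", x$montage$mode, 1e3 * x$montage$current_A))
  cat(sprintf("  CG: %d iterations, relative residual %.2e\n",
              x$report$iterations, x$report$relative_residual))
  cat(sprintf("  max |J| = %.1f mA/m^2\n", 1000 * max(x$field$magnitude)))
  invisible(x)
}
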