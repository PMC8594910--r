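test_that("reference hexahedral stiffness matches independent quadrature", {
  K <- phosfem:::hex_reference_stiffness()
  ## independent oracle: Simpson's rule per axis, exact for the quadratic
  ## integrand of grad N_a . grad N_b (and distinct from Gauss quadrature)
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  nodes <- c(0, 0.5, 1); wts <- c(1, 4, 1) / 6
  Ko <- matrix(0, 8, 8)
  for (ix in 1:3) for (iy in 1:3) for (iz in 1:3) {
    x <- nodes[ix]; y <- nodes[iy]; z <- nodes[iz]
    G <- t(vapply(1:8, function(a) {
      cc <- corners[a, ]
      fx <- if (cc[1] == 1) x else 1 - x; dx <- if (cc[1] == 1) 1 else -1
      fy <- if (cc[2] == 1) y else 1 - y; dy <- if (cc[2] == 1) 1 else -1
      fz <- if (cc[3] == 1) z else 1 - z; dz <- if (cc[3] == 1) 1 else -1
      c(dx * fy * fz, fx * dy * fz, fx * fy * dz)
    }, numeric(3)))
    Ko <- Ko + wts[ix] * wts[iy] * wts[iz] * (G %*% t(G))
  }
  expect_lt(max(abs(K - Ko)), 1e-14)
  expect_true(isSymmetric(K))
  expect_equal(rowSums(K), rep(0, 8), tolerance = 1e-14)
  ## single unit-cube element assembly reproduces sigma * h * K_ref
  ph <- voxel_phantom(array(1L, c(1, 1, 1)), 1000, c(0, 0, 0), "t")
  sys <- assemble_stiffness(ph, c(t = 1))            # h = 1 m
  expect_equal(as.matrix(sys$K), K, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("assembled stiffness has zero row sums and is linear in sigma", {
  bp <- bar_problem(n = 6)
  expect_lt(max(abs(Matrix::rowSums(bp$system$K))), 1e-12)
  ph <- bp$phantom
  s2 <- assemble_stiffness(ph, c(bar = 2))
  expect_equal(2 * as.matrix(bp$system$K), as.matrix(s2$K),
               tolerance = 1e-14)
  expect_error(assemble_stiffness(ph, c(other = 1)), "bar")
})

test_that("Neumann loads distribute the current equally over contact nodes", {
  bp <- bar_problem(n = 10, current = 1e-3)
  f <- bp$rhs
  expect_equal(sort(unique(f[f != 0])), c(-1e-3 / 4, 1e-3 / 4))
  expect_lt(abs(sum(f)), 1e-18)
  m0 <- bp$montage; m0$current_A <- 0
  expect_identical(build_rhs_neumann(bp$system, m0),
                   numeric(bp$system$nn))
  mbad <- bp$montage; mbad$patches[[1]]$contact_nodes <- integer(0)
  expect_error(build_rhs_neumann(bp$system, mbad), "contact nodes")
})

test_that("homogeneous bar solves to the series-resistor hand calculation", {
  bp <- bar_problem(n = 10, spacing = 2, current = 1)
  pot <- solve_potential(bp$system, bp$rhs, tol = 1e-12)
  phi <- pot$node_potentials
  ## R = L / (sigma A): 20 mm / (1 S/m * 4 mm^2) = 5000 ohm
  expect_equal(max(phi) - min(phi), 5000, tolerance = 1e-9)
  ## potential linear along the axis: equal drops between node layers
  xyz <- node_coords(bp$phantom, which(bp$system$node_index > 0))
  for (z in unique(xyz[, 3]))
    expect_lt(diff(range(phi[xyz[, 3] == z])), 1e-6)
  fld <- current_density(bp$system, pot)
  expect_equal(fld$magnitude, rep(1 / 4e-6, 10), tolerance = 1e-9)
  ## linearity: doubling I doubles J exactly
  pot2 <- solve_potential(bp$system, 2 * bp$rhs, tol = 1e-12)
  fld2 <- current_density(bp$system, pot2)
  expect_identical(2 * fld$vectors, fld2$vectors)
  ## air voxels carry zero density in the expanded array
  arr <- field_as_array(fld)
  expect_identical(dim(arr), dim(bp$phantom$labels))
})

test_that("two-layer bar splits the potential drop as series resistances", {
  bp <- bar_problem(n = 10, spacing = 2,
                    sigma = c(soft = 1, hard = 2),
                    labels = rep(c(1L, 2L), each = 5))
  pot <- solve_potential(bp$system, bp$rhs, tol = 1e-12)
  phi <- pot$node_potentials
  xyz <- node_coords(bp$phantom, which(bp$system$node_index > 0))
  pz <- function(z) mean(phi[xyz[, 3] == z])
  drop1 <- pz(0) - pz(10)     # sigma = 1 half
  drop2 <- pz(10) - pz(20)    # sigma = 2 half
  expect_equal(drop1 / drop2, 2, tolerance = 1e-9)
})

test_that("gauge choice does not affect the current density", {
  bp <- bar_problem(n = 8)
  p1 <- solve_potential(bp$system, bp$rhs, tol = 1e-12, gauge = "zero_mean")
  p2 <- solve_potential(bp$system, bp$rhs, tol = 1e-12, gauge = "pin")
  f1 <- current_density(bp$system, p1)
  f2 <- current_density(bp$system, p2)
  expect_equal(f1$vectors, f2$vectors, tolerance = 1e-9)
})

test_that("swapping source and sink negates the potential exactly", {
  bp <- bar_problem(n = 8)
  m2 <- bp$montage; m2$patches <- rev(m2$patches)
  p1 <- solve_potential(bp$system, bp$rhs, tol = 1e-12)
  p2 <- solve_potential(bp$system, build_rhs_neumann(bp$system, m2),
                        tol = 1e-12)
  expect_identical(p1$node_potentials, -p2$node_potentials)
})

test_that("discrete flux is conserved through closed surfaces", {
  bp <- bar_problem(n = 10, current = 1)
  pot <- solve_potential(bp$system, bp$rhs, tol = 1e-12)
  inside <- array(FALSE, dim(bp$phantom$labels))
  inside[, , 1:5] <- TRUE                 # contains the source end
  expect_equal(check_conservation(bp$system, pot, inside), 1,
               tolerance = 1e-8)
  mid <- array(FALSE, dim(bp$phantom$labels))
  mid[, , 4:6] <- TRUE                    # contains neither electrode
  expect_lt(abs(check_conservation(bp$system, pot, mid)), 1e-6)
})

test_that("loads on disconnected conducting components are rejected", {
  lab <- array(0L, c(1, 1, 9)); lab[1, 1, 1:4] <- 1L; lab[1, 1, 6:9] <- 1L
  ph <- voxel_phantom(lab, 2, c(0, 0, 0), "t")
  sys <- assemble_stiffness(ph, c(t = 1))
  nd <- dim(lab) + 1L
  nid <- function(k) 1L + 0L + nd[1] * (0L + nd[2] * k)
  g <- expand.grid(i = 0:1, j = 0:1)
  mont <- structure(list(name = "split", mode = "neumann", current_A = 1,
    patches = list(
      list(contact_nodes = 1L + g$i + nd[1] * (g$j + nd[2] * 0L)),
      list(contact_nodes = 1L + g$i + nd[1] * (g$j + nd[2] * 9L)))),
    class = "montage_spec")
  expect_error(solve_potential(sys, build_rhs_neumann(sys, mont)),
               "disconnected")
})

cem_cube <- function(impedance = 1e4, n = 16L) {
  ph <- voxel_phantom(array(1L, c(n, n, n)), 2, c(0, 0, 0), "scalp")
  sys <- assemble_stiffness(ph, c(scalp = 0.43))
  nd <- dim(ph$labels) + 1L
  g <- expand.grid(i = 5:11, j = 5:11)
  nid <- function(i, j, k) 1L + i + nd[1] * (j + nd[2] * k)
  mont <- structure(list(name = "cube", mode = "complete_electrode",
    current_A = 1e-3, contact_impedance_ohm = impedance,
    patches = list(
      list(contact_nodes = nid(g$i, g$j, 0L),
           contact_node_area_mm2 = rep(4, nrow(g))),
      list(contact_nodes = nid(g$i, g$j, n),
           contact_node_area_mm2 = rep(4, nrow(g))))),
    class = "montage_spec")
  list(ph = ph, sys = sys, mont = mont)
}

test_that("complete electrode model approaches the Dirichlet pair as z -> 0", {
  cc <- cem_cube(impedance = 1e-6)
  aug <- apply_complete_electrode(cc$sys, cc$mont)
  pot <- solve_potential(aug, tol = 1e-10)
  ## oracle: equal-potential patches, direct sparse solve, scaled to I
  K <- cc$sys$K
  cA <- cc$sys$node_index[cc$mont$patches[[1]]$contact_nodes]
  cB <- cc$sys$node_index[cc$mont$patches[[2]]$contact_nodes]
  free <- setdiff(seq_len(cc$sys$nn), c(cA, cB))
  phiD <- numeric(cc$sys$nn); phiD[cA] <- 1
  phiD[free] <- as.numeric(Matrix::solve(K[free, free],
                                         -K[free, cA] %*% rep(1, length(cA))))
  I0 <- sum((K %*% phiD)[cA])
  phiD <- phiD * (cc$mont$current_A / I0)
  f <- pot$node_potentials[seq_len(cc$sys$nn)]
  a <- f - mean(f); b <- phiD - mean(phiD)
  expect_lt(sqrt(sum((a - b)^2) / sum(b^2)), 0.01)
})

test_that("contact drop grows linearly in z while the interior J is fixed", {
  lo <- cem_cube(impedance = 1e4)
  hi <- cem_cube(impedance = 1e6)
  plo <- solve_potential(apply_complete_electrode(lo$sys, lo$mont), tol = 1e-10)
  phi <- solve_potential(apply_complete_electrode(hi$sys, hi$mont), tol = 1e-10)
  jlo <- current_density(lo$sys, plo)
  jhi <- current_density(hi$sys, phi)
  expect_lt(max(abs(jhi$magnitude - jlo$magnitude)) / max(jlo$magnitude),
            5e-3)
  drop <- function(pot, cc) {
    nodes <- cc$sys$node_index[cc$mont$patches[[1]]$contact_nodes]
    pot$node_potentials[cc$sys$nn + 1L] - mean(pot$node_potentials[nodes])
  }
  expect_equal(drop(phi, hi) / drop(plo, lo), 100, tolerance = 1e-3)
  ## per-electrode current equals +/- I at the solver tolerance
  expect_lt(plo$report$imbalance_A, 1e-8 * lo$mont$current_A)
})

test_that("non-positive contact impedance is rejected", {
  cc <- cem_cube()
  cc$mont$contact_impedance_ohm <- 0
  expect_error(apply_complete_electrode(cc$sys, cc$mont), "positive")
})
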