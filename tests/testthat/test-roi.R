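## shared coarse solution for field-based summaries
roi_solution <- function() cached("roi_solution", function() {
  ph <- place_montage(head4(), "F7-F8", current_A = 1e-3)
  list(ph = ph, rois = build_rois(ph),
       sol = simulate_montage(ph, conductivity_preset("model2")))
})

test_that("ROIs are nonempty, pairwise disjoint and follow the fixed rules", {
  rs <- roi_solution()
  rois <- rs$rois
  expect_true(all(vapply(rois, length, 1L) > 0L))
  nm <- names(rois)
  ## the retina layer is by definition part of the eye-surface layer; all
  ## other ROI pairs are disjoint
  expect_true(all(rois$retina_right %in% rois$eye_surface_right))
  expect_true(all(rois$retina_left %in% rois$eye_surface_left))
  nested <- function(a, b)
    (grepl("^retina", a) && grepl("^eye_surface", b)) ||
    (grepl("^retina", b) && grepl("^eye_surface", a))
  for (i in seq_along(rois)) for (j in seq_len(i - 1L))
    if (!nested(nm[i], nm[j]))
      expect_length(intersect(rois[[i]], rois[[j]]), 0L)
  ## retina ROI = retina-labeled posterior layer (same rule as embed_eyes)
  ph <- rs$ph
  rid <- match("retina", ph$tissue_names)
  d <- dim(ph$labels)
  right_lab <- which(ph$labels == rid)
  x <- ph$origin_mm[1] + (((right_lab - 1) %% d[1]) + 0.5) * ph$spacing_mm
  expect_setequal(rois$retina_right, right_lab[x > 0])
  ## mirror symmetry of the occipital caps
  mirror_vox <- function(v) {
    v0 <- v - 1L
    i <- v0 %% d[1]; rest <- v0 %/% d[1]
    (d[1] - 1L - i) + d[1] * rest + 1L
  }
  expect_setequal(mirror_vox(rois$oc_right), rois$oc_left)
  expect_error(build_rois(head4(), lgn_radius_mm = 0.1), "empty ROI")
})

test_that("ROI means are exact on uniform fields and linear in current", {
  bp <- bar_problem(n = 10, current = 1)
  pot <- solve_potential(bp$system, bp$rhs, tol = 1e-12)
  fld <- current_density(bp$system, pot)
  roi <- bp$system$active_voxels[3:7]
  expect_equal(mean_current_density(fld, roi), 1000 / 4e-6, tolerance = 1e-9)
  pot2 <- solve_potential(bp$system, 2 * bp$rhs, tol = 1e-12)
  fld2 <- current_density(bp$system, pot2)
  expect_equal(mean_current_density(fld2, roi),
               2 * mean_current_density(fld, roi), tolerance = 1e-12)
  expect_error(mean_current_density(fld, integer(0)), "empty")
})

test_that("summary-table round trip preserves the reference eye density", {
  fx <- load_fixtures()
  v <- fx$table1$eye_density_eye_model[fx$table1$montage == "Fp2-So"]
  expect_identical(v, 186.7)
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(fx$table1, tmp, row.names = FALSE)
  back <- utils::read.csv(tmp)
  expect_identical(back$eye_density_eye_model[back$montage == "Fp2-So"],
                   186.7)
})

test_that("retinal maps bin by quadrant and eccentricity and flip correctly", {
  rs <- roi_solution()
  fld <- rs$sol$field
  ## uniform synthetic field: all sector means equal
  uf <- fld
  uf$magnitude <- rep(2e-3, length(fld$magnitude))
  m <- retinal_topographic_map(uf, rs$ph, rs$rois$retina_right)
  expect_true(all(abs(m$mean[m$n > 0] - 2) < 1e-12))
  ## single hot element in the retinal lower-left quadrant shows up in the
  ## visual-field upper-right sector
  d <- dim(rs$ph$labels)
  ctr <- rs$ph$eyes$center_right
  v0 <- rs$rois$retina_right - 1L
  ax <- phosfem:::axis_centers(rs$ph)
  q <- cbind(ax$x[v0 %% d[1] + 1L] - ctr[1],
             ax$y[(v0 %/% d[1]) %% d[2] + 1L] - ctr[2],
             ax$z[v0 %/% (d[1] * d[2]) + 1L] - ctr[3])
  ll <- which(q[, 1] < 0 & q[, 3] < 0)[1]
  hot <- fld
  hot$magnitude <- rep(0, length(fld$magnitude))
  hot$magnitude[match(rs$rois$retina_right[ll], fld$voxels)] <- 1e-3
  mr <- retinal_topographic_map(hot, rs$ph, rs$rois$retina_right,
                                convention = "retinal")
  mv <- retinal_topographic_map(hot, rs$ph, rs$rois$retina_right,
                                convention = "visual_field")
  expect_gt(sum(mr$mean[, "lower_left"], na.rm = TRUE), 0)
  expect_gt(sum(mv$mean[, "upper_right"], na.rm = TRUE), 0)
  expect_equal(sum(mv$mean > 0, na.rm = TRUE), 1)
  ## sector means agree with brute-force membership enumeration, and the
  ## summary conserves the ROI total
  mreal <- retinal_topographic_map(fld, rs$ph, rs$rois$retina_right)
  mag <- 1000 * fld$magnitude[match(rs$rois$retina_right, fld$voxels)]
  pol <- acos(pmin(1, pmax(-1, (-q[, 2]) / sqrt(rowSums(q^2))))) * 180 / pi
  ring <- ifelse(pol <= 30, "central", "peripheral")
  quad <- ifelse(q[, 3] >= 0,
                 ifelse(q[, 1] >= 0, "upper_right", "upper_left"),
                 ifelse(q[, 1] >= 0, "lower_right", "lower_left"))
  for (rg in rownames(mreal$mean)) for (qd in colnames(mreal$mean)) {
    sel <- ring == rg & quad == qd
    if (any(sel)) expect_equal(mreal$mean[rg, qd], mean(mag[sel]))
  }
  expect_equal(sum(mreal$mean * mreal$n, na.rm = TRUE), sum(mag),
               tolerance = 1e-12)
  expect_error(retinal_topographic_map(fld, rs$ph, rs$rois$retina_right,
                                       optic_axis = c(0, 0, 0)), "axis")
})

test_that("electrode-eye distances match direct coordinate computation", {
  rs <- roi_solution()
  dd <- electrode_eye_distances(rs$ph, rois = rs$rois)
  ## direct geometry: centroid of each footprint to the right-eye center
  d <- dim(rs$ph$labels)
  ax <- phosfem:::axis_centers(rs$ph)
  byhand <- vapply(rs$ph$montage$patches, function(p) {
    v0 <- p$footprint_voxels - 1L
    pc <- c(mean(ax$x[v0 %% d[1] + 1L]),
            mean(ax$y[(v0 %/% d[1]) %% d[2] + 1L]),
            mean(ax$z[v0 %/% (d[1] * d[2]) + 1L]))
    sqrt(sum((pc - rs$ph$eyes$center_right)^2))
  }, 0)
  expect_equal(unname(dd["eye_cm"]), mean(byhand) / 10, tolerance = 1e-12)
})

test_that("near-eye montages deliver more retinal current than far ones", {
  rs <- roi_solution()
  cond <- conductivity_preset("model2")
  sol_so <- simulate_montage(place_montage(head4(), "Fp2-So"), cond)
  cz <- simulate_montage(place_montage(head4(), "Cz-F8"), cond)
  m_so <- mean_current_density(sol_so$field, rs$rois$retina_right)
  m_cz <- mean_current_density(cz$field, rs$rois$retina_right)
  expect_gt(m_so, m_cz)
})
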