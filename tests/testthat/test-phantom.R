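test_that("layered-head voxel counts match analytic shell volumes", {
  ph <- build_layered_head(c(92, 86, 80, 78),
                           c("scalp", "skull", "csf", "brain"), 2)
  cnt <- as.numeric(table(ph$labels[ph$labels > 0L]))
  shell <- function(r1, r2) 4 / 3 * pi * (r1^3 - r2^3) / 2^3
  expected <- c(shell(92, 86), shell(86, 80), shell(80, 78), shell(78, 0))
  expect_true(all(abs(cnt / expected - 1) < 0.05))
})

test_that("single-radius head is a homogeneous ball of the right volume", {
  ph <- build_layered_head(50, "scalp", 2)
  vol <- sum(ph$labels == 1L) * 2^3
  expect_lt(abs(vol / (4 / 3 * pi * 50^3) - 1), 0.02)
  expect_identical(sort(unique(as.integer(ph$labels))), c(0L, 1L))
})

test_that("a shell thinner than one voxel is rejected by name", {
  expect_error(
    build_layered_head(c(92, 86, 82), c("scalp", "skull", "csf"), 5),
    "skull")
  expect_error(
    build_layered_head(c(92, 86, 82), c("scalp", "skull", "csf"), 10),
    "thinner than one voxel")
})

test_that("phantom construction is deterministic and mirror-symmetric", {
  a <- default_head_phantom("model2", spacing_mm = 4, torso = FALSE)
  b <- default_head_phantom("model2", spacing_mm = 4, torso = FALSE)
  expect_identical(a$labels, b$labels)
  d <- dim(a$labels)
  expect_identical(a$labels, a$labels[d[1]:1, , ])   # midsagittal mirror
})

test_that("eyes satisfy the enclosure and layer invariants", {
  ph <- head4()
  lab <- ph$labels
  nm <- ph$tissue_names
  eye_ids <- match(c("sclera", "retina", "cornea", "vitreous", "aqueous",
                     "lens", "optic_nerve"), nm)
  eyemask <- array(lab %in% eye_ids, dim(lab))
  ## brute-force: no eye voxel may have an air face-neighbor
  idx <- which(eyemask, arr.ind = TRUE)
  d <- dim(lab)
  for (k in seq_len(nrow(idx))) {
    v <- idx[k, ]
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      w <- v; w[ax] <- w[ax] + s
      if (any(w < 1L) || any(w > d)) {
        fail("eye voxel on the grid boundary")
      } else {
        expect_gt(lab[w[1], w[2], w[3]], 0L)
      }
    }
  }
})

test_that("retina is a single connected one-element posterior layer", {
  ph <- head4()
  lab <- ph$labels
  rid <- match("retina", ph$tissue_names)
  ctr <- ph$eyes$center_right
  r <- ph$eyes$radius_mm
  ## independent reconstruction: geometric eyeball voxels (center within the
  ## eye radius) with a face neighbor outside the ball, on the posterior side
  d <- dim(lab)
  ax <- list(x = ph$origin_mm[1] + (seq_len(d[1]) - 0.5) * ph$spacing_mm,
             y = ph$origin_mm[2] + (seq_len(d[2]) - 0.5) * ph$spacing_mm,
             z = ph$origin_mm[3] + (seq_len(d[3]) - 0.5) * ph$spacing_mm)
  dx2 <- outer(outer((ax$x - ctr[1])^2, (ax$y - ctr[2])^2, "+"),
               (ax$z - ctr[3])^2, "+")
  ball <- dx2 <= r^2
  retina_expect <- integer(0)
  bidx <- which(ball, arr.ind = TRUE)
  for (k in seq_len(nrow(bidx))) {
    v <- bidx[k, ]
    onedge <- FALSE
    for (axn in 1:3) for (s in c(-1L, 1L)) {
      w <- v; w[axn] <- w[axn] + s
      if (any(w < 1L) || any(w > d) || !ball[w[1], w[2], w[3]]) onedge <- TRUE
    }
    qa <- (ax$y[v[2]] - ctr[2])     # optic axis is +y
    if (onedge && qa < 0)
      retina_expect <- c(retina_expect,
                         v[1] + d[1] * (v[2] - 1L + d[2] * (v[3] - 1L)))
  }
  retina_have <- which(lab == rid)                  # both eyes
  retina_have <- retina_have[                       # right eye only (x > 0)
    ax$x[(retina_have - 1) %% d[1] + 1] > 0]
  ## the optic-nerve stub overwrites the retina at the posterior pole, so the
  ## labeled retina is the reconstructed posterior layer minus nerve voxels
  expect_true(all(retina_have %in% retina_expect))
  missing <- setdiff(retina_expect, retina_have)
  if (length(missing)) {
    nid <- match("optic_nerve", ph$tissue_names)
    expect_true(all(lab[missing] == nid))
  }
  ## connectivity of the labeled layer under 26-adjacency
  mask <- array(FALSE, d); mask[retina_have] <- TRUE
  midx <- which(mask, arr.ind = TRUE)
  comp <- integer(nrow(midx)); comp[1] <- 1L
  repeat {
    grew <- FALSE
    for (k in which(comp == 0L)) {
      near <- comp > 0L &
        abs(midx[, 1] - midx[k, 1]) <= 1L &
        abs(midx[, 2] - midx[k, 2]) <= 1L &
        abs(midx[, 3] - midx[k, 3]) <= 1L
      if (any(near)) { comp[k] <- 1L; grew <- TRUE }
    }
    if (!grew) break
  }
  expect_true(all(comp == 1L))
})

test_that("optic nerve claims the posterior pole; eyes mirror exactly", {
  ph <- head4()
  ctr <- ph$eyes$center_right
  pole <- ctr - ph$eyes$radius_mm * ph$eyes$axis
  d <- dim(ph$labels)
  h <- ph$spacing_mm
  vi <- pmin(pmax(floor((pole - ph$origin_mm) / h) + 1, 1), d)
  expect_identical(ph$tissue_names[ph$labels[vi[1], vi[2], vi[3]]],
                   "optic_nerve")
  expect_identical(ph$labels, ph$labels[d[1]:1, , ])
})

test_that("an eye overlapping the skull errors unless the orbit is carved", {
  ph <- build_layered_head(c(92, 86, 80, 76),
                           c("scalp", "skull", "csf", "brain"), 4)
  expect_error(embed_eyes(ph, carve_orbit = FALSE), "skull")
  expect_silent({ph2 <- embed_eyes(ph)})
  ## an eye poking out of the head is rejected up front
  expect_error(embed_eyes(ph, eye_center_mm = c(40, 75, 0)),
               "fit inside")
})

test_that("torso attaches as one conducting component with a shoulder point", {
  ph <- head4t()
  expect_false(is.null(ph$torso))
  ## flood fill from the head center reaches the torso bottom
  cond <- ph$labels > 0L
  seed <- array(FALSE, dim(cond))
  seed[round(dim(cond)[1] / 2), round(dim(cond)[2] / 2),
       which.max(apply(cond, 3, sum))] <- TRUE
  reach <- phosfem:::flood_fill6(cond, seed & cond)
  expect_true(all(reach[cond]))
  ## rS landmark lies on the lateral torso surface
  rs <- ph$landmarks$rS
  expect_equal(rs[1], ph$torso$radius_mm)
  expect_true(rs[3] < -ph$head_radius_mm)
  ## zero-length torso is the identity
  base <- build_layered_head(c(46, 43, 40), c("scalp", "skull", "brain"), 2)
  expect_identical(attach_torso(base, length_mm = 0), base)
})

test_that("halving the spacing changes tissue volume fractions by < 3%", {
  frac <- function(spacing) {
    ph <- build_layered_head(c(92, 86, 80, 76),
                             c("scalp", "skull", "csf", "brain"), spacing)
    tab <- table(factor(ph$labels[ph$labels > 0L], levels = 1:4))
    as.numeric(tab) / sum(tab)
  }
  f4 <- frac(4); f2 <- frac(2)
  expect_true(all(abs(f2 - f4) < 0.03))
})
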