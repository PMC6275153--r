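test_that("sella centre is the arc-length centroid of the traced border", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(0, 0, 0))
  expect_vec_equal(sella_from_trace(sq), c(0.5, 0.5, 0))

  # brute-force oracle: centroid of a dense uniform arc-length resampling
  set.seed(31)
  tr <- matrix(cumsum(rnorm(30)), 10, 3)
  dense <- resample_polyline(tr, step = sum(sqrt(rowSums(diff(tr)^2))) / 1e4)
  expect_vec_equal(sella_from_trace(tr), colMeans(dense), 1e-3)

  # parameterization invariance: inserting collinear vertices changes nothing
  tr2 <- tr[rep(1:10, each = 2), ]
  for (i in seq(2, 20, by = 2)[-10]) tr2[i, ] <- (tr2[i - 1, ] + tr2[i + 1, ]) / 2
  expect_vec_equal(sella_from_trace(tr2), sella_from_trace(tr), 1e-9)

  expect_error(sella_from_trace(rbind(c(0, 0, 0), c(1, 1, 1))),
               class = "DegenerateTraceError")
})

test_that("constructed Sella and mid-Orbitale are exact midpoints, symmetric in arguments", {
  expect_vec_equal(construct_c_sella(c(10, 2, 4), c(-8, 2, 6)), c(1, 2, 5))
  p <- c(3.2, -1, 7)
  expect_vec_equal(construct_c_sella(p, p), p)
  expect_vec_equal(construct_c_sella(c(1, 2, 3), c(4, 5, 6)),
                   construct_c_sella(c(4, 5, 6), c(1, 2, 3)))
  expect_vec_equal(mid_orbitale(c(28, 40, -20), c(-28, 40, -20)), c(0, 40, -20))
  expect_vec_equal(mid_orbitale(c(30, 41, -18), c(-26, 39, -22)), c(2, 40, -20))
})

test_that("Porion axis runs right-to-left through the midpoint", {
  ax <- porion_axis(c(30, 0, 0), c(-30, 0, 0))
  expect_vec_equal(ax$point, c(0, 0, 0))
  expect_vec_equal(ax$direction, c(-1, 0, 0))

  ax2 <- porion_axis(c(30, 0, 0), c(-30, 2, 1))
  expect_vec_equal(ax2$point, c(0, 1, 0.5))
  expect_vec_equal(ax2$direction, c(-60, 2, 1) / sqrt(sum(c(-60, 2, 1)^2)), 1e-12)

  expect_error(porion_axis(c(1, 1, 1), c(1, 1, 1)), class = "DegenerateAxisError")
})

test_that("C-Orbitale keeps only the reliable coordinates of the raw Orbitale", {
  axis_x <- cf_line(c(0, 0, 0), c(1, 0, 0))
  # symmetric anatomy: no correction
  sym <- construct_c_orbitale(c(28, 40, -20), c(-28, 40, -20), c(0, 5, 6), axis_x)
  expect_vec_equal(sym$right, c(28, 40, -20))
  expect_vec_equal(sym$left, c(-28, 40, -20))
  # asymmetric anatomy: equalized offsets, shared Z, centred Y
  asym <- construct_c_orbitale(c(30, 40, -18), c(-26, 40, -22), c(0, 5, 6), axis_x)
  expect_vec_equal(asym$right, c(28, 40, -20))
  expect_vec_equal(asym$left, c(-28, 40, -20))
  # mediolateral (X) perturbations preserving the mean offset are discarded
  asym2 <- construct_c_orbitale(c(26, 40, -18), c(-30, 40, -22), c(0, 5, 6), axis_x)
  expect_vec_equal(asym2$right, asym$right)
  expect_vec_equal(asym2$left, asym$left)
  # the pair runs parallel to the axial projection of a tilted Porion axis,
  # centred mediolaterally on C-Sella and elsewhere on mid-Orbitale
  tilted <- cf_line(c(0, 0, 0), c(cos(0.2), sin(0.2), 0.05))
  cs <- c(0, 5, 6)
  co <- construct_c_orbitale(c(28, 40, -20), c(-28, 40, -20), cs, tilted)
  seg <- co$right - co$left
  expect_equal(seg[2] / seg[1], sin(0.2) / cos(0.2), tolerance = 1e-12)
  expect_equal(seg[3], 0, tolerance = 1e-12)
  xhat <- c(cos(0.2), sin(0.2), 0)
  mid <- (co$right + co$left) / 2
  expect_lt(abs(sum((mid - cs) * xhat)), 1e-12)          # centred on C-Sella
  moff <- mid - c(0, 40, -20)                            # vs mid-Orbitale
  expect_lt(sqrt(sum((moff - sum(moff * xhat) * xhat)^2)), 1e-12)
  expect_error(construct_c_orbitale(c(28, 40, -20), c(-28, 40, -20), cs,
                                    cf_line(c(0, 0, 0), c(0, 0, 1))),
               class = "MidlineUndefinedError")
})

test_that("C-FH is the orthogonal least-squares plane of its four points", {
  pl <- fit_cfh(c(30, -40, 0), c(-30, -40, 0), c(28, 40, 0), c(-28, 40, 0))
  expect_vec_equal(pl$normal, c(0, 0, 1))
  expect_lt(pl$fit_residual, 1e-12)

  # independent total-least-squares oracle via the covariance eigenproblem
  set.seed(32)
  pts <- rbind(c(30, -40, 0), c(-30, -40, 0), c(28, 40, 0), c(-28, 40, 0)) +
    matrix(rnorm(12, 0, 0.1), 4, 3)
  pl2 <- fit_cfh(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
  cov <- crossprod(sweep(pts, 2, colMeans(pts)))
  ev <- eigen(cov, symmetric = TRUE)$vectors[, 3]
  if (ev[3] < 0) ev <- -ev
  expect_lt(acos(min(1, abs(sum(pl2$normal * ev)))), 1e-9)

  # exactly-constructed inputs (two parallel lines) are coplanar
  o <- oriented_phantom()
  expect_lt(o$frame$cfh$fit_residual, 1e-9)

  expect_error(fit_cfh(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)),
               class = "DegeneratePlaneError")
})

test_that("corrected midline is in-plane, perpendicular to the Porion axis, anterior", {
  pl <- cf_plane(c(0, 0, 0), c(0, 0, 1))
  ml <- corrected_midline(c(0, 0, 0), cf_line(c(0, 0, 0), c(1, 0, 0)), pl,
                          anterior_ref = c(0, 40, 0))
  expect_vec_equal(ml$point, c(0, 0, 0))
  expect_vec_equal(ml$direction, c(0, 1, 0))

  th <- 10 * pi / 180
  ml2 <- corrected_midline(c(0, 0, 0), cf_line(c(0, 0, 0), c(cos(th), sin(th), 0)), pl)
  expect_vec_equal(ml2$direction, c(-sin(th), cos(th), 0), 1e-12)

  ml3 <- corrected_midline(c(0, 0, 5), cf_line(c(0, 0, 5), c(1, 0, 0)), pl)
  expect_vec_equal(ml3$point, c(0, 0, 0))

  expect_error(corrected_midline(c(0, 0, 0), cf_line(c(0, 0, 0), c(0, 0, 1)), pl),
               class = "MidlineUndefinedError")
})

test_that("orientation transform maps the frame onto canonical axes", {
  dp <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  fr <- orientation_transform(cf_plane(c(0, 0, 0), c(0, 0, 1)),
                              cf_line(c(0, 0, 0), c(0, 1, 0)), dp)
  expect_lt(rotation_angle(fr$orientation), 1e-9)
  expect_vec_equal(fr$orientation$translation, c(0, 0, 0))

  dp5 <- cbind(dp[, 1:2], 5)
  fr5 <- orientation_transform(cf_plane(c(0, 0, 5), c(0, 0, 1)),
                               cf_line(c(0, 0, 5), c(0, 1, 0)), dp5)
  expect_lt(rotation_angle(fr5$orientation), 1e-9)
  expect_vec_equal(fr5$orientation$translation, c(0, 0, -5))

  # equivariance: moving the inputs rigidly composes with the orientation
  set.seed(33)
  mv <- random_rigid_transform(30, 15)
  dp_m <- apply_transform(mv, dp)
  fr_m <- orientation_transform(
    cf_plane(apply_transform(mv, c(0, 0, 0)), as.numeric(mv$rotation %*% c(0, 0, 1))),
    cf_line(apply_transform(mv, c(0, 0, 0)), as.numeric(mv$rotation %*% c(0, 1, 0))),
    dp_m)
  comp <- compose_transforms(fr_m$orientation, mv)
  expect_lt(rotation_angle(compose_transforms(comp, invert_transform(fr$orientation))), 1e-9)
  expect_vec_equal(comp$translation, fr$orientation$translation, 1e-9)

  expect_error(orientation_transform(cf_plane(c(0, 0, 0), c(0, 0, 1)),
                                     cf_line(c(0, 0, 0), c(0, 0.5, 0.5)), dp),
               class = "FrameConstructionError")
})

test_that("applying the frame orients landmarks rigidly and checks the frame tag", {
  o <- oriented_phantom()
  frame <- o$frame
  lms <- generate_phantom(phantom_spec())$pre
  lms$frame <- "superimposed"
  oriented <- apply_frame(lms, frame)
  expect_identical(oriented$frame, "oriented")
  expect_vec_equal(dist(landmark_matrix(oriented)), dist(landmark_matrix(lms)), 1e-9)

  # C-FH defining points end up at |Z| <= fit residual
  dp <- rbind(lms$points$`R-Porion`, lms$points$`L-Porion`)
  dp_o <- apply_transform(frame$orientation, dp)
  expect_lt(max(abs(dp_o[, 3])), frame$cfh$fit_residual + 1e-9)

  lms$frame <- "native"
  expect_error(apply_frame(lms, frame), class = "FrameMismatchError")
})

test_that("symmetric phantom: C-Orbitale equals Orbitale and midline is the true midsagittal axis", {
  o <- oriented_phantom()
  cons <- attr(o$frame, "constructed")
  ph <- o$ph
  expect_vec_equal(cons$`R-C-Orbitale`, ph$pre$points$`R-Orbitale`)
  expect_vec_equal(cons$`L-C-Orbitale`, ph$pre$points$`L-Orbitale`)
  ml <- o$frame$midline
  expect_vec_equal(abs(ml$direction), c(0, 1, 0))
  expect_lt(abs(ml$point[1]), 1e-9)
  expect_lt(abs(ml$point[3]), 1e-9)
})

test_that("C-FH and midline are invariant to excluded Orbitale coordinates", {
  base <- generate_phantom(phantom_spec(asymmetry = list(
    `R-Orbitale` = c(-2, 1, 0), `L-Orbitale` = c(1, -0.5, 0))))$pre
  base$frame <- "superimposed"
  f0 <- build_reference_frame(base)

  pert <- base
  # mean-offset-preserving X perturbation (+delta toward midline on the right,
  # +delta away on the left) and antisymmetric Y perturbation
  pert$points$`R-Orbitale` <- pert$points$`R-Orbitale` + c(1.5, 0.7, 0)
  pert$points$`L-Orbitale` <- pert$points$`L-Orbitale` + c(1.5, -0.7, 0)
  f1 <- build_reference_frame(pert)
  expect_vec_equal(f1$cfh$normal, f0$cfh$normal)
  expect_vec_equal(f1$cfh$point, f0$cfh$point)
  expect_vec_equal(f1$midline$direction, f0$midline$direction)
  expect_vec_equal(f1$midline$point, f0$midline$point)
})

test_that("orientation is idempotent: an oriented frame yields the identity", {
  o <- oriented_phantom()
  pre_o <- o$pre
  f2 <- build_reference_frame(pre_o)
  expect_lt(rotation_angle(f2$orientation), 1e-9)
  expect_vec_equal(f2$orientation$translation, c(0, 0, 0))
})

test_that("reference frame JSON round-trips", {
  o <- oriented_phantom()
  f <- tempfile(fileext = ".json")
  write_reference_frame(o$frame, f)
  back <- read_reference_frame(f)
  expect_vec_equal(back$cfh$normal, o$frame$cfh$normal, 1e-12)
  expect_vec_equal(back$origin, o$frame$origin, 1e-12)
  expect_vec_equal(back$orientation$rotation, o$frame$orientation$rotation, 1e-12)
})
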