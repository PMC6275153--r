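test_that("mid-maxillary perpendicular plane is anteroposterior through the ANS-PNS midpoint", {
  aux <- mid_max_plane(c(0, 45, -25), c(0, -5, -25))
  expect_vec_equal(aux$plane$point, c(0, 20, -25))
  expect_vec_equal(aux$plane$normal, c(0, -1, 0))
  # differing Z: the normal is projected into C-FH, so its Z component is 0
  aux2 <- mid_max_plane(c(1, 45, -22), c(-1, -5, -28))
  expect_equal(aux2$plane$normal[3], 0, tolerance = 1e-12)
  expect_vec_equal(aux2$plane$point, c(0, 20, -25))
  # seeded inputs: point is always the midpoint
  set.seed(41)
  for (i in 1:5) {
    a <- rnorm(3) * 10; p <- rnorm(3) * 10
    if (sqrt(sum((a - p)[1:2]^2)) < 1e-3) next
    expect_vec_equal(mid_max_plane(a, p)$plane$point, (a + p) / 2, 1e-12)
  }
  expect_error(mid_max_plane(c(0, 10, -25), c(0, 10, -5)),
               class = "DegeneratePlaneError")
})

test_that("concavity detector finds an analytic notch apex and prefers the medial notch", {
  midl <- oriented_midline()
  notch_contour <- function(wall, apexes_x, apexes_z, halfh = 4) {
    zs <- seq(-8, -46, by = -0.05)
    ux <- vapply(zs, function(z) {
      d <- 0
      for (i in seq_along(apexes_x)) {
        dz <- z - apexes_z[i]
        if (abs(dz) < halfh)
          d <- max(d, (wall - apexes_x[i]) * (1 + cos(pi * dz / halfh)) / 2)
      }
      wall - d
    }, numeric(1))
    cbind(-ux, 21, zs)   # right side, on the plane y = 21
  }
  # single cosine notch: apex recovered within the resampling step
  ct <- notch_contour(33, 30, -25)
  got <- most_concave_point(ct, midl)
  expect_vec_equal(got, c(-30, 21, -25), 0.1)
  # two notches at 12 and 18 mm from the midline: the nearer one wins
  ct2 <- notch_contour(22, c(18, 12), c(-18, -36))
  got2 <- most_concave_point(ct2, midl)
  expect_vec_equal(got2, c(-12, 21, -36), 0.1)
  # exhaustive oracle: the detected point is the global medial extremum
  # among indentation apexes of the densely resampled contour
  rs <- resample_polyline(ct2, 0.02)
  oracle <- rs[which.min(abs(rs[, 1])), ]
  expect_vec_equal(got2, oracle, 0.1)
  # convex arcs carry no concavity
  th <- seq(-0.9, 0.9, length.out = 80)
  expect_error(most_concave_point(cbind(-33 - 6 * cos(th), 21, -25 + 12 * sin(th)),
                                  midl),
               class = "NoConcavityError")
  expect_error(most_concave_point(cbind(-33 + 6 * cos(th), 21, -25 + 12 * sin(th)),
                                  midl),
               class = "NoConcavityError")
})

test_that("most inferior point takes the lowest sample, ties broken toward the midline", {
  v <- rbind(c(20, 20, -30), c(14, 20, -38), c(10, 20, -31))
  expect_vec_equal(most_inferior_point(v), c(14, 20, -38), 1e-9)
  flat <- rbind(c(18, 20, -30), c(16, 20, -38), c(10, 20, -38), c(8, 20, -30))
  expect_vec_equal(most_inferior_point(flat), c(10, 20, -38), 1e-9)
  set.seed(42)
  zig <- cbind(10 + cumsum(rnorm(40, 0, 0.5)), 20, -30 - 5 * sin(seq(0, 3, length.out = 40)))
  rs <- resample_polyline(zig, 0.1, keep_vertices = TRUE)
  expect_vec_equal(most_inferior_point(zig), rs[which.min(rs[, 3]), ], 1e-9)
})

test_that("molar axis is the apical-plane normal through the centroid, equivariant", {
  ax <- molar_axis(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_vec_equal(ax$direction, c(0, 0, 1))
  expect_vec_equal(ax$point, c(1, 1, 0) / 3)
  set.seed(43)
  mv <- random_rigid_transform(25, 10)
  a <- c(-26, 27, -24); b <- c(-26, 19, -24); p <- c(-20, 23, -24)
  ax1 <- molar_axis(a, b, p)
  ax2 <- molar_axis(apply_transform(mv, a), apply_transform(mv, b),
                    apply_transform(mv, p))
  d_rot <- as.numeric(mv$rotation %*% ax1$direction)
  expect_lt(min(sqrt(sum((ax2$direction - d_rot)^2)),
                sqrt(sum((ax2$direction + d_rot)^2))), 1e-9)
  expect_vec_equal(ax2$point, apply_transform(mv, ax1$point), 1e-9)
  expect_error(molar_axis(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               class = "DegeneratePlaneError")
})

test_that("premolar axis runs from cusp tip toward the apex", {
  ax <- premolar_axis(c(-23, 23, -36), c(-19.5, 23, -16))
  expect_vec_equal(ax$point, c(-23, 23, -36))
  expect_vec_equal(ax$direction, c(3.5, 0, 20) / sqrt(3.5^2 + 400), 1e-12)
  expect_error(premolar_axis(c(1, 2, 3), c(1, 2, 3)), class = "DegenerateAxisError")
})

test_that("mediolateral change projects onto the C-FH mediolateral axis", {
  expect_equal(mediolateral_change(c(28, 20, -25), c(30.5, 20, -25)), 2.5)
  expect_equal(mediolateral_change(c(-26, 20, -25), c(-26, 22, -25)), 0)
  expect_equal(mediolateral_change(c(-28, 20, -25), c(-30.5, 21, -24)), 2.5)
  expect_error(mediolateral_change(c(28, 20, -25), c(-28, 20, -25)),
               class = "SideMismatchError")
  # simulation with known ground truth: mean recovery of a 2.0 mm expansion
  set.seed(44)
  reps <- replicate(100, {
    pre <- c(-30, 23, -25) + rnorm(3, 0, 0.1)
    post <- c(-32, 23, -25) + rnorm(3, 0, 0.1)
    mediolateral_change(pre, post)
  })
  expect_lt(abs(mean(reps) - 2.0), 0.03)
})

test_that("projected angular change matches an independent projection oracle", {
  o <- oriented_phantom()
  aux <- phantom_aux(o)
  a <- cf_line(c(-22, 23, -30), c(0, 0, 1))
  expect_equal(projected_angle_change(a, a, aux), 0)
  # in-plane rotation carrying the apex medially on the right side: +10 deg
  th <- 10 * pi / 180
  b <- cf_line(a$point, c(sin(th), 0, cos(th)))
  expect_equal(projected_angle_change(a, b, aux, lateral_sign = -1), 10,
               tolerance = 1e-9)
  # out-of-plane seeded axes against an arccos/cross oracle
  set.seed(45)
  for (i in 1:10) {
    d1 <- rnorm(3); d2 <- rnorm(3)
    proj <- function(d) {
      p <- d - sum(d * aux$plane$normal) * aux$plane$normal
      p / sqrt(sum(p^2))
    }
    p1 <- proj(d1); p2 <- proj(d2)
    mag <- acos(pmin(1, pmax(-1, sum(p1 * p2)))) * 180 / pi
    sgn <- sign(sum(cross_oracle(p1, p2) * aux$plane$normal))
    got <- projected_angle_change(cf_line(c(0, 0, 0), d1), cf_line(c(0, 0, 0), d2),
                                  aux, lateral_sign = 1)
    expect_equal(abs(got), mag, tolerance = 1e-9)
    if (mag > 1e-6) expect_equal(sign(got), sgn)
  }
  expect_error(projected_angle_change(cf_line(c(0, 0, 0), aux$plane$normal),
                                      a, aux),
               class = "ProjectionDegenerateError")
})

test_that("measure_all reproduces injected expansion exactly on a noiseless phantom", {
  rep0 <- run_measurements(phantom_spec(expansion = list(max_mm = 0, alveo_mm = 0,
                                                         premolar_deg = 0, molar_deg = 0)))
  expect_lt(max(abs(rep0$value)), 1e-9)

  spec <- phantom_spec(motion = rigid_transform(rotation_about(c(1, 2, 3), 5),
                                                c(3, -2, 1.5)))
  o <- oriented_phantom(spec)
  rep1 <- measure_all(o$pre, o$post, o$frame)
  truth <- o$ph$truth$changes[rep1$parameter]
  expect_vec_equal(rep1$value, truth, 1e-9)
  expect_setequal(rep1$parameter,
                  c("R-Max", "L-Max", "R-Cres", "L-Cres", "R-ALV", "L-ALV",
                    "R-Pre", "L-Pre", "R-6", "L-6"))
  expect_identical(rep1$kind[rep1$parameter == "R-Max"], "linear")
  expect_identical(rep1$kind[rep1$parameter == "R-Pre"], "angular")
})

test_that("semi-automated detection from contours recovers the expansion", {
  o <- oriented_phantom()
  strip <- function(lms) {
    lms$points <- lms$points[setdiff(names(lms$points),
                                     c("R-Max", "L-Max", "R-Alveo", "L-Alveo"))]
    lms
  }
  rep_tr <- measure_all(strip(o$pre), strip(o$post), o$frame, on_missing = "skip")
  for (p in c("R-Max", "L-Max", "R-Cres", "L-Cres")) {
    expect_lt(abs(rep_tr$value[rep_tr$parameter == p] -
                    o$ph$truth$changes[p]), 0.15)
  }
})

test_that("missing landmarks abort or skip per configuration", {
  o <- oriented_phantom()
  pre2 <- o$pre
  pre2$points$PNS <- NULL
  expect_error(measure_all(pre2, o$post, o$frame), class = "MissingLandmarkError")
  rep2 <- measure_all(pre2, o$post, o$frame, on_missing = "skip")
  expect_false(any(c("R-Pre", "R-6", "R-ALV") %in% rep2$parameter))
  expect_true(all(c("R-Max", "R-Cres") %in% rep2$parameter))
})

test_that("measurements are invariant to a common rigid motion of both records", {
  spec <- phantom_spec()
  o <- oriented_phantom(spec)
  base <- measure_all(o$pre, o$post, o$frame)

  set.seed(46)
  mv <- random_rigid_transform(25, 20)
  ph <- generate_phantom(spec)
  pre_m <- transform_landmarks(ph$pre, mv, new_frame = "superimposed")
  post_m <- transform_landmarks(ph$post, mv, new_frame = "superimposed")
  frame_m <- build_reference_frame(pre_m)
  rep_m <- measure_all(apply_frame(pre_m, frame_m), apply_frame(post_m, frame_m),
                       frame_m)
  expect_vec_equal(rep_m$value, base$value[match(rep_m$parameter, base$parameter)],
                   1e-9)
})

test_that("projection makes linear values lower bounds of the 3D displacement", {
  set.seed(47)
  for (i in 1:20) {
    pre <- c(-25, 20, -25) + rnorm(3)
    post <- pre + rnorm(3, 0, 2)
    d3 <- sqrt(sum((post - pre)^2))
    expect_lte(abs(mediolateral_change(pre, post)), d3 + 1e-12)
  }
})

test_that("mirroring the phantom across the midsagittal plane swaps R and L records", {
  spec <- phantom_spec(asymmetry = list(`R-Max` = c(0.4, 0, 0.2)))
  o <- oriented_phantom(spec)
  base <- measure_all(o$pre, o$post, o$frame)
  mirror <- function(lms) {
    swap <- function(nm) {
      out <- nm
      out[grepl("^R-", nm)] <- sub("^R-", "L-", nm[grepl("^R-", nm)])
      out[grepl("^L-", nm)] <- sub("^L-", "R-", nm[grepl("^L-", nm)])
      out <- sub("_right$", "_TMP", out)
      out <- sub("_left$", "_right", out)
      sub("_TMP$", "_left", out)
    }
    pts <- lapply(lms$points, function(p) p * c(-1, 1, 1))
    names(pts) <- swap(names(lms$points))
    trs <- lapply(lms$traces, function(m) m %*% diag(c(-1, 1, 1)))
    names(trs) <- swap(names(lms$traces))
    landmark_set(points = pts, traces = trs, frame = lms$frame)
  }
  ph <- generate_phantom(spec)
  pre_m <- mirror(ph$pre); pre_m$frame <- "superimposed"
  post_m <- mirror(ph$post); post_m$frame <- "superimposed"
  frame_m <- build_reference_frame(pre_m)
  rep_m <- measure_all(apply_frame(pre_m, frame_m), apply_frame(post_m, frame_m),
                       frame_m)
  swapped <- ifelse(grepl("^R-", base$parameter),
                    sub("^R-", "L-", base$parameter),
                    sub("^L-", "R-", base$parameter))
  expect_vec_equal(rep_m$value[match(swapped, rep_m$parameter)], base$value, 1e-9)
})
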