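# brute-force joint-histogram MI oracle on explicit sample pairs
mi_oracle <- function(f, m, bins) {
  to_bin <- function(v, r) round((v - r[1]) / max(r[2] - r[1], 1e-12) * (bins - 1))
  jf <- to_bin(f, range(f)); jm <- to_bin(m, range(m))
  joint <- table(factor(jf, levels = 0:(bins - 1)),
                 factor(jm, levels = 0:(bins - 1))) / length(f)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ent(rowSums(joint)) + ent(colSums(joint)) - ent(as.numeric(joint))
}

test_that("self mutual information equals the masked histogram entropy", {
  ph <- generate_phantom(phantom_spec())
  vx <- voxelize_phantom(ph)
  mi <- mutual_information(vx$fixed, vx$fixed, identity_transform(), vx$mask,
                           bins = 32)
  v <- vx$fixed$voxels[vx$mask]
  b <- round((v - min(vx$fixed$voxels)) /
               diff(range(vx$fixed$voxels)) * 31)
  p <- as.numeric(table(b)) / length(b)
  expect_equal(mi, -sum(p * log(p)), tolerance = 1e-9)
})

test_that("independent noise volumes share almost no information", {
  set.seed(61)
  a <- cf_volume(array(runif(64^3), dim = c(64, 64, 64)))
  b <- cf_volume(array(runif(64^3), dim = c(64, 64, 64)))
  mi <- mutual_information(a, b, bins = 32)
  expect_lt(mi, 0.05)
  expect_gte(mi, 0)
  expect_equal(mi, mi_oracle(as.vector(a$voxels), as.vector(b$voxels), 32),
               tolerance = 1e-9)
})

test_that("an empty mask is rejected", {
  a <- cf_volume(array(1, dim = c(4, 4, 4)))
  expect_error(mutual_information(a, a, mask = array(FALSE, dim = c(4, 4, 4))),
               class = "EmptyMaskError")
  expect_error(register_masked_rigid(a, a, array(FALSE, dim = c(4, 4, 4))),
               class = "EmptyMaskError")
})

test_that("resampling honours identity, integer shifts and the half-voxel ramp", {
  set.seed(62)
  vox <- array(rnorm(10^3), dim = c(10, 10, 10))
  vol <- cf_volume(vox, spacing = c(2, 2, 2), origin = c(-3, 4, 0))
  same <- resample_volume(vol, identity_transform(), vol)
  expect_vec_equal(same$voxels, vox, 1e-9)

  shift <- rigid_transform(diag(3), c(2, 0, 0))   # exactly one voxel along x
  sh <- resample_volume(vol, shift, vol, fill = NA)
  expect_vec_equal(sh$voxels[2:10, , ], vox[1:9, , ], 1e-9)

  ramp <- cf_volume(array(rep(seq_len(10), 100), dim = c(10, 10, 10)),
                    spacing = c(1, 1, 1))
  half <- resample_volume(ramp, rigid_transform(diag(3), c(0.5, 0, 0)), ramp,
                          fill = NA)
  inner <- half$voxels[2:10, , ]
  expected <- (ramp$voxels[1:9, , ] + ramp$voxels[2:10, , ]) / 2
  expect_vec_equal(inner, expected, 1e-9)
})

test_that("self-registration returns the identity within tight tolerance", {
  ph <- generate_phantom(phantom_spec(seed = 5))
  vx <- voxelize_phantom(ph, noise_frac = 0)
  res <- register_masked_rigid(vx$fixed, vx$fixed, vx$mask)
  expect_lt(rotation_angle(res$transform), 0.05)
  expect_lt(sqrt(sum(res$transform$translation^2)), 0.05)
  expect_gte(res$final_metric, res$initial_metric)
})

test_that("a known rigid motion is recovered despite unmasked treatment displacement", {
  M <- rigid_transform(rotation_about(c(0.2, 0.5, 1), 7), c(3, -2, 1.5))
  ph <- generate_phantom(phantom_spec(motion = M,
                                      expansion = list(max_mm = 5), seed = 8))
  vx <- voxelize_phantom(ph, noise_frac = 0.02)
  res <- register_masked_rigid(vx$fixed, vx$moving, vx$mask)
  err <- compose_transforms(res$transform, M)
  expect_lt(rotation_angle(err), 0.5)
  ctr <- c(0, 0, 4)
  expect_lt(sqrt(sum((apply_transform(err, ctr) - ctr)^2)), 0.5 * 2.2)
  expect_gte(res$final_metric, res$initial_metric)
})

test_that("registration is inverse-consistent on the phantom", {
  M <- rigid_transform(rotation_about(c(1, 0.3, -0.4), 5), c(-2, 1.5, 2))
  ph <- generate_phantom(phantom_spec(motion = M, seed = 12))
  vx <- voxelize_phantom(ph, noise_frac = 0.02)
  ab <- register_masked_rigid(vx$fixed, vx$moving, vx$mask)
  # reverse direction: mask carried to the moving grid through the true motion
  mask_idx <- which(vx$mask)
  d <- dim(vx$mask)
  idx <- cbind((mask_idx - 1) %% d[1], ((mask_idx - 1) %/% d[1]) %% d[2],
               (mask_idx - 1) %/% (d[1] * d[2]))
  w_fix <- index_to_world(vx$fixed, idx)
  w_mov <- apply_transform(invert_transform(vx$true_transform), w_fix)
  idx_m <- round(world_to_index(vx$moving, w_mov))
  keep <- idx_m[, 1] >= 0 & idx_m[, 1] < d[1] & idx_m[, 2] >= 0 &
    idx_m[, 2] < d[2] & idx_m[, 3] >= 0 & idx_m[, 3] < d[3]
  mask_m <- array(FALSE, dim = d)
  mask_m[idx_m[keep, , drop = FALSE] + 1] <- TRUE
  ba <- register_masked_rigid(vx$moving, vx$fixed, mask_m)
  comp <- compose_transforms(ab$transform, ba$transform)
  expect_lt(rotation_angle(comp), 0.2)
  ctr <- c(0, 0, 4)
  expect_lt(sqrt(sum((apply_transform(comp, ctr) - ctr)^2)), 0.2)
})
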