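# Parametric skull-like phantom: the validation test bed. Landmark layout is
# loosely adult-scale (inter-Porion ~110 mm, Sella near the origin) so that
# millimetre tolerances are meaningful. The right side sits at negative X
# (X positive toward the patient's left).

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Phantom specification
#'
#' Parameters of the synthetic skull-like phantom used to validate the
#' pipeline. Defaults encode the standard validation conditions: a 2.5 mm
#' per-side mediolateral expansion of the maxillary basal bone, 3.0 mm at
#' the alveolar crest, 6 degrees of buccal premolar tipping and 4 degrees of
#' buccal molar tipping, with no inter-timepoint motion, no asymmetry and
#' no digitization noise unless requested.
#'
#' @param scale overall size multiplier (1 = adult scale, inter-Porion
#'   ~110 mm).
#' @param asymmetry named list of per-landmark offsets (length-3, mm) added
#'   to the template anatomy (e.g. \code{list("R-Orbitale" = c(-2, 1, 0))}).
#' @param expansion list with \code{max_mm}, \code{alveo_mm} (per-side
#'   mediolateral displacement, mm) and \code{premolar_deg},
#'   \code{molar_deg} (buccal tipping, degrees).
#' @param motion \code{rigid_transform} applied to the whole post-treatment
#'   record (the inter-timepoint head motion the superimposition must
#'   recover).
#' @param pre_tilt \code{rigid_transform} from the phantom's ideal frame to
#'   the pre-treatment native frame (head mis-orientation at acquisition).
#' @param noise_sd isotropic digitization noise SD, mm, applied to every
#'   digitized point and trace vertex.
#' @param seed integer seed making the phantom byte-reproducible.
#' @return A \code{phantom_spec} list.
#' @export
phantom_spec <- function(scale = 1, asymmetry = list(),
                         expansion = list(max_mm = 2.5, alveo_mm = 3.0,
                                          premolar_deg = 6, molar_deg = 4),
                         motion = identity_transform(),
                         pre_tilt = identity_transform(),
                         noise_sd = 0, seed = 1L) {
  defaults <- list(max_mm = 2.5, alveo_mm = 3.0, premolar_deg = 6, molar_deg = 4)
  expansion <- utils::modifyList(defaults, expansion)
  stopifnot(noise_sd >= 0, scale > 0)
  structure(list(scale = scale, asymmetry = asymmetry, expansion = expansion,
                 motion = motion, pre_tilt = pre_tilt,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# template landmark positions (ideal frame: C-FH is Z=0, midsagittal is X=0)
.phantom_template <- function(scale) {
  pts <- list(
    `R-Porion`   = c(-55, -38, 0),
    `L-Porion`   = c( 55, -38, 0),
    `R-Orbitale` = c(-28,  42, 0),
    `L-Orbitale` = c( 28,  42, 0),
    ANS = c(0, 48, -22), PNS = c(0, -2, -22),
    `R-Max` = c(-30, 23, -25), `L-Max` = c(30, 23, -25),
    `R-Alveo` = c(-19, 23, -32), `L-Alveo` = c(19, 23, -32),
    `R-Pre-cusp` = c(-23, 23, -36), `R-Pre-apex` = c(-19.5, 23, -16),
    `L-Pre-cusp` = c( 23, 23, -36), `L-Pre-apex` = c( 19.5, 23, -16),
    `R-6-apex-mb` = c(-26, 27, -24), `R-6-apex-db` = c(-26, 19, -24),
    `R-6-apex-p`  = c(-20, 23, -24),
    `L-6-apex-mb` = c( 26, 27, -24), `L-6-apex-db` = c( 26, 19, -24),
    `L-6-apex-p`  = c( 20, 23, -24))
  lapply(pts, function(p) p * scale)
}

# closed elliptical sella border trace around a centre; point symmetry makes
# its arc-length centroid the centre exactly
.sella_border <- function(center, scale, n = 48) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  e1 <- c(0, 1, 0); e2 <- c(0.15, 0, 1); e2 <- e2 / sqrt(sum(e2^2))
  v <- t(vapply(th, function(t)
    center + scale * (3.5 * cos(t) * e1 + 2.5 * sin(t) * e2), numeric(3)))
  rbind(v, v[1, ])
}

# maxillary cortical-bone contour on the mid-maxillary plane (y fixed):
# lateral wall with a cosine notch whose apex is exactly the Max point, then
# the alveolar process with a V-shaped crest whose apex is the Alveo point.
.max_contour <- function(max_pt, alveo_pt, side_sign, scale) {
  y <- max_pt[2]
  wall_x <- abs(max_pt[1]) + 3 * scale       # wall base |X|
  depth <- 3 * scale                         # notch depth -> apex at Max
  notch_z <- max_pt[3]; notch_halfh <- 4 * scale
  zs <- seq(-12 * scale, alveo_pt[3] + 4 * scale, by = -0.25 * scale)
  ux <- vapply(zs, function(z) {
    dz <- z - notch_z
    if (abs(dz) < notch_halfh)
      wall_x - depth * (1 + cos(pi * dz / notch_halfh)) / 2
    else wall_x
  }, numeric(1))
  wall <- cbind(side_sign * ux, y, zs)
  # alveolar V: down-out to the crest apex, then up-in toward the palate
  crest <- rbind(
    c(side_sign * (abs(alveo_pt[1]) + 3 * scale), y, alveo_pt[3] + 4 * scale),
    c(side_sign * abs(alveo_pt[1]), y, alveo_pt[3]),
    c(side_sign * (abs(alveo_pt[1]) - 4 * scale), y, alveo_pt[3] + 5 * scale),
    c(side_sign * (abs(alveo_pt[1]) - 9 * scale), y, alveo_pt[3] + 8 * scale))
  rbind(wall, crest)
}

.expand_points <- function(pts, expansion) {
  out <- pts
  lat <- function(p, d) { p[1] <- p[1] + sign(p[1]) * d; p }
  for (nm in c("R-Max", "L-Max")) out[[nm]] <- lat(out[[nm]], expansion$max_mm)
  for (nm in c("R-Alveo", "L-Alveo")) out[[nm]] <- lat(out[[nm]], expansion$alveo_mm)
  # teeth translate with the alveolar process, then tip buccally
  tipy <- function(p, center, deg, buccal_sign) {
    # rotate about the anteroposterior (Y) axis through `center`; positive
    # buccal tip carries the superior end (apex) medially
    th <- buccal_sign * deg * pi / 180
    rel <- p - center
    center + c(cos(th) * rel[1] + sin(th) * rel[3], rel[2],
               -sin(th) * rel[1] + cos(th) * rel[3])
  }
  for (side in c("R", "L")) {
    s <- if (side == "R") -1 else 1          # lateral direction sign
    shift <- function(p) { p[1] <- p[1] + s * expansion$alveo_mm; p }
    pre_c <- sprintf("%s-Pre-cusp", side); pre_a <- sprintf("%s-Pre-apex", side)
    out[[pre_c]] <- shift(out[[pre_c]]); out[[pre_a]] <- shift(out[[pre_a]])
    # apex tips medially: for the right side (negative X) medial is +X
    out[[pre_a]] <- tipy(out[[pre_a]], out[[pre_c]], expansion$premolar_deg, -s)
    mnames <- sprintf("%s-6-apex-%s", side, c("mb", "db", "p"))
    ap <- lapply(out[mnames], shift)
    ctr <- Reduce(`+`, ap) / 3
    out[mnames] <- lapply(ap, tipy, center = ctr, deg = expansion$molar_deg,
                          buccal_sign = -s)
  }
  out
}

# angular change of the Alveo->Max line projected on the mid-max plane,
# computed directly from the injected geometry (positive = buccal tipping)
.alv_angle_truth <- function(pre, post, side) {
  s <- if (side == "R") -1 else 1
  u <- function(p) s * p[1]                  # lateral offset
  a <- c(u(pre[[sprintf("%s-Max", side)]]) - u(pre[[sprintf("%s-Alveo", side)]]),
         pre[[sprintf("%s-Max", side)]][3] - pre[[sprintf("%s-Alveo", side)]][3])
  b <- c(u(post[[sprintf("%s-Max", side)]]) - u(post[[sprintf("%s-Alveo", side)]]),
         post[[sprintf("%s-Max", side)]][3] - post[[sprintf("%s-Alveo", side)]][3])
  atan2(a[1] * b[2] - a[2] * b[1], sum(a * b)) * 180 / pi
}

#' Generate a synthetic skull-like phantom with known treatment change
#'
#' Builds pre- and post-treatment landmark sets (points, Sella border
#' traces, maxillary contours) with a known mediolateral expansion applied
#' to the treatment-affected landmarks only, a known rigid motion applied to
#' the whole post record, optional anatomical asymmetry, and optional
#' digitization noise. Reference structures (Sella, Porion, Orbitale) are
#' untouched by the expansion and are digitized once: they appear only in
#' the pre record.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return A list of class \code{phantom_truth}:
#' \describe{
#'   \item{pre}{\code{landmark_set}, native pre frame; reference + treatment
#'     landmarks and traces (noisy if requested).}
#'   \item{post}{\code{landmark_set}, native post frame; treatment landmarks
#'     and traces only.}
#'   \item{truth}{noiseless ground truth: \code{changes} (named vector of
#'     the ten change parameters), \code{motion}, \code{pre_tilt},
#'     \code{pre_ideal}/\code{post_ideal} (noiseless sets in the ideal
#'     frame), \code{midline} (true midsagittal \code{cf_line} in the pre
#'     frame), and \code{blobs} (voxelization model).}
#' }
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  .with_seed(spec$seed, {
    tmpl <- .phantom_template(spec$scale)
    for (nm in names(spec$asymmetry))
      tmpl[[nm]] <- tmpl[[nm]] + as.numeric(spec$asymmetry[[nm]])
    post_pts <- .expand_points(tmpl, spec$expansion)

    r_border <- .sella_border(c(-4.5, 0, 6) * spec$scale, spec$scale)
    l_border <- .sella_border(c( 4.5, 0, 6) * spec$scale, spec$scale)
    traces_pre <- list(
      sella_border_right = r_border, sella_border_left = l_border,
      max_contour_right = .max_contour(tmpl$`R-Max`, tmpl$`R-Alveo`, -1, spec$scale),
      max_contour_left  = .max_contour(tmpl$`L-Max`, tmpl$`L-Alveo`,  1, spec$scale))
    traces_post <- list(
      max_contour_right = .max_contour(post_pts$`R-Max`, post_pts$`R-Alveo`, -1, spec$scale),
      max_contour_left  = .max_contour(post_pts$`L-Max`, post_pts$`L-Alveo`,  1, spec$scale))

    changes <- c(
      `R-Max` = spec$expansion$max_mm, `L-Max` = spec$expansion$max_mm,
      `R-Cres` = spec$expansion$alveo_mm, `L-Cres` = spec$expansion$alveo_mm,
      `R-ALV` = .alv_angle_truth(tmpl, post_pts, "R"),
      `L-ALV` = .alv_angle_truth(tmpl, post_pts, "L"),
      `R-Pre` = spec$expansion$premolar_deg, `L-Pre` = spec$expansion$premolar_deg,
      `R-6` = spec$expansion$molar_deg, `L-6` = spec$expansion$molar_deg)

    pre_ideal <- landmark_set(points = tmpl, traces = traces_pre, frame = "native")
    treat_names <- c("ANS", "PNS", "R-Max", "L-Max", "R-Alveo", "L-Alveo",
                     grep("Pre-|6-apex", names(post_pts), value = TRUE))
    post_ideal <- landmark_set(points = post_pts[treat_names],
                               traces = traces_post, frame = "native")

    to_pre <- spec$pre_tilt
    to_post <- compose_transforms(spec$motion, spec$pre_tilt)
    pre_nat <- transform_landmarks(pre_ideal, to_pre)
    post_nat <- transform_landmarks(post_ideal, to_post)

    jitter_set <- function(lms, sd) {
      if (sd <= 0) return(lms)
      landmark_set(
        points = lapply(lms$points, function(p) p + stats::rnorm(3, 0, sd)),
        traces = lapply(lms$traces, function(tr)
          tr + matrix(stats::rnorm(length(tr), 0, sd), nrow(tr), 3)),
        frame = lms$frame)
    }
    pre <- jitter_set(pre_nat, spec$noise_sd)
    post <- jitter_set(post_nat, spec$noise_sd)

    midline_pre <- cf_line(apply_transform(to_pre, c(0, 0, 0)),
                           as.numeric(to_pre$rotation %*% c(0, 1, 0)))
    structure(list(
      pre = pre, post = post,
      truth = list(changes = changes, motion = spec$motion,
                   pre_tilt = spec$pre_tilt,
                   pre_ideal = pre_ideal, post_ideal = post_ideal,
                   pre_noiseless = pre_nat, post_noiseless = post_nat,
                   midline = midline_pre,
                   blobs = .phantom_blobs(spec)),
      spec = spec), class = "phantom_truth")
  })
}

# analytic blob model (ideal frame): stable cranial-base structures
# (hypophyseal fossa floor, sphenoid wings, crista galli) plus maxillary
# blobs displaced by the expansion
.phantom_blobs <- function(spec) {
  s <- spec$scale
  stable <- list(
    list(center = c(0, 0, 3) * s,    sigma = c(6, 8, 5) * s,   amp = 1000),
    list(center = c(-20, -5, 4) * s, sigma = c(10, 6, 5) * s,  amp = 900),
    list(center = c( 20, -5, 4) * s, sigma = c(10, 6, 5) * s,  amp = 900),
    list(center = c(0, 25, 8) * s,   sigma = c(5, 6, 5) * s,   amp = 800))
  e <- spec$expansion
  maxi <- list(
    list(center = c(-30, 23, -25) * s, sigma = c(6, 8, 6) * s, amp = 950),
    list(center = c( 30, 23, -25) * s, sigma = c(6, 8, 6) * s, amp = 950))
  maxi_post <- lapply(maxi, function(b) {
    b$center[1] <- b$center[1] + sign(b$center[1]) * e$max_mm; b
  })
  list(stable = stable, maxi_pre = maxi, maxi_post = maxi_post)
}

.eval_blobs <- function(world, blobs, t = NULL) {
  # blob field value at world positions; if t given, blobs are first moved
  # by the rigid transform t (evaluate at t^{-1} x with axis-aligned sigmas)
  if (!is.null(t)) world <- apply_transform(invert_transform(t), world)
  v <- numeric(nrow(world))
  for (b in blobs) {
    rel <- sweep(world, 2, b$center)
    d2 <- rowSums(sweep(rel, 2, b$sigma, "/")^2)
    # compact support (3 sigma) so blobs are strictly local: treatment blobs
    # contribute nothing inside the cranial-base mask
    v <- v + ifelse(d2 <= 9, b$amp * exp(-0.5 * d2), 0)
  }
  v
}

#' Voxelize a phantom into pre/post volumes and a cranial-base mask
#'
#' Renders the phantom's analytic blob model (smooth anisotropic Gaussians
#' at the stable cranial-base structures plus maxillary blobs that move
#' between timepoints) on a cubic lattice. The pre volume is rendered in the
#' pre-treatment native frame; the post volume has the inter-timepoint
#' motion applied, so registering post onto pre must recover the motion's
#' inverse. The binary mask, defined on the pre grid, covers only the stable
#' blobs and excludes the maxillary blobs entirely.
#'
#' @param truth a \code{phantom_truth}.
#' @param resolution voxel size, mm; blobs must span at least 2 voxels.
#' @param n grid size per axis (n^3 voxels).
#' @param noise_frac Gaussian voxel-noise SD as a fraction of the dynamic
#'   range (applied to both volumes, seeded from the phantom spec).
#' @return List with \code{fixed} (pre \code{cf_volume}), \code{moving}
#'   (post \code{cf_volume}), \code{mask} (logical array on the pre grid)
#'   and \code{true_transform} (the moving-to-fixed \code{rigid_transform}
#'   a perfect registration should return).
#' @export
voxelize_phantom <- function(truth, resolution = 2.2, n = 64, noise_frac = 0) {
  stopifnot(inherits(truth, "phantom_truth"))
  spec <- truth$spec
  blobs <- truth$truth$blobs
  min_sigma <- min(unlist(lapply(c(blobs$stable, blobs$maxi_pre),
                                 function(b) b$sigma)))
  if (min_sigma < 2 * resolution)
    stop_resolution(sprintf(
      "resolution %.3g mm too coarse: smallest blob sigma %.3g mm < 2 voxels",
      resolution, min_sigma))
  half <- resolution * (n - 1) / 2
  origin <- c(-half, -half + 10, -half)     # centre the anatomy vertically
  grid <- cf_volume(array(0, dim = c(n, n, n)),
                    spacing = rep(resolution, 3), origin = origin)
  idx <- as.matrix(expand.grid(i = 0:(n - 1), j = 0:(n - 1), k = 0:(n - 1)))
  w <- index_to_world(grid, idx)

  to_pre <- spec$pre_tilt
  to_post <- compose_transforms(spec$motion, spec$pre_tilt)
  pre_vals <- .eval_blobs(w, c(blobs$stable, blobs$maxi_pre), t = to_pre)
  post_vals <- .eval_blobs(w, c(blobs$stable, blobs$maxi_post), t = to_post)
  rng <- max(pre_vals) - min(pre_vals)
  .with_seed(spec$seed + 7L, {
    if (noise_frac > 0) {
      pre_vals <- pre_vals + stats::rnorm(length(pre_vals), 0, noise_frac * rng)
      post_vals <- post_vals + stats::rnorm(length(post_vals), 0, noise_frac * rng)
    }
  })
  fixed <- cf_volume(array(pre_vals, dim = c(n, n, n)),
                     spacing = rep(resolution, 3), origin = origin)
  moving <- cf_volume(array(post_vals, dim = c(n, n, n)),
                      spacing = rep(resolution, 3), origin = origin)
  # mask: within 2.5 sigma of a stable blob (in the pre frame)
  w_ideal <- apply_transform(invert_transform(to_pre), w)
  inmask <- rep(FALSE, nrow(w))
  for (b in blobs$stable) {
    rel <- sweep(w_ideal, 2, b$center)
    inmask <- inmask | rowSums(sweep(rel, 2, b$sigma, "/")^2) <= 2.5^2
  }
  list(fixed = fixed, moving = moving,
       mask = array(inmask, dim = c(n, n, n)),
       true_transform = invert_transform(spec$motion))
}

#' Simulate a repeated-digitization panel from phantom landmarks
#'
#' Emulates the reliability protocol: each landmark of each subject is
#' digitized by \code{n_raters} observers in \code{n_sessions} sessions.
#' Observations are truth + subject anatomy offset + per-rater bias
#' (normal, \code{rater_bias_sd}) + independent digitization noise.
#' \code{noise_sd} may be a single number or a named list of per-landmark
#' length-3 per-coordinate SDs (to emulate coordinate-dependent
#' reliability, e.g. high mediolateral Orbitale error from natural
#' asymmetry).
#'
#' @param landmarks named list of true landmark positions (length-3, mm);
#'   defaults to the reference landmarks of a default phantom.
#' @param n_subjects,n_raters,n_sessions panel dimensions.
#' @param noise_sd digitization noise SD, mm (scalar or named list of
#'   length-3 vectors).
#' @param rater_bias_sd SD of the per-rater, per-landmark constant bias, mm.
#' @param subject_sd SD of the between-subject anatomy spread, mm.
#' @param seed integer seed.
#' @return A \code{\link{digitization_panel}}.
#' @export
simulate_digitization <- function(landmarks = NULL, n_subjects = 20,
                                  n_raters = 3, n_sessions = 3,
                                  noise_sd = 0.1, rater_bias_sd = 0.05,
                                  subject_sd = 2, seed = 1L) {
  if (is.null(landmarks)) {
    tmpl <- .phantom_template(1)
    landmarks <- tmpl[c("R-Porion", "L-Porion", "R-Orbitale", "L-Orbitale")]
    landmarks$`C-Sella` <- c(0, 0, 6)
    landmarks$`R-Sella` <- c(-4.5, 0, 6); landmarks$`L-Sella` <- c(4.5, 0, 6)
  }
  sd_of <- function(lm) {
    if (is.list(noise_sd)) {
      s <- noise_sd[[lm]]
      if (is.null(s)) s <- noise_sd[[".default"]] %||% 0.1
      rep(as.numeric(s), length.out = 3)
    } else rep(noise_sd, 3)
  }
  .with_seed(seed, {
    rows <- vector("list", length(landmarks) * n_subjects * n_raters * n_sessions)
    i <- 0L
    for (lm in names(landmarks)) {
      sds <- sd_of(lm)
      subj_off <- matrix(stats::rnorm(3 * n_subjects, 0, subject_sd), n_subjects, 3)
      rater_bias <- matrix(stats::rnorm(3 * n_raters, 0, rater_bias_sd), n_raters, 3)
      for (s in seq_len(n_subjects)) for (r in seq_len(n_raters))
        for (ses in seq_len(n_sessions)) {
          obs <- landmarks[[lm]] + subj_off[s, ] + rater_bias[r, ] +
            stats::rnorm(3, 0, 1) * sds
          i <- i + 1L
          rows[[i]] <- data.frame(landmark = lm, subject = s, rater = r,
                                  session = ses,
                                  x = obs[1], y = obs[2], z = obs[3])
        }
    }
    digitization_panel(do.call(rbind, rows))
  })
}
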