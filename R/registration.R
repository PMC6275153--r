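#' Mutual information of two volumes under a rigid transform
#'
#' Shannon mutual information (nats) between the fixed volume's intensities
#' at the masked voxels and the moving volume resampled there through
#' \code{t}: \code{MI = H(F) + H(M) - H(F,M)} over the joint intensity
#' histogram. Intensities are binned over each volume's full dynamic range.
#' By default each sample falls in its nearest bin; with
#' \code{partial_volume = TRUE} each sample is spread linearly over the two
#' adjacent bins per axis, which makes the metric smooth in \code{t} (used
#' internally by the optimizer). Moving samples falling outside the moving
#' field of view are dropped from the histogram.
#'
#' @param fixed,moving \code{cf_volume}s.
#' @param t \code{rigid_transform} mapping moving world to fixed world.
#' @param mask logical array on the fixed grid selecting the voxels that
#'   enter the metric (the cranial-base mask).
#' @param bins histogram bins per image (>= 2).
#' @param partial_volume linear two-bin weighting instead of hard binning.
#' @return MI in nats (>= 0 up to histogram-estimation error).
#' @export
mutual_information <- function(fixed, moving, t = identity_transform(),
                               mask = NULL, bins = 32, partial_volume = FALSE) {
  if (bins < 2) cf_error("HeaderError", "bins must be >= 2")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(fixed$voxels))
  if (!any(mask)) stop_empty_mask("registration mask has no voxels")
  st <- .mi_state(fixed, moving, mask, bins)
  .mi_eval(st, t, partial_volume = partial_volume)
}

# precomputed quantities shared across metric evaluations
.mi_state <- function(fixed, moving, mask, bins) {
  d <- dim(fixed$voxels)
  if (!all(dim(mask) == d)) stop_empty_mask("mask shape differs from fixed volume")
  sel <- which(mask)
  idx <- cbind((sel - 1) %% d[1],
               ((sel - 1) %/% d[1]) %% d[2],
               (sel - 1) %/% (d[1] * d[2]))
  world <- index_to_world(fixed, idx)
  fvals <- fixed$voxels[sel]
  frange <- range(fixed$voxels); mrange <- range(moving$voxels)
  scale01 <- function(v, r) if (diff(r) > 0) (v - r[1]) / diff(r) else v * 0
  list(world = world, fixed = moving_clamp(scale01(fvals, frange)),
       moving_vol = moving, mrange = mrange, bins = as.integer(bins))
}

moving_clamp <- function(u) pmin(pmax(u, 0), 1)

.mi_eval <- function(st, t, partial_volume = FALSE) {
  wm <- apply_transform(invert_transform(t), st$world)
  mv <- sample_volume(st$moving_vol, wm, fill = NA_real_)
  ok <- !is.na(mv)
  if (!any(ok)) stop_no_overlap("volumes do not overlap under this transform")
  B <- st$bins
  fu <- st$fixed[ok] * (B - 1)
  mu <- moving_clamp(if (diff(st$mrange) > 0)
    (mv[ok] - st$mrange[1]) / diff(st$mrange) else mv[ok] * 0) * (B - 1)
  if (partial_volume) {
    f0 <- pmin(floor(fu), B - 2); fw <- fu - f0
    m0 <- pmin(floor(mu), B - 2); mw <- mu - m0
    ii <- c(f0     + B * m0,       f0 + 1 + B * m0,
            f0     + B * (m0 + 1), f0 + 1 + B * (m0 + 1)) + 1
    ww <- c((1 - fw) * (1 - mw), fw * (1 - mw), (1 - fw) * mw, fw * mw)
  } else {
    ii <- round(fu) + B * round(mu) + 1
    ww <- rep(1, length(fu))
  }
  agg <- rowsum(ww, ii)
  joint <- numeric(B * B)
  joint[as.integer(rownames(agg))] <- agg
  joint <- joint / sum(joint)
  jm <- matrix(joint, B, B)
  pf <- rowSums(jm); pm <- colSums(jm)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ent(pf) + ent(pm) - ent(joint)
}

.params_to_transform <- function(p, center) {
  R <- rotation_about(c(0, 0, 1), p[3]) %*%
       rotation_about(c(0, 1, 0), p[2]) %*%
       rotation_about(c(1, 0, 0), p[1])
  rigid_transform(R, as.numeric(center - R %*% center) + p[4:6])
}

#' Default registration settings
#'
#' @param bins joint-histogram bins per image.
#' @param sigmas multi-resolution smoothing schedule (Gaussian sigma in
#'   voxels per level, coarse to fine).
#' @param maxit Nelder-Mead iteration cap per level.
#' @param partial_volume smooth histogram weighting for the optimizer.
#' @param seed retained for interface completeness; the default metric uses
#'   every masked voxel (no stochastic sampling), so results do not depend
#'   on it.
#' @return List of settings for \code{\link{register_masked_rigid}}.
#' @export
registration_config <- function(bins = 32, sigmas = c(2, 1, 0), maxit = 400,
                                partial_volume = TRUE, seed = 0L) {
  list(bins = bins, sigmas = sigmas, maxit = maxit,
       partial_volume = partial_volume, seed = as.integer(seed))
}

#' Masked rigid registration by mutual-information maximization
#'
#' Fully automated, voxel-wise rigid superimposition of the post-treatment
#' (moving) volume onto the pre-treatment (fixed) volume, restricted to the
#' cranial-base mask so that structures affected by treatment or growth
#' cannot bias the alignment. The 6-parameter rigid transform (3 rotations,
#' 3 translations, rotating about the mask centroid) is optimized by
#' Nelder-Mead over a multi-resolution pyramid (Gaussian smoothing
#' \code{sigmas} voxels, coarse to fine), initialized by aligning the two
#' volumes' intensity centroids. Fully deterministic for a given config.
#'
#' @param fixed,moving \code{cf_volume}s (pre- and post-treatment).
#' @param mask logical array on the fixed grid; TRUE over the stable
#'   cranial-base structures only.
#' @param config settings from \code{\link{registration_config}}.
#' @return A \code{registration_result}: list with \code{transform}
#'   (moving to fixed, mm), \code{final_metric} and \code{initial_metric}
#'   (nats, hard-binned), \code{iterations} and \code{converged}.
#' @export
register_masked_rigid <- function(fixed, moving, mask,
                                  config = registration_config()) {
  if (is.null(mask) || !any(mask)) stop_empty_mask("registration mask is empty")
  d <- dim(fixed$voxels)
  # intensity-centroid initialization
  centroid <- function(vol) {
    v <- pmax(vol$voxels - min(vol$voxels), 0)
    dd <- dim(v)
    idx <- as.matrix(expand.grid(0:(dd[1] - 1), 0:(dd[2] - 1), 0:(dd[3] - 1)))
    w <- index_to_world(vol, idx)
    colSums(w * as.vector(v)) / sum(v)
  }
  init_t <- centroid(fixed) - centroid(moving)
  sel <- which(mask)
  idx <- cbind((sel - 1) %% d[1], ((sel - 1) %/% d[1]) %% d[2],
               (sel - 1) %/% (d[1] * d[2]))
  center <- colMeans(index_to_world(fixed, idx))

  p <- c(0, 0, 0, init_t)
  total_it <- 0L
  conv <- TRUE
  nlev <- length(config$sigmas)
  for (lev in seq_len(nlev)) {
    sg <- config$sigmas[lev]
    fs <- smooth_volume(fixed, sg); ms <- smooth_volume(moving, sg)
    st <- .mi_state(fs, ms, mask, config$bins)
    obj <- function(q) {
      tr <- tryCatch(.params_to_transform(q, center),
                     error = function(e) NULL)
      if (is.null(tr)) return(1e6)
      tryCatch(-.mi_eval(st, tr, partial_volume = config$partial_volume),
               NoOverlapError = function(e) 1e6)
    }
    # restart the simplex once at the finest level: Nelder-Mead can collapse
    # prematurely, and a fresh simplex at the current optimum recovers it
    for (run in seq_len(if (lev == nlev) 2L else 1L)) {
      opt <- stats::optim(p, obj, method = "Nelder-Mead",
                          control = list(maxit = config$maxit, reltol = 1e-9,
                                         parscale = c(1, 1, 1, 1, 1, 1)))
      p <- opt$par
      total_it <- total_it + opt$counts[1]
    }
    conv <- opt$convergence == 0
  }
  tfinal <- .params_to_transform(p, center)
  st0 <- .mi_state(fixed, moving, mask, config$bins)
  m_init <- .mi_eval(st0, rigid_transform(diag(3), init_t))
  m_final <- .mi_eval(st0, tfinal)
  if (m_final < m_init) {   # never report a transform worse than the start
    tfinal <- rigid_transform(diag(3), init_t)
    m_final <- m_init
    conv <- FALSE
  }
  tfinal$from <- "moving"; tfinal$to <- "fixed"
  structure(list(transform = tfinal, final_metric = m_final,
                 initial_metric = m_init, iterations = as.integer(total_it),
                 converged = conv),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result: MI %.4f -> %.4f nats, %d evals, converged=%s\n",
              x$initial_metric, x$final_metric, x$iterations, x$converged))
  print(x$transform)
  invisible(x)
}
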