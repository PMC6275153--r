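#' Arc-length resampling of a polyline
#'
#' Linear resampling at a fixed step along the cumulative arc length;
#' endpoints are retained. Used by the semi-automated landmark detectors so
#' that curvature and extremum searches do not depend on how densely a
#' contour was clicked.
#'
#' @param pts m x 3 matrix of ordered vertices, mm.
#' @param step resampling step, mm.
#' @param keep_vertices also retain the original vertices (non-uniform
#'   sampling, but exact corners survive; used by the extremum search, not
#'   by the curvature operator, which needs uniform spacing).
#' @return n x 3 matrix of resampled vertices.
#' @export
resample_polyline <- function(pts, step = 0.1, keep_vertices = FALSE) {
  pts <- as.matrix(pts)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total < step) return(pts)
  # drop zero-length duplicate vertices so approx() sees strictly increasing s
  keep <- c(TRUE, diff(s) > 0)
  pts <- pts[keep, , drop = FALSE]; s <- s[keep]
  tgt <- unique(c(seq(0, total, by = step), total))
  if (keep_vertices) tgt <- sort(unique(c(tgt, s)))
  apply(pts, 2, function(col) stats::approx(s, col, xout = tgt)$y)
}

#' Mid-maxillary perpendicular auxiliary plane
#'
#' The coronal-like cutting plane used to detect the maxillary landmarks:
#' through the midpoint of ANS and PNS, perpendicular to the corrected
#' Frankfort Horizontal, with its normal the anteroposterior direction
#' (the projection of PNS - ANS onto C-FH). Carries two in-plane unit axes:
#' \code{u}, mediolateral-like (positive X side), and \code{v},
#' superoinferior-like (positive superior), in which projected angles are
#' expressed.
#'
#' @param ans,pns the anterior / posterior nasal spine, oriented frame, mm.
#' @param frame the \code{reference_frame} (supplies the C-FH normal; in the
#'   oriented frame this is +Z). May be \code{NULL} for landmarks already in
#'   the oriented frame.
#' @return An object of class \code{aux_plane}: list(plane, u, v).
#' @export
mid_max_plane <- function(ans, pns, frame = NULL) {
  ans <- as.numeric(ans); pns <- as.numeric(pns)
  zn <- if (is.null(frame)) c(0, 0, 1) else
    as.numeric(frame$orientation$rotation %*% frame$cfh$normal)  # oriented-frame C-FH normal
  zn <- zn / sqrt(sum(zn^2))
  d <- pns - ans
  d <- d - sum(d * zn) * zn
  if (sqrt(sum(d^2)) < 1e-9)
    stop_degenerate_plane("ANS-PNS direction is parallel to the C-FH normal")
  n <- d / sqrt(sum(d^2))
  u <- cross3(n, zn)
  u <- u / sqrt(sum(u^2))
  if (u[1] < 0) u <- -u
  structure(list(plane = cf_plane((ans + pns) / 2, n), u = u, v = zn),
            class = "aux_plane")
}

# 2D coordinates of planar points in an aux plane's (u, v) basis
.aux_uv <- function(pts, aux) {
  pts <- if (is.null(dim(pts))) matrix(pts, 1) else as.matrix(pts)
  rel <- sweep(pts, 2, aux$plane$point)
  cbind(rel %*% aux$u, rel %*% aux$v)
}

#' Most concave point of a planar contour (R-Max / L-Max detector)
#'
#' Automatic digitization of the maxillary basal-bone point: on the
#' arc-length-resampled contour (cut of the cortical bone at the
#' mid-maxillary perpendicular plane), candidate concavities are the local
#' maxima of the smoothed discrete curvature that are simultaneously local
#' minima of mediolateral distance to the corrected midline — i.e. apexes
#' of indentations pointing toward the midline. Among candidates, the one
#' nearest the midline is returned. A contour with no such indentation
#' (e.g. a convex arc) raises \code{NoConcavityError}.
#'
#' @param contour m x 3 matrix (m >= 5) of ordered vertices lying in the
#'   auxiliary plane (within ~1e-6 mm), oriented frame, mm.
#' @param midline the corrected midline (\code{cf_line}); in the oriented
#'   frame this is the Y axis.
#' @param aux the \code{aux_plane} the contour lies in; fitted from the
#'   contour itself when \code{NULL}.
#' @param step arc-length resampling step, mm.
#' @param smooth moving-average window (samples) for the curvature signal.
#' @param method \code{"curvature"} (default, as described) or
#'   \code{"medial_extreme"}: simply the interior global minimum of midline
#'   distance.
#' @return Numeric length-3 point, mm.
#' @export
most_concave_point <- function(contour, midline, aux = NULL, step = 0.1,
                               smooth = 5, method = c("curvature", "medial_extreme")) {
  method <- match.arg(method)
  contour <- as.matrix(contour)
  if (nrow(contour) < 5L) stop_no_concavity("contour needs at least 5 vertices")
  if (is.null(aux)) aux <- .fit_aux_from_contour(contour)
  rs <- resample_polyline(contour, step = step)
  q <- .aux_uv(rs, aux)
  # mediolateral distance of each sample to the midline
  mid_u <- sum((midline$point - aux$plane$point) * aux$u)
  dml <- abs(q[, 1] - mid_u)
  n <- nrow(q)
  if (n < 5L) stop_no_concavity("contour too short after resampling")
  if (method == "medial_extreme") {
    i <- which.min(dml[2:(n - 1)]) + 1L
    if (dml[i] >= min(dml[c(1, n)]))
      stop_no_concavity("no interior medial extremum on contour")
    return(as.numeric(rs[i, ]))
  }
  # discrete curvature magnitude (second difference per step^2), smoothed
  d2 <- q[3:n, , drop = FALSE] + q[1:(n - 2), , drop = FALSE] -
        2 * q[2:(n - 1), , drop = FALSE]
  kappa <- c(0, sqrt(rowSums(d2^2)) / step^2, 0)
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    kappa <- stats::filter(kappa, k, sides = 2)
    kappa[is.na(kappa)] <- 0
    kappa <- as.numeric(kappa)
  }
  # candidate indentation apexes: strict interior local minima of midline
  # distance over a ~2 mm neighbourhood ...
  win <- max(2L, ceiling(2 / step))
  local_min_d <- vapply(2:(n - 1), function(i) {
    lo <- max(1, i - win); hi <- min(n, i + win)
    dml[i] <= min(dml[lo:hi]) + 1e-12 && dml[i] < min(dml[lo], dml[hi]) - 1e-9
  }, logical(1))
  cand <- which(local_min_d) + 1L
  # ... that are genuine concavities: the curvature near the apex must rise
  # clearly above the contour's baseline curvature (a smooth convex arc has
  # uniform curvature everywhere and is rejected)
  w2 <- max(1L, ceiling(0.5 / step))
  base_k <- stats::median(kappa[2:(n - 1)])
  is_concave <- vapply(cand, function(i) {
    lo <- max(1, i - w2); hi <- min(n, i + w2)
    max(kappa[lo:hi]) > max(1e-6, 2 * base_k)
  }, logical(1))
  cand <- cand[is_concave]
  if (!length(cand))
    stop_no_concavity("no concavity toward the midline found on contour")
  best <- cand[which.min(dml[cand])]
  as.numeric(rs[best, ])
}

# Total-least-squares plane of a contour, with in-plane axes chosen so u is
# mediolateral-like (max |X| component) and v superoinferior-like.
.fit_aux_from_contour <- function(contour) {
  ctr <- colMeans(contour)
  sv <- svd(sweep(contour, 2, ctr))
  nrm <- sv$v[, 3]
  zax <- c(0, 0, 1)
  v <- zax - sum(zax * nrm) * nrm
  if (sqrt(sum(v^2)) < 1e-9) stop_degenerate_plane("contour plane is horizontal")
  v <- v / sqrt(sum(v^2))
  u <- cross3(nrm, v)
  if (u[1] < 0) u <- -u
  structure(list(plane = cf_plane(ctr, nrm), u = u, v = v), class = "aux_plane")
}

#' Most inferior point of a planar contour (R-Alveo / L-Alveo detector)
#'
#' The most inferior point of the alveolar crest on the mid-maxillary
#' perpendicular plane: the minimum-Z sample of the arc-length-resampled
#' contour; ties (within \code{tie_tol}) are broken toward the midline
#' (smaller |X|).
#'
#' @param contour m x 3 matrix of ordered vertices, oriented frame, mm.
#' @param step arc-length resampling step, mm.
#' @param tie_tol tolerance (mm) within which Z values count as tied.
#' @return Numeric length-3 point, mm.
#' @export
most_inferior_point <- function(contour, step = 0.1, tie_tol = 1e-9) {
  rs <- resample_polyline(as.matrix(contour), step = step, keep_vertices = TRUE)
  zmin <- min(rs[, 3])
  tied <- which(rs[, 3] <= zmin + tie_tol)
  as.numeric(rs[tied[which.min(abs(rs[tied, 1]))], ])
}

#' Molar axis from the three root apices
#'
#' The line perpendicular to the plane of the mesiobuccal, distobuccal and
#' palatal root apices, through their centroid, signed superiorly.
#'
#' @param apex_mb,apex_db,apex_p the three root apices, mm.
#' @return A \code{cf_line}.
#' @export
molar_axis <- function(apex_mb, apex_db, apex_p) {
  a <- as.numeric(apex_mb); b <- as.numeric(apex_db); p <- as.numeric(apex_p)
  n <- cross3(b - a, p - a)
  if (sqrt(sum(n^2)) < 1e-9 * max(1, sqrt(sum((b - a)^2))))
    stop_degenerate_plane("molar root apices are collinear")
  n <- n / sqrt(sum(n^2))
  if (n[3] < 0) n <- -n
  cf_line((a + b + p) / 3, n)
}

#' Premolar axis from buccal cusp tip to buccal root apex
#' @param cusp_tip,root_apex the two defining points, mm.
#' @return A \code{cf_line} through the cusp tip, pointing toward the apex.
#' @export
premolar_axis <- function(cusp_tip, root_apex) {
  cusp_tip <- as.numeric(cusp_tip); root_apex <- as.numeric(root_apex)
  if (sqrt(sum((root_apex - cusp_tip)^2)) < 1e-9)
    stop_degenerate_axis("cusp tip and root apex coincide")
  cf_line(cusp_tip, root_apex - cusp_tip)
}

#' Mediolateral change of a landmark by projection onto C-FH
#'
#' The distance travelled mediolaterally: both positions are projected onto
#' the mediolateral axis of the corrected reference (the X axis of the
#' oriented frame) and the change in absolute offset from the corrected
#' midline is returned. Positive values mean movement away from the midline
#' (expansion); anteroposterior or vertical motion contributes nothing.
#'
#' @param p_pre,p_post the landmark at the two timepoints, oriented frame, mm.
#' @param side_tol below this |X| (mm) a point is treated as on the midline
#'   and the side-consistency check is waived.
#' @return Signed change in mm.
#' @export
mediolateral_change <- function(p_pre, p_post, side_tol = 0.5) {
  p_pre <- as.numeric(p_pre); p_post <- as.numeric(p_post)
  if (abs(p_pre[1]) >= side_tol && abs(p_post[1]) >= side_tol &&
      sign(p_pre[1]) != sign(p_post[1]))
    stop_side_mismatch("pre and post landmarks lie on opposite sides of the midline")
  abs(p_post[1]) - abs(p_pre[1])
}

#' Angular change of an axis projected on the auxiliary plane
#'
#' Projects both axis directions onto the mid-maxillary perpendicular plane
#' and returns the signed angle between the projections, in degrees,
#' expressed in the plane's (mediolateral, superoinferior) axes. With
#' \code{lateral_sign} set to the side of the measured structure
#' (sign of its X position), positive angles mean the inferior end (crown)
#' tips laterally — buccal tipping — and negative angles lingual tipping.
#'
#' @param axis_pre,axis_post \code{cf_line} axes at the two timepoints.
#' @param aux the \code{aux_plane} to project on.
#' @param lateral_sign +1 or -1: the sign of the in-plane mediolateral axis
#'   pointing laterally for the measured side.
#' @return Signed angle in degrees.
#' @export
projected_angle_change <- function(axis_pre, axis_post, aux, lateral_sign = 1) {
  proj <- function(d) {
    p <- d - sum(d * aux$plane$normal) * aux$plane$normal
    if (sqrt(sum(p^2)) < 1e-9)
      stop_projection_degen("axis is perpendicular to the auxiliary plane")
    p / sqrt(sum(p^2))
  }
  a <- proj(axis_pre$direction); b <- proj(axis_post$direction)
  u <- lateral_sign * aux$u
  a2 <- c(sum(a * u), sum(a * aux$v))
  b2 <- c(sum(b * u), sum(b * aux$v))
  atan2(a2[1] * b2[2] - a2[2] * b2[1], sum(a2 * b2)) * 180 / pi
}

.sign_conventions <- c(
  linear  = "positive = movement away from the corrected midline (expansion)",
  angular = "positive = inferior end tips laterally (buccal tipping)")

#' All treatment-change measurements for a superimposed pair
#'
#' Produces the ten standard change parameters from pre- and post-treatment
#' landmark sets in the oriented frame:
#' \itemize{
#'   \item \code{R-Max}, \code{L-Max}: mediolateral change of the maxillary
#'     basal-bone point (mm);
#'   \item \code{R-Cres}, \code{L-Cres}: mediolateral change of the alveolar
#'     crest point (mm);
#'   \item \code{R-ALV}, \code{L-ALV}: angular change of the line from Max to
#'     Alveo, projected on the mid-maxillary perpendicular plane (deg);
#'   \item \code{R-Pre}, \code{L-Pre}: angular change of the premolar axis,
#'     same projection (deg);
#'   \item \code{R-6}, \code{L-6}: angular change of the molar axis, same
#'     projection (deg).
#' }
#' \code{R-Max}/\code{L-Max} and \code{R-Alveo}/\code{L-Alveo} may be given
#' as points, or detected semi-automatically from contour traces named
#' \code{max_contour_right}/\code{max_contour_left} via
#' \code{\link{most_concave_point}} and \code{\link{most_inferior_point}}.
#' The auxiliary plane is built once, from the pre-treatment ANS/PNS, and
#' reused for the post record.
#'
#' @param pre,post \code{landmark_set}s with \code{frame == "oriented"}.
#' @param frame the \code{reference_frame} (sign conventions, midline).
#' @param on_missing \code{"error"}: a missing landmark aborts;
#'   \code{"skip"}: the affected measurements are dropped from the report.
#' @param concavity_method passed to \code{\link{most_concave_point}}.
#' @return A data frame (class \code{measurement_report}) with columns
#'   \code{parameter}, \code{kind}, \code{value}, \code{units},
#'   \code{sign_convention}.
#' @export
measure_all <- function(pre, post, frame, on_missing = c("error", "skip"),
                        concavity_method = "curvature") {
  on_missing <- match.arg(on_missing)
  for (s in list(pre, post)) if (s$frame != "oriented")
    stop_frame_mismatch("measurements require landmark sets in the oriented frame")
  midline_or <- cf_line(apply_transform(frame$orientation, frame$midline$point),
                        as.numeric(frame$orientation$rotation %*% frame$midline$direction))
  rows <- list()
  emit <- function(parameter, kind, value)
    rows[[parameter]] <<- data.frame(
      parameter = parameter, kind = kind, value = value,
      units = if (kind == "linear") "mm" else "deg",
      sign_convention = unname(.sign_conventions[kind]))
  try_measure <- function(expr) {
    tryCatch(expr, MissingLandmarkError = function(e) {
      if (on_missing == "error") stop(e)
      invisible(NULL)
    })
  }
  aux <- try_measure({
    mid_max_plane(landmark_point(pre, "ANS", "auxiliary plane"),
                  landmark_point(pre, "PNS", "auxiliary plane"), frame)
  })
  get_side_pt <- function(lms, name, contour_name, detector) {
    p <- lms$points[[name]]
    if (!is.null(p)) return(p)
    tr <- lms$traces[[contour_name]]
    if (is.null(tr))
      stop_missing_landmark(sprintf("neither point '%s' nor trace '%s' present",
                                    name, contour_name),
                            landmark = name)
    detector(tr)
  }
  for (side in c("R", "L")) {
    cname <- sprintf("max_contour_%s", if (side == "R") "right" else "left")
    maxn <- sprintf("%s-Max", side); alvn <- sprintf("%s-Alveo", side)
    detect_max <- function(tr) most_concave_point(tr, midline_or, aux = aux,
                                                  method = concavity_method)
    detect_alv <- function(tr) most_inferior_point(tr)
    pts <- try_measure({
      list(max_pre  = get_side_pt(pre,  maxn, cname, detect_max),
           max_post = get_side_pt(post, maxn, cname, detect_max),
           alv_pre  = get_side_pt(pre,  alvn, cname, detect_alv),
           alv_post = get_side_pt(post, alvn, cname, detect_alv))
    })
    if (!is.null(pts)) {
      emit(sprintf("%s-Max", side), "linear",
           mediolateral_change(pts$max_pre, pts$max_post))
      emit(sprintf("%s-Cres", side), "linear",
           mediolateral_change(pts$alv_pre, pts$alv_post))
      if (!is.null(aux)) {
        lat <- sign(pts$max_pre[1])
        emit(sprintf("%s-ALV", side), "angular",
             projected_angle_change(cf_line(pts$alv_pre, pts$max_pre - pts$alv_pre),
                                    cf_line(pts$alv_post, pts$max_post - pts$alv_post),
                                    aux, lateral_sign = lat))
      }
    }
    if (!is.null(aux)) {
      pre_ax <- try_measure(premolar_axis(
        landmark_point(pre, sprintf("%s-Pre-cusp", side), "premolar axis"),
        landmark_point(pre, sprintf("%s-Pre-apex", side), "premolar axis")))
      post_ax <- try_measure(premolar_axis(
        landmark_point(post, sprintf("%s-Pre-cusp", side), "premolar axis"),
        landmark_point(post, sprintf("%s-Pre-apex", side), "premolar axis")))
      if (!is.null(pre_ax) && !is.null(post_ax))
        emit(sprintf("%s-Pre", side), "angular",
             projected_angle_change(pre_ax, post_ax, aux,
                                    lateral_sign = sign(pre_ax$point[1])))
      m_ax <- function(lms) try_measure(molar_axis(
        landmark_point(lms, sprintf("%s-6-apex-mb", side), "molar axis"),
        landmark_point(lms, sprintf("%s-6-apex-db", side), "molar axis"),
        landmark_point(lms, sprintf("%s-6-apex-p", side), "molar axis")))
      pre_m <- m_ax(pre); post_m <- m_ax(post)
      if (!is.null(pre_m) && !is.null(post_m))
        emit(sprintf("%s-6", side), "angular",
             projected_angle_change(pre_m, post_m, aux,
                                    lateral_sign = sign(pre_m$point[1])))
    }
  }
  out <- do.call(rbind, unname(rows))
  ord <- c("R-Max", "L-Max", "R-Cres", "L-Cres", "R-ALV", "L-ALV",
           "R-Pre", "L-Pre", "R-6", "L-6")
  out <- out[order(match(out$parameter, ord)), ]
  rownames(out) <- NULL
  class(out) <- c("measurement_report", "data.frame")
  out
}

#' Write a measurement report as CSV
#' @param report a \code{measurement_report}.
#' @param path CSV output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
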