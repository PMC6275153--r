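#' Lines and planes in 3D
#'
#' Light containers used throughout the reference-frame and measurement
#' code: a \code{cf_line} is a point plus a unit direction; a \code{cf_plane}
#' is a point plus a unit normal, optionally carrying the maximum orthogonal
#' distance of its defining points (\code{fit_residual}, mm).
#'
#' @param point numeric length-3 position, mm.
#' @param direction,normal numeric length-3 vector; normalized internally.
#' @param fit_residual maximum orthogonal distance of the defining points, mm.
#' @return A \code{cf_line} or \code{cf_plane}.
#' @export
cf_line <- function(point, direction) {
  point <- as.numeric(point); direction <- as.numeric(direction)
  n <- sqrt(sum(direction^2))
  if (n < 1e-12) stop_degenerate_axis("line direction has zero length")
  structure(list(point = point, direction = direction / n), class = "cf_line")
}

#' @rdname cf_line
#' @export
cf_plane <- function(point, normal, fit_residual = 0) {
  point <- as.numeric(point); normal <- as.numeric(normal)
  n <- sqrt(sum(normal^2))
  if (n < 1e-12) stop_degenerate_plane("plane normal has zero length")
  structure(list(point = point, normal = normal / n,
                 fit_residual = as.numeric(fit_residual)), class = "cf_plane")
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(NULL)
  v / n
}

cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])

#' Orthogonal projection of a point onto a plane
#' @param p numeric length-3 point.
#' @param plane a \code{cf_plane}.
#' @return The projected point.
#' @export
project_point_on_plane <- function(p, plane)
  as.numeric(p) - sum((as.numeric(p) - plane$point) * plane$normal) * plane$normal

#' Centre of a traced Sella border
#'
#' The right and left Sella points are defined as the centres of the manually
#' traced 3D borders of the hypophyseal fossa. The centre is computed as the
#' arc-length-weighted centroid of the polyline (each segment contributes its
#' midpoint weighted by its length), which makes the result independent of
#' how densely the border was clicked. If the endpoints coincide (within
#' 1e-6 mm) the trace is treated as closed.
#'
#' @param border m x 3 matrix of ordered vertices (m >= 3), mm.
#' @return Numeric length-3 centroid, mm.
#' @export
sella_from_trace <- function(border) {
  border <- as.matrix(border)
  if (nrow(border) < 3L)
    stop_degenerate_trace("Sella border trace needs at least 3 vertices")
  closed <- sqrt(sum((border[1, ] - border[nrow(border), ])^2)) <= 1e-6
  if (closed) border <- border[-nrow(border), , drop = FALSE]
  v <- if (closed) rbind(border, border[1, ]) else border
  seg <- v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  if (sum(len) < 1e-12) stop_degenerate_trace("trace has zero total length")
  mid <- (v[-1, , drop = FALSE] + v[-nrow(v), , drop = FALSE]) / 2
  as.numeric(colSums(mid * len) / sum(len))
}

#' Constructed Sella: midpoint of the right and left Sella centres
#' @param r_sella,l_sella numeric length-3 points, mm.
#' @return The midpoint, mm.
#' @export
construct_c_sella <- function(r_sella, l_sella)
  (as.numeric(r_sella) + as.numeric(l_sella)) / 2

#' Porion axis
#'
#' The line passing between the two Porion points: through their midpoint,
#' with unit direction from the right toward the left Porion (which is the
#' +X direction when the anatomy sits in the package's world convention).
#'
#' @param r_po,l_po right and left Porion, mm.
#' @return A \code{cf_line}.
#' @export
porion_axis <- function(r_po, l_po) {
  r_po <- as.numeric(r_po); l_po <- as.numeric(l_po)
  if (sqrt(sum((l_po - r_po)^2)) <= 1e-6)
    stop_degenerate_axis("Porion points coincide")
  cf_line((r_po + l_po) / 2, l_po - r_po)
}

#' Mid-Orbitale: midpoint of the two Orbitale points
#' @param r_or,l_or right and left Orbitale, mm.
#' @return The midpoint, mm.
#' @export
mid_orbitale <- function(r_or, l_or)
  (as.numeric(r_or) + as.numeric(l_or)) / 2

#' Asymmetry-corrected Orbitale pair (C-Orbitale)
#'
#' Replaces the raw Orbitale points by a constructed pair that discards their
#' unreliable coordinates: both corrected points take the superoinferior (Z)
#' level of mid-Orbitale, sit at equal mediolateral distances from C-Sella,
#' and the segment joining them runs parallel to the axial projection of the
#' Porion axis, centred anteroposteriorly on mid-Orbitale. Only the
#' low-error coordinates (C-Sella X, mid-Orbitale Z, Porion direction)
#' survive into the construction, so mediolateral Orbitale asymmetry and
#' antisymmetric anteroposterior error cannot twist the reference plane.
#'
#' @param r_or,l_or raw right and left Orbitale, mm.
#' @param c_sella the constructed Sella point, mm.
#' @param axis the Porion axis (\code{cf_line}).
#' The construction is expressed in an anatomical basis: the vertical
#' direction \code{up} (by default world +Z; \code{\link{build_reference_frame}}
#' passes the normal of the raw Porion/Orbitale plane, which makes the whole
#' frame equivariant under rigid motion of the superimposed records), the
#' mediolateral direction (the Porion axis projected to horizontal) and the
#' anteroposterior direction completing the triad. With an aligned head this
#' reduces to the plain X/Y/Z rules.
#'
#' @param half_width \code{"mean"} (default): equal offsets of
#'   \code{mean(|X_r - X_cs|, |X_l - X_cs|)}, the least-perturbing rule that
#'   reduces to the raw points for symmetric anatomy; \code{"raw"}: keep each
#'   point's own mediolateral offset (no equalization).
#' @param up unit superior direction defining "level" for the construction.
#' @return List with elements \code{right} and \code{left} (length-3 points).
#' @export
construct_c_orbitale <- function(r_or, l_or, c_sella, axis,
                                 half_width = c("mean", "raw"),
                                 up = c(0, 0, 1)) {
  half_width <- match.arg(half_width)
  r_or <- as.numeric(r_or); l_or <- as.numeric(l_or); c_sella <- as.numeric(c_sella)
  zhat <- unit(as.numeric(up))
  if (is.null(zhat)) stop_midline_undefined("degenerate up direction")
  xhat <- unit(axis$direction - sum(axis$direction * zhat) * zhat)
  if (is.null(xhat))
    stop_midline_undefined("Porion axis has no mediolateral component")
  yhat <- cross3(zhat, xhat)
  m_or <- (r_or + l_or) / 2
  off_r <- sum((r_or - c_sella) * xhat)
  off_l <- sum((l_or - c_sella) * xhat)
  s_r <- if (off_r != 0) sign(off_r) else -sign(off_l)
  if (s_r == 0) s_r <- -1   # right side sits at negative X in convention
  w <- mean(abs(c(off_r, off_l)))
  dx_r <- if (half_width == "mean") s_r * w else off_r
  dx_l <- if (half_width == "mean") -s_r * w else off_l
  # anchor: mediolateral position of C-Sella, anteroposterior and vertical
  # position of mid-Orbitale; the pair extends from it along the horizontal
  # projection of the Porion axis
  anchor <- c_sella + sum((m_or - c_sella) * yhat) * yhat +
    sum((m_or - c_sella) * zhat) * zhat
  list(right = anchor + dx_r * xhat,
       left  = anchor + dx_l * xhat)
}

#' Corrected Frankfort Horizontal plane from its four defining points
#'
#' Orthogonal (total) least-squares plane through the right/left Porion and
#' right/left C-Orbitale points, with the normal oriented superiorly
#' (positive Z). With exactly constructed inputs the four points are coplanar
#' and \code{fit_residual} is ~0; digitized inputs need not be, and the
#' residual records how far off-plane they are.
#'
#' @param r_po,l_po,c_or_r,c_or_l the four defining points, mm.
#' @param up_hint direction the normal's sign is aligned with (superior);
#'   default world +Z. \code{\link{build_reference_frame}} passes an
#'   anatomy-derived hint so the construction does not depend on how the
#'   head happens to sit in world coordinates.
#' @return A \code{cf_plane} through the points' centroid.
#' @export
fit_cfh <- function(r_po, l_po, c_or_r, c_or_l, up_hint = c(0, 0, 1)) {
  pts <- rbind(as.numeric(r_po), as.numeric(l_po),
               as.numeric(c_or_r), as.numeric(c_or_l))
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop_degenerate_plane("defining points are collinear")
  normal <- sv$v[, 3]
  s <- sum(normal * as.numeric(up_hint))
  if (s < 0) normal <- -normal
  if (abs(s) < 1e-12)
    stop_degenerate_plane("cannot orient the plane normal from the up hint")
  cf_plane(ctr, normal, fit_residual = max(abs(X %*% normal)))
}

#' Corrected midline
#'
#' The in-plane line through the orthogonal projection of C-Sella onto the
#' corrected Frankfort Horizontal, perpendicular to the Porion axis
#' (direction = normalize(plane normal x Porion direction)), pointing
#' anteriorly. This replaces the conventional Frankfort midline, which is
#' distorted by Orbitale asymmetry.
#'
#' @param c_sella the constructed Sella point, mm.
#' @param axis the Porion axis (\code{cf_line}).
#' @param cfh the corrected Frankfort Horizontal (\code{cf_plane}).
#' @param anterior_ref optional point on the anterior side (typically
#'   mid-Orbitale) used to fix the direction's sign; defaults to +Y.
#' @return A \code{cf_line} lying in \code{cfh}.
#' @export
corrected_midline <- function(c_sella, axis, cfh, anterior_ref = NULL) {
  d <- cross3(cfh$normal, axis$direction)
  if (sqrt(sum(d^2)) < 1e-9)
    stop_midline_undefined("Porion axis is parallel to the C-FH normal")
  d <- d / sqrt(sum(d^2))
  p <- project_point_on_plane(c_sella, cfh)
  if (!is.null(anterior_ref)) {
    if (sum((as.numeric(anterior_ref) - p) * d) < 0) d <- -d
  } else if (d[2] < 0) d <- -d
  cf_line(p, d)
}

#' Reference frame: plane, midline, origin and orientation transform
#'
#' Builds the oriented coordinate system of the corrected Frankfort
#' Horizontal: a rigid transform that maps the C-FH normal to +Z, the
#' corrected midline direction to +Y (X completing a right-handed triad),
#' and the centre of C-FH — the centroid of the four defining points
#' projected onto the fitted plane — to the origin. Applying it to the
#' superimposed records "levels the head" and gives every subsequent
#' measurement the same mediolateral / anteroposterior / superoinferior
#' meaning.
#'
#' @param cfh the corrected Frankfort Horizontal (\code{cf_plane}).
#' @param midline the corrected midline (\code{cf_line}).
#' @param defining_points 4 x 3 matrix of the plane's defining points
#'   (R/L Porion, R/L C-Orbitale), mm.
#' @param tol tolerance for the midline-in-plane consistency checks.
#' @return An object of class \code{reference_frame} with fields \code{cfh},
#'   \code{midline}, \code{origin} and \code{orientation}
#'   (a \code{rigid_transform}, superimposed to oriented).
#' @export
orientation_transform <- function(cfh, midline, defining_points, tol = 1e-6) {
  n <- cfh$normal
  d <- midline$direction
  if (abs(sum(n * d)) > tol)
    stop_frame_construction("midline direction is not in the C-FH plane")
  if (abs(sum((midline$point - cfh$point) * n)) > tol + cfh$fit_residual)
    stop_frame_construction("midline point does not lie in the C-FH plane")
  d <- unit(d - sum(d * n) * n)      # exact in-plane direction
  x <- cross3(d, n)                  # mediolateral axis of the oriented frame
  defining_points <- as.matrix(defining_points)
  proj <- t(apply(defining_points, 1, project_point_on_plane, plane = cfh))
  origin <- colMeans(proj)
  R <- rbind(x, d, n)                # rows: maps x->e1, d->e2, n->e3
  orientation <- rigid_transform(R, as.numeric(-R %*% origin),
                                 from = "superimposed", to = "oriented")
  structure(list(cfh = cfh, midline = cf_line(project_point_on_plane(midline$point, cfh), d),
                 origin = origin, orientation = orientation),
            class = "reference_frame")
}

#' @export
print.reference_frame <- function(x, ...) {
  cat("reference_frame\n")
  cat(sprintf("  C-FH normal: (%.4f, %.4f, %.4f), fit residual %.4g mm\n",
              x$cfh$normal[1], x$cfh$normal[2], x$cfh$normal[3], x$cfh$fit_residual))
  cat(sprintf("  midline direction: (%.4f, %.4f, %.4f)\n",
              x$midline$direction[1], x$midline$direction[2], x$midline$direction[3]))
  cat(sprintf("  origin: (%.4f, %.4f, %.4f) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Construct the full corrected reference frame from digitized landmarks
#'
#' Convenience wrapper running the whole construction: Sella centres from
#' the traced fossa borders (or \code{R-Sella}/\code{L-Sella} points),
#' C-Sella, Porion axis, mid-Orbitale, C-Orbitale, the C-FH plane, the
#' corrected midline, and the orientation transform. Reference landmarks are
#' digitized once, on the superimposed pre-treatment record; the frame they
#' define is shared by both timepoints.
#'
#' @param lms a \code{landmark_set} holding \code{R-Porion}, \code{L-Porion},
#'   \code{R-Orbitale}, \code{L-Orbitale} and either \code{R-Sella}/
#'   \code{L-Sella} points or \code{sella_border_right}/\code{sella_border_left}
#'   traces.
#' @param half_width C-Orbitale half-width rule, see
#'   \code{\link{construct_c_orbitale}}.
#' @return A \code{reference_frame}; the constructed points are attached as
#'   attribute \code{"constructed"} (named list).
#' @export
build_reference_frame <- function(lms, half_width = c("mean", "raw")) {
  half_width <- match.arg(half_width)
  r_sella <- if (!is.null(lms$traces[["sella_border_right"]]))
    sella_from_trace(lms$traces[["sella_border_right"]]) else
    landmark_point(lms, "R-Sella", "reference frame")
  l_sella <- if (!is.null(lms$traces[["sella_border_left"]]))
    sella_from_trace(lms$traces[["sella_border_left"]]) else
    landmark_point(lms, "L-Sella", "reference frame")
  r_po <- landmark_point(lms, "R-Porion", "reference frame")
  l_po <- landmark_point(lms, "L-Porion", "reference frame")
  r_or <- landmark_point(lms, "R-Orbitale", "reference frame")
  l_or <- landmark_point(lms, "L-Orbitale", "reference frame")
  c_sella <- construct_c_sella(r_sella, l_sella)
  axis <- porion_axis(r_po, l_po)
  m_or <- mid_orbitale(r_or, l_or)
  # anatomy-derived vertical: normal of the raw Porion/Orbitale plane, signed
  # toward Sella (which sits above it). Using it instead of world Z makes the
  # frame equivariant under rigid motion of the superimposed records.
  hint <- c_sella - colMeans(rbind(r_po, l_po, r_or, l_or))
  raw <- fit_cfh(r_po, l_po, r_or, l_or, up_hint = hint)
  up <- raw$normal
  c_or <- construct_c_orbitale(r_or, l_or, c_sella, axis,
                               half_width = half_width, up = up)
  cfh <- fit_cfh(r_po, l_po, c_or$right, c_or$left, up_hint = up)
  midline <- corrected_midline(c_sella, axis, cfh, anterior_ref = m_or)
  frame <- orientation_transform(cfh, midline,
                                 rbind(r_po, l_po, c_or$right, c_or$left))
  attr(frame, "constructed") <- list(
    `R-Sella` = r_sella, `L-Sella` = l_sella, `C-Sella` = c_sella,
    `Mid-Orbitale` = m_or, `R-C-Orbitale` = c_or$right,
    `L-C-Orbitale` = c_or$left, porion_axis = axis)
  frame
}

#' Map a landmark set into the oriented reference frame
#'
#' Applies the frame's orientation transform to every point and trace.
#' Requires the input to be in the superimposed frame (the frame the
#' reference landmarks were digitized in); pairwise distances are preserved.
#'
#' @param lms a \code{landmark_set} with \code{frame == "superimposed"}.
#' @param frame a \code{reference_frame}.
#' @return The oriented \code{landmark_set}.
#' @export
apply_frame <- function(lms, frame) {
  if (lms$frame != "superimposed")
    stop_frame_mismatch(sprintf(
      "landmarks are in frame '%s'; orientation applies to 'superimposed'",
      lms$frame))
  transform_landmarks(lms, frame$orientation, new_frame = "oriented")
}

#' Write / read a reference frame as JSON
#' @param frame a \code{reference_frame}.
#' @param path JSON file path.
#' @return \code{write_reference_frame} returns \code{path} invisibly;
#'   \code{read_reference_frame} returns a \code{reference_frame}.
#' @export
write_reference_frame <- function(frame, path) {
  o <- frame$orientation
  obj <- list(type = "reference_frame", units = "mm",
              cfh = list(point = frame$cfh$point, normal = frame$cfh$normal,
                         fit_residual = frame$cfh$fit_residual),
              midline = list(point = frame$midline$point,
                             direction = frame$midline$direction),
              origin = frame$origin,
              orientation = rbind(cbind(o$rotation, o$translation), c(0, 0, 0, 1)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_reference_frame
#' @export
read_reference_frame <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- obj$orientation
  structure(list(
    cfh = cf_plane(obj$cfh$point, obj$cfh$normal, obj$cfh$fit_residual),
    midline = cf_line(obj$midline$point, obj$midline$direction),
    origin = as.numeric(obj$origin),
    orientation = rigid_transform(m[1:3, 1:3], m[1:3, 4],
                                  from = "superimposed", to = "oriented")),
    class = "reference_frame")
}
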