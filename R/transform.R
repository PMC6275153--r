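#' Rigid (rotation + translation) transforms in millimetres
#'
#' A rigid transform maps world coordinates by \code{x' = R x + t}, with
#' \code{R} a proper orthogonal 3x3 rotation and \code{t} a translation in mm.
#' Transforms carry optional \code{from}/\code{to} frame tags so that frame
#' mix-ups (e.g. applying a moving-to-fixed map to already-superimposed
#' landmarks) can be caught when reading them back from disk.
#'
#' @param rotation 3x3 proper orthogonal matrix (\code{R'R = I}, det +1).
#' @param translation numeric length-3 translation, mm.
#' @param from,to optional frame tags (e.g. \code{"native"},
#'   \code{"superimposed"}, \code{"oriented"}).
#' @return An object of class \code{rigid_transform}.
#' @export
#' @examples
#' t1 <- rigid_transform(rotation_about(c(0, 0, 1), 30), c(1, 0, 0))
#' t2 <- invert_transform(t1)
#' compose_transforms(t2, t1)  # identity
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            from = NULL, to = NULL) {
  rotation <- unname(as.matrix(rotation))
  translation <- unname(as.numeric(translation))
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    cf_error("TransformFormatError", "rotation must be 3x3 and translation length 3")
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    cf_error("TransformFormatError", "non-finite transform entries")
  ortho_err <- max(abs(crossprod(rotation) - diag(3)))
  if (ortho_err > 1e-9)
    cf_error("TransformFormatError",
             sprintf("rotation not orthogonal (max |R'R - I| = %.3g)", ortho_err))
  if (det(rotation) < 0)
    cf_error("TransformFormatError", "reflection (det = -1) is not a rigid rotation")
  structure(list(rotation = rotation, translation = translation,
                 from = from, to = to),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform",
      if (!is.null(x$from)) sprintf("[%s -> %s]", x$from, x$to %||% "?") else "",
      "\n")
  cat(sprintf("  rotation angle: %.4f deg, translation: (%.4f, %.4f, %.4f) mm\n",
              rotation_angle(x), x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Identity rigid transform
#' @inheritParams rigid_transform
#' @return A \code{rigid_transform} with zero rotation and translation.
#' @export
identity_transform <- function(from = NULL, to = NULL)
  rigid_transform(diag(3), c(0, 0, 0), from = from, to = to)

#' Rotation matrix about an axis
#'
#' Rodrigues rotation by \code{angle_deg} degrees about \code{axis}
#' (normalized internally).
#' @param axis numeric length-3 rotation axis.
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) cf_error("TransformFormatError", "zero-length rotation axis")
  k <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to points
#' @param t a \code{rigid_transform}.
#' @param pts numeric length-3 point or an n x 3 matrix of points (mm).
#' @return Transformed points with the same shape as the input.
#' @export
apply_transform <- function(t, pts) {
  stopifnot(inherits(t, "rigid_transform"))
  if (is.null(dim(pts))) {
    as.numeric(t$rotation %*% as.numeric(pts) + t$translation)
  } else {
    out <- pts %*% t(t$rotation)
    out <- sweep(out, 2, t$translation, "+")
    dimnames(out) <- dimnames(pts)
    out
  }
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying \code{b} first and then
#' \code{a}: \code{(a o b)(x) = a(b(x))}.
#' @param a,b \code{rigid_transform} objects.
#' @return A \code{rigid_transform}.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation,
                  from = b$from, to = a$to)
}

#' Invert a rigid transform
#' @param t a \code{rigid_transform}.
#' @return The inverse \code{rigid_transform}.
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), as.numeric(-t(t$rotation) %*% t$translation),
                  from = t$to, to = t$from)
}

#' Rotation angle of a rigid transform
#'
#' The geodesic rotation magnitude, in degrees, of the transform's rotation
#' part; useful for expressing registration error as a single angle.
#' @param t a \code{rigid_transform}.
#' @return Rotation angle in degrees, in [0, 180].
#' @export
rotation_angle <- function(t) {
  R <- t$rotation
  # atan2 form: well-conditioned near zero, unlike acos((tr-1)/2)
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
  ctheta <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  atan2(sqrt(sum(v^2)), ctheta) * 180 / pi
}

#' Write / read a rigid transform as JSON
#'
#' The transform is stored as a 4x4 homogeneous matrix in a small JSON
#' envelope together with its source and target frame tags, so a transform
#' can never be silently applied between the wrong frames.
#' @param t a \code{rigid_transform}.
#' @param path file path for the JSON envelope.
#' @return \code{write_transform} returns \code{path} invisibly;
#'   \code{read_transform} returns a \code{rigid_transform}.
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "rigid_transform"))
  m <- rbind(cbind(t$rotation, t$translation), c(0, 0, 0, 1))
  obj <- list(type = "rigid_transform", units = "mm",
              matrix = m,
              from = t$from %||% NA, to = t$to %||% NA)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- obj$matrix
  if (is.null(dim(m)) || !all(dim(m) == c(4L, 4L)))
    stop_transform_format("transform file does not contain a 4x4 matrix")
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || det(R) < 0)
    stop_transform_format("stored matrix is not a proper rotation")
  tag <- function(v) if (is.null(v) || length(v) == 0 || is.na(v)) NULL else v
  rigid_transform(R, m[1:3, 4], from = tag(obj$from), to = tag(obj$to))
}

#' Random rigid transform (for simulation and testing)
#'
#' Draws a uniformly random rotation axis, a rotation angle uniform on
#' \code{[0, max_angle_deg]} and a translation uniform in the cube
#' \code{[-max_trans_mm, max_trans_mm]^3}. Uses the current RNG state.
#' @param max_angle_deg maximum rotation angle, degrees.
#' @param max_trans_mm maximum per-axis translation, mm.
#' @return A \code{rigid_transform}.
#' @export
random_rigid_transform <- function(max_angle_deg = 10, max_trans_mm = 10) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  rigid_transform(rotation_about(ax, stats::runif(1, 0, max_angle_deg)),
                  stats::runif(3, -max_trans_mm, max_trans_mm))
}
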