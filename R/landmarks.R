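#' Named 3D landmarks and polyline traces
#'
#' A \code{landmark_set} bundles named 3D points (e.g. \code{R-Porion},
#' \code{ANS}) and named polyline traces (e.g. the manually traced borders of
#' the hypophyseal fossa, or a maxillary cortical-bone contour), all in mm, in
#' a single coordinate frame identified by \code{frame}:
#' \describe{
#'   \item{native}{the volume's own coordinate system before superimposition;}
#'   \item{superimposed}{after rigid superimposition onto the pre-treatment
#'     record;}
#'   \item{oriented}{after head orientation into the corrected Frankfort
#'     Horizontal frame.}
#' }
#'
#' @param points named list of numeric length-3 vectors, or an n x 3 matrix
#'   with row names; mm.
#' @param traces named list of m x 3 matrices (m >= 2 ordered vertices); mm.
#' @param frame frame tag, one of \code{"native"}, \code{"superimposed"},
#'   \code{"oriented"}.
#' @return An object of class \code{landmark_set}.
#' @export
landmark_set <- function(points = list(), traces = list(), frame = "native") {
  frame <- match.arg(frame, c("native", "superimposed", "oriented"))
  if (is.matrix(points)) {
    nm <- rownames(points)
    points <- lapply(seq_len(nrow(points)), function(i) as.numeric(points[i, ]))
    names(points) <- nm
  }
  if (length(points) && (is.null(names(points)) || anyDuplicated(names(points))))
    stop_duplicate_landmark("point names must be present and unique")
  if (length(traces) && (is.null(names(traces)) || anyDuplicated(names(traces))))
    stop_duplicate_landmark("trace names must be present and unique")
  points <- lapply(points, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3L || !all(is.finite(p)))
      stop_parse("each point must be 3 finite coordinates")
    p
  })
  traces <- lapply(traces, function(tr) {
    tr <- unname(as.matrix(tr))
    if (ncol(tr) != 3L || nrow(tr) < 2L || !all(is.finite(tr)))
      stop_parse("each trace must be an m x 3 matrix of finite coordinates, m >= 2")
    tr
  })
  structure(list(points = points, traces = traces, frame = frame),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set [%s]: %d points, %d traces\n",
              x$frame, length(x$points), length(x$traces)))
  if (length(x$points)) cat("  points:", paste(names(x$points), collapse = ", "), "\n")
  if (length(x$traces)) cat("  traces:", paste(names(x$traces), collapse = ", "), "\n")
  invisible(x)
}

#' Fetch a landmark point, failing informatively when absent
#' @param lms a \code{landmark_set}.
#' @param name landmark name.
#' @param measurement optional measurement name for the error condition.
#' @return Numeric length-3 position, mm.
#' @export
landmark_point <- function(lms, name, measurement = NULL) {
  p <- lms$points[[name]]
  if (is.null(p))
    stop_missing_landmark(sprintf("landmark '%s' is missing%s", name,
                                  if (is.null(measurement)) "" else
                                    sprintf(" (needed for %s)", measurement)),
                          landmark = name, measurement = measurement)
  p
}

#' Points of a landmark set as a matrix
#' @param lms a \code{landmark_set}.
#' @return n x 3 matrix with landmark names as row names.
#' @export
landmark_matrix <- function(lms) {
  if (!length(lms$points)) return(matrix(numeric(0), 0, 3))
  m <- do.call(rbind, lms$points)
  rownames(m) <- names(lms$points)
  m
}

#' Apply a rigid transform to every point and trace of a landmark set
#' @param lms a \code{landmark_set}.
#' @param t a \code{rigid_transform}.
#' @param new_frame frame tag of the result (default: keep).
#' @return A transformed \code{landmark_set}.
#' @export
transform_landmarks <- function(lms, t, new_frame = lms$frame) {
  landmark_set(points = lapply(lms$points, function(p) apply_transform(t, p)),
               traces = lapply(lms$traces, function(tr) apply_transform(t, tr)),
               frame = new_frame)
}

#' Read and write landmark points as CSV
#'
#' Points travel as a plain CSV with columns \code{name,x,y,z,frame}
#' (mm; one frame tag per file). Traces travel as JSON, see
#' \code{\link{read_traces}}.
#'
#' @param path CSV file path.
#' @return \code{read_landmarks} returns a \code{landmark_set} (no traces);
#'   \code{write_landmarks} returns \code{path} invisibly.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop_parse("landmark CSV must have columns name,x,y,z[,frame]")
  if (anyDuplicated(df$name))
    stop_duplicate_landmark(sprintf("duplicate landmark name(s): %s",
      paste(unique(df$name[duplicated(df$name)]), collapse = ", ")))
  xyz <- as.matrix(df[, c("x", "y", "z")])
  if (!is.numeric(xyz) || !all(is.finite(xyz)))
    stop_parse("non-finite or non-numeric coordinate in landmark CSV")
  frame <- if ("frame" %in% names(df) && nrow(df)) unique(df$frame) else "native"
  if (length(frame) > 1)
    stop_parse("landmark CSV mixes frame tags; one frame per file")
  pts <- lapply(seq_len(nrow(df)), function(i) as.numeric(xyz[i, ]))
  names(pts) <- df$name
  landmark_set(points = pts, frame = if (length(frame)) frame else "native")
}

#' @rdname read_landmarks
#' @param lms a \code{landmark_set}.
#' @export
write_landmarks <- function(lms, path) {
  m <- landmark_matrix(lms)
  df <- data.frame(name = rownames(m), x = m[, 1], y = m[, 2], z = m[, 3],
                   frame = lms$frame)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write polyline traces as JSON
#'
#' Each trace is an object \code{{name, frame, vertices: [[x,y,z], ...]}};
#' a file holds a list of such objects. Vertex order is preserved.
#'
#' @param path JSON file path.
#' @return \code{read_traces} returns a \code{landmark_set} (no points);
#'   \code{write_traces} returns \code{path} invisibly.
#' @export
read_traces <- function(path) {
  objs <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  if (is.data.frame(objs)) objs <- split(objs, seq_len(nrow(objs)))
  traces <- list()
  frames <- character(0)
  for (o in objs) {
    if (is.data.frame(o)) o <- as.list(o)
    v <- o$vertices
    if (is.list(v) && !is.matrix(v)) v <- do.call(rbind, lapply(v, unlist))
    if (is.list(v)) v <- v[[1]]
    v <- as.matrix(v)
    if (!all(is.finite(v))) stop_parse("non-finite vertex in trace file")
    nm <- as.character(o$name)
    if (nm %in% names(traces))
      stop_duplicate_landmark(sprintf("duplicate trace name '%s'", nm))
    traces[[nm]] <- v
    frames <- union(frames, as.character(o$frame %||% "native"))
  }
  if (length(frames) > 1) stop_parse("trace file mixes frame tags")
  landmark_set(traces = traces,
               frame = if (length(frames)) frames else "native")
}

#' @rdname read_traces
#' @param lms a \code{landmark_set}.
#' @export
write_traces <- function(lms, path) {
  objs <- lapply(names(lms$traces), function(nm)
    list(name = nm, frame = lms$frame, vertices = unname(lms$traces[[nm]])))
  jsonlite::write_json(objs, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Merge landmark sets sharing one frame
#' @param ... \code{landmark_set} objects with identical frame tags.
#' @return A combined \code{landmark_set}.
#' @export
merge_landmarks <- function(...) {
  sets <- list(...)
  frames <- unique(vapply(sets, function(s) s$frame, character(1)))
  if (length(frames) != 1)
    stop_frame_mismatch("cannot merge landmark sets from different frames")
  landmark_set(points = do.call(c, lapply(sets, function(s) s$points)),
               traces = do.call(c, lapply(sets, function(s) s$traces)),
               frame = frames)
}
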