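# Classed error conditions so callers can distinguish contract violations
# programmatically (tryCatch on the class) rather than by message matching.

cf_error <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "cephaloframe_error")))
}

cf_warn <- function(class, message, ...) {
  warning(warningCondition(message, ..., class = c(class, "cephaloframe_warning")))
}

#' @keywords internal
stop_mixed_series      <- function(msg) cf_error("MixedSeriesError", msg)
stop_header            <- function(msg) cf_error("HeaderError", msg)
stop_duplicate_landmark<- function(msg) cf_error("DuplicateLandmarkError", msg)
stop_parse             <- function(msg) cf_error("ParseError", msg)
stop_transform_format  <- function(msg) cf_error("TransformFormatError", msg)
stop_empty_mask        <- function(msg) cf_error("EmptyMaskError", msg)
stop_no_overlap        <- function(msg) cf_error("NoOverlapError", msg)
stop_degenerate_trace  <- function(msg) cf_error("DegenerateTraceError", msg)
stop_degenerate_axis   <- function(msg) cf_error("DegenerateAxisError", msg)
stop_degenerate_plane  <- function(msg) cf_error("DegeneratePlaneError", msg)
stop_midline_undefined <- function(msg) cf_error("MidlineUndefinedError", msg)
stop_frame_construction<- function(msg) cf_error("FrameConstructionError", msg)
stop_frame_mismatch    <- function(msg) cf_error("FrameMismatchError", msg)
stop_no_concavity      <- function(msg) cf_error("NoConcavityError", msg)
stop_side_mismatch     <- function(msg) cf_error("SideMismatchError", msg)
stop_projection_degen  <- function(msg) cf_error("ProjectionDegenerateError", msg)
stop_missing_landmark  <- function(msg, landmark = NULL, measurement = NULL)
  cf_error("MissingLandmarkError", msg, landmark = landmark, measurement = measurement)
stop_incomplete_panel  <- function(msg) cf_error("IncompletePanelError", msg)
stop_insufficient_reps <- function(msg) cf_error("InsufficientRepeatsError", msg)
stop_resolution        <- function(msg) cf_error("ResolutionError", msg)
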