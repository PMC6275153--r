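#' Pipeline configuration
#'
#' Validated bag of inputs and options for \code{\link{run_pipeline}}.
#' Unknown keys are rejected so silent typos cannot disable a stage.
#'
#' @param pre_volume,post_volume,mask_volume paths to the pre/post volumes
#'   and the cranial-base mask (NIfTI, or DICOM directory for the volumes);
#'   all three optional when \code{transform} is given or the records are
#'   already superimposed.
#' @param transform optional path to a precomputed moving-to-fixed
#'   transform JSON (skips the registration stage).
#' @param pre_landmarks,post_landmarks landmark CSV paths (pre carries the
#'   reference landmarks, digitized once).
#' @param pre_traces,post_traces optional trace JSON paths.
#' @param out_dir output directory (created if needed).
#' @param bins,sigmas,maxit registration settings, see
#'   \code{\link{registration_config}}.
#' @param half_width C-Orbitale rule, see \code{\link{construct_c_orbitale}}.
#' @param concavity_method see \code{\link{most_concave_point}}.
#' @param on_missing see \code{\link{measure_all}}.
#' @param seed integer seed recorded in the manifest.
#' @return A validated \code{pipeline_config} list.
#' @export
pipeline_config <- function(pre_landmarks, out_dir,
                            post_landmarks = NULL,
                            pre_volume = NULL, post_volume = NULL,
                            mask_volume = NULL, transform = NULL,
                            pre_traces = NULL, post_traces = NULL,
                            bins = 32, sigmas = c(2, 1, 0), maxit = 400,
                            half_width = "mean",
                            concavity_method = "curvature",
                            on_missing = "error", seed = 0L) {
  cfg <- as.list(environment())
  for (key in c("pre_landmarks")) if (is.null(cfg[[key]]))
    cf_error("ParseError", sprintf("pipeline config requires '%s'", key))
  paths <- c("pre_landmarks", "post_landmarks", "pre_volume", "post_volume",
             "mask_volume", "transform", "pre_traces", "post_traces")
  for (key in paths) if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
    cf_error("ParseError", sprintf("input '%s' does not exist: %s", key, cfg[[key]]))
  has_vols <- !is.null(cfg$pre_volume) || !is.null(cfg$post_volume) ||
    !is.null(cfg$mask_volume)
  if (has_vols && (is.null(cfg$pre_volume) || is.null(cfg$post_volume) ||
                   is.null(cfg$mask_volume)))
    cf_error("ParseError",
             "registration needs all of pre_volume, post_volume, mask_volume")
  structure(cfg, class = "pipeline_config")
}

#' Run the full evaluation pipeline
#'
#' Executes the four user steps in order — superimpose, identify the
#' reference once, orient, measure — writing every intermediate artifact to
#' \code{out_dir}: the superimposition transform (\code{transform.json}),
#' the reference frame (\code{frame.json}), oriented landmarks, the change
#' report (\code{report.csv}) and a manifest (\code{manifest.json})
#' recording the package version, options, registration metric and the
#' C-FH fit residual.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return List with \code{report}, \code{frame}, \code{transform} and
#'   \code{manifest}, invisibly the same data written to \code{out_dir}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cf_error("PipelineStageError",
               sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  reg <- NULL
  t_sup <- stage("register", {
    if (!is.null(config$transform)) read_transform(config$transform)
    else if (!is.null(config$pre_volume)) {
      fixed <- read_volume(config$pre_volume)
      moving <- read_volume(config$post_volume)
      maskv <- read_volume(config$mask_volume)
      reg <<- register_masked_rigid(fixed, moving, maskv$voxels > 0.5,
                                    registration_config(bins = config$bins,
                                                        sigmas = config$sigmas,
                                                        maxit = config$maxit,
                                                        seed = config$seed))
      reg$transform
    } else identity_transform(from = "moving", to = "fixed")
  })
  write_transform(t_sup, file.path(config$out_dir, "transform.json"))

  pre <- stage("reference", {
    lms <- read_landmarks(config$pre_landmarks)
    if (!is.null(config$pre_traces))
      lms <- merge_landmarks(lms, read_traces(config$pre_traces))
    lms$frame <- "superimposed"   # the pre record defines the superimposed frame
    lms
  })
  frame <- stage("reference", build_reference_frame(pre, half_width = config$half_width))
  write_reference_frame(frame, file.path(config$out_dir, "frame.json"))

  result <- list(frame = frame, transform = t_sup, report = NULL)
  if (!is.null(config$post_landmarks)) {
    post <- stage("orient", {
      lms <- read_landmarks(config$post_landmarks)
      if (!is.null(config$post_traces))
        lms <- merge_landmarks(lms, read_traces(config$post_traces))
      transform_landmarks(lms, t_sup, new_frame = "superimposed")
    })
    pre_o <- stage("orient", apply_frame(pre, frame))
    post_o <- stage("orient", apply_frame(post, frame))
    write_landmarks(pre_o, file.path(config$out_dir, "pre_oriented.csv"))
    write_landmarks(post_o, file.path(config$out_dir, "post_oriented.csv"))
    result$report <- stage("measure",
      measure_all(pre_o, post_o, frame, on_missing = config$on_missing,
                  concavity_method = config$concavity_method))
    write_report(result$report, file.path(config$out_dir, "report.csv"))
  }
  manifest <- list(
    package = "cephaloframe",
    version = as.character(utils::packageVersion("cephaloframe")),
    seed = config$seed,
    options = list(bins = config$bins, sigmas = config$sigmas,
                   half_width = config$half_width,
                   concavity_method = config$concavity_method),
    cfh_fit_residual_mm = frame$cfh$fit_residual,
    registration = if (!is.null(reg))
      list(initial_metric = reg$initial_metric,
           final_metric = reg$final_metric,
           iterations = reg$iterations, converged = reg$converged),
    sign_conventions = as.list(.sign_conventions))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  result$manifest <- manifest
  invisible(result)
}
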