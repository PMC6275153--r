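#' Intraclass correlation from a subjects x raters matrix
#'
#' Two-way random-effects ICC computed from the two-way ANOVA mean squares
#' of a complete subjects x raters table. The default model is absolute
#' agreement: \code{form = "single"} gives ICC(2,1), the reliability of one
#' measurement, and \code{form = "average"} gives ICC(2,k), the reliability
#' of the mean of the k raters/sessions. \code{model = "consistency"}
#' (ICC(3,1)/ICC(3,k)) drops the rater variance from the denominator.
#'
#' With mean squares MSR (subjects), MSC (raters), MSE (residual),
#' n subjects and k raters:
#' \deqn{ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)}
#' \deqn{ICC(2,k) = (MSR - MSE) / (MSR + (MSC - MSE) / n)}
#'
#' Negative estimates (possible when between-subject variance is tiny) are
#' clamped to 0 and flagged via attribute \code{"clamped"}.
#'
#' @param values numeric matrix, subjects in rows, raters (or sessions) in
#'   columns; no missing cells.
#' @param form \code{"single"} or \code{"average"}.
#' @param model \code{"agreement"} (two-way random, absolute agreement,
#'   default) or \code{"consistency"}.
#' @return ICC point estimate in [0, 1]; attribute \code{"clamped"} is TRUE
#'   when a negative estimate was clamped.
#' @export
icc <- function(values, form = c("single", "average"),
                model = c("agreement", "consistency")) {
  form <- match.arg(form); model <- match.arg(model)
  values <- as.matrix(values)
  if (anyNA(values) || !all(is.finite(values)))
    stop_incomplete_panel("panel has missing or non-finite cells")
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2)
    stop_incomplete_panel("need at least 2 subjects and 2 raters")
  grand <- mean(values)
  rm_ <- rowMeans(values); cm_ <- colMeans(values)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm_ - grand)^2) / (k - 1)
  sse <- sum((values - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm_) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  num <- msr - mse
  den <- switch(paste(model, form),
    "agreement single"    = msr + (k - 1) * mse + k * (msc - mse) / n,
    "agreement average"   = msr + (msc - mse) / n,
    "consistency single"  = msr + (k - 1) * mse,
    "consistency average" = msr)
  est <- if (den <= 0) 0 else num / den
  clamped <- FALSE
  if (!is.finite(est) || est < 0) { est <- 0; clamped <- TRUE }
  if (est > 1) est <- 1
  structure(est, clamped = clamped)
}

#' Pooled digitization standard deviation per coordinate
#'
#' Repeatability of a digitized coordinate: the sample SD across repeats is
#' computed per subject and pooled across subjects by root mean square
#' (equivalently, from the pooled within-subject sum of squares). Adding a
#' per-subject constant (true anatomy) leaves it unchanged.
#'
#' @param values numeric matrix, subjects in rows, repeats in columns.
#' @param pooling \code{"rms"} (default) or \code{"grand"}: pooled SD of
#'   deviations from subject means; identical for balanced panels.
#' @return Pooled SD, mm.
#' @export
coordinate_sd <- function(values, pooling = c("rms", "grand")) {
  pooling <- match.arg(pooling)
  values <- as.matrix(values)
  if (ncol(values) < 2)
    stop_insufficient_reps("need at least 2 repeats per subject")
  if (anyNA(values) || !all(is.finite(values)))
    stop_incomplete_panel("panel has missing or non-finite cells")
  if (pooling == "rms") {
    sqrt(mean(apply(values, 1, stats::var)))
  } else {
    dev <- values - rowMeans(values)
    sqrt(sum(dev^2) / (length(values) - nrow(values)))
  }
}

#' Digitization panel (long format)
#'
#' Repeated landmark digitizations as a long data frame with columns
#' \code{landmark, subject, rater, session, x, y, z} (mm), the layout the
#' reliability protocol produces: each landmark identified on each subject
#' by each observer in each weekly session.
#'
#' @param df data frame with the columns above.
#' @return The validated data frame, classed \code{digitization_panel}.
#' @export
digitization_panel <- function(df) {
  need <- c("landmark", "subject", "rater", "session", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop_parse(sprintf("panel needs columns %s", paste(need, collapse = ", ")))
  if (any(!is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop_incomplete_panel("panel has non-finite coordinates")
  class(df) <- c("digitization_panel", "data.frame")
  df
}

# subjects x repeats matrix for one landmark/coordinate; repeat factor is
# 'session' (intra-rater) or 'rater' (inter-rater)
.panel_matrix <- function(panel, lm, coord, repeat_var, fixed_var, fixed_level) {
  sub <- panel[panel$landmark == lm & panel[[fixed_var]] == fixed_level, ]
  tab <- tapply(sub[[coord]], list(sub$subject, sub[[repeat_var]]), mean)
  if (anyNA(tab))
    stop_incomplete_panel(sprintf("incomplete panel for %s/%s", lm, coord))
  unname(tab)
}

#' Reliability table (ICC and SD per landmark and coordinate)
#'
#' Builds the reliability report validating the reference-frame
#' digitizations: for every landmark and every coordinate (X, Y, Z, in the
#' original volume coordinate system before orientation), the intra- or
#' inter-rater ICC in Single and Average Measures form, plus the pooled
#' digitization SD.
#'
#' \code{mode = "intra"} treats one rater's repeated sessions as the
#' repeat factor (rater fixed, default the first); \code{mode = "inter"}
#' treats the raters as the repeat factor at one session (default the
#' first).
#'
#' @param panel a \code{digitization_panel}.
#' @param mode \code{"intra"} or \code{"inter"}.
#' @param fixed_level which rater (intra) / session (inter) to condition on;
#'   default the first level present.
#' @param model ICC model, see \code{\link{icc}}.
#' @return Data frame with columns \code{landmark}, \code{measures}
#'   (\code{"Single"}/\code{"Average"}) and \code{X_ICC, X_SD, Y_ICC, Y_SD,
#'   Z_ICC, Z_SD}.
#' @export
build_reliability_table <- function(panel, mode = c("intra", "inter"),
                                    fixed_level = NULL, model = "agreement") {
  mode <- match.arg(mode)
  repeat_var <- if (mode == "intra") "session" else "rater"
  fixed_var <- if (mode == "intra") "rater" else "session"
  if (is.null(fixed_level)) fixed_level <- sort(unique(panel[[fixed_var]]))[1]
  lms <- unique(panel$landmark)
  rows <- list()
  for (lm in lms) {
    vals <- list()
    for (coord in c("x", "y", "z")) {
      m <- .panel_matrix(panel, lm, coord, repeat_var, fixed_var, fixed_level)
      vals[[coord]] <- list(single = as.numeric(icc(m, "single", model)),
                            average = as.numeric(icc(m, "average", model)),
                            sd = coordinate_sd(m))
    }
    for (ms in c("Single", "Average")) {
      key <- tolower(ms)
      rows[[paste(lm, ms)]] <- data.frame(
        landmark = lm, measures = ms,
        X_ICC = vals$x[[key]], X_SD = vals$x$sd,
        Y_ICC = vals$y[[key]], Y_SD = vals$y$sd,
        Z_ICC = vals$z[[key]], Z_SD = vals$z$sd)
    }
  }
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  class(out) <- c("reliability_table", "data.frame")
  out
}
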