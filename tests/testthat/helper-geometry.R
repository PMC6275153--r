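# shared helpers for the suite

expect_vec_equal <- function(actual, expected, tol = 1e-9) {
  expect_lt(max(abs(as.numeric(actual) - as.numeric(expected))), tol)
}

# phantom -> superimposed/oriented landmark sets + frame, skipping voxels.
# Uses the generator's true inverse motion for the superimposition so that
# measurement properties are tested in isolation from registration.
oriented_phantom <- function(spec = phantom_spec()) {
  ph <- generate_phantom(spec)
  pre <- ph$pre
  pre$frame <- "superimposed"
  post <- transform_landmarks(ph$post, invert_transform(spec$motion),
                              new_frame = "superimposed")
  frame <- build_reference_frame(pre)
  list(ph = ph, frame = frame,
       pre = apply_frame(pre, frame), post = apply_frame(post, frame))
}

run_measurements <- function(spec = phantom_spec(), ...) {
  o <- oriented_phantom(spec)
  measure_all(o$pre, o$post, o$frame, ...)
}

# default aux plane of the phantom in the oriented frame (coronal cut at the
# ANS-PNS midpoint) and the oriented midline
phantom_aux <- function(o) {
  mid_max_plane(o$pre$points$ANS, o$pre$points$PNS, o$frame)
}

oriented_midline <- function() cf_line(c(0, 0, 0), c(0, 1, 0))

# independent two-way ANOVA oracle for the ICC, built on stats::aov
aov_icc_oracle <- function(m, form) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  rn <- trimws(rownames(tab))
  msr <- tab[rn == "subj", "Mean Sq"]; msc <- tab[rn == "rater", "Mean Sq"]
  mse <- tab[rn == "Residuals", "Mean Sq"]
  if (form == "single")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (msc - mse) / n)
}

# subjects x sessions matrix for one landmark/coordinate at rater 1
.panel_matrix_test <- function(panel, lm, coord) {
  sub <- panel[panel$landmark == lm & panel$rater == 1, ]
  unname(tapply(sub[[coord]], list(sub$subject, sub$session), mean))
}

cross_oracle <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
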