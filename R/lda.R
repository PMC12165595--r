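# Two-class Fisher linear discriminant with an exponential
# distance-to-boundary confidence mapping.

# Default exponent of the confidence mapping: chosen so a point on the
# boundary maps to 63% and the furthest training point to 100%.
LDA_KAPPA <- log(100 / 63)

#' Fit a two-class Fisher linear discriminant
#'
#' Equal-prior Fisher LDA on the (r543, r578) features: with pooled
#' within-class covariance `S` and class means `m_eso`, `m_tra`, the weights
#' are `w = S^{-1} (m_eso - m_tra)` and the offset
#' `b = -w . (m_eso + m_tra) / 2`, with the sign fixed so the tracheal side of
#' the boundary is negative (`w.x + b < 0` classifies trachea). The largest
#' absolute boundary distance over the training points, `d_max`, is stored to
#' anchor the confidence mapping. With `prior = "empirical"` the offset is
#' shifted by the log prior ratio.
#'
#' @param features data.frame with `r543`, `r578` and a `label` column (or
#'   `labels` given separately); at least two points per class.
#' @param labels optional character vector of organ labels.
#' @param prior "equal" (default; the cohort is balanced by design) or
#'   "empirical".
#' @return An object of class `lda_model` with elements `w`, `b`, `d_max`.
#' @export
lda_fit <- function(features, labels = NULL, prior = c("equal", "empirical")) {
  prior <- match.arg(prior)
  X <- feature_matrix(features)
  lab <- feature_labels(features, labels)
  n_by <- table(factor(lab, levels = ORGANS))
  if (any(n_by < 2L)) {
    abort_fit("LDA needs at least two points per class")
  }
  Xe <- X[lab == "esophagus", , drop = FALSE]
  Xt <- X[lab == "trachea", , drop = FALSE]
  mu_e <- colMeans(Xe); mu_t <- colMeans(Xt)
  S <- ((nrow(Xe) - 1L) * cov(Xe) + (nrow(Xt) - 1L) * cov(Xt)) /
    (nrow(X) - 2L)
  w <- tryCatch(solve(S, mu_e - mu_t), error = function(e) {
    abort_fit("pooled within-class covariance is singular (collinear features)")
  })
  if (sqrt(sum(w^2)) < .Machine$double.eps) {
    abort_fit("degenerate discriminant: identical class means")
  }
  b <- -sum(w * (mu_e + mu_t)) / 2
  if (prior == "empirical") {
    b <- b + log(n_by[["esophagus"]] / n_by[["trachea"]])
  }
  # Convention: trachea negative. w = S^-1 d with d = mu_e - mu_t already
  # satisfies it (w.d > 0), but enforce explicitly for robustness.
  if (sum(w * mu_t) + b > 0) { w <- -w; b <- -b }
  d_max <- max(abs(X %*% w + b)) / sqrt(sum(w^2))
  structure(list(w = as.numeric(w), b = as.numeric(b), d_max = d_max,
                 means = rbind(esophagus = mu_e, trachea = mu_t),
                 prior = prior),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> w = (%.4g, %.4g), b = %.4g, d_max = %.4g\n",
              x$w[1L], x$w[2L], x$b, x$d_max))
  invisible(x)
}

#' Percentage confidence from distance to the LDA boundary
#'
#' The perpendicular distance `d = |w.x + b| / ||w||` is normalized by the
#' largest training-set distance `d_max` (`u = min(d / d_max, 1)`) and scaled
#' exponentially: `confidence = 100 * exp(kappa * (u - 1))`. With the default
#' `kappa = log(100/63)` the furthest training point maps to 100% and a point
#' on the boundary to 63%. Points beyond `d_max` saturate at 100%.
#'
#' @param model a fitted [lda_model].
#' @param x numeric `(r543, r578)` pair, or a matrix/data.frame of such rows.
#' @param kappa confidence decay constant (per unit normalized distance).
#' @return Confidence in percent (vectorized over rows of `x`).
#' @export
lda_confidence <- function(model, x, kappa = LDA_KAPPA) {
  if (!inherits(model, "lda_model") || is.null(model$d_max) || model$d_max <= 0) {
    abort_state("model must be a fitted lda_model with d_max > 0")
  }
  X <- if (is.data.frame(x)) feature_matrix(x) else matrix(as.numeric(x), ncol = 2L)
  d <- abs(X %*% model$w + model$b) / sqrt(sum(model$w^2))
  u <- pmin(d / model$d_max, 1)
  as.numeric(100 * exp(kappa * (u - 1)))
}

#' Classify points with a fitted LDA model
#'
#' Label by the sign of the discriminant `w.x + b`: negative (left/below the
#' boundary line in the trough plane) is trachea, positive is esophagus; an
#' exact zero is classified trachea by convention, at the minimum confidence.
#'
#' @param model a fitted [lda_model].
#' @param x numeric `(r543, r578)` pair, or a matrix/data.frame of rows.
#' @param kappa passed to [lda_confidence].
#' @return data.frame with `label` and `confidence` (one row per input point).
#' @export
lda_classify <- function(model, x, kappa = LDA_KAPPA) {
  if (!inherits(model, "lda_model")) abort_state("model must be a fitted lda_model")
  X <- if (is.data.frame(x)) feature_matrix(x) else matrix(as.numeric(x), ncol = 2L)
  s <- as.numeric(X %*% model$w + model$b)
  data.frame(label = ifelse(s <= 0, "trachea", "esophagus"),
             confidence = lda_confidence(model, X, kappa = kappa))
}

#' Classify a cohort with LDA under a protocol
#'
#' Resubstitution classifies every point with the model fitted on the full
#' cohort; leave-one-out refits the discriminant without each point before
#' classifying it (confidence then uses that refit's own `d_max`).
#'
#' @param features labeled feature data.frame (see [lda_fit]).
#' @param labels optional labels vector.
#' @param protocol "resubstitution" or "loo".
#' @param prior,kappa passed through to [lda_fit] / [lda_confidence].
#' @return data.frame with `label` and `confidence` per point.
#' @export
lda_classify_cohort <- function(features, labels = NULL,
                                protocol = c("resubstitution", "loo"),
                                prior = "equal", kappa = LDA_KAPPA) {
  protocol <- match.arg(protocol)
  lab <- feature_labels(features, labels)
  if (protocol == "resubstitution") {
    model <- lda_fit(features, lab, prior = prior)
    return(lda_classify(model, features, kappa = kappa))
  }
  n <- nrow(features)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    m <- lda_fit(features[-i, , drop = FALSE], lab[-i], prior = prior)
    out[[i]] <- lda_classify(m, features[i, , drop = FALSE], kappa = kappa)
  }
  do.call(rbind, out)
}
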