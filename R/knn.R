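# Minkowski K-nearest-neighbor classifier with vote-fraction confidence.

#' Minkowski distance between two feature vectors
#'
#' `(|dx|^p + |dy|^p)^(1/p)` over the (r543, r578) coordinates; `p = 2` is
#' Euclidean, `p = 1` Manhattan.
#'
#' @param a,b numeric feature vectors of equal length.
#' @param p Minkowski order, `>= 1`.
#' @return Non-negative scalar distance.
#' @export
minkowski_distance <- function(a, b, p = 2) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 1) {
    abort_parameter("Minkowski order p must be a single number >= 1")
  }
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) abort_parameter("feature vectors must have equal length")
  sum(abs(a - b)^p)^(1 / p)
}

feature_matrix <- function(features) {
  if (!is.data.frame(features) || !all(c("r543", "r578") %in% names(features))) {
    abort_validation("features must be a data.frame with r543 and r578 columns")
  }
  cbind(features$r543, features$r578)
}

feature_labels <- function(features, labels) {
  if (is.null(labels)) labels <- features$label
  if (is.null(labels)) {
    abort_validation("labels must be supplied (or a 'label' column present)")
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(features)) {
    abort_validation("labels must match the number of feature rows")
  }
  if (!all(labels %in% ORGANS)) {
    abort_validation(sprintf("labels must be in {%s}", paste(ORGANS, collapse = ", ")))
  }
  labels
}

# Deterministic tie-break rank: distance ties at the k-th rank admit the
# point with the lexicographically smallest (pair_id, organ, acq_index); when
# metadata is absent, row order stands in.
tie_rank <- function(features) {
  if (all(c("pair_id", "organ", "acq_index") %in% names(features))) {
    ord <- order(features$pair_id, match(features$organ, ORGANS),
                 features$acq_index)
    rank <- integer(nrow(features)); rank[ord] <- seq_len(nrow(features))
    rank
  } else {
    seq_len(nrow(features))
  }
}

#' Fit (store) a K-nearest-neighbor model
#'
#' K-NN has no training step beyond retaining the labeled cohort; this
#' validates the feature set and fixes the neighbor count `k` and Minkowski
#' order `p`. The model supports `k + 1` votes (query plus neighbors) so the
#' cohort size must be at least `k + 1`.
#'
#' @param features data.frame with `r543`, `r578`, a `label` column (or
#'   `labels` supplied separately), and optionally the acquisition metadata
#'   used for deterministic distance tie-breaking.
#' @param labels optional character vector of organ labels.
#' @param k neighbor count (default 10, the count used with the 11-vote
#'   inclusive scheme).
#' @param p Minkowski order (default 2, Euclidean).
#' @return An object of class `knn_model`.
#' @export
knn_model <- function(features, labels = NULL, k = 10, p = 2) {
  X <- feature_matrix(features)
  lab <- feature_labels(features, labels)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    abort_parameter("k must be a positive integer")
  }
  if (!is.numeric(p) || length(p) != 1L || p < 1) {
    abort_parameter("Minkowski order p must be >= 1")
  }
  if (length(unique(lab)) < 2L) {
    abort_validation("training data must contain both classes")
  }
  if (k + 1 > nrow(X)) {
    abort_validation("k + 1 must not exceed the training-set size")
  }
  structure(list(X = X, labels = lab, k = as.integer(k), p = p,
                 tie_rank = tie_rank(features)),
            class = "knn_model")
}

#' Classify a point with the K-NN vote
#'
#' The voting set is the query's `k` nearest training points; when the query
#' is itself a member of the training cohort (`self_index` given and
#' `self_vote = TRUE`, the resubstitution protocol), the query's own label
#' joins the vote, giving `k + 1` votes in total, and the query is excluded
#' from the neighbor search. Confidence is the majority vote fraction in
#' percent: e.g. 8 tracheal votes out of 11 classify as trachea with 72.7%
#' confidence. An even voting set that splits equally falls back to the label
#' of the single nearest neighbor, flagged via `tie = TRUE` (confidence 50%).
#'
#' @param model a [knn_model].
#' @param query numeric `(r543, r578)` pair; defaults to the training point at
#'   `self_index`.
#' @param self_index index of the query within the training cohort, or `NULL`
#'   for an external query.
#' @param self_vote logical; include the query's own label as a vote
#'   (defaults to `TRUE` whenever `self_index` is given; set `FALSE` for
#'   leave-one-out evaluation).
#' @return List with `label`, `confidence` (percent), `votes` (named count per
#'   class), and `tie`.
#' @export
knn_classify <- function(model, query = NULL, self_index = NULL,
                         self_vote = !is.null(self_index)) {
  if (!inherits(model, "knn_model")) abort_state("model must be a knn_model")
  if (is.null(query)) {
    if (is.null(self_index)) abort_parameter("supply a query or self_index")
    query <- model$X[self_index, ]
  }
  if (isTRUE(self_vote) && is.null(self_index)) {
    abort_parameter("self_vote requires self_index (the query's own label)")
  }
  query <- as.numeric(query)
  d <- (abs(model$X[, 1L] - query[1L])^model$p +
          abs(model$X[, 2L] - query[2L])^model$p)^(1 / model$p)
  cand <- seq_len(nrow(model$X))
  if (!is.null(self_index)) cand <- cand[-self_index]
  ord <- cand[order(d[cand], model$tie_rank[cand])]
  nn <- ord[seq_len(model$k)]
  votes_lab <- model$labels[nn]
  if (isTRUE(self_vote)) votes_lab <- c(votes_lab, model$labels[self_index])
  votes <- vapply(ORGANS, function(o) sum(votes_lab == o), integer(1L))
  denom <- length(votes_lab)
  tie <- votes[1L] == votes[2L]
  label <- if (tie) model$labels[ord[1L]] else ORGANS[which.max(votes)]
  list(label = label,
       confidence = 100 * votes[[label]] / denom,
       votes = votes, tie = tie)
}

#' Classify a whole cohort with K-NN
#'
#' Applies [knn_classify] to every training point under the chosen protocol:
#' `"resubstitution"` (the default, matching the inclusive 11-vote scheme)
#' keeps the point's own vote; `"loo"` removes the point entirely (k votes)
#' for an honest generalization estimate.
#'
#' @param model a [knn_model].
#' @param protocol "resubstitution" or "loo".
#' @return data.frame with `label`, `confidence`, `tie` per training point.
#' @export
knn_classify_cohort <- function(model, protocol = c("resubstitution", "loo")) {
  protocol <- match.arg(protocol)
  n <- nrow(model$X)
  res <- lapply(seq_len(n), function(i) {
    knn_classify(model, self_index = i,
                 self_vote = protocol == "resubstitution")
  })
  data.frame(label = vapply(res, `[[`, character(1L), "label"),
             confidence = vapply(res, `[[`, numeric(1L), "confidence"),
             tie = vapply(res, `[[`, logical(1L), "tie"))
}
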