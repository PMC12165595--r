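# Fixtures are built in code; nothing is read from disk except what the tests
# themselves write to tempdirs.

# Random two-class 2-D feature set with acquisition-style metadata.
toy_features <- function(n_per_class = 20, seed = 1, sep = 1,
                         sd = 0.3) {
  set.seed(seed)
  n <- 2L * n_per_class
  data.frame(
    pair_id = rep(seq_len(n_per_class), 2L),
    organ = rep(c("trachea", "esophagus"), each = n_per_class),
    acq_index = rep(1L, n),
    r543 = c(rnorm(n_per_class, 0, sd), rnorm(n_per_class, sep, sd)),
    r578 = c(rnorm(n_per_class, 0, sd), rnorm(n_per_class, sep, sd)),
    label = rep(c("trachea", "esophagus"), each = n_per_class)
  )
}

# Two congruent unit-square point sets: their pooled sample covariance is
# exactly isotropic, so the Fisher boundary must be the perpendicular
# bisector of the class means.
square_classes <- function(offset = c(2, 1)) {
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  data.frame(
    r543 = c(sq[, 1], sq[, 1] + offset[1]),
    r578 = c(sq[, 2], sq[, 2] + offset[2]),
    label = rep(c("trachea", "esophagus"), each = 4L)
  )
}

# Minimal hand-built dataset on a short grid covering the analysis band.
tiny_dataset <- function(n_spectra = 3, grid = seq(530, 590, by = 2)) {
  refs <- reference_set(grid, dark = rep(100, length(grid)),
                        white = rep(100, length(grid)) + 1000)
  vals <- sapply(seq_len(n_spectra), function(j) {
    100 + 1000 * (0.5 + 0.01 * j * sin(grid / 10))
  })
  meta <- data.frame(pair_id = 1L, organ = rep("trachea", n_spectra),
                     acq_index = seq_len(n_spectra))
  spectra_dataset(spectra_set(grid, vals, meta), refs,
                  provenance = list(text = "hand-built fixture", seed = 0L))
}

# Exhaustive K-NN oracle: full distance loop, full sort, manual vote count.
# Deliberately shares no code path with knn_classify.
oracle_knn <- function(X, labels, query, k, p, self_index = NULL,
                       self_vote = !is.null(self_index)) {
  n <- nrow(X)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- (sum(abs(X[i, ] - query)^p))^(1 / p)
  idx <- seq_len(n)
  if (!is.null(self_index)) { d <- d[-self_index]; idx <- idx[-self_index] }
  ord <- idx[order(d, idx)]
  votes <- labels[ord[seq_len(k)]]
  if (self_vote) votes <- c(votes, labels[self_index])
  n_t <- sum(votes == "trachea"); n_e <- sum(votes == "esophagus")
  if (n_t == n_e) {
    lab <- labels[ord[1L]]
  } else {
    lab <- if (n_t > n_e) "trachea" else "esophagus"
  }
  list(label = lab,
       confidence = 100 * max(n_t, n_e, sum(votes == lab)) / length(votes))
}

# Closed-form feature oracle for the generator model: computes the expected
# (r543, r578) of a noiseless tissue spectrum with known depths, from the
# model's analytic form, independently of the preprocessing code.
oracle_features <- function(d543, d578, centers = c(543, 578),
                            widths = c(9, 11)) {
  gauss <- function(l, c, s) exp(-(l - c)^2 / (2 * s^2))
  base <- function(l) 1 + 2e-5 * (l - 561) - 1.5e-7 * (l - 561)^2
  R <- function(l) base(l) * (1 - d543 * gauss(l, centers[1], widths[1]) -
                                d578 * gauss(l, centers[2], widths[2]))
  c(r543 = R(543) / R(561), r578 = R(578) / R(561))
}

# Bisection on the exact binomial tail sum: the lower Clopper-Pearson bound
# p_L solves P(X >= x | p_L) = alpha / 2 for x > 0.
oracle_cp_lower <- function(x, n, alpha = 0.05, tol = 1e-13) {
  if (x == 0) return(0)
  upper_tail <- function(p) sum(dbinom(x:n, n, p))
  lo <- 0; hi <- 1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (upper_tail(mid) < alpha / 2) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}
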