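# Independent oracles used by the tests. These deliberately re-derive
# quantities by brute force or naive summation, separate from the package's
# code paths.

# Jaccard similarity by explicit set operations on sorted integer vectors.
oracle_jaccard <- function(s1, s2) {
  length(intersect(s1, s2)) / length(union(s1, s2))
}

# Hinge objective by literal term-by-term summation over dense rows.
oracle_objective <- function(w, x_dense, y, C, reg, bias = 0) {
  total <- if (reg == "L1") sum(abs(w)) else 0.5 * sum(w^2)
  for (i in seq_len(nrow(x_dense))) {
    total <- total + C * max(1 - y[i] * (sum(w * x_dense[i, ]) + bias), 0)
  }
  total
}

# Generic convex oracle: projected subgradient descent with Polyak-style
# decaying steps, tracking the best iterate. Slow but solver-agnostic.
oracle_subgradient <- function(x_dense, y, C, reg, iters = 30000) {
  d <- ncol(x_dense)
  w <- numeric(d)
  best <- Inf
  g0 <- sqrt(sum((C * crossprod(x_dense, y))^2)) + 1
  for (t in seq_len(iters)) {
    margins <- 1 - y * as.numeric(x_dense %*% w)
    active <- margins > 0
    g_loss <- -C * crossprod(x_dense[active, , drop = FALSE], y[active])
    g_reg <- if (reg == "L1") sign(w) else w
    g <- as.numeric(g_loss) + g_reg
    w <- w - (1 / (g0 * sqrt(t))) * g
    obj <- oracle_objective_fast(w, x_dense, y, C, reg)
    if (obj < best) best <- obj
  }
  best
}

oracle_objective_fast <- function(w, x_dense, y, C, reg, bias = 0) {
  r <- if (reg == "L1") sum(abs(w)) else 0.5 * sum(w^2)
  r + C * sum(pmax(1 - y * (as.numeric(x_dense %*% w) + bias), 0))
}

# AUC as the trapezoidal area under the empirical ROC curve.
oracle_auc_trapezoid <- function(scores, labels) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- sapply(thr, function(t) mean(scores[labels == 1] >= t))
  fpr <- sapply(thr, function(t) mean(scores[labels == -1] >= t))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Weight recovery by the explicit inverse-mapping route: build the inverse
# permutation tables and the one-to-many h-preimage lists, push each compact
# coordinate's weight back to tensor features, and average over blocks.
oracle_recover <- function(model, family, indices) {
  stopifnot(family$mode == "explicit")
  m <- family$m
  acc <- numeric(m)
  for (k in seq_len(family$ell) - 1L) {
    perm <- cpisketch:::family_permutation(family, k)   # perm[x+1] = pi_k(x)
    inv <- integer(m); inv[perm + 1L] <- seq_len(m) - 1L  # pi_k^{-1}
    h_all <- additional_hash(seq_len(m) - 1L, family)
    for (v in 0:(family$n_bins - 1L)) {
      wv <- model$weights[k * family$n_bins + v + 1L]
      if (wv == 0) next
      pre_t <- which(h_all == v) - 1L          # h^{-1}(v), minhash values
      feats <- inv[pre_t + 1L]                 # pi_k^{-1} of each
      acc[feats + 1L] <- acc[feats + 1L] + wv
    }
  }
  (acc / family$ell)[indices + 1L]
}

# Small labeled synthetic design for solver tests: planted halfspace over
# binary features. A margin gap around the split keeps the instance
# separable: rows scoring too close to the planted boundary are discarded.
make_halfspace <- function(n, d, seed, density = 0.3, gap = 0.3) {
  set.seed(seed)
  x <- matrix(as.numeric(runif(3 * n * d) < density), 3 * n, d)
  w_true <- rnorm(d)
  s <- as.numeric(x %*% w_true)
  keep <- which(abs(s - median(s)) > gap * sd(s))[seq_len(n)]
  x <- x[keep, , drop = FALSE]; s <- s[keep]
  y <- ifelse(s >= median(s), 1, -1)
  list(x = x, y = y)
}

design_from_dense <- function(x_dense, y) {
  ids <- tibble::tibble(compound_id = sprintf("c%d", seq_len(nrow(x_dense))),
                        protein_id = "p1")
  feats <- tibble::tibble(
    compound_id = ids$compound_id, protein_id = ids$protein_id,
    label = y,
    features = lapply(seq_len(nrow(x_dense)),
                      function(i) which(x_dense[i, ] == 1) - 1L))
  design_direct(feats, d = ncol(x_dense), d_prime = 1)
}

# Shared strong-signal study conditions: a 60 x 40 panel over an 80-feature
# tensor space with noiseless labels from 30 planted weights; chosen so the
# uncompressed linear model separates the classes almost perfectly.
strong_config <- function(seed) {
  synthetic_config(n_compounds = 60, n_proteins = 40, d = 10, d_prime = 8,
                   compound_density = 0.4, protein_density = 0.4,
                   n_planted = 30, effect_scale = 1, label_noise = 0,
                   positive_fraction = 0.2, seed = seed)
}
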