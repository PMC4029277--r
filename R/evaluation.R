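# Fold sizes differing by at most one, remainder to the lowest-indexed folds.
fold_sizes <- function(n, n_folds) {
  base <- n %/% n_folds
  sizes <- rep(base, n_folds)
  extra <- n %% n_folds
  if (extra > 0) sizes[seq_len(extra)] <- base + 1
  sizes
}

# Shuffle indices and deal them into folds of near-equal size.
deal_folds <- function(n, n_folds) {
  fold <- integer(n)
  fold[sample.int(n)] <- rep(seq_len(n_folds), times = fold_sizes(n, n_folds))
  fold
}

#' Pair-wise cross-validation split
#'
#' Randomly partitions labeled compound-protein pairs into `n_folds` test
#' folds of near-equal size (pair-wise CV: missing-interaction detection
#' among known entities).
#'
#' @param pairs Tibble of labeled pairs (needs a `label` column when
#'   `stratified = TRUE`).
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed; same seed, same assignment.
#' @param stratified Balance label proportions across folds (within one
#'   pair per class).
#' @return A `fold_assignment` object: `pairs` with an added integer `fold`
#'   column, plus `scheme`, `n_folds`, `seed` attributes.
#' @export
pairwise_cv_split <- function(pairs, n_folds = 5, seed = 1L,
                              stratified = FALSE) {
  n_folds <- check_count(n_folds, "n_folds", min = 2)
  pairs <- as_tibble(pairs)
  if (nrow(pairs) < n_folds) {
    stop_validation(sprintf("need at least %d pairs for %d folds.",
                            n_folds, n_folds))
  }
  fold <- with_seed(seed, {
    if (stratified) {
      f <- integer(nrow(pairs))
      for (lab in unique(pairs$label)) {
        idx <- which(pairs$label == lab)
        f[idx] <- deal_folds(length(idx), n_folds)
      }
      f
    } else {
      deal_folds(nrow(pairs), n_folds)
    }
  })
  out <- mutate(pairs, fold = fold)
  structure(out, scheme = "pairwise", n_folds = n_folds, seed = seed,
            class = c("fold_assignment", class(out)))
}

#' Block-wise cross-validation split
#'
#' Partitions compounds and proteins separately into `n_folds` subsets.
#' Fold `i` tests the pairs whose compound is in compound-fold `i` AND
#' whose protein is in protein-fold `i`; it trains on pairs whose compound
#' and protein both lie in the remaining folds. Pairs straddling the split
#' are used in neither, so no test compound or protein is ever seen in
#' training (the cold-start setting).
#'
#' @param compound_ids,protein_ids Character vectors of entity ids.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return A list of class `fold_assignment_blockwise` with tibbles
#'   `compound_folds` and `protein_folds` (`entity_id`, `fold`).
#' @export
blockwise_cv_split <- function(compound_ids, protein_ids, n_folds = 5,
                               seed = 1L) {
  n_folds <- check_count(n_folds, "n_folds", min = 2)
  compound_ids <- unique(as.character(compound_ids))
  protein_ids <- unique(as.character(protein_ids))
  if (length(compound_ids) < n_folds || length(protein_ids) < n_folds) {
    stop_validation(sprintf("need at least %d compounds and proteins.", n_folds))
  }
  with_seed(seed, {
    cf <- deal_folds(length(compound_ids), n_folds)
    pf <- deal_folds(length(protein_ids), n_folds)
    structure(list(
      compound_folds = tibble(entity_id = compound_ids, fold = cf),
      protein_folds = tibble(entity_id = protein_ids, fold = pf)
    ), scheme = "blockwise", n_folds = n_folds, seed = seed,
    class = "fold_assignment_blockwise")
  })
}

# Train/test pair indices for fold i under either scheme.
fold_indices <- function(assignment, pairs, i) {
  if (inherits(assignment, "fold_assignment_blockwise")) {
    cf <- assignment$compound_folds$fold[
      match(pairs$compound_id, assignment$compound_folds$entity_id)]
    pf <- assignment$protein_folds$fold[
      match(pairs$protein_id, assignment$protein_folds$entity_id)]
    list(test = which(cf == i & pf == i),
         train = which(cf != i & pf != i))
  } else {
    list(test = which(assignment$fold == i),
         train = which(assignment$fold != i))
  }
}

#' Sample negative pairs uniformly from the unlabeled complement
#'
#' Interaction gold standards list only positives; all other compound x
#' protein combinations are treated as (presumed) negatives. This draws a
#' uniform sample without replacement from that complement.
#'
#' @param positives Tibble of positive pairs (`compound_id`, `protein_id`).
#' @param compound_ids,protein_ids The full entity universes.
#' @param ratio Negatives per positive; `Inf` takes the whole complement.
#' @param seed Integer seed.
#' @return Tibble of sampled pairs with `label = -1`.
#' @export
sample_negatives <- function(positives, compound_ids, protein_ids,
                             ratio = 1, seed = 1L) {
  compound_ids <- unique(as.character(compound_ids))
  protein_ids <- unique(as.character(protein_ids))
  nc <- length(compound_ids); np <- length(protein_ids)
  if (nc * np > 2e7) {
    stop_validation("entity grid too large to enumerate negatives in memory.")
  }
  pos_idx <- (match(positives$compound_id, compound_ids) - 1) * np +
    (match(positives$protein_id, protein_ids) - 1)
  if (anyNA(pos_idx)) stop_validation("positives reference unknown entities.")
  all_neg <- setdiff(seq_len(nc * np) - 1, pos_idx)
  n_pos <- nrow(positives)
  if (is.infinite(ratio)) {
    take <- all_neg
  } else {
    if (ratio <= 0) stop_validation("`ratio` must be positive.")
    want <- round(ratio * n_pos)
    if (want > length(all_neg)) {
      stop_validation(sprintf(
        "ratio %.3g infeasible: at most %.3g negatives per positive available.",
        ratio, length(all_neg) / n_pos))
    }
    take <- with_seed(seed, sample(all_neg, want))
  }
  tibble(compound_id = compound_ids[take %/% np + 1],
         protein_id = protein_ids[take %% np + 1],
         label = -1L)
}

#' Area under the ROC curve
#'
#' Mann-Whitney rank form with midrank tie handling:
#' `AUC = P(score+ > score-) + 0.5 * P(score+ = score-)`.
#'
#' @param scores Numeric decision scores.
#' @param labels +1/-1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop_validation("`scores` and `labels` must have the same length.")
  }
  pos <- labels == 1; neg <- labels == -1
  if (!any(pos) || !any(neg)) {
    abort("AUC is undefined with a single class.",
          class = "cpisketch_undefined_auc_error")
  }
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(pos); n_neg <- sum(neg)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Run a cross-validation experiment
#'
#' Full protocol on a labeled dataset: build pair feature sets once, encode
#' them (compact mode) or use them directly, split into folds under the
#' chosen scheme, and for every candidate `C` train on each fold's training
#' pairs and score its test pairs by AUC. When a `C` grid is given, the
#' reported model selection picks the `C` with the best mean test AUC, the
#' protocol used for the published C-sweeps (`10^-5 ... 10^5`).
#'
#' @param dataset An [interaction_dataset()] with labeled pairs.
#' @param scheme `"pairwise"` or `"blockwise"`.
#' @param mode `"compact"` (sketched features, MH-SVM) or `"direct"` (raw
#'   tensor features).
#' @param regularization `"L2"` or `"L1"`.
#' @param C Numeric vector of hinge-loss weights to sweep.
#' @param ell,n_bins Sketch parameters (compact mode); `n_bins` is capped at
#'   the tensor dimension `M = D * D'`.
#' @param n_folds Number of folds (default 5).
#' @param seed Master seed: fold assignment, hash family and solver are all
#'   derived from it.
#' @param stratified Stratify pairwise folds by label.
#' @param skip_empty Drop pairs with empty feature sets instead of erroring.
#' @param blockwise_pairing `"diagonal"` tests compound-fold i against
#'   protein-fold i (`n_folds` test blocks); `"grid"` tests every
#'   compound-fold x protein-fold combination.
#' @param tolerance,max_iterations,fit_bias Solver controls (see
#'   [train_linear_svm()]).
#' @return An object of class `cv_result`: per-fold tibble (`fold`, `C`,
#'   `auc`, sizes, elapsed seconds), the selected `best_C`, its mean and sd
#'   AUC, and the experiment settings. `tidy()` returns the fold table,
#'   `glance()` the one-row summary, `autoplot()` the AUC-vs-C curve.
#' @export
run_cv_experiment <- function(dataset,
                              scheme = c("pairwise", "blockwise"),
                              mode = c("compact", "direct"),
                              regularization = c("L2", "L1"),
                              C = 1, ell = 10, n_bins = 2^16,
                              n_folds = 5, seed = 1L, stratified = FALSE,
                              skip_empty = FALSE,
                              blockwise_pairing = c("diagonal", "grid"),
                              tolerance = 1e-3, max_iterations = 1000,
                              fit_bias = FALSE) {
  stopifnot(inherits(dataset, "cpi_dataset"))
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  regularization <- match.arg(regularization)
  blockwise_pairing <- match.arg(blockwise_pairing)
  d <- fp_dimension(dataset$compounds)
  d_prime <- fp_dimension(dataset$proteins)
  m <- d * d_prime

  feats <- pair_features(dataset)
  empty <- lengths(feats$features) == 0
  if (any(empty)) {
    if (!skip_empty) {
      abort(sprintf("pair (%s, %s) has an empty feature set; use skip_empty = TRUE.",
                    feats$compound_id[empty][1], feats$protein_id[empty][1]),
            class = "cpisketch_empty_set_error")
    }
    warn(sprintf("dropping %d pair(s) with empty feature sets.", sum(empty)))
    feats <- feats[!empty, , drop = FALSE]
  }

  if (mode == "compact") {
    n_bins_eff <- min(n_bins, m)
    family <- hash_family(ell, m, n_bins_eff,
                          master_seed = mix_seed(seed, 1L, stream = 4L))
    encoded <- compact_encode(feats, family)
    design_all <- design_compact(encoded, family)
  } else {
    family <- NULL
    design_all <- design_direct(feats, d, d_prime)
  }

  assignment <- if (scheme == "pairwise") {
    pairwise_cv_split(feats, n_folds, seed = mix_seed(seed, 2L, stream = 4L),
                      stratified = stratified)
  } else {
    blockwise_cv_split(dataset$compounds$entity_id,
                       dataset$proteins$entity_id, n_folds,
                       seed = mix_seed(seed, 2L, stream = 4L))
  }

  fold_defs <- if (scheme == "blockwise" && blockwise_pairing == "grid") {
    expand.grid(ci = seq_len(n_folds), pi = seq_len(n_folds))
  } else {
    data.frame(ci = seq_len(n_folds), pi = seq_len(n_folds))
  }

  rows <- list()
  for (f in seq_len(nrow(fold_defs))) {
    if (scheme == "blockwise") {
      cf <- assignment$compound_folds$fold[
        match(feats$compound_id, assignment$compound_folds$entity_id)]
      pf <- assignment$protein_folds$fold[
        match(feats$protein_id, assignment$protein_folds$entity_id)]
      test <- which(cf == fold_defs$ci[f] & pf == fold_defs$pi[f])
      train <- which(cf != fold_defs$ci[f] & pf != fold_defs$pi[f])
    } else {
      ix <- fold_indices(assignment, feats, f)
      test <- ix$test; train <- ix$train
    }
    if (!length(test) || length(unique(design_all$y[test])) < 2 ||
        length(unique(design_all$y[train])) < 2) {
      warn(sprintf("fold %d skipped: a split lacks both classes.", f))
      next
    }
    x_train <- design_all$x[train, , drop = FALSE]
    x_test <- design_all$x[test, , drop = FALSE]
    dtr <- new_design(x_train, design_all$y[train], design_all$ids[train, ],
                      mode = mode, family = family, d = d, d_prime = d_prime)
    for (cc in C) {
      t0 <- proc.time()[["elapsed"]]
      fit <- train_linear_svm(dtr, regularization, C = cc,
                              tolerance = tolerance,
                              max_iterations = max_iterations,
                              fit_bias = fit_bias,
                              seed = mix_seed(seed, f, stream = 5L))
      scores <- as.numeric(x_test %*% fit$weights) + fit$bias
      rows[[length(rows) + 1L]] <- tibble(
        fold = f, C = cc,
        auc = auc_score(scores, design_all$y[test]),
        n_train = length(train), n_test = length(test),
        n_nonzero = sum(fit$weights != 0),
        seconds = proc.time()[["elapsed"]] - t0)
    }
  }
  folds <- bind_rows(rows)
  if (!nrow(folds)) abort("no usable folds.", class = "cpisketch_degenerate_error")
  by_c <- folds |> group_by(C) |>
    summarise(mean_auc = mean(auc), sd_auc = stats::sd(auc), .groups = "drop")
  best <- by_c[which.max(by_c$mean_auc), ]
  structure(list(
    folds = folds, by_c = by_c,
    best_C = best$C, mean_auc = best$mean_auc, sd_auc = best$sd_auc,
    settings = list(scheme = scheme, mode = mode,
                    regularization = regularization, ell = ell,
                    n_bins = if (mode == "compact") family$n_bins else NA,
                    n_folds = n_folds, seed = seed,
                    stratified = stratified,
                    blockwise_pairing = blockwise_pairing),
    family = family
  ), class = "cv_result")
}

#' @exportS3Method base::print
print.cv_result <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "<cv_result: %s CV, %s%sSVM%s | best C = %g, AUC = %.3f +/- %.3f over %d folds>\n",
    s$scheme, if (s$mode == "compact") "MH-" else "", s$regularization,
    if (s$mode == "compact") sprintf(" (ell = %d, N = %g)", s$ell, s$n_bins) else "",
    x$best_C, x$mean_auc, if (is.na(x$sd_auc)) 0 else x$sd_auc,
    length(unique(x$folds$fold))))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @export
glance.cv_result <- function(x, ...) {
  s <- x$settings
  tibble(scheme = s$scheme, mode = s$mode,
         regularization = s$regularization,
         best_C = x$best_C, mean_auc = x$mean_auc, sd_auc = x$sd_auc,
         n_folds = s$n_folds, seed = s$seed)
}

#' @export
autoplot.cv_result <- function(object, ...) {
  df <- object$folds
  ggplot2::ggplot(df, ggplot2::aes(x = .data$C, y = .data$auc,
                                   group = factor(.data$fold),
                                   colour = factor(.data$fold))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "C (hinge-loss weight)", y = "test AUC",
                  colour = "fold",
                  title = sprintf("%s cross-validation, %s%sSVM",
                                  object$settings$scheme,
                                  if (object$settings$mode == "compact") "MH-" else "",
                                  object$settings$regularization)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL

#' Plot the additional-hashing collision law
#'
#' Collision probability of one compact-fingerprint coordinate as a function
#' of the bin count `N`, for several Jaccard similarities: the curves drop
#' toward their limit `J` and are flat beyond a few hundred bins, showing
#' why small `N` sacrifices almost nothing.
#'
#' @param j Jaccard similarities to draw (one curve each).
#' @param log2_n Range of `log2(N)` values.
#' @return A ggplot object.
#' @export
plot_collision_law <- function(j = c(0.1, 0.3, 0.5, 0.7), log2_n = 2:16) {
  df <- tidyr::expand_grid(J = j, log2N = log2_n) |>
    mutate(p = collision_probability_vec(.data$J, 2^.data$log2N))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2N, y = .data$p,
                                   colour = factor(.data$J))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(log[2](N)), y = "collision probability",
                  colour = "Jaccard J") +
    ggplot2::theme_minimal()
}

collision_probability_vec <- function(j, n) {
  mapply(function(jj, nn) collision_probability(jj, nn), j, n)
}
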