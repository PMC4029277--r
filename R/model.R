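#' Training designs for hinge-loss linear models
#'
#' A design bundles a sparse binary feature matrix, labels and pair ids.
#' `design_compact()` builds it from compact fingerprints (feature width
#' `ell * N`, exactly `ell` ones per row); `design_direct()` builds it from
#' raw tensor-product feature sets (feature width `D * D'`), the
#' uncompressed representation the sketched one is compared against.
#'
#' @param encoded Output of [compact_encode()] (must carry a `label` column).
#' @param family The encoding [hash_family()].
#' @return An object of class `svm_design` with elements `x` (dgCMatrix),
#'   `y` (+1/-1), `ids` (tibble), `mode`, and `family` (compact mode).
#' @export
design_compact <- function(encoded, family) {
  stopifnot(inherits(family, "hash_family"))
  if (!"label" %in% names(encoded)) stop_validation("`encoded` needs a label column.")
  new_design(compact_matrix(encoded, family), encoded$label,
             encoded[c("compound_id", "protein_id")],
             mode = "compact", family = family)
}

#' @rdname design_compact
#' @param features Output of [pair_features()] (list-column of tensor
#'   feature indices plus a `label` column).
#' @param d,d_prime Compound / protein fingerprint dimensions.
#' @export
design_direct <- function(features, d, d_prime) {
  d <- check_count(d, "d"); d_prime <- check_count(d_prime, "d_prime")
  width <- d * d_prime
  if (width >= .Machine$integer.max) {
    stop_validation("D * D' exceeds the representable matrix width; use compact mode.")
  }
  if (!"label" %in% names(features)) stop_validation("`features` needs a label column.")
  lens <- lengths(features$features)
  x <- Matrix::sparseMatrix(
    i = rep(seq_len(nrow(features)), lens),
    j = unlist(features$features, use.names = FALSE) + 1,
    x = 1, dims = c(nrow(features), width))
  new_design(x, features$label, features[c("compound_id", "protein_id")],
             mode = "direct", family = NULL, d = d, d_prime = d_prime)
}

new_design <- function(x, y, ids, mode, family, d = NULL, d_prime = NULL) {
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop_validation("labels must be +1/-1.")
  x <- methods::as(methods::as(x, "CsparseMatrix"), "dMatrix")
  if (length(x@x) && any(x@x != 1)) stop_validation("design entries must be 0/1.")
  structure(list(x = x, y = y, ids = as_tibble(ids), mode = mode,
                 family = family, d = d, d_prime = d_prime),
            class = "svm_design")
}

#' @rdname design_compact
#' @param design An `svm_design`.
#' @param rows Integer row indices to keep.
#' @export
design_subset <- function(design, rows) {
  stopifnot(inherits(design, "svm_design"))
  new_design(design$x[rows, , drop = FALSE], design$y[rows],
             design$ids[rows, , drop = FALSE], mode = design$mode,
             family = design$family, d = design$d, d_prime = design$d_prime)
}

#' @exportS3Method base::print
print.svm_design <- function(x, ...) {
  cat(sprintf("<svm_design (%s): %d examples x %d features, %d positive>\n",
              x$mode, nrow(x$x), ncol(x$x), sum(x$y > 0)))
  invisible(x)
}

#' Regularized hinge-loss objective
#'
#' Evaluates `R(w) + C * sum_i max(1 - y_i (w'x_i + bias), 0)` with
#' `R(w) = ||w||_1` (L1) or `0.5 ||w||_2^2` (L2) — the objective both
#' [train_linear_svm()] and its reference oracles minimize.
#'
#' @param weights Numeric weight vector (length = feature width).
#' @param design An [design_compact()]/[design_direct()] object.
#' @param regularization `"L1"` or `"L2"`.
#' @param C Positive hinge-loss weight.
#' @param bias Intercept (default 0).
#' @return The objective value.
#' @export
hinge_objective <- function(weights, design, regularization = c("L2", "L1"),
                            C = 1, bias = 0) {
  regularization <- match.arg(regularization)
  if (length(weights) != ncol(design$x)) {
    stop_validation(sprintf("weight length %d != feature width %d.",
                            length(weights), ncol(design$x)))
  }
  if (C <= 0) stop_validation("`C` must be positive.")
  margins <- 1 - design$y * (as.numeric(design$x %*% weights) + bias)
  reg <- if (regularization == "L1") sum(abs(weights)) else 0.5 * sum(weights^2)
  reg + C * sum(pmax(margins, 0))
}

#' Train an L1- or L2-regularized hinge-loss linear model
#'
#' Fits `min_w R(w) + C * sum_i max(1 - y_i w'x_i, 0)` over sparse binary
#' features. The L2 problem is solved by dual coordinate descent (one
#' box-constrained dual variable per example, cyclic order, stopping on the
#' duality gap of the best iterate). The L1 problem is solved by ADMM whose
#' weight step is cyclic coordinate descent with soft-thresholding, so L1
#' solutions carry exact zeros. Both solvers return the best primal iterate
#' seen; its objective, recorded per sweep in `trace`, is non-increasing by
#' construction. On compact fingerprints this is the sketched classifier
#' (MH-L1SVM / MH-L2SVM); on direct tensor features it is the uncompressed
#' baseline (L1SVM / L2SVM).
#'
#' @param design An [design_compact()] or [design_direct()] object with both
#'   classes present.
#' @param regularization `"L2"` (dense weights) or `"L1"` (sparsity-inducing).
#' @param C Positive hinge-loss weight; larger C fits the training labels
#'   harder.
#' @param tolerance Relative objective-decrease stopping threshold per sweep.
#' @param max_iterations Maximum number of coordinate sweeps; hitting it
#'   raises a warning and flags the model as non-converged.
#' @param seed Accepted for interface stability; the cyclic coordinate order
#'   makes the solver deterministic regardless.
#' @param fit_bias Fit an unpenalized intercept (default `FALSE`; compact
#'   rows have constant sum `ell`, which largely absorbs an intercept).
#' @return An object of class `cpi_svm` carrying `weights`, `bias`,
#'   `regularization`, `C`, `mode`, `family` (compact mode), the final
#'   `objective`, the per-sweep objective `trace`, and a `converged` flag.
#' @export
train_linear_svm <- function(design, regularization = c("L2", "L1"), C = 1,
                             tolerance = 1e-3, max_iterations = 1000,
                             seed = 1L, fit_bias = FALSE) {
  stopifnot(inherits(design, "svm_design"))
  regularization <- match.arg(regularization)
  if (C <= 0) stop_validation("`C` must be positive.")
  if (length(unique(design$y)) < 2) {
    abort("training labels contain a single class; cannot fit a classifier.",
          class = "cpisketch_degenerate_error")
  }
  x <- design$x
  fit <- if (regularization == "L2") {
    xt <- Matrix::t(x)
    cpp_train_l2_dual(xt@p, xt@i, nrow(x), ncol(x), design$y, C,
                      isTRUE(fit_bias), tolerance, as.integer(max_iterations))
  } else {
    cpp_train_l1_admm(x@p, x@i, nrow(x), ncol(x), design$y, C,
                      isTRUE(fit_bias), rho = max(1, C), tol = tolerance,
                      max_iters = as.integer(max_iterations))
  }
  if (!fit$converged) {
    warn(sprintf("solver did not converge within %d iterations.",
                 max_iterations))
  }
  structure(list(
    weights = fit$weights, bias = fit$bias,
    regularization = regularization, C = C,
    mode = design$mode, family = design$family,
    d = design$d, d_prime = design$d_prime,
    objective = fit$objective, trace = fit$trace,
    sweeps = fit$sweeps, converged = fit$converged
  ), class = "cpi_svm")
}

#' @exportS3Method base::print
print.cpi_svm <- function(x, ...) {
  cat(sprintf(
    "<cpi_svm: %s%s, C = %g, %d/%d nonzero weights, objective %.6g%s>\n",
    if (x$mode == "compact") "MH-" else "", paste0(x$regularization, "SVM"),
    x$C, sum(x$weights != 0), length(x$weights), x$objective,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Decision scores of a fitted model
#'
#' `score_i = w'x_i + bias`; the predicted class is `sign(score)`.
#'
#' @param model A fitted [train_linear_svm()] model.
#' @param newdata An `svm_design`, a sparse 0/1 matrix of matching width, an
#'   encoded tibble (compact mode), or a pair-features tibble (direct mode).
#' @return Numeric score vector.
#' @export
decision_scores <- function(model, newdata) {
  stopifnot(inherits(model, "cpi_svm"))
  x <- if (inherits(newdata, "svm_design")) {
    newdata$x
  } else if (methods::is(newdata, "Matrix") || is.matrix(newdata)) {
    newdata
  } else if (is.data.frame(newdata) && "bins" %in% names(newdata)) {
    if (model$mode != "compact") stop_validation("encoded rows need a compact-mode model.")
    compact_matrix(newdata, model$family)
  } else if (is.data.frame(newdata) && "features" %in% names(newdata)) {
    if (model$mode != "direct") stop_validation("feature rows need a direct-mode model.")
    lens <- lengths(newdata$features)
    Matrix::sparseMatrix(i = rep(seq_len(nrow(newdata)), lens),
                         j = unlist(newdata$features, use.names = FALSE) + 1,
                         x = 1, dims = c(nrow(newdata), length(model$weights)))
  } else {
    stop_validation("unsupported `newdata` for decision_scores().")
  }
  if (ncol(x) != length(model$weights)) {
    stop_validation(sprintf("feature width %d != model width %d.",
                            ncol(x), length(model$weights)))
  }
  as.numeric(x %*% model$weights) + model$bias
}

#' @export
predict.cpi_svm <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  s <- decision_scores(object, newdata)
  if (type == "score") s else ifelse(s >= 0, 1L, -1L)
}

#' @export
tidy.cpi_svm <- function(x, ...) {
  nz <- which(x$weights != 0)
  tibble(index = nz - 1L, weight = x$weights[nz])
}

#' @export
glance.cpi_svm <- function(x, ...) {
  tibble(mode = x$mode, regularization = x$regularization, C = x$C,
         objective = x$objective, n_nonzero = sum(x$weights != 0),
         n_features = length(x$weights), sweeps = x$sweeps,
         converged = x$converged)
}

# ---- serialization ---------------------------------------------------------

#' Save / load a fitted model as JSON
#'
#' Weights are stored sparsely as (index, value) pairs; a compact-mode model
#' stores its hash family as the five defining fields.
#'
#' @param model A [train_linear_svm()] fit.
#' @param path Output path.
#' @return `path` invisibly; `read_model()` returns the `cpi_svm`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cpi_svm"))
  nz <- which(model$weights != 0)
  payload <- list(
    format = "cpisketch-model-1",
    mode = model$mode, regularization = model$regularization,
    C = model$C, bias = model$bias,
    n_features = length(model$weights),
    d = model$d, d_prime = model$d_prime,
    family = if (!is.null(model$family)) family_fields(model$family),
    weight_index = nz - 1L, weight_value = model$weights[nz],
    objective = model$objective, converged = model$converged
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "cpisketch-model-1")) {
    abort(sprintf("%s: not a cpisketch model file.", path),
          class = "cpisketch_parse_error")
  }
  w <- numeric(p$n_features)
  if (length(p$weight_index)) w[p$weight_index + 1] <- p$weight_value
  structure(list(
    weights = w, bias = p$bias %||% 0,
    regularization = p$regularization, C = p$C, mode = p$mode,
    family = if (!is.null(p$family)) family_from_fields(as.list(p$family)),
    d = p$d, d_prime = p$d_prime,
    objective = p$objective, trace = NULL, sweeps = NA_integer_,
    converged = isTRUE(p$converged)
  ), class = "cpi_svm")
}
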