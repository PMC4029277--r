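#' Recover tensor-feature weights from a compact-fingerprint model
#'
#' A compact-mode model carries weights on sketch coordinates `k*N + b`. To
#' interpret them in the original substructure-x-domain space, each tensor
#' feature `i` is pushed forward through every permutation and the
#' additional hash, and the touched weights are averaged over the `ell`
#' blocks:
#' `recovered[i] = (1/ell) * sum_k w[k*N + h(pi_k(i))]`.
#' This forward composition is exactly equivalent to applying the inverse
#' maps `h^-1` then `pi_k^-1` to each compact coordinate and averaging, but
#' needs no stored inverse tables.
#'
#' @param model A compact-mode [train_linear_svm()] fit carrying its hash
#'   family.
#' @param restrict_to Tensor feature indices to recover. Usually the set of
#'   features observed in a dataset (see [pair_features()]); enumerating all
#'   `D * D'` indices is possible but wasteful.
#' @param d_prime Protein fingerprint dimension `D'`, used to decompose
#'   tensor indices into (substructure, domain); taken from the model when
#'   it was fitted through [design_direct()] metadata, otherwise required.
#' @return A tibble of class `cpi_recovered` with columns `tensor_index`,
#'   `compound_bit`, `protein_bit`, `weight`, carrying `ell` and `n_bins`
#'   as attributes.
#' @export
recover_weights <- function(model, restrict_to, d_prime = NULL) {
  stopifnot(inherits(model, "cpi_svm"))
  if (model$mode != "compact") {
    abort("direct-mode weights are already in tensor coordinates; nothing to recover.",
          class = "cpisketch_mode_error")
  }
  family <- model$family
  d_prime <- d_prime %||% model$d_prime
  if (is.null(d_prime)) stop_validation("`d_prime` is required to decompose tensor indices.")
  idx <- sort(unique(as.numeric(restrict_to)))
  if (!length(idx)) stop_validation("`restrict_to` must be non-empty.")
  if (min(idx) < 0 || max(idx) >= family$m) {
    stop_validation(sprintf("tensor indices must lie in [0, %g).", family$m))
  }
  acc <- numeric(length(idx))
  for (k in seq_len(family$ell) - 1L) {
    tk <- if (family$mode == "explicit") {
      family_permutation(family, k)[idx + 1L]
    } else {
      cpp_affine_hash(idx, family$perm_a[k + 1L], family$perm_b[k + 1L],
                      family$p)
    }
    bins <- additional_hash(tk, family)
    acc <- acc + model$weights[k * family$n_bins + bins + 1L]
  }
  un <- tensor_unindex(idx, d_prime)
  out <- tibble(tensor_index = idx,
                compound_bit = un$compound_bit,
                protein_bit = un$protein_bit,
                weight = acc / family$ell)
  attr(out, "ell") <- family$ell
  attr(out, "n_bins") <- family$n_bins
  class(out) <- c("cpi_recovered", class(out))
  out
}

#' Rank substructure-domain features by recovered weight
#'
#' Sorts recovered (or direct) tensor-feature weights in decreasing order;
#' large positive weights mark substructure-domain co-occurrences the model
#' associates with interaction. Ties are broken by ascending tensor index so
#' the ranking is deterministic.
#'
#' @param recovered A [recover_weights()] table (any tibble with
#'   `tensor_index` and `weight` columns works).
#' @param k Number of top entries to return; if larger than the number of
#'   entries, all are returned with a message.
#' @param compound_labels,protein_labels Optional character vectors mapping
#'   bit index + 1 to a human-readable label (e.g. substructure or PFAM
#'   names).
#' @return A tibble sorted by descending weight with columns
#'   `compound_bit`, `protein_bit`, optional labels, and `weight`.
#' @export
top_features <- function(recovered, k, compound_labels = NULL,
                         protein_labels = NULL) {
  k <- check_count(k, "k")
  stopifnot(all(c("tensor_index", "weight") %in% names(recovered)))
  ord <- order(-recovered$weight, recovered$tensor_index)
  if (k > nrow(recovered)) {
    inform(sprintf("k = %d exceeds the %d available entries; returning all.",
                   k, nrow(recovered)))
    k <- nrow(recovered)
  }
  out <- as_tibble(recovered)[ord[seq_len(k)], , drop = FALSE]
  if (!is.null(compound_labels)) {
    out$compound_label <- compound_labels[out$compound_bit + 1]
  }
  if (!is.null(protein_labels)) {
    out$protein_label <- protein_labels[out$protein_bit + 1]
  }
  cols <- c("compound_bit", "protein_bit",
            intersect(c("compound_label", "protein_label"), names(out)),
            "weight", "tensor_index")
  out[, cols]
}

#' Write a ranked feature table to TSV
#'
#' @param features Output of [top_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_top_features <- function(features, path) {
  cols <- intersect(c("compound_bit", "protein_bit", "compound_label",
                      "protein_label", "weight"), names(features))
  utils::write.table(features[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
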