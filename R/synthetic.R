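#' Configuration for the synthetic interaction generator
#'
#' The generator emulates the statistical shape of chemogenomic screening
#' data: sparse i.i.d. binary fingerprints for compounds and proteins, and
#' interaction labels produced by a planted sparse linear model over
#' substructure-x-domain tensor features — exactly the hypothesis class of
#' the classifier, so planted ground truth is available for recovery tests.
#' It makes no attempt at realistic chemistry (no substructure
#' co-occurrence structure or domain grammar).
#'
#' @param n_compounds,n_proteins Entity counts (defaults 100 x 80, a
#'   desk-scale analog of a screening panel).
#' @param d,d_prime Fingerprint dimensions (defaults 50 and 40).
#' @param compound_density,protein_density Per-bit activation probabilities
#'   in (0, 1); default 0.1, matching the sparsity regime of substructure /
#'   domain fingerprints.
#' @param n_planted Number of nonzero planted tensor weights (default 20).
#' @param effect_scale Magnitude of planted weights (each is
#'   `+/- effect_scale`).
#' @param label_noise Probability of flipping each label, in `[0, 0.5)`.
#' @param positive_fraction Target fraction of positive labels after noise.
#' @param seed Integer seed; the whole dataset is deterministic given the
#'   config.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_compounds = 100, n_proteins = 80,
                             d = 50, d_prime = 40,
                             compound_density = 0.1, protein_density = 0.1,
                             n_planted = 20, effect_scale = 1,
                             label_noise = 0.05, positive_fraction = 0.2,
                             seed = 1L) {
  cfg <- list(n_compounds = check_count(n_compounds, "n_compounds"),
              n_proteins = check_count(n_proteins, "n_proteins"),
              d = check_count(d, "d"), d_prime = check_count(d_prime, "d_prime"),
              compound_density = compound_density,
              protein_density = protein_density,
              n_planted = check_count(n_planted, "n_planted"),
              effect_scale = effect_scale, label_noise = label_noise,
              positive_fraction = positive_fraction, seed = as.integer(seed))
  if (compound_density <= 0 || compound_density >= 1 ||
      protein_density <= 0 || protein_density >= 1) {
    stop_validation("densities must lie in (0, 1).")
  }
  if (label_noise < 0 || label_noise >= 0.5) {
    stop_validation("`label_noise` must lie in [0, 0.5).")
  }
  if (positive_fraction <= 0 || positive_fraction >= 1) {
    stop_validation("`positive_fraction` must lie in (0, 1).")
  }
  if (cfg$n_planted > cfg$d * cfg$d_prime) {
    stop_validation("`n_planted` cannot exceed D * D'.")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic interaction dataset with planted structure
#'
#' Draws fingerprints bit-wise i.i.d., plants `n_planted` tensor weights of
#' `+/- effect_scale` at uniformly chosen substructure-x-domain features,
#' scores every compound x protein pair by the sum of planted weights on
#' its active tensor features, labels the top-scoring fraction positive,
#' and finally flips each label independently with probability
#' `label_noise`. Ties in the raw score (common, since most pairs touch no
#' planted feature) are broken by a tiny seeded uniform jitter, and the
#' pre-noise positive fraction is noise-compensated,
#' `(positive_fraction - label_noise) / (1 - 2 * label_noise)`, so the
#' realized post-noise fraction is centred on the target.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `cpi_synth`: `dataset` (an
#'   [interaction_dataset()] labeling every pair), `planted` (tibble of
#'   planted tensor features and weights), `threshold` (raw-score cut), and
#'   `config`.
#' @export
generate_synthetic_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  pf0 <- (config$positive_fraction - config$label_noise) /
    (1 - 2 * config$label_noise)
  if (pf0 <= 0 || pf0 >= 1) {
    abort("positive_fraction is unreachable at this label_noise; adjust the config.",
          class = "cpisketch_generation_error")
  }
  with_seed(config$seed, {
    draw_fp <- function(n, dim, dens, prefix) {
      fingerprint_tbl(sprintf("%s%03d", prefix, seq_len(n)),
                      lapply(seq_len(n), function(i) which(runif(dim) < dens) - 1L),
                      dimension = dim)
    }
    compounds <- draw_fp(config$n_compounds, config$d,
                         config$compound_density, "c")
    proteins <- draw_fp(config$n_proteins, config$d_prime,
                        config$protein_density, "p")
    m <- config$d * config$d_prime
    planted_idx <- sort(sample.int(m, config$n_planted) - 1)
    planted_w <- sample(c(-1, 1), config$n_planted, replace = TRUE) *
      config$effect_scale
    wmap <- numeric(m)
    wmap[planted_idx + 1] <- planted_w

    grid <- tidyr::expand_grid(compound_id = compounds$entity_id,
                               protein_id = proteins$entity_id)
    ca <- compounds$active; names(ca) <- compounds$entity_id
    pa <- proteins$active; names(pa) <- proteins$entity_id
    score <- purrr::map2_dbl(grid$compound_id, grid$protein_id, function(ci, pi) {
      s <- pair_set(ca[[ci]], pa[[pi]], config$d_prime)
      if (length(s)) sum(wmap[s + 1]) else 0
    })
    if (length(unique(score)) == 1) {
      abort(paste0("all pair scores are identical; no labeling threshold exists. ",
                   "Increase densities, n_planted or effect_scale."),
            class = "cpisketch_generation_error")
    }
    jitter <- runif(length(score)) * 1e-9
    n_pos <- max(1L, round(pf0 * length(score)))
    threshold <- sort(score + jitter, decreasing = TRUE)[n_pos]
    label <- ifelse(score + jitter >= threshold, 1L, -1L)
    if (config$label_noise > 0) {
      flip <- runif(length(label)) < config$label_noise
      label[flip] <- -label[flip]
    }
    un <- tensor_unindex(planted_idx, config$d_prime)
    structure(list(
      dataset = interaction_dataset(compounds, proteins,
                                    mutate(grid, label = label)),
      planted = tibble(tensor_index = planted_idx,
                       compound_bit = un$compound_bit,
                       protein_bit = un$protein_bit,
                       weight = planted_w),
      threshold = threshold,
      config = config
    ), class = "cpi_synth")
  })
}

#' @exportS3Method base::print
print.cpi_synth <- function(x, ...) {
  cat(sprintf("<cpi_synth: %d planted features, threshold %.3g>\n",
              nrow(x$planted), x$threshold))
  print(x$dataset)
  invisible(x)
}

#' Write / read a dataset directory
#'
#' Writes `compounds.tsv`, `proteins.tsv` and `interactions.tsv` in the
#' package's TSV dialects; `read_dataset()` reassembles the
#' [interaction_dataset()].
#'
#' @param dataset An [interaction_dataset()].
#' @param dir Directory (created if missing).
#' @param dialect Fingerprint dialect to write.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, dialect = "sparse") {
  stopifnot(inherits(dataset, "cpi_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fingerprints(dataset$compounds, file.path(dir, "compounds.tsv"), dialect)
  write_fingerprints(dataset$proteins, file.path(dir, "proteins.tsv"), dialect)
  write_interactions(dataset$pairs, file.path(dir, "interactions.tsv"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  interaction_dataset(
    read_fingerprints(file.path(dir, "compounds.tsv")),
    read_fingerprints(file.path(dir, "proteins.tsv")),
    read_interactions(file.path(dir, "interactions.tsv")))
}
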