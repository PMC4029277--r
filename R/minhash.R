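#' Define a minwise hash family
#'
#' A hash family bundles everything needed to sketch feature sets: `ell`
#' random permutations `pi_k` of the feature universe `[0, M)` and one
#' additional 2-universal hash `h` mapping minhash values into `[0, N)`.
#' The whole family is reconstructible from `(ell, m, n_bins, master_seed,
#' mode)`; per-permutation seeds are derived deterministically from the
#' master seed, so nothing of size `M` is ever stored.
#'
#' Two permutation realizations are available: `"explicit"` draws each
#' `pi_k` as a seeded uniform random permutation of `[0, M)` (exact minwise
#' theory; the default, intended for `M` up to ~2^24), and `"universal"`
#' approximates `pi_k(x) = (a_k x + b_k) mod p` with `p` the smallest prime
#' `>= M`, for universes too large to permute explicitly. Note the universal
#' mode acts on `[0, p)`, so hash values can slightly exceed `M - 1`.
#'
#' @param ell Number of permutations (sketch length).
#' @param m Universe size `M`; for pair feature sets this is `D * D'`.
#' @param n_bins Additional-hash range `N` (`N <= M`); each minhash value is
#'   folded into `[0, N)`.
#' @param master_seed Integer seed; same arguments always give the same family.
#' @param mode `"explicit"` or `"universal"` (see Details).
#' @param identity_hash If `TRUE` (requires `n_bins >= m`), the additional
#'   hash is the identity, which disables the additional-hashing stage; used
#'   for studying the raw minhash signature.
#' @return An object of class `hash_family`.
#' @export
hash_family <- function(ell, m, n_bins, master_seed = 1L,
                        mode = c("explicit", "universal"),
                        identity_hash = FALSE) {
  ell <- check_count(ell, "ell")
  m <- check_count(m, "m")
  n_bins <- check_count(n_bins, "n_bins")
  mode <- match.arg(mode)
  if (n_bins > m) stop_validation("`n_bins` must be <= `m` (N <= M).")
  if (identity_hash && n_bins < m) {
    stop_validation("identity_hash requires n_bins >= m.")
  }
  p <- next_prime(m)
  # additional hash h: seeded affine map derived from (master_seed, ell)
  h_par <- with_seed(mix_seed(master_seed, ell, stream = 2L), {
    c(a = sample.int(p - 1, 1), b = sample.int(p, 1) - 1)
  })
  fam <- structure(list(
    ell = ell, m = m, n_bins = n_bins,
    master_seed = as.integer(master_seed), mode = mode,
    identity_hash = identity_hash, p = p,
    h_a = unname(h_par["a"]), h_b = unname(h_par["b"])
  ), class = "hash_family")
  if (mode == "universal") {
    par <- with_seed(mix_seed(master_seed, 0L, stream = 3L), {
      list(a = sample.int(p - 1, ell, replace = TRUE),
           b = sample.int(p, ell, replace = TRUE) - 1)
    })
    fam$perm_a <- par$a
    fam$perm_b <- par$b
  }
  fam
}

#' @exportS3Method base::print
print.hash_family <- function(x, ...) {
  cat(sprintf(
    "<hash_family: ell = %d, M = %g, N = %g, mode = %s%s, master_seed = %d>\n",
    x$ell, x$m, x$n_bins, x$mode,
    if (x$identity_hash) ", identity h" else "", x$master_seed))
  invisible(x)
}

# k-th permutation images of [0, M), 0-based, as an integer vector
# (explicit mode only). Generated on demand from the derived seed.
family_permutation <- function(family, k) {
  stopifnot(inherits(family, "hash_family"))
  if (k < 0 || k >= family$ell) stop_validation("permutation index out of range.")
  if (family$mode != "explicit") {
    stop_validation("explicit permutations only exist in explicit mode.")
  }
  with_seed(mix_seed(family$master_seed, k, stream = 1L),
            sample.int(family$m) - 1L)
}

#' Jaccard similarity of two index sets
#'
#' @param s1,s2 Integer vectors (sets of active indices); at least one must
#'   be non-empty.
#' @return `|s1 ∩ s2| / |s1 ∪ s2|`.
#' @examples
#' jaccard(c(1, 2, 3), c(2, 3, 4))  # 0.5
#' @export
jaccard <- function(s1, s2) {
  s1 <- unique(s1); s2 <- unique(s2)
  if (!length(s1) && !length(s2)) {
    abort("Jaccard similarity of two empty sets is undefined.",
          class = "cpisketch_undefined_similarity_error")
  }
  length(intersect(s1, s2)) / length(union(s1, s2))
}

#' Minwise hash value of a set under one permutation
#'
#' `minhash_value()` evaluates `min_{x in S} pi_k(x)` for the `k`-th
#' permutation of a hash family. `minwise_min()` is the same primitive for an
#' explicitly supplied permutation written in the conventional 1-based
#' presentation: `perm[j]` is the image of element `j`, elements `1..length(perm)`.
#'
#' @param s Non-empty set of integers in `[0, M)`.
#' @param k Permutation index in `[0, ell)`.
#' @param family A [hash_family()].
#' @return The minimum permuted value.
#' @examples
#' # the permutation (1..8) -> (3,8,7,1,2,6,4,5) sends {1,4,6,7} to
#' # {3,1,6,4}, whose minimum is 1
#' minwise_min(c(1, 4, 6, 7), c(3, 8, 7, 1, 2, 6, 4, 5))
#' @export
minhash_value <- function(s, k, family) {
  s <- validate_hash_set(s, family)
  if (family$mode == "explicit") {
    min(family_permutation(family, k)[s + 1L])
  } else {
    a <- family$perm_a[k + 1L]; b <- family$perm_b[k + 1L]
    min(cpp_affine_hash(as.numeric(s), a, b, family$p))
  }
}

#' @rdname minhash_value
#' @param perm Integer vector: `perm[j]` is the image of element `j` under
#'   the permutation (1-based presentation).
#' @export
minwise_min <- function(s, perm) {
  s <- as.integer(s)
  if (!length(s)) abort("minwise hash of an empty set is undefined.",
                        class = "cpisketch_empty_set_error")
  if (min(s) < 1 || max(s) > length(perm)) {
    stop_validation("set elements must index into the permutation (1-based).")
  }
  min(perm[s])
}

validate_hash_set <- function(s, family) {
  stopifnot(inherits(family, "hash_family"))
  s <- as.integer(s)
  if (!length(s)) {
    abort("minwise hash of an empty set is undefined.",
          class = "cpisketch_empty_set_error")
  }
  if (min(s) < 0 || max(s) >= family$m) {
    stop_validation(sprintf("set elements must lie in [0, %g).", family$m))
  }
  s
}

#' Additional hashing of minhash values
#'
#' Folds a minhash value `t` into the small range `[0, N)` with the family's
#' seeded 2-universal hash `h(t) = ((a t + b) mod p) mod N`. Equal inputs
#' always collide; distinct inputs collide with probability ~ `1/N`, which
#' gives the compact-fingerprint collision law of [collision_probability()].
#'
#' @param t Integer vector of minhash values in `[0, p)` (`p` the family's
#'   prime universe size).
#' @param family A [hash_family()].
#' @return Integer vector of bins in `[0, N)`.
#' @export
additional_hash <- function(t, family) {
  stopifnot(inherits(family, "hash_family"))
  t <- as.numeric(t)
  if (any(t < 0) || any(t >= family$p)) {
    stop_validation(sprintf("hash input must lie in [0, %g).", family$p))
  }
  if (family$identity_hash) return(as.integer(t))
  as.integer(cpp_affine_hash(t, family$h_a, family$h_b, family$p) %% family$n_bins)
}

#' Collision probability of additionally hashed minhash values
#'
#' For two sets with Jaccard similarity `J`, one coordinate of their compact
#' fingerprints collides with probability `1 - ((N-1)/N) (1 - J)`: the
#' minhash values agree with probability `J`, and disagreeing values are
#' folded onto the same bin with probability `1/N`. The law is increasing in
#' `J` and tends to `J` as `N` grows, which is why small bin counts lose
#' almost nothing once `N` is a few hundred.
#'
#' @param j Jaccard similarity in `[0, 1]` (vectorized).
#' @param n_bins Additional-hash range `N >= 1`.
#' @return Collision probability in `[0, 1]`.
#' @examples
#' collision_probability(0.5, 2)   # 0.75
#' @export
collision_probability <- function(j, n_bins) {
  n_bins <- check_count(n_bins, "n_bins")
  j <- as.numeric(j)
  if (any(j < 0 | j > 1)) stop_validation("`j` must lie in [0, 1].")
  1 - ((n_bins - 1) / n_bins) * (1 - j)
}

# signatures for a list of sets: n x ell integer matrix of raw minhash values
minhash_signatures <- function(sets, family) {
  stopifnot(inherits(family, "hash_family"))
  lens <- lengths(sets)
  if (any(lens == 0)) {
    abort(sprintf("minwise hash of an empty set is undefined (set %d).",
                  which(lens == 0)[1]),
          class = "cpisketch_empty_set_error")
  }
  flat <- as.integer(unlist(sets, use.names = FALSE))
  if (length(flat) && (min(flat) < 0 || max(flat) >= family$m)) {
    stop_validation(sprintf("set elements must lie in [0, %g).", family$m))
  }
  sig <- matrix(0L, nrow = length(sets), ncol = family$ell)
  for (k in seq_len(family$ell) - 1L) {
    sig[, k + 1L] <- if (family$mode == "explicit") {
      cpp_min_permuted(flat, as.integer(lens), family_permutation(family, k))
    } else {
      cpp_min_affine(flat, as.integer(lens),
                     family$perm_a[k + 1L], family$perm_b[k + 1L], family$p)
    }
  }
  sig
}

#' Compact fingerprint of one feature set
#'
#' Sketches a pair feature set into `ell` bins: `bins[k] = h(min pi_k(S))`.
#' The equivalent dense form is an `ell * N` binary vector with exactly one
#' 1 in each consecutive block of `N` ([compact_dense()]).
#'
#' @param s Non-empty set of integers in `[0, M)`.
#' @param family A [hash_family()].
#' @return Integer vector of length `ell` with values in `[0, N)`.
#' @export
compact_fingerprint <- function(s, family) {
  s <- validate_hash_set(s, family)
  additional_hash(minhash_signatures(list(s), family)[1, ], family)
}

#' @rdname compact_fingerprint
#' @param bins Length-`ell` integer vector of bins.
#' @return `compact_dense()`: the `ell * N` 0/1 expansion.
#' @export
compact_dense <- function(bins, family) {
  stopifnot(inherits(family, "hash_family"), length(bins) == family$ell)
  v <- integer(family$ell * family$n_bins)
  v[(seq_len(family$ell) - 1L) * family$n_bins + as.integer(bins) + 1L] <- 1L
  v
}

#' Encode pair feature sets as compact fingerprints
#'
#' @param features A pair table with a `features` list-column, as produced by
#'   [pair_features()].
#' @param family A [hash_family()] whose universe `M` equals the dataset's
#'   `D * D'`.
#' @param skip_empty Empty feature sets (all-zero compound or protein
#'   fingerprints) cannot be sketched. With `skip_empty = FALSE` (default)
#'   they raise an error naming the offending pair; with `TRUE` they are
#'   dropped with a warning.
#' @return `features` with the `features` column replaced by a `bins`
#'   list-column of length-`ell` integer vectors.
#' @export
compact_encode <- function(features, family, skip_empty = FALSE) {
  stopifnot(inherits(family, "hash_family"))
  features <- as_tibble(features)
  if (!"features" %in% names(features)) {
    stop_validation("`features` must carry a `features` list-column; see pair_features().")
  }
  empty <- lengths(features$features) == 0
  if (any(empty)) {
    who <- features[empty, c("compound_id", "protein_id")]
    if (!skip_empty) {
      abort(sprintf(
        "pair (%s, %s) has an empty feature set; use skip_empty = TRUE to drop such pairs.",
        who$compound_id[1], who$protein_id[1]),
        class = "cpisketch_empty_set_error",
        compound_id = who$compound_id[1], protein_id = who$protein_id[1])
    }
    warn(sprintf("dropping %d pair(s) with empty feature sets.", sum(empty)))
    features <- features[!empty, , drop = FALSE]
  }
  sig <- minhash_signatures(features$features, family)
  bins <- additional_hash(as.vector(sig), family)
  dim(bins) <- dim(sig)
  out <- features
  out$features <- NULL
  out$bins <- lapply(seq_len(nrow(sig)), function(i) bins[i, ])
  out
}

#' Sparse design matrix of compact fingerprints
#'
#' Expands encoded bins into the sparse `n x (ell * N)` 0/1 matrix whose row
#' `i` is the dense compact fingerprint of pair `i` (column `k*N + bins[k]`).
#'
#' @param encoded Output of [compact_encode()].
#' @param family The encoding [hash_family()].
#' @return A `Matrix::sparseMatrix` (dgCMatrix).
#' @export
compact_matrix <- function(encoded, family) {
  stopifnot(inherits(family, "hash_family"))
  width <- family$ell * family$n_bins
  if (width >= .Machine$integer.max) {
    stop_validation("ell * N exceeds the representable matrix width.")
  }
  n <- nrow(encoded)
  ell <- family$ell
  cols <- unlist(lapply(encoded$bins, function(b) {
    (seq_len(ell) - 1) * family$n_bins + b + 1
  }), use.names = FALSE)
  rows <- rep(seq_len(n), each = ell)
  Matrix::sparseMatrix(i = rows, j = cols, x = 1, dims = c(n, width))
}

# ---- serialization ---------------------------------------------------------

family_fields <- function(family) {
  list(ell = family$ell, m = family$m, n_bins = family$n_bins,
       master_seed = family$master_seed, mode = family$mode,
       identity_hash = family$identity_hash)
}

family_from_fields <- function(fields) {
  hash_family(ell = fields$ell, m = fields$m, n_bins = fields$n_bins,
              master_seed = fields$master_seed, mode = fields$mode,
              identity_hash = isTRUE(fields$identity_hash))
}

#' Write / read encoded compact fingerprints
#'
#' Writes a TSV `compound_id<TAB>protein_id<TAB>label<TAB>b_0,...,b_{ell-1}`
#' plus a JSON sidecar `<path>.family.json` holding the five defining fields
#' of the hash family (never the raw permutations).
#'
#' @param encoded Output of [compact_encode()].
#' @param family The encoding [hash_family()].
#' @param path Output TSV path.
#' @return `path`, invisibly (`read_encoded()` returns a list with elements
#'   `encoded` and `family`).
#' @export
write_encoded <- function(encoded, family, path) {
  bins <- vapply(encoded$bins, function(b) paste(b, collapse = ","), character(1))
  label <- if ("label" %in% names(encoded)) encoded$label else rep(0L, nrow(encoded))
  writeLines(c("#compact", paste(encoded$compound_id, encoded$protein_id,
                                 label, bins, sep = "\t")), path)
  jsonlite::write_json(family_fields(family), paste0(path, ".family.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_encoded
#' @export
read_encoded <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "#compact") {
    abort(sprintf("%s: expected '#compact' header line.", path),
          class = "cpisketch_parse_error")
  }
  family <- family_from_fields(
    jsonlite::read_json(paste0(path, ".family.json"), simplifyVector = TRUE))
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  encoded <- tibble(
    compound_id = vapply(parts, `[`, character(1), 1),
    protein_id = vapply(parts, `[`, character(1), 2),
    label = as.integer(vapply(parts, `[`, character(1), 3)),
    bins = lapply(parts, function(p) as.integer(strsplit(p[4], ",")[[1]]))
  )
  list(encoded = encoded, family = family)
}
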