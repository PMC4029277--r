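#' Build a fingerprint table
#'
#' A fingerprint table holds one binary fingerprint per entity (compound or
#' protein): a declared dimension `D` and, per entity, the sorted set of
#' active bit indices in `[0, D)`. Compound fingerprints typically mark
#' chemical substructures (e.g. the 881 PubChem substructure keys) and
#' protein fingerprints mark domain annotations (e.g. PFAM domains).
#'
#' @param id Character vector of unique entity ids.
#' @param active List of integer vectors; element `i` holds the active bit
#'   indices (0-based) of entity `i`. Indices are sorted and deduplicated.
#' @param dimension Single positive integer, the fingerprint length.
#' @return A tibble of class `cpi_fp` with columns `entity_id` and `active`
#'   (list-column), carrying `dimension` as an attribute.
#' @examples
#' fingerprint_tbl(c("c1", "c2"), list(c(0L, 2L), 1L), dimension = 3)
#' @export
fingerprint_tbl <- function(id, active, dimension) {
  dimension <- check_count(dimension, "dimension")
  if (length(id) != length(active)) {
    stop_validation("`id` and `active` must have the same length.")
  }
  if (anyDuplicated(id)) {
    stop_validation(sprintf("duplicate entity id: '%s'",
                            id[duplicated(id)][1]))
  }
  active <- lapply(active, function(a) {
    a <- sort(unique(as.integer(a)))
    if (length(a) && (min(a) < 0 || max(a) >= dimension)) {
      stop_validation(sprintf(
        "active index %d outside [0, %d)", a[a < 0 | a >= dimension][1],
        dimension))
    }
    a
  })
  out <- tibble(entity_id = as.character(id), active = active)
  attr(out, "dimension") <- dimension
  class(out) <- c("cpi_fp", class(out))
  out
}

#' @exportS3Method base::print
print.cpi_fp <- function(x, ...) {
  cat(sprintf("<fingerprint table: %d entities, dimension %d>\n",
              nrow(x), fp_dimension(x)))
  NextMethod()
}

#' Fingerprint dimension
#' @param x A fingerprint table from [fingerprint_tbl()].
#' @return The declared dimension.
#' @export
fp_dimension <- function(x) {
  d <- attr(x, "dimension")
  if (is.null(d)) stop_validation("not a fingerprint table: no dimension attribute.")
  d
}

# ---- file I/O --------------------------------------------------------------
# Format: two header lines `#dimension=<int>` and `#dialect=<bitstring|sparse>`
# followed by `id<TAB>payload` rows. bitstring payload is a 0/1 string of
# length `dimension`; sparse payload is a comma-separated list of active
# 0-based indices (empty string for an all-zero fingerprint).

#' Read a fingerprint table from TSV
#'
#' @param path File path.
#' @param dialect `"bitstring"`, `"sparse"`, or `NULL` to take the dialect
#'   declared in the file header.
#' @return A [fingerprint_tbl()].
#' @export
read_fingerprints <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) < 2 || !grepl("^#dimension=", lines[1]) ||
      !grepl("^#dialect=", lines[2])) {
    abort(sprintf("%s: expected '#dimension=' and '#dialect=' header lines.",
                  path), class = "cpisketch_parse_error")
  }
  dimension <- suppressWarnings(as.integer(sub("^#dimension=", "", lines[1])))
  if (is.na(dimension) || dimension < 1) {
    abort(sprintf("%s:1: bad dimension header.", path),
          class = "cpisketch_parse_error")
  }
  file_dialect <- sub("^#dialect=", "", lines[2])
  dialect <- dialect %||% file_dialect
  dialect <- match.arg(dialect, c("bitstring", "sparse"))
  body <- lines[-(1:2)]
  body_no <- seq_along(body) + 2L
  keep <- nzchar(body)
  body <- body[keep]; body_no <- body_no[keep]

  ids <- character(length(body))
  active <- vector("list", length(body))
  for (i in seq_along(body)) {
    parts <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (!length(parts) %in% c(1L, 2L) || !nzchar(parts[1])) {
      abort(sprintf("%s:%d: malformed row (expected id<TAB>payload).",
                    path, body_no[i]), class = "cpisketch_parse_error")
    }
    ids[i] <- parts[1]
    payload <- if (length(parts) == 2L) parts[2] else ""
    if (dialect == "bitstring") {
      if (!grepl("^[01]*$", payload) || nchar(payload) != dimension) {
        abort(sprintf(
          "%s:%d: bitstring payload must be a 0/1 string of length %d.",
          path, body_no[i], dimension), class = "cpisketch_parse_error")
      }
      active[[i]] <- which(strsplit(payload, "", fixed = TRUE)[[1]] == "1") - 1L
    } else {
      if (payload == "") {
        active[[i]] <- integer(0)
      } else {
        if (!grepl("^[0-9]+(,[0-9]+)*$", payload)) {
          abort(sprintf("%s:%d: sparse payload must be comma-separated integers.",
                        path, body_no[i]), class = "cpisketch_parse_error")
        }
        active[[i]] <- as.integer(strsplit(payload, ",", fixed = TRUE)[[1]])
      }
    }
  }
  out <- fingerprint_tbl(ids, active, dimension)
  attr(out, "dialect") <- dialect
  out
}

#' Write a fingerprint table to TSV
#'
#' @param x A [fingerprint_tbl()].
#' @param path Output path.
#' @param dialect Output dialect; defaults to the dialect the table was read
#'   with, else `"sparse"`.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(x, path, dialect = NULL) {
  dialect <- dialect %||% attr(x, "dialect") %||% "sparse"
  dialect <- match.arg(dialect, c("bitstring", "sparse"))
  dimension <- fp_dimension(x)
  payload <- if (dialect == "bitstring") {
    vapply(x$active, function(a) {
      bits <- rep("0", dimension)
      bits[a + 1L] <- "1"
      paste(bits, collapse = "")
    }, character(1))
  } else {
    vapply(x$active, function(a) paste(a, collapse = ","), character(1))
  }
  lines <- c(sprintf("#dimension=%d", as.integer(dimension)),
             sprintf("#dialect=%s", dialect),
             paste(x$entity_id, payload, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write an interaction table
#'
#' Interaction tables are TSV files with a `#interactions` header line and
#' rows `compound_id<TAB>protein_id<TAB>label`, label in `{1, -1}`.
#'
#' @param path File path.
#' @return A tibble with columns `compound_id`, `protein_id`, `label`.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "#interactions") {
    abort(sprintf("%s: expected '#interactions' header line.", path),
          class = "cpisketch_parse_error")
  }
  body <- lines[-1]
  body_no <- seq_along(body) + 1L
  keep <- nzchar(body)
  body <- body[keep]; body_no <- body_no[keep]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    abort(sprintf("%s:%d: malformed row (expected 3 tab-separated fields).",
                  path, body_no[bad[1]]), class = "cpisketch_parse_error")
  }
  label <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 3)))
  bad <- which(is.na(label) | !label %in% c(1L, -1L))
  if (length(bad)) {
    abort(sprintf("%s:%d: label must be 1 or -1.", path, body_no[bad[1]]),
          class = "cpisketch_parse_error")
  }
  tibble(compound_id = vapply(parts, `[`, character(1), 1),
         protein_id = vapply(parts, `[`, character(1), 2),
         label = label)
}

#' @rdname read_interactions
#' @param pairs A tibble with columns `compound_id`, `protein_id`, `label`.
#' @export
write_interactions <- function(pairs, path) {
  stopifnot(all(c("compound_id", "protein_id", "label") %in% names(pairs)))
  writeLines(c("#interactions",
               paste(pairs$compound_id, pairs$protein_id, pairs$label,
                     sep = "\t")),
             path)
  invisible(path)
}

# ---- tensor-product features ----------------------------------------------

#' Tensor-product feature indexing
#'
#' A compound-protein pair is described by the tensor product of the two
#' fingerprints: bit `(c, p)` of the pair feature space is active iff
#' compound bit `c` and protein bit `p` are both active. Features are laid
#' out compound-major, so the flat index is `c * D' + p` with `D'` the
#' protein fingerprint dimension. All indices are 0-based.
#'
#' @param c,p Integer vectors of compound / protein bit indices.
#' @param i Integer vector of flat tensor feature indices.
#' @param d_prime Protein fingerprint dimension `D'`.
#' @return `tensor_index()` returns flat indices; `tensor_unindex()` returns
#'   a tibble with columns `compound_bit` and `protein_bit`.
#' @examples
#' tensor_index(2, 1, d_prime = 3)      # 7
#' tensor_unindex(7, d_prime = 3)
#' @export
tensor_index <- function(c, p, d_prime) {
  d_prime <- check_count(d_prime, "d_prime")
  c <- as.numeric(c); p <- as.numeric(p)
  if (any(c < 0) || any(p < 0)) stop_validation("bit indices must be >= 0.")
  if (any(p >= d_prime)) {
    stop_validation(sprintf("protein bit index %g >= d_prime = %g.",
                            p[p >= d_prime][1], d_prime))
  }
  c * d_prime + p
}

#' @rdname tensor_index
#' @export
tensor_unindex <- function(i, d_prime) {
  d_prime <- check_count(d_prime, "d_prime")
  i <- as.numeric(i)
  if (any(i < 0)) stop_validation("tensor index must be >= 0.")
  tibble(compound_bit = i %/% d_prime, protein_bit = i %% d_prime)
}

#' Tensor-product feature set of one compound-protein pair
#'
#' Computes the active feature set `S(C, P)` of the pair fingerprint without
#' ever materializing the dense `D * D'` vector: the set of flat indices
#' `c * D' + p` over all active compound bits `c` and protein bits `p`.
#'
#' @param compound_active,protein_active Integer vectors of active bits.
#' @param d_prime Protein fingerprint dimension.
#' @return Sorted numeric vector of active tensor feature indices.
#' @examples
#' pair_set(c(0, 2), 1, d_prime = 3)  # 1, 7
#' @export
pair_set <- function(compound_active, protein_active, d_prime) {
  d_prime <- check_count(d_prime, "d_prime")
  if (!length(compound_active) || !length(protein_active)) return(numeric(0))
  sort(as.vector(outer(as.numeric(compound_active) * d_prime,
                       as.numeric(protein_active), `+`)))
}

# ---- interaction dataset ---------------------------------------------------

#' Assemble a labeled interaction dataset
#'
#' Bundles compound fingerprints, protein fingerprints and a labeled pair
#' table, validating the cross-references.
#'
#' @param compounds,proteins Fingerprint tables ([fingerprint_tbl()]).
#' @param pairs Tibble with columns `compound_id`, `protein_id`,
#'   `label` in `{1, -1}`.
#' @return A list of class `cpi_dataset` with elements `compounds`,
#'   `proteins`, `pairs`.
#' @export
interaction_dataset <- function(compounds, proteins, pairs) {
  stopifnot(inherits(compounds, "cpi_fp"), inherits(proteins, "cpi_fp"))
  pairs <- as_tibble(pairs)
  if (!all(c("compound_id", "protein_id", "label") %in% names(pairs))) {
    stop_validation("`pairs` needs columns compound_id, protein_id, label.")
  }
  if (!all(pairs$label %in% c(1L, -1L))) {
    stop_validation("pair labels must be 1 or -1.")
  }
  miss_c <- setdiff(pairs$compound_id, compounds$entity_id)
  if (length(miss_c)) {
    stop_validation(sprintf("pair references unknown compound '%s'.", miss_c[1]))
  }
  miss_p <- setdiff(pairs$protein_id, proteins$entity_id)
  if (length(miss_p)) {
    stop_validation(sprintf("pair references unknown protein '%s'.", miss_p[1]))
  }
  key <- paste(pairs$compound_id, pairs$protein_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- pairs[duplicated(key), , drop = FALSE]
    stop_validation(sprintf("duplicate pair (%s, %s).",
                            dup$compound_id[1], dup$protein_id[1]))
  }
  structure(list(compounds = compounds, proteins = proteins,
                 pairs = mutate(pairs, label = as.integer(label))),
            class = "cpi_dataset")
}

#' @exportS3Method base::print
print.cpi_dataset <- function(x, ...) {
  cat(sprintf(paste0(
    "<cpi_dataset: %d compounds (D = %d), %d proteins (D' = %d), ",
    "%d labeled pairs (%d positive)>\n"),
    nrow(x$compounds), fp_dimension(x$compounds),
    nrow(x$proteins), fp_dimension(x$proteins),
    nrow(x$pairs), sum(x$pairs$label == 1)))
  invisible(x)
}

#' Tensor-product feature sets for every pair of a dataset
#'
#' @param dataset A [interaction_dataset()].
#' @return The dataset's pair table with an added list-column `features`
#'   holding each pair's active tensor feature indices.
#' @export
pair_features <- function(dataset) {
  stopifnot(inherits(dataset, "cpi_dataset"))
  d_prime <- fp_dimension(dataset$proteins)
  ca <- dataset$compounds$active
  names(ca) <- dataset$compounds$entity_id
  pa <- dataset$proteins$active
  names(pa) <- dataset$proteins$entity_id
  feats <- purrr::map2(dataset$pairs$compound_id, dataset$pairs$protein_id,
                       function(ci, pi) pair_set(ca[[ci]], pa[[pi]], d_prime))
  mutate(dataset$pairs, features = feats)
}

#' Total tensor feature dimension of a dataset
#' @param dataset A [interaction_dataset()].
#' @return `D * D'`.
#' @export
tensor_dimension <- function(dataset) {
  fp_dimension(dataset$compounds) * fp_dimension(dataset$proteins)
}
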