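test_that("hash families are deterministic and explicit permutations are bijections", {
  f1 <- hash_family(5, 8, 4, master_seed = 9)
  f2 <- hash_family(5, 8, 4, master_seed = 9)
  for (k in 0:4) {
    p1 <- cpisketch:::family_permutation(f1, k)
    expect_identical(p1, cpisketch:::family_permutation(f2, k))
    expect_identical(sort(p1), 0:7)
  }
  f3 <- hash_family(5, 8, 4, master_seed = 10)
  expect_false(identical(cpisketch:::family_permutation(f1, 0),
                         cpisketch:::family_permutation(f3, 0)))
  expect_error(hash_family(5, 8, 9), class = "cpisketch_validation_error")
  expect_error(hash_family(0, 8, 4), class = "cpisketch_validation_error")
})

test_that("minwise hash values are minima of permuted sets", {
  # the printed worked example: (1..8) -> (3,8,7,1,2,6,4,5) sends {1,4,6,7}
  # to {3,1,6,4}, minimum 1
  expect_equal(minwise_min(c(1, 4, 6, 7), c(3, 8, 7, 1, 2, 6, 4, 5)), 1)
  expect_equal(minwise_min(c(5, 2, 9), 1:10), 2)        # identity permutation
  perm <- sample(1:20)
  expect_equal(minwise_min(5, perm), perm[5])           # singleton
  expect_error(minwise_min(integer(0), 1:4), class = "cpisketch_empty_set_error")

  fam <- hash_family(3, 16, 16, master_seed = 2)
  s <- c(1L, 5L, 9L)
  for (k in 0:2) {
    expect_equal(minhash_value(s, k, fam),
                 min(cpisketch:::family_permutation(fam, k)[s + 1]))
  }
  expect_error(minhash_value(integer(0), 0, fam),
               class = "cpisketch_empty_set_error")
})

test_that("jaccard similarity matches its set definition", {
  expect_equal(jaccard(c(3, 9), c(3, 9)), 1)
  expect_equal(jaccard(c(1, 2), c(3, 4)), 0)
  expect_equal(jaccard(1:3, 2:4), 0.5)
  expect_equal(jaccard(1:3, integer(0)), 0)
  expect_error(jaccard(integer(0), integer(0)),
               class = "cpisketch_undefined_similarity_error")
})

test_that("signature collision rates estimate Jaccard similarity", {
  set.seed(31)
  s1 <- sort(sample(0:15, 7)); s2 <- sort(sample(0:15, 9))
  j <- oracle_jaccard(s1, s2)
  fam <- hash_family(2000, 16, 16, master_seed = 4, identity_hash = TRUE)
  sig <- cpisketch:::minhash_signatures(list(s1, s2), fam)
  frac <- mean(sig[1, ] == sig[2, ])
  se <- sqrt(j * (1 - j) / 2000)
  expect_lt(abs(frac - j), 3 * se)

  # expected Hamming distance of raw signatures is ell * (1 - J)
  ham <- sum(sig[1, ] != sig[2, ])
  expect_lt(abs(ham - 2000 * (1 - j)), 3 * sqrt(2000 * j * (1 - j)))
})

test_that("additional hashing folds values consistently and uniformly", {
  fam <- hash_family(1, 2^20, 16, master_seed = 5)
  t <- c(0, 17, 2^19)
  expect_identical(additional_hash(t, fam), additional_hash(t, fam))
  expect_true(all(additional_hash(t, fam) >= 0 &
                  additional_hash(t, fam) < 16))
  expect_error(additional_hash(-1, fam), class = "cpisketch_validation_error")

  # identity configuration: N = M disables the folding
  fid <- hash_family(1, 64, 64, master_seed = 5, identity_hash = TRUE)
  expect_identical(additional_hash(0:63, fid), 0:63)

  # distinct random inputs collide with probability ~ 1/N
  set.seed(6)
  a <- sample(0:(2^20 - 1), 1e5); b <- sample(0:(2^20 - 1), 1e5)
  keep <- a != b
  frac <- mean(additional_hash(a[keep], fam) == additional_hash(b[keep], fam))
  p <- 1 / 16
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / sum(keep)))
})

test_that("the collision law is correct and saturates toward Jaccard", {
  expect_equal(collision_probability(1, 7), 1)
  expect_equal(collision_probability(0, 16), 1 / 16)
  expect_equal(collision_probability(0.5, 2), 0.75)
  expect_error(collision_probability(1.2, 4), class = "cpisketch_validation_error")

  j <- seq(0, 1, by = 0.1)
  # monotone in J, and saturated well before N = 2^16
  expect_true(all(diff(collision_probability(j, 64)) > 0))
  expect_true(all(abs(collision_probability(j, 2^16) -
                      collision_probability(j, 2^32)) < 1e-4))
  expect_true(all(abs(collision_probability(j, 2^32) - j) < 1e-4))
})

test_that("compact fingerprints expand to one-hot blocks and obey the collision law", {
  fam <- hash_family(2, 16, 4, master_seed = 3)
  dense <- compact_dense(c(2L, 0L), fam)
  expect_identical(dense, c(0L, 0L, 1L, 0L, 1L, 0L, 0L, 0L))

  # degenerate h: bins equal raw minhash values
  fid <- hash_family(1, 32, 32, master_seed = 8, identity_hash = TRUE)
  s <- c(3L, 19L, 30L)
  expect_equal(compact_fingerprint(s, fid)[1], minhash_value(s, 0, fid))

  # Monte-Carlo check of the collision law at J = 0.6
  s1 <- 0:39; s2 <- 10:49
  j <- oracle_jaccard(s1, s2)
  expect_equal(j, 0.6)
  fam2 <- hash_family(5000, 64, 8, master_seed = 12)
  enc <- cpisketch:::minhash_signatures(list(s1, s2), fam2)
  bins <- matrix(additional_hash(as.vector(enc), fam2), nrow = 2)
  frac <- mean(bins[1, ] == bins[2, ])
  p <- collision_probability(j, 8)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 5000))
})

test_that("encoding keeps ids, errors on empty sets, and round trips with its family", {
  comp <- fingerprint_tbl(c("c1", "c2"), list(c(0L, 2L), integer(0)), 3)
  prot <- fingerprint_tbl("p1", list(1L), 4)
  ds <- interaction_dataset(comp, prot,
    tibble::tibble(compound_id = c("c1", "c2"), protein_id = "p1",
                   label = c(1L, -1L)))
  feats <- pair_features(ds)
  fam <- hash_family(6, 12, 4, master_seed = 1)

  err <- expect_error(compact_encode(feats, fam),
                      class = "cpisketch_empty_set_error")
  expect_match(conditionMessage(err), "c2")
  expect_warning(enc <- compact_encode(feats, fam, skip_empty = TRUE),
                 "dropping 1")
  expect_equal(nrow(enc), 1)
  expect_length(enc$bins[[1]], 6)

  # file round trip, family reconstructed from its five fields
  dir <- withr::local_tempdir()
  path <- file.path(dir, "enc.tsv")
  suppressWarnings(write_encoded(enc, fam, path))
  back <- read_encoded(path)
  expect_identical(back$encoded$bins, enc$bins)
  expect_identical(
    cpisketch:::family_permutation(back$family, 2),
    cpisketch:::family_permutation(fam, 2))

  # the design matrix has exactly ell ones per row, one per block
  x <- compact_matrix(enc, fam)
  expect_equal(dim(x), c(1, 24))
  expect_equal(Matrix::rowSums(x), 6, ignore_attr = TRUE)
})

test_that("universal-hash mode approximates explicit-permutation sketching", {
  set.seed(19)
  sets <- replicate(40, sort(sample(0:499, sample(5:30, 1))), simplify = FALSE)
  fam_u <- hash_family(400, 500, 64, master_seed = 3, mode = "universal")
  sig <- cpisketch:::minhash_signatures(sets, fam_u)
  # estimated Jaccard from signature agreement tracks the exact value
  est <- ex <- numeric(0)
  for (i in 1:10) {
    a <- sets[[2 * i - 1]]; b <- sets[[2 * i]]
    sa <- sig[2 * i - 1, ]; sb <- sig[2 * i, ]
    est <- c(est, mean(sa == sb)); ex <- c(ex, oracle_jaccard(a, b))
  }
  expect_gt(cor(est, ex, method = "spearman"), 0.7)
  expect_lt(max(abs(est - ex)), 0.15)
})
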