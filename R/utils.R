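# Internal helpers shared across modules.

stop_validation <- function(msg, ..., class = character()) {
  abort(msg, class = c(class, "cpisketch_validation_error"), ...)
}

check_count <- function(x, name, min = 1) {
  if (length(x) != 1 || is.na(x) || !is.numeric(x) || x != floor(x) || x < min) {
    stop_validation(sprintf("`%s` must be a single integer >= %d, got %s.",
                            name, min, deparse(substitute(x))))
  }
  as.numeric(x)
}

# Deterministic 31-bit seed derived from a master seed, an index and a stream
# id. All intermediate products stay below 2^53 so the arithmetic is exact in
# doubles and identical across platforms.
mix_seed <- function(master, k, stream = 1L) {
  m <- as.numeric(master) %% 2147483647
  s <- (m * 48271 + as.numeric(k) * 69621 + as.numeric(stream) * 8253729 + 1) %% 2147483647
  as.integer(s)
}

# Smallest prime >= n by trial division; n is at most a few tens of millions
# here, so this is instantaneous.
next_prime <- function(n) {
  n <- max(2, ceiling(n))
  is_prime <- function(x) {
    if (x < 4) return(x >= 2)
    if (x %% 2 == 0) return(FALSE)
    d <- 3
    while (d * d <= x) {
      if (x %% d == 0) return(FALSE)
      d <- d + 2
    }
    TRUE
  }
  while (!is_prime(n)) n <- n + 1
  n
}

with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}
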