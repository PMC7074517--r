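# Internal helpers: seed plumbing and input checks.

# Derive a reproducible child seed from a master seed and one or more
# stream indices. Lehmer-style mixing keeps everything inside the 32-bit
# signed range so set.seed() never overflows.
derive_seed <- function(master, ...) {
  m <- 2147483647
  x <- as.double(master %% m)
  for (k in c(...)) {
    x <- (x * 48271 + as.double(k) * 16807 + 12345) %% m
  }
  as.integer(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_input <- function(...) stop(..., call. = FALSE)

check_binary_labels <- function(y, require_both = TRUE) {
  if (!all(y %in% c(0, 1))) {
    stop_input("class labels must be coded 0 (control) / 1 (case)")
  }
  if (require_both && length(unique(y)) < 2L) {
    stop_input("both classes must be present")
  }
  invisible(as.numeric(y))
}

# Stratified fold assignment: within each class, fold ids 1..k are tiled
# and shuffled, so class proportions are as even as arithmetic allows.
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < 1L) next
    ids <- rep_len(seq_len(k), length(idx))
    folds[idx] <- sample(ids)
  }
  folds
}

# Polynomial rolling hash of a string, used to stamp resolved configs in
# reports so a regenerated report can be checked against its inputs.
config_digest <- function(txt) {
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
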