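## Internal helpers: seeded substreams and integer allocation.

# Deterministic 31-adic string hash folded into [0, 2^31 - 2].
.hash_string <- function(name) {
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% 2147483647
  h
}

# Derive a reproducible substream seed from a master seed and a stream name,
# so that e.g. fraction draws and contact draws consume independent streams.
.substream_seed <- function(master, name) {
  as.integer((as.numeric(master) * 48271 + .hash_string(name)) %% 2147483647)
}

# Evaluate `expr` under the named substream without disturbing the caller's
# RNG state.
.with_substream <- function(master, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.substream_seed(master, name))
  expr
}

# Largest-remainder apportionment: integer counts n_i with sum(n_i) = total
# and n_i as close to fractions * total as possible. Fraction vectors whose
# sum deviates from 1 by the 3-decimal rounding slack are apportioned on
# their normalised proportions so the total stays exact.
.largest_remainder <- function(fractions, total) {
  stopifnot(total >= 0, all(fractions >= 0))
  if (sum(fractions) > 0) fractions <- fractions / sum(fractions)
  raw <- fractions * total
  base <- floor(raw)
  rem <- raw - base
  short <- as.integer(round(total - sum(base)))
  if (short > 0) {
    idx <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[idx] <- base[idx] + 1
  } else if (short < 0) {
    eligible <- which(base > 0)
    idx <- eligible[order(rem[eligible])][seq_len(-short)]
    base[idx] <- base[idx] - 1
  }
  as.integer(base)
}

# Short hex digest of a character vector, for config digests in logs.
.digest_string <- function(x) {
  sprintf("%08x", .hash_string(paste(x, collapse = "\n")))
}

.log_stage <- function(stage, ..., verbose = TRUE) {
  if (isTRUE(verbose))
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                    paste(..., collapse = " ")))
  invisible(NULL)
}
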