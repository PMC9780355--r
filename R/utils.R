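# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Derive a vector of independent child seeds from one parent seed without
# disturbing the caller's RNG state.  Child seeds stay below 2^31 - 1.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1].", name),
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d.", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

# Largest-remainder apportionment: integer counts summing exactly to `total`,
# proportional to nonnegative `weights`.  Ties in remainder broken by position.
largest_remainder <- function(weights, total) {
  stopifnot(all(weights >= 0), sum(weights) > 0)
  quota <- weights / sum(weights) * total
  base <- floor(quota)
  short <- total - sum(base)
  if (short > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
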