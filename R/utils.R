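# Internal helpers shared across modules.

SIGN_LEVELS <- c("activating", "inhibiting", "unknown")

# Locale-independent lexicographic sort (C collation via radix).
sort_lex <- function(x) sort(x, method = "radix")

order_lex <- function(x) order(x, method = "radix")

# Numeric encoding of signs for product-of-signs propagation:
# activating = 1, inhibiting = -1, unknown = 0.
sign_to_num <- function(s) {
  out <- integer(length(s))
  out[s == "activating"] <- 1L
  out[s == "inhibiting"] <- -1L
  out
}

num_to_sign <- function(v) {
  s <- rep("unknown", length(v))
  s[v == 1L] <- "activating"
  s[v == -1L] <- "inhibiting"
  s
}

# Derive a reproducible sub-seed from a master seed and a salt; kept within
# the 32-bit signed integer range R requires of set.seed().
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  salt_num <- if (is.character(salt)) {
    sum(as.integer(charToRaw(salt)) * seq_along(charToRaw(salt)))
  } else {
    as.numeric(salt)
  }
  as.integer((abs(seed) * 7919 + salt_num * 104729 + 13) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
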