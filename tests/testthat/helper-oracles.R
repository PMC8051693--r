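# Independent oracles used across tests. These deliberately share no code
# with the package implementations they check.

# Naive reproduce-or-extend LZ76 parser on a binary string: grow the
# current phrase while it can be copied from the prior history (substring
# search); a final incomplete phrase counts as a word.
naive_lz76 <- function(s) {
  if (!is.character(s)) s <- paste(as.integer(s), collapse = "")
  n <- nchar(s)
  c_words <- 0L
  l <- 1L
  while (l <= n) {
    j <- l
    repeat {
      phrase <- substr(s, l, j)
      history <- substr(s, 1L, j - 1L)
      if (j > n || !grepl(phrase, history, fixed = TRUE)) break
      j <- j + 1L
    }
    # phrase s[l..j] is new (or we ran off the end while still copyable)
    c_words <- c_words + 1L
    l <- j + 1L
  }
  c_words
}

# Brute-force symbolic transfer entropy: explicit probability tables over
# the full alphabet, plug-in TE in bits.
brute_te <- function(x_sym, y_sym, delta, alphabet_size) {
  m <- length(y_sym)
  yf <- y_sym[(1 + delta):m]
  yp <- y_sym[1:(m - delta)]
  xp <- x_sym[1:(m - delta)]
  n <- length(yf)
  A <- alphabet_size
  p3 <- array(0, dim = c(A, A, A))
  for (t in seq_len(n)) {
    p3[yf[t] + 1L, yp[t] + 1L, xp[t] + 1L] <-
      p3[yf[t] + 1L, yp[t] + 1L, xp[t] + 1L] + 1
  }
  p3 <- p3 / n
  te <- 0
  for (a in 1:A) for (b in 1:A) for (cc in 1:A) {
    pabc <- p3[a, b, cc]
    if (pabc == 0) next
    p_bc <- sum(p3[, b, cc])
    p_ab <- sum(p3[a, b, ])
    p_b <- sum(p3[, b, ])
    te <- te + pabc * log2((pabc / p_bc) / (p_ab / p_b))
  }
  te
}

# All binary strings of a given length, as integer vectors.
all_binary_strings <- function(len) {
  lapply(0:(2^len - 1L), function(v) {
    as.integer(intToBits(v))[seq_len(len)]
  })
}

# Small deterministic test hypnogram builders.
hyp <- function(...) hypnogram(c(...))
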