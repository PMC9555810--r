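# Independent brute-force oracles, kept deliberately naive and separate
# from the package's lookup/vectorised code paths.

# Rule-based classification: one pair at a time, written from the category
# definitions rather than as a table lookup. Codes: 1 like ... 5 dislike.
oracle_classify <- function(f, d) {
  if (f == 1 && d == 1) return("Q")
  if (f == 5 && d == 5) return("Q")
  if (f == 1 && d == 5) return("O")
  if (f == 1) return("A") # likes provision, tolerates absence
  if (f == 5) return("R") # dislikes provision
  if (d == 5) return("M") # tolerates provision, dislikes absence
  if (d == 1) return("R") # prefers absence
  "I"
}

# One-pair-at-a-time recount of a long response table.
oracle_counts <- function(long) {
  out <- list()
  for (k in sort(unique(long$attribute_id))) {
    sub <- long[long$attribute_id == k, ]
    tally <- c(m = 0L, o = 0L, a = 0L, i = 0L, q = 0L, r = 0L)
    for (j in seq_len(nrow(sub))) {
      cc <- tolower(oracle_classify(sub$functional[j], sub$dysfunctional[j]))
      tally[cc] <- tally[cc] + 1L
    }
    out[[length(out) + 1]] <- c(attribute_id = k, tally, n = nrow(sub))
  }
  as.data.frame(do.call(rbind, out))
}

# Naive mid-rank Mann-Whitney Z with tie-corrected variance, written
# independently of the package implementation.
oracle_rank_sum_z <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  w <- sum(r[seq_along(x)])
  e <- length(x) * (n + 1) / 2
  tie_sizes <- as.numeric(table(pooled))
  v <- length(x) * length(y) / 12 * ((n + 1) - sum(tie_sizes^3 - tie_sizes) / (n * (n - 1)))
  (w - e) / sqrt(v)
}

# Random valid per-attribute count vector with total n.
random_counts <- function(n_total, n_attr = 1) {
  rows <- t(replicate(n_attr, as.integer(stats::rmultinom(1, n_total, prob = runif(6)))))
  out <- as.data.frame(rows)
  names(out) <- c("m", "o", "a", "i", "q", "r")
  out$attribute_id <- seq_len(n_attr)
  out
}
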