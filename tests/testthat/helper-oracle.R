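# Independent reference implementations used to define correctness of the
# production code paths.  They are deliberately naive and share no code with
# the package internals.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_seq <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Brute-force positional scores under identity similarity: enumerate every
# (window start i, shift h) pair with both windows fully in bounds, score it
# by direct residue comparison, and give each covered position the running
# maximum.  Positions covered by no window score 0.
oracle_positional_scores <- function(q, k, F) {
  qc <- strsplit(q, "")[[1]]
  kc <- strsplit(k, "")[[1]]
  m <- length(qc)
  n <- length(kc)
  S <- rep(-Inf, m)
  if (m >= F && n >= F) {
    for (i in 1:(m - F + 1)) {
      for (h in (1 - i):(n - F + 1 - i)) {
        rate <- sum(qc[i:(i + F - 1)] == kc[(i + h):(i + h + F - 1)])
        span <- i:(i + F - 1)
        S[span] <- pmax(S[span], rate)
      }
    }
  }
  S[!is.finite(S)] <- 0
  S
}

# Pairwise-count AUC: fraction of (positive, negative) pairs ranked
# concordantly, ties counted one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Small deterministic dataset: one class of near-identical sequences vs. a
# dissimilar complement, for directional checks of the full chain.
toy_dataset <- function() {
  base <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  seqs <- c(
    A1 = base,
    A2 = sub("T", "S", base),       # one substitution from A1
    A3 = sub("Q", "N", base),       # one substitution from A1
    B1 = random_seq(33),
    B2 = random_seq(33),
    B3 = random_seq(33))
  member <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L), ncol = 1,
                   dimnames = list(names(seqs), "L1"))
  list(sequences = seqs, interactions = interaction_table(member))
}
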