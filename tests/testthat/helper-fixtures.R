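# Small builders and independent oracles shared across tests.

sig_ab <- function(na = 3, nb = 3) {
  signature_set(list(A = paste0("a", seq_len(na)),
                     B = paste0("b", seq_len(nb))))
}

sig_abc <- function(sizes = c(4, 4, 4)) {
  signature_set(list(A = paste0("a", seq_len(sizes[1])),
                     B = paste0("b", seq_len(sizes[2])),
                     C = paste0("c", seq_len(sizes[3]))))
}

# brute-force classical Hebb rule: explicit double loop over Eq. terms
hebb_classic_oracle <- function(patterns) {
  patterns <- as.matrix(patterns)
  N <- nrow(patterns)
  W <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    W[i, j] <- sum(patterns[i, ] * patterns[j, ]) / N
  }
  W
}

# brute-force modified Hebb rule, term by term
hebb_modified_oracle <- function(bank) {
  N <- bank$N
  p <- bank$p
  W <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    W[i, j] <- (p / (2 * N)) *
      (sum(bank$templates[i, ] * bank$templates[j, ]) + 2 - p)
  }
  W
}

# brute-force energy: explicit double sum
energy_oracle <- function(W, x) {
  e <- 0
  for (i in seq_along(x)) for (j in seq_along(x))
    e <- e - 0.5 * W[i, j] * x[i] * x[j]
  unname(e)
}

# random disjoint signature layout for property loops
random_layout <- function(p, max_size = 8) {
  sizes <- sample(2:max_size, p, replace = TRUE)
  genes <- lapply(seq_len(p), function(k)
    sprintf("cl%d_g%d", k, seq_len(sizes[k])))
  names(genes) <- paste0("K", seq_len(p))
  signature_set(genes)
}
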