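# Independent brute-force oracles and small fixture builders shared by
# the test files.  These deliberately avoid the package's vectorized
# code paths: pooling enumerates covering windows one by one, AUC counts
# positive/negative pairs, entropy recounts subwords with a set.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_sequence <- function(L) paste(sample(AA20, L, replace = TRUE),
                                     collapse = "")

# direct two-stage computation: explicit window loop, then for every
# residue an explicit scan over all windows that cover it
brute_pool <- function(vals, N) {
  L <- length(vals)
  N0 <- floor(N / 2)
  padded <- c(rep(0, N0), vals, rep(0, N0))
  W <- length(padded) - N + 1
  v <- vapply(seq_len(W), function(i) mean(padded[i:(i + N - 1)]),
              numeric(1))
  vapply(seq_len(L), function(j) {
    pj <- j + N0                      # padded position of residue j
    covering <- Filter(function(i) pj >= i && pj <= i + N - 1, seq_len(W))
    mean(v[unlist(covering)])
  }, numeric(1))
}

# tie-aware Mann-Whitney pair statistic
mw_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (p in sp) tot <- tot + sum(p > sn) + 0.5 * sum(p == sn)
  tot / (length(sp) * length(sn))
}

# entropy of a single window by explicit subword-set enumeration
brute_window_entropy <- function(window_letters, A = 20) {
  N <- length(window_letters)
  n <- 1
  while (A^(n + 1) + n <= N) n <- n + 1
  if (A^n + n - 1 > N) n <- 1
  m <- min(A^n + n - 1, N)
  grams <- character(0)
  for (s in seq_len(m - n + 1))
    grams <- c(grams, paste(window_letters[s:(s + n - 1)], collapse = ""))
  log(length(unique(grams)), base = A) / n
}

# minimal toy scale over the 20 letters
toy_scale <- function(values, name = "toy") {
  structure(list(name = name,
                 values = stats::setNames(values, AA20)),
            class = "ScaleTable")
}

write_tmp_fasta <- function(text) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(text, path)
  path
}

# small labelled dataset + both branch feature stacks, for model tests
tiny_pipeline_data <- function(n = 6, delta = 2, seed = 11) {
  d <- make_dataset(fixture_config(n_sequences = n,
                                   length_range = c(120L, 160L),
                                   delta = delta, seed = seed))
  p1 <- featurize_records(d$records, "properties")
  p2 <- featurize_records(d$records, "profile", pssms = d$pssms)
  list(data = d, p1 = p1, p2 = p2,
       labels = unlist(lapply(d$records, `[[`, "labels")))
}
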