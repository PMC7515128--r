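# Per-residue feature extraction.
#
# Both feature branches share one pipeline: pad the per-position track
# with floor(N/2) zeros on each side, average within every length-N
# window, then assign each residue the mean of all window values whose
# window covers it.  Window i covers padded positions i..i+N-1 for
# i = 1..L0-N+1 (L0 = L + 2*floor(N/2)); residue j sits at padded
# position j + N0, so the windows covering it are
# i in [j+N0-N+1, j+N0], clamped to the valid window range.  The clamped
# range reproduces the interior case (exactly N windows) and both edge
# cases in a single formula.

#' Window configuration for feature pooling
#'
#' @param sizes ordered integer window lengths; default \code{c(10, 45, 90)}
#'   (a short window resolving the MoRF itself plus two longer windows
#'   capturing its disordered surroundings).
#' @param logistic_pssm if \code{TRUE}, squash raw PSSM log-odds through
#'   1/(1+exp(-x)) before averaging (off by default; raw averaging is the
#'   reference behaviour).
#' @param entropy_alphabet alphabet size A used by the topological entropy
#'   normalization (default 20).
#' @return object of class \code{WindowConfig}.
#' @export
window_config <- function(sizes = c(10L, 45L, 90L), logistic_pssm = FALSE,
                          entropy_alphabet = 20L) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 1L || any(sizes < 2L))
    abort2("window sizes must be integers >= 2", "morfmlp_config_error")
  structure(list(sizes = sizes, logistic_pssm = isTRUE(logistic_pssm),
                 entropy_alphabet = as.integer(entropy_alphabet)),
            class = "WindowConfig")
}

#' Pad a per-position track for windowing
#'
#' Appends \code{floor(N/2)} pad elements to both ends: 0 for numeric
#' tracks, the pad symbol \code{"-"} for residue-letter tracks.
#'
#' @param values numeric vector or character vector of single letters.
#' @param N window size.
#' @return padded vector of length \code{length(values) + 2*floor(N/2)}.
#' @export
pad <- function(values, N) {
  N0 <- floor(N / 2)
  if (is.character(values)) c(rep(PAD_CHAR, N0), values, rep(PAD_CHAR, N0))
  else c(rep(0, N0), as.numeric(values), rep(0, N0))
}

# residue letters -> scale values; X gets the scale mean, pads 0
scale_lookup <- function(scale) {
  v <- scale$values
  c(v, X = mean(v))
}

#' Per-window scale averages
#'
#' Pads the sequence's scale-value track with zeros and returns the mean
#' scale value of every length-N window over the padded track,
#' \code{v[i] = mean(padded[i..i+N-1])}, i = 1..L0-N+1.
#'
#' @param record a \code{SequenceRecord}.
#' @param scale a \code{ScaleTable}.
#' @param N window size.
#' @return numeric vector of window values.
#' @export
window_scale_values <- function(record, scale, N) {
  res <- strsplit(record$residues, "")[[1]]
  vals <- unname(scale_lookup(scale)[res])
  rolling_mean(pad(vals, N), N)
}

rolling_mean <- function(xp, N) {
  W <- length(xp) - N + 1L
  cs <- c(0, cumsum(xp))
  (cs[(N + 1L):(length(xp) + 1L)] - cs[seq_len(W)]) / N
}

#' Per-window topological entropy
#'
#' For each length-N window over the padded letter track the complexity
#' value is \code{log_A(#distinct n-subwords in the first m letters) / n}
#' where n is the largest integer >= 1 with \code{A^n + n - 1 <= N}
#' (clamped to n = 1 when no such integer exists, i.e. N < A) and
#' \code{m = min(A^n + n - 1, N)}.  With the default A = 20 and windows
#' 10/45/90 this always resolves to n = 1: the normalized count of
#' distinct letters among the first m window positions.  Pad characters
#' (and X) count as symbols distinct from the 20 residue letters, so
#' terminal windows are not artificially low-complexity.
#'
#' @param record a \code{SequenceRecord}.
#' @param N window size.
#' @param alphabet_size normalizing alphabet size A.
#' @return numeric vector of window entropy values in
#'   \code{[0, log_A(m - n + 1)/n]}.
#' @export
window_entropy_values <- function(record, N, alphabet_size = 20L) {
  A <- as.integer(alphabet_size)
  n <- 1L
  while (A^(n + 1L) + n <= N) n <- n + 1L     # largest n: A^n + n - 1 <= N
  if (A^n + n - 1L > N) n <- 1L               # clamp for short windows
  m <- min(A^n + n - 1L, N)
  letters_ <- pad(strsplit(record$residues, "")[[1]], N)
  W <- length(letters_) - N + 1L
  padded <- paste(letters_, collapse = "")
  starts <- seq_len(m - n + 1L)
  vapply(seq_len(W), function(i) {
    head_ <- substr(padded, i, i + m - 1L)
    grams <- substring(head_, starts, starts + n - 1L)
    log(length(unique(grams)), base = A) / n
  }, numeric(1))
}

#' Pool per-window values onto residues
#'
#' Residue j receives the mean of all window values whose window covers
#' it: \code{x[j] = mean(v[i])} for
#' \code{i in [max(1, j+N0-N+1), min(j+N0, W)]}, \code{N0 = floor(N/2)},
#' \code{W = L0-N+1}.  Interior residues average exactly N windows; edge
#' residues average the (fewer) windows that exist.
#'
#' @param v per-window values from \code{\link{window_scale_values}} or
#'   \code{\link{window_entropy_values}}.
#' @param L sequence length.
#' @param N window size.
#' @return numeric vector of length L.
#' @export
pool_to_residues <- function(v, L, N) {
  N0 <- floor(N / 2)
  W <- L + 2L * N0 - N + 1L
  if (length(v) != W)
    abort2(sprintf("expected %d window values, got %d", W, length(v)),
           "morfmlp_config_error")
  j <- seq_len(L)
  lo <- pmax(1L, j + N0 - N + 1L)
  hi <- pmin(j + N0, W)
  cs <- c(0, cumsum(v))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

warn_short <- function(record, sizes) {
  L <- nchar(record$residues)
  if (any(sizes >= L))
    warning(sprintf(
      "sequence '%s' (L=%d) is not longer than window size %d; pooling remains defined but windows are pad-dominated",
      record$id, L, max(sizes)), call. = FALSE)
}

#' Sequence-property feature matrix (branch "properties")
#'
#' For each window size: 16 per-window tracks -- topological entropy
#' first, then the 15 property scales in their file order -- each pooled
#' onto residues.  Columns are grouped by window size (all 16 properties
#' at the first size, then the second, ...), giving D = 16 x n_sizes
#' columns (48 at the defaults).
#'
#' @param record a \code{SequenceRecord}.
#' @param scales list of exactly 15 \code{ScaleTable}s
#'   (default \code{\link{default_scales}()}).
#' @param config a \code{\link{window_config}}.
#' @return object of class \code{FeatureMatrix}: \code{sequence_id},
#'   \code{values} (L x D), \code{column_names} ("property@N"),
#'   \code{branch = "properties"}.
#' @export
property_features <- function(record, scales = default_scales(),
                              config = window_config()) {
  if (length(scales) != 15L)
    abort2(sprintf("need exactly 15 property scales (plus entropy), got %d",
                   length(scales)), "morfmlp_config_error")
  warn_short(record, config$sizes)
  L <- nchar(record$residues)
  blocks <- lapply(config$sizes, function(N) {
    tracks <- c(list(entropy = window_entropy_values(
      record, N, config$entropy_alphabet)),
      setNames(lapply(scales, window_scale_values, record = record, N = N),
               vapply(scales, `[[`, character(1), "name")))
    cols <- vapply(tracks, pool_to_residues, numeric(L), L = L, N = N)
    if (is.null(dim(cols))) cols <- matrix(cols, nrow = 1L)  # L = 1
    colnames(cols) <- paste0(names(tracks), "@", N)
    cols
  })
  values <- do.call(cbind, blocks)
  new_feature_matrix(record$id, values, "properties")
}

#' Evolutionary-profile feature matrix (branch "profile")
#'
#' For each window size: each of the 20 PSSM rows is zero-padded,
#' averaged per window and pooled onto residues, giving D = 20 x n_sizes
#' columns (60 at the defaults).  Rows follow the PSI-BLAST column order.
#'
#' @param record a \code{SequenceRecord}.
#' @param pssm the paired \code{PSSMProfile}.
#' @param config a \code{\link{window_config}}.
#' @return a \code{FeatureMatrix} with \code{branch = "profile"}.
#' @export
profile_features <- function(record, pssm, config = window_config()) {
  L <- nchar(record$residues)
  if (!identical(pssm$sequence_id, record$id))
    abort2(sprintf("PSSM is for '%s', record is '%s'", pssm$sequence_id,
                   record$id), "morfmlp_alignment_error")
  if (ncol(pssm$matrix) != L)
    abort2(sprintf("PSSM has %d columns for %d residues of '%s'",
                   ncol(pssm$matrix), L, record$id),
           "morfmlp_alignment_error")
  warn_short(record, config$sizes)
  mat <- pssm$matrix
  if (config$logistic_pssm) mat <- 1 / (1 + exp(-mat))
  blocks <- lapply(config$sizes, function(N) {
    cols <- vapply(seq_len(20L), function(r)
      pool_to_residues(rolling_mean(pad(mat[r, ], N), N), L, N),
      numeric(L))
    if (is.null(dim(cols))) cols <- matrix(cols, nrow = 1L)  # L = 1
    colnames(cols) <- paste0(PSSM_AA_ORDER, "@", N)
    cols
  })
  values <- do.call(cbind, blocks)
  new_feature_matrix(record$id, values, "profile")
}

new_feature_matrix <- function(sequence_id, values, branch) {
  if (any(!is.finite(values)))
    abort2(sprintf("non-finite feature value for '%s'", sequence_id),
           "morfmlp_config_error")
  structure(list(sequence_id = sequence_id, values = values,
                 column_names = colnames(values), branch = branch),
            class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix '%s' [%s]: %d residues x %d features\n",
              x$sequence_id, x$branch, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Stack per-sequence feature matrices for training
#'
#' @param records list of \code{SequenceRecord} (labels optional).
#' @param branch "properties" or "profile".
#' @param scales scale list (properties branch).
#' @param pssms named list of \code{PSSMProfile}, keyed by sequence id
#'   (profile branch).
#' @param config a \code{\link{window_config}}.
#' @return list with \code{features} (sum(L) x D matrix), \code{labels}
#'   (or NULL), \code{index} data.frame (sequence_id, position).
#' @export
featurize_records <- function(records, branch = c("properties", "profile"),
                              scales = default_scales(), pssms = NULL,
                              config = window_config()) {
  branch <- match.arg(branch)
  mats <- lapply(records, function(rec) {
    if (branch == "properties") property_features(rec, scales, config)
    else {
      p <- pssms[[rec$id]]
      if (is.null(p))
        abort2(sprintf("no PSSM provided for sequence '%s'", rec$id),
               "morfmlp_config_error")
      profile_features(rec, p, config)
    }
  })
  features <- do.call(rbind, lapply(mats, `[[`, "values"))
  labs <- lapply(records, `[[`, "labels")
  labels <- if (any(vapply(labs, is.null, logical(1)))) NULL
            else unlist(labs, use.names = FALSE)
  index <- data.frame(
    sequence_id = rep(vapply(records, `[[`, character(1), "id"),
                      vapply(records, function(r) nchar(r$residues),
                             integer(1))),
    position = unlist(lapply(records,
                             function(r) seq_len(nchar(r$residues)))),
    stringsAsFactors = FALSE)
  list(features = features, labels = labels, index = index)
}
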