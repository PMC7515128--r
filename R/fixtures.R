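# Synthetic fixtures: sequences with planted MoRF intervals, matching
# region annotations and PSSM files, with a tunable effect size so the
# full train -> fuse -> evaluate loop runs with zero downloads.
#
# The planted signal acts through both branches: MoRF residues are drawn
# from a composition tilted toward a designated letter set (moving the
# scale averages and lowering windowed letter diversity), and PSSM
# columns inside MoRFs receive a +delta shift on the rows of those same
# letters, on top of independent integer-rounded Gaussian noise.  At
# delta = 0 MoRF and background residues are exchangeable, so trained
# models must score at chance.

#' Fixture generator configuration
#'
#' @param n_sequences number of sequences (default 50).
#' @param length_range inclusive range of sequence lengths (default
#'   250-350, i.e. roughly 300-residue chains).
#' @param morf_length_range inclusive MoRF interval length range
#'   (default 10-70).
#' @param n_morf_range inclusive range of MoRF intervals per sequence
#'   (default 0-2).
#' @param background length-20 composition over the alphabetically
#'   ordered amino acids (default uniform).
#' @param delta effect size: composition tilt exp(delta) on the MoRF
#'   letter set and +delta PSSM shift on the matching rows (default 2,
#'   a strong planted signal; 0 = pure null).
#' @param pssm_noise sd of the integer-rounded Gaussian PSSM noise
#'   (default 2, PSI-BLAST log-odds magnitude).
#' @param morf_letters letters enriched inside MoRFs (default the
#'   hydrophobic/aromatic set ILVFWYM, which separates on most
#'   physicochemical scales).
#' @param seed RNG seed; the generator is fully seed-reproducible.
#' @return object of class \code{FixtureConfig}.
#' @export
fixture_config <- function(n_sequences = 50L, length_range = c(250L, 350L),
                           morf_length_range = c(10L, 70L),
                           n_morf_range = c(0L, 2L),
                           background = rep(1 / 20, 20L), delta = 2,
                           pssm_noise = 2,
                           morf_letters = c("I", "L", "V", "F", "W", "Y", "M"),
                           seed = 1L) {
  length_range <- as.integer(length_range)
  morf_length_range <- as.integer(morf_length_range)
  if (delta < 0)
    abort2("delta must be >= 0", "morfmlp_config_error")
  if (morf_length_range[1L] > length_range[1L])
    abort2("minimum MoRF length exceeds minimum sequence length",
           "morfmlp_config_error")
  if (length(background) != 20L || any(background < 0) ||
      sum(background) <= 0)
    abort2("background must be 20 nonnegative weights",
           "morfmlp_config_error")
  structure(list(n_sequences = as.integer(n_sequences),
                 length_range = length_range,
                 morf_length_range = morf_length_range,
                 n_morf_range = as.integer(n_morf_range),
                 background = background / sum(background),
                 delta = as.numeric(delta),
                 pssm_noise = as.numeric(pssm_noise),
                 morf_letters = toupper(morf_letters),
                 seed = as.integer(seed)),
            class = "FixtureConfig")
}

# Non-overlapping interval placement by rejection; intervals never
# touch so distinct regions stay distinct in the annotation file.
#
# Starts are sampled with terminus overhang (the interval is then
# truncated to the chain, keeping at least min_inside residues): with
# interior-only starts, residues near the termini would be covered by
# fewer candidate placements, making "distance from terminus" — which
# the window features expose through their pads — informative about the
# labels even at delta = 0.  Overhang placement keeps MoRF coverage
# position-uniform so the zero-effect world is a genuine null.
place_intervals <- function(L, lens, max_tries = 500L, min_inside = 10L) {
  taken <- integer(0)
  out <- list()
  for (len in lens) {
    if (len > L)
      abort2(sprintf("cannot place interval of length %d in sequence of length %d",
                     len, L), "morfmlp_config_error")
    keep <- min(len, min_inside)
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      s <- sample.int(L - keep + len - keep + 1L, 1L) - (len - keep)
      lo <- max(1L, s)
      hi <- min(L, s + len - 1L)
      pad_span <- max(1L, lo - 1L):min(L, hi + 1L)
      if (!any(pad_span %in% taken)) {
        taken <- c(taken, lo:hi)
        out[[length(out) + 1L]] <- c(lo, hi)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      abort2(sprintf("infeasible interval packing (lengths %s in L=%d)",
                     paste(lens, collapse = ","), L),
             "morfmlp_config_error")
  }
  out
}

#' Generate a synthetic MoRF dataset
#'
#' @param config a \code{\link{fixture_config}}.
#' @param dir optional output directory; when given, writes
#'   \code{sequences.fasta}, \code{regions.tsv} and one PSI-BLAST-dialect
#'   PSSM file per sequence under \code{pssm/}.
#' @return (invisibly when writing) list with \code{records} (labelled
#'   \code{SequenceRecord}s), \code{regions} (data.frame),
#'   \code{pssms} (named list of \code{PSSMProfile}), and \code{paths}
#'   when \code{dir} was given.
#' @export
make_dataset <- function(config = fixture_config(), dir = NULL) {
  set.seed(config$seed)
  bg <- config$background
  tilt <- bg * exp(config$delta * (AA_ALPHABET %in% config$morf_letters))
  tilt <- tilt / sum(tilt)
  pssm_rows <- which(PSSM_AA_ORDER %in% config$morf_letters)

  records <- vector("list", config$n_sequences)
  regions <- list()
  pssms <- list()
  for (i in seq_len(config$n_sequences)) {
    id <- sprintf("syn%03d", i)
    L <- sample(config$length_range[1L]:config$length_range[2L], 1L)
    k <- sample(config$n_morf_range[1L]:config$n_morf_range[2L], 1L)
    lens <- if (k > 0L)
      sample(config$morf_length_range[1L]:config$morf_length_range[2L], k,
             replace = TRUE) else integer(0)
    ivs <- place_intervals(L, lens)
    lab <- integer(L)
    for (iv in ivs) lab[iv[1L]:iv[2L]] <- 1L
    res <- character(L)
    res[lab == 0L] <- sample(AA_ALPHABET, sum(lab == 0L), replace = TRUE,
                             prob = bg)
    if (any(lab == 1L))
      res[lab == 1L] <- sample(AA_ALPHABET, sum(lab == 1L), replace = TRUE,
                               prob = tilt)
    rec <- sequence_record(id, paste(res, collapse = ""), labels = lab)
    records[[i]] <- rec
    for (iv in ivs)
      regions[[length(regions) + 1L]] <-
        data.frame(sequence_id = id, start = iv[1L], end = iv[2L],
                   stringsAsFactors = FALSE)
    shift <- outer(seq_len(20L) %in% pssm_rows, lab == 1L) * config$delta
    mat <- matrix(round(rnorm(20L * L, sd = config$pssm_noise) + shift),
                  nrow = 20L, dimnames = list(PSSM_AA_ORDER, NULL))
    mat <- pmin(pmax(mat, -10), 12)
    pssms[[id]] <- structure(list(sequence_id = id, matrix = mat,
                                  query = rec$residues),
                             class = "PSSMProfile")
  }
  regions <- if (length(regions) > 0L) do.call(rbind, regions)
             else data.frame(sequence_id = character(0), start = integer(0),
                             end = integer(0), stringsAsFactors = FALSE)
  out <- list(records = records, regions = regions, pssms = pssms)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "pssm"), recursive = TRUE,
               showWarnings = FALSE)
    fasta <- file.path(dir, "sequences.fasta")
    regf <- file.path(dir, "regions.tsv")
    write_fasta(records, fasta)
    write_regions(regions, regf)
    for (id in names(pssms))
      write_pssm(pssms[[id]], file.path(dir, "pssm", paste0(id, ".pssm")))
    out$paths <- list(fasta = fasta, regions = regf,
                      pssm_dir = file.path(dir, "pssm"))
    return(invisible(out))
  }
  out
}

#' Fixed worked examples with independently derived expected values
#'
#' Small frozen instances used across the unit tests, each paired with
#' its expected output derived outside the production code path:
#' \itemize{
#'   \item \code{pooling}: sequence "ACD" with scale A=1, C=2, D=3 and
#'     N = 2.  Padded values (0,1,2,3,0) give window means
#'     (0.5, 1.5, 2.5, 1.5); enumerating the windows covering each
#'     residue by hand gives x = (1, 2, 2).
#'   \item \code{forward}: a 2-2-2-1 network computed by scalar
#'     arithmetic.  x=(1,-1); z1 = (1*1+0*(-1)+0.5, 0*1+1*(-1)-0.5)
#'     = (1.5,-1.5), relu -> (1.5, 0); z2 = (1.5+0, 1.5*1+0*(-1)+0.25)
#'     = (1.5, 1.75), relu unchanged; z3 = 0.2*1.5 - 0.4*1.75 + 0.1
#'     = -0.3; sigmoid(-0.3) = 1/(1+e^0.3) = 0.42555748318834102.
#'   \item \code{roc}: scores (.9,.8,.7,.6,.4,.2), labels (1,0,1,1,0,0).
#'     Exhaustive threshold enumeration gives the operating points
#'     (fpr,tpr) = (0,0),(0,1/3),(1/3,1/3),(1/3,2/3),(1/3,1),(2/3,1),
#'     (1,1); pair counting gives AUC = 7/9; smallest FPR with
#'     TPR >= (0.2, 0.3, 0.4) is (0, 0, 1/3).
#' }
#'
#' @return nested list of inputs and frozen expected outputs.
#' @export
make_worked_example <- function() {
  list(
    pooling = list(
      record = sequence_record("wk_pool", "ACD"),
      scale = structure(list(name = "toy",
                             values = setNames(c(1, 2, 3, rep(0, 17)),
                                               AA_ALPHABET)),
                        class = "ScaleTable"),
      N = 2L,
      expected_windows = c(0.5, 1.5, 2.5, 1.5),
      expected_pooled = c(1, 2, 2)),
    forward = list(
      params = list(W1 = matrix(c(1, 0, 0, 1), 2, 2),
                    b1 = c(0.5, -0.5),
                    W2 = matrix(c(1, 0, 1, -1), 2, 2),
                    b2 = c(0, 0.25),
                    W3 = matrix(c(0.2, -0.4), 2, 1),
                    b3 = 0.1),
      input = matrix(c(1, -1), 1, 2),
      expected_score = 0.42555748318834102),
    roc = list(
      scores = c(0.9, 0.8, 0.7, 0.6, 0.4, 0.2),
      labels = c(1L, 0L, 1L, 1L, 0L, 0L),
      expected_fpr = c(0, 0, 1 / 3, 1 / 3, 1 / 3, 2 / 3, 1),
      expected_tpr = c(0, 1 / 3, 1 / 3, 2 / 3, 1, 1, 1),
      expected_auc = 7 / 9,
      expected_fpr_at_tpr = c(0, 0, 1 / 3)))
}
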