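# Readers and writers for every external format the tool touches:
# FASTA, PSI-BLAST ascii PSSM, amino-acid scale tables, MoRF region
# annotations, per-residue prediction tracks and serialized models.
#
# Coordinates are 1-based inclusive in all files; internal label vectors
# are plain per-residue vectors so no half-open bookkeeping leaks out.

#' Construct a sequence record
#'
#' A \code{SequenceRecord} couples a sequence identifier with a residue
#' string over the 20-letter amino-acid alphabet and, optionally, a
#' per-residue binary MoRF label vector.
#'
#' Residues are canonicalized: lower case is raised, the ambiguity codes
#' B, Z, U and O are mapped to D, E, C and K respectively, and any other
#' non-standard letter (including X) becomes \code{"X"} with a warning.
#' \code{"X"} is retained as its own symbol so sequence length -- and hence
#' label alignment -- is never altered; downstream feature code assigns it
#' the mean scale value and a zero profile contribution.
#'
#' @param id sequence identifier (non-empty string).
#' @param residues residue string, length >= 1.
#' @param labels optional integer/logical vector, one entry per residue,
#'   1 = MoRF residue.
#' @return an object of class \code{SequenceRecord} with fields
#'   \code{id}, \code{residues}, \code{labels}.
#' @export
sequence_record <- function(id, residues, labels = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    abort2("sequence id must be a non-empty string", "morfmlp_format_error")
  residues <- canonicalize_residues(residues, id = id)
  L <- nchar(residues)
  if (L < 1L)
    abort2(sprintf("sequence '%s' is empty", id), "morfmlp_format_error")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != L)
      abort2(sprintf("sequence '%s': %d labels for %d residues",
                     id, length(labels), L), "morfmlp_format_error")
    if (!all(labels %in% c(0L, 1L)))
      abort2(sprintf("sequence '%s': labels must be 0/1", id),
             "morfmlp_format_error")
  }
  structure(list(id = id, residues = residues, labels = labels),
            class = "SequenceRecord")
}

#' @export
print.SequenceRecord <- function(x, ...) {
  cat(sprintf("SequenceRecord '%s': %d residues%s\n", x$id,
              nchar(x$residues),
              if (is.null(x$labels)) "" else
                sprintf(", %d MoRF-labelled", sum(x$labels))))
  invisible(x)
}

# B/Z/U/O have unambiguous stand-ins; everything else non-standard -> X.
canonicalize_residues <- function(residues, id = "?") {
  if (!is.character(residues) || length(residues) != 1L)
    abort2("residues must be a single string", "morfmlp_format_error")
  residues <- toupper(gsub("[[:space:]*]", "", residues))
  residues <- chartr("BZUO", "DECK", residues)
  bad <- setdiff(strsplit(residues, "")[[1]], c(AA_ALPHABET, "X"))
  if (length(bad) > 0L) {
    warning(sprintf("sequence '%s': non-standard residue(s) %s mapped to X",
                    id, paste(unique(bad), collapse = ",")),
            call. = FALSE)
    residues <- chartr(paste(unique(bad), collapse = ""),
                       strrep("X", length(unique(bad))), residues)
  }
  if (grepl("X", residues, fixed = TRUE) && length(bad) == 0L)
    warning(sprintf("sequence '%s' contains X residues", id), call. = FALSE)
  residues
}

#' Read a multi-record FASTA file
#'
#' @param path path to a FASTA file.
#' @return list of \code{\link{sequence_record}} objects in file order.
#'   Record ids are the first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    abort2(sprintf("FASTA file not found: %s", path), "morfmlp_format_error")
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    abort2(sprintf("cannot parse FASTA %s: %s", path,
                                   conditionMessage(e)),
                           "morfmlp_format_error"))
  if (length(set) == 0L)
    abort2(sprintf("not a FASTA file (no records): %s", path),
           "morfmlp_format_error")
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    abort2(sprintf("duplicate sequence id '%s' in %s",
                   ids[duplicated(ids)][1L], path), "morfmlp_format_error")
  seqs <- as.character(set)
  if (any(!nzchar(seqs)))
    abort2(sprintf("FASTA record without sequence in %s", path),
           "morfmlp_format_error")
  unname(Map(sequence_record, ids, seqs))
}

#' Write sequence records to FASTA
#'
#' @param records list of \code{SequenceRecord}.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    writeLines(paste0(">", rec$id), con)
    L <- nchar(rec$residues)
    starts <- seq(1L, L, by = width)
    writeLines(substring(rec$residues, starts, pmin(starts + width - 1L, L)),
               con)
  }
  invisible(path)
}

#' Read a PSI-BLAST ascii PSSM
#'
#' Parses the dialect produced by \code{psiblast -out_ascii_pssm}: header
#' lines, then one row per sequence position holding the position index,
#' the query residue, 20 integer log-odds scores, 20 percentage columns
#' and two trailing reals.  Only the 20 log-odds columns are used; they
#' are returned transposed to a 20 x L matrix whose rows follow the
#' PSI-BLAST amino-acid column order (ARNDCQEGHILKMFPSTWYV).
#'
#' @param path path to the PSSM file.
#' @param record the paired \code{SequenceRecord}; the file's residue
#'   column must match \code{record$residues} position by position
#'   (\code{X} on either side matches anything).
#' @return object of class \code{PSSMProfile}: fields \code{sequence_id},
#'   \code{matrix} (20 x L), \code{query}.
#' @export
read_pssm <- function(path, record) {
  if (!file.exists(path))
    abort2(sprintf("PSSM file not found: %s", path), "morfmlp_format_error")
  lines <- readLines(path, warn = FALSE)
  rows <- grep("^\\s*[0-9]+\\s+[A-Za-z]", lines, value = TRUE)
  if (length(rows) == 0L)
    abort2(sprintf("no PSSM rows found in %s (truncated or wrong format?)",
                   path), "morfmlp_format_error")
  toks <- strsplit(trimws(rows), "\\s+")
  nt <- lengths(toks)
  # 2 leading fields + 20 log-odds; percentages and information columns
  # may be absent in trimmed fixtures but scores must be complete
  if (any(nt < 22L))
    abort2(sprintf("truncated PSSM row (position %s) in %s",
                   toks[[which(nt < 22L)[1L]]][1L], path),
           "morfmlp_format_error")
  L <- nchar(record$residues)
  if (length(rows) != L)
    abort2(sprintf(
      "PSSM/sequence length mismatch for '%s': %d rows vs %d residues",
      record$id, length(rows), L), "morfmlp_alignment_error")
  qres <- toupper(vapply(toks, `[`, character(1), 2L))
  sres <- strsplit(record$residues, "")[[1]]
  mism <- which(qres != sres & qres != "X" & sres != "X")
  if (length(mism) > 0L)
    abort2(sprintf(
      "PSSM residue mismatch for '%s' at position %d: file has %s, sequence has %s",
      record$id, mism[1L], qres[mism[1L]], sres[mism[1L]]),
      "morfmlp_alignment_error")
  scores <- vapply(toks, function(tk) as.numeric(tk[3:22]), numeric(20L))
  if (any(!is.finite(scores)))
    abort2(sprintf("non-numeric PSSM score in %s", path),
           "morfmlp_format_error")
  mat <- matrix(scores, nrow = 20L, dimnames = list(PSSM_AA_ORDER, NULL))
  structure(list(sequence_id = record$id, matrix = mat,
                 query = record$residues),
            class = "PSSMProfile")
}

#' Write a PSSM profile in PSI-BLAST ascii dialect
#'
#' Fixture-side inverse of \code{\link{read_pssm}}: emits the header, the
#' two-row column banner, one row per position with the 20 log-odds
#' scores, 20 zero percentage columns and two zero trailing reals.
#'
#' @param pssm a \code{PSSMProfile}.
#' @param path output path.
#' @export
write_pssm <- function(pssm, path) {
  mat <- pssm$matrix
  L <- ncol(mat)
  res <- strsplit(pssm$query, "")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
               paste0("           ",
                      paste(sprintf("%3s", rep(PSSM_AA_ORDER, 2L)),
                            collapse = " "))), con)
  for (j in seq_len(L)) {
    writeLines(paste0(sprintf("%5d %s ", j, res[j]),
                      paste(sprintf("%3d", as.integer(round(mat[, j]))),
                            collapse = " "),
                      " ",
                      paste(sprintf("%3d", rep(0L, 20L)), collapse = " "),
                      sprintf("  %4.2f %8.2f", 0, 0)), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Read amino-acid scale tables
#'
#' The scale flat file holds one scale per block: a name line starting
#' with \code{>} (first token = scale name, remainder free description),
#' followed by 20 \code{letter value} pairs, one per line.  Lines starting
#' with \code{#} and blank lines are ignored.
#'
#' @param path path to a scale file.
#' @return list of \code{ScaleTable} objects (fields \code{name},
#'   \code{values}: named numeric of length 20) in file order.
#' @export
read_scales <- function(path) {
  if (!file.exists(path))
    abort2(sprintf("scale file not found: %s", path), "morfmlp_format_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (length(lines) == 0L || !hdr[1L])
    abort2(sprintf("no scale blocks in %s", path), "morfmlp_format_error")
  blocks <- split(lines, cumsum(hdr))
  lapply(unname(blocks), function(bl) {
    name <- strsplit(sub("^>\\s*", "", bl[1L]), "\\s+")[[1]][1L]
    body <- strsplit(trimws(bl[-1L]), "\\s+")
    letters_ <- toupper(vapply(body, `[`, character(1), 1L))
    vals <- suppressWarnings(as.numeric(vapply(body, `[`, character(1), 2L)))
    if (anyDuplicated(letters_))
      abort2(sprintf("scale '%s': duplicate letter %s", name,
                     letters_[duplicated(letters_)][1L]),
             "morfmlp_format_error")
    missing_ <- setdiff(AA_ALPHABET, letters_)
    if (length(missing_) > 0L)
      abort2(sprintf("scale '%s': missing letter %s", name, missing_[1L]),
             "morfmlp_format_error")
    extra <- setdiff(letters_, AA_ALPHABET)
    if (length(extra) > 0L)
      abort2(sprintf("scale '%s': unknown letter %s", name, extra[1L]),
             "morfmlp_format_error")
    if (any(!is.finite(vals)))
      abort2(sprintf("scale '%s': non-finite value", name),
             "morfmlp_format_error")
    structure(list(name = name,
                   values = setNames(vals, letters_)[AA_ALPHABET]),
              class = "ScaleTable")
  })
}

#' Default amino-acid scale set
#'
#' Returns the 15 property scales shipped with the package (13
#' physicochemical scales in the AAindex tradition plus two
#' secondary-structure/disorder propensity scales); together with the
#' topological-entropy functional these make the 16 per-window sequence
#' properties.  See \code{inst/extdata/scales_default.txt} for provenance
#' notes on each scale.
#'
#' @return list of 15 \code{ScaleTable} objects.
#' @export
default_scales <- function() {
  read_scales(system.file("extdata", "scales_default.txt",
                          package = "morfmlp", mustWork = TRUE))
}

#' Read MoRF region annotations
#'
#' @param path TSV with header columns \code{sequence_id}, \code{start},
#'   \code{end}; coordinates 1-based inclusive.  \code{#} lines ignored.
#' @return data.frame with those columns.
#' @export
read_regions <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sequence_id", "start", "end")
  if (!all(need %in% names(df)))
    abort2(sprintf("regions file %s must have columns %s", path,
                   paste(need, collapse = ", ")), "morfmlp_format_error")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 1L |
                 df$start > df$end)
  if (length(bad) > 0L)
    abort2(sprintf("invalid region at line %d of %s (start=%s end=%s)",
                   bad[1L], path, df$start[bad[1L]], df$end[bad[1L]]),
           "morfmlp_format_error")
  df[need]
}

#' Write MoRF region annotations
#' @param regions data.frame with sequence_id/start/end.
#' @param path output path.
#' @param header optional comment lines (without leading \code{#}).
#' @export
write_regions <- function(regions, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines("sequence_id\tstart\tend", con)
  if (nrow(regions) > 0L)
    writeLines(sprintf("%s\t%d\t%d", regions$sequence_id,
                       as.integer(regions$start), as.integer(regions$end)),
               con)
  invisible(path)
}

#' Apply region annotations to sequence records as per-residue labels
#'
#' Overlapping regions are unioned.  Every annotated sequence_id must
#' exist among the records; regions extending past a sequence end are an
#' error.
#'
#' @param records list of \code{SequenceRecord}.
#' @param regions data.frame from \code{\link{read_regions}}.
#' @return the records, each with a 0/1 \code{labels} vector.
#' @export
apply_regions <- function(records, regions) {
  ids <- vapply(records, `[[`, character(1), "id")
  unknown <- setdiff(unique(regions$sequence_id), ids)
  if (length(unknown) > 0L)
    abort2(sprintf("region refers to unknown sequence_id '%s'", unknown[1L]),
           "morfmlp_format_error")
  lapply(records, function(rec) {
    L <- nchar(rec$residues)
    lab <- integer(L)
    sel <- regions[regions$sequence_id == rec$id, , drop = FALSE]
    for (k in seq_len(nrow(sel))) {
      if (sel$end[k] > L)
        abort2(sprintf("region %d-%d exceeds length %d of '%s'",
                       sel$start[k], sel$end[k], L, rec$id),
               "morfmlp_format_error")
      lab[sel$start[k]:sel$end[k]] <- 1L
    }
    rec$labels <- lab
    rec
  })
}

#' Recover minimal region annotations from per-residue labels
#' @param record a labelled \code{SequenceRecord}.
#' @return data.frame sequence_id/start/end (maximal runs of 1-labels).
#' @export
labels_to_regions <- function(record) {
  if (is.null(record$labels))
    abort2(sprintf("sequence '%s' has no labels", record$id),
           "morfmlp_format_error")
  r <- rle(record$labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  data.frame(sequence_id = rep(record$id, sum(keep)),
             start = starts[keep], end = ends[keep],
             stringsAsFactors = FALSE)
}

#' Construct a prediction track
#' @param sequence_id sequence identifier.
#' @param scores per-residue scores in [0,1].
#' @param calls optional 0/1 calls.
#' @return object of class \code{PredictionTrack}.
#' @export
prediction_track <- function(sequence_id, scores, calls = NULL) {
  scores <- as.numeric(scores)
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1))
    abort2(sprintf("scores for '%s' must be finite and in [0,1]",
                   sequence_id), "morfmlp_format_error")
  if (!is.null(calls) && length(calls) != length(scores))
    abort2(sprintf("calls/scores length mismatch for '%s'", sequence_id),
           "morfmlp_format_error")
  structure(list(sequence_id = sequence_id, scores = scores,
                 calls = if (is.null(calls)) NULL else as.integer(calls)),
            class = "PredictionTrack")
}

#' @export
print.PredictionTrack <- function(x, ...) {
  cat(sprintf("PredictionTrack '%s': %d residues, score range %.3f-%.3f%s\n",
              x$sequence_id, length(x$scores), min(x$scores),
              max(x$scores),
              if (is.null(x$calls)) "" else
                sprintf(", %d called MoRF", sum(x$calls))))
  invisible(x)
}

#' Write prediction tracks to TSV
#'
#' Columns: sequence_id, position (1-based), residue, score (6 decimal
#' places), call (empty when no calls were made).
#'
#' @param tracks list of \code{PredictionTrack}.
#' @param path output path.
#' @param records optional list of \code{SequenceRecord} supplying the
#'   residue column; \code{.} is written when unavailable.
#' @param header optional comment lines (without leading \code{#}).
#' @export
write_predictions <- function(tracks, path, records = NULL, header = NULL) {
  res_of <- list()
  if (!is.null(records))
    for (rec in records) res_of[[rec$id]] <- strsplit(rec$residues, "")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines("sequence_id\tposition\tresidue\tscore\tcall", con)
  for (tr in tracks) {
    L <- length(tr$scores)
    res <- res_of[[tr$sequence_id]] %||% rep(".", L)
    calls <- if (is.null(tr$calls)) rep("", L) else as.character(tr$calls)
    writeLines(sprintf("%s\t%d\t%s\t%.6f\t%s", tr$sequence_id,
                       seq_len(L), res, tr$scores, calls), con)
  }
  invisible(path)
}

#' Read prediction tracks from TSV
#' @param path file written by \code{\link{write_predictions}}.
#' @return list of \code{PredictionTrack} in file order.
#' @export
read_predictions <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   colClasses = c(score = "numeric"))
  need <- c("sequence_id", "position", "score")
  if (!all(need %in% names(df)))
    abort2(sprintf("prediction file %s must have columns %s", path,
                   paste(need, collapse = ", ")), "morfmlp_format_error")
  ids <- unique(df$sequence_id)
  lapply(ids, function(id) {
    sub <- df[df$sequence_id == id, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    if (!identical(as.integer(sub$position), seq_len(nrow(sub))))
      abort2(sprintf("non-contiguous positions for '%s' in %s", id, path),
             "morfmlp_format_error")
    calls <- NULL
    if ("call" %in% names(sub) && !all(is.na(sub$call)) &&
        !all(sub$call == ""))
      calls <- as.integer(sub$call)
    prediction_track(id, sub$score, calls)
  })
}

#' Save an ensemble model to a JSON archive
#'
#' The archive is plain JSON with an embedded \code{format_version};
#' numbers are written at full precision so save/load round-trips are
#' bit-exact.
#'
#' @param model an \code{EnsembleModel} from \code{\link{train_mlp}}.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "EnsembleModel"))
  payload <- list(
    format_version = MODEL_FORMAT_VERSION,
    branch = model$branch,
    config = model$config[c("input_dim", "hidden_sizes", "dropout_keep",
                            "learning_rate", "epochs", "batch_size",
                            "seed", "inverted_dropout")],
    standardizer = list(mean = model$standardizer$mean,
                        sd = model$standardizer$sd),
    members = lapply(model$members, function(p)
      list(W1 = p$W1, b1 = p$b1, W2 = p$W2, b2 = p$b2,
           W3 = p$W3, b3 = p$b3)))
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Load an ensemble model saved by \code{\link{save_model}}
#' @param path model archive path.
#' @return an \code{EnsembleModel}.
#' @export
load_model <- function(path) {
  payload <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                      error = function(e)
                        abort2(sprintf("cannot parse model file %s: %s",
                                       path, conditionMessage(e)),
                               "morfmlp_format_error"))
  ver <- payload$format_version
  if (is.null(ver) || !identical(as.integer(ver), MODEL_FORMAT_VERSION))
    abort2(sprintf("model format version %s not supported (expected %d)",
                   ver %||% "<missing>", MODEL_FORMAT_VERSION),
           "morfmlp_format_error")
  if (is.null(payload$members) || is.null(payload$standardizer))
    abort2(sprintf("model file %s is incomplete", path),
           "morfmlp_format_error")
  cfg <- payload$config
  config <- mlp_config(input_dim = cfg$input_dim,
                       hidden_sizes = cfg$hidden_sizes,
                       dropout_keep = cfg$dropout_keep,
                       learning_rate = cfg$learning_rate,
                       epochs = cfg$epochs, batch_size = cfg$batch_size,
                       seed = cfg$seed,
                       inverted_dropout = cfg$inverted_dropout)
  members <- lapply(seq_len(if (is.data.frame(payload$members))
    nrow(payload$members) else length(payload$members)), function(i) {
      m <- if (is.data.frame(payload$members)) {
        lapply(payload$members, function(col) col[[i]])
      } else payload$members[[i]]
      list(W1 = as.matrix(m$W1), b1 = as.numeric(m$b1),
           W2 = as.matrix(m$W2), b2 = as.numeric(m$b2),
           W3 = as.matrix(m$W3), b3 = as.numeric(m$b3))
    })
  structure(list(members = members,
                 standardizer = list(
                   mean = as.numeric(payload$standardizer$mean),
                   sd = as.numeric(payload$standardizer$sd)),
                 config = config,
                 branch = payload$branch %||% NA_character_),
            class = "EnsembleModel")
}
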