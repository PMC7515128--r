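test_that("read_fasta parses records in order with token ids", {
  path <- write_tmp_fasta(c(">s1 some description", "MKV",
                            ">s2", "ACDE", "FGH"))
  recs <- read_fasta(path)
  expect_length(recs, 2L)
  expect_equal(vapply(recs, `[[`, character(1), "id"), c("s1", "s2"))
  expect_equal(recs[[1]]$residues, "MKV")
  expect_equal(recs[[2]]$residues, "ACDEFGH")
})

test_that("read_fasta rejects empty files and duplicate ids", {
  empty <- write_tmp_fasta(character(0))
  expect_error(read_fasta(empty), class = "morfmlp_format_error")
  dup <- write_tmp_fasta(c(">a", "MK", ">a other", "VV"))
  expect_error(read_fasta(dup), "duplicate sequence id 'a'",
               class = "morfmlp_format_error")
})

test_that("non-standard residues are canonicalized with a warning", {
  # B->D, Z->E, U->C, O->K silently; J (and X) -> X with a warning
  expect_equal(sequence_record("s", "MBZUOK")$residues, "MDECKK")
  expect_warning(rec <- sequence_record("s", "MJV"), "mapped to X")
  expect_equal(rec$residues, "MXV")
  path <- write_tmp_fasta(c(">s1", "MKJ"))
  expect_warning(recs <- read_fasta(path), "mapped to X")
  expect_equal(recs[[1]]$residues, "MKX")
})

test_that("PSSM writer/reader round-trips the 20xL matrix", {
  set.seed(1)
  rec <- sequence_record("p1", random_sequence(7))
  mat <- matrix(sample(-10:12, 20 * 7, replace = TRUE), nrow = 20,
                dimnames = list(morfmlp:::PSSM_AA_ORDER, NULL))
  pssm <- structure(list(sequence_id = "p1", matrix = mat,
                         query = rec$residues), class = "PSSMProfile")
  path <- withr::local_tempfile(fileext = ".pssm")
  write_pssm(pssm, path)
  back <- read_pssm(path, rec)
  expect_identical(unname(back$matrix), unname(mat) + 0)  # numeric compare
  # all-zero matrix survives too
  pssm$matrix[] <- 0
  write_pssm(pssm, path)
  expect_true(all(read_pssm(path, rec)$matrix == 0))
})

test_that("PSSM alignment errors name the first offending position", {
  rec <- sequence_record("p1", "MKV")
  mat <- matrix(0, 20, 3, dimnames = list(morfmlp:::PSSM_AA_ORDER, NULL))
  pssm <- structure(list(sequence_id = "p1", matrix = mat, query = "MAV"),
                    class = "PSSMProfile")
  path <- withr::local_tempfile()
  write_pssm(pssm, path)
  expect_error(read_pssm(path, rec), "position 2",
               class = "morfmlp_alignment_error")
  # length mismatch
  rec4 <- sequence_record("p1", "MAVA")
  expect_error(read_pssm(path, rec4), "3 rows vs 4 residues",
               class = "morfmlp_alignment_error")
  # truncated row
  lines <- readLines(path)
  row_idx <- grep("^\\s*2\\s", lines)
  lines[row_idx] <- substr(lines[row_idx], 1, 30)
  writeLines(lines, path)
  expect_error(read_pssm(path, sequence_record("p1", "MAV")),
               class = "morfmlp_format_error")
})

test_that("scale file parsing: default set, constants, bad blocks", {
  scales <- default_scales()
  expect_length(scales, 15L)
  expect_true(all(vapply(scales, function(s)
    length(s$values) == 20 && all(is.finite(s$values)), logical(1))))

  path <- withr::local_tempfile()
  writeLines(c(">const demo", paste(AA20, "1.0")), path)
  one <- read_scales(path)
  expect_length(one, 1L)
  expect_true(all(one[[1]]$values == 1.0))

  writeLines(c(">dup", paste(AA20, "1.0"), "A 2.0"), path)
  expect_error(read_scales(path), "duplicate letter A",
               class = "morfmlp_format_error")
  writeLines(c(">short", paste(AA20[-1], "1.0")), path)
  expect_error(read_scales(path), "missing letter A",
               class = "morfmlp_format_error")
})

test_that("region annotations label residues as interval unions", {
  rec <- sequence_record("s1", "MKVAA")
  regions <- data.frame(sequence_id = "s1", start = 2L, end = 4L)
  lab <- apply_regions(list(rec), regions)[[1]]$labels
  expect_equal(lab, c(0L, 1L, 1L, 1L, 0L))
  overlapping <- data.frame(sequence_id = c("s1", "s1"),
                            start = c(2L, 4L), end = c(4L, 5L))
  lab2 <- apply_regions(list(rec), overlapping)[[1]]$labels
  expect_equal(lab2, c(0L, 1L, 1L, 1L, 1L))
  # region -> label -> region reconstruction returns the union
  rec2 <- apply_regions(list(rec), overlapping)[[1]]
  expect_equal(labels_to_regions(rec2),
               data.frame(sequence_id = "s1", start = 2L, end = 5L))
  expect_error(apply_regions(list(rec),
                             data.frame(sequence_id = "nope",
                                        start = 1L, end = 2L)),
               "unknown sequence_id", class = "morfmlp_format_error")
})

test_that("region files round-trip and reject inverted intervals", {
  path <- withr::local_tempfile()
  regions <- data.frame(sequence_id = c("a", "b"), start = c(2L, 1L),
                        end = c(9L, 5L), stringsAsFactors = FALSE)
  write_regions(regions, path, header = "demo")
  expect_equal(read_regions(path), regions)
  writeLines(c("sequence_id\tstart\tend", "a\t5\t2"), path)
  expect_error(read_regions(path), class = "morfmlp_format_error")
})

test_that("prediction tracks round-trip scores to 6 decimals", {
  set.seed(2)
  tracks <- list(prediction_track("s1", round(runif(8), 6),
                                  calls = rep(c(0L, 1L), 4)),
                 prediction_track("s2", round(runif(3), 6)))
  path <- withr::local_tempfile()
  write_predictions(tracks, path, header = "demo")
  back <- read_predictions(path)
  expect_equal(back[[1]]$scores, tracks[[1]]$scores)
  expect_equal(back[[1]]$calls, tracks[[1]]$calls)
  expect_equal(back[[2]]$scores, tracks[[2]]$scores)
  expect_error(prediction_track("s", c(0.2, 1.4)),
               class = "morfmlp_format_error")
})

test_that("model archives round-trip bit-exactly and check versions", {
  dat <- tiny_pipeline_data(n = 3, seed = 5)
  cfg <- mlp1_config(ncol(dat$p1$features), epochs = 3L, seed = 9L)
  model <- suppressWarnings(   # tiny fixture may be positive-heavy
    train_mlp(dat$p1$features, dat$labels, cfg, n_members = 2L,
              branch = "properties"))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  save_model(model, f1)
  loaded <- load_model(f1)
  save_model(loaded, f2)
  expect_identical(readLines(f1), readLines(f2))  # save-load-save stable
  expect_equal(predict(loaded, dat$p1$features),
               predict(model, dat$p1$features))

  # truncation and version bumps are explicit errors
  full <- readLines(f1)
  writeLines(head(full, length(full) %/% 2), f2)
  expect_error(load_model(f2), class = "morfmlp_format_error")
  writeLines(sub('"format_version": 1', '"format_version": 99', full), f2)
  expect_error(load_model(f2), "version 99",
               class = "morfmlp_format_error")
})
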