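test_that("padding adds floor(N/2) zero elements per side", {
  expect_length(pad(numeric(3), 10), 13L)   # 3 + 2*5
  expect_length(pad(numeric(5), 45), 49L)   # 5 + 2*22
  padded <- pad(c(1.5, 2.5), 7)
  expect_identical(padded[c(1:3, 6:8)], rep(0, 6))
  expect_identical(pad(c("A", "C"), 4), c("-", "-", "A", "C", "-", "-"))
})

test_that("window scale averages match direct window means", {
  const <- toy_scale(rep(3, 20))
  rec <- sequence_record("s", strrep("A", 12))
  v <- window_scale_values(rec, const, 4)
  # interior windows see only residues -> exactly c; edge windows see
  # c * (covered count)/N
  expect_equal(v[3:(length(v) - 2)], rep(3, length(v) - 4))
  expect_equal(v[1], 3 * 2 / 4)   # first window: 2 pads of the 4 slots
  expect_equal(v[2], 3 * 3 / 4)

  set.seed(41)
  rec8 <- sequence_record("r8", random_sequence(8))
  sc <- toy_scale(round(rnorm(20), 3))
  got <- window_scale_values(rec8, sc, 4)
  vals <- unname(sc$values[strsplit(rec8$residues, "")[[1]]])
  padded <- c(0, 0, vals, 0, 0)
  want <- vapply(seq_len(length(padded) - 3),
                 function(i) mean(padded[i:(i + 3)]), numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("topological entropy: degenerate, maximal and random windows", {
  # constant residues: interior windows hold one distinct letter -> 0
  recA <- sequence_record("a", strrep("A", 30))
  vA <- window_entropy_values(recA, 10)
  N0 <- 5
  interior <- (N0 + 1):(length(vA) - N0)
  expect_true(all(vA[interior] == 0))
  # terminal windows mix pads (a distinct symbol) with A -> nonzero
  expect_gt(vA[1], 0)

  # 20 distinct letters with N = 20: n = 1, m = 20 -> log_20(20) = 1
  rec20 <- sequence_record("u", paste(AA20, collapse = ""))
  v20 <- window_entropy_values(rec20, 20)
  expect_equal(max(v20), 1)

  # random 45-mers against the subword-set oracle
  set.seed(7)
  for (k in 1:5) {
    rec <- sequence_record("r", random_sequence(45))
    N <- 45
    got <- window_entropy_values(rec, N)
    letters_ <- pad(strsplit(rec$residues, "")[[1]], N)
    W <- length(letters_) - N + 1
    want <- vapply(seq_len(W), function(i)
      brute_window_entropy(letters_[i:(i + N - 1)]), numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("entropy values stay in the admissible range", {
  set.seed(8)
  for (N in c(10, 20, 45, 90)) {
    rec <- sequence_record("r", random_sequence(60))
    v <- window_entropy_values(rec, N)
    A <- 20
    n <- 1
    while (A^(n + 1) + n <= N) n <- n + 1
    if (A^n + n - 1 > N) n <- 1
    m <- min(A^n + n - 1, N)
    expect_true(all(v >= 0 & v <= log(m - n + 1, A) / n + 1e-15))
  }
})

test_that("pooling: constants, interior window counts, L=3/N=2 case", {
  expect_equal(pool_to_residues(rep(2.5, 11), 10, 2), rep(2.5, 10))

  # interior residues average exactly N windows; residue 1 averages
  # min(1+N0, W) windows
  for (N in c(4, 7, 10)) {
    L <- 30
    N0 <- floor(N / 2)
    W <- L + 2 * N0 - N + 1
    j <- seq_len(L)
    count <- pmin(j + N0, W) - pmax(1, j + N0 - N + 1) + 1
    interior <- j > N0 & j <= L - N0
    expect_true(all(count[interior] == N))
    expect_equal(count[1], min(1 + N0, W))
  }

  we <- make_worked_example()$pooling
  v <- window_scale_values(we$record, we$scale, we$N)
  expect_equal(v, we$expected_windows)
  x <- pool_to_residues(v, 3, we$N)
  expect_equal(x, we$expected_pooled)   # x1 = (v1+v2)/2 etc., by hand
})

test_that("two-stage pooling equals the brute-force oracle", {
  set.seed(13)
  for (k in 1:60) {
    L <- sample(2:30, 1)
    N <- sample(2:12, 1)
    vals <- rnorm(L)
    rec <- sequence_record("r", random_sequence(L))
    sc <- toy_scale(rnorm(20))
    resvals <- unname(sc$values[strsplit(rec$residues, "")[[1]]])
    got <- suppressWarnings(
      pool_to_residues(window_scale_values(rec, sc, N), L, N))
    expect_equal(got, brute_pool(resvals, N), tolerance = 1e-12)
  }
})

test_that("feature matrices have the documented dimensions", {
  rec <- sequence_record("s", random_sequence(40))
  fm <- suppressWarnings(property_features(rec))
  expect_equal(ncol(fm$values), 48L)
  expect_equal(nrow(fm$values), 40L)
  expect_equal(fm$branch, "properties")
  expect_true(all(grepl("@(10|45|90)$", fm$column_names)))
  expect_equal(sum(grepl("^entropy@", fm$column_names)), 3L)

  one <- suppressWarnings(property_features(
    rec, config = window_config(10)))
  expect_equal(ncol(one$values), 16L)

  expect_error(property_features(rec, scales = default_scales()[1:3]),
               "15 property scales", class = "morfmlp_config_error")

  # determinism
  fm2 <- suppressWarnings(property_features(rec))
  expect_identical(fm$values, fm2$values)
})

test_that("profile features: dimensions, zeros, constant propagation", {
  rec <- sequence_record("s", random_sequence(40))
  zero <- structure(list(sequence_id = "s",
                         matrix = matrix(0, 20, 40), query = rec$residues),
                    class = "PSSMProfile")
  pf <- suppressWarnings(profile_features(rec, zero))
  expect_equal(dim(pf$values), c(40L, 60L))
  expect_true(all(pf$values == 0))

  # constant PSSM value c, single window: interior residues get exactly c
  rec2 <- sequence_record("t", random_sequence(60))
  const <- structure(list(sequence_id = "t",
                          matrix = matrix(2.5, 20, 60),
                          query = rec2$residues), class = "PSSMProfile")
  pfc <- profile_features(rec2, const, window_config(10))
  N0 <- 5
  interior <- (2 * N0 + 1):(60 - 2 * N0)   # beyond both averaging edges
  expect_true(all(abs(pfc$values[interior, ] - 2.5) < 1e-12))

  wrong <- structure(list(sequence_id = "other", matrix = matrix(0, 20, 60),
                          query = rec2$residues), class = "PSSMProfile")
  expect_error(profile_features(rec2, wrong),
               class = "morfmlp_alignment_error")
})

test_that("interior features are translation-equivariant", {
  set.seed(23)
  base <- random_sequence(120)
  prefix <- random_sequence(10)
  cfg <- window_config(10)
  f0 <- property_features(sequence_record("a", base), config = cfg)$values
  f1 <- property_features(sequence_record("b", paste0(prefix, base)),
                          config = cfg)$values
  # rows farther than N0+N from both ends are pure functions of the
  # local window content, hence shift with the sequence
  N <- 10; N0 <- 5
  safe <- (N0 + N + 1):(120 - N0 - N)
  expect_equal(f1[safe + 10, ], f0[safe, ], tolerance = 1e-12)
})

test_that("short and single-residue sequences stay finite with warning", {
  rec1 <- sequence_record("one", "M")
  expect_warning(fm <- property_features(rec1), "pad-dominated")
  expect_true(all(is.finite(fm$values)))
  expect_equal(dim(fm$values), c(1L, 48L))
})
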