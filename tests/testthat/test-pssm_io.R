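test_that("parse_pssm reads a hand-written PSI-BLAST matrix", {
  txt <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste("           ", paste(sprintf("%3s", c(AA_ALPHABET, AA_ALPHABET)),
                               collapse = " ")),
    paste("    1 M  ", paste(sprintf("%3d", 1:20), collapse = " "),
          paste(sprintf("%3d", rep(0L, 20)), collapse = " "), " 0.30 0.09"),
    paste("    2 K  ", paste(sprintf("%3d", rep(-2L, 20)), collapse = " "),
          paste(sprintf("%3d", rep(0L, 20)), collapse = " "), " 0.30 0.09"),
    paste("    3 V  ", paste(sprintf("%3d", 20:1), collapse = " "),
          paste(sprintf("%3d", rep(0L, 20)), collapse = " "), " 0.30 0.09"),
    "",
    "                      K         Lambda",
    "Standard Ungapped    0.1347     0.3179")
  p <- parse_pssm(txt, sequence_id = "toy")
  expect_s3_class(p, "pssm_profile")
  expect_equal(p$length, 3L)
  expect_identical(dim(p$scores), c(3L, 20L))
  expect_identical(p$residues, c("M", "K", "V"))
  expect_equal(unname(p$scores[1, ]), 1:20)
  expect_equal(unname(p$scores[3, ]), 20:1)
  expect_true(is.integer(p$scores))
})

test_that("parser reorders score columns by the header alphabet", {
  perm <- c(2:20, 1L)  # header starts at R and wraps back to A
  txt <- c(paste(" ", paste(AA_ALPHABET[perm], collapse = "  ")),
           paste("    1 A ", paste(sprintf("%3d", perm), collapse = " "),
                 paste(sprintf("%3d", rep(0L, 20)), collapse = " ")))
  p <- parse_pssm(txt)
  # score for amino acid j was written as the value j, wherever it sat
  expect_equal(unname(p$scores[1, ]), 1:20)
})

test_that("malformed and empty PSSM inputs raise informative errors", {
  bad <- c(paste(" ", paste(c(AA_ALPHABET, AA_ALPHABET), collapse = " ")),
           "    1 M   1 2 3")
  expect_error(parse_pssm(bad), "line 2")
  expect_error(parse_pssm("no matrix here"), "header not found")
  hdr_only <- paste(" ", paste(c(AA_ALPHABET, AA_ALPHABET), collapse = " "))
  expect_error(parse_pssm(c(hdr_only, "")), "empty")
})

test_that("pssm_profile validates its invariants", {
  expect_error(pssm_profile("x", "MK", matrix(0L, 2L, 19L)), "20 columns")
  expect_error(pssm_profile("x", "MKV", matrix(0L, 2L, 20L)), "2 rows")
  expect_error(pssm_profile("x", "MK", matrix(0.5, 2L, 20L)), "whole")
  p <- pssm_profile("x", "mbu", matrix(1L, 3L, 20L))  # non-canonical B, U
  expect_identical(p$residues, c("M", "X", "X"))
})

test_that("write_pssm emits one row per position with 20 score columns", {
  p <- random_profile(1L)
  txt <- write_pssm(p)
  rows <- grep("^\\s*\\d+ ", txt, value = TRUE)
  expect_length(rows, 1L)
  toks <- strsplit(trimws(rows), "[ \t]+")[[1L]]
  expect_gte(length(toks) - 2L, 40L)  # 20 scores + 20 percentages
})

test_that("parse/write round-trips are identities on random profiles", {
  set.seed(42)
  for (i in 1:50) {
    p <- random_profile(id = sprintf("rt%02d", i))
    q <- parse_pssm(write_pssm(p), sequence_id = p$sequence_id)
    expect_identical(q$scores, p$scores)
    expect_identical(q$residues, p$residues)
    expect_identical(q$length, p$length)
  }
})

test_that("FASTA reader and writer round-trip and keep record order", {
  set.seed(1)
  recs <- data.frame(
    id = sprintf("seq%02d", 1:7),
    sequence = vapply(1:7, function(i)
      paste(sample(AA_ALPHABET, 25, replace = TRUE), collapse = ""),
      character(1L)))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, path)
  back <- read_fasta(path)
  expect_equal(back, recs)
  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_fasta(empty), "empty")
})

test_that("save_dataset / load_manifest reproduce the in-memory dataset", {
  set.seed(7)
  ds <- labeled_dataset(lapply(1:6, function(i) random_profile(id = paste0("s", i))),
                        rep(c("positive", "negative"), each = 3L))
  dir <- withr::local_tempdir()
  manifest <- save_dataset(ds, dir)
  back <- load_manifest(manifest)
  expect_equal(length(back), 6L)
  expect_identical(as.character(back$labels), as.character(ds$labels))
  for (i in 1:6) {
    expect_identical(back$profiles[[i]]$scores, ds$profiles[[i]]$scores)
    expect_identical(back$profiles[[i]]$residues, ds$profiles[[i]]$residues)
  }
})

test_that("manifest loading fails clearly on a missing profile file", {
  dir <- withr::local_tempdir()
  writeLines(c("path\tlabel", "ghost.pssm\tpositive"),
             file.path(dir, "manifest.tsv"))
  expect_error(load_manifest(file.path(dir, "manifest.tsv")),
               "entry 1.*ghost")
})

test_that("binary labels are validated", {
  p <- list(random_profile(3L))
  expect_error(labeled_dataset(p, "maybe"), "binary")
  expect_error(labeled_dataset(p, 2), "0/1")
  expect_identical(as.character(labeled_dataset(p, TRUE)$labels), "positive")
})
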