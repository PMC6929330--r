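#' Construct a PSSM profile object
#'
#' A PSSM profile is an N x 20 matrix of integer position-specific scores
#' (log-odds units) together with the query residue at each of the N
#' positions. Rows are sequence positions, columns are the 20 canonical
#' amino acids in the fixed [AA_ALPHABET] order. Non-canonical residues
#' (B, Z, U, O, J, ...) keep their score rows but are stored as the unknown
#' symbol `"X"`.
#'
#' @param sequence_id identifier string.
#' @param residues residue letters: a single string or a character vector of
#'   single letters, length N.
#' @param scores numeric N x 20 matrix of whole-valued scores.
#' @return An object of class `pssm_profile` with fields `sequence_id`,
#'   `residues` (length-N character vector), `scores` (N x 20 integer
#'   matrix with `AA_ALPHABET` column names) and `length`.
#' @examples
#' p <- pssm_profile("toy", "MKV", matrix(0L, 3, 20))
#' p$length
#' @export
pssm_profile <- function(sequence_id, residues, scores) {
  stopifnot(is.character(sequence_id), length(sequence_id) == 1L)
  residues <- normalize_residues(residues)
  if (length(residues) < 1L)
    stop("a PSSM profile must have at least one position")
  if (!is.matrix(scores) || ncol(scores) != 20L)
    stop("'scores' must be a matrix with exactly 20 columns")
  if (nrow(scores) != length(residues))
    stop(sprintf("scores has %d rows but there are %d residues",
                 nrow(scores), length(residues)))
  if (anyNA(scores) || any(scores != round(scores)))
    stop("PSSM scores must be whole numbers (log-odds integers)")
  storage.mode(scores) <- "integer"
  dimnames(scores) <- list(NULL, AA_ALPHABET)
  structure(
    list(sequence_id = sequence_id, residues = residues,
         scores = scores, length = length(residues)),
    class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("<pssm_profile> %s: %d positions x 20 amino-acid columns\n",
              x$sequence_id, x$length))
  cat("  sequence:", paste0(head(x$residues, 40L), collapse = ""),
      if (x$length > 40L) "..." else "", "\n")
  invisible(x)
}

# --- PSI-BLAST ASCII PSSM -------------------------------------------------

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the matrix dialect written by `psiblast -out_ascii_pssm`: header
#' lines, then one row per position holding the position index, the query
#' residue and 40 numeric columns (20 log-odds scores followed by 20
#' weighted observed percentages), then footer statistics. Only the first
#' 20 numeric columns (the scores) are kept; percentages and footer are
#' discarded.
#'
#' @param text the file content: a single string (possibly containing
#'   newlines) or a character vector of lines.
#' @param sequence_id identifier to attach; defaults to `"pssm"`.
#' @return A [pssm_profile].
#' @seealso [read_pssm()] to read from a file, [write_pssm()] for the
#'   inverse operation.
#' @export
parse_pssm <- function(text, sequence_id = "pssm") {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  toks <- lapply(text, function(l) strsplit(trimws(l), "[ \t]+")[[1L]])

  # locate the column-header line: >= 20 tokens, first 20 a permutation of
  # the canonical alphabet (PSI-BLAST prints the 20 letters twice)
  hdr <- which(vapply(toks, function(tk)
    length(tk) >= 20L && all(sort(tk[1:20]) == sort(AA_ALPHABET)),
    logical(1L)))
  if (length(hdr) == 0L)
    stop("not a PSI-BLAST ASCII PSSM: amino-acid column header not found")
  hdr <- hdr[1L]
  col_order <- match(AA_ALPHABET, toks[[hdr]][1:20])

  residues <- character(0)
  scores <- list()
  for (i in seq(hdr + 1L, length.out = max(0L, length(text) - hdr))) {
    tk <- toks[[i]]
    if (length(tk) == 0L || tk[1L] == "") {
      if (length(residues) > 0L) break else next
    }
    if (!grepl("^[0-9]+$", tk[1L])) {
      if (length(residues) > 0L) break else next  # footer / preamble
    }
    if (length(tk) < 22L)
      stop(sprintf(
        "malformed PSSM row at line %d: expected 20 score columns, found %d",
        i, max(0L, length(tk) - 2L)))
    sc <- suppressWarnings(as.numeric(tk[3:22]))
    if (anyNA(sc))
      stop(sprintf("malformed PSSM row at line %d: non-numeric score", i))
    residues[length(residues) + 1L] <- tk[2L]
    scores[[length(scores) + 1L]] <- sc[col_order]
  }
  if (length(residues) == 0L)
    stop("empty PSSM: no matrix rows found")
  pssm_profile(sequence_id, residues,
               do.call(rbind, scores))
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' @param path file path.
#' @param sequence_id identifier; defaults to the file name without
#'   extension.
#' @return A [pssm_profile].
#' @export
read_pssm <- function(path, sequence_id = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  if (is.null(sequence_id))
    sequence_id <- tools::file_path_sans_ext(basename(path))
  parse_pssm(readLines(path, warn = FALSE), sequence_id = sequence_id)
}

#' Write a PSSM profile in PSI-BLAST ASCII format
#'
#' Emits the same dialect [parse_pssm()] consumes: a descriptive line, the
#' doubled amino-acid column header, one row per position with the 20
#' log-odds scores followed by 20 zero percentage columns and two zero
#' statistics, and a short footer. `parse_pssm(write_pssm(p))` reproduces
#' `p` exactly (percentages carry no information here and are written as
#' zeros).
#'
#' @param profile a [pssm_profile].
#' @param path optional output file; when `NULL` the text is returned.
#' @return Invisibly (or visibly when `path` is `NULL`) the character
#'   vector of lines.
#' @export
write_pssm <- function(profile, path = NULL) {
  stopifnot(inherits(profile, "pssm_profile"))
  hdr2 <- paste0("           ",
                 paste(sprintf("%3s", c(AA_ALPHABET, AA_ALPHABET)),
                       collapse = " "))
  rows <- vapply(seq_len(profile$length), function(i) {
    paste0(sprintf("%5d %s  ", i, profile$residues[i]),
           paste(sprintf("%3d", profile$scores[i, ]), collapse = " "),
           " ",
           paste(sprintf("%3d", integer(20L)), collapse = " "),
           "  0.00 0.00")
  }, character(1L))
  out <- c("",
           paste("Last position-specific scoring matrix computed,",
                 "weighted observed percentages rounded down,",
                 "information per position, and",
                 "relative weight of gapless real matches to pseudocounts"),
           hdr2, rows, "", "                      K         Lambda")
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

# --- FASTA ----------------------------------------------------------------

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return A data.frame with columns `id` (first word of each header) and
#'   `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  data.frame(id = vapply(strsplit(names(aa), "[ \t]"), `[`, character(1L), 1L),
             sequence = as.character(aa),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write protein sequences to a FASTA file
#'
#' @param records data.frame with columns `id` and `sequence`, or a named
#'   character vector of sequences.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records))
    records <- data.frame(id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- records$id
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

# --- labeled datasets and manifests ---------------------------------------

#' Construct a labeled PSSM dataset
#'
#' @param profiles list of [pssm_profile] objects.
#' @param labels binary labels: `"positive"`/`"negative"` (adaptor proteins
#'   are the positive class), a logical vector, or 0/1.
#' @param metadata free-form provenance list (synthetic parameters, file
#'   paths, ...).
#' @return An object of class `labeled_dataset` with fields `profiles`,
#'   `labels` (factor with levels negative, positive) and `metadata`.
#' @export
labeled_dataset <- function(profiles, labels, metadata = list()) {
  stopifnot(is.list(profiles),
            all(vapply(profiles, inherits, logical(1L), "pssm_profile")))
  labels <- as_binary_labels(labels)
  if (length(labels) != length(profiles))
    stop("number of labels must equal number of profiles")
  structure(list(profiles = profiles, labels = labels, metadata = metadata),
            class = "labeled_dataset")
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) labels <- ifelse(labels, "positive", "negative")
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    labels <- ifelse(labels == 1, "positive", "negative")
  }
  labels <- tolower(as.character(labels))
  if (!all(labels %in% c("positive", "negative")))
    stop("labels must be binary: 'positive' or 'negative'")
  factor(labels, levels = c("negative", "positive"))
}

# 0/1 integer view of the labels (1 = positive / adaptor)
labels01 <- function(dataset) as.integer(dataset$labels == "positive")

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d profiles (%d positive, %d negative)\n",
              length(x$profiles), sum(x$labels == "positive"),
              sum(x$labels == "negative")))
  invisible(x)
}

#' @export
length.labeled_dataset <- function(x) length(x$profiles)

#' Subset a labeled dataset
#' @param x a `labeled_dataset`.
#' @param i index vector over profiles.
#' @param ... unused.
#' @export
`[.labeled_dataset` <- function(x, i, ...) {
  labeled_dataset(x$profiles[i], x$labels[i], x$metadata)
}

#' Load a dataset manifest
#'
#' The manifest is a two-column tab-separated file with header columns
#' `path` and `label`; paths are resolved relative to the manifest's
#' directory. Every referenced PSSM file is read and validated.
#'
#' @param path manifest file path.
#' @return A [labeled_dataset()]; `metadata$manifest` records the source.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(tab)))
    stop("manifest must have 'path' and 'label' columns")
  if (nrow(tab) == 0L) stop("empty manifest: ", path)
  base <- dirname(normalizePath(path))
  profiles <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    f <- tab$path[i]
    full <- if (grepl("^(/|[A-Za-z]:)", f)) f else file.path(base, f)
    if (!file.exists(full))
      stop(sprintf("manifest entry %d: profile file not found: %s", i, f))
    profiles[[i]] <- read_pssm(full)
  }
  labeled_dataset(profiles, tab$label,
                  metadata = list(manifest = normalizePath(path)))
}

#' Save a dataset as PSSM files plus a manifest
#'
#' Writes one PSI-BLAST ASCII PSSM file per profile and a `manifest.tsv`
#' with columns `path` and `label`, the format [load_manifest()] reads.
#'
#' @param dataset a `labeled_dataset`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
save_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(dataset$profiles, `[[`, character(1L), "sequence_id")
  files <- sprintf("%04d_%s.pssm", seq_along(ids), gsub("[^A-Za-z0-9_.-]", "_", ids))
  for (i in seq_along(files))
    write_pssm(dataset$profiles[[i]], file.path(dir, files[i]))
  manifest <- file.path(dir, "manifest.tsv")
  write.table(data.frame(path = files,
                         label = as.character(dataset$labels)),
              manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
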