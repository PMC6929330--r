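#' Configuration for the synthetic PSSM generator
#'
#' The generator emulates variable-length N x 20 integer PSSM profiles in
#' which the class signal is placed under experimental control:
#'
#' * `signal_mode = "order"` — every profile, of either class, carries one
#'   conserved (score-elevated) block and one depleted block of
#'   `motif_length` positions, one in each half of the sequence. Positives
#'   carry the elevated block in the first half and the depleted block in
#'   the second; negatives carry the same two blocks in swapped order.
#'   Per-column score sums are therefore identically distributed in the two
#'   classes, so any row-order-destroying summary (the 400-dimensional
#'   summed representation in particular) carries no class signal, while an
#'   order-aware model can separate the classes.
#' * `signal_mode = "composition"` — positives receive a global mean shift
#'   of `effect_size` on five designated score columns (A, R, N, D, C) at
#'   every position; classical composition-based baselines can succeed.
#' * `signal_mode = "none"` — both classes follow the background law.
#'
#' Background scores are drawn i.i.d. as a rounded normal (mean 0, sd 2)
#' clipped to \[-10, 10\], matching the typical dynamic range of PSI-BLAST
#' log-odds; block/shift effects are added before the final clipping.
#'
#' @param n_positive,n_negative class counts. Defaults 100 and 500 give the
#'   1:5 imbalance typical of curated positive-vs-background protein sets.
#' @param length_range integer range of sequence lengths (uniform draw);
#'   minimum admissible length is 9 so the convolutional front-end emits at
#'   least one step.
#' @param signal_mode `"order"`, `"composition"` or `"none"`.
#' @param motif_length block length in positions (order mode).
#' @param effect_size score offset, in PSSM log-odds units, added to the
#'   affected entries.
#' @param seed integer; one global seed expands into independent
#'   per-profile substreams, so profile i is reproducible regardless of
#'   generation order.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_positive = 100L, n_negative = 500L,
                             length_range = c(90L, 270L),
                             signal_mode = c("order", "composition", "none"),
                             motif_length = 15L, effect_size = 4,
                             seed = 7L) {
  signal_mode <- match.arg(signal_mode)
  stopifnot(n_positive >= 0L, n_negative >= 0L,
            length(length_range) == 2L, length_range[1L] <= length_range[2L],
            motif_length >= 1L, effect_size >= 0)
  if (length_range[1L] < 9L)
    stop("minimum sequence length is 9 (the front-end downsamples by 9)")
  if (signal_mode == "order" && 2L * motif_length > length_range[1L])
    stop("motif_length too large: each half must hold one block")
  structure(list(n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 length_range = as.integer(length_range),
                 signal_mode = signal_mode,
                 motif_length = as.integer(motif_length),
                 effect_size = effect_size,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Columns carrying the compositional shift in composition mode.
COMPOSITION_COLUMNS <- 1:5  # A, R, N, D, C

# Derive a per-profile substream seed from the global seed (kept < 2^31).
substream_seed <- function(seed, index) {
  as.integer((as.double(seed %% 65011L) * 33013 + index * 7919) %% 2147483587)
}

clip_scores <- function(x) {
  x[x > 10] <- 10
  x[x < -10] <- -10
  x
}

#' Generate one synthetic PSSM profile
#'
#' See [synthetic_config()] for the generative law. The profile is drawn
#' from the substream `config$seed` x `index`, so a dataset is reproducible
#' profile-by-profile.
#'
#' @param length sequence length (positions); must be at least 9 and within
#'   the configured range.
#' @param label `"positive"` or `"negative"`.
#' @param config a [synthetic_config()].
#' @param index substream index (default 1).
#' @return A [pssm_profile].
#' @export
generate_profile <- function(length, label, config, index = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  label <- as.character(as_binary_labels(label))
  if (length < 9L) stop("sequence length must be at least 9")
  n <- as.integer(length)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(config$seed, index))

  residues <- sample(AA_ALPHABET, n, replace = TRUE)
  scores <- matrix(round(rnorm(n * 20L, mean = 0, sd = 2)), nrow = n)

  if (config$signal_mode == "order" && config$effect_size > 0) {
    m <- config$motif_length
    half <- n %/% 2L
    start1 <- sample.int(half - m + 1L, 1L)
    start2 <- half + sample.int(n - half - m + 1L, 1L)
    s1 <- if (label == "positive") config$effect_size else -config$effect_size
    scores[start1:(start1 + m - 1L), ] <- scores[start1:(start1 + m - 1L), ] + s1
    scores[start2:(start2 + m - 1L), ] <- scores[start2:(start2 + m - 1L), ] - s1
  } else if (config$signal_mode == "composition" &&
             config$effect_size > 0 && label == "positive") {
    scores[, COMPOSITION_COLUMNS] <-
      scores[, COMPOSITION_COLUMNS] + config$effect_size
  }
  pssm_profile(sprintf("syn%06d_%s", index, substr(label, 1L, 3L)),
               residues, clip_scores(scores))
}

#' Generate a labeled synthetic dataset
#'
#' Draws `n_positive + n_negative` profiles (positives first) with lengths
#' uniform over `length_range`, independent of the label. Given the same
#' config (including seed) the result is bitwise identical.
#'
#' @param config a [synthetic_config()].
#' @return A [labeled_dataset()]; `metadata$config` stores the generator
#'   settings.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_positive + config$n_negative
  labels <- rep(c("positive", "negative"),
                c(config$n_positive, config$n_negative))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(config$seed, 0L))
  lens <- sample(seq(config$length_range[1L], config$length_range[2L]),
                 n, replace = TRUE)
  profiles <- lapply(seq_len(n), function(i)
    generate_profile(lens[i], labels[i], config, index = i))
  labeled_dataset(profiles, labels, metadata = list(config = unclass(config)))
}

# Save/restore the global RNG stream so generation is a pure function of
# the config and does not disturb the caller's RNG state.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
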