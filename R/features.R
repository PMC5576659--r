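## Feature channels fused by the SVM.  Canonical channel order (fixed, part
## of the model contract): ID_AA, S_P, SS_FREQ, S_SS, S_H, S_C, S_SA.

CHANNELS <- c("ID_AA", "S_P", "SS_FREQ", "S_SS", "S_H", "S_C", "S_SA")

channel_column <- c(
  S_P = "residues", S_SS = "ss3", S_H = "hydro6", S_C = "charge3",
  S_SA = "sa4"
)
channel_alphabet_name <- c(
  S_P = "residue21", S_SS = "ss3", S_H = "hydro6", S_C = "charge3",
  S_SA = "sa4"
)

#' Validate and order a channel configuration
#'
#' @param channels character vector, subset of
#'   `ID_AA, S_P, SS_FREQ, S_SS, S_H, S_C, S_SA` (case-insensitive).
#' @return channels in canonical order.
#' @export
feature_config <- function(channels) {
  ch <- toupper(channels)
  bad <- setdiff(ch, CHANNELS)
  if (length(bad)) {
    stop("unknown channel(s): ", paste(bad, collapse = ", "),
      "; available: ", paste(CHANNELS, collapse = ", "),
      call. = FALSE
    )
  }
  if (!length(ch)) stop("at least one channel is required", call. = FALSE)
  CHANNELS[CHANNELS %in% ch]
}

#' Per-ion channel presets
#'
#' Encodes which feature blocks are worth fitting per ion: the five
#' conservation-sensitive transition metals (Zn, Cu, Fe2, Fe3, Co) default
#' to the PWSM-only pathway (channel `S_P`, classified by paired matrix
#' scores); the others use the full fused vector, except Mn which drops the
#' polarization-charge block (`S_C`) — dropping it leaves accuracy
#' essentially unchanged.  For Ca the hydropathy block is uninformative in
#' isolation but contributes within the full model, so it is kept.
#' Presets are defaults, not restrictions.
#'
#' @param ion ion label as in [ion_window()].
#' @return list with `channels` (canonical order) and `classifier`
#'   (`"pwsm"` or `"svm"`).
#' @export
ion_preset <- function(ion) {
  key <- tolower(ion)
  pwsm_ions <- c("zn", "cu", "fe2", "fe3", "co")
  if (key %in% pwsm_ions) {
    return(list(channels = "S_P", classifier = "pwsm"))
  }
  full <- CHANNELS
  if (key == "mn") full <- setdiff(full, "S_C")
  list(channels = feature_config(full), classifier = "svm")
}

#' Fit the channel models on training segments
#'
#' Fits, per enabled channel: a [pwsm_pair()] on the corresponding channel
#' strings (`S_P` residues, `S_H` hydropathy, `S_C` charge, `S_SS`
#' secondary structure, `S_SA` binned solvent accessibility), and for
#' `ID_AA` the positive/negative composition count sources.  `SS_FREQ`
#' needs no fitting.  All models must be fitted on training-fold segments
#' only; refit per fold inside cross-validation.
#'
#' @param segments a labeled `metseg_segments` data frame containing both
#'   classes and every column the requested channels need.
#' @param channels a [feature_config()].
#' @param background background mode passed to [pwsm_pair()].
#' @return object of class `channel_models`.
#' @export
fit_channel_models <- function(segments, channels, background = "pooled") {
  channels <- feature_config(channels)
  pos <- segments$label == "positive"
  if (sum(pos) < 2L || sum(!pos) < 2L) {
    stop("need at least 2 segments of each class", call. = FALSE)
  }
  models <- list()
  for (ch in setdiff(channels, c("ID_AA", "SS_FREQ"))) {
    col <- channel_column[[ch]]
    if (is.null(segments[[col]])) {
      stop(
        "channel ", ch, " requires segment column '", col,
        "' (missing annotation)",
        call. = FALSE
      )
    }
    models[[ch]] <- pwsm_pair(
      segments[[col]][pos], segments[[col]][!pos],
      metseg_alphabet(channel_alphabet_name[[ch]]),
      background = background
    )
  }
  if ("ID_AA" %in% channels) {
    cc <- composition_counts(segments$residues)
    models$ID_AA <- list(
      positive = colSums(cc[pos, , drop = FALSE]),
      negative = colSums(cc[!pos, , drop = FALSE])
    )
  }
  if ("SS_FREQ" %in% channels && is.null(segments$ss3)) {
    stop("channel SS_FREQ requires segment column 'ss3' (missing annotation)",
      call. = FALSE
    )
  }
  structure(
    list(channels = channels, L = attr(segments, "L"), models = models),
    class = "channel_models"
  )
}

ss_frequencies <- function(ss3) {
  cc <- composition_counts(ss3, metseg_alphabet("ss3"))
  real <- cc[, c("H", "E", "C"), drop = FALSE]
  tot <- rowSums(real)
  out <- real / ifelse(tot > 0, tot, 1)
  colnames(out) <- c("ss_h", "ss_e", "ss_c")
  out
}

#' Build the fused feature matrix
#'
#' Concatenates, in canonical channel order: the `ID_AA` 2-vector, the `S_P`
#' score pair, the `SS_FREQ` 3-vector (H/E/C frequencies over non-padding
#' positions), and the `S_SS`, `S_H`, `S_C`, `S_SA` score pairs — e.g.
#' dimension 15 for the full set.  Deterministic; dropping a channel yields
#' exactly the sub-layout of the full vector.
#'
#' @param segments a `metseg_segments` data frame.
#' @param models a [fit_channel_models()] result.
#' @return numeric matrix `n x dim` with a `layout` attribute mapping each
#'   channel to its column indices; row order follows `segments`.
#' @export
featurize_segments <- function(segments, models) {
  stopifnot(inherits(models, "channel_models"))
  blocks <- list()
  for (ch in models$channels) {
    if (ch == "ID_AA") {
      cc <- composition_counts(segments$residues)
      b <- id_features(cc, models$models$ID_AA$positive, models$models$ID_AA$negative)
      colnames(b) <- c("id_aa_pos", "id_aa_neg")
    } else if (ch == "SS_FREQ") {
      if (is.null(segments$ss3)) {
        stop("segments lack 'ss3' required by SS_FREQ", call. = FALSE)
      }
      b <- ss_frequencies(segments$ss3)
    } else {
      col <- channel_column[[ch]]
      if (is.null(segments[[col]])) {
        stop("segments lack '", col, "' required by ", ch, call. = FALSE)
      }
      pair <- models$models[[ch]]
      b <- cbind(
        score_segments(pair$positive, segments[[col]]),
        score_segments(pair$negative, segments[[col]])
      )
      colnames(b) <- paste0(tolower(ch), c("_pos", "_neg"))
    }
    blocks[[ch]] <- b
  }
  out <- do.call(cbind, blocks)
  stopifnot(all(is.finite(out)))
  k <- 0L
  layout <- list()
  for (ch in models$channels) {
    w <- ncol(blocks[[ch]])
    layout[[ch]] <- seq.int(k + 1L, k + w)
    k <- k + w
  }
  attr(out, "layout") <- layout
  rownames(out) <- NULL
  out
}

#' Write a feature matrix to disk
#'
#' Dense TSV (header = column layout, first column the label) or sparse
#' libsvm text format (`label index:value ...`, 1-based indices).
#'
#' @param x feature matrix from [featurize_segments()].
#' @param labels character or +/-1 labels, one per row.
#' @param path output path.
#' @param format `"tsv"` or `"libsvm"`.
#' @return `path`, invisibly.
#' @export
write_features <- function(x, labels, path, format = c("tsv", "libsvm")) {
  format <- match.arg(format)
  y <- if (is.numeric(labels)) labels else ifelse(labels == "positive", 1L, -1L)
  if (format == "tsv") {
    df <- data.frame(label = y, x, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- vapply(seq_len(nrow(x)), function(i) {
      v <- x[i, ]
      nz <- which(v != 0)
      paste(y[i], paste0(nz, ":", formatC(v[nz], format = "g", digits = 10),
        collapse = " "
      ))
    }, "")
    writeLines(lines, path)
  }
  invisible(path)
}
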