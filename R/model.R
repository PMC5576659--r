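## Evaluation protocol: Sn/Sp/Acc/MCC, balanced negative subsampling,
## repeated 5-fold cross-validation, final model training and per-residue
## prediction.  All randomness flows from one master seed through
## derive_seed(); the global RNG state is saved and restored around every
## internal draw.

derive_seed <- function(seed, a, b = 0L) {
  as.integer((as.double(seed) * 100003 + a * 10007 + b * 101) %% 2147483647)
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Confusion counts of a binary prediction
#'
#' @param predicted,truth character vectors over
#'   `{"positive","negative"}` of equal length.
#' @return named integer vector `TP, TN, FP, FN`.
#' @export
confusion_counts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  c(
    TP = sum(predicted == "positive" & truth == "positive"),
    TN = sum(predicted == "negative" & truth == "negative"),
    FP = sum(predicted == "positive" & truth == "negative"),
    FN = sum(predicted == "negative" & truth == "positive")
  )
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)` and accuracy
#' `Acc = (TP+TN)/total`, all in percent, plus the Matthews correlation
#' coefficient `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`
#' in `[-1,1]`.  A metric whose denominator is zero is reported as `NA`
#' (undefined), never as a silent zero.
#'
#' @param counts named vector or list with elements `TP`, `TN`, `FP`, `FN`.
#' @return named numeric vector `Sn, Sp, Acc, MCC` (percent scale for the
#'   first three).
#' @export
metseg_metrics <- function(counts) {
  tp <- as.double(counts[["TP"]])
  tn <- as.double(counts[["TN"]])
  fp <- as.double(counts[["FP"]])
  fn <- as.double(counts[["FN"]])
  if (any(c(tp, tn, fp, fn) < 0)) stop("negative confusion counts", call. = FALSE)
  total <- tp + tn + fp + fn
  sn <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  acc <- if (total > 0) 100 * (tp + tn) / total else NA_real_
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else NA_real_
  c(Sn = sn, Sp = sp, Acc = acc, MCC = mcc)
}

#' Balanced negative subsampling
#'
#' Uniform sample, without replacement, of `n_positives` elements of
#' `negatives`, reproducible from `rep_seed`.  Used to draw a
#' class-balanced training set from heavily imbalanced binding-site data;
#' the protocol repeats it (default ten times) and averages.
#'
#' @param negatives vector (e.g. of segment row indices).
#' @param n_positives sample size.
#' @param rep_seed integer seed for this repetition.
#' @return subset of `negatives` of length `n_positives`.
#' @export
balanced_subsample <- function(negatives, n_positives, rep_seed) {
  if (length(negatives) < n_positives) {
    stop("fewer negatives (", length(negatives), ") than positives (",
      n_positives, ")",
      call. = FALSE
    )
  }
  idx <- with_seed(rep_seed, sample.int(length(negatives), n_positives))
  negatives[idx]
}

assign_folds <- function(segments, rows, n_folds, fold_seed, group_by_chain) {
  fold <- integer(length(rows))
  if (group_by_chain) {
    ch <- segments$chain_id[rows]
    uch <- unique(ch)
    perm <- with_seed(fold_seed, sample(length(uch)))
    chain_fold <- integer(length(uch))
    chain_fold[perm] <- rep(seq_len(n_folds), length.out = length(uch))
    fold <- chain_fold[match(ch, uch)]
  } else {
    perm <- with_seed(fold_seed, sample(length(rows)))
    fold[perm] <- rep(seq_len(n_folds), length.out = length(rows))
  }
  fold
}

segments_L <- function(segments) {
  attr(segments, "L") %||% nchar(segments$residues[1L])
}

fit_and_eval_fold <- function(segments, train_rows, test_rows, channels,
                              classifier, cost, gamma, scale_range,
                              background) {
  tr <- segments[train_rows, , drop = FALSE]
  te <- segments[test_rows, , drop = FALSE]
  attr(tr, "L") <- attr(te, "L") <- segments_L(segments)
  class(tr) <- class(te) <- c("metseg_segments", "data.frame")
  if (classifier == "pwsm") {
    pos <- tr$label == "positive"
    pair <- pwsm_pair(tr$residues[pos], tr$residues[!pos],
      metseg_alphabet("residue21"),
      background = background
    )
    pred <- classify_segments(pair, te$residues)$label
  } else {
    models <- fit_channel_models(tr, channels, background = background)
    xtr <- featurize_segments(tr, models)
    sc <- fit_scaling(xtr, scale_range[1L], scale_range[2L])
    fit <- svm_fit(apply_scaling(sc, xtr), tr$label, cost = cost, gamma = gamma)
    pred <- svm_predict(fit, apply_scaling(sc, featurize_segments(te, models)))
  }
  confusion_counts(pred, te$label)
}

#' Balanced-subsampling repeated cross-validation
#'
#' The protocol: for each of `n_reps` repetitions, draw negatives to match
#' the positive count ([balanced_subsample()]), shuffle the balanced set
#' into `n_folds` folds, and for each fold fit everything — channel models,
#' feature scaling, SVM — on the other folds only and evaluate on the
#' held-out fold.  The headline figures average the per-fold metrics over
#' all `n_folds * n_reps` evaluations; pooled-count metrics are reported
#' alongside for transparency.
#'
#' @param segments labeled `metseg_segments` data frame (both classes).
#' @param channels channel set (see [feature_config()]); ignored when
#'   `classifier = "pwsm"`, which uses the residue matrices alone.
#' @param classifier `"svm"` (fused channels) or `"pwsm"` (paired-matrix
#'   score comparison only).
#' @param n_folds,n_reps protocol sizes (defaults 5 and 10).
#' @param seed master seed; every subsample and fold shuffle derives from it.
#' @param cost,gamma SVM parameters (defaults: 1 and 1/dim).
#' @param scale_range feature scaling target range.
#' @param background PWSM background mode (`"pooled"` or `"uniform"`).
#' @param group_by_chain if `TRUE`, folds are assigned at chain level so
#'   segments of one chain never straddle folds (stricter than the default
#'   segment-level protocol; recommended for chain-level claims).
#' @return object of class `metseg_report`: `folds` (per-rep, per-fold
#'   counts and metrics), `summary` (mean per-fold metrics), `pooled`
#'   (metrics of summed counts), `meta`.
#' @export
cross_validate <- function(segments, channels = "S_P",
                           classifier = c("svm", "pwsm"),
                           n_folds = 5L, n_reps = 10L, seed = 1L,
                           cost = 1, gamma = NULL, scale_range = c(-1, 1),
                           background = "pooled", group_by_chain = FALSE) {
  classifier <- match.arg(classifier)
  if (classifier == "svm") channels <- feature_config(channels)
  pos_rows <- which(segments$label == "positive")
  neg_rows <- which(segments$label == "negative")
  if (length(pos_rows) < n_folds) {
    stop("need at least ", n_folds, " positive segments", call. = FALSE)
  }
  rows <- vector("list", n_reps * n_folds)
  k <- 0L
  for (r in seq_len(n_reps)) {
    bal <- c(
      pos_rows,
      balanced_subsample(neg_rows, length(pos_rows), derive_seed(seed, r))
    )
    fold <- assign_folds(
      segments, bal, n_folds, derive_seed(seed, r, 1L),
      group_by_chain
    )
    for (f in seq_len(n_folds)) {
      cc <- fit_and_eval_fold(
        segments, bal[fold != f], bal[fold == f],
        channels, classifier, cost, gamma, scale_range, background
      )
      k <- k + 1L
      rows[[k]] <- data.frame(
        rep = r, fold = f,
        TP = cc[["TP"]], TN = cc[["TN"]], FP = cc[["FP"]], FN = cc[["FN"]],
        t(metseg_metrics(cc))
      )
    }
  }
  folds <- do.call(rbind, rows)
  pooled <- metseg_metrics(colSums(folds[c("TP", "TN", "FP", "FN")]))
  structure(
    list(
      folds = folds,
      summary = colMeans(folds[c("Sn", "Sp", "Acc", "MCC")], na.rm = TRUE),
      pooled = pooled,
      meta = list(
        classifier = classifier,
        channels = if (classifier == "svm") channels else "S_P",
        L = segments_L(segments), n_folds = n_folds, n_reps = n_reps,
        seed = seed, cost = cost,
        gamma = gamma %||% "1/dim",
        scale_range = scale_range, background = background,
        group_by_chain = group_by_chain,
        n_positive = length(pos_rows), n_negative = length(neg_rows)
      )
    ),
    class = "metseg_report"
  )
}

#' @export
print.metseg_report <- function(x, ...) {
  m <- x$meta
  cat(
    "<metseg_report> ", m$classifier, " classifier, L=", m$L,
    ", ", m$n_folds, "-fold x ", m$n_reps, " reps, seed ", m$seed, "\n",
    "  channels: ", paste(m$channels, collapse = "+"), "\n",
    "  mean per-fold:  Sn ", fmt_pct(x$summary[["Sn"]]),
    "  Sp ", fmt_pct(x$summary[["Sp"]]),
    "  Acc ", fmt_pct(x$summary[["Acc"]]),
    "  MCC ", round(x$summary[["MCC"]], 3), "\n",
    "  pooled counts:  Sn ", fmt_pct(x$pooled[["Sn"]]),
    "  Sp ", fmt_pct(x$pooled[["Sp"]]),
    "  Acc ", fmt_pct(x$pooled[["Acc"]]),
    "  MCC ", round(x$pooled[["MCC"]], 3), "\n",
    sep = ""
  )
  invisible(x)
}

fmt_pct <- function(x) if (is.na(x)) "NA" else paste0(round(x, 1), "%")

#' Train the final prediction model
#'
#' Draws one balanced training set (all positives plus a matched negative
#' subsample), fits the channel models, the feature scaling and — unless
#' `classifier = "pwsm"` — the C-SVC, and returns a self-contained bundle
#' from which [predict_chain()] can score any annotated chain.
#'
#' @inheritParams cross_validate
#' @param ion optional ion label stored in the bundle (also sets the default
#'   window via [ion_window()] at the CLI level).
#' @param balance draw a balanced negative subsample (default); `FALSE`
#'   trains on all segments as given.
#' @return object of class `metseg_model`.
#' @export
train_final <- function(segments, channels = "S_P",
                        classifier = c("svm", "pwsm"), seed = 1L,
                        ion = NULL, cost = 1, gamma = NULL,
                        scale_range = c(-1, 1), background = "pooled",
                        balance = TRUE) {
  classifier <- match.arg(classifier)
  pos_rows <- which(segments$label == "positive")
  neg_rows <- which(segments$label == "negative")
  if (!length(pos_rows) || !length(neg_rows)) {
    stop("training data must contain both classes", call. = FALSE)
  }
  rows <- if (balance && length(neg_rows) > length(pos_rows)) {
    c(pos_rows, balanced_subsample(neg_rows, length(pos_rows), derive_seed(seed, 0L)))
  } else {
    c(pos_rows, neg_rows)
  }
  tr <- segments[rows, , drop = FALSE]
  attr(tr, "L") <- segments_L(segments)
  class(tr) <- c("metseg_segments", "data.frame")
  fit_channels <- if (classifier == "svm") {
    feature_config(channels)
  } else {
    "S_P"
  }
  models <- fit_channel_models(tr, fit_channels, background = background)
  scaling <- NULL
  fit <- NULL
  if (classifier == "svm") {
    xtr <- featurize_segments(tr, models)
    scaling <- fit_scaling(xtr, scale_range[1L], scale_range[2L])
    fit <- svm_fit(apply_scaling(scaling, xtr), tr$label,
      cost = cost, gamma = gamma
    )
  }
  structure(
    list(
      ion = ion, L = segments_L(segments),
      channels = models$channels, classifier = classifier,
      models = models, scaling = scaling, svm = fit,
      meta = list(
        seed = seed, cost = cost, background = background,
        n_positive = length(pos_rows), n_train = length(rows)
      )
    ),
    class = "metseg_model"
  )
}

#' @export
print.metseg_model <- function(x, ...) {
  cat(
    "<metseg_model> ", x$classifier, " model",
    if (!is.null(x$ion)) paste0(" for ", x$ion) else "",
    ": L=", x$L, ", channels ", paste(x$channels, collapse = "+"),
    ", trained on ", x$meta$n_train, " segments\n",
    sep = ""
  )
  invisible(x)
}

#' Predict binding residues along a chain
#'
#' Windows every residue of the chain, featurizes each segment with the
#' bundle's channel models, applies the training-fold scaling, and labels by
#' SVM decision value (or, for a PWSM-only bundle, by paired matrix score
#' comparison).
#'
#' @param model a [train_final()] bundle (possibly reloaded with
#'   [read_model()]).
#' @param chain a [protein_chain()] carrying whatever annotations the
#'   bundle's channels require.
#' @return `data.frame` with columns `chain_id`, `position`, `residue`,
#'   `call`, `s_pos`, `s_neg`, `svm_decision`.
#' @export
predict_chain <- function(model, chain) {
  stopifnot(inherits(model, "metseg_model"), inherits(chain, "protein_chain"))
  segs <- extract_segments(chain, model$L)
  s_pair <- model$models$models$S_P
  s_pos <- s_neg <- rep(NA_real_, nrow(segs))
  if (!is.null(s_pair)) {
    s_pos <- score_segments(s_pair$positive, segs$residues)
    s_neg <- score_segments(s_pair$negative, segs$residues)
  }
  if (model$classifier == "pwsm") {
    call <- ifelse(s_pos > s_neg, "positive", "negative")
    dec <- rep(NA_real_, nrow(segs))
  } else {
    x <- featurize_segments(segs, model$models)
    dec <- svm_decision(model$svm, apply_scaling(model$scaling, x))
    call <- ifelse(dec > 0, "positive", "negative")
  }
  data.frame(
    chain_id = segs$chain_id, position = segs$center,
    residue = substring(chain$sequence, segs$center, segs$center),
    call = call, s_pos = s_pos, s_neg = s_neg, svm_decision = dec,
    stringsAsFactors = FALSE
  )
}

## ---- model bundle serialization (plain text directory) ------------------

g17 <- function(x) sprintf("%.17g", x)

#' Save / load a model bundle
#'
#' The bundle is a directory of plain-text files: a JSON manifest (protocol
#' parameters, scaling ranges, composition sources, SVM coefficients), one
#' inspectable matrix file per PWSM (see [write_pwsm()]) and a TSV of
#' support vectors.  Numeric values are written with 17 significant digits,
#' so save / load / predict round-trips bit-exactly.
#'
#' @param model a [train_final()] bundle.
#' @param dir directory path (created if needed).
#' @return `write_model` returns `dir` invisibly; `read_model` the rebuilt
#'   `metseg_model`.
#' @export
write_model <- function(model, dir) {
  stopifnot(inherits(model, "metseg_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format = "metseg-model-1",
    ion = model$ion, classifier = model$classifier,
    L = model$L, channels = model$channels,
    meta = model$meta
  )
  for (ch in setdiff(model$channels, c("ID_AA", "SS_FREQ"))) {
    pair <- model$models$models[[ch]]
    write_pwsm(pair$positive, file.path(dir, paste0("pwsm_", ch, "_positive.txt")))
    write_pwsm(pair$negative, file.path(dir, paste0("pwsm_", ch, "_negative.txt")))
  }
  if ("ID_AA" %in% model$channels) {
    manifest$id_sources <- list(
      alphabet = paste(metseg_alphabet("residue21"), collapse = ""),
      positive = as.numeric(model$models$models$ID_AA$positive),
      negative = as.numeric(model$models$models$ID_AA$negative)
    )
  }
  if (!is.null(model$scaling)) {
    manifest$scaling <- list(
      min = g17(model$scaling$min), max = g17(model$scaling$max),
      lower = model$scaling$lower, upper = model$scaling$upper
    )
  }
  if (!is.null(model$svm)) {
    manifest$svm <- list(
      rho = g17(model$svm$rho), gamma = g17(model$svm$gamma),
      cost = model$svm$cost, n_train = model$svm$n_train,
      iterations = model$svm$iterations
    )
    sv <- data.frame(coef = g17(model$svm$coef))
    svm_mat <- model$svm$sv
    for (j in seq_len(ncol(svm_mat))) {
      sv[[paste0("f", j)]] <- g17(svm_mat[, j])
    }
    utils::write.table(sv, file.path(dir, "svm_sv.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
    simplifyVector = TRUE
  )
  if (!identical(manifest$format, "metseg-model-1")) {
    stop("not a metseg model bundle: ", dir, call. = FALSE)
  }
  channels <- manifest$channels
  models <- list()
  for (ch in setdiff(channels, c("ID_AA", "SS_FREQ"))) {
    models[[ch]] <- structure(
      list(
        positive = read_pwsm(file.path(dir, paste0("pwsm_", ch, "_positive.txt"))),
        negative = read_pwsm(file.path(dir, paste0("pwsm_", ch, "_negative.txt")))
      ),
      class = "pwsm_pair"
    )
  }
  if ("ID_AA" %in% channels) {
    alpha <- chars(manifest$id_sources$alphabet)
    pos <- as.numeric(manifest$id_sources$positive)
    neg <- as.numeric(manifest$id_sources$negative)
    names(pos) <- names(neg) <- alpha
    models$ID_AA <- list(positive = pos, negative = neg)
  }
  scaling <- NULL
  if (!is.null(manifest$scaling)) {
    scaling <- structure(
      list(
        min = as.numeric(manifest$scaling$min),
        max = as.numeric(manifest$scaling$max),
        lower = manifest$scaling$lower, upper = manifest$scaling$upper
      ),
      class = "metseg_scaling"
    )
  }
  fit <- NULL
  if (!is.null(manifest$svm)) {
    sv <- utils::read.table(file.path(dir, "svm_sv.tsv"),
      sep = "\t", header = TRUE, colClasses = "character"
    )
    fit <- structure(
      list(
        sv = as.matrix(as.data.frame(lapply(sv[-1L], as.numeric))),
        coef = as.numeric(sv$coef),
        rho = as.numeric(manifest$svm$rho),
        gamma = as.numeric(manifest$svm$gamma),
        cost = manifest$svm$cost, n_train = manifest$svm$n_train,
        iterations = manifest$svm$iterations
      ),
      class = "metseg_svm"
    )
  }
  structure(
    list(
      ion = manifest$ion, L = manifest$L, channels = channels,
      classifier = manifest$classifier,
      models = structure(
        list(channels = channels, L = manifest$L, models = models),
        class = "channel_models"
      ),
      scaling = scaling, svm = fit, meta = manifest$meta
    ),
    class = "metseg_model"
  )
}

#' Independent-test evaluation
#'
#' Evaluates a trained bundle on an independent segment set *without*
#' balancing: every negative segment is scored, matching the deployment
#' regime where non-binding residues vastly outnumber binding ones.  This
#' is a different protocol from balanced cross-validation and its
#' specificity-driven metrics are not comparable to CV figures.
#'
#' @param model a [train_final()] bundle.
#' @param segments labeled `metseg_segments` data frame.
#' @return list with `counts`, `metrics`.
#' @export
evaluate_independent <- function(model, segments) {
  stopifnot(inherits(model, "metseg_model"))
  if (model$classifier == "pwsm") {
    pair <- model$models$models$S_P
    pred <- classify_segments(pair, segments$residues)$label
  } else {
    segs <- segments
    attr(segs, "L") <- segments_L(segments)
    class(segs) <- c("metseg_segments", "data.frame")
    x <- featurize_segments(segs, model$models)
    pred <- svm_predict(model$svm, apply_scaling(model$scaling, x))
  }
  cc <- confusion_counts(pred, segments$label)
  list(counts = cc, metrics = metseg_metrics(cc))
}
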