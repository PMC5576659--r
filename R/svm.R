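## C-SVC with RBF kernel on dense feature matrices, plus the range scaling
## step that precedes it.  The dual is solved by the SMO routine in
## src/svm.cpp; defaults mirror the libsvm conventions the protocol assumes
## (cost = 1, gamma = 1/dim, stopping tolerance 1e-3, scaling to [-1, 1]).

#' Fit per-feature range scaling
#'
#' Learns, per column, the affine map sending the training minimum/maximum
#' to `lower`/`upper` (default `[-1, 1]`).  Constant columns map to the
#' midpoint.  Fit on training folds only; the map is order-preserving and
#' applied unchanged to test data (test values may fall outside the range).
#'
#' @param x numeric training matrix.
#' @param lower,upper target range.
#' @return object of class `metseg_scaling`.
#' @export
fit_scaling <- function(x, lower = -1, upper = 1) {
  stopifnot(is.matrix(x), upper > lower)
  structure(
    list(
      min = apply(x, 2L, min), max = apply(x, 2L, max),
      lower = lower, upper = upper
    ),
    class = "metseg_scaling"
  )
}

#' Apply a fitted scaling
#'
#' Refuses to rescale a matrix that has already been scaled (a double
#' application would silently distort every feature).
#'
#' @param scaling a [fit_scaling()] object.
#' @param x matrix with the same columns as the training matrix.
#' @return scaled matrix, tagged with attribute `metseg_scaled`.
#' @export
apply_scaling <- function(scaling, x) {
  stopifnot(inherits(scaling, "metseg_scaling"), is.matrix(x))
  if (isTRUE(attr(x, "metseg_scaled"))) {
    stop("matrix is already scaled; refusing to scale twice", call. = FALSE)
  }
  if (ncol(x) != length(scaling$min)) {
    stop("column count does not match the fitted scaling", call. = FALSE)
  }
  span <- scaling$max - scaling$min
  out <- x
  for (j in seq_len(ncol(x))) {
    if (span[j] > 0) {
      out[, j] <- scaling$lower +
        (x[, j] - scaling$min[j]) / span[j] * (scaling$upper - scaling$lower)
    } else {
      out[, j] <- (scaling$lower + scaling$upper) / 2
    }
  }
  attr(out, "metseg_scaled") <- TRUE
  attr(out, "layout") <- attr(x, "layout")
  out
}

#' Train a C-SVC with RBF kernel
#'
#' Solves the soft-margin dual by SMO on a precomputed kernel matrix.
#' Defaults are the conventional ones: `cost = 1`, `gamma = 1/ncol(x)`,
#' stopping tolerance `1e-3`.  Only support vectors are retained.
#'
#' @param x numeric feature matrix (rows = samples), normally pre-scaled.
#' @param y labels: `"positive"`/`"negative"`, a factor, or +/-1.
#' @param cost soft-margin cost `C > 0`.
#' @param gamma RBF width; default `1/ncol(x)`.
#' @param eps SMO stopping tolerance.
#' @param max_iter iteration guard.
#' @return object of class `metseg_svm` with fields `sv` (support vectors),
#'   `coef` (`alpha_i y_i`), `rho`, `gamma`, `cost`, `iterations`,
#'   `objective`.
#' @export
svm_fit <- function(x, y, cost = 1, gamma = NULL, eps = 1e-3,
                    max_iter = 1e7L) {
  stopifnot(is.matrix(x), nrow(x) >= 2L, cost > 0)
  yy <- to_pm1(y)
  if (length(yy) != nrow(x)) stop("length(y) != nrow(x)", call. = FALSE)
  if (length(unique(yy)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  K <- rbf_kernel_cpp(x, x, gamma)
  fit <- smo_train_cpp(K, as.integer(yy), cost, eps, as.integer(max_iter))
  sv <- fit$alpha > 1e-12
  structure(
    list(
      sv = x[sv, , drop = FALSE],
      coef = fit$alpha[sv] * yy[sv],
      rho = fit$rho, gamma = gamma, cost = cost,
      iterations = fit$iterations, objective = fit$objective,
      n_train = nrow(x)
    ),
    class = "metseg_svm"
  )
}

to_pm1 <- function(y) {
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) stop("numeric labels must be +/-1", call. = FALSE)
    return(as.integer(y))
  }
  y <- as.character(y)
  if (!all(y %in% c("positive", "negative"))) {
    stop("labels must be 'positive'/'negative' or +/-1", call. = FALSE)
  }
  ifelse(y == "positive", 1L, -1L)
}

#' SVM decision values and class predictions
#'
#' `svm_decision` returns `f(x) = sum_i coef_i K(sv_i, x) - rho`;
#' `svm_predict` thresholds it at 0 (`positive` iff `f(x) > 0`).
#'
#' @param model a [svm_fit()] object.
#' @param x matrix of samples on the same (scaled) feature space.
#' @return numeric decision values, or a character label vector.
#' @export
svm_decision <- function(model, x) {
  stopifnot(inherits(model, "metseg_svm"), is.matrix(x))
  if (ncol(x) != ncol(model$sv)) {
    stop("feature dimension mismatch", call. = FALSE)
  }
  K <- rbf_kernel_cpp(x, model$sv, model$gamma)
  drop(K %*% model$coef) - model$rho
}

#' @rdname svm_decision
#' @export
svm_predict <- function(model, x) {
  ifelse(svm_decision(model, x) > 0, "positive", "negative")
}

#' @export
print.metseg_svm <- function(x, ...) {
  cat(
    "<metseg_svm> C-SVC/RBF: ", nrow(x$sv), " SVs of ", x$n_train,
    ", cost=", x$cost, ", gamma=", signif(x$gamma, 4),
    ", iterations=", x$iterations, "\n",
    sep = ""
  )
  invisible(x)
}
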