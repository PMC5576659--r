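test_that("metrics match hand-evaluated confusion counts", {
  m <- metseg_metrics(c(TP = 8, TN = 7, FP = 3, FN = 2))
  expect_equal(m[["Sn"]], 80)
  expect_equal(m[["Sp"]], 70)
  expect_equal(m[["Acc"]], 75)
  expect_equal(m[["MCC"]], 50 / sqrt(9900))
  perfect <- metseg_metrics(c(TP = 5, TN = 9, FP = 0, FN = 0))
  expect_equal(unname(perfect), c(100, 100, 100, 1))
})

test_that("undefined metrics are NA sentinels, never silent zeros", {
  m <- metseg_metrics(c(TP = 0, TN = 10, FP = 0, FN = 0))
  expect_true(is.na(m[["Sn"]]))
  expect_true(is.na(m[["MCC"]]))
  expect_equal(m[["Sp"]], 100)
  expect_error(metseg_metrics(c(TP = -1, TN = 1, FP = 1, FN = 1)), "negative")
})

test_that("metrics agree with a brute-force oracle on random vectors", {
  set.seed(10)
  for (i in 1:200) {
    n <- sample(5:50, 1)
    pred <- sample(c("positive", "negative"), n, replace = TRUE)
    truth <- sample(c("positive", "negative"), n, replace = TRUE)
    cc <- confusion_counts(pred, truth)
    expect_equal(sum(cc), n)
    # brute-force recomputation, element by element
    tp <- tn <- fp <- fn <- 0
    for (j in seq_len(n)) {
      if (pred[j] == "positive" && truth[j] == "positive") tp <- tp + 1
      if (pred[j] == "negative" && truth[j] == "negative") tn <- tn + 1
      if (pred[j] == "positive" && truth[j] == "negative") fp <- fp + 1
      if (pred[j] == "negative" && truth[j] == "positive") fn <- fn + 1
    }
    expect_equal(unname(cc), c(tp, tn, fp, fn))
    m <- metseg_metrics(cc)
    if (!anyNA(m)) {
      expect_equal(m[["Sn"]], 100 * tp / (tp + fn))
      expect_equal(m[["Acc"]], 100 * (tp + tn) / n)
      expect_equal(
        m[["MCC"]],
        (tp * tn - fp * fn) /
          sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
      )
    }
  }
})

test_that("random labels give MCC near zero at large n", {
  set.seed(11)
  n <- 10000
  pred <- sample(c("positive", "negative"), n, replace = TRUE)
  truth <- sample(c("positive", "negative"), n, replace = TRUE)
  expect_lt(abs(metseg_metrics(confusion_counts(pred, truth))[["MCC"]]), 0.05)
})

test_that("balanced subsampling is seeded and without replacement", {
  negs <- paste0("n", 1:100)
  s1 <- balanced_subsample(negs, 10, 7)
  s2 <- balanced_subsample(negs, 10, 7)
  expect_identical(s1, s2)
  expect_equal(length(s1), 10)
  expect_false(anyDuplicated(s1) > 0)
  expect_false(identical(s1, balanced_subsample(negs, 10, 8)))
  expect_error(balanced_subsample(negs[1:5], 10, 1), "fewer negatives")
  # ten repetitions cover well beyond a single subsample
  reps <- unique(unlist(lapply(0:9, function(r) balanced_subsample(negs, 10, r))))
  expect_gt(length(reps), 10)
  # subsampling must not disturb the global RNG stream
  set.seed(123)
  a <- stats::runif(1)
  set.seed(123)
  invisible(balanced_subsample(negs, 10, 7))
  expect_identical(stats::runif(1), a)
})

test_that("channel models are fitted from training folds only", {
  segs <- strong_signal_segments(n_chains = 30)
  pos <- which(segs$label == "positive")
  neg <- balanced_subsample(which(segs$label == "negative"), length(pos), 1)
  bal <- c(pos, neg)
  train <- bal[seq_len(floor(0.8 * length(bal)))]
  tr <- segs[train, ]
  attr(tr, "L") <- 7
  class(tr) <- class(segs)
  models <- fit_channel_models(tr, c("ID_AA", "S_P"))
  n_pos_train <- sum(tr$label == "positive")
  n_neg_train <- sum(tr$label == "negative")
  expect_equal(models$models$S_P$positive$N, n_pos_train)
  expect_equal(models$models$S_P$negative$N, n_neg_train)
  expect_equal(sum(models$models$ID_AA$positive), n_pos_train * 7)
  expect_equal(sum(models$models$ID_AA$negative), n_neg_train * 7)
})

test_that("cross-validation is reproducible and leakage-guarded", {
  segs <- strong_signal_segments(n_chains = 40)
  r1 <- cross_validate(segs, classifier = "pwsm", n_reps = 2, seed = 9)
  r2 <- cross_validate(segs, classifier = "pwsm", n_reps = 2, seed = 9)
  expect_identical(r1$folds, r2$folds)
  expect_false(identical(
    r1$folds,
    cross_validate(segs, classifier = "pwsm", n_reps = 2, seed = 10)$folds
  ))
  expect_equal(nrow(r1$folds), 10) # 5 folds x 2 reps
  npos <- sum(segs$label == "positive")
  fold_sizes <- rowSums(r1$folds[c("TP", "TN", "FP", "FN")])
  # each rep evaluates the whole balanced set, split into near-equal folds
  expect_equal(sum(fold_sizes), 2 * 2 * npos)
  expect_true(all(abs(fold_sizes - 2 * npos / 5) < 1))
  expect_error(
    cross_validate(segs[segs$label == "negative", ][1:50, ], classifier = "pwsm"),
    "positive"
  )
})

test_that("group-by-chain keeps chains within one fold", {
  ds <- generate_dataset(simulation_spec(n_chains = 25, seed = 2, theta = 0.9))
  segs <- extract_segments_all(ds$chains, 7)
  rows <- which(segs$label == "positive")
  fold <- metseg:::assign_folds(segs, rows, 5, 99, group_by_chain = TRUE)
  split_chains <- tapply(fold, segs$chain_id[rows], function(f) length(unique(f)))
  expect_true(all(split_chains == 1))
})

test_that("chain-level grouped CV runs end to end", {
  segs <- strong_signal_segments(n_chains = 50)
  r <- cross_validate(segs,
    classifier = "pwsm", n_reps = 2, seed = 4,
    group_by_chain = TRUE
  )
  expect_gt(r$summary[["MCC"]], 0.5)
})

test_that("an uninformative world yields MCC indistinguishable from zero", {
  spec <- simulation_spec(
    n_chains = 120, seed = 13, theta = 0,
    ss_pos = c(H = 1, E = 1, C = 1), ss_neg = c(H = 1, E = 1, C = 1),
    rsa_pos = list(means = 0.4, sd = 0.2, weights = 1),
    rsa_neg = list(means = 0.4, sd = 0.2, weights = 1)
  )
  segs <- extract_segments_all(generate_dataset(spec)$chains, 7)
  r <- cross_validate(segs,
    channels = c("ID_AA", "S_P", "SS_FREQ", "S_SS", "S_SA"),
    classifier = "svm", n_reps = 3, seed = 14
  )
  expect_lt(abs(r$summary[["MCC"]]), 0.1)
})

test_that("final model recovers planted sites on training chains", {
  ds <- generate_dataset(simulation_spec(
    n_chains = 80, seed = 17,
    theta = 0.95, flank_decay = 1
  ))
  segs <- extract_segments_all(ds$chains, 7)
  model <- train_final(segs,
    channels = c("ID_AA", "S_P", "SS_FREQ", "S_SS", "S_H", "S_C", "S_SA"),
    classifier = "svm", seed = 3, ion = "zn"
  )
  chain <- ds$chains[[1]]
  calls <- predict_chain(model, chain)
  expect_equal(nrow(calls), nchar(chain$sequence))
  expect_equal(
    calls$residue,
    strsplit(chain$sequence, "")[[1]]
  )
  hits <- calls$position[calls$call == "positive"]
  recovered <- mean(chain$binding_positions %in% hits)
  expect_gte(recovered, 0.9)
  # pwsm-only pathway on the same data
  pmodel <- train_final(segs, classifier = "pwsm", seed = 3)
  pcalls <- predict_chain(pmodel, chain)
  expect_true(all(is.na(pcalls$svm_decision)))
  expect_equal(
    pcalls$call,
    ifelse(pcalls$s_pos > pcalls$s_neg, "positive", "negative")
  )
})

test_that("model bundles round-trip through the text directory format", {
  ds <- generate_dataset(simulation_spec(n_chains = 30, seed = 19, theta = 0.9))
  segs <- extract_segments_all(ds$chains, 7)
  model <- train_final(segs,
    channels = c("ID_AA", "S_P", "S_SS", "S_SA"),
    classifier = "svm", seed = 5, ion = "mn"
  )
  dir <- withr::local_tempdir()
  write_model(model, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "pwsm_S_P_positive.txt")))
  back <- read_model(dir)
  chain <- ds$chains[[2]]
  expect_identical(predict_chain(back, chain), predict_chain(model, chain))
  expect_equal(back$ion, "mn")
  # pwsm bundle too
  pm <- train_final(segs, classifier = "pwsm", seed = 5)
  pdir <- withr::local_tempdir()
  write_model(pm, pdir)
  expect_identical(
    predict_chain(read_model(pdir), chain),
    predict_chain(pm, chain)
  )
})

test_that("independent-test evaluation uses the full imbalanced set", {
  segs <- strong_signal_segments(n_chains = 60)
  model <- train_final(segs, classifier = "pwsm", seed = 8)
  ev <- evaluate_independent(model, segs)
  expect_equal(sum(ev$counts), nrow(segs))
  expect_gt(ev$metrics[["Sn"]], 50)
})
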