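test_that("per-class metrics match hand-computed values", {
  # class L: predicted column (TP=3, FP=1), observed row (TP=3, FN=3)
  cm <- confusion_matrix(
    observed = c(rep("L", 6), rep("O", 2)),
    predicted = c("L", "L", "L", "O", "O", "O", "L", "O"))
  expect_equal(class_accuracy(cm, "L"), 3 / 4)
  expect_equal(class_coverage(cm, "L"), 1 / 2)
  expect_equal(gav(cm, "L"), sqrt(0.75 * 0.5))
  expect_equal(round(gav(cm, "L"), 4), 0.6124)
  expect_error(class_accuracy(cm, "Z"), "unknown class")
})

test_that("a diagonal confusion matrix is perfect on every measure", {
  cm <- confusion_matrix(rep(c("A", "B", "C"), 4), rep(c("A", "B", "C"), 4))
  for (cl in c("A", "B", "C")) {
    expect_equal(class_accuracy(cm, cl), 1)
    expect_equal(class_coverage(cm, cl), 1)
    expect_equal(gav(cm, cl), 1)
  }
  expect_equal(overall_q(cm), 1)
})

test_that("a never-predicted class has missing accuracy, zero coverage", {
  cm <- confusion_matrix(c("A", "A", "B"), c("B", "B", "B"),
                         classes = c("A", "B"))
  expect_true(is.na(class_accuracy(cm, "A")))
  expect_equal(class_coverage(cm, "A"), 0)
  expect_true(is.na(gav(cm, "A")))
})

test_that("overall Qn follows the correct/observed ratio", {
  # 2-class confusion [[3,1],[2,4]]
  cm <- confusion_matrix(c(rep("A", 4), rep("B", 6)),
                         c("A", "A", "A", "B", "A", "A", "B", "B", "B", "B"))
  expect_equal(unclass(cm)[1, ], c(A = 3L, B = 1L), ignore_attr = TRUE)
  expect_equal(unclass(cm)[2, ], c(A = 2L, B = 4L), ignore_attr = TRUE)
  expect_equal(overall_q(cm), 0.7)
  # restricted to one class it reduces to that class's coverage
  expect_equal(overall_q(cm, "A"), class_coverage(cm, "A"))
  expect_error(overall_q(cm, character(0)), "empty")
})

test_that("Qn decomposes into prevalence-weighted coverage", {
  set.seed(77)
  obs <- sample(c("A", "B", "C"), 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.6, obs, sample(c("A", "B", "C"), 60, TRUE))
  cm <- confusion_matrix(obs, pred)
  cov <- vapply(rownames(cm), function(l) class_coverage(cm, l), numeric(1))
  prev <- rowSums(cm) / sum(cm)
  expect_equal(overall_q(cm), sum(cov * prev))
})

test_that("bootstrap SE is deterministic, zero for perfect predictions,
           and matches an independent re-implementation", {
  set.seed(5)
  obs <- sample(c("A", "B"), 40, replace = TRUE)
  pred <- ifelse(runif(40) < 0.5, obs, sample(c("A", "B"), 40, TRUE))
  tb <- tibble::tibble(observed = obs, predicted = pred)
  cfg <- eval_config(n_bootstrap = 1000, bootstrap_fraction = 0.5,
                     seed = 11)
  se1 <- bootstrap_se(tb, "accuracy", cfg)
  se2 <- bootstrap_se(tb, "accuracy", cfg)
  expect_identical(se1, se2)

  # independent same-protocol re-implementation
  vals <- numeric(1000)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv)
  set.seed(11)
  m <- ceiling(0.5 * 40)
  for (b in 1:1000) {
    idx <- sample.int(40, m, replace = FALSE)
    vals[b] <- mean(obs[idx] == pred[idx])
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  expect_equal(se1, sd(vals) / sqrt(1000), tolerance = 1e-12)

  perfect <- tibble::tibble(observed = obs, predicted = obs)
  expect_equal(bootstrap_se(perfect, "accuracy", cfg), 0)
  # the conventional bootstrap sd behind the flag
  cfg_sd <- eval_config(n_bootstrap = 1000, bootstrap_fraction = 0.5,
                        seed = 11, se_mode = "sd")
  expect_equal(bootstrap_se(tb, "accuracy", cfg_sd), sd(vals),
               tolerance = 1e-12)
})

test_that("bootstrap sd scales like one over sqrt of subset size", {
  set.seed(9)
  tb <- tibble::tibble(observed = rep("A", 400),
                       predicted = sample(c("A", "B"), 400, TRUE))
  sds <- vapply(c(0.2, 0.8), function(fr) {
    bootstrap_se(tb, "accuracy",
                 eval_config(n_bootstrap = 400, bootstrap_fraction = fr,
                             seed = 3, se_mode = "sd"))
  }, numeric(1))
  # ratio of sds ~ sqrt(m2/m1) = 2, with finite-population shrinkage
  # making the large-fraction draw tighter than iid sampling would
  expect_gt(sds[1] / sds[2], sqrt(0.8 / 0.2) * 0.7)
})

test_that("stratified folds balance classes and partition the data", {
  lab <- tibble::tibble(id = sprintf("p%02d", 1:10),
                        class = rep(c("A", "B"), 5))
  folds <- stratified_kfold(lab, n_folds = 5, seed = 2)
  for (f in folds) {
    expect_length(f$test_ids, 2)
    expect_setequal(c(f$train_ids, f$test_ids), lab$id)
    cls <- lab$class[match(f$test_ids, lab$id)]
    expect_setequal(cls, c("A", "B"))
  }
  expect_setequal(unlist(lapply(folds, `[[`, "test_ids")), lab$id)
  # determinism
  folds2 <- stratified_kfold(lab, n_folds = 5, seed = 2)
  expect_identical(folds, folds2)
  # per-class counts differ by at most one on uneven classes
  lab3 <- tibble::tibble(id = sprintf("q%02d", 1:23),
                         class = rep(c("A", "B", "C"), length.out = 23))
  f3 <- stratified_kfold(lab3, n_folds = 3, seed = 4)
  for (cl in c("A", "B", "C")) {
    counts <- vapply(f3, function(f) {
      sum(lab3$class[match(f$test_ids, lab3$id)] == cl)
    }, integer(1))
    expect_lte(diff(range(counts)), 1)
  }
  expect_error(stratified_kfold(lab[1:3, ], n_folds = 5), "fewer proteins")
  expect_warning(stratified_kfold(
    tibble::tibble(id = c("a", "b", "c", "d", "e", "f"),
                   class = c("A", "A", "A", "A", "A", "B")),
    n_folds = 3, seed = 1), "fewer members")
})

test_that("cross-validation reports strong recovery on the clean set", {
  cv <- strong_bacteria_cv()
  expect_gte(cv$qn, 0.90)
  expect_equal(sort(cv$reported_classes),
               sort(default_topology("bacteria")$leaves))
  expect_equal(nrow(cv$predictions), 300)
  expect_setequal(cv$predictions$id, strong_bacteria_data()$id)
})

test_that("label shuffling collapses accuracy to the prior baseline", {
  cv <- shuffled_bacteria_cv()
  expect_lt(abs(cv$qn - 1 / 6), 0.1)
})

test_that("small classes are excluded from the reported metrics", {
  topo <- default_topology("archaea")
  d <- generate_dataset(synthetic_spec(topo, n_per_class = 25,
                                       seq_length = 60, seed = 91))
  d <- d[!(d$class == "PM" & as.integer(sub("^.*_", "", d$id)) > 10), ]
  expect_message(
    cv <- cross_validate(d, topo, kernel_params(k = 5, sigma = 7.5),
                         eval_config(seed = 6, min_class_size_report = 20)),
    "PM")
  expect_false("PM" %in% cv$metrics$class)
  expect_false("PM" %in% cv$reported_classes)
  # excluded from Qn as well: Qn equals the restricted ratio
  expect_equal(cv$qn, overall_q(cv$confusion, cv$reported_classes))
})

test_that("ri curves match the hand-built three-prediction case", {
  tb <- tibble::tibble(observed = c("A", "A", "A"),
                       predicted = c("A", "B", "A"),
                       ri = c(90, 90, 10))
  rc <- ri_curves(tb)
  at50 <- rc[rc$threshold == 50, ]
  expect_equal(at50$accuracy, 0.5)
  expect_equal(at50$coverage, 0.5)
  at0 <- rc[rc$threshold == 0, ]
  expect_equal(at0$accuracy, 2 / 3)  # overall fraction correct
  expect_equal(at0$coverage, 1)
})

test_that("ri curves: coverage non-increasing, perfect set stays at 1", {
  cv <- noisy_bacteria_cv()
  rc <- ri_curves(cv$predictions)
  expect_true(all(diff(rc$coverage) <= 1e-12))
  expect_equal(rc$coverage[1], 1)
  perfect <- tibble::tibble(observed = c("A", "B"), predicted = c("A", "B"),
                            ri = c(100, 100))
  rp <- ri_curves(perfect)
  expect_true(all(rp$accuracy == 1 & rp$coverage == 1))
  expect_error(ri_curves(tibble::tibble(observed = "A", predicted = "A",
                                        ri = 150)), "\\[0, 100\\]")
})
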