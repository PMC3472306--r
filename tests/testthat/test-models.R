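make_planted_block <- function(n = 200, n_noise = 39, seed = 1) {
  withr::with_seed(seed, {
    labels <- rep(c(1L, 0L), each = n / 2)
    informative <- labels * 2 + rnorm(n, sd = 0.5)
    noise <- matrix(rnorm(n * n_noise), nrow = n)
    colnames(noise) <- paste0("noise", seq_len(n_noise))
    list(features = cbind(data.frame(signal = informative), noise),
         labels = labels)
  })
}

test_that("cfs_select finds the informative column among pure noise", {
  blk <- make_planted_block(seed = 31)
  sel <- cfs_select(blk$features, blk$labels)
  expect_true("signal" %in% sel)
  # merit of the single informative column beats any single noise column
  merits <- vapply(colnames(blk$features), function(col) {
    cfs_merit(blk$features, blk$labels, col)
  }, numeric(1))
  expect_equal(names(which.max(merits)), "signal")
})

test_that("a perfectly correlated duplicate is not retained alongside the original", {
  blk <- make_planted_block(n = 100, n_noise = 5, seed = 32)
  blk$features$copy <- blk$features$signal
  # adding the duplicate never improves the merit: with a perfect duplicate
  # the pair's merit collapses to the single column's (2 rcf / sqrt(2 + 2))
  expect_lte(cfs_merit(blk$features, blk$labels, c("signal", "copy")),
             cfs_merit(blk$features, blk$labels, "signal") + 1e-12)
  sel <- cfs_select(blk$features, blk$labels)
  expect_equal(sum(sel %in% c("signal", "copy")), 1)
})

test_that("cfs_select on two columns equals the exhaustive subset argmax", {
  for (s in 1:10) {
    blk <- withr::with_seed(s, {
      labels <- rep(c(1L, 0L), each = 30)
      data.frame(f1 = labels + rnorm(60, sd = runif(1, 0.3, 3)),
                 f2 = labels + rnorm(60, sd = runif(1, 0.3, 3)))
    })
    labels <- rep(c(1L, 0L), each = 30)
    subsets <- list("f1", "f2", c("f1", "f2"))
    merits <- vapply(subsets, function(ss) cfs_merit(blk, labels, ss),
                     numeric(1))
    expect_equal(sort(cfs_select(blk, labels)),
                 sort(subsets[[which.max(merits)]]))
  }
  expect_error(cfs_select(data.frame(x = rnorm(10)), rep(1, 10)),
               "constant label")
})

test_that("trees separate separable data and stay honest on noise", {
  x <- data.frame(f = c(rnorm(20, -3), rnorm(20, 3)))
  y <- rep(c(0L, 1L), each = 20)
  m <- train_tree(x, y, seed = 1)
  pred <- predict(m, x)
  expect_equal(mean(pred$label == y), 1.0)
  expect_equal(length(tree_split_attributes(m)), 1)

  # permutation null: labels independent of features
  withr::with_seed(33, {
    blk <- data.frame(a = rnorm(200), b = rnorm(200))
    yn <- sample(rep(c(0L, 1L), 100))
    folds <- sample(rep(1:10, 20))
  })
  mn <- train_tree(blk, yn, seed = 2)
  expect_lte(sum(mn$tree$frame$var == "<leaf>"), 3)
  acc <- mean(vapply(1:10, function(k) {
    mk <- train_tree(blk[folds != k, ], yn[folds != k], seed = k)
    mean(predict(mk, blk[folds == k, ])$label == yn[folds == k])
  }, numeric(1)))
  expect_gt(acc, 0.35)
  expect_lt(acc, 0.65)

  expect_error(train_tree(x, rep(1L, 40)), "both classes")
})

test_that("tree training is deterministic under a fixed seed", {
  blk <- withr::with_seed(34, data.frame(a = rnorm(80), b = rnorm(80)))
  y <- as.integer(blk$a + rnorm(80) > 0)
  p1 <- predict(train_tree(blk, y, seed = 5), blk)
  p2 <- predict(train_tree(blk, y, seed = 5), blk)
  expect_identical(p1, p2)
})

test_that("control cutoffs behave at the extremes and prefer specificity", {
  p <- random_pwm(8, seed = 40)
  segs <- withr::with_seed(41, replicate(60, paste(sample(DNA, 8, TRUE),
                                                   collapse = "")))
  out0 <- control_predict(segs, p, cutoff = 0)
  expect_true(all(out0$label == 1)) # specificity 0
  out2 <- control_predict(segs, p, cutoff = 1.01)
  expect_true(all(out2$label == 0)) # sensitivity 0
  expect_error(control_predict(segs, NULL, 0.5), "PWM")

  # planted PWM data: the selected cutoff is specificity-heavy
  pos <- sample_sites(p, 40, seed = 42)
  scores <- control_predict(c(pos, segs[1:40]), p, 0)$score
  labels <- rep(c(1, 0), each = 40)
  cut <- choose_control_cutoff(scores, labels)
  pred <- as.integer(scores >= cut)
  cm <- compute_metrics(confusion_counts(pred, labels))
  expect_gte(cm$specificity, cm$sensitivity)
  expect_gt(cm$sensitivity, 0)
})

test_that("metrics follow their defining formulas, with NA for empty denominators", {
  m <- compute_metrics(list(TP = 5, FP = 0, TN = 5, FN = 0))
  expect_equal(unlist(m), c(sensitivity = 1, specificity = 1, accuracy = 1))
  m2 <- compute_metrics(list(TP = 3, FP = 2, TN = 2, FN = 1))
  expect_equal(unlist(m2),
               c(sensitivity = 0.75, specificity = 0.5, accuracy = 0.625))
  m3 <- compute_metrics(list(TP = 0, FP = 0, TN = 4, FN = 0))
  expect_true(is.na(m3$sensitivity))
  expect_equal(m3$specificity, 1)

  withr::with_seed(43, {
    for (i in 1:200) {
      cnt <- as.list(setNames(rpois(4, 5) + 1, c("TP", "FP", "TN", "FN")))
      got <- compute_metrics(cnt)
      expect_equal(got$sensitivity, cnt$TP / (cnt$TP + cnt$FN))
      expect_equal(got$specificity, cnt$TN / (cnt$TN + cnt$FP))
      expect_equal(got$accuracy,
                   (cnt$TP + cnt$TN) / (cnt$TP + cnt$TN + cnt$FP + cnt$FN))
    }
  })
})

test_that("compute_auc equals pair counting, with ties at one half", {
  expect_equal(compute_auc(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3)), 1)
  expect_equal(compute_auc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(compute_auc(1:4, rep(1, 4)), "both classes")

  withr::with_seed(44, {
    for (i in 1:40) {
      scores <- sample(seq(0, 1, by = 0.1), 50, replace = TRUE) # many ties
      labels <- rbinom(50, 1, 0.5)
      if (length(unique(labels)) < 2) next
      expect_equal(compute_auc(scores, labels), oracle_auc(scores, labels))
    }
  })
})

test_that("cross-validation is stratified and recovers planted signal", {
  tab <- random_property_table(6, seed = 50)
  catalog <- motif_catalog(character(), numeric())
  # a sharp (strong-consensus) PWM: planted positives are clearly separable
  cons_idx <- withr::with_seed(51, sample(1:4, 10, replace = TRUE))
  freq <- matrix(0.1 / 3, 4, 10)
  freq[cbind(cons_idx, 1:10)] <- 0.9
  p <- pwm(freq)
  pos <- sample_sites(p, 50, seed = 52)
  neg <- withr::with_seed(53, replicate(50, paste(sample(DNA, 10, TRUE),
                                                  collapse = "")))
  inst <- data.frame(instance_id = sprintf("i%03d", 1:100),
                     label = rep(c(1L, 0L), each = 50),
                     sequence = c(pos, neg), stringsAsFactors = FALSE)
  res <- crossvalidate(inst, "sequence", x = p, table = tab,
                       catalog = catalog, seed = 3)
  expect_gte(res$accuracy, 0.95)

  shuffled <- inst
  shuffled$label <- withr::with_seed(54, sample(inst$label))
  res0 <- crossvalidate(shuffled, "structure", table = tab, catalog = catalog,
                        seed = 3)
  expect_gt(res0$accuracy, 0.3)
  expect_lt(res0$accuracy, 0.7)

  folds <- tfbstrio:::stratified_folds(inst$label, 10, seed = 8)
  per_class <- table(folds, inst$label)
  expect_lte(max(per_class) - min(per_class), 1)

  expect_error(crossvalidate(inst[1:15, ], "structure", table = tab,
                             catalog = catalog), "at least 10")
  # single-class input hits the same guard (zero of the other class)
  expect_error(crossvalidate(inst[inst$label == 1, ], "structure", table = tab,
                             catalog = catalog), "at least 10")
  expect_error(crossvalidate(inst, "control", x = NULL, table = tab,
                             catalog = catalog), "requires a PWM")
})

test_that("feature selection sees only the training fold", {
  blk <- make_planted_block(n = 100, n_noise = 10, seed = 60)
  test_rows <- 81:100
  sel1 <- cfs_select(blk$features[-test_rows, ], blk$labels[-test_rows])
  permuted <- blk$features
  permuted[test_rows, ] <- withr::with_seed(61, {
    permuted[sample(test_rows), sample(ncol(permuted))]
  })
  sel2 <- cfs_select(permuted[-test_rows, ], blk$labels[-test_rows])
  expect_identical(sel1, sel2)
})

test_that("run_model_suite produces the expected grid of rows", {
  tab <- random_property_table(4, seed = 70)
  catalog <- motif_catalog("TGACTCA", 12)
  p <- random_pwm(8, seed = 71)
  pos <- sample_sites(p, 12, seed = 72)
  pool <- withr::with_seed(73, replicate(300, paste(sample(DNA, 8, TRUE),
                                                    collapse = "")))
  bundle <- assemble_instance_sets(pos, pool, n_sets = 3, seed = 74)
  with_pwm <- run_model_suite(bundle, x = p, table = tab, catalog = catalog,
                              seed = 7, n_folds = 6)
  expect_equal(nrow(with_pwm$results), 5 * 3)
  without <- run_model_suite(bundle, x = NULL, table = tab, catalog = catalog,
                             seed = 7, n_folds = 6)
  expect_equal(nrow(without$results), 3 * 3)
  expect_false(any(c("control", "sequence") %in% without$results$model))

  summ <- summarize_performance(with_pwm$results)
  expect_equal(nrow(summ), 5 * 4)
  perc <- as.matrix(summ[, c("p5", "p25", "p50", "p75", "p95")])
  expect_true(all(diff(t(perc)) >= -1e-12))
})
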