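#' CFS merit of a feature subset
#'
#' The correlation-based feature selection merit
#' `k * rcf / sqrt(k + k * (k - 1) * rff)`, where `rcf` is the mean absolute
#' feature-class correlation of the subset and `rff` the mean absolute
#' pairwise feature-feature correlation. Higher merit rewards features
#' correlated with the label and penalizes redundancy among them.
#'
#' @param features numeric matrix or data frame of feature columns.
#' @param labels vector coercible to 0/1.
#' @param subset character vector of column names to evaluate.
#' @return the merit (a single number).
#' @export
cfs_merit <- function(features, labels, subset) {
  cors <- cfs_correlations(as.matrix(features), as.numeric(labels))
  cfs_merit_(cors$rcf, cors$rff, match(subset, colnames(features)))
}

cfs_correlations <- function(m, y) {
  if (length(unique(y)) < 2) stop("constant label", call. = FALSE)
  rcf <- abs(suppressWarnings(stats::cor(m, y)))[, 1]
  rcf[is.na(rcf)] <- 0
  rff <- abs(suppressWarnings(stats::cor(m)))
  rff[is.na(rff)] <- 0
  list(rcf = rcf, rff = rff)
}

cfs_merit_ <- function(rcf, rff, idx) {
  k <- length(idx)
  if (k == 0) return(0)
  mean_rcf <- mean(rcf[idx])
  mean_rff <- if (k > 1) {
    sub <- rff[idx, idx, drop = FALSE]
    (sum(sub) - k) / (k * (k - 1))
  } else 0
  k * mean_rcf / sqrt(k + k * (k - 1) * mean_rff)
}

#' Correlation-based feature selection (CFS)
#'
#' Maximizes the CFS merit by best-first forward search: starting from the
#' empty set, the best open subset is expanded by each unused feature;
#' the search stops after `max_stale` consecutive expansions that fail to
#' improve on the best merit seen. The selection never comes back empty: if no
#' subset beats the empty set, the single feature most correlated with the
#' label is returned.
#'
#' @param features numeric matrix or data frame of feature columns.
#' @param labels vector coercible to 0/1; both classes must be present.
#' @param max_stale non-improving expansions tolerated before stopping
#'   (default 5).
#' @return selected column names, in the original (canonical) column order.
#' @export
cfs_select <- function(features, labels, max_stale = 5) {
  m <- as.matrix(features)
  cols <- colnames(m)
  cors <- cfs_correlations(m, as.numeric(labels))
  n <- ncol(m)

  key <- function(idx) paste0("s", paste(sort(idx), collapse = ","))
  open_sets <- list(integer(0))
  open_merit <- 0
  visited <- new.env(parent = emptyenv())
  assign(key(integer(0)), TRUE, envir = visited)
  best_idx <- integer(0)
  best_merit <- 0
  stale <- 0

  while (length(open_sets) > 0 && stale < max_stale) {
    pick <- which.max(open_merit)
    cur <- open_sets[[pick]]
    open_sets <- open_sets[-pick]
    open_merit <- open_merit[-pick]
    improved <- FALSE
    for (f in setdiff(seq_len(n), cur)) {
      cand <- c(cur, f)
      k <- key(cand)
      if (!is.null(visited[[k]])) next
      assign(k, TRUE, envir = visited)
      merit <- cfs_merit_(cors$rcf, cors$rff, cand)
      open_sets[[length(open_sets) + 1]] <- cand
      open_merit <- c(open_merit, merit)
      if (merit > best_merit + 1e-12) {
        best_merit <- merit
        best_idx <- cand
        improved <- TRUE
      }
    }
    stale <- if (improved) 0 else stale + 1
  }
  if (length(best_idx) == 0) best_idx <- which.max(cors$rcf)
  cols[sort(best_idx)]
}

#' Train a decision-tree TFBS identification model
#'
#' Top-down induction with the information (entropy) split criterion and
#' cost-complexity pruning: the tree is grown with `cp = 0` and pruned at the
#' complexity parameter selected by the internal cross-validation 1-SE rule
#' (smallest tree whose risk is within one standard error of the minimum).
#' Training is deterministic under a fixed seed.
#'
#' @param features data frame or matrix of feature columns.
#' @param labels vector coercible to 0/1; both classes must be present.
#' @param config list of overrides for [rpart::rpart.control()] values
#'   (`minsplit`, `minbucket`, `xval`).
#' @param seed integer seed (controls the pruning cross-validation split).
#' @return an object of class `tfbs_model` with elements `kind`,
#'   `feature_columns`, `tree`.
#' @export
train_tree <- function(features, labels, config = list(), seed = 1) {
  df <- as.data.frame(features)
  y <- factor(ifelse(as.numeric(labels) > 0, "pos", "neg"),
              levels = c("neg", "pos"))
  if (nrow(df) < 2) stop("need at least 2 instances", call. = FALSE)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  ctrl <- utils::modifyList(
    list(minsplit = 4, minbucket = 2, xval = 10, cp = 0, maxsurrogate = 0),
    config
  )
  df$.label <- y
  fit <- with_seed(seed, rpart::rpart(
    .label ~ ., data = df, method = "class",
    parms = list(split = "information"),
    control = do.call(rpart::rpart.control, ctrl)
  ))
  cp <- fit$cptable
  if (nrow(cp) > 1 && "xerror" %in% colnames(cp)) {
    thr <- min(cp[, "xerror"]) + cp[which.min(cp[, "xerror"]), "xstd"]
    best <- which(cp[, "xerror"] <= thr)[1] # 1-SE rule: smallest such tree
    fit <- rpart::prune(fit, cp = cp[best, "CP"])
  }
  structure(list(kind = "tree", feature_columns = names(df)[names(df) != ".label"],
                 tree = fit, seed = seed),
            class = "tfbs_model")
}

#' Predict with a trained TFBS model
#'
#' @param object a `tfbs_model`.
#' @param newdata data frame containing the model's feature columns.
#' @param ... unused.
#' @return list with `score` (positive-class probability, the positive-leaf
#'   fraction) and `label` (1/0).
#' @export
predict.tfbs_model <- function(object, newdata, ...) {
  p <- predict(object$tree, as.data.frame(newdata), type = "prob")[, "pos"]
  list(score = unname(p), label = as.integer(p > 0.5))
}

#' Attributes a tree splits on
#'
#' @param model a `tfbs_model`.
#' @return character vector of feature names used in at least one split.
#' @export
tree_split_attributes <- function(model) {
  vars <- as.character(model$tree$frame$var)
  unique(vars[vars != "<leaf>"])
}

#' Control-model cutoff selection
#'
#' Chooses the decision cutoff on the normalized matrix similarity by grid
#' search over the observed training scores: among cutoffs with sensitivity
#' above zero, the one maximizing specificity is taken (ties broken toward the
#' lower cutoff). This yields the specificity-heavy operating point
#' characteristic of threshold-based PWM matching.
#'
#' @param scores numeric training scores ([match_similarity_score()]).
#' @param labels training labels (1/0).
#' @return the selected cutoff.
#' @export
choose_control_cutoff <- function(scores, labels) {
  labels <- as.integer(as.numeric(labels) > 0)
  cand <- sort(unique(scores))
  best_cut <- cand[1]
  best_spec <- -1
  for (cut in cand) {
    pred <- as.integer(scores >= cut)
    sens <- sum(pred == 1 & labels == 1) / max(sum(labels == 1), 1)
    spec <- sum(pred == 0 & labels == 0) / max(sum(labels == 0), 1)
    if (sens > 0 && spec > best_spec + 1e-12) {
      best_spec <- spec
      best_cut <- cut
    }
  }
  best_cut
}

#' Control-model prediction (threshold on normalized PWM similarity)
#'
#' @param segments character vector of DNA segments.
#' @param x a [pwm]; required (the control model is unavailable without a
#'   PWM).
#' @param cutoff decision cutoff in \[0, 1\].
#' @return list with `score` and `label`.
#' @export
control_predict <- function(segments, x, cutoff) {
  if (is.null(x)) {
    stop("control model unavailable without a PWM", call. = FALSE)
  }
  score <- vapply(segments, function(s) {
    if (nchar(s) == x$length) match_similarity_score(s, x)
    else scan_sequence_score(s, x, score_fun = match_similarity_score)
  }, numeric(1), USE.NAMES = FALSE)
  list(score = score, label = as.integer(score >= cutoff))
}

#' Confusion counts from predictions
#'
#' @param predicted predicted labels (1/0).
#' @param actual true labels (1/0).
#' @return list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(predicted, actual) {
  predicted <- as.integer(as.numeric(predicted) > 0)
  actual <- as.integer(as.numeric(actual) > 0)
  list(TP = sum(predicted == 1 & actual == 1),
       FP = sum(predicted == 1 & actual == 0),
       TN = sum(predicted == 0 & actual == 0),
       FN = sum(predicted == 0 & actual == 1))
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`. A metric whose denominator is
#' zero is returned as `NA` (undefined), never silently as 0.
#'
#' @param counts list with `TP`, `FP`, `TN`, `FN` (see [confusion_counts()]).
#' @return list with `sensitivity`, `specificity`, `accuracy`.
#' @export
compute_metrics <- function(counts) {
  with(counts, {
    total <- TP + TN + FP + FN
    list(
      sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
      specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
      accuracy = if (total > 0) (TP + TN) / total else NA_real_
    )
  })
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with ties counted as one half; identical to
#' the trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels true labels (1/0); both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.integer(as.numeric(labels) > 0)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

model_feature_columns <- function(kind, featurized, table) {
  structure_cols <- intersect(rownames(table), names(featurized))
  switch(kind,
    sequence = "sequence_feature",
    structure = structure_cols,
    evolution = "evolution_feature",
    hybrid = feature_columns(featurized),
    stop("unknown model kind: ", kind, call. = FALSE)
  )
}

stratified_folds <- function(labels, n_folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Cross-validated evaluation of one TFBS identification model
#'
#' Runs a stratified k-fold cross-validation of one model kind on a balanced
#' instance set. Features are computed per instance; for the hybrid model,
#' correlation-based feature selection is performed inside each training fold
#' only. Confusion counts are pooled over folds (micro-average) and the AUC is
#' computed from the pooled test-fold scores.
#'
#' @param instances instance-set data frame (columns `instance_id`, `label`,
#'   `sequence`).
#' @param kind one of `"control"`, `"sequence"`, `"structure"`, `"evolution"`,
#'   `"hybrid"`.
#' @param x a [pwm] or `NULL` (required for the control and sequence models;
#'   when `NULL`, the hybrid model uses the 39 remaining columns).
#' @param table a `dinuc_table`.
#' @param catalog a [motif_catalog].
#' @param seed integer seed (fold assignment and tree pruning).
#' @param n_folds number of folds, default 10.
#' @param featurized optional precomputed output of [featurize()] for
#'   `instances` (saves recomputation across model kinds).
#' @return list with `sensitivity`, `specificity`, `accuracy`, `auc`, `counts`
#'   and, for tree models, `trees` (one per fold).
#' @export
crossvalidate <- function(instances, kind, x = NULL, table, catalog, seed = 1,
                          n_folds = 10, featurized = NULL) {
  labels <- as.integer(instances$label)
  if (min(table(factor(labels, levels = c(0, 1)))) < n_folds) {
    stop("need at least ", n_folds, " instances per class for stratified ",
         n_folds, "-fold cross-validation", call. = FALSE)
  }
  if (kind %in% c("control", "sequence") && is.null(x)) {
    stop("the ", kind, " model requires a PWM", call. = FALSE)
  }
  fold <- stratified_folds(labels, n_folds, derive_seed(seed, 101))

  if (kind == "control") {
    scores <- control_predict(instances$sequence, x, cutoff = 0)$score
    pooled_pred <- integer(length(labels))
    for (k in seq_len(n_folds)) {
      test <- fold == k
      cutoff <- choose_control_cutoff(scores[!test], labels[!test])
      pooled_pred[test] <- as.integer(scores[test] >= cutoff)
    }
    counts <- confusion_counts(pooled_pred, labels)
    metrics <- compute_metrics(counts)
    return(c(metrics, list(auc = compute_auc(scores, labels),
                           counts = counts)))
  }

  if (is.null(featurized)) {
    featurized <- featurize(instances, x = x, table = table, catalog = catalog)
  }
  pooled_pred <- integer(length(labels))
  pooled_score <- numeric(length(labels))
  trees <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    test <- fold == k
    cols <- model_feature_columns(kind, featurized, table)
    if (kind == "hybrid") {
      cols <- cfs_select(featurized[!test, feature_columns(featurized),
                                    drop = FALSE],
                         labels[!test])
    }
    model <- train_tree(featurized[!test, cols, drop = FALSE], labels[!test],
                        seed = derive_seed(seed, 200 + k))
    pred <- predict(model, featurized[test, cols, drop = FALSE])
    pooled_pred[test] <- pred$label
    pooled_score[test] <- pred$score
    trees[[k]] <- model
  }
  counts <- confusion_counts(pooled_pred, labels)
  metrics <- compute_metrics(counts)
  c(metrics, list(auc = compute_auc(pooled_score, labels), counts = counts,
                  trees = trees))
}

#' Evaluate all model kinds on a TF's balanced sets
#'
#' For each of the TF's balanced instance sets, evaluates every applicable
#' model under cross-validation: all five kinds (control, sequence, structure,
#' evolution, hybrid) when a PWM is available, otherwise the three kinds that
#' do not need one.
#'
#' @param bundle list of instance-set data frames
#'   (see [assemble_instance_sets()]).
#' @param x a [pwm] or `NULL`.
#' @param table a `dinuc_table`.
#' @param catalog a [motif_catalog].
#' @param seed integer seed.
#' @param n_folds folds per cross-validation, default 10.
#' @param collect_trees also return the per-fold structure/hybrid trees (for
#'   attribute-frequency analysis).
#' @return list with `results` (data frame: `set_id`, `model`, `sensitivity`,
#'   `specificity`, `accuracy`, `auc`) and `trees` (list of `tfbs_model`, or
#'   `NULL`).
#' @export
run_model_suite <- function(bundle, x = NULL, table, catalog, seed = 1,
                            n_folds = 10, collect_trees = FALSE) {
  kinds <- if (is.null(x)) c("structure", "evolution", "hybrid") else
    c("control", "sequence", "structure", "evolution", "hybrid")
  rows <- list()
  trees <- list()
  for (i in seq_along(bundle)) {
    set <- bundle[[i]]
    featurized <- featurize(set, x = x, table = table, catalog = catalog)
    for (kind in kinds) {
      res <- crossvalidate(set, kind, x = x, table = table, catalog = catalog,
                           seed = derive_seed(seed, i), n_folds = n_folds,
                           featurized = featurized)
      rows[[length(rows) + 1]] <- data.frame(
        set_id = set$set_id[1], model = kind,
        sensitivity = res$sensitivity, specificity = res$specificity,
        accuracy = res$accuracy, auc = res$auc, stringsAsFactors = FALSE
      )
      if (collect_trees && kind %in% c("structure", "hybrid")) {
        trees <- c(trees, res$trees)
      }
    }
  }
  list(results = do.call(rbind, rows),
       trees = if (collect_trees) trees else NULL)
}

#' Summarize model performance across sets
#'
#' Mean, standard deviation and the 5th/25th/50th/75th/95th percentiles of
#' each metric, per model kind, across evaluation rows.
#'
#' @param results the `results` data frame of [run_model_suite()] (possibly
#'   concatenated over TFs).
#' @return data frame with one row per (model, metric).
#' @export
summarize_performance <- function(results) {
  metrics <- c("sensitivity", "specificity", "accuracy", "auc")
  out <- list()
  for (m in unique(results$model)) {
    sub <- results[results$model == m, ]
    for (met in metrics) {
      v <- sub[[met]]
      q <- stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), na.rm = TRUE)
      out[[length(out) + 1]] <- data.frame(
        model = m, metric = met, mean = mean(v, na.rm = TRUE),
        sd = stats::sd(v, na.rm = TRUE),
        p5 = q[[1]], p25 = q[[2]], p50 = q[[3]], p75 = q[[4]], p95 = q[[5]],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
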