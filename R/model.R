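# Random-forest pathogenicity classifier.
#
# The TraP score of a variant is the fraction of a 1,000-tree random forest
# voting "pathogenic" (class 1), so a score of 0.45 means exactly 450 trees
# voted pathogenic.  Each split draws floor(sqrt(N)) candidate features.
# Tier thresholds: < 0.459 benign, [0.459, 0.93) possibly damaging,
# >= 0.93 probably damaging; the conservation-free model defaults to
# 0.66 / 0.955.

TRAP_THRESHOLDS <- c(0.459, 0.93)
GERPLESS_THRESHOLDS <- c(0.66, 0.955)
TRAP_MODEL_VERSION <- "1"

#' Train the TraP random forest
#'
#' @param features Data.frame or matrix whose columns include the feature
#'   registry (extra columns are ignored); one row per training variant.
#' @param labels Vector of 0 (benign) / 1 (pathogenic), one per row.
#' @param seed Integer seed; the same seed reproduces the model exactly.
#' @param ntree Number of trees (default 1000).
#' @param registry Feature columns to use, in order (default the 20-feature
#'   registry).
#' @param thresholds Length-2 increasing tier thresholds.
#' @param classwt Optional class weights (`c("0" = ..., "1" = ...)`);
#'   unweighted by default, matching the imbalanced-set default.
#' @return A `trap_model`: list with the fitted forest, `registry`,
#'   `ntree`, `mtry`, `oob_error`, `importance` (mean decrease in Gini),
#'   `thresholds` and `seed`.
#' @export
trap_train <- function(features, labels, seed = 1L, ntree = 1000L,
                       registry = feature_registry(),
                       thresholds = TRAP_THRESHOLDS, classwt = NULL) {
  x <- as.data.frame(features)[, registry, drop = FALSE]
  if (anyNA(x)) stop("NA in feature matrix; impute before training")
  y <- factor(labels, levels = c(0, 1))
  if (anyNA(y)) stop("labels must be 0/1")
  if (length(unique(y)) < 2L || min(table(y)) < 2L)
    stop("need >= 2 rows of each class")
  mtry <- max(1L, floor(sqrt(length(registry))))
  set.seed(as.integer(seed))
  forest <- randomForest::randomForest(
    x = x, y = y, ntree = as.integer(ntree), mtry = mtry,
    importance = FALSE, classwt = classwt)
  imp <- randomForest::importance(forest, type = 2)[, 1]
  structure(list(forest = forest, registry = registry,
                 ntree = as.integer(ntree), mtry = mtry,
                 oob_error = unname(forest$err.rate[forest$ntree, "OOB"]),
                 importance = imp, thresholds = thresholds,
                 seed = as.integer(seed)),
            class = "trap_model")
}

#' Train the conservation-free (GERP-less) model
#'
#' Identical pipeline on the 19-feature registry with `gerp_rs` removed;
#' tier thresholds default to 0.66 / 0.955.
#'
#' @inheritParams trap_train
#' @return A `trap_model` with a 19-feature registry.
#' @export
trap_train_gerpless <- function(features, labels, seed = 1L, ntree = 1000L,
                                thresholds = GERPLESS_THRESHOLDS,
                                classwt = NULL) {
  trap_train(features, labels, seed = seed, ntree = ntree,
             registry = feature_registry(gerpless = TRUE),
             thresholds = thresholds, classwt = classwt)
}

#' @export
print.trap_model <- function(x, ...) {
  cat(sprintf("TraP model: %d trees, mtry=%d, %d features, OOB error %.4f\n",
              x$ntree, x$mtry, length(x$registry), x$oob_error))
  invisible(x)
}

#' Score variants with a trained model
#'
#' @param model A `trap_model`.
#' @param features Data.frame containing the model's registry columns.
#' @param thresholds Tier thresholds (default: the model's).
#' @return A data.frame with columns `trap` (vote fraction in \[0,1\]) and
#'   `tier`.
#' @export
trap_score <- function(model, features, thresholds = model$thresholds) {
  x <- as.data.frame(features)
  missing <- setdiff(model$registry, names(x))
  if (length(missing))
    stop("feature columns missing from input: ",
         paste(missing, collapse = ", "))
  x <- x[, model$registry, drop = FALSE]
  votes <- stats::predict(model$forest, newdata = x, type = "vote",
                          norm.votes = TRUE)
  value <- unname(votes[, "1"])
  data.frame(trap = value,
             tier = trap_classify(value, thresholds),
             stringsAsFactors = FALSE)
}

#' Tier classification of a TraP score
#'
#' @param value Numeric vector of scores in \[0, 1\].
#' @param thresholds Length-2 increasing vector `(t1, t2)` in (0, 1):
#'   `< t1` benign, `[t1, t2)` possibly damaging, `>= t2` probably
#'   damaging.  Defaults to 0.459 / 0.93.
#' @return Character vector of tiers.
#' @export
trap_classify <- function(value, thresholds = TRAP_THRESHOLDS) {
  stopifnot(length(thresholds) == 2L, thresholds[1] < thresholds[2],
            all(thresholds > 0), all(thresholds < 1))
  if (any(is.na(value)) || any(value < 0) || any(value > 1))
    stop("scores must lie in [0, 1]")
  ifelse(value >= thresholds[2], "probably_damaging",
         ifelse(value >= thresholds[1], "possibly_damaging", "benign"))
}

#' Repeated k-fold cross-validated AUC
#'
#' Per repeat: shuffle the rows, split into `folds` unstratified folds,
#' train on each 90% and score the held-out 10%; once every sample is
#' scored, compute one pooled AUC for the repeat.  The mean over repeats is
#' the headline AUC.  A shuffle leaving any training fold single-class is
#' redrawn (with a message).
#'
#' @inheritParams trap_train
#' @param folds Number of folds (default 10).
#' @param repeats Number of shuffles (default 10).  With the same `seed`,
#'   repeat r is identical regardless of the total number of repeats.
#' @return List with `auc` (one per repeat) and `mean_auc`.
#' @export
trap_cv <- function(features, labels, folds = 10L, repeats = 10L,
                    seed = 1L, ntree = 1000L,
                    registry = feature_registry()) {
  x <- as.data.frame(features)[, registry, drop = FALSE]
  y <- as.integer(labels)
  n <- nrow(x)
  if (min(table(y)) < folds) stop("need >= folds rows per class")
  aucs <- numeric(repeats)
  for (r in seq_len(repeats)) {
    set.seed(as.integer(seed) + r - 1L)
    repeat {
      perm <- sample.int(n)
      fold_of <- rep_len(seq_len(folds), n)[order(perm)]
      ok <- all(vapply(seq_len(folds), function(f)
        length(unique(y[fold_of != f])) == 2L, TRUE))
      if (ok) break
      message("re-shuffling: a training fold had a single class")
    }
    scores <- numeric(n)
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      m <- trap_train(x[tr, , drop = FALSE], y[tr],
                      seed = as.integer(seed) + 1000L * r + f,
                      ntree = ntree, registry = registry)
      scores[!tr] <- trap_score(m, x[!tr, , drop = FALSE])$trap
    }
    aucs[r] <- roc_auc(scores, y)$auc
  }
  list(auc = aucs, mean_auc = mean(aucs))
}

#' Feature importances, descending
#'
#' @param model A `trap_model`.
#' @return Data.frame with `feature` and `gini` (mean decrease in Gini),
#'   sorted decreasing.
#' @export
feature_importance <- function(model) {
  imp <- sort(model$importance, decreasing = TRUE)
  data.frame(feature = names(imp), gini = unname(imp),
             stringsAsFactors = FALSE)
}

#' Persist a trained model
#'
#' Writes a versioned archive holding the registry, thresholds, seed and
#' serialized forest; [read_trap_model()] verifies the registry hash on
#' load.
#'
#' @param model A `trap_model`.
#' @param path Output path (`.rds`).
#' @return `path`, invisibly.
#' @export
write_trap_model <- function(model, path) {
  payload <- list(version = TRAP_MODEL_VERSION,
                  registry = model$registry,
                  registry_hash = registry_hash(model$registry),
                  thresholds = model$thresholds,
                  seed = model$seed, model = model)
  saveRDS(payload, path)
  invisible(path)
}

#' Load a model written by [write_trap_model()]
#' @param path Archive path.
#' @return A `trap_model`.
#' @export
read_trap_model <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$version, TRAP_MODEL_VERSION))
    stop("unsupported model archive version: ", payload$version)
  if (!identical(registry_hash(payload$registry), payload$registry_hash))
    stop("model archive registry hash mismatch")
  payload$model
}

# Order-sensitive checksum of the registry names (no digest dependency).
registry_hash <- function(registry) {
  s <- paste(registry, collapse = "|")
  codes <- utf8ToInt(s)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  sprintf("%d:%d", length(registry), h)
}
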