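#' Configuration of the pathomic diversity analysis
#'
#' Defaults follow the study workflow: per-case downscaling to the first
#' image, 1000 stratified 75/25 train-test splits, and a bagged
#' decision-tree ensemble (100 bootstrap-sampled unpruned trees, all
#' features considered at every split — bagging, not a random forest).
#'
#' @param n_iterations number of random splits (default 1000).
#' @param train_fraction per-class training fraction (default 0.75).
#' @param n_trees trees per ensemble (default 100).
#' @param max_depth optional tree depth cap (default unlimited).
#' @param seed integer seed for the whole run.
#' @param downscale keep only the first image per case (default TRUE).
#' @param stratified per-class splits (default TRUE; FALSE draws a single
#'   global split and redraws until every class reaches the training set).
#' @param fpr_grid false-positive-rate grid for vertical ROC averaging.
#' @return A validated `diversity_config` list.
#' @export
diversity_config <- function(n_iterations = 1000L, train_fraction = 0.75,
                             n_trees = 100L, max_depth = NULL, seed = 1L,
                             downscale = TRUE, stratified = TRUE,
                             fpr_grid = seq(0, 1, by = 0.01)) {
  stopifnot(n_iterations >= 1, train_fraction > 0, train_fraction < 1,
            n_trees >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 train_fraction = train_fraction,
                 n_trees = as.integer(n_trees), max_depth = max_depth,
                 seed = as.integer(seed), downscale = downscale,
                 stratified = stratified, fpr_grid = fpr_grid),
            class = "diversity_config")
}

#' Downscale a profile table to the first image of each case
#'
#' Keeps exactly one profile per case: the first image in the case's
#' recorded order — natural-order sort of `image_id` (so `s2` precedes
#' `s10`), overridable via an explicit ordering column.
#'
#' @param profiles profile tibble.
#' @param order_col optional name of a column giving the image order.
#' @return Tibble with one row per case; idempotent.
#' @export
downscale_first_image <- function(profiles, order_col = NULL) {
  stopifnot(all(c("case_id", "image_id") %in% names(profiles)))
  keep <- integer(0)
  for (cid in unique(profiles$case_id)) {
    idx <- which(profiles$case_id == cid)
    ord <- if (is.null(order_col)) natural_order(profiles$image_id[idx])
           else order(profiles[[order_col]][idx])
    keep <- c(keep, idx[ord[1]])
  }
  profiles[sort(keep), ]
}

# training-split size per class: round to nearest, ties away from zero,
# clamped so that every class keeps >= 1 training and >= 1 test case
stratified_train_size <- function(n, frac) {
  pmin(pmax(floor(n * frac + 0.5), 1L), n - 1L)
}

# median imputer fitted on training rows only (anti-leakage boundary)
fit_median_imputer <- function(x) {
  vals <- vapply(x, function(col) {
    m <- stats::median(col[is.finite(col)])
    if (is.finite(m)) m else 0
  }, numeric(1))
  list(values = vals)
}

apply_imputer <- function(x, imputer) {
  for (j in seq_along(x)) {
    bad <- !is.finite(x[[j]])
    if (any(bad)) x[[j]][bad] <- imputer$values[[j]]
  }
  x
}

#' Fit and evaluate one train/test split (lower-level building block)
#'
#' Imputes missing features from training-split medians only, fits the
#' bagged tree ensemble on the training rows and predicts the rest.
#' Exposed so the anti-leakage boundary is directly testable.
#'
#' @param x feature data frame (all rows).
#' @param y factor of class labels.
#' @param train_idx integer indices of the training rows.
#' @param cfg a [diversity_config()].
#' @return List: `imputer`, fitted `model`, test `pred` (factor),
#'   `votes` (matrix of per-class vote fractions), `test_idx`.
#' @export
diversity_split_fit <- function(x, y, train_idx, cfg = diversity_config()) {
  test_idx <- setdiff(seq_len(nrow(x)), train_idx)
  imputer <- fit_median_imputer(x[train_idx, , drop = FALSE])
  xtr <- apply_imputer(x[train_idx, , drop = FALSE], imputer)
  xte <- apply_imputer(x[test_idx, , drop = FALSE], imputer)
  args <- list(x = xtr, y = droplevels_keep(y[train_idx], levels(y)),
               ntree = cfg$n_trees, mtry = ncol(xtr), replace = TRUE,
               nodesize = 1L)
  if (!is.null(cfg$max_depth)) args$maxnodes <- 2L^cfg$max_depth
  model <- do.call(randomForest::randomForest, args)
  votes <- stats::predict(model, xte, type = "prob")
  pred <- factor(colnames(votes)[max.col(votes, ties.method = "first")],
                 levels = levels(y))
  list(imputer = imputer, model = model, pred = pred, votes = votes,
       test_idx = test_idx)
}

# keep full level set (stratification guarantees all levels in training)
droplevels_keep <- function(f, lev) factor(as.character(f), levels = lev)

#' Pathomic diversity: repeated-split bagged-tree classification
#'
#' Stage 2 of the analysis. Over `cfg$n_iterations` random stratified
#' splits: fit a bagged decision-tree ensemble on the training profiles
#' (missing values imputed from training medians), predict the held-out
#' profiles, and accumulate per-(true, predicted) counts. The aggregated
#' confusion matrix reports, per true class, the percentage of test
#' appearances predicted as each class. One-vs-rest ROC curves are
#' vertically averaged on a fixed FPR grid; the per-class AUC is the mean
#' of per-iteration trapezoidal AUCs. Fully reproducible from `cfg$seed`.
#'
#' @param profiles profile tibble ([profile_columns()] layout).
#' @param cfg a [diversity_config()].
#' @return Object of class `diversity_result`: `confusion_counts`,
#'   `confusion_pct`, `test_appearances`, `roc` (class/fpr/tpr tibble),
#'   `auc` (named per-class means), `accuracies`, `config`.
#' @export
run_diversity <- function(profiles, cfg = diversity_config()) {
  if (cfg$downscale) profiles <- downscale_first_image(profiles)
  lev <- intersect(pathomic_entities(), unique(profiles$diagnosis))
  lev <- c(lev, sort(setdiff(unique(profiles$diagnosis), lev)))
  y <- factor(profiles$diagnosis, levels = lev)
  if (nlevels(y) < 2) stopf("need >= 2 classes, have %d", nlevels(y))
  tabn <- table(y)
  if (any(tabn < 2)) {
    stopf("every class needs >= 2 cases for stratified splitting (violated: %s)",
          paste(names(tabn)[tabn < 2], collapse = ", "))
  }
  x <- as.data.frame(profiles[, feature_registry()])
  k <- nlevels(y)
  counts <- matrix(0, k, k, dimnames = list(true = levels(y), predicted = levels(y)))
  appearances <- stats::setNames(numeric(k), levels(y))
  grid <- cfg$fpr_grid
  tpr_sum <- matrix(0, k, length(grid), dimnames = list(levels(y), NULL))
  tpr_n <- auc_sum <- auc_n <- stats::setNames(numeric(k), levels(y))
  accuracies <- numeric(cfg$n_iterations)

  withr::with_seed(child_seed(cfg$seed, "diversity"), {
    for (it in seq_len(cfg$n_iterations)) {
      train_idx <- draw_split(y, cfg)
      fit <- diversity_split_fit(x, y, train_idx, cfg)
      yte <- y[fit$test_idx]
      if (!all(levels(y) %in% as.character(y[train_idx]))) {
        stopf("internal error: class absent from a training split")
      }
      counts <- counts + table(true = yte, predicted = fit$pred)
      appearances <- appearances + as.numeric(table(yte))
      accuracies[it] <- mean(fit$pred == yte)
      for (cl in levels(y)) {
        pos <- yte == cl
        if (!any(pos) || all(pos)) next
        score <- fit$votes[, cl]
        auc_sum[cl] <- auc_sum[cl] + auc_rank(score, pos)
        auc_n[cl] <- auc_n[cl] + 1
        tpr_sum[cl, ] <- tpr_sum[cl, ] + tpr_at_fpr(score, pos, grid)
        tpr_n[cl] <- tpr_n[cl] + 1
      }
    }
  })
  pct <- sweep(counts, 1, pmax(appearances, 1), "/") * 100
  roc <- dplyr::bind_rows(lapply(levels(y), function(cl) {
    tibble::tibble(class = cl, fpr = grid,
                   tpr = tpr_sum[cl, ] / max(tpr_n[cl], 1))
  }))
  structure(list(confusion_counts = counts, confusion_pct = pct,
                 test_appearances = appearances, roc = roc,
                 auc = auc_sum / pmax(auc_n, 1), accuracies = accuracies,
                 config = cfg, classes = levels(y)),
            class = "diversity_result")
}

draw_split <- function(y, cfg) {
  if (cfg$stratified) {
    unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      sample(idx, stratified_train_size(length(idx), cfg$train_fraction))
    }), use.names = FALSE)
  } else {
    n <- length(y)
    for (attempt in 1:100) {
      tr <- sample.int(n, min(max(floor(n * cfg$train_fraction + 0.5), 1L), n - 1L))
      if (all(levels(y) %in% as.character(y[tr]))) return(tr)
    }
    stopf("could not draw an unstratified split covering every class")
  }
}

# AUC of scores for a binary indicator via the rank (Mann-Whitney) identity
auc_rank <- function(score, pos) {
  r <- rank(score)
  np <- sum(pos); nn <- sum(!pos)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

# stepwise ROC evaluated at fixed FPR values (vertical averaging support)
tpr_at_fpr <- function(score, pos, grid) {
  ord <- order(score, decreasing = TRUE)
  pos <- pos[ord]; score <- score[ord]
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- !duplicated(score[length(score):1])[length(score):1]  # last index per tied score
  tpr <- c(0, tp[last] / max(tp[length(tp)], 1))
  fpr <- c(0, fp[last] / max(fp[length(fp)], 1))
  vapply(grid, function(g) max(tpr[fpr <= g + 1e-12]), numeric(1))
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("<diversity_result> %d classes, %d iterations\n",
              length(x$classes), x$config$n_iterations))
  cat("aggregated confusion (% of test appearances per true class):\n")
  print(round(x$confusion_pct, 1))
  cat("mean one-vs-rest AUC:\n")
  print(round(x$auc, 3))
  invisible(x)
}

#' Permutation-based feature attribution of the full-data ensemble
#'
#' Model-agnostic attribution: the ensemble is fitted on the full
#' (optionally downscaled) table without splitting; each feature column
#' is then permuted `n_repeats` times and the attribution is the mean
#' absolute change of the predicted class probabilities. A constant
#' feature has attribution exactly 0. Deterministic given `cfg$seed`.
#'
#' @param profiles profile tibble.
#' @param cfg a [diversity_config()].
#' @param n_repeats permutations per feature (default 20).
#' @return Tibble (`feature`, `attribution`), sorted decreasing.
#' @export
feature_attribution <- function(profiles, cfg = diversity_config(),
                                n_repeats = 20L) {
  if (cfg$downscale) profiles <- downscale_first_image(profiles)
  y <- factor(profiles$diagnosis)
  x <- as.data.frame(profiles[, feature_registry()])
  imputer <- fit_median_imputer(x)
  x <- apply_imputer(x, imputer)
  withr::with_seed(child_seed(cfg$seed, "attribution"), {
    args <- list(x = x, y = y, ntree = cfg$n_trees, mtry = ncol(x),
                 replace = TRUE, nodesize = 1L)
    if (!is.null(cfg$max_depth)) args$maxnodes <- 2L^cfg$max_depth
    model <- do.call(randomForest::randomForest, args)
    base <- stats::predict(model, x, type = "prob")
    attribution <- vapply(names(x), function(f) {
      mean(vapply(seq_len(n_repeats), function(rep) {
        xp <- x
        xp[[f]] <- xp[[f]][sample.int(nrow(xp))]
        mean(abs(stats::predict(model, xp, type = "prob") - base))
      }, numeric(1)))
    }, numeric(1))
  })
  out <- tibble::tibble(feature = names(attribution),
                        attribution = as.numeric(attribution))
  out[order(-out$attribution), ]
}
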