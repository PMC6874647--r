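#' Classifier configuration
#'
#' Per-cancer-type binary feedforward networks: ReLU hidden activations, a
#' single sigmoid output unit, binary cross-entropy loss, RMSprop optimiser.
#' The hidden architecture is configurable; `c(128, 64)` is the logged
#' default.
#'
#' @param hidden_layers Integer vector of hidden-layer widths.
#' @param epochs Training epochs per model.
#' @param batch_size Mini-batch size.
#' @param learning_rate RMSprop learning rate.
#' @param seed Integer seed for weight initialisation and batch shuffling.
#' @return A list of class `model_config`.
#' @export
model_config <- function(hidden_layers = c(128L, 64L), epochs = 100L,
                         batch_size = 8L, learning_rate = 1e-3, seed = 1L) {
  stopifnot(length(hidden_layers) >= 1, all(hidden_layers >= 1),
            epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(
    list(
      hidden_layers = as.integer(hidden_layers),
      hidden_activation = "relu", output_activation = "sigmoid",
      loss = "binary_crossentropy", optimizer = "rmsprop",
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      learning_rate = learning_rate, seed = as.integer(seed)
    ),
    class = "model_config"
  )
}

#' Read / write a driver label table
#'
#' Labels are stored as one row per positive (gene, cancer type) pair; a
#' gene may be a driver for several types, and a gene appearing in no row is
#' a non-driver. The gene universe is taken from the feature matrix, not
#' from this table.
#'
#' @param path TSV path with header columns `gene_id`, `cancer_type`.
#' @return Tibble with columns `gene_id`, `cancer_type`.
#' @export
read_labels <- function(path) {
  df <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (!all(c("gene_id", "cancer_type") %in% names(df))) {
    stop("label table must have columns gene_id, cancer_type",
         call. = FALSE)
  }
  df[, c("gene_id", "cancer_type")]
}

#' @rdname read_labels
#' @param labels Tibble of positive pairs.
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(labels[, c("gene_id", "cancer_type")], path)
  invisible(path)
}

#' Assemble a balanced training set for one cancer type
#'
#' Positives are the feature-bearing genes labelled as drivers of
#' `cancer_type`; negatives are an equally sized uniform sample (without
#' replacement) from the feature-bearing genes that are drivers of *no*
#' cancer type.
#'
#' @param features A `gene_features` tibble.
#' @param labels Tibble of positive (gene_id, cancer_type) pairs.
#' @param cancer_type The type to train for.
#' @param seed Integer seed controlling the negative sample.
#' @return Tibble with columns `gene_id`, `label` (logical), plus attributes
#'   `cancer_type` and `seed`.
#' @export
assemble_training_set <- function(features, labels, cancer_type, seed = 1L) {
  if (!cancer_type %in% labels$cancer_type) {
    stop("no positive genes labelled for cancer type '", cancer_type, "'",
         call. = FALSE)
  }
  pos <- sort(intersect(
    labels$gene_id[labels$cancer_type == cancer_type], features$gene_id
  ))
  if (length(pos) == 0L) {
    stop("no feature-bearing positives for cancer type '", cancer_type,
         "'", call. = FALSE)
  }
  nondriver <- sort(setdiff(features$gene_id, unique(labels$gene_id)))
  if (length(nondriver) < length(pos)) {
    stop(
      "not enough non-driver genes to balance ", length(pos),
      " positives (have ", length(nondriver), ")",
      call. = FALSE
    )
  }
  neg <- with_local_seed(seed, sort(sample(nondriver, length(pos))))
  out <- tibble::tibble(
    gene_id = c(pos, neg),
    label = rep(c(TRUE, FALSE), c(length(pos), length(neg)))
  )
  attr(out, "cancer_type") <- cancer_type
  attr(out, "seed") <- seed
  out
}

#' F-score from confusion counts
#'
#' `2PR/(P+R)` with precision `tp/(tp+fp)` and recall `tp/(tp+fn)`; defined
#' as 0 when there are no true positives.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return F-score in `[0, 1]`.
#' @export
f_score <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability `P(score+ > score-) +
#' 0.5 P(score+ = score-)` over all positive-negative pairs, via midranks.
#'
#' @param scores Numeric prediction scores.
#' @param labels Logical (or 0/1) true labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores),
            !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_auc needs both classes present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC and precision-recall curve points
#'
#' @param scores Numeric prediction scores.
#' @param labels Logical true labels.
#' @return Tibble of curve points: `threshold`, `fpr`, `tpr` for
#'   `roc_points()`; `threshold`, `recall`, `precision` for `pr_points()`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  thr <- c(Inf, scores[ord][!duplicated(scores[ord])])
  tp <- vapply(thr, function(t) sum(scores >= t & labels), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & !labels), numeric(1))
  tibble::tibble(
    threshold = thr,
    fpr = fp / sum(!labels),
    tpr = tp / sum(labels)
  )
}

#' @rdname roc_points
#' @export
pr_points <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  thr <- scores[ord][!duplicated(scores[ord])]
  tp <- vapply(thr, function(t) sum(scores >= t & labels), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & !labels), numeric(1))
  tibble::tibble(
    threshold = thr,
    recall = tp / sum(labels),
    precision = ifelse(tp + fp == 0, 1, tp / (tp + fp))
  )
}

threshold_metrics <- function(scores, labels, threshold = 0.5) {
  pred <- scores >= threshold
  tp <- sum(pred & labels)
  fp <- sum(pred & !labels)
  fn <- sum(!pred & labels)
  tibble::tibble(
    precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    recall = if (tp + fn == 0) 0 else tp / (tp + fn),
    f_score = f_score(tp, fp, fn)
  )
}

# Stratified fold assignment: shuffle within each class, deal folds
# round-robin so per-fold class counts differ by at most one.
stratified_folds <- function(labels, k, seed) {
  with_local_seed(seed, {
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

#' Stratified k-fold cross-validation of per-type driver classifiers
#'
#' For every cancer type in `labels`, assembles a balanced training set
#' ([assemble_training_set()]), splits it into `k` stratified folds, trains
#' the configured network on `k - 1` folds and scores the held-out fold.
#' Per-type metrics are pooled over the concatenated held-out scores; an
#' `"overall"` result micro-averages the pooled predictions across all
#' types.
#'
#' @param features A `gene_features` tibble.
#' @param labels Tibble of positive (gene_id, cancer_type) pairs; every type
#'   must have at least `k` feature-bearing positives.
#' @param config A [model_config()].
#' @param k Number of folds (default 10).
#' @param seed Integer master seed; per-type negative sampling, fold
#'   assignment and model training derive their streams from it.
#' @param threshold Score threshold for precision/recall/F (default 0.5).
#' @return A `driver_cv` object with elements `scores` (per-gene held-out
#'   scores), `folds` (per-fold metrics), `pooled` (per-type and overall
#'   pooled metrics), and the call configuration.
#' @export
cross_validate <- function(features, labels, config = model_config(),
                           k = 10L, seed = 1L, threshold = 0.5) {
  stopifnot(inherits(config, "model_config"))
  types <- sort(unique(labels$cancer_type))
  xmat <- features_matrix(features)

  n_pos <- vapply(types, function(t) {
    length(intersect(labels$gene_id[labels$cancer_type == t],
                     features$gene_id))
  }, integer(1))
  short <- types[n_pos < k]
  if (length(short) > 0L) {
    stop(
      "cancer type(s) with fewer than k=", k, " feature-bearing ",
      "positives: ", paste(short, collapse = ", "),
      call. = FALSE
    )
  }

  scores <- purrr::map_dfr(types, function(type) {
    ts <- assemble_training_set(features, labels, type,
                                seed = derive_seed(seed, paste0("neg:", type)))
    fold <- stratified_folds(ts$label, k,
                             seed = derive_seed(seed, paste0("fold:", type)))
    x <- xmat[ts$gene_id, , drop = FALSE]
    y <- as.numeric(ts$label)
    purrr::map_dfr(seq_len(k), function(f) {
      test <- fold == f
      model <- mlp_fit(
        x[!test, , drop = FALSE], y[!test],
        hidden = config$hidden_layers, epochs = config$epochs,
        batch_size = config$batch_size,
        learning_rate = config$learning_rate,
        seed = derive_seed(seed, paste0("fit:", type, ":", f))
      )
      tibble::tibble(
        cancer_type = type, gene_id = ts$gene_id[test], fold = f,
        label = ts$label[test],
        score = mlp_predict(model, x[test, , drop = FALSE])
      )
    })
  })

  fold_metrics <- scores |>
    dplyr::group_by(.data$cancer_type, .data$fold) |>
    dplyr::group_modify(function(df, key) {
      dplyr::bind_cols(
        threshold_metrics(df$score, df$label, threshold),
        tibble::tibble(
          auc = if (any(df$label) && any(!df$label)) {
            roc_auc(df$score, df$label)
          } else {
            NA_real_
          }
        )
      )
    }) |>
    dplyr::ungroup()

  pool_one <- function(df, name) {
    dplyr::bind_cols(
      tibble::tibble(cancer_type = name),
      threshold_metrics(df$score, df$label, threshold),
      tibble::tibble(
        auc = roc_auc(df$score, df$label),
        n_pos = sum(df$label), n_neg = sum(!df$label)
      )
    )
  }
  pooled <- dplyr::bind_rows(
    purrr::map_dfr(types, function(t) {
      pool_one(scores[scores$cancer_type == t, ], t)
    }),
    pool_one(scores, "overall")
  )

  structure(
    list(scores = scores, folds = fold_metrics, pooled = pooled,
         k = as.integer(k), threshold = threshold, seed = as.integer(seed),
         config = config, mode = attr(features, "mode")),
    class = "driver_cv"
  )
}

#' @export
print.driver_cv <- function(x, ...) {
  ov <- x$pooled[x$pooled$cancer_type == "overall", ]
  cat(sprintf(
    "<driver_cv> %d cancer types, %d-fold; pooled AUC %.3f, F %.3f\n",
    nrow(x$pooled) - 1L, x$k, ov$auc, ov$f_score
  ))
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `driver_cv` object.
#' @param ... Unused.
#' @export
tidy.driver_cv <- function(x, ...) {
  x$folds
}

#' @rdname cross_validate
#' @export
glance.driver_cv <- function(x, ...) {
  ov <- x$pooled[x$pooled$cancer_type == "overall", ]
  per_type <- x$pooled[x$pooled$cancer_type != "overall", ]
  tibble::tibble(
    mode = x$mode %||% NA_character_,
    n_types = nrow(per_type),
    k = x$k,
    micro_f_score = ov$f_score,
    micro_auc = ov$auc,
    macro_f_score = mean(per_type$f_score),
    macro_auc = mean(per_type$auc)
  )
}

#' Plot pooled ROC or precision-recall curves from a cross-validation
#'
#' @param object A `driver_cv` object.
#' @param type `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.driver_cv <- function(object, type = c("roc", "pr"), ...) {
  type <- match.arg(type)
  groups <- c(sort(unique(object$scores$cancer_type)), "overall")
  pts <- purrr::map_dfr(groups, function(g) {
    df <- if (g == "overall") {
      object$scores
    } else {
      object$scores[object$scores$cancer_type == g, ]
    }
    fn <- if (type == "roc") roc_points else pr_points
    dplyr::bind_cols(tibble::tibble(group = g), fn(df$score, df$label))
  })
  if (type == "roc") {
    ggplot2::ggplot(pts, ggplot2::aes(.data$fpr, .data$tpr,
                                      colour = .data$group)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::geom_step() +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    colour = "Cancer type")
  } else {
    ggplot2::ggplot(pts, ggplot2::aes(.data$recall, .data$precision,
                                      colour = .data$group)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::labs(x = "Recall", y = "Precision", colour = "Cancer type")
  }
}

#' Train one final model per cancer type
#'
#' Fits the configured network per cancer type on the full balanced
#' training set (no held-out folds), for use with [predict_candidates()].
#'
#' @inheritParams cross_validate
#' @return A named list of fitted models (class `driver_models`) with the
#'   feature width recorded.
#' @export
train_driver_models <- function(features, labels, config = model_config(),
                                seed = 1L) {
  types <- sort(unique(labels$cancer_type))
  xmat <- features_matrix(features)
  models <- stats::setNames(lapply(types, function(type) {
    ts <- assemble_training_set(features, labels, type,
                                seed = derive_seed(seed, paste0("neg:", type)))
    mlp_fit(
      xmat[ts$gene_id, , drop = FALSE], as.numeric(ts$label),
      hidden = config$hidden_layers, epochs = config$epochs,
      batch_size = config$batch_size,
      learning_rate = config$learning_rate,
      seed = derive_seed(seed, paste0("final:", type))
    )
  }), types)
  structure(
    list(models = models, feature_dim = ncol(xmat), config = config,
         seed = as.integer(seed)),
    class = "driver_models"
  )
}

#' Call novel candidate driver genes
#'
#' Scores every feature-bearing gene with each per-type model and reports,
#' per cancer type, the genes scoring at or above the threshold that are
#' *not* already labelled as drivers of that type, sorted by descending
#' score.
#'
#' @param models A `driver_models` object from [train_driver_models()].
#' @param features A `gene_features` tibble with the same feature width the
#'   models were trained on.
#' @param labels Tibble of known positive (gene_id, cancer_type) pairs.
#' @param threshold Minimum score to call a candidate (default 0.5).
#' @return Tibble with columns `cancer_type`, `gene_id`, `score`.
#' @export
predict_candidates <- function(models, features, labels, threshold = 0.5) {
  stopifnot(inherits(models, "driver_models"))
  xmat <- features_matrix(features)
  if (ncol(xmat) != models$feature_dim) {
    stop(
      "feature width ", ncol(xmat), " does not match the width ",
      models$feature_dim, " the models were trained on",
      call. = FALSE
    )
  }
  purrr::map_dfr(names(models$models), function(type) {
    score <- mlp_predict(models$models[[type]], xmat)
    known <- labels$gene_id[labels$cancer_type == type]
    keep <- score >= threshold & !features$gene_id %in% known
    out <- tibble::tibble(
      cancer_type = type,
      gene_id = features$gene_id[keep],
      score = score[keep]
    )
    dplyr::arrange(out, dplyr::desc(.data$score))
  })
}
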