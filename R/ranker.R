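#' Model pools
#'
#' A `model_pool` holds the candidate (decoy) structures for one target
#' together with the predictor-group label of each model, its submitting
#' server rank, and — when the native structure is known — its true GDT-TS.
#'
#' @param models named list of [ca_structure()] objects (unique names).
#' @param target_id target identifier.
#' @param group character vector of group labels per model (recycled).
#' @param server_rank optional integer rank per model (1 = best); defaults to
#'   input order.
#' @param true_score optional numeric vector of true GDT-TS in \[0, 1\].
#' @return An object of class `model_pool`.
#' @export
model_pool <- function(models, target_id = "target", group = "g1",
                       server_rank = NULL, true_score = NULL) {
  if (is.null(names(models)) || anyDuplicated(names(models)))
    stop("models must be a uniquely named list")
  n <- length(models)
  group <- rep_len(as.character(group), n)
  if (is.null(server_rank)) server_rank <- seq_len(n)
  if (!is.null(true_score)) {
    stopifnot(length(true_score) == n)
    if (any(true_score < 0 | true_score > 1, na.rm = TRUE))
      stop("true_score must lie in [0, 1]")
  }
  structure(list(target_id = target_id, models = models,
                 group = stats::setNames(group, names(models)),
                 server_rank = stats::setNames(as.integer(server_rank),
                                               names(models)),
                 true_score = if (is.null(true_score)) NULL else
                   stats::setNames(as.numeric(true_score), names(models))),
            class = "model_pool")
}

#' @export
print.model_pool <- function(x, ...) {
  cat(sprintf("<model_pool> target %s: %d models, %d group(s)%s\n",
              x$target_id, length(x$models), length(unique(x$group)),
              if (is.null(x$true_score)) "" else ", true scores known"))
  invisible(x)
}

#' Subset a model pool by model id
#' @param pool a [model_pool()].
#' @param ids model ids to keep, in the given order.
#' @return A [model_pool()].
#' @export
pool_subset <- function(pool, ids) {
  stopifnot(all(ids %in% names(pool$models)))
  model_pool(pool$models[ids], pool$target_id, pool$group[ids],
             pool$server_rank[ids],
             if (is.null(pool$true_score)) NULL else pool$true_score[ids])
}

#' Remove redundant same-group models from a pool
#'
#' Models are visited greedily in `server_rank` order; a model is dropped when
#' an already-kept model from the same group is more similar than `cutoff`
#' (pairwise GDT-TS greater than `cutoff`). Pairs from different groups are
#' never filtered.
#'
#' @param pool a [model_pool()].
#' @param cutoff GDT-TS redundancy cutoff.
#' @param sim optional precomputed pairwise GDT-TS matrix (see
#'   [pairwise_matrix()]); computed when missing.
#' @return The filtered [model_pool()].
#' @export
filter_redundant <- function(pool, cutoff = 0.95, sim = NULL) {
  ids <- names(pool$models)
  if (length(ids) < 2L) return(pool)
  if (is.null(sim)) sim <- pairwise_matrix(pool, "gdt_ts")
  ord <- ids[order(pool$server_rank[ids], ids)]
  kept <- character(0)
  for (id in ord) {
    same <- kept[pool$group[kept] == pool$group[id]]
    if (!length(same) || all(sim[id, same] <= cutoff)) kept <- c(kept, id)
  }
  pool_subset(pool, ids[ids %in% kept])
}

#' Pairwise-consensus quality scores
#'
#' The consensus (clustering) score of a model is its mean structural
#' similarity to every other model in the pool — the principle behind
#' pairwise multi-model quality assessment.
#'
#' @param pool a [model_pool()] with at least two models.
#' @param metric `"gdt_ts"` or `"tm_score"`.
#' @param sim optional precomputed pairwise similarity matrix.
#' @return A tibble with columns `model_id` and `score`, in pool order.
#' @export
consensus_scores <- function(pool, metric = c("gdt_ts", "tm_score"),
                             sim = NULL) {
  metric <- match.arg(metric)
  if (length(pool$models) < 2L)
    stop("consensus scores need at least 2 models")
  if (is.null(sim)) sim <- pairwise_matrix(pool, metric)
  n <- nrow(sim)
  sc <- (rowSums(sim) - 1) / (n - 1)
  tibble::tibble(model_id = rownames(sim), score = as.numeric(sc))
}

#' Rankings
#'
#' A `ranking` is a tibble of model ids with predicted scores, sorted by
#' descending score with ties broken deterministically by model id.
#'
#' @param model_id character vector of model ids.
#' @param score numeric scores (higher = better).
#' @return A tibble of class `ranking` with columns `model_id`, `score`,
#'   `rank`.
#' @export
new_ranking <- function(model_id, score) {
  stopifnot(length(model_id) == length(score), !anyDuplicated(model_id))
  ord <- order(-score, model_id)
  out <- tibble::tibble(model_id = as.character(model_id)[ord],
                        score = as.numeric(score)[ord],
                        rank = seq_along(ord))
  class(out) <- c("ranking", class(out))
  out
}

#' Average several rankings by mean rank position
#'
#' Models are re-ranked by the mean of their rank positions across the input
#' rankings (ascending), which is robust to incomparable score scales across
#' methods; ties are broken by model id.
#'
#' @param rankings list of at least two [new_ranking()] objects over the same
#'   model set.
#' @return A [new_ranking()] whose `score` is the negated mean rank.
#' @export
rank_average <- function(rankings) {
  stopifnot(length(rankings) >= 2L)
  ids <- sort(rankings[[1L]]$model_id)
  for (r in rankings)
    if (!identical(sort(r$model_id), ids))
      stop("rankings must cover the same model set")
  mr <- rowMeans(vapply(rankings, function(r) r$rank[match(ids, r$model_id)],
                        numeric(length(ids))))
  new_ranking(ids, -mr)
}

#' Take the top models of a ranking
#' @param ranking a [new_ranking()].
#' @param n number of models.
#' @return Character vector of the first `min(n, size)` model ids.
#' @export
select_top <- function(ranking, n = 5) {
  utils::head(ranking$model_id, max(0L, n))
}

# --- feature table -----------------------------------------------------------

#' Per-model feature table for quality assessment
#'
#' Assembles the 2D feature families for every model in a pool: the nine
#' distance-map matching scores of [map_match_scores()] against the predicted
#' map, the three per-class contact matching scores of
#' [contact_match_record()], the pool consensus score, and any auxiliary
#' per-model columns (stand-ins for external single-model tools).
#'
#' @param pool a [model_pool()].
#' @param predicted_map predicted L x L distance map.
#' @param predicted_contacts optional scored `contact_set`; derived from the
#'   predicted map when missing.
#' @param consensus include the pairwise-consensus column (needs >= 2 models).
#' @param aux optional data frame with a `model_id` column plus numeric
#'   auxiliary columns.
#' @param scheme distance scheme for model maps, `"cb"` (Ca fallback) or
#'   `"ca"`.
#' @return A tibble keyed by `model_id` with one numeric column per feature.
#' @export
feature_table <- function(pool, predicted_map, predicted_contacts = NULL,
                          consensus = TRUE, aux = NULL, scheme = "cb") {
  predicted_map <- check_distance_map(predicted_map)
  L <- nrow(predicted_map)
  if (is.null(predicted_contacts)) {
    pm <- predicted_map
    dimnames(pm) <- NULL
    cs <- contacts_from_map(pm, threshold = 12, separation_class = "any")
    # convert distances to a monotone confidence so closer pairs rank first
    predicted_contacts <- new_contact_set(cs$i, cs$j,
                                          1 - pm[cbind(cs$i, cs$j)] / 12,
                                          "any")
  }
  pred_orb <- orb_descriptors(normalize_map(predicted_map))
  rows <- lapply(names(pool$models), function(id) {
    s <- pool$models[[id]]
    mm <- distance_map(s, scheme)
    dimnames(mm) <- NULL
    if (nrow(mm) != L)
      stop("model ", id, " length differs from the predicted map size")
    cbind(tibble::tibble(model_id = id),
          map_match_scores(predicted_map, mm, .predicted_orb = pred_orb),
          contact_match_record(predicted_contacts, mm, L))
  })
  out <- do.call(rbind, rows)
  if (consensus && length(pool$models) >= 2L) {
    cons <- consensus_scores(pool)
    out$consensus <- cons$score[match(out$model_id, cons$model_id)]
  }
  if (!is.null(aux)) {
    stopifnot("model_id" %in% names(aux))
    out <- merge(out, aux, by = "model_id", all.x = TRUE, sort = FALSE)
    out <- tibble::as_tibble(out[match(names(pool$models), out$model_id), ])
  }
  out
}

# --- stacked quality-assessment regressor ------------------------------------

impute_medians <- function(x, med = NULL) {
  if (is.null(med)) med <- apply(x, 2L, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(x))) {
    bad <- !is.finite(x[, j])
    if (any(bad)) x[bad, j] <- med[j]
  }
  list(x = x, medians = med)
}

fit_learner <- function(x, y, hidden, decay, maxit, seed) {
  with_local_seed(seed, function()
    nnet::nnet(x, y, size = hidden, decay = decay, maxit = maxit,
               linout = TRUE, trace = FALSE, MaxNWts = 50000L))
}

#' Train the two-level stacked quality-assessment regressor
#'
#' Level 1 is an ensemble of ten feed-forward regressors trained by tenfold
#' cross-validation to predict GDT-TS from the feature columns; the
#' out-of-fold level-1 predictions are then combined with the original
#' features as inputs to a single level-2 regressor that produces the final
#' score. Training is deterministic for a fixed `seed`.
#'
#' @param features feature tibble with a `model_id` column and numeric feature
#'   columns (>= 50 rows). Non-finite entries are imputed with the column
#'   median (flagged with a message).
#' @param labels true GDT-TS per row, in \[0, 1\].
#' @param seed integer seed controlling fold assignment and weight
#'   initialisation.
#' @param hidden hidden-layer size of each regressor.
#' @param decay,maxit weight decay and optimiser iteration cap.
#' @param n_folds number of level-1 cross-validation folds.
#' @param n_level2 size of the level-2 ensemble: independently initialised
#'   level-2 regressors whose predictions are averaged, reducing the variance
#'   of the final arbiter.
#' @return An object of class `qa_stack`.
#' @export
train_stacked_qa <- function(features, labels, seed = 1L, hidden = 24L,
                             decay = 1e-2, maxit = 500L, n_folds = 10L,
                             n_level2 = 5L) {
  stopifnot("model_id" %in% names(features))
  x <- as.matrix(features[, setdiff(names(features), "model_id"), drop = FALSE])
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n < 50L) stop("at least 50 training rows are required")
  labels <- as.numeric(labels)
  stopifnot(length(labels) == n)
  if (any(labels < 0 | labels > 1)) stop("labels must lie in [0, 1]")
  if (stats::sd(labels) == 0)
    warning("zero-variance labels: the fitted model is degenerate")
  if (any(!is.finite(x))) message("imputing non-finite feature values with column medians")
  imp <- impute_medians(x)
  x <- imp$x
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- scale(x, ctr, scl)

  folds <- with_local_seed(seed, function()
    sample(rep_len(seq_len(n_folds), n)))
  level1 <- vector("list", n_folds)
  oof <- numeric(n)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    level1[[f]] <- fit_learner(xs[tr, , drop = FALSE], labels[tr],
                               hidden, decay, maxit, seed * 1000L + f)
    oof[!tr] <- as.numeric(stats::predict(level1[[f]],
                                          xs[!tr, , drop = FALSE]))
  }
  oof <- pmin(1, pmax(0, oof))
  x2 <- cbind(xs, stacked = oof)
  level2 <- lapply(seq_len(n_level2), function(k)
    fit_learner(x2, labels, hidden, decay, maxit, seed * 1000L + 500L + k))
  structure(list(level1 = level1, level2 = level2, folds = folds,
                 feature_schema = colnames(x), center = ctr, scale = scl,
                 medians = imp$medians, training_seed = seed,
                 n_folds = n_folds),
            class = "qa_stack")
}

#' @export
print.qa_stack <- function(x, ...) {
  cat(sprintf("<qa_stack> %d level-1 regressors + %d-net level-2 ensemble over %d features (seed %d)\n",
              length(x$level1), length(x$level2), length(x$feature_schema),
              x$training_seed))
  invisible(x)
}

#' Predict model quality with a stacked regressor
#'
#' Level-1 output for new rows is the mean prediction of the ten fold models;
#' the level-2 regressor maps it, together with the features, to the final
#' score, clipped to \[0, 1\].
#'
#' @param model a [train_stacked_qa()] fit.
#' @param features feature tibble with a `model_id` column and the training
#'   schema's columns.
#' @return A [new_ranking()] over the rows of `features`.
#' @export
predict_qa <- function(model, features) {
  stopifnot(inherits(model, "qa_stack"), "model_id" %in% names(features))
  missing <- setdiff(model$feature_schema, names(features))
  if (length(missing))
    stop("missing feature columns: ", paste(missing, collapse = ", "))
  x <- as.matrix(features[, model$feature_schema, drop = FALSE])
  storage.mode(x) <- "double"
  x <- impute_medians(x, model$medians)$x
  xs <- scale(x, model$center, model$scale)
  l1 <- rowMeans(vapply(model$level1,
                        function(m) as.numeric(stats::predict(m, xs)),
                        numeric(nrow(xs))))
  l1 <- pmin(1, pmax(0, l1))
  x2 <- cbind(xs, stacked = l1)
  pred <- rowMeans(vapply(model$level2,
                          function(m) as.numeric(stats::predict(m, x2)),
                          numeric(nrow(x2))))
  new_ranking(features$model_id, pmin(1, pmax(0, pred)))
}

#' @export
summary.qa_stack <- function(object, ...) {
  tibble::tibble(n_level1 = length(object$level1),
                 n_features = length(object$feature_schema),
                 n_folds = object$n_folds,
                 training_seed = object$training_seed)
}
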