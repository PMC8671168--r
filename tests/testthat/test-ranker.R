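# pool where pairwise similarities are controlled: identical copies score
# GDT-TS 1 (> 0.95), heavy independent noise scores well below 0.95
controlled_pool <- function(groups, copies_of = NULL, seed = 1) {
  s <- make_native(40, seed = seed)
  set.seed(seed + 100)
  models <- list()
  for (k in seq_along(groups)) {
    models[[k]] <- if (!is.null(copies_of) && !is.na(copies_of[k]))
      models[[copies_of[k]]]
    else ca_structure(s$ca_coords + matrix(rnorm(120, sd = 6), 40, 3),
                      residue_index = s$residue_index)
  }
  names(models) <- sprintf("m%02d", seq_along(groups))
  model_pool(models, group = groups)
}

test_that("redundancy filtering removes same-group near-duplicates only", {
  # m01/m02 identical (GDT 1 > 0.95) same group: lower-ranked m02 dropped
  pool <- controlled_pool(c("A", "A", "B"), copies_of = c(NA, 1, NA))
  kept <- filter_redundant(pool, 0.95)
  expect_equal(names(kept$models), c("m01", "m03"))

  # identical pair across different groups: both kept
  pool2 <- controlled_pool(c("A", "B"), copies_of = c(NA, 1))
  expect_gt(pairwise_matrix(pool2)["m01", "m02"], 0.95)
  expect_equal(names(filter_redundant(pool2)$models), c("m01", "m02"))

  # same group but similarity below the cutoff: both kept
  pool3 <- controlled_pool(c("A", "A"))
  expect_lt(pairwise_matrix(pool3)["m01", "m02"], 0.95)
  expect_equal(names(filter_redundant(pool3)$models), c("m01", "m02"))
})

test_that("filter_redundant is idempotent", {
  pool <- controlled_pool(c("A", "A", "A", "B", "B"),
                          copies_of = c(NA, 1, NA, NA, 4))
  once <- filter_redundant(pool)
  twice <- filter_redundant(once)
  expect_equal(names(once$models), names(twice$models))
})

test_that("consensus scores equal mean pairwise similarity; outliers score lowest", {
  s <- make_native(40, seed = 2)
  same <- model_pool(list(a = s, b = s, c = s))
  cs <- consensus_scores(same)
  expect_equal(cs$score, rep(1, 3))

  # one heavy outlier among near-identical decoys
  set.seed(9)
  near <- lapply(1:4, function(k)
    ca_structure(s$ca_coords + matrix(rnorm(120, sd = 0.3), 40, 3),
                 residue_index = s$residue_index))
  outlier <- ca_structure(s$ca_coords + matrix(rnorm(120, sd = 8), 40, 3),
                          residue_index = s$residue_index)
  pool <- model_pool(c(setNames(near, paste0("n", 1:4)), list(out = outlier)))
  sim <- pairwise_matrix(pool)
  cs2 <- consensus_scores(pool, sim = sim)
  expect_equal(cs2$model_id[which.min(cs2$score)], "out")
  # direct mean recomputation
  for (k in 1:5)
    expect_equal(cs2$score[k], mean(sim[k, -k]))

  two <- model_pool(list(a = near[[1]], b = outlier))
  cs3 <- consensus_scores(two)
  expect_equal(cs3$score[1], cs3$score[2])
  expect_error(consensus_scores(model_pool(list(a = s))), "at least 2")
})

test_that("adding copies of a model inflates its consensus score", {
  s <- make_native(40, seed = 4)
  set.seed(11)
  mk <- function(sd) ca_structure(s$ca_coords + matrix(rnorm(120, sd = sd),
                                                       40, 3),
                                  residue_index = s$residue_index)
  a <- mk(3); b <- mk(3); c <- mk(3)
  base <- model_pool(list(a = a, b = b, c = c))
  base_score <- consensus_scores(base)$score[1]
  padded <- model_pool(list(a = a, b = b, c = c, a2 = a, a3 = a))
  pad_score <- consensus_scores(padded)$score[1]
  expect_gt(pad_score, base_score)
})

test_that("rank_average combines rankings by mean rank with id tie-breaks", {
  r1 <- new_ranking(c("a", "b", "c", "d"), c(4, 3, 2, 1))
  expect_equal(rank_average(list(r1, r1))$model_id, r1$model_id)

  # ranks (1,3) and (3,1) tie; id order decides
  ra <- new_ranking(c("x", "y"), c(2, 1))
  rb <- new_ranking(c("x", "y"), c(1, 2))
  expect_equal(rank_average(list(ra, rb))$model_id, c("x", "y"))

  r2 <- new_ranking(c("a", "b", "c", "d"), c(1, 4, 3, 2))
  r3 <- new_ranking(c("a", "b", "c", "d"), c(2, 1, 4, 3))
  avg <- rank_average(list(r1, r2, r3))
  hand <- sort(c(a = mean(c(1, 4, 3)), b = mean(c(2, 1, 4)),
                 c = mean(c(3, 2, 1)), d = mean(c(4, 3, 2))))
  expect_equal(avg$model_id, names(hand))
  expect_error(rank_average(list(r1, new_ranking(c("a", "b"), 1:2))),
               "same model set")
})

test_that("select_top truncates in order", {
  r <- new_ranking(sprintf("m%02d", 1:10), seq(1, 0.1, length.out = 10))
  expect_equal(select_top(r, 5), sprintf("m%02d", 1:5))
  expect_equal(select_top(new_ranking(c("a", "b", "c"), 3:1), 5),
               c("a", "b", "c"))
  expect_equal(select_top(r, 0), character(0))
})

test_that("stacked QA handles constant labels and enforces its schema", {
  set.seed(3)
  ft <- tibble::tibble(model_id = sprintf("m%03d", 1:60),
                       f1 = runif(60), f2 = rnorm(60), f3 = runif(60))
  expect_warning(fit <- train_stacked_qa(ft, rep(0.5, 60), seed = 7),
                 "zero-variance")
  pred <- predict_qa(fit, ft)
  expect_true(all(pred$score >= 0.45 & pred$score <= 0.55))

  bad <- ft
  names(bad)[2] <- "f1_renamed"
  expect_error(predict_qa(fit, bad), "f1")
  expect_error(train_stacked_qa(ft[1:30, ], rep(0.5, 30)), "50")
})

test_that("stacked QA training is bit-reproducible for a fixed seed", {
  set.seed(8)
  n <- 80
  ft <- tibble::tibble(model_id = sprintf("m%03d", 1:n),
                       f1 = runif(n), f2 = rnorm(n))
  labels <- pmin(1, pmax(0, 0.5 + 0.3 * ft$f1 - 0.1 * ft$f2 +
                           rnorm(n, 0, 0.05)))
  f1 <- train_stacked_qa(ft, labels, seed = 42)
  f2 <- train_stacked_qa(ft, labels, seed = 42)
  expect_identical(predict_qa(f1, ft)$score, predict_qa(f2, ft)$score)
  expect_identical(f1$folds, f2$folds)
  # folds partition rows into the configured number of disjoint groups
  expect_equal(sort(unique(f1$folds)), 1:10)
  expect_equal(length(f1$folds), n)
})

test_that("stacked QA learns informative features and clips to [0, 1]", {
  set.seed(13)
  n <- 150
  truth <- runif(n, 0.1, 0.95)
  ft <- tibble::tibble(model_id = sprintf("m%03d", 1:n),
                       g1 = truth + rnorm(n, 0, 0.07),
                       g2 = truth + rnorm(n, 0, 0.15),
                       junk = rnorm(n))
  tr <- 1:100; te <- 101:150
  fit <- train_stacked_qa(ft[tr, ], truth[tr], seed = 5)
  pred <- predict_qa(fit, ft[te, ])
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  got <- pred$score[match(ft$model_id[te], pred$model_id)]
  expect_gt(cor(got, truth[te], method = "spearman"), 0.7)
})

test_that("missing feature values are median-imputed", {
  set.seed(21)
  n <- 60
  ft <- tibble::tibble(model_id = sprintf("m%03d", 1:n),
                       f1 = runif(n), f2 = rnorm(n))
  ft$f1[c(3, 10)] <- NA
  labels <- pmin(1, pmax(0, 0.4 + 0.2 * ft$f2 / 3))
  expect_message(fit <- train_stacked_qa(ft, labels, seed = 2), "imputing")
  expect_true(all(is.finite(predict_qa(fit, ft)$score)))
})
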