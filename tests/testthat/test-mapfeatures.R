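random_map <- function(L, lo = 0, hi = 20) {
  m <- matrix(0, L, L)
  m[upper.tri(m)] <- runif(L * (L - 1) / 2, lo, hi)
  m + t(m)
}

test_that("normalize_map caps and scales linearly", {
  z <- matrix(0, 4, 4)
  expect_equal(normalize_map(z), z)
  m <- matrix(c(0, 16, 16, 0), 2, 2)
  m2 <- matrix(c(0, 32, 32, 0), 2, 2)
  expect_equal(normalize_map(m)[1, 2], 1)
  expect_equal(normalize_map(m2)[1, 2], 1)
  m8 <- matrix(c(0, 8, 8, 0), 2, 2)
  expect_equal(normalize_map(m8)[1, 2], 0.5)
  expect_error(normalize_map(m, cap = 0), "positive")
})

test_that("self-comparison attains the identity extreme of every score", {
  s <- make_native(50, seed = 2)
  m <- distance_map(s, "cb"); dimnames(m) <- NULL
  r <- map_match_scores(m, m)
  expect_equal(r$ssim, 1)
  expect_equal(r$psnr, 100)
  expect_equal(r$gist, 1)
  expect_equal(r$rmse, 0)
  expect_equal(r$recall, 1)
  expect_equal(r$precision, 1)
  expect_equal(r$phash, 1)
  expect_equal(r$pearson, 1)
  expect_equal(r$orb, 1)
})

test_that("a uniform +1 A offset gives rmse 1 and pearson 1", {
  s <- make_native(40, seed = 3)
  m <- distance_map(s, "cb"); dimnames(m) <- NULL
  shifted <- m + 1
  diag(shifted) <- 0
  r <- map_match_scores(m, shifted)
  expect_equal(r$rmse, 1, tolerance = 1e-12)
  expect_equal(r$pearson, 1, tolerance = 1e-12)
})

test_that("pearson collapses toward 0 for permuted maps", {
  rs <- numeric(20)
  for (k in 1:20) {
    set.seed(400 + k)
    m <- random_map(60)
    p <- sample(60)
    r <- map_match_scores(m[p, p], m)
    rs[k] <- r$pearson
  }
  expect_true(all(abs(rs) < 0.2))
})

test_that("every feature respects its documented range on random map pairs", {
  set.seed(77)
  for (k in 1:40) {
    L <- sample(c(20, 40, 60), 1)
    r <- map_match_scores(random_map(L), random_map(L))
    for (f in c("ssim", "recall", "precision", "phash", "orb", "gist"))
      expect_true(r[[f]] >= 0 && r[[f]] <= 1, info = f)
    expect_true(r$pearson >= -1 && r$pearson <= 1)
    expect_gte(r$rmse, 0)
    expect_true(is.finite(r$psnr))
  }
})

test_that("rmse and ssim are symmetric; precision/recall swap on swap", {
  set.seed(5)
  a <- random_map(40); b <- random_map(40)
  r1 <- map_match_scores(a, b)
  r2 <- map_match_scores(b, a)
  expect_equal(r1$rmse, r2$rmse)
  expect_equal(r1$ssim, r2$ssim, tolerance = 1e-9)
  expect_equal(r1$precision, r2$recall)
  expect_equal(r1$recall, r2$precision)
})

test_that("rmse grows and pearson falls as predicted-map noise grows", {
  s <- make_native(60, seed = 11)
  truth <- distance_map(s, "cb"); dimnames(truth) <- NULL
  sds <- c(0.25, 1, 3, 6)
  rmse <- pe <- numeric(length(sds))
  for (k in seq_along(sds)) {
    pm <- make_predicted_map(s, sds[k], seed = 50 + k)
    r <- map_match_scores(pm, truth)
    rmse[k] <- r$rmse; pe[k] <- r$pearson
  }
  expect_true(all(diff(rmse) > 0))
  expect_true(all(diff(pe) < 0))
})

test_that("topk_contacts follows score order with lexicographic ties", {
  cs <- distrank:::new_contact_set(c(1, 1, 2, 3), c(30, 40, 33, 40),
                                   c(0.9, 0.5, 0.9, 0.2), "any")
  expect_equal(nrow(topk_contacts(cs, 0, "long")), 0L)

  # all scores equal: first k pairs in (i, j) order
  eq <- distrank:::new_contact_set(c(2, 1, 1), c(30, 40, 28), rep(0.5, 3),
                                   "any")
  top2 <- topk_contacts(eq, 2, "long")
  expect_equal(top2$i, c(1L, 1L))
  expect_equal(top2$j, c(28L, 40L))

  set.seed(12)
  L <- 60
  m <- random_map(L, 0, 30)
  all_c <- contacts_from_map(m, 30, "any")
  scored <- distrank:::new_contact_set(all_c$i, all_c$j,
                                       round(runif(nrow(all_c)), 2), "any")
  got <- topk_contacts(scored, 25, "long")
  df <- as.data.frame(scored)
  df <- df[df$j - df$i >= 24, ]
  want <- head(df[order(-df$score, df$i, df$j), ], 25)
  want <- want[order(want$i, want$j), ]   # contact sets are stored in (i,j) order
  expect_equal(got$i, want$i)
  expect_equal(got$j, want$j)
  expect_equal(got$score, want$score)
  expect_warning(topk_contacts(scored, 10000, "long"), "candidate pairs")
})

test_that("contact_match counts precision as stated", {
  mk <- function(i, j) distrank:::new_contact_set(i, j, rep(1, length(i)),
                                                  "any")
  pred <- mk(rep(1:5, each = 6), rep(1:5, each = 6) + 6 + sequence(rep(6, 5)))
  expect_equal(nrow(pred), 30L)
  model <- mk(pred$i[1:18], pred$j[1:18])
  expect_equal(contact_match(pred, model), 0.6)
  expect_equal(contact_match(model, model), 1)
  disjoint <- mk(model$i, model$j + 1L)
  expect_equal(contact_match(pred[19:30, ], disjoint), 0)
  expect_warning(z <- contact_match(mk(integer(), integer()), model), "empty")
  expect_equal(z, 0)
})

test_that("contact_match_record scores each class against the model map", {
  s <- make_native(60, seed = 1)
  m <- distance_map(s, "cb"); dimnames(m) <- NULL
  # predictions derived from the generating structure at zero noise
  pm <- make_predicted_map(s, 0)
  cs <- contacts_from_map(pm, 8, "any")
  scored <- distrank:::new_contact_set(cs$i, cs$j, 1 - pm[cbind(cs$i, cs$j)] / 8,
                                       "any")
  rec <- contact_match_record(scored, m, 60)
  expect_equal(rec$short_score, 1)
  expect_equal(rec$medium_score, 1)
  expect_equal(rec$long_score, 1)

  # L = 10: no long-range pair can exist; flagged zero
  s10 <- make_native(10, seed = 3)
  m10 <- distance_map(s10, "cb"); dimnames(m10) <- NULL
  cs10 <- contacts_from_map(m10, 8, "any")
  sc10 <- distrank:::new_contact_set(cs10$i, cs10$j, rep(1, nrow(cs10)), "any")
  rec10 <- contact_match_record(sc10, m10, 10)
  expect_equal(rec10$long_score, 0)
  expect_true(attr(rec10, "flagged")[["long"]])

  # planted-contact enumeration oracle: precision by hand counting
  pm2 <- make_predicted_map(s, 2, seed = 9)
  cs2 <- contacts_from_map(pm2, 8, "any")
  sc2 <- distrank:::new_contact_set(cs2$i, cs2$j, 1 - pm2[cbind(cs2$i, cs2$j)] / 8,
                                    "any")
  rec2 <- contact_match_record(sc2, m, 60)
  for (cls in c("short", "medium", "long")) {
    b <- switch(cls, short = c(6, 11), medium = c(12, 23), long = c(24, 1e9))
    df <- as.data.frame(sc2)
    df <- df[df$j - df$i >= b[1] & df$j - df$i <= b[2], ]
    df <- head(df[order(-df$score, df$i, df$j), ], 30)
    hand <- if (nrow(df) == 0) 0 else mean(m[cbind(df$i, df$j)] <= 8)
    expect_equal(rec2[[paste0(cls, "_score")]], hand, info = cls)
  }
})
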