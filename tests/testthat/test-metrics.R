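test_that("confusion counts enumerate the four outcomes exactly", {
  cc <- confusion(rep("disease", 5), rep("disease", 5))
  expect_equal(unclass(cc)[c("tp", "fp", "tn", "fn")],
               list(tp = 5L, fp = 0L, tn = 0L, fn = 0L), ignore_attr = TRUE)
  cc2 <- confusion(c("disease", "normal", "disease", "normal"),
                   c("disease", "disease", "normal", "normal"))
  expect_equal(cc2$tp, 1); expect_equal(cc2$fp, 1)
  expect_equal(cc2$fn, 1); expect_equal(cc2$tn, 1)
  # ternary labels collapse to normal-vs-any-disease
  cc3 <- confusion(c("disease1", "disease2", "normal"),
                   c("disease2", "normal", "disease1"))
  expect_equal(cc3$tp, 1); expect_equal(cc3$fn, 1); expect_equal(cc3$fp, 1)
  expect_error(confusion("normal", c("normal", "normal")), "length")
  # brute-force pair loop on a random vector pair
  set.seed(1)
  l <- sample(c("normal", "disease"), 500, replace = TRUE)
  p <- sample(c("normal", "disease"), 500, replace = TRUE)
  cc4 <- confusion(l, p)
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in 1:500) {
    if (l[i] == "disease" && p[i] == "disease") tp <- tp + 1
    if (l[i] == "normal" && p[i] == "disease") fp <- fp + 1
    if (l[i] == "normal" && p[i] == "normal") tn <- tn + 1
    if (l[i] == "disease" && p[i] == "normal") fn <- fn + 1
  }
  expect_equal(unclass(cc4)[1:4], list(tp = tp, fp = fp, tn = tn, fn = fn),
               ignore_attr = TRUE)
})

test_that("the five measures match hand arithmetic and flag zero denominators", {
  m <- classification_metrics(list(tp = 50, tn = 40, fp = 5, fn = 5))
  expect_equal(m$accuracy, 0.90)
  expect_equal(m$precision, 10 / 11)
  expect_equal(m$recall, 10 / 11)
  expect_equal(m$specificity, 40 / 45)
  expect_equal(m$f1, 10 / 11)   # harmonic mean of two equal ratios
  perfect <- classification_metrics(list(tp = 10, tn = 10, fp = 0, fn = 0))
  expect_true(all(unlist(perfect[c("accuracy", "recall", "specificity",
                                   "precision", "f1")]) == 1))
  # no positives predicted and none present: flagged 0, never NaN
  deg <- classification_metrics(list(tp = 0, tn = 10, fp = 0, fn = 0))
  expect_equal(deg$precision, 0)
  expect_equal(deg$recall, 0)
  expect_true(all(c("precision", "recall") %in% attr(deg, "flagged")))
  expect_error(classification_metrics(list(tp = 0, tn = 0, fp = 0, fn = 0)),
               "no scored")
})

test_that("stratified folds partition the cohort and preserve class ratios", {
  co <- tiny_cohort(100, seed = 2)
  fold <- cardiohawk:::stratified_folds(co$records$label, 5, seed = 3)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(as.vector(table(fold)), rep(20, 5))
  for (f in 1:5) {
    tab <- table(co$records$label[fold == f])
    expect_lte(abs(tab[["normal"]] - tab[["disease"]]), 1)
  }
  expect_identical(fold, cardiohawk:::stratified_folds(co$records$label, 5, 3))
  expect_error(cardiohawk:::stratified_folds(c("a", rep("b", 10)), 3, 1),
               "fewer than k")
})

test_that("kfold scores a constant classifier at the class proportion", {
  co <- tiny_cohort(100, seed = 4)
  res <- kfold(co$records, k = 5,
               train_fn = function(rec, str) "const",
               predict_fn = function(model, rec, str)
                 rep("disease", nrow(rec)),
               seed = 5)
  expect_length(res$folds, 5)
  for (m in res$folds) {
    expect_equal(m$accuracy, 0.5)   # balanced cohort, constant prediction
    expect_equal(m$recall, 1)
    expect_equal(m$specificity, 0)
  }
  expect_equal(res$summary$mean[["accuracy"]], 0.5)
  # folds are disjoint and exhaustive
  expect_equal(sort(unique(res$assignments)), 1:5)
  expect_equal(length(res$assignments), 100)
})

test_that("split sweeps report one timed row per requested ratio", {
  co <- tiny_cohort(100, seed = 6)
  sw <- split_sweep(co$records, ratios = c(0.5, 0.7),
                    train_fn = function(rec, str) {
                      thr <- mean(rec$bp)
                      function(newrec) ifelse(newrec$bp > thr,
                                              "disease", "normal")
                    },
                    predict_fn = function(model, rec, str) model(rec),
                    seed = 7)
  expect_equal(nrow(sw), 2)
  expect_equal(sw$ratio, c(0.5, 0.7))
  expect_true(all(sw$build_seconds >= 0))
  expect_true(all(sw$accuracy > 0.8))   # BP threshold separates the classes
  # a 50:50 split on n = 100 trains on exactly 50 records
  sp <- cardiohawk:::stratified_split(co$records, 0.5, 1)
  expect_equal(nrow(sp$train), 50)
  expect_equal(nrow(sp$test), 50)
})

test_that("multi-run outcomes match order-statistic and moment oracles", {
  const <- multirun_outcomes(rep(0.8, 10))
  expect_equal(const$sd, 0)
  expect_equal(const$best, const$worst)
  expect_equal(const$best, const$mean)
  two <- multirun_outcomes(c(0, 1))
  expect_equal(two$mean, 0.5)
  expect_equal(two$sd, sqrt(0.5), tolerance = 1e-12)   # n-1 denominator
  set.seed(8)
  x <- runif(50)
  mo <- multirun_outcomes(x)
  expect_equal(mo$best, max(x))
  expect_equal(mo$worst, min(x))
  expect_equal(mo$median, sort(x)[c(25, 26)] |> mean())
  expect_equal(mo$variance, mo$sd^2, tolerance = 1e-12)
  expect_equal(mo$sd, sqrt(sum((x - mean(x))^2) / 49), tolerance = 1e-12)
  lo <- multirun_outcomes(x, maximize = FALSE)
  expect_equal(lo$best, min(x))
  expect_error(multirun_outcomes(1), "at least 2")
})
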