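test_that("overall metrics handle identity, anti-correlation, and tied ranks", {
  ds <- toy_grid(2, 2, function(c, d) c + 2 * d)
  m <- overall_metrics(ds, identity_predictions(ds))
  expect_equal(m$pcc, 1)
  expect_equal(m$scc, 1)
  expect_equal(m$rmse, 0)
  expect_equal(m$mae, 0)
  expect_equal(m$r2, 1)
  neg <- prediction_table(data.frame(cell_id = ds$cell_id,
                                     drug_id = ds$drug_id,
                                     predicted = -ds$response))
  m2 <- overall_metrics(ds, neg)
  expect_equal(m2$pcc, -1)
  expect_equal(m2$scc, -1)
  # hand-ranked oracle: truth 1:4, pred {2,1,4,3} -> 1 - 6*4/60 = 0.6
  ds3 <- triplet_dataset(data.frame(cell_id = sprintf("C%d", 1:4),
                                    drug_id = "D1", response = 1:4))
  p3 <- prediction_table(data.frame(cell_id = sprintf("C%d", 1:4),
                                    drug_id = "D1",
                                    predicted = c(2, 1, 4, 3)))
  expect_equal(overall_metrics(ds3, p3)$scc, 0.6)
  # zero-variance predictions -> undefined correlation markers, not zeros
  flat <- prediction_table(data.frame(cell_id = ds$cell_id,
                                      drug_id = ds$drug_id, predicted = 1))
  m4 <- overall_metrics(ds, flat)
  expect_true(is.na(m4$pcc))
  expect_true(is.na(m4$scc))
  expect_false(is.na(m4$rmse))
  expect_error(overall_metrics(ds[1, ], flat), ">= 2 matched")
})

test_that("per-drug metrics expose what overall metrics hide", {
  # within-drug identity, but drug B offset by +10: per-drug SCC perfect,
  # overall RMSE blown up
  ds <- toy_grid(6, 2, function(c, d) c)
  offset <- ifelse(ds$drug_id == "D02", 10, 0)
  pred <- prediction_table(data.frame(cell_id = ds$cell_id,
                                      drug_id = ds$drug_id,
                                      predicted = ds$response + offset))
  pd <- per_drug_metrics(ds, pred)
  expect_equal(pd$scc, c(1, 1))
  expect_gt(overall_metrics(ds, pred)$rmse, 5)
  # below min_pairs -> undefined markers with the count preserved
  small <- triplet_dataset(data.frame(cell_id = c("C1", "C2", "C1", "C2", "C3"),
                                      drug_id = c("DA", "DA", "DB", "DB", "DB"),
                                      response = 1:5))
  pd2 <- per_drug_metrics(small, identity_predictions(small), min_pairs = 3)
  expect_equal(pd2$n_pairs[pd2$drug_id == "DA"], 2)
  expect_true(is.na(pd2$scc[pd2$drug_id == "DA"]))
  expect_equal(pd2$scc[pd2$drug_id == "DB"], 1)
})

test_that("per-cell metrics mirror per-drug and agree with a grouping oracle", {
  set.seed(11)
  ds <- toy_grid(5, 8, function(c, d) rnorm(1))
  pred <- prediction_table(data.frame(cell_id = ds$cell_id,
                                      drug_id = ds$drug_id,
                                      predicted = ds$response + rnorm(40, 0, 0.5)))
  pc <- per_cell_metrics(ds, pred)
  expect_equal(nrow(pc), 5)
  joined <- merge(as.data.frame(ds), as.data.frame(pred))
  for (cell in pc$cell_id) {
    sub <- joined[joined$cell_id == cell, ]
    expect_equal(pc$scc[pc$cell_id == cell],
                 spearman_bf(sub$response, sub$predicted), tolerance = 1e-12)
    expect_equal(pc$rmse[pc$cell_id == cell],
                 rmse_bf(sub$response, sub$predicted), tolerance = 1e-12)
  }
  single <- triplet_dataset(data.frame(cell_id = "C1",
                                       drug_id = sprintf("D%d", 1:5),
                                       response = 1:5))
  expect_equal(nrow(per_cell_metrics(single, identity_predictions(single))), 1)
})

test_that("monotone per-drug transforms leave SCC alone but move overall PCC", {
  set.seed(5)
  ds <- toy_grid(12, 4, function(c, d) rnorm(1))
  pred <- identity_predictions(ds)
  # cube predictions within one drug: a monotone within-drug transform
  warped <- as.data.frame(pred)
  warped$predicted <- ifelse(warped$drug_id == "D02",
                             warped$predicted^3 + 50, warped$predicted)
  warped <- prediction_table(warped)
  expect_equal(per_drug_metrics(ds, warped)$scc, rep(1, 4))
  expect_lt(overall_metrics(ds, warped)$pcc, 0.999)
})

test_that("per-drug residuals reassemble the overall RMSE", {
  set.seed(21)
  ds <- toy_grid(9, 5, function(c, d) rnorm(1))
  pred <- prediction_table(data.frame(cell_id = ds$cell_id,
                                      drug_id = ds$drug_id,
                                      predicted = ds$response + rnorm(45)))
  pd <- per_drug_metrics(ds, pred, min_pairs = 2)
  overall <- overall_metrics(ds, pred)
  expect_equal(overall$rmse^2 * overall$n_pairs,
               sum(pd$n_pairs * pd$rmse^2), tolerance = 1e-12)
})

test_that("fraction_above applies strict inequality and excludes undefined", {
  tab <- tibble::tibble(drug_id = sprintf("D%d", 1:4), n_pairs = 10,
                        pcc = NA, scc = c(0.6, 0.4, 0.9, 0.1), rmse = 1)
  expect_equal(fraction_above(tab)$fraction, 0.5)
  tab$scc <- rep(0.5, 4)
  expect_equal(fraction_above(tab)$fraction, 0)  # strictly greater
  tab$scc <- c(0.6, NA, 0.9, NA)
  fa <- fraction_above(tab)
  expect_equal(fa$fraction, 1)
  expect_equal(fa$n_scorable, 2)
  expect_equal(fa$n_unscorable, 2)
  tab$scc <- rep(NA_real_, 4)
  expect_true(is.na(fraction_above(tab)$fraction))
})

test_that("binary metrics reproduce hand-computed contingency arithmetic", {
  # TP=8 FN=2 FP=1 TN=9 from scores in {0,1} at threshold 0.5
  n <- 20
  calls <- tibble::tibble(
    cell_id = sprintf("C%d", 1:n), drug_id = "D1",
    call = factor(rep(c("sensitive", "resistant"), each = 10),
                  levels = c("sensitive", "resistant", "undefined")))
  score <- c(rep(1, 8), rep(0, 2), rep(1, 1), rep(0, 9))
  pred <- prediction_table(data.frame(cell_id = sprintf("C%d", 1:n),
                                      drug_id = "D1", predicted = score))
  bm <- binary_metrics(calls, pred)
  expect_equal(c(bm$tp, bm$fn, bm$fp, bm$tn), c(8, 2, 1, 9))
  expect_equal(bm$sen, 0.8)
  expect_equal(bm$spc, 0.9)
  expect_equal(bm$gm, sqrt(0.72))
  expect_equal(bm$dor, 36)
  expect_equal(bm$acc, 17 / 20)
  expect_equal(bm$fpr, 0.1)
  expect_equal(bm$mcc, mcc_bf(8, 2, 1, 9))
  # perfect separation
  perfect <- prediction_table(data.frame(cell_id = sprintf("C%d", 1:n),
                                         drug_id = "D1",
                                         predicted = rep(c(1, 0), each = 10)))
  bp <- binary_metrics(calls, perfect)
  expect_equal(bp$auroc, 1)
  expect_equal(bp$mcc, 1)
  expect_equal(bp$auprc, 1)
  # zero contingency cell -> Haldane-corrected DOR, finite
  expect_equal(bp$dor, (10.5 * 10.5) / (0.5 * 0.5))
  # undefined calls excluded and counted; single-class truth -> NA AUROC
  calls2 <- calls
  calls2$call[11:20] <- "undefined"
  expect_error(binary_metrics(calls2[11:20, ], pred), ">= 2 matched")
  calls3 <- calls
  calls3$call[1:3] <- "undefined"
  bm3 <- binary_metrics(calls3, pred)
  expect_equal(bm3$n_undefined_excluded, 3)
  one_class <- calls
  one_class$call <- factor("sensitive",
                           levels = c("sensitive", "resistant", "undefined"))
  expect_true(is.na(binary_metrics(one_class, pred)$auroc))
})

test_that("null scores give chance-level AUROC on balanced labels", {
  aurocs <- sapply(1:200, function(i) {
    withr::with_seed(7000 + i, {
      y <- rep(c(TRUE, FALSE), each = 25)
      calls <- tibble::tibble(cell_id = sprintf("C%d", 1:50), drug_id = "D",
                              call = ifelse(y, "sensitive", "resistant"))
      pred <- prediction_table(data.frame(cell_id = sprintf("C%d", 1:50),
                                          drug_id = "D",
                                          predicted = runif(50)))
      binary_metrics(calls, pred)$auroc
    })
  })
  expect_lt(abs(mean(aurocs) - 0.5), 0.05)
})

test_that("package metrics agree with brute-force oracles on random instances", {
  for (i in 1:100) {
    dat <- withr::with_seed(500 + i, {
      n <- sample(5:40, 1)
      list(y = rnorm(n), yhat = rnorm(n),
           labels = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.5, 0.5)),
           scores = sample(seq(0, 1, 0.1), n, replace = TRUE))  # ties on purpose
    })
    ds <- triplet_dataset(data.frame(cell_id = sprintf("C%d", seq_along(dat$y)),
                                     drug_id = "D1", response = dat$y))
    pred <- prediction_table(data.frame(cell_id = sprintf("C%d", seq_along(dat$y)),
                                        drug_id = "D1", predicted = dat$yhat))
    m <- overall_metrics(ds, pred)
    expect_equal(m$pcc, pearson_bf(dat$y, dat$yhat), tolerance = 1e-12)
    expect_equal(m$scc, spearman_bf(dat$y, dat$yhat), tolerance = 1e-12)
    expect_equal(m$rmse, rmse_bf(dat$y, dat$yhat), tolerance = 1e-12)
    if (any(dat$labels) && any(!dat$labels)) {
      calls <- tibble::tibble(cell_id = sprintf("C%d", seq_along(dat$y)),
                              drug_id = "D1",
                              call = ifelse(dat$labels, "sensitive", "resistant"))
      sc <- prediction_table(data.frame(cell_id = sprintf("C%d", seq_along(dat$y)),
                                        drug_id = "D1", predicted = dat$scores))
      bm <- binary_metrics(calls, sc)
      expect_equal(bm$auroc, auroc_bf(dat$labels, dat$scores), tolerance = 1e-12)
      expect_equal(bm$mcc, mcc_bf(bm$tp, bm$fn, bm$fp, bm$tn), tolerance = 1e-12)
    }
  }
})

test_that("metric_report bundles views consistently", {
  set.seed(99)
  ds <- toy_grid(10, 6, function(c, d) rnorm(1))
  pred <- prediction_table(data.frame(cell_id = ds$cell_id, drug_id = ds$drug_id,
                                      predicted = ds$response + rnorm(60, 0, 0.3)))
  rep <- metric_report(ds, pred)
  expect_equal(rep$summary$fraction,
               fraction_above(rep$per_drug, "scc", 0.5)$fraction)
  expect_equal(nrow(rep$per_drug), 6)
  expect_equal(nrow(rep$per_cell), 10)
  expect_output(print(rep), "per-drug")
})
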