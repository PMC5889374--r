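test_that("a replication is deterministic with fields and denominators", {
  r1 <- run_replication("stringent", 3, 0.4, bank_2pl, seed = 77)
  r2 <- run_replication("stringent", 3, 0.4, bank_2pl, seed = 77)
  expect_equal(r1, r2)
  # rates are multiples of their denominators
  expect_equal(r1$det_05 * 3, round(r1$det_05 * 3))
  expect_equal(r1$fp_05 * 9, round(r1$fp_05 * 9))
  expect_true(all(c(r1$det_05, r1$det_01, r1$fp_05, r1$fp_01) >= 0))
  expect_true(all(c(r1$det_05, r1$det_01, r1$fp_05, r1$fp_01) <= 1))
})

test_that("the study harness aggregates a small grid correctly", {
  st <- run_study(bank_2pl, bias_types = "stringent",
                  n_biased_levels = c(1, 6), rate_levels = c(0.1, 0.6),
                  reps = 3, root_seed = 42)
  expect_equal(nrow(st$outcomes), 4 * 3)
  s <- summary(st)
  expect_equal(nrow(s$per_setting), 4)
  # marginal mean equals the hand aggregate of per-replication rates
  expect_equal(s$by_type$det_05, mean(st$outcomes$det_05))
  man <- tapply(st$outcomes$det_05, st$outcomes$rate, mean)
  expect_equal(s$by_rate$det_05,
               as.vector(man[as.character(s$by_rate$rate)]))
  # rerun with the same root seed reproduces outcomes exactly
  st2 <- run_study(bank_2pl, bias_types = "stringent",
                   n_biased_levels = c(1, 6), rate_levels = c(0.1, 0.6),
                   reps = 3, root_seed = 42)
  expect_equal(st$outcomes, st2$outcomes)
})

test_that("single-replication summaries flag undefined SDs", {
  st <- run_study(bank_2pl, bias_types = "lenient", n_biased_levels = 2,
                  rate_levels = 0.3, reps = 1, root_seed = 8)
  s <- summary(st)
  expect_true(is.na(s$per_setting$det_05_sd))
  expect_equal(s$per_setting$det_05, st$outcomes$det_05)
})

test_that("ANOVA handles constant responses and a two-cell toy exactly", {
  d <- data.frame(y = rep(1, 12),
                  f = rep(c("a", "b"), each = 6))
  out <- factorial_anova(d, response = "y", factors = "f")
  expect_equal(out$sum_sq, c(0, 0), tolerance = 1e-12)
  expect_equal(out$partial_eta_sq[1], 0)
  # 1,1,1 vs 0,0,0: SS_effect = 1.5, SS_residual = 0, eta = 1
  d <- data.frame(y = c(1, 1, 1, 0, 0, 0),
                  f = rep(c("a", "b"), each = 3))
  out <- factorial_anova(d, response = "y", factors = "f")
  expect_equal(out$sum_sq[out$effect == "f"], 1.5)
  expect_equal(out$sum_sq[out$effect == "Residuals"], 0)
  expect_equal(out$partial_eta_sq[out$effect == "f"], 1)
})

test_that("three-way ANOVA matches a brute-force cell-means oracle", {
  set.seed(501)
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), C = c("c1", "c2"),
                   rep = 1:5, stringsAsFactors = FALSE)
  d$y <- runif(nrow(d))
  out <- factorial_anova(d, response = "y", factors = c("A", "B", "C"))

  # oracle: balanced decomposition from cell and marginal means
  gm <- mean(d$y)
  n <- nrow(d)
  mA <- tapply(d$y, d$A, mean); mB <- tapply(d$y, d$B, mean)
  mC <- tapply(d$y, d$C, mean)
  mAB <- tapply(d$y, list(d$A, d$B), mean)
  mAC <- tapply(d$y, list(d$A, d$C), mean)
  mBC <- tapply(d$y, list(d$B, d$C), mean)
  mABC <- tapply(d$y, list(d$A, d$B, d$C), mean)
  ssA <- (n / 2) * sum((mA - gm)^2)
  ssB <- (n / 2) * sum((mB - gm)^2)
  ssC <- (n / 2) * sum((mC - gm)^2)
  ssAB <- (n / 4) * sum((mAB - outer(mA, mB, `+`) + gm)^2)
  ssAC <- (n / 4) * sum((mAC - outer(mA, mC, `+`) + gm)^2)
  ssBC <- (n / 4) * sum((mBC - outer(mB, mC, `+`) + gm)^2)
  cellABC <- mABC
  addABC <- array(0, dim = dim(mABC))
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    addABC[i, j, k] <- mAB[i, j] + mAC[i, k] + mBC[j, k] -
      mA[i] - mB[j] - mC[k] + gm
  }
  ssABC <- (n / 8) * sum((cellABC - addABC)^2)
  ssTot <- sum((d$y - gm)^2)
  ssRes <- ssTot - (ssA + ssB + ssC + ssAB + ssAC + ssBC + ssABC)

  expect_equal(out$sum_sq[out$effect == "A"], ssA, tolerance = 1e-8)
  expect_equal(out$sum_sq[out$effect == "B"], ssB, tolerance = 1e-8)
  expect_equal(out$sum_sq[out$effect == "C"], ssC, tolerance = 1e-8)
  expect_equal(out$sum_sq[out$effect == "A:B"], ssAB, tolerance = 1e-8)
  expect_equal(out$sum_sq[out$effect == "A:C"], ssAC, tolerance = 1e-8)
  expect_equal(out$sum_sq[out$effect == "B:C"], ssBC, tolerance = 1e-8)
  expect_equal(out$sum_sq[out$effect == "A:B:C"], ssABC, tolerance = 1e-8)
  expect_equal(out$sum_sq[out$effect == "Residuals"], ssRes,
               tolerance = 1e-8)
  # F from the oracle sums of squares
  expect_equal(out$F[out$effect == "A"], (ssA / 1) / (ssRes / (n - 8)),
               tolerance = 1e-8)
  # conservation: component SS add up to the total
  expect_equal(sum(out$sum_sq), ssTot, tolerance = 1e-8)
})

test_that("unbalanced designs are refused", {
  d <- data.frame(y = runif(5), f = c("a", "a", "a", "b", "b"))
  expect_error(factorial_anova(d, response = "y", factors = "f"),
               "unbalanced")
})

test_that("effect-size labels follow the 0.01/0.06/0.14 thresholds", {
  expect_equal(classify_effect_size(c(0.005, 0.01, 0.059, 0.06, 0.139,
                                      0.14, 0.53)),
               c("negligible", "small", "small", "medium", "medium",
                 "large", "large"))
  expect_error(classify_effect_size(1.2))
})
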