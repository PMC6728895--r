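test_that("penalty grid divides (0, T] into equal parts", {
  g <- lambda_grid(120, 80)
  expect_equal(g$values[1], 1.5)
  expect_equal(g$values[2], 3.0)
  expect_equal(g$values[80], 120)
  expect_true(all(diff(g$values) > 0))
  expect_equal(lambda_grid(1, 2)$values, c(0.5, 1))
  expect_equal(lambda_grid(7, 1)$values, 7)
  expect_error(lambda_grid(-1, 10), "positive")
  expect_error(lambda_grid(10, 0), "positive")
})

test_that("unpenalized fit matches the logistic MLE and huge penalties give
           the all-zero vector", {
  set.seed(201)
  dat <- logistic_data(300, c(1.2, -0.6), 0.4)
  fit0 <- fit_l1_logistic(dat$y, dat$Theta, 0)
  ml <- glm(dat$y ~ dat$Theta, family = binomial())
  expect_equal(fit0$b, unname(coef(ml)[1]), tolerance = 1e-4)
  expect_equal(fit0$a, unname(coef(ml)[-1]), tolerance = 1e-4)
  lmax <- lambda_max(dat$y, dat$Theta)
  for (lam in c(lmax, lmax * 1.5, 1e4)) {
    fz <- fit_l1_logistic(dat$y, dat$Theta, lam)
    expect_identical(fz$a, c(0, 0))
  }
  just_below <- fit_l1_logistic(dat$y, dat$Theta, lmax * 0.95)
  expect_gt(sum(just_below$a != 0), 0)
  expect_error(fit_l1_logistic(dat$y, dat$Theta, -1), ">= 0")
  expect_error(fit_l1_logistic(c(dat$y[-1], 2), dat$Theta, 1), "0 or 1")
})

test_that("coordinate descent agrees with a proximal-gradient oracle", {
  set.seed(202)
  dat <- logistic_data(200, c(1.4, 0), -0.3)
  fit <- fit_l1_logistic(dat$y, dat$Theta, 20)
  orc <- oracle_prox_l1(dat$y, dat$Theta, 20)
  obj_fit <- l1_objective(dat$y, dat$Theta, fit$b, fit$a, 20)
  expect_lt(abs(obj_fit - orc$objective), 1e-6)
  expect_equal(fit$a, orc$a, tolerance = 1e-4)
})

test_that("coordinate descent agrees with glmnet on the lambda/n scale", {
  skip_if_not_installed("glmnet")
  set.seed(203)
  dat <- logistic_data(400, c(1.1, 0.8, 0), 0.2)
  for (lam in c(5, 20, 60)) {
    fit <- fit_l1_logistic(dat$y, dat$Theta, lam)
    gn <- glmnet::glmnet(dat$Theta, dat$y, family = "binomial",
                         lambda = lam / 400, standardize = FALSE,
                         thresh = 1e-14)
    expect_equal(fit$b, unname(gn$a0), tolerance = 1e-3)
    expect_equal(fit$a, as.numeric(gn$beta), tolerance = 1e-3)
  }
})

test_that("KKT certificates hold along every path", {
  set.seed(204)
  grid <- lambda_grid(120, 40)
  for (r in 1:6) {
    K <- sample(2:3, 1)
    a <- runif(K, 0.7, 1.7) * rbinom(K, 1, 0.7)
    if (all(a == 0)) a[1] <- 1.2
    dat <- logistic_data(150, a, rnorm(1))
    p <- path_fit(dat$y, dat$Theta, grid)
    viol <- vapply(seq_len(grid$W), function(w)
      l1_kkt(dat$y, dat$Theta, p$b[w], p$a[w, ], p$lambda[w]), numeric(1))
    expect_lt(max(viol), 1e-4)
    # candidate pattern is exactly the support
    expect_identical(p$support, matrix(as.integer(p$a != 0), grid$W, K))
  }
})

test_that("warm-started path solutions match cold starts", {
  set.seed(205)
  dat <- logistic_data(250, c(1.3, -0.9), 0.1)
  grid <- lambda_grid(60, 12)
  p <- path_fit(dat$y, dat$Theta, grid)
  for (w in c(1, 5, 12)) {
    cold <- fit_l1_logistic(dat$y, dat$Theta, grid$values[w])
    expect_lt(abs(l1_objective(dat$y, dat$Theta, p$b[w], p$a[w, ],
                               grid$values[w]) -
                  l1_objective(dat$y, dat$Theta, cold$b, cold$a,
                               grid$values[w])), 1e-6)
  }
  # support is non-increasing in the penalty on this well-separated item
  expect_true(all(diff(rowSums(p$support)) <= 0))
})

test_that("BIC follows the Schwarz form", {
  expect_equal(bic(-100, 2, 400), 200 + 2 * log(400))
  expect_equal(bic(0, 0, 10), 0)
  expect_true(all(diff(bic(-50, 1:5, 400)) > 0))
  expect_error(bic(-1, 1, 0), "at least 1")
})

# build a minimal path object with a prescribed BIC row
fake_path <- function(bic_row, support, lambda) {
  W <- length(bic_row)
  structure(list(lambda = lambda, W = W, b = numeric(W),
                 a = support * 0.5, support = support,
                 loglik = numeric(W), df = rowSums(support) + 1,
                 bic = bic_row, n = 100, K = ncol(support)),
            class = "lprm_path")
}

test_that("pattern selection minimizes the BIC with ties toward sparsity", {
  lam <- lambda_grid(4, 4)$values
  sup <- matrix(c(1L, 1L,
                  1L, 0L,
                  1L, 0L,
                  0L, 0L), 4, 2, byrow = TRUE)
  p1 <- fake_path(c(10, 8, 8, 30), sup, lam)
  p2 <- fake_path(c(9, 12, 7, 25), sup, lam)
  joint <- select_optimal_patterns(list(p1, p2), "joint")
  # totals: 19, 20, 15, 55 -> w* = 3
  expect_equal(joint$w_sel, c(3L, 3L))
  expect_identical(joint$Q_hat, rbind(sup[3, ], sup[3, ]))
  per <- select_optimal_patterns(list(p1, p2), "per_item")
  # item 1 ties at w = 2, 3 -> larger lambda wins
  expect_equal(per$w_sel, c(3L, 3L))
  expect_lte(sum(p1$bic[per$w_sel[1]] + p2$bic[per$w_sel[2]]),
             sum(p1$bic[joint$w_sel[1]] + p2$bic[joint$w_sel[2]]))
  # brute force joint minimum
  B <- rbind(p1$bic, p2$bic)
  expect_equal(joint$w_sel[1], unname(which.min(colSums(B))))
  # per-item total never exceeds the joint total, random paths
  set.seed(206)
  for (r in 1:10) {
    ps <- lapply(1:4, function(j)
      fake_path(runif(4, 50, 150), sup, lam))
    B <- do.call(rbind, lapply(ps, `[[`, "bic"))
    tj <- sum(B[cbind(1:4, select_optimal_patterns(ps, "joint")$w_sel)])
    tp <- sum(B[cbind(1:4, select_optimal_patterns(ps, "per_item")$w_sel)])
    expect_lte(tp, tj)
  }
  # single-column grid returns that column in both modes
  p0 <- fake_path(5, sup[2, , drop = FALSE], lam[1])
  expect_equal(select_optimal_patterns(list(p0), "joint")$w_sel, 1L)
  expect_error(select_optimal_patterns(list(p1, fake_path(1:3, sup[1:3, ],
                                                          lam[1:3]))),
               "same penalty grid")
})

test_that("restricted refits recover parameters and closed forms", {
  set.seed(207)
  dat <- logistic_data(400, c(1.4, 0), 0.5)
  # all-zero pattern: closed-form intercept
  f0 <- refit_item(dat$y, dat$Theta, c(0, 0))
  expect_equal(f0$b, qlogis(mean(dat$y)), tolerance = 1e-6)
  expect_identical(f0$a, c(0, 0))
  # all-ones pattern equals the unpenalized lasso fit
  f1 <- refit_item(dat$y, dat$Theta, c(1, 1))
  l0 <- fit_l1_logistic(dat$y, dat$Theta, 0)
  expect_equal(f1$a, l0$a, tolerance = 1e-5)
  expect_equal(f1$b, l0$b, tolerance = 1e-5)
  # restricted refit under the true pattern: recovery over repeated draws
  errs <- vapply(1:5, function(r) {
    dat <- logistic_data(400, c(1.4, 0), 0.5)
    f <- refit_item(dat$y, dat$Theta, c(1, 0))
    expect_identical(f$a[2], 0)
    abs(f$a[1] - 1.4)
  }, numeric(1))
  expect_lt(median(errs), 0.2)
  expect_error(refit_item(c(0, 1), matrix(rnorm(4), 2), c(1, 1)),
               "observations")
})

test_that("pattern recovery is near-perfect with true abilities and highly
           discriminating items", {
  set.seed(208)
  pats <- rbind(c(1, 0), c(0, 1), c(1, 1))[rep(1:3, each = 4), ]
  n <- 400
  paths <- vector("list", nrow(pats))
  for (j in seq_len(nrow(pats))) {
    a <- runif(2, 1.1, 1.7) * pats[j, ]
    dat <- logistic_data(n, a, rnorm(1))
    paths[[j]] <- path_fit(dat$y, dat$Theta, lambda_grid())
  }
  sel <- suppressWarnings(select_optimal_patterns(paths, "joint"))
  expect_gte(csr(pats, sel$Q_hat), 0.98)
})

test_that("detect_patterns accepts long data frames and writes its outputs", {
  set.seed(209)
  scores <- matrix(rnorm(600), 300, 2)
  long <- do.call(rbind, lapply(1:3, function(j) {
    a <- c(1.5, 0) * (if (j < 3) c(1, 0) else c(1, 1)) + c(0, 1.3) * (j == 2)
    ids <- ((j - 1) * 100 + 1):(j * 100 + 100)
    ids <- ids[ids <= 300]
    p <- plogis(drop(scores[ids, ] %*% a))
    data.frame(item_id = j, examinee_id = ids,
               response = as.integer(runif(length(ids)) < p))
  }))
  res <- suppressWarnings(
    detect_patterns(long, scores, grid = lambda_grid(60, 20)))
  expect_s3_class(res, "lprm_result")
  expect_equal(nrow(res$patterns), 3)
  expect_true(all(c("q_1", "q_2", "a_1", "a_2", "b") %in%
                    names(res$patterns)))
  dir <- tempfile()
  write_pattern_result(res, dir)
  expect_true(file.exists(file.path(dir, "patterns.csv")))
  dump <- read.csv(file.path(dir, "path_dump.csv"))
  expect_equal(nrow(dump), 3 * 20)
})
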