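#' Prior specification for MAP scoring and Bayesian item selection
#'
#' The multivariate-normal prior used both by the MAP trait estimator and
#' by Bayesian A-optimality (where its inverse covariance enters the
#' selection criterion). Defaults to a standard normal prior (zero mean,
#' identity covariance), the common default of CAT software; the
#' generating ability covariance can be supplied instead via `cov`.
#'
#' @param K trait dimensionality (used when `mean`/`cov` are missing).
#' @param mean prior mean vector (default zeros).
#' @param cov prior covariance matrix (default identity), symmetric
#'   positive definite.
#' @return An object of class `prior_spec` with `mean`, `cov`, `cov_inv`.
#' @export
prior_spec <- function(K = NULL, mean = NULL, cov = NULL) {
  if (is.null(K)) K <- if (!is.null(mean)) length(mean) else nrow(cov)
  if (is.null(K)) stop("supply 'K', 'mean' or 'cov'")
  if (is.null(mean)) mean <- rep(0, K)
  if (is.null(cov)) cov <- diag(K)
  cov <- as.matrix(cov)
  if (!isTRUE(all.equal(cov, t(cov))) || !all(dim(cov) == length(mean)))
    stop("'cov' must be a symmetric matrix conforming to 'mean'")
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("'cov' must be positive definite")
  structure(list(mean = as.numeric(mean), cov = cov, cov_inv = solve(cov)),
            class = "prior_spec")
}

# normalise an "items" argument to a list(a = m x K matrix, b = m-vector)
.as_item_block <- function(items) {
  if (inherits(items, "item_pool")) return(list(a = items$a, b = items$b))
  if (inherits(items, "item_params"))
    return(list(a = rbind(items$a), b = items$b))
  if (is.list(items) && !is.null(items$a))
    return(list(a = as.matrix(items$a), b = as.numeric(items$b)))
  stop("'items' must be an item_pool, item_params, or list(a =, b =)")
}

#' MAP ability estimate
#'
#' Maximum a posteriori estimate of the ability vector given responses to
#' a set of items under the M2PLM with a multivariate-normal prior.
#' Solved by Newton-Raphson with step halving; the log-posterior is
#' globally concave (logistic likelihood plus Gaussian prior), so the
#' mode is unique. With no responses the estimate is the prior mean and
#' the posterior covariance the prior covariance.
#'
#' @param responses 0/1 vector of length m.
#' @param items the administered items: an [item_pool()] subset or a
#'   `list(a = m x K matrix, b = m-vector)`.
#' @param prior a [prior_spec()].
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter Newton iteration cap; on non-convergence the best
#'   iterate is returned with `converged = FALSE`.
#' @return List with `theta` (MAP estimate), `cov` (inverse of the
#'   accumulated item information at `theta` plus the prior inverse
#'   covariance), `se` (square roots of its diagonal), `info` (item
#'   information only), `converged`, `iterations`.
#' @export
map_estimate <- function(responses, items, prior, tol = 1e-6,
                         max_iter = 50L) {
  stopifnot(inherits(prior, "prior_spec"))
  y <- as.numeric(responses)
  if (!.is_binary(y)) stop("responses must be 0 or 1")
  mu <- prior$mean
  S0inv <- prior$cov_inv
  K <- length(mu)
  if (length(y) == 0L) {
    return(list(theta = mu, cov = prior$cov, se = sqrt(diag(prior$cov)),
                info = matrix(0, K, K), converged = TRUE, iterations = 0L))
  }
  blk <- .as_item_block(items)
  A <- blk$a
  b <- blk$b
  if (nrow(A) != length(y)) stop("one item per response required")
  if (ncol(A) != K) stop(sprintf("items have K = %d; prior has K = %d",
                                 ncol(A), K))
  obj <- function(th) {
    p <- .clip01(plogis(drop(A %*% th) + b))
    sum(y * log(p) + (1 - y) * log(1 - p)) -
      0.5 * drop(crossprod(th - mu, S0inv %*% (th - mu)))
  }
  theta <- mu
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    p <- plogis(drop(A %*% theta) + b)
    g <- drop(crossprod(A, y - p)) - drop(S0inv %*% (theta - mu))
    if (sqrt(sum(g * g)) < tol) {
      converged <- TRUE
      break
    }
    w <- p * (1 - p)
    H <- crossprod(A * w, A) + S0inv
    step <- solve(H, g)
    f0 <- obj(theta)
    t <- 1
    h <- 0L
    while (obj(theta + t * step) < f0 && h < 30L) {
      t <- t / 2
      h <- h + 1L
    }
    theta <- theta + t * step
  }
  if (!converged) {
    p <- plogis(drop(A %*% theta) + b)
    g <- drop(crossprod(A, y - p)) - drop(S0inv %*% (theta - mu))
    converged <- sqrt(sum(g * g)) < tol
    if (!converged)
      warning("MAP estimation did not reach the gradient tolerance; ",
              "returning the best iterate")
  }
  p <- plogis(drop(A %*% theta) + b)
  w <- p * (1 - p)
  info <- crossprod(A * w, A)
  pc <- solve(info + S0inv)
  list(theta = as.numeric(theta), cov = pc, se = sqrt(diag(pc)),
       info = info, converged = converged, iterations = it)
}

# item information summands at theta for a block of items, vectorised
.block_pc <- function(pool, ids, theta) {
  eta <- drop(pool$a[ids, , drop = FALSE] %*% theta) + pool$b[ids]
  p <- plogis(eta)
  p * (1 - p)
}

#' D-optimality item selection
#'
#' Returns the remaining item maximizing the determinant of the
#' accumulated Fisher information plus the candidate item's information,
#' both evaluated at the current ability estimate. A ridge of 1e-6 on the
#' diagonal regularizes the determinant while the accumulated information
#' is still rank-deficient (each item contributes only a rank-one matrix,
#' so every candidate determinant is zero until K linearly independent
#' discrimination vectors have been administered): with the ridge the
#' criterion prefers the maximum-information item at the first step and
#' direction-completing items immediately after, instead of being decided
#' by rounding noise. Candidates within rounding error (relative 1e-9) of
#' the optimum count as tied and the lowest item id wins, making
#' selection deterministic.
#'
#' @param theta_hat current ability estimate.
#' @param info K x K accumulated information of the administered items at
#'   `theta_hat`.
#' @param remaining integer ids of candidate items (rows of `pool`).
#' @param pool an [item_pool()].
#' @return A single item id.
#' @export
select_item_d <- function(theta_hat, info, remaining, pool) {
  if (length(remaining) == 0L) stop("no remaining items to select from")
  remaining <- sort(remaining)
  pc <- .block_pc(pool, remaining, theta_hat)
  ridged <- info + diag(1e-6, nrow(info))
  vals <- vapply(seq_along(remaining), function(i) {
    a <- pool$a[remaining[i], ]
    det(ridged + pc[i] * tcrossprod(a))
  }, numeric(1))
  best <- max(vals)
  remaining[which(vals >= best - 1e-9 * abs(best))[1]]
}

#' Bayesian A-optimality item selection
#'
#' Returns the remaining item minimizing the trace of the inverse of the
#' accumulated information plus the candidate's information plus the
#' prior inverse covariance (the posterior covariance trace after adding
#' the candidate). The prior makes the matrix positive definite even
#' early in the test. Ties break toward the lowest item id.
#'
#' @inheritParams select_item_d
#' @param prior a [prior_spec()] supplying the inverse covariance.
#' @return A single item id.
#' @export
select_item_bayes_a <- function(theta_hat, info, remaining, pool, prior) {
  if (length(remaining) == 0L) stop("no remaining items to select from")
  remaining <- sort(remaining)
  pc <- .block_pc(pool, remaining, theta_hat)
  base <- info + prior$cov_inv
  vals <- vapply(seq_along(remaining), function(i) {
    a <- pool$a[remaining[i], ]
    sum(diag(solve(base + pc[i] * tcrossprod(a))))
  }, numeric(1))
  best <- min(vals)
  remaining[which(vals <= best + 1e-9 * abs(best))[1]]
}

# one administration step bookkeeping shared by the R reference engine
.update_state <- function(state, pool, j, y, prior) {
  state$administered <- c(state$administered, j)
  state$responses <- c(state$responses, y)
  fit <- map_estimate(state$responses,
                      list(a = pool$a[state$administered, , drop = FALSE],
                           b = pool$b[state$administered]),
                      prior)
  state$theta_hat <- fit$theta
  state$info <- fit$info
  state$cov <- fit$cov
  state$se <- fit$se
  state$se_history <- rbind(state$se_history, fit$se)
  state
}

.new_state <- function(pool, prior) {
  list(administered = integer(0), responses = integer(0),
       theta_hat = prior$mean, info = matrix(0, pool$K, pool$K),
       cov = prior$cov, se = sqrt(diag(prior$cov)), se_history = NULL)
}

.administer_loop <- function(theta_true, pool, criterion, prior, stop_fun,
                             uniforms) {
  ops <- operational_ids(pool)
  state <- .new_state(pool, prior)
  step <- 0L
  repeat {
    step <- step + 1L
    remaining <- setdiff(ops, state$administered)
    j <- if (criterion == "D") {
      select_item_d(state$theta_hat, state$info, remaining, pool)
    } else {
      select_item_bayes_a(state$theta_hat, state$info, remaining, pool, prior)
    }
    p <- plogis(sum(pool$a[j, ] * theta_true) + pool$b[j])
    u <- if (is.null(uniforms)) runif(1L) else uniforms[step]
    y <- as.integer(u < p)
    state <- .update_state(state, pool, j, y, prior)
    if (stop_fun(step, state$se)) break
  }
  state$test_length <- step
  class(state) <- "test_state"
  state
}

#' Administer a fixed-length adaptive test to one examinee
#'
#' Pure-R reference administration: items are selected one at a time by
#' the chosen criterion, the response is simulated from the M2PLM at the
#' examinee's true ability, and the MAP estimate (and the information
#' accumulated at it) is refreshed after every response. The first item
#' is selected at the prior mean. Exactly `Z0` distinct operational items
#' are administered. The compiled engine behind [run_cohort()] performs
#' the identical computation.
#'
#' @param theta_true the examinee's true ability vector.
#' @param pool an [item_pool()].
#' @param Z0 test length.
#' @param criterion `"D"` or `"bayesA"`.
#' @param prior a [prior_spec()].
#' @param uniforms optional vector of uniforms (one per step) replacing
#'   `runif()` draws; used for exact comparisons across engines.
#' @return A `test_state` list: `administered`, `responses`, `theta_hat`,
#'   `cov`, `se`, `se_history`, `test_length`.
#' @export
administer_fixed <- function(theta_true, pool, Z0, criterion = c("D", "bayesA"),
                             prior, uniforms = NULL) {
  criterion <- match.arg(criterion)
  if (Z0 > length(operational_ids(pool)))
    stop("'Z0' cannot exceed the number of operational items")
  .administer_loop(theta_true, pool, criterion, prior,
                   function(step, se) step >= Z0, uniforms)
}

#' Administer a variable-length adaptive test to one examinee
#'
#' Standard-error stopping rule: the test ends at the first step, after a
#' minimum of K items, at which every posterior standard error is at or
#' below `se_threshold`, and in any case after `max_items` items.
#'
#' @inheritParams administer_fixed
#' @param se_threshold posterior-SE stopping threshold (0.3 in the
#'   simulation studies).
#' @param max_items hard cap on the test length (100 in the studies).
#' @return A `test_state` list; see [administer_fixed()].
#' @export
administer_variable <- function(theta_true, pool, criterion = c("D", "bayesA"),
                                prior, se_threshold = 0.3, max_items = 100L,
                                uniforms = NULL) {
  criterion <- match.arg(criterion)
  if (se_threshold <= 0) stop("'se_threshold' must be positive")
  K <- pool$K
  .administer_loop(theta_true, pool, criterion, prior,
                   function(step, se)
                     (step >= K && max(se) <= se_threshold) ||
                     step >= max_items,
                   uniforms)
}

#' Fixed-length and variable-length stopping rules
#'
#' Constructors for the stopping-rule argument of [run_cohort()] and
#' [run_config()].
#'
#' @param Z0 fixed test length.
#' @return A list describing the rule.
#' @export
stopping_fixed <- function(Z0 = 50) {
  list(type = "fixed", Z0 = as.integer(Z0))
}

#' @rdname stopping_fixed
#' @param se posterior-SE threshold.
#' @param max_items cap on the number of operational items.
#' @export
stopping_variable <- function(se = 0.3, max_items = 100) {
  list(type = "variable", se = se, max_items = as.integer(max_items))
}

# replenished responses at true abilities; U is an N x Z1 uniform matrix
.replenished_responses <- function(pool, abilities, assignment, U) {
  out <- list()
  for (g in seq_along(assignment$item_groups)) {
    items <- assignment$item_groups[[g]]
    exam <- assignment$examinee_groups[[g]]
    eta <- abilities[exam, , drop = FALSE] %*%
      t(pool$a[items, , drop = FALSE])
    p <- plogis(sweep(eta, 2, pool$b[items], "+"))
    y <- (U[exam, seq_along(items), drop = FALSE] < p) * 1L
    for (s in seq_along(items)) {
      out[[as.character(items[s])]] <-
        list(examinees = exam, responses = as.integer(y[, s]))
    }
  }
  out[order(as.integer(names(out)))]
}

#' Administer an MCAT cohort
#'
#' Runs the full adaptive test for every examinee (compiled engine) and
#' then administers each examinee's assigned replenished items at the
#' true ability. Replenished responses never enter the ability estimates,
#' so their position in the test is immaterial; exposure is recorded for
#' operational items only. All randomness is drawn from the R stream
#' before the compiled loop runs, so results are reproducible under
#' `set.seed()` and identical to the pure-R reference administration.
#'
#' @param pool an [item_pool()].
#' @param abilities N x K matrix of true abilities.
#' @param assignment a [make_group_assignment()] result.
#' @param criterion `"D"` or `"bayesA"`.
#' @param prior a [prior_spec()]; defaults to the standard-normal prior.
#' @param stopping [stopping_fixed()] or [stopping_variable()].
#' @return An object of class `cohort_result`: `theta_hat` and `se`
#'   (N x K), `test_length`, `administered` and `responses` (N x max
#'   length, zero-padded, pool item ids), `exposure_counts` (named, per
#'   operational item), `replenished` (per item: answering examinees and
#'   responses), plus `N`, `K`, `stopping`.
#' @export
run_cohort <- function(pool, abilities, assignment,
                       criterion = c("D", "bayesA"), prior = NULL,
                       stopping = stopping_fixed(50)) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(pool, "item_pool"))
  abilities <- as.matrix(abilities)
  N <- nrow(abilities)
  K <- pool$K
  if (ncol(abilities) != K) stop("'abilities' must have K columns")
  if (is.null(prior)) prior <- prior_spec(K)
  ops <- operational_ids(pool)
  maxlen <- if (stopping$type == "fixed") stopping$Z0 else stopping$max_items
  U <- matrix(runif(N * maxlen), N, maxlen)
  Z1 <- length(assignment$item_groups[[1]])
  Urep <- matrix(runif(N * Z1), N, Z1)
  res <- cpp_run_cohort(pool$a[ops, , drop = FALSE], pool$b[ops],
                        abilities, U,
                        if (criterion == "D") 0L else 1L,
                        prior$mean, prior$cov_inv,
                        if (stopping$type == "fixed") 0L else 1L,
                        if (stopping$type == "fixed") stopping$Z0 else 0L,
                        if (stopping$type == "variable") stopping$se else 0,
                        maxlen)
  administered <- res$administered
  administered[administered > 0L] <- ops[administered[administered > 0L]]
  exposure <- as.integer(res$exposure)
  names(exposure) <- as.character(ops)
  replenished <- .replenished_responses(pool, abilities, assignment, Urep)
  structure(list(theta_hat = res$theta_hat, se = res$se,
                 test_length = as.integer(res$test_length),
                 administered = administered, responses = res$responses,
                 exposure_counts = exposure, replenished = replenished,
                 N = N, K = K, criterion = criterion, stopping = stopping),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("MCAT cohort: N = %d examinees, K = %d traits, %s selection\n",
              x$N, x$K, x$criterion))
  cat(sprintf("  test length: %s (mean %.1f); %d replenished items with %d responses each\n",
              if (x$stopping$type == "fixed") x$stopping$Z0 else
                sprintf("variable (SE <= %.2f, max %d)", x$stopping$se,
                        x$stopping$max_items),
              mean(x$test_length), length(x$replenished),
              length(x$replenished[[1]]$responses)))
  invisible(x)
}

#' Serialize a cohort result to CSV files
#'
#' Writes `theta_hat.csv` (`examinee_id, theta_1..K, se_1..K,
#' test_length`), `replenished_responses.csv`
#' (`item_id, examinee_id, response`) and `exposure.csv`
#' (`item_id, exposure_rate`) under `dir`.
#'
#' @param cohort a [run_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_result <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  K <- cohort$K
  th <- data.frame(examinee_id = seq_len(cohort$N))
  for (k in seq_len(K)) th[[paste0("theta_", k)]] <- cohort$theta_hat[, k]
  for (k in seq_len(K)) th[[paste0("se_", k)]] <- cohort$se[, k]
  th$test_length <- cohort$test_length
  utils::write.csv(th, file.path(dir, "theta_hat.csv"), row.names = FALSE)
  rep_df <- do.call(rbind, lapply(names(cohort$replenished), function(id) {
    blk <- cohort$replenished[[id]]
    data.frame(item_id = as.integer(id), examinee_id = blk$examinees,
               response = blk$responses)
  }))
  utils::write.csv(rep_df, file.path(dir, "replenished_responses.csv"),
                   row.names = FALSE)
  exp_df <- data.frame(item_id = as.integer(names(cohort$exposure_counts)),
                       exposure_rate = cohort$exposure_counts / cohort$N)
  utils::write.csv(exp_df, file.path(dir, "exposure.csv"), row.names = FALSE)
  invisible(dir)
}
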