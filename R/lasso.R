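#' Penalty grid for the L1-regularized path
#'
#' The interval (0, T] is divided into W equal parts and the W grid
#' points `w * T / W`, w = 1..W, are used as penalty values. The defaults
#' T = 120, W = 80 are the calibrated settings of the simulation studies
#' (the penalty multiplies the summed, not averaged, log-likelihood, so
#' T scales with the per-item respondent count).
#'
#' @param T right endpoint of the penalty interval (> 0).
#' @param W number of grid points (>= 1).
#' @return Object of class `lambda_grid` with `T`, `W` and increasing
#'   `values` ending at `T`.
#' @examples
#' lambda_grid(120, 80)$values[1:3]  # 1.5 3.0 4.5
#' @export
lambda_grid <- function(T = 120, W = 80) {
  if (!is.numeric(T) || length(T) != 1L || T <= 0) stop("'T' must be positive")
  W <- as.integer(W)
  if (is.na(W) || W < 1L) stop("'W' must be a positive integer")
  structure(list(T = T, W = W, values = seq_len(W) * (T / W)),
            class = "lambda_grid")
}

#' @export
print.lambda_grid <- function(x, ...) {
  cat(sprintf("Penalty grid: W = %d values, lambda = %.4g .. %.4g (T = %g)\n",
              x$W, x$values[1], x$T, x$T))
  invisible(x)
}

.soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# unpenalized Bernoulli log-likelihood at (b, a)
.logistic_loglik <- function(y, Theta, b, a) {
  p <- .clip01(plogis(drop(Theta %*% a) + b))
  sum(y * log(p) + (1 - y) * log(1 - p))
}

#' L1-penalized logistic regression for one item
#'
#' Minimizes the negative Bernoulli log-likelihood plus
#' `lambda * sum(abs(a))` over the intercept `b` (unpenalized) and the
#' discrimination vector `a`, with the trait scores as fixed covariates.
#' Solved by cyclical coordinate descent on the iteratively reweighted
#' least-squares quadratic surrogate with coordinate-wise soft
#' thresholding, so zeros in `a` are exact. The score columns are not
#' standardized: MAP trait estimates share a common scale by
#' construction, and standardizing would distort the common penalty
#' grid.
#'
#' At convergence the Karush-Kuhn-Tucker conditions of the exact
#' objective hold (see [l1_kkt()]); the IRLS weight floor affects only
#' the iteration path, not the fixed point. Under complete separation at
#' small penalties, coefficients are capped at +/-25 in absolute value
#' and the fit is flagged.
#'
#' @param y 0/1 response vector of length n (n > K required).
#' @param Theta n x K matrix of trait scores.
#' @param lambda penalty (>= 0).
#' @param tol convergence tolerance on the maximum coefficient change.
#' @param max_iter cap on outer reweighting iterations.
#' @param init optional warm start: a list with `b` and `a`.
#' @return List with `b`, `a` (exact zeros off-support), `loglik`
#'   (unpenalized log-likelihood at the solution), `lambda`, `converged`,
#'   `separation`.
#' @export
fit_l1_logistic <- function(y, Theta, lambda, tol = 1e-8, max_iter = 200L,
                            init = NULL) {
  y <- as.numeric(y)
  Theta <- as.matrix(Theta)
  n <- nrow(Theta)
  K <- ncol(Theta)
  if (!.is_binary(y)) stop("responses must be 0 or 1")
  if (length(y) != n) stop("'y' and 'Theta' must have matching rows")
  if (n <= K) stop("need more observations than traits (n > K)")
  if (!is.numeric(lambda) || lambda < 0) stop("'lambda' must be >= 0")
  cap <- 25
  wmin <- 1e-5
  if (is.null(init)) {
    b <- qlogis(.clip01(mean(y), 1e-4))
    a <- numeric(K)
  } else {
    b <- init$b
    a <- init$a
  }
  separation <- FALSE
  converged <- FALSE
  xsq <- NULL
  for (outer in seq_len(max_iter)) {
    old <- c(b, a)
    eta <- drop(Theta %*% a) + b
    p <- plogis(eta)
    w <- pmax(p * (1 - p), wmin)
    z <- eta + (y - p) / w
    sw <- sum(w)
    wx <- Theta * w
    denom <- colSums(wx * Theta)
    r <- z - eta
    # cyclical coordinate descent on the weighted least-squares surrogate
    for (sweep in seq_len(1000L)) {
      delmax <- 0
      dnew <- sum(w * r) / sw
      if (abs(b + dnew) > cap) {       # complete separation guard
        dnew <- sign(b + dnew) * cap - b
        separation <- TRUE
      }
      r <- r - dnew
      b <- b + dnew
      delmax <- max(delmax, abs(dnew))
      for (k in seq_len(K)) {
        zk <- sum(wx[, k] * r) + denom[k] * a[k]
        anew <- .soft(zk, lambda) / denom[k]
        if (abs(anew) > cap) {
          anew <- sign(anew) * cap
          separation <- TRUE
        }
        d <- anew - a[k]
        if (d != 0) {
          r <- r - d * Theta[, k]
          a[k] <- anew
        }
        delmax <- max(delmax, abs(d))
      }
      if (delmax < tol) break
    }
    if (max(abs(c(b, a) - old)) < tol) {
      converged <- TRUE
      break
    }
  }
  list(b = b, a = a, loglik = .logistic_loglik(y, Theta, b, a),
       lambda = lambda, converged = converged, separation = separation)
}

#' KKT residual of an L1-penalized logistic solution
#'
#' Maximum violation of the stationarity conditions of the penalized
#' objective at `(b, a)`: for a zero coordinate the absolute likelihood
#' gradient may not exceed `lambda`; for a nonzero coordinate the
#' gradient plus `lambda * sign(a_k)` must vanish; the intercept gradient
#' must vanish. A correct solution has a residual at the solver
#' tolerance.
#'
#' @inheritParams fit_l1_logistic
#' @param b,a candidate solution.
#' @return Scalar maximum violation (0 = exact stationarity).
#' @export
l1_kkt <- function(y, Theta, b, a, lambda) {
  Theta <- as.matrix(Theta)
  p <- plogis(drop(Theta %*% a) + b)
  gb <- -sum(y - p)                    # d(-l)/db
  ga <- -drop(crossprod(Theta, y - p)) # d(-l)/da_k
  viol <- abs(gb)
  for (k in seq_along(a)) {
    viol <- max(viol, if (a[k] == 0) max(0, abs(ga[k]) - lambda)
                      else abs(ga[k] + lambda * sign(a[k])))
  }
  viol
}

#' Smallest penalty with an all-zero discrimination vector
#'
#' The maximum absolute likelihood gradient over the trait coordinates at
#' the intercept-only fit; any penalty at or above this value yields
#' `a = 0`.
#'
#' @inheritParams fit_l1_logistic
#' @return Scalar.
#' @export
lambda_max <- function(y, Theta) {
  Theta <- as.matrix(Theta)
  max(abs(drop(crossprod(Theta, y - mean(y)))))
}

#' Fit the full penalty path for one item
#'
#' Runs [fit_l1_logistic()] at every grid value, warm-starting each fit
#' from the solution at the next-larger penalty (the path is traversed
#' from sparse to dense). The candidate item-trait pattern at each grid
#' point is the support of the fitted discrimination vector, and a BIC is
#' attached to each point with degrees of freedom equal to the support
#' size plus one for the intercept.
#'
#' @inheritParams fit_l1_logistic
#' @param grid a [lambda_grid()].
#' @param bic_mode `"refit"` (default) evaluates the BIC log-likelihood
#'   at the unpenalized maximum likelihood restricted to the support, so
#'   the criterion compares patterns rather than shrinkage levels;
#'   `"shrunken"` evaluates it at the penalized estimates.
#' @return Object of class `lprm_path`: `lambda`, `b` (W), `a` (W x K),
#'   `support` (W x K 0/1), `loglik`, `df`, `bic`, `n`, `bic_mode`.
#' @export
path_fit <- function(y, Theta, grid = lambda_grid(),
                     bic_mode = c("refit", "shrunken"), tol = 1e-8) {
  bic_mode <- match.arg(bic_mode)
  stopifnot(inherits(grid, "lambda_grid"))
  Theta <- as.matrix(Theta)
  W <- grid$W
  K <- ncol(Theta)
  n <- length(y)
  bmat <- numeric(W)
  amat <- matrix(0, W, K)
  ll <- numeric(W)
  fit <- NULL
  for (w in rev(seq_len(W))) {
    fit <- fit_l1_logistic(y, Theta, grid$values[w], tol = tol, init = fit)
    bmat[w] <- fit$b
    amat[w, ] <- fit$a
    ll[w] <- fit$loglik
  }
  support <- matrix(as.integer(amat != 0), W, K)
  df <- rowSums(support) + 1L
  if (bic_mode == "refit") {
    keys <- apply(support, 1, paste, collapse = "")
    cache <- new.env(parent = emptyenv())
    ll <- vapply(seq_len(W), function(w) {
      key <- keys[w]
      if (is.null(cache[[key]]))
        cache[[key]] <- refit_item(y, Theta, support[w, ])$loglik
      cache[[key]]
    }, numeric(1))
  }
  structure(list(lambda = grid$values, T = grid$T, W = W,
                 b = bmat, a = amat, support = support,
                 loglik = ll, df = df, bic = bic(ll, df, n),
                 n = n, K = K, bic_mode = bic_mode),
            class = "lprm_path")
}

#' @export
print.lprm_path <- function(x, ...) {
  best <- which.min(x$bic)
  cat(sprintf("L1 path: W = %d penalties, n = %d, K = %d; min BIC %.2f at lambda = %.3g (pattern %s)\n",
              x$W, x$n, x$K, x$bic[best], x$lambda[best],
              paste(x$support[best, ], collapse = "")))
  invisible(x)
}

#' Bayesian information criterion
#'
#' Schwarz form `-2 * loglik + df * log(n)`. In the pattern-selection
#' step `df` is the support size of the discrimination vector plus one
#' for the intercept, and `n` is the item's respondent count (400 in the
#' simulation studies), not the cohort size.
#'
#' @param loglik log-likelihood value(s).
#' @param df degrees of freedom.
#' @param n number of observations (>= 1).
#' @return Numeric BIC value(s).
#' @export
bic <- function(loglik, df, n) {
  if (any(n < 1)) stop("'n' must be at least 1")
  -2 * loglik + df * log(n)
}

#' Select optimal item-trait patterns along the path
#'
#' In `"joint"` mode (the default) a single grid index minimizing the
#' total BIC summed over all items is chosen and every item receives its
#' pattern at that penalty — the literal reading of choosing the pattern
#' combination with the minimum of BIC_1..BIC_W. In `"per_item"` mode
#' each item minimizes its own BIC independently. Ties are broken toward
#' the larger penalty (the sparser solution). A warning is raised if any
#' selected support carries a negative discrimination estimate (it still
#' counts as "measured").
#'
#' @param paths list of [path_fit()] results sharing one grid.
#' @param mode `"joint"` or `"per_item"`.
#' @return List with `Q_hat` (J1 x K 0/1 matrix), `w_sel` (selected grid
#'   index per item), `lambda_sel`, `mode`.
#' @export
select_optimal_patterns <- function(paths, mode = c("joint", "per_item")) {
  mode <- match.arg(mode)
  stopifnot(length(paths) >= 1L,
            all(vapply(paths, inherits, TRUE, "lprm_path")))
  lam <- paths[[1]]$lambda
  for (p in paths)
    if (!isTRUE(all.equal(p$lambda, lam)))
      stop("all paths must share the same penalty grid")
  B <- do.call(rbind, lapply(paths, `[[`, "bic"))
  J1 <- length(paths)
  if (mode == "joint") {
    tot <- colSums(B)
    wstar <- max(which(tot == min(tot)))
    w_sel <- rep(wstar, J1)
  } else {
    w_sel <- vapply(seq_len(J1), function(j)
      max(which(B[j, ] == min(B[j, ]))), integer(1))
  }
  Q_hat <- do.call(rbind, lapply(seq_len(J1), function(j)
    paths[[j]]$support[w_sel[j], ]))
  neg <- any(vapply(seq_len(J1), function(j)
    any(paths[[j]]$a[w_sel[j], ] < 0), TRUE))
  if (neg)
    warning("a selected pattern carries a negative discrimination ",
            "estimate; the trait is still counted as measured")
  list(Q_hat = Q_hat, w_sel = w_sel, lambda_sel = lam[w_sel], mode = mode)
}

#' Refit item parameters under a fixed pattern
#'
#' Unpenalized maximum likelihood with the discriminations forced to zero
#' off the pattern support (the simplified relaxed-LASSO refit used for
#' item calibration after pattern detection). Newton-Raphson with step
#' halving to a gradient norm below `tol`; under complete separation the
#' coefficients are capped at +/-25 and flagged.
#'
#' @inheritParams fit_l1_logistic
#' @param Q 0/1 pattern vector of length K.
#' @return List with `a` (length K, zeros exactly off-support), `b`,
#'   `loglik`, `converged`, `separation`.
#' @export
refit_item <- function(y, Theta, Q, tol = 1e-8, max_iter = 100L) {
  y <- as.numeric(y)
  Theta <- as.matrix(Theta)
  Q <- as.integer(Q)
  K <- ncol(Theta)
  if (length(Q) != K || !all(Q %in% c(0L, 1L)))
    stop("'Q' must be a 0/1 vector of length K")
  if (length(y) <= sum(Q) + 1L)
    stop("need more observations than free parameters")
  X <- cbind(1, Theta[, Q == 1L, drop = FALSE])
  beta <- c(qlogis(.clip01(mean(y), 1e-4)), numeric(sum(Q)))
  cap <- 25
  separation <- FALSE
  converged <- FALSE
  obj <- function(bt) {
    p <- .clip01(plogis(drop(X %*% bt)))
    sum(y * log(p) + (1 - y) * log(1 - p))
  }
  for (it in seq_len(max_iter)) {
    p <- plogis(drop(X %*% beta))
    g <- drop(crossprod(X, y - p))
    if (sqrt(sum(g * g)) < tol) {
      converged <- TRUE
      break
    }
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X * w, X)
    step <- tryCatch(solve(H, g), error = function(e) g / max(diag(H)))
    f0 <- obj(beta)
    t <- 1
    h <- 0L
    while (obj(beta + t * step) < f0 && h < 30L) {
      t <- t / 2
      h <- h + 1L
    }
    beta <- beta + t * step
    if (any(abs(beta) > cap)) {
      beta <- pmin(pmax(beta, -cap), cap)
      separation <- TRUE
    }
  }
  a <- numeric(K)
  a[Q == 1L] <- beta[-1L]
  list(a = a, b = beta[1L],
       loglik = .logistic_loglik(y, Theta, beta[1L], a),
       converged = converged || separation, separation = separation)
}

#' Detect item-trait patterns for a batch of replenished items
#'
#' High-level entry point of the pattern-recognition step: given each
#' item's binary responses and the trait scores of the responding
#' examinees, fit the full penalty path per item, select the optimal
#' patterns by BIC, and (optionally) refit the item parameters without
#' penalty under the detected patterns.
#'
#' @param responses either a long data frame with columns `item_id`,
#'   `examinee_id`, `response`, or a named list of per-item lists with
#'   `examinees` and `responses` (the `replenished` component of a
#'   [run_cohort()] result).
#' @param scores trait scores: a matrix whose rows are indexed by
#'   examinee id, or a data frame with `examinee_id` and `theta_1..K`.
#' @param grid a [lambda_grid()].
#' @param selection pattern selection mode, see
#'   [select_optimal_patterns()].
#' @param bic_mode see [path_fit()].
#' @param refit if `TRUE`, re-estimate `(a, b)` by restricted maximum
#'   likelihood under each detected pattern.
#' @return Object of class `lprm_result`: `patterns` (data frame with
#'   `item_id`, `q_1..q_K`, `lambda_index`, `lambda`, refit `a_1..a_K`,
#'   `b`), `Q_hat`, `paths`, and the refit list.
#' @export
detect_patterns <- function(responses, scores, grid = lambda_grid(),
                            selection = c("joint", "per_item"),
                            bic_mode = c("refit", "shrunken"),
                            refit = TRUE) {
  selection <- match.arg(selection)
  bic_mode <- match.arg(bic_mode)
  if (is.data.frame(responses)) {
    stopifnot(all(c("item_id", "examinee_id", "response") %in%
                    names(responses)))
    responses <- lapply(split(responses, responses$item_id), function(d)
      list(examinees = d$examinee_id, responses = d$response))
  }
  if (is.data.frame(scores)) {
    stopifnot("examinee_id" %in% names(scores))
    thcols <- grep("^theta_[0-9]+$", names(scores), value = TRUE)
    m <- as.matrix(scores[, sort(thcols), drop = FALSE])
    rownames(m) <- NULL
    scores_mat <- matrix(NA_real_, max(scores$examinee_id), ncol(m))
    scores_mat[scores$examinee_id, ] <- m
    scores <- scores_mat
  }
  ids <- names(responses)
  if (is.null(ids)) ids <- as.character(seq_along(responses))
  paths <- lapply(responses, function(blk)
    path_fit(blk$responses, scores[blk$examinees, , drop = FALSE],
             grid = grid, bic_mode = bic_mode))
  sel <- select_optimal_patterns(paths, mode = selection)
  K <- ncol(sel$Q_hat)
  refits <- NULL
  if (refit) {
    refits <- lapply(seq_along(responses), function(j)
      refit_item(responses[[j]]$responses,
                 scores[responses[[j]]$examinees, , drop = FALSE],
                 sel$Q_hat[j, ]))
  }
  patterns <- data.frame(item_id = ids)
  for (k in seq_len(K)) patterns[[paste0("q_", k)]] <- sel$Q_hat[, k]
  patterns$lambda_index <- sel$w_sel
  patterns$lambda <- sel$lambda_sel
  if (refit) {
    for (k in seq_len(K))
      patterns[[paste0("a_", k)]] <-
        vapply(refits, function(f) f$a[k], numeric(1))
    patterns$b <- vapply(refits, `[[`, numeric(1), "b")
  }
  structure(list(patterns = patterns, Q_hat = sel$Q_hat, w_sel = sel$w_sel,
                 paths = paths, refits = refits, selection = selection),
            class = "lprm_result")
}

#' @export
print.lprm_result <- function(x, ...) {
  cat(sprintf("LPRM pattern detection: %d items, %s BIC selection\n",
              nrow(x$patterns), x$selection))
  print(utils::head(x$patterns, 10))
  if (nrow(x$patterns) > 10) cat("  ...\n")
  invisible(x)
}

#' Write pattern-detection results
#'
#' Writes the detected patterns (and refits) to `patterns.csv` and the
#' full per-item penalty path (intercepts, discriminations, BIC) to
#' `path_dump.csv` under `dir`.
#'
#' @param x an [detect_patterns()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pattern_result <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$patterns, file.path(dir, "patterns.csv"),
                   row.names = FALSE)
  dump <- do.call(rbind, lapply(seq_along(x$paths), function(j) {
    p <- x$paths[[j]]
    d <- data.frame(item_id = x$patterns$item_id[j],
                    lambda = p$lambda, b = p$b)
    for (k in seq_len(p$K)) d[[paste0("a_", k)]] <- p$a[, k]
    d$loglik <- p$loglik
    d$df <- p$df
    d$bic <- p$bic
    d
  }))
  utils::write.csv(dump, file.path(dir, "path_dump.csv"), row.names = FALSE)
  invisible(dir)
}
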