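# Independent oracles: kept deliberately naive and separate from the
# implementations they check.

# penalized objective: negative summed log-likelihood + lambda * ||a||_1
l1_objective <- function(y, Theta, b, a, lambda) {
  p <- pmin(pmax(plogis(drop(Theta %*% a) + b), 1e-12), 1 - 1e-12)
  -sum(y * log(p) + (1 - y) * log(1 - p)) + lambda * sum(abs(a))
}

# proximal-gradient (ISTA) solver with backtracking line search
oracle_prox_l1 <- function(y, Theta, lambda, iters = 20000L) {
  n <- nrow(Theta)
  K <- ncol(Theta)
  b <- 0
  a <- numeric(K)
  L <- 0.25 * max(colSums(cbind(1, Theta)^2))  # Lipschitz bound
  for (i in seq_len(iters)) {
    p <- plogis(drop(Theta %*% a) + b)
    gb <- -sum(y - p)
    ga <- -drop(crossprod(Theta, y - p))
    b_new <- b - gb / L
    a_new <- sign(a - ga / L) * pmax(abs(a - ga / L) - lambda / L, 0)
    if (max(abs(c(b_new - b, a_new - a))) < 1e-10) {
      b <- b_new
      a <- a_new
      break
    }
    b <- b_new
    a <- a_new
  }
  list(b = b, a = a, objective = l1_objective(y, Theta, b, a, lambda))
}

# dense grid search for the one-dimensional MAP posterior mode
oracle_grid_map_1d <- function(responses, a, b, prior_sd = 1) {
  grid <- seq(-4, 4, by = 1e-3)
  lp <- vapply(grid, function(th) {
    p <- pmin(pmax(plogis(a * th + b), 1e-12), 1 - 1e-12)
    sum(responses * log(p) + (1 - responses) * log(1 - p)) -
      0.5 * th^2 / prior_sd^2
  }, numeric(1))
  grid[which.max(lp)]
}
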