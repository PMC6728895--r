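# Small deterministic fixtures used across test files.

# shrunken two-dimensional design: 24 operational + 6 replenished items,
# 40 examinees, 2 groups of 3 replenished items
small_design <- function(N = 40, Z0 = 10) {
  study_design(K = 2,
               pattern_layout = data.frame(pattern = c("10", "01", "11"),
                                           operational = 8,
                                           replenished = 2),
               disc_range = c(1.1, 1.7), N = N, ability_cov = diag(2),
               Z0 = Z0, Z1 = 3, n_groups = 2)
}

# random toy pool for selection-oracle tests
toy_pool <- function(J = 20, K = 2) {
  q <- matrix(0L, J, K)
  for (j in seq_len(J)) q[j, sample(K, sample(K, 1))] <- 1L
  a <- matrix(runif(J * K, 0.7, 1.7), J, K) * q
  item_pool(a = a, b = rnorm(J), role = rep("operational", J))
}

# synthetic single-item data for the L1 solver tests
logistic_data <- function(n, a, b) {
  K <- length(a)
  Theta <- matrix(rnorm(n * K), n, K)
  p <- plogis(drop(Theta %*% a) + b)
  list(y = as.integer(runif(n) < p), Theta = Theta)
}

.pool_item_test <- function(pool, j) item_params(pool$a[j, ], pool$b[j])
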