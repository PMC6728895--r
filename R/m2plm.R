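#' Item parameters for the M2PLM
#'
#' Bundle the discrimination vector, intercept and (optionally) the true
#' item-trait pattern of a single item under the compensatory
#' multidimensional two-parameter logistic model. The pattern defaults to
#' the support of the discrimination vector.
#'
#' @param a numeric vector of K discrimination parameters.
#' @param b scalar intercept.
#' @param Q optional 0/1 vector of length K marking which traits the item
#'   measures; defaults to `as.integer(a != 0)`.
#' @return An object of class `item_params`.
#' @examples
#' it <- item_params(a = c(1.2, 0), b = -0.5)
#' it$Q  # 1 0
#' @export
item_params <- function(a, b, Q = NULL) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(b) != 1L || !is.finite(b)) stop("'b' must be a finite scalar")
  if (!all(is.finite(a))) stop("'a' must be finite")
  if (is.null(Q)) {
    Q <- as.integer(a != 0)
  } else {
    Q <- as.integer(Q)
    if (length(Q) != length(a)) stop("'Q' must have the same length as 'a'")
    if (!all(Q %in% c(0L, 1L))) stop("'Q' entries must be 0 or 1")
  }
  structure(list(a = a, b = b, Q = Q), class = "item_params")
}

#' @export
print.item_params <- function(x, ...) {
  cat("M2PLM item: K =", length(x$a),
      " a = (", paste(signif(x$a, 4), collapse = ", "),
      ")  b =", signif(x$b, 4),
      " pattern =", paste(x$Q, collapse = ""), "\n")
  invisible(x)
}

.check_theta <- function(theta, item) {
  K <- length(item$a)
  theta <- as.numeric(theta)
  if (length(theta) != K)
    stop(sprintf("ability vector has length %d; expected K = %d",
                 length(theta), K))
  theta
}

#' Response probability under the M2PLM
#'
#' Probability of a correct (1) response given an ability vector and item
#' parameters: the standard logistic function of the linear predictor
#' \eqn{a^T \theta + b}.
#'
#' @param theta ability vector of length K.
#' @param item an [item_params()] object.
#' @return A probability strictly inside (0, 1).
#' @export
response_probability <- function(theta, item) {
  theta <- .check_theta(theta, item)
  plogis(sum(item$a * theta) + item$b)
}

#' Log-likelihood of binary responses to one item
#'
#' Bernoulli log-likelihood of a vector of 0/1 responses to a single item
#' for given ability vectors. Probabilities are clipped to
#' \[1e-12, 1 - 1e-12\] before taking logs so the value stays finite at
#' extreme abilities.
#'
#' @param responses 0/1 vector of length n.
#' @param thetas n x K matrix of ability vectors (one row per response).
#' @param item an [item_params()] object.
#' @return Scalar log-likelihood (<= 0); 0 for empty data.
#' @export
log_likelihood <- function(responses, thetas, item) {
  responses <- as.numeric(responses)
  if (!.is_binary(responses)) stop("responses must be 0 or 1")
  thetas <- rbind(thetas)  # vector -> 1 x K
  if (length(responses) == 0L) return(0)
  if (nrow(thetas) != length(responses))
    stop("'responses' and 'thetas' must have the same number of rows")
  if (ncol(thetas) != length(item$a))
    stop(sprintf("ability matrix has %d columns; expected K = %d",
                 ncol(thetas), length(item$a)))
  p <- .clip01(plogis(drop(thetas %*% item$a) + item$b))
  sum(responses * log(p) + (1 - responses) * log(1 - p))
}

#' Fisher information matrix of one item
#'
#' For the M2PLM the Fisher information contributed by a single item at
#' ability `theta` is \eqn{P(1-P)\, a a^T}: a rank-one, symmetric,
#' positive semi-definite K x K matrix.
#'
#' @inheritParams response_probability
#' @return K x K matrix.
#' @export
fisher_information <- function(theta, item) {
  theta <- .check_theta(theta, item)
  p <- response_probability(theta, item)
  p * (1 - p) * tcrossprod(item$a)
}

#' Simulate a single binary response
#'
#' Bernoulli draw with success probability [response_probability()].
#' Uses the R random number stream, so results are reproducible under
#' `set.seed()`.
#'
#' @inheritParams response_probability
#' @return Integer 0 or 1.
#' @export
simulate_response <- function(theta, item) {
  as.integer(runif(1L) < response_probability(theta, item))
}

# ---- item pools ------------------------------------------------------------

#' Construct an item pool
#'
#' An item pool holds the parameters of all operational and replenished
#' items measuring K latent traits.
#'
#' @param a J x K matrix of discrimination parameters (0 where a trait is
#'   not measured).
#' @param b length-J vector of intercepts.
#' @param role character vector of length J with values `"operational"` or
#'   `"replenished"`.
#' @param Q optional J x K 0/1 pattern matrix; defaults to the support of
#'   `a`.
#' @return An object of class `item_pool` with elements `a`, `b`, `Q`,
#'   `role`, `K`, `J`.
#' @seealso [generate_item_pool()], [read_item_pool()]
#' @export
item_pool <- function(a, b, role, Q = NULL) {
  a <- as.matrix(a)
  b <- as.numeric(b)
  J <- nrow(a)
  if (length(b) != J) stop("'b' must have one entry per item")
  role <- as.character(role)
  if (length(role) != J || !all(role %in% c("operational", "replenished")))
    stop("'role' must be 'operational' or 'replenished' for every item")
  if (is.null(Q)) {
    Q <- matrix(as.integer(a != 0), J, ncol(a))
  } else {
    Q <- as.matrix(Q)
    storage.mode(Q) <- "integer"
    if (!all(dim(Q) == dim(a))) stop("'Q' must have the same shape as 'a'")
    if (!all(Q %in% c(0L, 1L))) stop("'Q' entries must be 0 or 1")
  }
  structure(list(a = a, b = b, Q = Q, role = role,
                 K = ncol(a), J = J),
            class = "item_pool")
}

#' @export
print.item_pool <- function(x, ...) {
  cat(sprintf("Item pool: %d items (%d operational, %d replenished), K = %d traits\n",
              x$J, sum(x$role == "operational"),
              sum(x$role == "replenished"), x$K))
  rng <- range(x$a[x$Q == 1L])
  cat(sprintf("  nonzero discriminations in [%.3f, %.3f]; intercepts in [%.3f, %.3f]\n",
              rng[1], rng[2], min(x$b), max(x$b)))
  invisible(x)
}

#' @rdname item_pool
#' @param pool an `item_pool`.
#' @export
operational_ids <- function(pool) which(pool$role == "operational")

#' @rdname item_pool
#' @export
replenished_ids <- function(pool) which(pool$role == "replenished")

# single item as item_params
.pool_item <- function(pool, j) item_params(pool$a[j, ], pool$b[j], pool$Q[j, ])

#' Read/write an item pool as a delimited table
#'
#' The on-disk format is a CSV with header
#' `item_id, role, b, a_1..a_K, q_1..q_K`.
#'
#' @param pool an [item_pool()].
#' @param file path to a CSV file.
#' @return `read_item_pool()` returns an `item_pool`;
#'   `write_item_pool()` returns `file` invisibly.
#' @export
write_item_pool <- function(pool, file) {
  K <- pool$K
  df <- data.frame(item_id = seq_len(pool$J), role = pool$role, b = pool$b)
  a <- as.data.frame(pool$a)
  names(a) <- paste0("a_", seq_len(K))
  q <- as.data.frame(pool$Q)
  names(q) <- paste0("q_", seq_len(K))
  utils::write.csv(cbind(df, a, q), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_item_pool
#' @export
read_item_pool <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  acols <- grep("^a_[0-9]+$", names(df), value = TRUE)
  qcols <- grep("^q_[0-9]+$", names(df), value = TRUE)
  need <- c("item_id", "role", "b")
  if (!all(need %in% names(df)) || length(acols) == 0L ||
      length(acols) != length(qcols))
    stop("item pool table must have columns item_id, role, b, a_1..a_K, q_1..q_K")
  ord <- order(df$item_id)
  df <- df[ord, , drop = FALSE]
  item_pool(a = unname(as.matrix(df[, acols[order(acols)], drop = FALSE])),
            b = df$b, role = df$role,
            Q = unname(as.matrix(df[, qcols[order(qcols)], drop = FALSE])))
}
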