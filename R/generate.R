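#' Generate a synthetic item pool from a study design
#'
#' Items are laid out operational-first, grouped by item-trait pattern in
#' the order of `design$pattern_layout`, with the replenished items
#' appended in the same pattern order. For every item the nonzero
#' discriminations (where the pattern has a 1) are drawn uniformly from
#' `design$disc_range` and the intercept from the standard normal; both
#' operational and replenished items share these distributions. Uses the
#' R random number stream.
#'
#' @param design a [study_design()].
#' @return An [item_pool()] whose pattern matrix has no all-zero rows and
#'   whose `Q` equals the support of `a` exactly.
#' @export
generate_item_pool <- function(design) {
  stopifnot(inherits(design, "study_design"))
  K <- design$K
  lay <- design$pattern_layout
  one_block <- function(pattern, count) {
    q <- .pattern_to_vec(pattern, K)
    a <- matrix(0, count, K)
    nsup <- sum(q)
    a[, q == 1L] <- matrix(runif(count * nsup, design$disc_range[1],
                                 design$disc_range[2]), count, nsup)
    a
  }
  a_op <- do.call(rbind, Map(one_block, lay$pattern, lay$operational))
  a_rep <- do.call(rbind, Map(one_block, lay$pattern, lay$replenished))
  a <- rbind(a_op, a_rep)
  b <- rnorm(nrow(a))
  role <- rep(c("operational", "replenished"), c(design$J0, design$J1))
  item_pool(a = a, b = b, role = role)
}

#' Sample examinee abilities
#'
#' Draws `N` i.i.d. ability vectors from a multivariate normal with mean
#' zero and the given covariance.
#'
#' @param N number of examinees.
#' @param cov K x K symmetric positive definite covariance matrix.
#' @return N x K matrix of abilities.
#' @export
generate_abilities <- function(N, cov) {
  cov <- as.matrix(cov)
  if (!isTRUE(all.equal(cov, t(cov))))
    stop("'cov' must be symmetric")
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("'cov' must be positive definite")
  MASS::mvrnorm(N, mu = rep(0, ncol(cov)), Sigma = cov)
}

#' Assign replenished items and examinees to groups
#'
#' Partitions the replenished items into `n_groups` blocks of `Z1` items
#' and the examinees into `n_groups` equal blocks; examinees in group g
#' answer exactly the items of group g, so each replenished item is
#' answered by `N / n_groups` examinees. Items are spread round-robin by
#' pattern, so every group receives the same number of items of each
#' pattern (two per pattern in the two-dimensional designs, one per
#' pattern in the three-dimensional designs); the item order within a
#' group is then shuffled using the R random number stream.
#'
#' @param design a [study_design()].
#' @return A list of class `group_assignment` with `item_groups` and
#'   `examinee_groups`, each a list of `n_groups` disjoint, exhaustive
#'   integer vectors (item ids refer to rows of the generated pool).
#' @export
make_group_assignment <- function(design) {
  stopifnot(inherits(design, "study_design"))
  G <- design$n_groups
  lay <- design$pattern_layout
  item_groups <- vector("list", G)
  next_id <- design$J0 + 1L
  for (r in seq_len(nrow(lay))) {
    cnt <- lay$replenished[r]
    ids <- seq.int(next_id, length.out = cnt)
    next_id <- next_id + cnt
    grp <- ((seq_len(cnt) - 1L) %% G) + 1L   # round-robin by pattern
    for (g in seq_len(G))
      item_groups[[g]] <- c(item_groups[[g]], ids[grp == g])
  }
  item_groups <- lapply(item_groups, function(ids)
    if (length(ids) > 1L) sample(ids) else ids)
  per <- design$N %/% G
  examinee_groups <- split(seq_len(design$N), rep(seq_len(G), each = per))
  names(examinee_groups) <- NULL
  structure(list(item_groups = item_groups,
                 examinee_groups = examinee_groups),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  G <- length(x$item_groups)
  cat(sprintf("Group assignment: %d groups, %d items and %d examinees per group\n",
              G, length(x$item_groups[[1]]), length(x$examinee_groups[[1]])))
  invisible(x)
}
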