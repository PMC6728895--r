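#' Define a simulation study design
#'
#' A study design collects everything needed to generate one synthetic
#' MCAT cohort: the trait dimensionality, the composition of the item
#' pool by item-trait pattern, the discrimination range, the examinee
#' sample, the ability covariance, and the replenished-item assignment
#' layout.
#'
#' @param K number of latent traits.
#' @param pattern_layout data frame with columns `pattern` (binary string
#'   of length K, e.g. `"10"`), `operational` and `replenished` (item
#'   counts per pattern).
#' @param disc_range length-2 numeric; nonzero discriminations are drawn
#'   uniformly from this interval.
#' @param N examinee sample size.
#' @param ability_cov K x K ability covariance matrix (symmetric positive
#'   definite, unit diagonal).
#' @param Z0 operational test length under the fixed-length rule.
#' @param Z1 number of replenished items administered to each examinee.
#' @param n_groups number of replenished-item / examinee groups; each
#'   replenished item is answered by `N / n_groups` examinees.
#' @return An object of class `study_design`.
#' @seealso [design_preset()] for the shipped two- and three-dimensional
#'   designs.
#' @export
study_design <- function(K, pattern_layout, disc_range, N, ability_cov,
                         Z0, Z1, n_groups) {
  pattern_layout <- as.data.frame(pattern_layout)
  stopifnot(all(c("pattern", "operational", "replenished") %in%
                  names(pattern_layout)))
  pats <- as.character(pattern_layout$pattern)
  if (any(nchar(pats) != K) || any(!grepl("^[01]+$", pats)))
    stop("each pattern must be a 0/1 string of length K")
  if (any(vapply(pats, function(p) !grepl("1", p), TRUE)))
    stop("all-zero item-trait patterns are not allowed")
  J0 <- sum(pattern_layout$operational)
  J1 <- sum(pattern_layout$replenished)
  ability_cov <- as.matrix(ability_cov)
  if (!isTRUE(all.equal(ability_cov, t(ability_cov))) ||
      !all(dim(ability_cov) == K))
    stop("'ability_cov' must be a symmetric K x K matrix")
  if (!isTRUE(all.equal(unname(diag(ability_cov)), rep(1, K))))
    stop("'ability_cov' must have a unit diagonal")
  ev <- eigen(ability_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("'ability_cov' must be positive definite")
  if (J1 != n_groups * Z1)
    stop("J1 must equal n_groups * Z1 (got J1 = ", J1, ", n_groups * Z1 = ",
         n_groups * Z1, ")")
  if (N %% n_groups != 0)
    stop("'N' must be divisible by 'n_groups'")
  if (any(pattern_layout$replenished %% n_groups != 0))
    stop("each pattern's replenished count must be divisible by 'n_groups'")
  if (Z0 > J0) stop("'Z0' cannot exceed the number of operational items")
  structure(list(K = K, J0 = J0, J1 = J1,
                 pattern_layout = pattern_layout,
                 disc_range = as.numeric(disc_range),
                 N = as.integer(N), ability_cov = ability_cov,
                 Z0 = as.integer(Z0), Z1 = as.integer(Z1),
                 n_groups = as.integer(n_groups)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design: K = %d, J0 = %d operational + J1 = %d replenished items\n",
              x$K, x$J0, x$J1))
  cat(sprintf("  a ~ U(%.2f, %.2f), b ~ N(0,1); N = %d examinees, Z0 = %d, Z1 = %d, %d groups\n",
              x$disc_range[1], x$disc_range[2], x$N, x$Z0, x$Z1, x$n_groups))
  od <- x$ability_cov[upper.tri(x$ability_cov)]
  cat("  ability covariance off-diagonals:",
      paste(signif(od, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Shipped study designs
#'
#' Named presets for the simulation studies: two-dimensional pools with
#' 900 operational + 30 replenished items split evenly over the patterns
#' 10/01/11, and three-dimensional pools with 910 operational + 35
#' replenished items split evenly over the seven nonzero 3-bit patterns.
#' `"moderate"` pools draw nonzero discriminations from U(0.7, 1.3),
#' `"high"` pools from U(1.1, 1.7); intercepts are standard normal.
#'
#' @param name one of `"study1_moderate"`, `"study1_high"`,
#'   `"study2_moderate"`, `"study2_high"`.
#' @param correlated if `TRUE`, use the correlated ability covariance
#'   (off-diagonal 0.3 in two dimensions; 0.2/0.3/0.5 in three);
#'   otherwise the identity.
#' @param Z0 fixed-length operational test length (50 by default; 25 is
#'   the short-test condition).
#' @param N examinee sample size (2000 by default).
#' @return A [study_design()].
#' @examples
#' design_preset("study1_high")
#' @export
design_preset <- function(name = c("study1_moderate", "study1_high",
                                   "study2_moderate", "study2_high"),
                          correlated = FALSE, Z0 = 50, N = 2000) {
  name <- match.arg(name)
  moderate <- grepl("moderate", name)
  disc <- if (moderate) c(0.7, 1.3) else c(1.1, 1.7)
  if (grepl("study1", name)) {
    layout <- data.frame(pattern = c("10", "01", "11"),
                         operational = 300, replenished = 10)
    cov <- if (correlated) matrix(c(1, 0.3, 0.3, 1), 2) else diag(2)
    study_design(K = 2, pattern_layout = layout, disc_range = disc,
                 N = N, ability_cov = cov, Z0 = Z0, Z1 = 6, n_groups = 5)
  } else {
    layout <- data.frame(pattern = c("100", "010", "001", "110", "101",
                                     "011", "111"),
                         operational = 130, replenished = 5)
    cov <- if (correlated) {
      matrix(c(1, 0.2, 0.3,
               0.2, 1, 0.5,
               0.3, 0.5, 1), 3)
    } else diag(3)
    study_design(K = 3, pattern_layout = layout, disc_range = disc,
                 N = N, ability_cov = cov, Z0 = Z0, Z1 = 7, n_groups = 5)
  }
}

.pattern_to_vec <- function(pattern, K) {
  as.integer(strsplit(pattern, "")[[1]])
}
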