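#' Correct specification rate
#'
#' Fraction of item-by-trait pattern entries on which the detected
#' patterns agree with the truth.
#'
#' @param Q_true,Q_hat J1 x K 0/1 matrices (or vectors of equal length).
#' @return Proportion in \[0, 1\].
#' @export
csr <- function(Q_true, Q_hat) {
  Q_true <- as.matrix(Q_true)
  Q_hat <- as.matrix(Q_hat)
  if (!all(dim(Q_true) == dim(Q_hat)))
    stop("'Q_true' and 'Q_hat' must have the same shape")
  mean(Q_true == Q_hat)
}

#' Ability recovery indices
#'
#' Mean absolute error and root mean squared error of ability estimates,
#' averaged over all N x K entries.
#'
#' @param theta_true,theta_hat N x K matrices.
#' @return Scalar error.
#' @export
ame_theta <- function(theta_true, theta_hat) {
  theta_true <- as.matrix(theta_true)
  theta_hat <- as.matrix(theta_hat)
  if (!all(dim(theta_true) == dim(theta_hat)))
    stop("'theta_true' and 'theta_hat' must have the same shape")
  mean(abs(theta_hat - theta_true))
}

#' @rdname ame_theta
#' @export
rmse_theta <- function(theta_true, theta_hat) {
  theta_true <- as.matrix(theta_true)
  theta_hat <- as.matrix(theta_hat)
  if (!all(dim(theta_true) == dim(theta_hat)))
    stop("'theta_true' and 'theta_hat' must have the same shape")
  sqrt(mean((theta_hat - theta_true)^2))
}

#' Item-parameter recovery indices
#'
#' Mean absolute errors of the discrimination matrix (over all J1 x K
#' entries, including structural zeros, so pattern errors propagate into
#' the discrimination error) and of the intercept vector.
#'
#' @param a_true,a_hat J1 x K discrimination matrices.
#' @param b_true,b_hat length-J1 intercept vectors.
#' @return List with `a` and `b` mean absolute errors.
#' @export
ame_item <- function(a_true, a_hat, b_true, b_hat) {
  a_true <- as.matrix(a_true)
  a_hat <- as.matrix(a_hat)
  if (!all(dim(a_true) == dim(a_hat)))
    stop("'a_true' and 'a_hat' must have the same shape")
  if (length(b_true) != length(b_hat))
    stop("'b_true' and 'b_hat' must have the same length")
  list(a = mean(abs(a_hat - a_true)), b = mean(abs(b_hat - b_true)))
}

#' Exposure summary of the operational items
#'
#' Collects per-item observed exposure rates together with the test
#' design constants needed by the exposure diagnostics. Can be built
#' directly from a fixed-length [run_cohort()] result.
#'
#' @param x either a numeric vector of exposure rates (one per
#'   operational item) or a `cohort_result` from a fixed-length run.
#' @param N examinee count (required for numeric `x`).
#' @param Z0 fixed test length.
#' @param J0 operational pool size (defaults to `length(x)`).
#' @return Object of class `exposure_summary` with `rates`, `N`, `Z0`,
#'   `J0`.
#' @export
exposure_summary <- function(x, N = NULL, Z0 = NULL, J0 = NULL) {
  if (inherits(x, "cohort_result")) {
    if (x$stopping$type != "fixed")
      stop("exposure diagnostics are defined for fixed-length tests")
    return(exposure_summary(x$exposure_counts / x$N, N = x$N,
                            Z0 = x$stopping$Z0,
                            J0 = length(x$exposure_counts)))
  }
  rates <- as.numeric(x)
  if (is.null(J0)) J0 <- length(rates)
  if (is.null(N) || is.null(Z0)) stop("supply 'N' and 'Z0'")
  if (any(rates < 0 | rates > 1)) stop("exposure rates must lie in [0, 1]")
  structure(list(rates = rates, N = as.integer(N), Z0 = as.integer(Z0),
                 J0 = as.integer(J0)),
            class = "exposure_summary")
}

#' Exposure chi-square statistic
#'
#' Sum over operational items of the squared deviation of the observed
#' exposure rate from the uniform rate Z0/J0, scaled by Z0/J0. Zero means
#' perfectly uniform exposure; larger values indicate overexposure of
#' some items.
#'
#' @param summary an [exposure_summary()].
#' @return Scalar statistic.
#' @export
exposure_chi_square <- function(summary) {
  stopifnot(inherits(summary, "exposure_summary"))
  if (summary$Z0 == 0) stop("'Z0' must be positive")
  u <- summary$Z0 / summary$J0
  sum((summary$rates - u)^2 / u)
}

#' Test overlap ratio
#'
#' Expected proportion of items shared by two randomly drawn examinees'
#' tests: `N * sum(ER^2) / ((N - 1) * Z0) - 1 / (N - 1)`. Equals 1 when
#' everyone receives the identical test and approaches Z0/J0 under
#' uniform exposure.
#'
#' @param summary an [exposure_summary()].
#' @return Scalar in \[0, 1\] when the rates sum to Z0.
#' @export
test_overlap_ratio <- function(summary) {
  stopifnot(inherits(summary, "exposure_summary"))
  if (summary$N < 2) stop("'N' must be at least 2")
  summary$N * sum(summary$rates^2) /
    ((summary$N - 1) * summary$Z0) - 1 / (summary$N - 1)
}
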