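#' Estimate leukocyte proportions by constrained projection
#'
#' Reference-based cell-type deconvolution: for each sample, the
#' methylation vector over the reference CpGs is projected onto the
#' cell-type profile matrix under the constraints of non-negative
#' proportions summing to at most one,
#' `p-hat = argmin ||m - R p||^2  s.t.  p_k >= 0, sum_k p_k <= 1`.
#' The quadratic program is solved exactly (dual active-set method via
#' `quadprog`); the unexplained mass `1 - sum(p-hat)` and the residual norm
#' are reported alongside.
#'
#' @param sample_betas Numeric vector (one sample) or matrix (samples x
#'   reference CpGs) of beta values over the reference CpGs.
#' @param reference A `cell_reference` (or bare profile matrix m_ref x K).
#' @return For a single sample, a list `proportions` (K-vector),
#'   `residual_norm`; for a matrix, a list with `proportions` (n x K
#'   matrix) and `residual_norm` (n-vector).
#' @export
estimate_proportions <- function(sample_betas, reference) {
  R <- if (inherits(reference, "cell_reference")) reference$profiles
       else as.matrix(reference)
  K <- ncol(R)
  if (qr(R)$rank < K)
    stop("reference profile matrix is rank deficient; cell types not identifiable",
         call. = FALSE)
  solve_one <- function(m) {
    stopifnot(length(m) == nrow(R))
    D <- crossprod(R)
    d <- crossprod(R, m)
    # constraints A' p >= b: p_k >= 0 (I), -sum(p) >= -1
    A <- cbind(diag(K), -rep(1, K))
    b0 <- c(rep(0, K), -1)
    # small ridge keeps D numerically positive definite
    sol <- quadprog::solve.QP(D + diag(1e-10, K), d, A, b0)
    p <- pmax(0, sol$solution)
    if (sum(p) > 1) p <- p / sum(p)
    list(proportions = p, residual_norm = sqrt(sum((m - R %*% p)^2)))
  }
  if (is.matrix(sample_betas)) {
    res <- apply(sample_betas, 1, solve_one)
    props <- t(vapply(res, `[[`, numeric(K), "proportions"))
    colnames(props) <- colnames(R)
    rownames(props) <- rownames(sample_betas)
    list(proportions = props,
         residual_norm = vapply(res, `[[`, numeric(1), "residual_norm"))
  } else {
    out <- solve_one(as.numeric(sample_betas))
    names(out$proportions) <- colnames(R)
    out
  }
}
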