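#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR q-values: `q_i = min_{j: p_(j) >= p_(i)} m * p_(j) / j`,
#' monotone in p. Backed by `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed, passed
#'   through).
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

.fit_ols <- function(y, X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient fixed design; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  est <- qr.coef(qx, y)
  res <- y - X %*% est
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(pmax(0, diag(XtXinv) * s2))
  tval <- est / se
  list(term = colnames(X), coef = as.numeric(est), se = unname(se),
       p = unname(2 * stats::pt(-abs(tval), df)), batch_var = 0,
       resid_var = s2, converged = TRUE, n_used = length(y),
       method = "ols")
}

#' Fit a batch-random-effect linear model
#'
#' Restricted-maximum-likelihood fit of
#' `y = X gamma + u_batch + e`, `u ~ N(0, sigma_b^2)`, `e ~ N(0, sigma^2)`
#' via `lme4::lmer`, with Wald tests per fixed coefficient (normal
#' reference). Rows with missing outcome, design entries or batch are
#' dropped listwise. With fewer than two batches the model degrades to
#' ordinary least squares (t-based Wald tests) with a notice in the result.
#'
#' @param outcome Numeric outcome vector (methylation beta values).
#' @param fixed_design Numeric matrix of fixed-effect columns (no
#'   intercept; one is added).
#' @param batch Batch labels (random intercept grouping).
#' @return A list: `term`, `coef`, `se`, `p`, `batch_var`, `resid_var`,
#'   `converged`, `n_used`, `method` ("lmer" or "ols").
#' @export
fit_mixed_lm <- function(outcome, fixed_design, batch) {
  X <- as.matrix(fixed_design)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  ok <- !is.na(outcome) & stats::complete.cases(X) & !is.na(batch)
  y <- outcome[ok]
  X <- X[ok, , drop = FALSE]
  b <- factor(batch[ok])
  X1 <- cbind("(Intercept)" = 1, X)
  if (nlevels(b) < 2) {
    out <- .fit_ols(y, X1)
    out$note <- "single batch: reduced to fixed-effects OLS"
    return(out)
  }
  qx <- qr(X1)
  if (qx$rank < ncol(X1)) {
    bad <- colnames(X1)[qx$pivot[(qx$rank + 1):ncol(X1)]]
    stop("rank-deficient fixed design; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(.y = y, X, check.names = FALSE)
  df$.batch <- b
  terms <- colnames(X)
  safe <- make.names(terms, unique = TRUE)
  colnames(df)[seq_along(terms) + 1L] <- safe
  fml <- stats::as.formula(paste(".y ~", paste(safe, collapse = " + "),
                                 "+ (1 | .batch)"))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = df, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))
    )),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(term = c("(Intercept)", terms), coef = rep(NA_real_, ncol(X1)),
                se = rep(NA_real_, ncol(X1)), p = rep(NA_real_, ncol(X1)),
                batch_var = NA_real_, resid_var = NA_real_, converged = FALSE,
                n_used = length(y), method = "lmer",
                note = conditionMessage(fit)))
  }
  sm <- summary(fit)$coefficients
  vc <- lme4::VarCorr(fit)
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  z <- est / se
  list(term = c("(Intercept)", terms), coef = as.numeric(est),
       se = as.numeric(se), p = 2 * stats::pnorm(-abs(z)),
       batch_var = as.numeric(vc$.batch[1]),
       resid_var = attr(vc, "sc")^2, converged = TRUE,
       n_used = length(y), method = "lmer")
}

#' Build the fully adjusted fixed-effect design matrix
#'
#' Dummy-codes the standard adjustment set: age, sex, smoking status,
#' alcohol, BMI class, physical activity, CVD/diabetes/cancer prevalence,
#' and K-1 of the K cell-proportion columns (the last is dropped to avoid
#' collinearity with the intercept, proportions summing to ~1).
#'
#' @param cohort Cohort data.frame.
#' @param cell_cols Names of the cell-proportion columns to adjust for.
#' @param include_smoking Include smoking-status dummies (dropped when
#'   smoking is itself the predictor under study, e.g. attribution models).
#' @return Numeric design matrix (no intercept), rows aligned to `cohort`.
#' @export
covariate_design <- function(cohort, cell_cols = NULL,
                             include_smoking = TRUE) {
  d <- data.frame(
    age = cohort$age,
    sex_male = as.numeric(cohort$sex == "male"),
    alcohol_low = as.numeric(cohort$alcohol == "low"),
    alcohol_intermediate = as.numeric(cohort$alcohol == "intermediate"),
    alcohol_high = as.numeric(cohort$alcohol == "high"),
    bmi_overweight = as.numeric(cohort$bmi_class == "overweight"),
    bmi_obese = as.numeric(cohort$bmi_class == "obese"),
    activity_low = as.numeric(cohort$activity == "low"),
    activity_medium_high = as.numeric(cohort$activity == "medium_high"),
    cvd_yes = as.numeric(cohort$cvd == "yes"),
    diabetes_yes = as.numeric(cohort$diabetes == "yes"),
    cancer_yes = as.numeric(cohort$cancer == "yes")
  )
  if (include_smoking) {
    d$smoking_current <- as.numeric(cohort$smoking_status == "current")
    d$smoking_former <- as.numeric(cohort$smoking_status == "former")
  }
  if (!is.null(cell_cols) && length(cell_cols) > 1) {
    use <- cell_cols[-length(cell_cols)]  # K-1 proportions
    for (cc in use) d[[cc]] <- cohort[[cc]]
  }
  X <- as.matrix(d)
  # a level absent from this panel leaves an all-constant dummy: drop it
  keep <- apply(X, 2, function(col) stats::var(col, na.rm = TRUE) > 0)
  X[, keep, drop = FALSE]
}

fit_pair <- function(beta, genotypes, cohort, cpg_id, snp_id, X0,
                     snp_coding = "additive") {
  g <- genotypes$G[, snp_id]
  y <- beta[, cpg_id]
  if (snp_coding == "categorical") {
    S <- cbind(snp_het = as.numeric(g == 1L), snp_hom = as.numeric(g == 2L))
  } else {
    S <- cbind(snp = as.numeric(g))
  }
  ok <- !is.na(g)
  if (length(unique(g[ok])) < 2)
    return(list(coef = NA_real_, se = NA_real_, p = NA_real_,
                n_used = sum(ok), converged = FALSE))
  fit <- fit_mixed_lm(y, cbind(S, X0), cohort$batch)
  i <- match(colnames(S)[1], fit$term)
  list(coef = fit$coef[i], se = fit$se[i], p = fit$p[i],
       n_used = fit$n_used, converged = fit$converged)
}

#' Two-stage discovery/validation mQTL scan
#'
#' Stage 1 fits the fully adjusted batch-random-effect model for every
#' SNP-CpG pair in the discovery panel (SNP as a single additive
#' minor-allele-count predictor by default) and applies Benjamini-Hochberg
#' FDR over all SNP-term p-values. Pairs with discovery FDR < `alpha` are
#' refit in the validation panel; BH-FDR is then applied over the
#' survivors' validation p-values only, and pairs below `alpha` again are
#' flagged as mQTLs.
#'
#' @param pairs Pair table (post-QC): `cpg_id`, `snp_id`, plus any columns
#'   carried through.
#' @param discovery,validation Panel lists with elements `cohort`, `beta`,
#'   `genotypes`; the cohort must carry the adjustment covariates and the
#'   cell-proportion columns named in `cell_cols`.
#' @param cell_cols Names of cell-proportion covariate columns.
#' @param alpha FDR threshold used at both stages.
#' @param snp_coding `"additive"` (default) or `"categorical"`.
#' @return `pairs` with added columns disc_coef/disc_se/disc_p/disc_fdr,
#'   valid_coef/valid_se/valid_p/valid_fdr, sign_concordant, is_mqtl.
#' @export
run_two_stage <- function(pairs, discovery, validation, cell_cols,
                          alpha = 0.05, snp_coding = "additive") {
  res <- pairs
  X0d <- covariate_design(discovery$cohort, cell_cols)
  st1 <- lapply(seq_len(nrow(pairs)), function(i)
    fit_pair(discovery$beta, discovery$genotypes, discovery$cohort,
             pairs$cpg_id[i], pairs$snp_id[i], X0d, snp_coding))
  res$disc_coef <- vapply(st1, `[[`, numeric(1), "coef")
  res$disc_se <- vapply(st1, `[[`, numeric(1), "se")
  res$disc_p <- vapply(st1, `[[`, numeric(1), "p")
  res$disc_fdr <- bh_fdr(res$disc_p)
  res$valid_coef <- NA_real_
  res$valid_se <- NA_real_
  res$valid_p <- NA_real_
  res$valid_fdr <- NA_real_
  surv <- which(!is.na(res$disc_fdr) & res$disc_fdr < alpha)
  if (length(surv) == 0) {
    warning("no pairs passed the discovery stage")
    res$sign_concordant <- NA
    res$is_mqtl <- FALSE
    return(res)
  }
  X0v <- covariate_design(validation$cohort, cell_cols)
  st2 <- lapply(surv, function(i)
    fit_pair(validation$beta, validation$genotypes, validation$cohort,
             pairs$cpg_id[i], pairs$snp_id[i], X0v, snp_coding))
  res$valid_coef[surv] <- vapply(st2, `[[`, numeric(1), "coef")
  res$valid_se[surv] <- vapply(st2, `[[`, numeric(1), "se")
  res$valid_p[surv] <- vapply(st2, `[[`, numeric(1), "p")
  res$valid_fdr[surv] <- bh_fdr(res$valid_p[surv])
  res$sign_concordant <- sign(res$disc_coef) == sign(res$valid_coef)
  res$is_mqtl <- !is.na(res$valid_fdr) & res$valid_fdr < alpha
  res
}
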