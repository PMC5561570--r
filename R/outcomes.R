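outcome_covariates <- function(cohort) {
  covariate_design(cohort, cell_cols = NULL, include_smoking = FALSE)
}

fit_binary_outcome <- function(ind, carrier, X) {
  ok <- !is.na(ind) & !is.na(carrier) & stats::complete.cases(X)
  if (length(unique(ind[ok])) < 2 || length(unique(carrier[ok])) < 2)
    return(list(est = NA_real_, se = NA_real_, p = NA_real_,
                n = sum(ok), note = "degenerate outcome or predictor"))
  df <- data.frame(ind = ind[ok], carrier = carrier[ok], X[ok, , drop = FALSE])
  fit <- suppressWarnings(stats::glm(ind ~ ., data = df, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  note <- NA_character_
  if (!fit$converged || any(abs(sm["carrier", "Estimate"]) > 15))
    note <- "separation or non-convergence"
  list(est = sm["carrier", "Estimate"], se = sm["carrier", "Std. Error"],
       p = sm["carrier", "Pr(>|z|)"], n = sum(ok), note = note)
}

fit_linear_outcome <- function(yv, carrier, X) {
  ok <- !is.na(yv) & !is.na(carrier) & stats::complete.cases(X)
  if (length(unique(carrier[ok])) < 2)
    return(list(est = NA_real_, se = NA_real_, p = NA_real_,
                n = sum(ok), note = "degenerate predictor"))
  df <- data.frame(yv = yv[ok], carrier = carrier[ok], X[ok, , drop = FALSE])
  sm <- summary(stats::lm(yv ~ ., data = df))$coefficients
  list(est = sm["carrier", "Estimate"], se = sm["carrier", "Std. Error"],
       p = sm["carrier", "Pr(>|t|)"], n = sum(ok), note = NA_character_)
}

#' Scan mQTLs against six active smoking indicators
#'
#' For each unique mQTL SNP (dominant carrier coding), tests association
#' with: ever vs never smoking, current vs never, current vs former
#' (logistic regressions on the indicator-specific subset), and pack-years,
#' smoking duration and age of initiation (linear models among ever
#' smokers). Models adjust for age, sex, alcohol, BMI class, activity, and
#' baseline CVD/diabetes/cancer; no smoking-derived covariates enter (the
#' outcome is the smoking phenotype itself) and no batch term (phenotypes
#' are not plate-measured). BH-FDR is applied within each indicator family
#' across SNPs.
#'
#' @param snp_ids Character vector of mQTL SNP ids.
#' @param cohort Pooled cohort data.frame.
#' @param genotypes Pooled `genotype_matrix`.
#' @param alpha FDR threshold for the `significant` flag.
#' @return Data.frame: snp_id, outcome, estimate (log-odds or linear
#'   coefficient), se, p, fdr, n_used, significant, note.
#' @export
smoking_association_scan <- function(snp_ids, cohort, genotypes,
                                     alpha = 0.05) {
  X <- outcome_covariates(cohort)
  st <- cohort$smoking_status
  ever <- st %in% c("current", "former")
  specs <- list(
    ever_vs_never = list(type = "binary",
                         ind = as.numeric(ever), sub = rep(TRUE, nrow(cohort))),
    current_vs_never = list(type = "binary",
                            ind = as.numeric(st == "current"),
                            sub = st %in% c("current", "never")),
    current_vs_former = list(type = "binary",
                             ind = as.numeric(st == "current"),
                             sub = st %in% c("current", "former")),
    pack_years = list(type = "linear", ind = cohort$pack_years, sub = ever),
    duration = list(type = "linear", ind = cohort$smoking_duration, sub = ever),
    initiation_age = list(type = "linear", ind = cohort$initiation_age,
                          sub = ever)
  )
  rows <- list()
  for (oname in names(specs)) {
    sp <- specs[[oname]]
    sub <- sp$sub
    if (length(unique(sp$ind[sub & !is.na(sp$ind)])) < 2) {
      message("indicator ", oname, " has a single class: skipped")
      next
    }
    for (snp in snp_ids) {
      carrier <- recode_dominant(genotypes$G[sub, snp])
      f <- if (sp$type == "binary")
        fit_binary_outcome(sp$ind[sub], carrier, X[sub, , drop = FALSE])
      else
        fit_linear_outcome(sp$ind[sub], carrier, X[sub, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = snp, outcome = oname, estimate = f$est, se = f$se,
        p = f$p, n_used = f$n, note = f$note, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$fdr <- NA_real_
  for (oname in unique(res$outcome)) {
    i <- res$outcome == oname
    res$fdr[i] <- bh_fdr(res$p[i])
  }
  res$significant <- !is.na(res$fdr) & res$fdr < alpha
  rownames(res) <- NULL
  res
}

#' Scan mQTLs against all-cause mortality
#'
#' Cox proportional-hazards model (Breslow ties) of time to death on
#' carrier status plus the full covariate set (age, sex, smoking status,
#' alcohol, BMI class, activity, CVD/diabetes/cancer), panels pooled;
#' BH-FDR across SNPs.
#'
#' @inheritParams smoking_association_scan
#' @return Data.frame: snp_id, outcome ("mortality"), estimate (log-hazard
#'   ratio), se, p, fdr, n_used, n_events, significant, note.
#' @export
cox_mortality_scan <- function(snp_ids, cohort, genotypes, alpha = 0.05) {
  stopifnot(all(cohort$followup_time > 0))
  dead <- as.numeric(cohort$dead == "yes")
  if (sum(dead) < 1) stop("no death events", call. = FALSE)
  X <- covariate_design(cohort, cell_cols = NULL, include_smoking = TRUE)
  rows <- lapply(snp_ids, function(snp) {
    carrier <- recode_dominant(genotypes$G[, snp])
    ok <- !is.na(carrier) & stats::complete.cases(X)
    df <- data.frame(time = cohort$followup_time[ok], dead = dead[ok],
                     carrier = carrier[ok], X[ok, , drop = FALSE])
    est <- se <- p <- NA_real_; note <- NA_character_
    if (length(unique(carrier[ok])) < 2) {
      note <- "degenerate predictor"
    } else {
      fit <- tryCatch(
        survival::coxph(survival::Surv(time, dead) ~ ., data = df,
                        ties = "breslow"),
        warning = function(w) {
          f <- suppressWarnings(
            survival::coxph(survival::Surv(time, dead) ~ ., data = df,
                            ties = "breslow"))
          attr(f, "note") <- conditionMessage(w)
          f
        },
        error = function(e) e)
      if (inherits(fit, "error")) {
        note <- conditionMessage(fit)
      } else {
        if (!is.null(attr(fit, "note"))) note <- attr(fit, "note")
        sm <- summary(fit)$coefficients
        est <- sm["carrier", "coef"]; se <- sm["carrier", "se(coef)"]
        p <- sm["carrier", "Pr(>|z|)"]
      }
    }
    data.frame(snp_id = snp, outcome = "mortality", estimate = est, se = se,
               p = p, n_used = sum(ok), n_events = sum(dead[ok]),
               note = note, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- bh_fdr(res$p)
  res$significant <- !is.na(res$fdr) & res$fdr < alpha
  rownames(res) <- NULL
  res
}
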