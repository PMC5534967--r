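# Univariate ordinal twin structural modelling: ACE / ADE / AE / CE / E by
# full maximum likelihood on the liability scale, with linear age and sex
# threshold covariates, likelihood-ratio tests, AIC and profile CIs.

.biometric_models <- c("ACE", "ADE", "AE", "CE", "E")

.model_components <- function(model) {
  if (!model %in% .biometric_models) stop("unknown model: ", model)
  # unnamed default is the E model (no free variance components)
  switch(model, ACE = c("a2", "c2"), ADE = c("a2", "d2"),
         AE = "a2", CE = "c2", character(0))
}

# Twin liability correlations implied by standardized components.
.twin_cor <- function(a2, c2, d2) {
  c(MZ = a2 + c2 + d2, DZ = 0.5 * a2 + c2 + 0.25 * d2)
}

# Map unconstrained path parameters to standardized proportions. The unique
# environment path is fixed at 1 and everything is normalized, so e2 > 0
# always and the proportions sum to 1 by construction.
.comp_from_par <- function(par, model) {
  comps <- .model_components(model)
  vals <- c(a2 = 0, c2 = 0, d2 = 0)
  if (length(comps)) vals[comps] <- par^2
  tot <- sum(vals) + 1
  c(a2 = unname(vals["a2"]) / tot, c2 = unname(vals["c2"]) / tot,
    d2 = unname(vals["d2"]) / tot, e2 = 1 / tot)
}

.par_from_comp <- function(a2 = 0, c2 = 0, d2 = 0, model) {
  comps <- .model_components(model)
  e2 <- 1 - a2 - c2 - d2
  vals <- c(a2 = a2, c2 = c2, d2 = d2)
  sqrt(pmax(vals[comps], 1e-8) / e2)
}

# Internal fitting data: per-zygosity status pairs with covariates, or
# aggregated contingency tables when no covariates are in play.
.biometric_data <- function(records, classification, covariates, exclude) {
  rec <- .collapse_status(records, classification, exclude)
  labels <- attr(rec, "labels")
  k <- length(labels)
  zyg <- ifelse(startsWith(rec$zygosity_group, "MZ"), "MZ", "DZ")
  miss1 <- is.na(rec$status1)
  miss2 <- is.na(rec$status2)
  keep <- !(miss1 & miss2)
  rec <- rec[keep, , drop = FALSE]
  zyg <- zyg[keep]
  age_ref <- mean(rec$age)
  use_cov <- length(covariates) > 0L
  list(rec = rec, zyg = zyg, k = k, labels = labels, age_ref = age_ref,
       use_age = "age" %in% covariates, use_sex = "sex" %in% covariates,
       n_pairs = c(MZ = sum(zyg == "MZ"), DZ = sum(zyg == "DZ")),
       tabs = if (!use_cov) {
         lapply(c(MZ = "MZ", DZ = "DZ"), function(z) {
           sub <- rec[zyg == z & !is.na(rec$status1) & !is.na(rec$status2), ]
           if (!nrow(sub)) return(NULL)
           m <- table(factor(sub$status1, levels = 0:(k - 1L)),
                      factor(sub$status2, levels = 0:(k - 1L)))
           matrix(as.numeric(m), k, k)
         })
       } else NULL,
       marg = if (!use_cov) {
         lapply(c(MZ = "MZ", DZ = "DZ"), function(z) {
           sub <- rec[zyg == z, ]
           s <- c(sub$status1[is.na(sub$status2)],
                  sub$status2[is.na(sub$status1)])
           s <- s[!is.na(s)]
           if (!length(s)) return(NULL)
           as.numeric(table(factor(s, levels = 0:(k - 1L))))
         })
       } else NULL)
}

# Negative log-likelihood given standardized components + thresholds + betas.
.biometric_nll <- function(dat, comp, thr, beta_age = 0, beta_sex = 0) {
  r <- .twin_cor(comp[["a2"]], comp[["c2"]], comp[["d2"]])
  ll <- 0
  if (!is.null(dat$tabs)) {
    for (z in c("MZ", "DZ")) {
      tab <- dat$tabs[[z]]
      if (!is.null(tab)) {
        p <- .bvn_cell_probs(r[[z]], thr, thr)
        ll <- ll + sum(tab * log(pmax(p, 1e-300)))
      }
      mg <- dat$marg[[z]]
      if (!is.null(mg)) {
        pm <- diff(c(0, pnorm(thr), 1))
        ll <- ll + sum(mg * log(pmax(pm, 1e-300)))
      }
    }
  } else {
    rec <- dat$rec
    bnds <- c(-Inf, thr, Inf)
    sex_num <- function(s) ifelse(s == "M", 1, 0)
    sh1 <- beta_age * (rec$age - dat$age_ref) + beta_sex * sex_num(rec$sex1)
    sh2 <- beta_age * (rec$age - dat$age_ref) + beta_sex * sex_num(rec$sex2)
    for (z in c("MZ", "DZ")) {
      i <- dat$zyg == z
      if (!any(i)) next
      s1 <- rec$status1[i]; s2 <- rec$status2[i]
      both <- !is.na(s1) & !is.na(s2)
      if (any(both)) {
        p <- bvn_rect(bnds[s1[both] + 1L] + sh1[i][both],
                      bnds[s1[both] + 2L] + sh1[i][both],
                      bnds[s2[both] + 1L] + sh2[i][both],
                      bnds[s2[both] + 2L] + sh2[i][both],
                      r[[z]])
        ll <- ll + sum(log(pmax(p, 1e-300)))
      }
      for (w in 1:2) {
        s <- if (w == 1) s1 else s2
        sh <- if (w == 1) sh1[i] else sh2[i]
        only <- !is.na(s) & is.na(if (w == 1) s2 else s1)
        if (any(only)) {
          pm <- pnorm(bnds[s[only] + 2L] + sh[only]) -
            pnorm(bnds[s[only] + 1L] + sh[only])
          ll <- ll + sum(log(pmax(pm, 1e-300)))
        }
      }
    }
  }
  -ll
}

# Fixed multi-start grid on the simplex of (first, second) components.
.start_grid <- list(c(0.3, 0.3), c(0.6, 0.05), c(0.05, 0.6),
                    c(0.1, 0.1), c(0.45, 0.25))

#' Fit a univariate ordinal twin variance-components model
#'
#' Full maximum likelihood for the liability-threshold twin model: each
#' twin's ordinal status arises from a standard-normal liability cut at
#' shared thresholds (optionally shifted linearly by age and sex), and the
#' within-pair liability correlation is `a2 + c2 + d2` for MZ pairs and
#' `0.5 a2 + c2 + 0.25 d2` for DZ pairs. Components are standardized
#' proportions of liability variance (path-coefficient parameterization, so
#' estimates are non-negative and sum to 1). Optimization is quasi-Newton
#' from a fixed grid of five starting points; ties are broken by lowest
#' deviance then lexicographic parameter order, so fits are deterministic.
#'
#' @param records twin-pair records.
#' @param model one of `"ACE"`, `"ADE"`, `"AE"`, `"CE"`, `"E"`.
#' @param classification collapse rule, as in [crosstab()].
#' @param covariates character subset of `c("age", "sex")`: linear threshold
#'   covariates (sex coded 0 = female, 1 = male).
#' @param exclude pair- vs individual-level exclusion for the `"minor"` /
#'   `"major"` classifications (see [crosstab()]; `"individual"` retains the
#'   non-excluded co-twin through its marginal likelihood).
#' @param ci compute 95% profile-likelihood CIs for the variance components.
#' @return object of class `biometric_fit`: `estimates` (named proportions
#'   `a2`, `c2`, `d2`, `e2`), `ci`, `thresholds`, `betas`, `minus2LL`,
#'   `aic`, `npar`, `converged`, `n_pairs_by_group`.
#' @examples
#' rec <- simulate_cohort(cohort_preset("aged", seed = 1))
#' fit_biometric(rec, "AE", classification = "two")
#' @export
fit_biometric <- function(records, model = c("ACE", "ADE", "AE", "CE", "E"),
                          classification = c("three", "two", "minor",
                                             "major"),
                          covariates = character(),
                          exclude = c("pair", "individual"),
                          ci = FALSE) {
  model <- match.arg(model)
  classification <- match.arg(classification)
  exclude <- match.arg(exclude)
  stopifnot(all(covariates %in% c("age", "sex")))
  comps <- .model_components(model)
  zclass <- unique(ifelse(startsWith(records$zygosity_group, "MZ"),
                          "MZ", "DZ"))
  if (length(comps) && length(zclass) < 2L)
    stop("fit_biometric: models with A, C or D need both MZ and DZ pairs")

  dat <- .biometric_data(records, classification, covariates, exclude)
  n_thr <- dat$k - 1L
  n_beta <- dat$use_age + dat$use_sex
  n_comp <- length(comps)

  # Parameter vector: [comp paths | thresholds (transformed) | betas].
  thr_tab <- if (!is.null(dat$tabs))
    Reduce(`+`, Filter(Negate(is.null), dat$tabs)) else {
      k <- dat$k
      s <- c(dat$rec$status1, dat$rec$status2)
      s <- s[!is.na(s)]
      diag(as.numeric(table(factor(s, levels = 0:(k - 1L)))) / 2)
    }
  thr0 <- .thr_start(thr_tab, shared = TRUE)

  obj <- function(par) {
    comp <- .comp_from_par(par[seq_len(n_comp)], model)
    thr <- .par_to_thr(par[n_comp + seq_len(n_thr)])
    ba <- if (dat$use_age) par[n_comp + n_thr + 1L] else 0
    bs <- if (dat$use_sex) par[n_comp + n_thr + n_beta] else 0
    .biometric_nll(dat, comp, thr, ba, bs)
  }

  starts <- if (n_comp == 0L) list(numeric(0)) else
    lapply(.start_grid, function(s) {
      if (n_comp == 1L)
        .par_from_comp(a2 = s[1] + s[2], model = model)[1] else
          switch(model,
                 ACE = .par_from_comp(a2 = s[1], c2 = s[2], model = model),
                 ADE = .par_from_comp(a2 = s[1], d2 = s[2], model = model))
    })
  if (n_comp == 1L && model == "CE")
    starts <- lapply(.start_grid, function(s)
      .par_from_comp(c2 = s[1] + s[2], model = model)[1])

  best <- NULL
  for (st in unique(starts)) {
    p0 <- c(st, .thr_to_par(thr0), rep(0, n_beta))
    opt <- nlminb(p0, obj, control = list(rel.tol = 1e-10, abs.tol = 0,
                                          iter.max = 500, eval.max = 1000))
    if (is.null(best) || opt$objective < best$objective - 1e-9 ||
        (abs(opt$objective - best$objective) <= 1e-9 &&
         isTRUE(all(opt$par < best$par))))
      best <- opt
  }

  comp <- .comp_from_par(best$par[seq_len(n_comp)], model)
  if (model == "E") comp <- c(a2 = 0, c2 = 0, d2 = 0, e2 = 1)
  thr <- .par_to_thr(best$par[n_comp + seq_len(n_thr)])
  fit <- structure(list(
    model = model, classification = classification,
    covariates = covariates, exclude = exclude,
    estimates = comp,
    ci = NULL,
    thresholds = thr,
    betas = c(age = if (dat$use_age) best$par[n_comp + n_thr + 1L] else NA,
              sex = if (dat$use_sex) best$par[n_comp + n_thr + n_beta]
                    else NA),
    minus2LL = 2 * best$objective,
    npar = n_comp + n_thr + n_beta,
    aic = 2 * best$objective + 2 * (n_comp + n_thr + n_beta),
    converged = best$convergence == 0,
    n_pairs_by_group = dat$n_pairs,
    age_ref = dat$age_ref,
    data = dat), class = "biometric_fit")
  if (ci) {
    fit$ci <- lapply(setNames(nm = c(comps, "e2")), function(cm)
      profile_ci(fit, cm))
  }
  fit
}

#' @export
print.biometric_fit <- function(x, ...) {
  cat(sprintf("%s liability-threshold twin model (%s-category%s)\n",
              x$model, x$classification,
              if (length(x$covariates))
                paste0(", covariates: ",
                       paste(x$covariates, collapse = "+")) else ""))
  est <- x$estimates[x$estimates > 0 | names(x$estimates) == "e2"]
  shown <- c(.model_components(x$model), "e2")
  for (nm in shown) {
    cat(sprintf("  %s = %.3f", nm, x$estimates[[nm]]))
    if (!is.null(x$ci[[nm]]))
      cat(sprintf(" (%.2f-%.2f)", x$ci[[nm]][1], x$ci[[nm]][2]))
    cat("\n")
  }
  cat(sprintf("  -2LL = %.2f, AIC = %.2f, npar = %d, converged: %s\n",
              x$minus2LL, x$aic, x$npar, x$converged))
  invisible(x)
}

#' @export
logLik.biometric_fit <- function(object, ...) {
  structure(-object$minus2LL / 2, df = object$npar, class = "logLik")
}

#' AIC of a twin model fit
#'
#' `AIC = -2LL + 2 * (number of free parameters)`. Only differences between
#' models fitted to the same data are meaningful; model selection takes the
#' lowest value as most parsimonious.
#'
#' @param object a `biometric_fit`.
#' @param ... ignored.
#' @param k penalty per parameter (default 2).
#' @export
AIC.biometric_fit <- function(object, ..., k = 2) {
  object$minus2LL + k * object$npar
}

#' Per-pair log-likelihood of the liability-threshold twin model
#'
#' The log-probability of each pair's observed status combination: the
#' standard bivariate normal rectangle between the (covariate-shifted)
#' thresholds of the two twins, with correlation `a2 + c2 + d2` (MZ) or
#' `0.5 a2 + c2 + 0.25 d2` (DZ). Exposed mainly for testing and for
#' building custom likelihoods.
#'
#' @param records twin-pair records (three-category statuses used as-is).
#' @param a2,c2,d2 standardized variance proportions (e2 implied).
#' @param thresholds increasing cutpoints.
#' @param beta_age,beta_sex linear threshold effects.
#' @param age_ref reference age (defaults to the mean age in `records`).
#' @return numeric vector of per-pair log-probabilities.
#' @export
pair_loglik <- function(records, a2 = 0, c2 = 0, d2 = 0, thresholds,
                        beta_age = 0, beta_sex = 0, age_ref = NULL) {
  if (a2 + c2 + d2 >= 1 + 1e-12 || min(a2, c2, d2) < 0)
    stop("pair_loglik: invalid variance proportions")
  if (is.null(age_ref)) age_ref <- mean(records$age)
  r <- .twin_cor(a2, c2, d2)
  rho <- ifelse(startsWith(records$zygosity_group, "MZ"), r[["MZ"]],
                r[["DZ"]])
  bnds <- c(-Inf, thresholds, Inf)
  sex_num <- function(s) ifelse(s == "M", 1, 0)
  sh1 <- beta_age * (records$age - age_ref) + beta_sex * sex_num(records$sex1)
  sh2 <- beta_age * (records$age - age_ref) + beta_sex * sex_num(records$sex2)
  s1 <- records$status1; s2 <- records$status2
  p <- bvn_rect(bnds[s1 + 1L] + sh1, bnds[s1 + 2L] + sh1,
                bnds[s2 + 1L] + sh2, bnds[s2 + 2L] + sh2, rho)
  log(pmax(p, .Machine$double.xmin))
}

#' Likelihood-ratio test between nested twin models
#'
#' Deviance difference between a nested and a full model fitted to the same
#' records, referred to a central chi-squared with degrees of freedom equal
#' to the difference in free parameters. (For components on the boundary of
#' the parameter space this central reference is conservative in the usual
#' 50:50-mixture sense; `mixture = TRUE` applies the boundary-corrected
#' mixture for a single dropped component.)
#'
#' @param full,nested `biometric_fit` objects; `nested`'s components must be
#'   a subset of `full`'s.
#' @param mixture use the 0.5 chi2(df-1) + 0.5 chi2(df) boundary mixture.
#' @return object of class `twin_lrt`: `chi2`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, nested, mixture = FALSE) {
  stopifnot(inherits(full, "biometric_fit"), inherits(nested,
                                                      "biometric_fit"))
  fc <- .model_components(full$model)
  nc <- .model_components(nested$model)
  if (!all(nc %in% fc) || full$model == nested$model)
    stop("likelihood_ratio_test: '", nested$model,
         "' is not nested in '", full$model, "'")
  if (full$classification != nested$classification ||
      !identical(full$n_pairs_by_group, nested$n_pairs_by_group))
    stop("likelihood_ratio_test: fits are not on the same data")
  lrt_from_deviance(nested$minus2LL, full$minus2LL,
                    full$npar - nested$npar, mixture = mixture)
}

#' Likelihood-ratio p-value from deviances
#'
#' The elementary worked-example form of the test: given the deviances
#' (-2 log-likelihoods) of a nested and a full model and the difference in
#' free parameters, returns the chi-squared statistic and upper-tail
#' p-value.
#'
#' @param minus2LL_nested,minus2LL_full deviances of the two models.
#' @param df difference in free parameter count.
#' @param mixture boundary-corrected 50:50 mixture reference.
#' @return object of class `twin_lrt`.
#' @examples
#' lrt_from_deviance(1460.62, 1446.58, df = 2)  # p = 8.9e-4
#' lrt_from_deviance(476.73, 475.73, df = 1)    # p = 0.32
#' @export
lrt_from_deviance <- function(minus2LL_nested, minus2LL_full, df,
                              mixture = FALSE) {
  chi2 <- minus2LL_nested - minus2LL_full
  if (chi2 < 0) {
    if (chi2 < -1e-6)
      warning("negative LRT statistic (", format(chi2),
              "); clamping to 0 - check convergence")
    chi2 <- 0
  }
  p <- if (mixture) {
    0.5 * pchisq(chi2, df, lower.tail = FALSE) +
      0.5 * (if (df > 1) pchisq(chi2, df - 1, lower.tail = FALSE) else
        as.numeric(chi2 == 0))
  } else pchisq(chi2, df, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = df, p = p, mixture = mixture),
            class = "twin_lrt")
}

#' @export
print.twin_lrt <- function(x, ...) {
  cat(sprintf("LRT: chi2 = %.4g, df = %d, p = %.3g%s\n", x$chi2, x$df, x$p,
              if (x$mixture) " (boundary mixture)" else ""))
  invisible(x)
}

# Refit with one component's proportion fixed at `value`; returns the
# profiled deviance. Remaining components share 1 - value via their own
# path parameters.
.profile_deviance <- function(fit, component, value) {
  dat <- fit$data
  model <- fit$model
  comps <- .model_components(model)
  free <- setdiff(comps, component)
  n_thr <- dat$k - 1L
  n_beta <- dat$use_age + dat$use_sex
  n_free <- length(free)

  make_comp <- function(par) {
    vals <- c(a2 = 0, c2 = 0, d2 = 0)
    if (component %in% names(vals)) {
      vals[component] <- value
      rest <- 1 - value
    } else rest <- 1 - value  # component == "e2": rest is split below
    if (component == "e2") {
      # free comps + fixed e2: proportions of (1 - e2) via softmax-like map
      if (n_free == 0L) {
        vals[comps] <- 1 - value
      } else {
        w <- exp(c(par[seq_len(max(n_free - 1L, 0L))], 0))
        vals[comps] <- (1 - value) * w / sum(w)
      }
      e2 <- value
    } else {
      if (n_free >= 1L) {
        w <- exp(c(par[seq_len(max(n_free - 1L, 0L))], 0))
        frac <- plogis(par[n_free])  # share of the remainder going to comps
        vals[free] <- rest * frac * w / sum(w)
        e2 <- rest * (1 - frac)
      } else e2 <- rest
    }
    c(vals, e2 = unname(e2))
  }
  n_cpar <- if (component == "e2") max(n_free - 1L, 0L) else n_free

  obj <- function(par) {
    comp <- make_comp(par[seq_len(n_cpar)])
    thr <- .par_to_thr(par[n_cpar + seq_len(n_thr)])
    ba <- if (dat$use_age) par[n_cpar + n_thr + 1L] else 0
    bs <- if (dat$use_sex) par[n_cpar + n_thr + n_beta] else 0
    .biometric_nll(dat, comp, thr, ba, bs)
  }
  p0 <- c(rep(0, n_cpar), .thr_to_par(fit$thresholds),
          rep(0, n_beta))
  if (dat$use_age && !is.na(fit$betas[["age"]]))
    p0[n_cpar + n_thr + 1L] <- fit$betas[["age"]]
  if (dat$use_sex && !is.na(fit$betas[["sex"]]))
    p0[n_cpar + n_thr + n_beta] <- fit$betas[["sex"]]
  2 * nlminb(p0, obj, control = list(rel.tol = 1e-10, abs.tol = 0,
                                     iter.max = 500,
                                     eval.max = 1000))$objective
}

#' Profile-likelihood confidence interval for a variance component
#'
#' Endpoints are the component values at which the profiled deviance rises
#' `qchisq(level, 1)` (3.84 for 95%) above its minimum, clamped to the unit
#' interval; a component estimated at a boundary yields a one-sided
#' interval with the bound exactly 0 or 1.
#'
#' @param fit a converged `biometric_fit`.
#' @param component one of the fit's components (or `"e2"`).
#' @param level confidence level.
#' @return numeric `c(low, high)`; attribute `"one_sided"` flags boundary
#'   truncation.
#' @export
profile_ci <- function(fit, component, level = 0.95) {
  stopifnot(inherits(fit, "biometric_fit"))
  valid <- c(.model_components(fit$model), "e2")
  if (!component %in% valid)
    stop("profile_ci: component '", component, "' not in model ",
         fit$model)
  hat <- fit$estimates[[component]]
  crit <- fit$minus2LL + qchisq(level, 1L)
  f <- function(v) .profile_deviance(fit, component, v) - crit
  eps <- 1e-6
  lo <- if (hat <= eps || f(eps) <= 0) 0 else
    uniroot(f, c(eps, hat), tol = 1e-4)$root
  hi <- if (hat >= 1 - eps || f(1 - eps) <= 0) 1 else
    uniroot(f, c(hat, 1 - eps), tol = 1e-4)$root
  structure(c(lo, hi), one_sided = (lo == 0) || (hi == 1))
}

#' Fit the full model ladder and compare
#'
#' Fits ACE, AE, CE, E and ADE to the same records and assembles the
#' comparison grid: deviance, likelihood-ratio p-values against the full
#' ACE and ADE models, AIC, and the standardized component estimates.
#'
#' @param records twin-pair records.
#' @param classification collapse rule, as in [crosstab()].
#' @param covariates character subset of `c("age", "sex")`.
#' @param ci compute profile CIs for each fitted component (slower).
#' @param models model ladder to fit.
#' @return `data.frame` with one row per model (`minus2LL`, `p_vs_ACE`,
#'   `p_vs_ADE`, `AIC`, `A`, `C_or_D`, `E`, ...); the fits themselves are in
#'   `attr(, "fits")`.
#' @export
compare_biometric <- function(records, classification = "three",
                              covariates = character(), ci = FALSE,
                              models = c("ACE", "AE", "CE", "E", "ADE")) {
  fits <- lapply(setNames(nm = models), function(m)
    fit_biometric(records, m, classification, covariates, ci = ci))
  p_vs <- function(m, full) {
    if (!full %in% models || m == full) return(NA_real_)
    nc <- .model_components(m); fc <- .model_components(full)
    if (!all(nc %in% fc)) return(NA_real_)
    likelihood_ratio_test(fits[[full]], fits[[m]])$p
  }
  fmt_ci <- function(fit, comp) {
    v <- fit$estimates[[comp]]
    if (!is.null(fit$ci[[comp]]))
      sprintf("%.2f (%.2f-%.2f)", v, fit$ci[[comp]][1], fit$ci[[comp]][2])
    else sprintf("%.2f", v)
  }
  rows <- lapply(models, function(m) {
    f <- fits[[m]]
    cd <- if (m %in% c("ACE", "CE")) "c2" else if (m == "ADE") "d2" else NA
    data.frame(
      model = m,
      minus2LL = f$minus2LL,
      p_vs_ACE = p_vs(m, "ACE"),
      p_vs_ADE = p_vs(m, "ADE"),
      AIC = f$aic,
      A = if (m %in% c("ACE", "ADE", "AE")) fmt_ci(f, "a2") else "\u2014",
      C_or_D = if (!is.na(cd)) fmt_ci(f, cd) else "\u2014",
      E = fmt_ci(f, "e2"),
      converged = f$converged,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}
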