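# Maximum-likelihood polychoric / tetrachoric correlation and the
# multiple-threshold goodness-of-fit test.

# Ordered thresholds <-> unconstrained parameters (first cutpoint free,
# subsequent gaps on the log scale).
.thr_to_par <- function(t) c(t[1L], if (length(t) > 1L) log(diff(t)))
.par_to_thr <- function(p) cumsum(c(p[1L], if (length(p) > 1L) exp(p[-1L])))

# Threshold start values from table margins (pooled when shared).
.thr_start <- function(counts, margin = 1L, shared = TRUE) {
  n <- sum(counts)
  if (shared) {
    m <- (rowSums(counts) + colSums(counts)) / (2 * n)
  } else {
    m <- if (margin == 1L) rowSums(counts) / n else colSums(counts) / n
  }
  cum <- cumsum(m)[-length(m)]
  qnorm(pmin(pmax(cum, 1e-4), 1 - 1e-4))
}

.polychoric_nll <- function(counts, rho, thr_row, thr_col) {
  p <- .bvn_cell_probs(rho, thr_row, thr_col)
  -sum(counts * log(pmax(p, 1e-300)))
}

#' Maximum-likelihood polychoric correlation of a twin pair table
#'
#' Joint one-stage maximum likelihood over the latent correlation and the
#' liability thresholds, under the assumption that the two ordinal margins
#' discretize a standard bivariate normal. For a 2 x 2 table this is the
#' tetrachoric correlation. The correlation is optimized on the Fisher-z
#' scale and thresholds through ordered log-gap transforms, so constraints
#' are implicit; the 95% CI is obtained from the profile likelihood.
#'
#' @param tab a `pair_table` (or a plain count matrix).
#' @param equal_thresholds constrain the two margins to share thresholds
#'   (the natural default for exchangeable same-sex twins; set `FALSE` e.g.
#'   for opposite-sex pairs).
#' @param ci compute the profile-likelihood CI for the correlation.
#' @param conf_level confidence level for the CI.
#' @return object of class `polychoric_fit` with `rho`, `rho_ci`,
#'   `thresholds` (list with `row`, `col`), `loglik`, `n`, `gof` (the
#'   multiple-threshold goodness-of-fit test, see
#'   [multiple_threshold_gof()]), `estimable` and `converged`.
#' @examples
#' tab <- pair_table(matrix(c(60, 15, 15, 10), 2, 2), c("ND", "D"))
#' fit_polychoric(tab)
#' @export
fit_polychoric <- function(tab, equal_thresholds = TRUE, ci = TRUE,
                           conf_level = 0.95) {
  if (!inherits(tab, "pair_table")) tab <- pair_table(tab)
  counts <- tab$counts
  k1 <- nrow(counts); k2 <- ncol(counts)
  res <- structure(list(rho = NA_real_, rho_ci = c(NA_real_, NA_real_),
                        thresholds = NULL, loglik = NA_real_,
                        n = sum(counts), counts = counts,
                        equal_thresholds = equal_thresholds,
                        gof = NULL, estimable = FALSE, converged = FALSE,
                        reason = NA_character_,
                        zygosity_group = tab$zygosity_group),
                   class = "polychoric_fit")
  if (sum(rowSums(counts) > 0) < 2L || sum(colSums(counts) > 0) < 2L) {
    res$reason <- "a margin has fewer than 2 non-empty categories"
    return(res)
  }
  if (equal_thresholds && k1 != k2)
    stop("fit_polychoric: equal_thresholds requires a square table")

  if (equal_thresholds) {
    t0 <- .thr_start(counts, shared = TRUE)
    n_thr <- k1 - 1L
    unpack <- function(par) {
      thr <- .par_to_thr(par[-1L])
      list(rho = tanh(par[1L]), thr_row = thr, thr_col = thr)
    }
    start_thr <- .thr_to_par(t0)
  } else {
    tr0 <- .thr_start(counts, 1L, shared = FALSE)
    tc0 <- .thr_start(counts, 2L, shared = FALSE)
    n_thr <- (k1 - 1L) + (k2 - 1L)
    unpack <- function(par) {
      list(rho = tanh(par[1L]),
           thr_row = .par_to_thr(par[2:k1]),
           thr_col = .par_to_thr(par[(k1 + 1L):(k1 + k2 - 1L)]))
    }
    start_thr <- c(.thr_to_par(tr0), .thr_to_par(tc0))
  }

  obj <- function(par) {
    u <- unpack(par)
    .polychoric_nll(counts, u$rho, u$thr_row, u$thr_col)
  }
  # Deterministic multi-start on the correlation: 0 and the (shrunk)
  # Pearson correlation of the category scores.
  n <- sum(counts)
  sc_r <- row(counts); sc_c <- col(counts)
  mr <- sum(sc_r * counts) / n; mc <- sum(sc_c * counts) / n
  vr <- sum((sc_r - mr)^2 * counts); vc <- sum((sc_c - mc)^2 * counts)
  r_obs <- if (vr > 0 && vc > 0)
    sum((sc_r - mr) * (sc_c - mc) * counts) / sqrt(vr * vc) else 0
  starts <- unique(c(0, 0.9 * r_obs))
  best <- NULL
  for (z0 in atanh(pmin(pmax(starts, -0.99), 0.99))) {
    opt <- nlminb(c(z0, start_thr), obj,
                  control = list(rel.tol = 1e-12, abs.tol = 0,
                                 iter.max = 500, eval.max = 1000))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  u <- unpack(best$par)
  res$rho <- u$rho
  res$thresholds <- list(row = u$thr_row, col = u$thr_col)
  res$loglik <- -best$objective
  res$n_free <- 1L + n_thr
  res$estimable <- TRUE
  res$converged <- best$convergence == 0 || best$objective < Inf
  res$gof <- multiple_threshold_gof(tab, res)

  if (ci) {
    qc <- qchisq(conf_level, 1L)
    prof <- function(rho0) {
      pobj <- function(par) {
        if (equal_thresholds) {
          thr <- .par_to_thr(par)
          .polychoric_nll(counts, rho0, thr, thr)
        } else {
          .polychoric_nll(counts, rho0, .par_to_thr(par[1:(k1 - 1L)]),
                          .par_to_thr(par[k1:(k1 + k2 - 2L)]))
        }
      }
      nlminb(best$par[-1L], pobj,
             control = list(rel.tol = 1e-12, abs.tol = 0))$objective
    }
    f <- function(rho0) 2 * (prof(rho0) - best$objective) - qc
    lim <- 1 - 1e-6
    res$rho_ci <- c(
      if (f(-lim) < 0) -1 else
        uniroot(f, c(-lim, res$rho), tol = 1e-6)$root,
      if (f(lim) < 0) 1 else
        uniroot(f, c(res$rho, lim), tol = 1e-6)$root)
  }
  res
}

#' @export
print.polychoric_fit <- function(x, ...) {
  if (!x$estimable) {
    cat("Polychoric correlation: not estimable (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("Polychoric correlation: %.3f (%.3f-%.3f), n = %d\n",
              x$rho, x$rho_ci[1], x$rho_ci[2], round(x$n)))
  if (!is.null(x$gof) && isTRUE(x$gof$estimable))
    cat(sprintf("Multiple-threshold GOF: chi2 = %.3f, df = %d, p = %.3f\n",
                x$gof$chi2, x$gof$df, x$gof$p))
  invisible(x)
}

#' Multiple-threshold goodness-of-fit test
#'
#' Pearson chi-squared comparison of the observed cell frequencies with
#' those implied by the fitted bivariate-normal liability model. A
#' non-significant result is consistent with the ordered categories being
#' severity levels on a single liability continuum. Degrees of freedom are
#' `(k1 * k2 - 1) - (free thresholds + 1)`.
#'
#' @param tab a `pair_table` (or count matrix).
#' @param fit the corresponding [fit_polychoric()] result.
#' @return list with `chi2`, `df`, `p`, `expected`, `estimable`, `reason`.
#' @export
multiple_threshold_gof <- function(tab, fit) {
  if (!inherits(tab, "pair_table")) tab <- pair_table(tab)
  counts <- tab$counts
  out <- list(chi2 = NA_real_, df = NA_integer_, p = NA_real_,
              expected = NULL, estimable = FALSE, reason = NA_character_)
  if (!isTRUE(fit$estimable)) {
    out$reason <- "correlation fit not estimable"
    return(out)
  }
  p <- .bvn_cell_probs(fit$rho, fit$thresholds$row, fit$thresholds$col)
  e <- sum(counts) * p
  out$expected <- e
  if (any(e < 1e-12 & counts > 0)) {
    out$reason <- "expected count ~0 in a non-empty cell"
    return(out)
  }
  use <- e > 1e-12
  chi2 <- sum((counts[use] - e[use])^2 / e[use])
  n_thr <- if (fit$equal_thresholds) nrow(counts) - 1L else
    (nrow(counts) - 1L) + (ncol(counts) - 1L)
  df <- (nrow(counts) * ncol(counts) - 1L) - (n_thr + 1L)
  if (df < 1L) {
    out$reason <- "model saturates the table (df < 1)"
    return(out)
  }
  out$chi2 <- chi2
  out$df <- df
  out$p <- pchisq(chi2, df, lower.tail = FALSE)
  out$estimable <- TRUE
  out
}

# Standard zygosity groupings used in reporting. Each entry: the member
# groups and whether opposite-sex orientation needs aligning (MF transposed
# onto FM so that the female twin is always the row).
.groupings <- list(
  "Complete pairs" = .zygosity_groups,
  "MZ"   = c("MZ-FF", "MZ-MM"),
  "MZf"  = "MZ-FF",
  "MZm"  = "MZ-MM",
  "DZ"   = c("DZ-FF", "DZ-MM", "DZ-FM", "DZ-MF"),
  "DZss" = c("DZ-FF", "DZ-MM"),
  "DZf"  = "DZ-FF",
  "DZm"  = "DZ-MM",
  "DZos" = c("DZ-FM", "DZ-MF"))

# Pool groups into one table, orienting opposite-sex pairs female-first.
.pooled_table <- function(records, groups, classification = "three") {
  groups <- intersect(groups, unique(records$zygosity_group))
  if (!length(groups)) return(NULL)
  k <- switch(classification, three = 3L, 2L)
  labels <- switch(classification, three = c("ND", "MiD", "MD"),
                   two = c("ND", "MiD/MD"),
                   minor = c("ND", "MiD"), major = c("ND", "MD"))
  total <- matrix(0, k, k)
  for (g in groups) {
    ct <- tryCatch(crosstab(records, g, classification)$counts,
                   error = function(e) NULL)
    if (is.null(ct)) next
    if (g == "DZ-MF") ct <- t(ct)
    total <- total + ct
  }
  if (sum(total) == 0) return(NULL)
  pair_table(total, labels, paste(groups, collapse = "+"),
             opposite_sex = all(groups %in% .opp_sex_groups))
}

#' Polychoric fits and goodness-of-fit across zygosity groupings
#'
#' Fits the multiple-threshold model within each standard zygosity grouping
#' (complete pairs, MZ, MZf, MZm, DZ, DZss, DZf, DZm, DZos) and reports the
#' correlation and goodness-of-fit p-value per grouping. Two variants are
#' available for pooled groupings: `"pooled"` sums the member tables and
#' performs a single fit; `"multigroup"` maximizes the joint likelihood with
#' thresholds equated across member groups but a separate correlation per
#' group (its GOF then aggregates over all member-group cells).
#'
#' @param records twin-pair records.
#' @param classification collapse rule, as in [crosstab()].
#' @param groupings subset of grouping names to report.
#' @param method `"pooled"` (default) or `"multigroup"`.
#' @return `data.frame` with one row per grouping: `grouping`, `n_pairs`,
#'   `rho`, `ci_low`, `ci_high`, `gof_chi2`, `gof_df`, `gof_p`, `method`.
#' @export
polychoric_groupings <- function(records,
                                 classification = "three",
                                 groupings = names(.groupings),
                                 method = c("pooled", "multigroup")) {
  method <- match.arg(method)
  rows <- lapply(groupings, function(gn) {
    members <- .groupings[[gn]]
    if (is.null(members)) stop("unknown grouping: ", gn)
    base <- data.frame(grouping = gn, n_pairs = NA_real_, rho = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_,
                       gof_chi2 = NA_real_, gof_df = NA_integer_,
                       gof_p = NA_real_, method = method,
                       stringsAsFactors = FALSE)
    if (method == "pooled" || length(intersect(members,
        unique(records$zygosity_group))) <= 1L) {
      tab <- .pooled_table(records, members, classification)
      if (is.null(tab)) return(base)
      fit <- fit_polychoric(tab, equal_thresholds = TRUE)
      if (!fit$estimable) return(base)
      base$n_pairs <- sum(tab$counts)
      base$rho <- fit$rho
      base$ci_low <- fit$rho_ci[1]; base$ci_high <- fit$rho_ci[2]
      if (isTRUE(fit$gof$estimable)) {
        base$gof_chi2 <- fit$gof$chi2
        base$gof_df <- fit$gof$df
        base$gof_p <- fit$gof$p
      }
      base
    } else {
      present <- intersect(members, unique(records$zygosity_group))
      tabs <- lapply(present, function(g) {
        ct <- crosstab(records, g, classification)$counts
        if (g == "DZ-MF") ct <- t(ct)
        ct
      })
      fit <- .fit_polychoric_multigroup(tabs)
      base$n_pairs <- sum(vapply(tabs, sum, numeric(1)))
      base$rho <- fit$rho_common
      base$gof_chi2 <- fit$gof$chi2
      base$gof_df <- fit$gof$df
      base$gof_p <- fit$gof$p
      base
    }
  })
  do.call(rbind, rows)
}

# Joint ML over several tables: shared thresholds, one correlation per
# group. GOF sums Pearson contributions over all member-group cells;
# df = sum_g (k^2 - 1) - (#thresholds + #groups).
.fit_polychoric_multigroup <- function(tabs) {
  k <- nrow(tabs[[1L]])
  G <- length(tabs)
  pooled <- Reduce(`+`, tabs)
  t0 <- .thr_start(pooled, shared = TRUE)
  obj <- function(par) {
    thr <- .par_to_thr(par[(G + 1L):(G + k - 1L)])
    s <- 0
    for (g in seq_len(G))
      s <- s + .polychoric_nll(tabs[[g]], tanh(par[g]), thr, thr)
    s
  }
  opt <- nlminb(c(rep(0, G), .thr_to_par(t0)), obj,
                control = list(rel.tol = 1e-12, abs.tol = 0,
                               iter.max = 1000, eval.max = 2000))
  thr <- .par_to_thr(opt$par[(G + 1L):(G + k - 1L)])
  rhos <- tanh(opt$par[seq_len(G)])
  chi2 <- 0
  for (g in seq_len(G)) {
    e <- sum(tabs[[g]]) * .bvn_cell_probs(rhos[g], thr, thr)
    use <- e > 1e-12
    chi2 <- chi2 + sum((tabs[[g]][use] - e[use])^2 / e[use])
  }
  df <- G * (k * k - 1L) - ((k - 1L) + G)
  # Weighted (by pairs) summary correlation for reporting.
  w <- vapply(tabs, sum, numeric(1))
  list(rhos = rhos, rho_common = sum(rhos * w) / sum(w), thresholds = thr,
       loglik = -opt$objective,
       gof = list(chi2 = chi2, df = df,
                  p = pchisq(chi2, df, lower.tail = FALSE),
                  estimable = TRUE))
}

#' Polychoric correlations by depression classification and zygosity
#'
#' Fits the polychoric (or tetrachoric) correlation within pooled MZ and
#' pooled DZ pairs for each depression classification, the comparison that
#' carries the genetic signal (MZ > DZ indicates additive genetic variance).
#'
#' @param records twin-pair records.
#' @param classifications character vector of collapse rules.
#' @return `data.frame` with columns `classification`, `zygosity`, `n_pairs`,
#'   `rho`, `ci_low`, `ci_high`.
#' @export
polychoric_by_classification <- function(records,
                                         classifications = c("minor", "major",
                                                             "two", "three")) {
  rows <- list()
  for (cl in classifications) {
    for (z in c("MZ", "DZ")) {
      members <- if (z == "MZ") c("MZ-FF", "MZ-MM") else
        c("DZ-FF", "DZ-MM", "DZ-FM", "DZ-MF")
      tab <- tryCatch(.pooled_table(records, members, cl),
                      error = function(e) NULL)
      row <- data.frame(classification = cl, zygosity = z,
                        n_pairs = NA_real_, rho = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        stringsAsFactors = FALSE)
      if (!is.null(tab)) {
        fit <- fit_polychoric(tab, equal_thresholds = TRUE)
        if (fit$estimable) {
          row$n_pairs <- sum(tab$counts)
          row$rho <- fit$rho
          row$ci_low <- fit$rho_ci[1]
          row$ci_high <- fit$rho_ci[2]
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
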