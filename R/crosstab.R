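# Proband / co-twin cross-tabulation and familial relative risks.

# Collapse three-category statuses according to a classification rule.
# Returns the records with status columns recoded to 0..(k-1) and pairs
# dropped per the exclusion mode; attribute "labels" gives category names.
.collapse_status <- function(records, classification = c("three", "two",
                                                         "minor", "major"),
                             exclude = c("pair", "individual")) {
  classification <- match.arg(classification)
  exclude <- match.arg(exclude)
  s1 <- records$status1
  s2 <- records$status2
  if (classification == "three") {
    labels <- c("ND", "MiD", "MD")
  } else if (classification == "two") {
    s1 <- pmin(s1, 1L); s2 <- pmin(s2, 1L)
    labels <- c("ND", "MiD/MD")
  } else {
    drop_cat <- if (classification == "minor") 2L else 1L
    labels <- if (classification == "minor") c("ND", "MiD") else c("ND", "MD")
    excl1 <- s1 == drop_cat
    excl2 <- s2 == drop_cat
    if (exclude == "pair") {
      keep <- !(excl1 | excl2)
      records <- records[keep, , drop = FALSE]
      s1 <- s1[keep]; s2 <- s2[keep]
    } else {
      s1[excl1] <- NA_integer_
      s2[excl2] <- NA_integer_
    }
    if (classification == "major") {
      s1 <- ifelse(s1 == 2L, 1L, s1)
      s2 <- ifelse(s2 == 2L, 1L, s2)
    }
  }
  records$status1 <- as.integer(s1)
  records$status2 <- as.integer(s2)
  attr(records, "labels") <- labels
  records
}

#' Construct a twin pair table
#'
#' A `pair_table` holds the k x k contingency table of co-twin ordinal
#' statuses for one zygosity grouping: rows index the proband (twin 1),
#' columns the co-twin. Usually built by [crosstab()]; this constructor is
#' for tables supplied directly as counts.
#'
#' @param counts square non-negative count matrix (half-counts allowed,
#'   e.g. after [symmetrize()]).
#' @param labels optional category labels.
#' @param zygosity_group label of the group(s) the table represents.
#' @param opposite_sex flag marking tables whose rows and columns refer to
#'   different sexes (refused by [symmetrize()]).
#' @return object of class `pair_table`.
#' @export
pair_table <- function(counts, labels = NULL, zygosity_group = NA_character_,
                       opposite_sex = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("pair_table: counts must be non-negative")
  if (sum(counts) == 0) stop("pair_table: table total must be positive")
  if (!is.null(labels)) dimnames(counts) <- list(labels, labels)
  structure(list(counts = counts,
                 labels = rownames(counts),
                 zygosity_group = zygosity_group,
                 opposite_sex = opposite_sex),
            class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  cat("Twin pair table (", x$zygosity_group, ", n = ", sum(x$counts), ")\n",
      sep = "")
  print(x$counts)
  invisible(x)
}

#' Cross-tabulate co-twin statuses
#'
#' Builds the k x k contingency table of (twin 1, twin 2) ordinal statuses
#' for a selection of zygosity groups, after applying a classification
#' collapse rule. Rows index the proband (twin 1); for the opposite-sex
#' groups the row twin is the listed proband sex (`DZ-FM`: female proband).
#'
#' @param records twin-pair records as produced by [simulate_cohort()] or
#'   [read_twin_table()].
#' @param groups character vector of zygosity groups to pool (default: all
#'   groups present).
#' @param classification `"three"` (non-depressed/minor/major), `"two"`
#'   (minor and major merged), `"minor"` (major-depression pairs excluded) or
#'   `"major"` (minor-depression pairs excluded).
#' @param exclude for the `"minor"`/`"major"` classifications, whether an
#'   excluded status drops the whole pair (`"pair"`, default) or only the
#'   individual (`"individual"`; the affected cell becomes missing and the
#'   pair is dropped from the table).
#' @return object of class `pair_table`.
#' @export
crosstab <- function(records, groups = NULL,
                     classification = c("three", "two", "minor", "major"),
                     exclude = c("pair", "individual")) {
  classification <- match.arg(classification)
  exclude <- match.arg(exclude)
  if (is.null(groups)) groups <- unique(records$zygosity_group)
  sel <- records[records$zygosity_group %in% groups, , drop = FALSE]
  if (nrow(sel) == 0)
    stop("crosstab: no pairs in the selected groups: ",
         paste(groups, collapse = ", "))
  sel <- .collapse_status(sel, classification, exclude)
  labels <- attr(sel, "labels")
  keep <- !is.na(sel$status1) & !is.na(sel$status2)
  sel <- sel[keep, , drop = FALSE]
  if (nrow(sel) == 0)
    stop("crosstab: all selected pairs excluded by the classification rule")
  k <- length(labels)
  counts <- table(factor(sel$status1, levels = 0:(k - 1L)),
                  factor(sel$status2, levels = 0:(k - 1L)))
  counts <- matrix(as.numeric(counts), k, k)
  opp <- all(groups %in% .opp_sex_groups)
  pair_table(counts, labels,
             zygosity_group = paste(sort(groups), collapse = "+"),
             opposite_sex = opp)
}

# Transpose a pair table (swap proband and co-twin roles).
.transpose_table <- function(tab) {
  tab$counts <- t(tab$counts)
  tab
}

#' Symmetrize a same-sex pair table
#'
#' Averages over using twin 1 or twin 2 as the proband:
#' `counts' = (counts + t(counts)) / 2`. The pair total is preserved and
#' half-counts are permitted. Opposite-sex tables are refused, since there
#' the proband direction is meaningful.
#'
#' @param tab a square `pair_table` from a same-sex group.
#' @return the symmetrized `pair_table`.
#' @export
symmetrize <- function(tab) {
  stopifnot(inherits(tab, "pair_table"))
  if (isTRUE(tab$opposite_sex))
    stop("symmetrize: refusing to symmetrize an opposite-sex table ",
         "(proband direction is meaningful)")
  if (nrow(tab$counts) != ncol(tab$counts))
    stop("symmetrize: table must be square")
  tab$counts <- (tab$counts + t(tab$counts)) / 2
  tab
}

.match_categories <- function(labels, x, what) {
  if (is.character(x)) {
    idx <- match(x, labels)
    if (any(is.na(idx)))
      stop("relative_risk: unknown ", what, " category: ",
           paste(x[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(x)
}

#' Proband to co-twin relative risk
#'
#' Risk of the co-twin outcome given a proband in `condition`, relative to
#' the co-twin risk given a non-depressed proband (the first table
#' category). Conditions and outcomes may be single categories or unions
#' (member cells are summed before risks are formed). The 95% confidence
#' interval uses the Katz log-interval
#' `exp(log RR +- z * sqrt(1/x1 - 1/n1 + 1/x0 - 1/n0))`.
#'
#' Same-sex tables should be [symmetrize()]d first so that the estimate
#' averages over the choice of proband.
#'
#' @param tab a `pair_table`.
#' @param condition proband categories (labels or 1-based indices),
#'   excluding the non-depressed reference category.
#' @param outcome co-twin outcome categories (labels or indices).
#' @param conf_level confidence level, default 0.95.
#' @return object of class `rr_estimate` with fields `rr`, `ci_low`,
#'   `ci_high`, `estimable`, `reason`, and the underlying counts.
#' @export
relative_risk <- function(tab, condition, outcome, conf_level = 0.95) {
  stopifnot(inherits(tab, "pair_table"))
  cts <- tab$counts
  labels <- tab$labels %||% as.character(seq_len(nrow(cts)))
  cond <- .match_categories(labels, condition, "condition")
  outc <- .match_categories(labels, outcome, "outcome")
  if (1L %in% cond)
    stop("relative_risk: the proband condition may not include the ",
         "non-depressed reference category")
  x1 <- sum(cts[cond, outc, drop = FALSE])
  n1 <- sum(cts[cond, , drop = FALSE])
  x0 <- sum(cts[1L, outc])
  n0 <- sum(cts[1L, ])
  res <- list(condition = labels[cond], outcome = labels[outc],
              x1 = x1, n1 = n1, x0 = x0, n0 = n0,
              rr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              estimable = FALSE, reason = NA_character_,
              conf_level = conf_level,
              zygosity_group = tab$zygosity_group)
  if (n1 == 0) {
    res$reason <- "no probands in condition"
  } else if (n0 == 0) {
    res$reason <- "no non-depressed probands"
  } else if (x0 == 0) {
    res$reason <- "zero reference risk"
  } else if (x1 == 0) {
    res$rr <- 0
    res$reason <- "zero outcome count in condition rows"
  } else {
    res$rr <- (x1 / n1) / (x0 / n0)
    z <- qnorm(1 - (1 - conf_level) / 2)
    se <- sqrt(1 / x1 - 1 / n1 + 1 / x0 - 1 / n0)
    res$ci_low <- exp(log(res$rr) - z * se)
    res$ci_high <- exp(log(res$rr) + z * se)
    res$estimable <- TRUE
  }
  structure(res, class = "rr_estimate")
}

#' @export
print.rr_estimate <- function(x, ...) {
  cat(sprintf("RR[%s -> %s | %s]: ", paste(x$condition, collapse = "/"),
              paste(x$outcome, collapse = "/"), x$zygosity_group))
  if (x$estimable)
    cat(sprintf("%.2f (%.2f-%.2f)\n", x$rr, x$ci_low, x$ci_high))
  else cat(sprintf("not estimable (%s)\n", x$reason))
  invisible(x)
}

#' Familial relative-risk table
#'
#' Computes the full grid of proband-condition by co-twin-outcome relative
#' risks (MiD, MD and their union) for the standard zygosity groupings:
#' pooled MZ (symmetrized), pooled same-sex DZ (symmetrized), and the two
#' proband orientations of opposite-sex DZ pairs (the table for a female
#' proband pools `DZ-FM` with the transpose of `DZ-MF`, and conversely).
#'
#' @param records twin-pair records with three-category statuses.
#' @return a `data.frame` with one row per condition-outcome pair and one
#'   column per grouping, each cell rendered as `"RR (low-high)"` with an
#'   em-dash for non-estimable entries; the underlying `rr_estimate`
#'   objects are in `attr(, "estimates")`.
#' @export
rr_table <- function(records) {
  specs <- expand.grid(outcome = c("MiD", "MD", "MiD/MD"),
                       condition = c("MiD", "MD", "MiD/MD"),
                       stringsAsFactors = FALSE)[, 2:1]
  cat_sets <- list("MiD" = "MiD", "MD" = "MD", "MiD/MD" = c("MiD", "MD"))

  groups_present <- unique(records$zygosity_group)
  tabs <- list()
  mzg <- intersect(c("MZ-FF", "MZ-MM"), groups_present)
  if (length(mzg))
    tabs[["MZ"]] <- symmetrize(crosstab(records, mzg, "three"))
  dzss <- intersect(c("DZ-FF", "DZ-MM"), groups_present)
  if (length(dzss))
    tabs[["DZss"]] <- symmetrize(crosstab(records, dzss, "three"))
  has_fm <- "DZ-FM" %in% groups_present
  has_mf <- "DZ-MF" %in% groups_present
  if (has_fm || has_mf) {
    fm <- if (has_fm) crosstab(records, "DZ-FM", "three")$counts else 0
    mf <- if (has_mf) crosstab(records, "DZ-MF", "three")$counts else 0
    tabs[["DZos F-M"]] <- pair_table(fm + t(mf), c("ND", "MiD", "MD"),
                                     "DZos-FM", opposite_sex = TRUE)
    tabs[["DZos M-F"]] <- pair_table(mf + t(fm), c("ND", "MiD", "MD"),
                                     "DZos-MF", opposite_sex = TRUE)
  }

  ests <- lapply(names(tabs), function(gn) {
    lapply(seq_len(nrow(specs)), function(i)
      relative_risk(tabs[[gn]], cat_sets[[specs$condition[i]]],
                    cat_sets[[specs$outcome[i]]]))
  })
  names(ests) <- names(tabs)

  out <- data.frame(proband_cotwin = paste0(specs$condition, "-",
                                            specs$outcome),
                    stringsAsFactors = FALSE)
  for (gn in names(ests)) {
    out[[gn]] <- vapply(ests[[gn]], function(e) {
      if (e$estimable && e$rr > 0)
        sprintf("%.2f (%.2f-%.2f)", e$rr, e$ci_low, e$ci_high)
      else "\u2014"
    }, character(1))
  }
  attr(out, "estimates") <- ests
  attr(out, "tables") <- tabs
  out
}
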