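# Synthetic twin-cohort generation under the liability-threshold model.

# Run code with a local, seeded RNG stream; the caller's RNG state is
# untouched. All randomness in the package flows through this helper.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Liability thresholds implied by category prevalences
#'
#' For ordered categories non-depressed < minor < major with prevalences
#' `p_minor` and `p_major`, the cutpoints on the standard-normal liability
#' scale are the upper quantiles of `p_minor + p_major` and `p_major`.
#'
#' @param p_minor,p_major category prevalences in (0, 1) with
#'   `p_minor + p_major < 1`.
#' @return numeric vector of two increasing thresholds.
#' @examples
#' thresholds_from_prevalence(0.0898, 0.0205)  # c(1.2249, 2.0433)
#' @export
thresholds_from_prevalence <- function(p_minor, p_major) {
  stopifnot(p_minor > 0, p_major > 0, p_minor + p_major < 1)
  c(qnorm(1 - (p_minor + p_major)), qnorm(1 - p_major))
}

#' Simulation parameters for a synthetic twin cohort
#'
#' Bundles the liability-variance decomposition, thresholds (or the
#' prevalences they are derived from), linear age/sex threshold effects, and
#' the per-group pair counts of a twin cohort simulated under the
#' bivariate-normal liability model.
#'
#' @param a2,c2,d2 additive-genetic, common-environment and dominance
#'   proportions of liability variance. `c2` and `d2` may not both be
#'   positive (ACE or ADE, never ACDE: the two are not jointly identifiable
#'   from twin pairs).
#' @param e2 unique-environment proportion; defaults to `1 - a2 - c2 - d2`.
#' @param prevalences named or positional vector `c(minor, major)` of category
#'   prevalences from which thresholds are derived; ignored when `thresholds`
#'   is given directly.
#' @param thresholds ordered liability cutpoints (standard-normal units);
#'   length 1 gives a two-category phenotype, length 2 the full
#'   non-depressed/minor/major classification.
#' @param beta_age linear age effect on the thresholds (per year, probit
#'   scale); positive values make depression rarer at older ages.
#' @param beta_sex male-female threshold difference (probit scale); positive
#'   values make depression rarer in males. Sex is coded 0 = female, 1 = male.
#' @param n_pairs named integer vector of pair counts per zygosity group,
#'   names among `MZ-FF, MZ-MM, DZ-FF, DZ-MM, DZ-FM, DZ-MF`.
#' @param age_range numeric `c(min, max)` in years; ages are drawn uniformly.
#' @param seed integer RNG seed carried with the parameters.
#' @return object of class `sim_params`.
#' @seealso [cohort_preset()] for ready-made cohort configurations,
#'   [simulate_cohort()] to generate records.
#' @export
sim_params <- function(a2 = 0.47, c2 = 0, d2 = 0, e2 = NULL,
                       prevalences = c(minor = 0.0898, major = 0.0205),
                       thresholds = NULL,
                       beta_age = 0, beta_sex = 0,
                       n_pairs = c("MZ-FF" = 250, "MZ-MM" = 250,
                                   "DZ-FF" = 250, "DZ-MM" = 250),
                       age_range = c(50, 92),
                       seed = NULL) {
  if (is.null(e2)) e2 <- 1 - a2 - c2 - d2
  comp <- c(a2 = a2, c2 = c2, d2 = d2, e2 = e2)
  if (any(comp < 0))
    stop("sim_params: variance components must be non-negative")
  if (abs(sum(comp) - 1) > 1e-12)
    stop("sim_params: a2 + c2 + d2 + e2 must equal 1 (got ", sum(comp), ")")
  if (c2 > 0 && d2 > 0)
    stop("sim_params: c2 and d2 may not both be positive (ACE or ADE only)")
  if (is.null(thresholds)) {
    stopifnot(length(prevalences) == 2L)
    thresholds <- thresholds_from_prevalence(prevalences[[1L]],
                                             prevalences[[2L]])
  }
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 1L || is.unsorted(thresholds, strictly = TRUE))
    stop("sim_params: thresholds must be strictly increasing")
  if (!all(names(n_pairs) %in% .zygosity_groups))
    stop("sim_params: unknown zygosity group in n_pairs: ",
         paste(setdiff(names(n_pairs), .zygosity_groups), collapse = ", "))
  if (any(n_pairs < 0) || sum(n_pairs) == 0)
    stop("sim_params: n_pairs must be non-negative with positive total")
  stopifnot(length(age_range) == 2L, age_range[1] <= age_range[2])
  structure(list(a2 = a2, c2 = c2, d2 = d2, e2 = e2,
                 thresholds = thresholds,
                 beta_age = beta_age, beta_sex = beta_sex,
                 n_pairs = n_pairs, age_range = as.numeric(age_range),
                 seed = seed),
            class = "sim_params")
}

#' Preset cohort configurations
#'
#' Two ready-made configurations emulating the structure of the study
#' cohorts: `"aged"`, an older-adult cohort of 1220 pairs (643 MZ, 577 DZ;
#' ages 50-92) with current-depression prevalences 8.98% minor / 2.05% major,
#' and `"te"`, a young-adult cohort of 2363 pairs (1005 MZ, 1358 DZ; ages
#' 23-38) with lifetime prevalences 7.70% minor / 37.41% major. Liability
#' variance is AE with a2 = 0.47 (aged) and 0.40 (te), the three-category
#' additive-genetic point estimates for the corresponding phenotypes.
#'
#' @param name `"aged"` or `"te"`.
#' @param ... overrides passed on to [sim_params()] (e.g. `a2`, `seed`).
#' @return object of class `sim_params`.
#' @export
cohort_preset <- function(name = c("aged", "te"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    aged = list(a2 = 0.47, e2 = 0.53,
                prevalences = c(minor = 0.0898, major = 0.0205),
                n_pairs = c("MZ-FF" = 491, "MZ-MM" = 152, "DZ-FF" = 263,
                            "DZ-MM" = 73, "DZ-FM" = 136, "DZ-MF" = 105),
                age_range = c(50, 92)),
    te = list(a2 = 0.40, e2 = 0.60,
              prevalences = c(minor = 0.0770, major = 0.3741),
              n_pairs = c("MZ-FF" = 609, "MZ-MM" = 396, "DZ-FF" = 455,
                          "DZ-MM" = 349, "DZ-FM" = 301, "DZ-MF" = 253),
              age_range = c(23, 38)))
  args <- utils::modifyList(base, list(...))
  do.call(sim_params, args)
}

#' Map liabilities to ordinal statuses
#'
#' An individual's status is the number of (covariate-shifted) thresholds
#' strictly below their liability; a liability exactly at a shifted threshold
#' falls in the lower category. Each threshold is shifted by
#' `beta_age * (age - age_ref) + beta_sex * sex` (parallel-threshold
#' covariate model).
#'
#' @param liability numeric vector of standard-normal liabilities.
#' @param thresholds strictly increasing cutpoints.
#' @param age,sex covariate vectors (sex coded 0 = female, 1 = male);
#'   ignored when the corresponding effect is 0.
#' @param beta_age,beta_sex linear threshold effects (probit scale).
#' @param age_ref reference (cohort mean) age.
#' @return integer statuses in `0:length(thresholds)`.
#' @export
liability_to_status <- function(liability, thresholds, age = 0, sex = 0,
                                beta_age = 0, beta_sex = 0, age_ref = 0) {
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 1L || is.unsorted(thresholds, strictly = TRUE))
    stop("liability_to_status: thresholds must be strictly increasing")
  shift <- beta_age * (age - age_ref) + beta_sex * sex
  status <- integer(length(liability))
  for (t in thresholds) status <- status + (liability > t + shift)
  as.integer(status)
}

# Draw a symptom profile consistent with an ordinal status: counts uniform on
# the category-consistent range, a core symptom forced for categories 1-2.
.draw_symptoms <- function(status) {
  n <- length(status)
  out <- matrix(0L, n, 9L)
  count <- integer(n)
  count[status == 0L] <- sample(0:1, sum(status == 0L), replace = TRUE)
  count[status == 1L] <- sample(2:4, sum(status == 1L), replace = TRUE)
  count[status == 2L] <- sample(5:9, sum(status == 2L), replace = TRUE)
  for (i in seq_len(n)) {
    k <- count[i]
    if (k == 0L) next
    if (status[i] >= 1L) {
      core <- sample(1:2, 1L)
      rest <- sample(setdiff(1:9, core), k - 1L)
      out[i, c(core, rest)] <- 1L
    } else {
      out[i, sample(1:9, k)] <- 1L
    }
  }
  colnames(out) <- paste0("sym", 1:9)
  out
}

#' Simulate a twin cohort under the liability-threshold model
#'
#' Draws, per pair, bivariate standard-normal liabilities with correlation
#' `a2 + c2 + d2` (MZ) or `0.5 a2 + c2 + 0.25 d2` (DZ), ages uniform over the
#' configured range, and converts liabilities to ordinal statuses via
#' [liability_to_status()] with the configured thresholds and age/sex
#' effects. The reference age is the midpoint of `age_range`.
#'
#' @param params a [sim_params()] object.
#' @param seed optional integer overriding `params$seed`.
#' @param symptoms if `TRUE`, also draw per-twin DSM symptom-indicator
#'   vectors consistent with each status (columns `sym1_1 ... sym9_2`).
#' @param keep_liability if `TRUE`, retain the latent liabilities as columns
#'   `liab1`, `liab2` (useful for checking the generator itself).
#' @return a `data.frame` of twin-pair records with columns `pair_id`,
#'   `zygosity_group`, `age`, `sex1`, `sex2` (`"F"`/`"M"`), `status1`,
#'   `status2`, plus optional symptom and liability columns.
#' @examples
#' rec <- simulate_cohort(cohort_preset("aged", seed = 1))
#' table(rec$status1)
#' @export
simulate_cohort <- function(params, seed = NULL, symptoms = FALSE,
                            keep_liability = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(seed)) seed <- params$seed
  with_seed(seed, {
    groups <- names(params$n_pairs)
    rmz <- params$a2 + params$c2 + params$d2
    rdz <- 0.5 * params$a2 + params$c2 + 0.25 * params$d2
    age_ref <- mean(params$age_range)
    pieces <- lapply(groups, function(g) {
      n <- params$n_pairs[[g]]
      if (n == 0L) return(NULL)
      r <- if (startsWith(g, "MZ")) rmz else rdz
      l1 <- rnorm(n)
      l2 <- r * l1 + sqrt(1 - r^2) * rnorm(n)
      age <- runif(n, params$age_range[1], params$age_range[2])
      sexes <- strsplit(sub("^.*-", "", g), "")[[1]]
      s1 <- ifelse(sexes[1] == "M", 1, 0)
      s2 <- ifelse(sexes[2] == "M", 1, 0)
      df <- data.frame(
        zygosity_group = g, age = age,
        sex1 = sexes[1], sex2 = sexes[2],
        status1 = liability_to_status(l1, params$thresholds, age, s1,
                                      params$beta_age, params$beta_sex,
                                      age_ref),
        status2 = liability_to_status(l2, params$thresholds, age, s2,
                                      params$beta_age, params$beta_sex,
                                      age_ref),
        stringsAsFactors = FALSE)
      if (keep_liability) { df$liab1 <- l1; df$liab2 <- l2 }
      df
    })
    rec <- do.call(rbind, pieces)
    rec <- cbind(pair_id = sprintf("P%05d", seq_len(nrow(rec))), rec,
                 stringsAsFactors = FALSE)
    if (symptoms) {
      sy1 <- .draw_symptoms(rec$status1)
      sy2 <- .draw_symptoms(rec$status2)
      colnames(sy1) <- paste0(colnames(sy1), "_1")
      colnames(sy2) <- paste0(colnames(sy2), "_2")
      rec <- cbind(rec, sy1, sy2)
    }
    attr(rec, "age_ref") <- age_ref
    rec
  })
}
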