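#' Classify DSM-IV symptom profiles into depression categories
#'
#' Applies the symptom-count rule for current/lifetime depression: an
#' individual endorsing at least five of the nine DSM-IV major depressive
#' episode criteria, among them depressed mood or anhedonia, is classified as
#' major depression (2); two to four criteria including a core symptom as
#' minor depression (1); everyone else - including any number of endorsed
#' criteria without a core symptom - as non-depressed (0).
#'
#' @param symptoms a logical/0-1 vector of length 9, or an `n x 9` matrix with
#'   one profile per row. Positions 1 and 2 are the core symptoms (depressed
#'   mood and anhedonia); positions 3-9 the remaining criteria (appetite or
#'   weight change, sleep disturbance, psychomotor change, fatigue,
#'   worthlessness or guilt, impaired concentration, thoughts of death).
#' @return integer vector of ordinal statuses: 0 (non-depressed),
#'   1 (minor depression), 2 (major depression).
#' @examples
#' classify_dsm(c(1, 0, 1, 1, 1, 1, 0, 0, 0))  # 5 symptoms incl. core -> 2
#' classify_dsm(c(0, 1, 1, 1, 0, 0, 0, 0, 0))  # 3 symptoms incl. core -> 1
#' classify_dsm(c(0, 0, 1, 1, 1, 1, 0, 0, 0))  # 4 symptoms, no core  -> 0
#' @export
classify_dsm <- function(symptoms) {
  if (is.null(dim(symptoms))) {
    if (length(symptoms) != 9L)
      stop("classify_dsm: expected exactly 9 symptom indicators, got ",
           length(symptoms))
    symptoms <- matrix(symptoms, nrow = 1L)
    scalar <- TRUE
  } else {
    symptoms <- as.matrix(symptoms)
    if (ncol(symptoms) != 9L)
      stop("classify_dsm: expected 9 symptom columns, got ", ncol(symptoms))
    scalar <- FALSE
  }
  s <- symptoms * 1
  if (any(is.na(s)) || !all(s %in% c(0, 1)))
    stop("classify_dsm: symptom indicators must be binary (0/1)")
  total <- rowSums(s)
  core <- s[, 1L] == 1 | s[, 2L] == 1
  status <- integer(nrow(s))
  status[core & total >= 5] <- 2L
  status[core & total >= 2 & total <= 4] <- 1L
  if (scalar) status[[1L]] else status
}
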