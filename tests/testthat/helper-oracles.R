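# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force DSM symptom-count classifier, a literal transcription of the
# two diagnostic rules: >= 5 criteria incl. a core symptom -> major; 2-4
# criteria incl. a core symptom -> minor; otherwise non-depressed.
oracle_classify <- function(symptoms) {
  total <- sum(symptoms)
  core <- symptoms[1] == 1 || symptoms[2] == 1
  if (total >= 5 && core) return(2L)
  if (total >= 2 && total <= 4 && core) return(1L)
  0L
}

# All 512 binary symptom vectors, one per row.
all_symptom_vectors <- function() {
  m <- as.matrix(expand.grid(rep(list(0:1), 9)))
  colnames(m) <- paste0("s", 1:9)
  m
}

# Closed-form orthant probability P(X > 0, Y > 0) = 1/4 + asin(rho)/(2 pi).
orthant_prob <- function(rho) 0.25 + asin(rho) / (2 * pi)

# Dense 2-D Gauss-Legendre tensor-product integration of the bivariate
# normal density over a finite rectangle; nodes chosen high enough that the
# quadrature error is far below 1e-10.
dense_rect_prob <- function(lo1, hi1, lo2, hi2, rho, n_nodes = 120) {
  lo1 <- max(lo1, -8.5); lo2 <- max(lo2, -8.5)
  hi1 <- min(hi1, 8.5); hi2 <- min(hi2, 8.5)
  gl <- function(a, b, n) {
    # Golub-Welsch via eigen decomposition of the Jacobi matrix.
    i <- seq_len(n - 1)
    beta <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- beta
    J[cbind(i + 1, i)] <- beta
    e <- eigen(J, symmetric = TRUE)
    x <- e$values
    w <- 2 * e$vectors[1, ]^2
    list(x = (b - a) / 2 * x + (a + b) / 2, w = (b - a) / 2 * w)
  }
  g1 <- gl(lo1, hi1, n_nodes)
  g2 <- gl(lo2, hi2, n_nodes)
  dens <- function(x, y)
    exp(-(x^2 - 2 * rho * x * y + y^2) / (2 * (1 - rho^2))) /
      (2 * pi * sqrt(1 - rho^2))
  sum(outer(g1$w, g2$w) * outer(g1$x, g2$x, dens))
}

# Multinomial draw of a k x k table from the bivariate-normal liability
# model, without using the package's cell-probability code.
draw_bvn_table <- function(n, rho, thresholds) {
  l1 <- rnorm(n)
  l2 <- rho * l1 + sqrt(1 - rho^2) * rnorm(n)
  cut_at <- c(-Inf, thresholds, Inf)
  s1 <- cut(l1, cut_at, labels = FALSE)
  s2 <- cut(l2, cut_at, labels = FALSE)
  k <- length(thresholds) + 1L
  matrix(as.numeric(table(factor(s1, 1:k), factor(s2, 1:k))), k, k)
}

# Small deterministic record set for structural tests.
toy_records <- function() {
  data.frame(
    pair_id = paste0("P", 1:6),
    zygosity_group = c("MZ-FF", "MZ-FF", "DZ-FF", "DZ-MM", "DZ-FM", "DZ-MF"),
    age = c(55, 60, 65, 70, 75, 80),
    sex1 = c("F", "F", "F", "M", "F", "M"),
    sex2 = c("F", "F", "F", "M", "M", "F"),
    status1 = c(0L, 1L, 2L, 0L, 1L, 2L),
    status2 = c(0L, 2L, 1L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
}
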