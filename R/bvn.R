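# Standard bivariate normal probabilities.
#
# Vectorised implementation of the Drezner-Wesolowsky/Genz hybrid algorithm:
# Gauss-Legendre quadrature over asin(rho) for moderate correlations and an
# asymptotic expansion plus quadrature near |rho| = 1. Absolute accuracy is
# well below 1e-12, comfortably inside the 1e-10 contract of bvn_rect().

# 20-point Gauss-Legendre nodes/weights on [-1, 1] (negative half; symmetric).
.gl20_x <- c(
  -0.993128599185093552, -0.963971927277912588, -0.912234428251325280,
  -0.839116971822217561, -0.746331906460150130, -0.636053680726515580,
  -0.510867001950826349, -0.373706088715418328, -0.227785851141644957,
  -0.076526521133497227)
.gl20_w <- c(
  0.017614007139152579, 0.040601429800388021, 0.062672048334107860,
  0.083276741576706975, 0.101930119817240525, 0.118194531961519481,
  0.131688638449174222, 0.142096109318381209, 0.149172986472603603,
  0.152753387130726004)

# Upper-tail probability P(X > h, Y > k) for finite h, k and |r| < 1.
# All three arguments must have equal length.
.bvnu <- function(h, k, r) {
  res <- numeric(length(h))

  lo <- abs(r) < 0.925
  if (any(lo)) {
    hh <- h[lo]; kk <- k[lo]; rr <- r[lo]
    hk <- hh * kk
    hs <- (hh * hh + kk * kk) / 2
    asr <- asin(rr)
    bvn <- 0
    for (i in seq_along(.gl20_x)) {
      for (is in c(-1, 1)) {
        sn <- sin(asr * (is * .gl20_x[i] + 1) / 2)
        bvn <- bvn + .gl20_w[i] * exp((sn * hk - hs) / (1 - sn * sn))
      }
    }
    res[lo] <- bvn * asr / (4 * pi) + pnorm(-hh) * pnorm(-kk)
  }

  if (any(!lo)) {
    hh <- h[!lo]; kk <- k[!lo]; rr <- r[!lo]
    neg <- rr < 0
    kk[neg] <- -kk[neg]
    hk <- hh * kk
    bvn <- numeric(length(hh))
    as_ <- (1 - rr) * (1 + rr)
    a <- sqrt(as_)
    bs <- (hh - kk)^2
    cc <- (4 - hk) / 8
    dd <- (12 - hk) / 16
    asr0 <- -(bs / as_ + hk) / 2
    m <- asr0 > -100
    t0 <- a * exp(asr0) * (1 - cc * (bs - as_) * (1 - dd * bs / 5) / 3 +
                             cc * dd * as_ * as_ / 5)
    bvn[m] <- t0[m]
    m2 <- -hk < 100
    b <- sqrt(bs)
    t1 <- exp(-hk / 2) * sqrt(2 * pi) * pnorm(-b / a) * b *
      (1 - cc * bs * (1 - dd * bs / 5) / 3)
    bvn[m2] <- bvn[m2] - t1[m2]
    ah <- a / 2
    for (i in seq_along(.gl20_x)) {
      for (is in c(-1, 1)) {
        xs <- (ah * (is * .gl20_x[i] + 1))^2
        rs <- sqrt(1 - xs)
        asr1 <- -(bs / xs + hk) / 2
        term <- ah * .gl20_w[i] * exp(asr1) *
          (exp(-hk * (1 - rs) / (2 * (1 + rs))) / rs -
             (1 + cc * xs * (1 + dd * xs)))
        ok <- asr1 > -100
        bvn[ok] <- bvn[ok] + term[ok]
      }
    }
    bvn <- -bvn / (2 * pi)
    pos <- !neg
    if (any(pos)) bvn[pos] <- bvn[pos] + pnorm(-pmax(hh, kk))[pos]
    if (any(neg)) {
      bvn[neg] <- -bvn[neg]
      add <- neg & (kk > hh)
      if (any(add)) bvn[add] <- bvn[add] + (pnorm(kk) - pnorm(hh))[add]
    }
    res[!lo] <- bvn
  }

  pmin(pmax(res, 0), 1)
}

#' Standard bivariate normal CDF
#'
#' `pbvn(h, k, rho)` computes `P(X <= h, Y <= k)` for a standard bivariate
#' normal vector `(X, Y)` with correlation `rho`. Vectorised over all three
#' arguments (recycled to a common length); infinite bounds and `rho = +-1`
#' (the degenerate one-dimensional limits) are handled exactly.
#'
#' @param h,k upper integration bounds (may be `-Inf`/`Inf`).
#' @param rho latent correlation(s) in `[-1, 1]`.
#' @return vector of probabilities.
#' @examples
#' pbvn(0, 0, 0.5)          # 1/4 + asin(0.5) / (2 * pi) = 1/3
#' pbvn(Inf, 1.96, 0.7)     # marginal: pnorm(1.96)
#' @export
pbvn <- function(h, k, rho) {
  n <- max(length(h), length(k), length(rho))
  h <- rep_len(as.numeric(h), n)
  k <- rep_len(as.numeric(k), n)
  rho <- rep_len(as.numeric(rho), n)
  if (any(is.na(h) | is.na(k) | is.na(rho)))
    stop("pbvn: NA arguments are not allowed")
  if (any(abs(rho) > 1))
    stop("pbvn: |rho| must be <= 1")

  out <- numeric(n)
  # Degenerate correlations: comonotone / antithetic limits.
  d1 <- rho == 1
  dm <- rho == -1
  out[d1] <- pnorm(pmin(h[d1], k[d1]))
  out[dm] <- pmax(0, pnorm(h[dm]) + pnorm(k[dm]) - 1)

  gen <- !(d1 | dm)
  if (any(gen)) {
    hg <- h[gen]; kg <- k[gen]; rg <- rho[gen]
    og <- numeric(length(hg))
    zero <- hg == -Inf | kg == -Inf
    hinf <- !zero & hg == Inf
    kinf <- !zero & !hinf & kg == Inf
    og[hinf] <- pnorm(kg[hinf])
    og[kinf] <- pnorm(hg[kinf])
    fin <- !(zero | hinf | kinf)
    if (any(fin)) og[fin] <- .bvnu(-hg[fin], -kg[fin], rg[fin])
    out[gen] <- og
  }
  out
}

#' Rectangle probability under the standard bivariate normal
#'
#' Probability that a standard bivariate normal vector with correlation `rho`
#' falls in the rectangle `(lo1, hi1] x (lo2, hi2]`. This is the kernel from
#' which every cell probability of the liability-threshold model is built.
#'
#' @param lo1,hi1 liability bounds on the first axis (may be infinite).
#' @param lo2,hi2 bounds on the second axis.
#' @param rho latent correlation in `[-1, 1]`.
#' @return vector of probabilities in `[0, 1]`.
#' @examples
#' bvn_rect(0, Inf, 0, Inf, 0)    # independent positive quadrant: 0.25
#' bvn_rect(-Inf, Inf, -Inf, Inf, 0.8)  # whole plane: 1
#' @export
bvn_rect <- function(lo1, hi1, lo2, hi2, rho) {
  n <- max(length(lo1), length(hi1), length(lo2), length(hi2), length(rho))
  lo1 <- rep_len(as.numeric(lo1), n); hi1 <- rep_len(as.numeric(hi1), n)
  lo2 <- rep_len(as.numeric(lo2), n); hi2 <- rep_len(as.numeric(hi2), n)
  rho <- rep_len(as.numeric(rho), n)
  if (any(lo1 >= hi1) || any(lo2 >= hi2))
    stop("bvn_rect: lower bounds must be strictly below upper bounds")
  p <- pbvn(hi1, hi2, rho) - pbvn(lo1, hi2, rho) -
    pbvn(hi1, lo2, rho) + pbvn(lo1, lo2, rho)
  pmin(pmax(p, 0), 1)
}

# Cell probabilities of a k1 x k2 ordinal table under the bivariate normal
# liability model: thresholds are the interior cutpoints per margin.
.bvn_cell_probs <- function(rho, thr_row, thr_col) {
  br <- c(-Inf, thr_row, Inf)
  bc <- c(-Inf, thr_col, Inf)
  k1 <- length(br) - 1L
  k2 <- length(bc) - 1L
  cdf <- matrix(pbvn(rep(br, times = k2 + 1L), rep(bc, each = k1 + 1L), rho),
                k1 + 1L, k2 + 1L)
  p <- cdf[-1L, -1L, drop = FALSE] - cdf[-(k1 + 1L), -1L, drop = FALSE] -
    cdf[-1L, -(k2 + 1L), drop = FALSE] + cdf[-(k1 + 1L), -(k2 + 1L), drop = FALSE]
  pmax(p, 0)
}
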