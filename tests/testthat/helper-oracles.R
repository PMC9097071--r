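# Independent brute-force oracles, deliberately naive implementations
# that share no code path with the package.

# analytic-signal envelope from the explicit DFT construction:
# forward DFT by summation, one-sided doubling, inverse DFT by summation.
oracle_envelope <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  W <- exp(-2i * pi * outer(k, k) / n)
  X <- as.vector(W %*% x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Winv <- exp(2i * pi * outer(k, k) / n)
  Mod(as.vector(Winv %*% (X * h)) / n)
}

# exhaustive scan of the SD peak rule over every interior sample
oracle_peaks <- function(x) {
  th <- mean(x) + sd(x)
  hits <- integer(0)
  for (i in 2:(length(x) - 1)) {
    if (x[i] > th && x[i] > x[i - 1] && x[i] >= x[i + 1])
      hits <- c(hits, i)
  }
  hits
}

# direct bilinear interpolation of matrix m at (row, col) real coordinates
oracle_bilinear <- function(m, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  r0 <- min(max(r0, 1), nrow(m) - 1)
  c0 <- min(max(c0, 1), ncol(m) - 1)
  fr <- r - r0; fc <- c - c0
  m[r0, c0] * (1 - fr) * (1 - fc) + m[r0 + 1, c0] * fr * (1 - fc) +
    m[r0, c0 + 1] * (1 - fr) * fc + m[r0 + 1, c0 + 1] * fr * fc
}

# one-way repeated-measures F from explicit sums of squares
# (y: subjects x levels matrix)
oracle_rm_f <- function(y) {
  n <- nrow(y); m <- ncol(y)
  grand <- mean(y)
  ss_cond <- n * sum((colMeans(y) - grand)^2)
  ss_subj <- m * sum((rowMeans(y) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  (ss_cond / (m - 1)) / (ss_err / ((n - 1) * (m - 1)))
}

# Kruskal-Wallis H with tie correction, from first principles
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  n <- length(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Pearson r from the covariance formula
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  num / den
}

# build a bare FRA grid for feature tests (bands x intensities)
make_fra <- function(m, bands = abr_bands(),
                     intensities = abr_intensities()) {
  dimnames(m) <- list(bands, as.character(intensities))
  structure(m, band_centers = band_center(bands),
            intensities = intensities,
            class = c("fra", "matrix", "array"))
}

# single-band ground truth shorthand
gt1 <- function(s, band = "9-11", noise_sd = 0, ...) {
  ground_truth_animal(stats::setNames(list(stats::setNames(s, band)),
                                      "pre"),
                      noise_sd = noise_sd, ...)
}
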