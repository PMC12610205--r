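# Independent oracles, deliberately naive: each recomputes a quantity by
# direct enumeration so the pipeline implementations can be checked
# against a second route.

# Otsu by exhaustive search: for every candidate threshold compute the two
# class weights/means directly and maximize between-class variance.
oracle_otsu <- function(h) {
  best <- 0L; bestval <- -Inf
  tot <- sum(h)
  for (t in 0:255) {
    lo <- 0:t; hi <- if (t < 255) (t + 1):255 else integer(0)
    n0 <- sum(h[lo + 1]); n1 <- tot - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(lo * h[lo + 1]) / n0
    mu1 <- sum(hi * h[hi + 1]) / n1
    v <- (n0 / tot) * (n1 / tot) * (mu0 - mu1)^2
    if (v > bestval + 1e-12) { bestval <- v; best <- t }
  }
  best
}

# coverage by an explicit double loop over the region's pixels
oracle_coverage <- function(region, signal) {
  h <- nrow(signal)
  hits <- 0L
  for (p in region$pixels) {
    r <- ((p - 1) %% h) + 1
    cc <- ((p - 1) %/% h) + 1
    if (signal[r, cc] != 0) hits <- hits + 1L
  }
  hits / region$area
}

# ICC(A,1) via R's own two-way ANOVA fit rather than closed-form sums
oracle_icc_a1 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  row = factor(rep(seq_len(n), k)),
                  col = factor(rep(seq_len(k), each = n)))
  av <- summary(stats::aov(y ~ row + col, data = d))[[1]]
  msr <- av["row", "Mean Sq"]; msc <- av["col", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# mean gray by per-pixel accumulation
oracle_mean_gray <- function(region, channel) {
  h <- nrow(channel)
  s <- 0
  for (p in region$pixels) {
    r <- ((p - 1) %% h) + 1
    cc <- ((p - 1) %/% h) + 1
    s <- s + channel[r, cc]
  }
  s / region$area
}

# random histogram mixing smooth bimodal shapes and sparse spikes
random_histogram <- function() {
  kind <- sample(3, 1)
  if (kind == 1L) {
    x <- c(rnorm(2000, runif(1, 40, 90), runif(1, 5, 25)),
           rnorm(1500, runif(1, 140, 220), runif(1, 5, 30)))
  } else if (kind == 2L) {
    x <- runif(3000, 0, 255)
  } else {
    x <- sample(0:255, 400, replace = TRUE)
  }
  tabulate(pmin(255, pmax(0, round(x))) + 1L, nbins = 256L)
}
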