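#' @title Histogram auto-thresholding
#'
#' @description
#' Global threshold selection on 256-bin histograms, covering the 17
#' algorithms of the ImageJ/Fiji AutoThreshold suite: Default, Huang, Huang2,
#' Intermodes, IsoData, Li, MaxEntropy, Mean, MinError, Minimum, Moments,
#' Otsu, Percentile, RenyiEntropy, Shanbhag, Triangle and Yen. Each is
#' implemented from its primary published description; where the ImageJ
#' variant deviates from the primary source (notably "Default", the
#' platform's original iterative intermeans, and "Huang2") the platform
#' variant is followed as documented. All thresholds are integers in
#' \code{[0, 255]}; internal ties break toward the lower threshold.
#'
#' @name autothreshold
NULL

#' Available threshold algorithm names
#' @return Character vector of the 17 method names.
#' @export
threshold_methods <- function() c(
  "Default", "Huang", "Huang2", "Intermodes", "IsoData", "Li", "MaxEntropy",
  "Mean", "MinError", "Minimum", "Moments", "Otsu", "Percentile",
  "RenyiEntropy", "Shanbhag", "Triangle", "Yen"
)

#' 256-bin intensity histogram
#'
#' @param img Canonical 8-bit single-channel image.
#' @return Integer vector of length 256; element \code{v + 1} counts pixels
#'   with value \code{v}.
#' @export
histogram256 <- function(img) {
  img <- assert_gray(img)
  tabulate(as.integer(img) + 1L, nbins = 256L)
}

# ---- helpers (0-based intensity levels throughout: bin b holds level b-1) ----

lvls <- 0:255

first_nonzero <- function(h) which(h > 0)[1L] - 1L          # level
last_nonzero <- function(h) max(which(h > 0)) - 1L          # level

# ---- individual algorithms; each takes integer counts of length 256 ----

# ImageJ's original iterative intermeans ("Default"): walk the candidate
# threshold upward from the lowest occupied bin until it passes the midpoint
# of the two class means.
th_default <- function(h) {
  mn <- first_nonzero(h); mx <- last_nonzero(h)
  if (mn >= mx) return(128L)
  moving <- mn
  repeat {
    lo <- mn:moving; hi <- (moving + 1L):mx
    m1 <- sum(lo * h[lo + 1L]) / sum(h[lo + 1L])
    m2 <- sum(hi * h[hi + 1L]) / sum(h[hi + 1L])
    res <- (m1 + m2) / 2
    moving <- moving + 1L
    if (!((moving + 1L) <= res && moving < mx - 1L)) break
  }
  as.integer(round(res))
}

# Ridler & Calvard iterative selection as implemented on the platform
# (integer class means).
th_isodata <- function(h) {
  g <- which(h[-1L] > 0)[1L]            # level of first occupied bin above 0, per platform convention
  if (is.na(g)) g <- 1L
  g <- g + 1L                           # start one level above it
  repeat {
    lo <- 0:(g - 1L); hi <- seq.int(g + 1L, 255L)
    totl <- sum(h[lo + 1L]); toth <- if (g >= 255L) 0 else sum(h[hi + 1L])
    if (totl > 0 && toth > 0) {
      l <- sum(lo * h[lo + 1L]) %/% totl
      hh <- sum(hi * h[hi + 1L]) %/% toth
      if (g == as.integer(round((l + hh) / 2))) return(as.integer(g))
    }
    g <- g + 1L
    if (g > 254L) return(128L)
  }
}

# Huang & Wang: minimize measured fuzziness (Shannon entropy of the
# membership function); platform form with rounded class means.
th_huang <- function(h, round_mu = TRUE) {
  first <- first_nonzero(h); last <- last_nonzero(h)
  if (first == last) return(as.integer(first))
  idx <- first:last
  S <- cumsum(h[idx + 1L])              # S[i] = count up to level first+i-1
  W <- cumsum(idx * h[idx + 1L])
  C <- last - first
  # entropy summand as a function of |level - class mean|
  dmax <- C
  dd <- 1:dmax
  mu_d <- 1 / (1 + dd / C)
  Smu <- c(0, -mu_d * log(mu_d) - (1 - mu_d) * log(1 - mu_d))  # Smu[d+1]
  best <- first; bestval <- Inf
  n <- length(idx)
  for (ti in seq_len(n)) {
    t <- idx[ti]
    mu1 <- W[ti] / S[ti]
    if (round_mu) mu1 <- round(mu1)
    ent <- sum(Smu[pmin(abs(idx[1:ti] - mu1), dmax) + 1L] * h[idx[1:ti] + 1L])
    if (ti < n) {
      mu2 <- (W[n] - W[ti]) / (S[n] - S[ti])
      if (round_mu) mu2 <- round(mu2)
      ii <- idx[(ti + 1L):n]
      ent <- ent + sum(Smu[pmin(abs(ii - mu2), dmax) + 1L] * h[ii + 1L])
    }
    if (ent < bestval) { bestval <- ent; best <- t }
  }
  as.integer(best)
}

# Huang2: same fuzziness criterion with unrounded class means (the second,
# faster implementation shipped by the platform differs from Huang only in
# bin-level details; continuous means are the documented variant here).
th_huang2 <- function(h) th_huang(h, round_mu = FALSE)

# 3-point running-mean smoothing used by Intermodes/Minimum
smooth3 <- function(x) {
  n <- length(x)
  (c(0, x[-n]) + x + c(x[-1L], 0)) / 3
}

bimodal <- function(x) {
  n <- length(x)
  peaks <- sum(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n])
  peaks == 2L
}

# Some histograms (e.g. all mass in the outermost bins) never develop two
# interior modes under running-mean smoothing; those fall back to the Mean
# threshold with a warning so batch runs stay robust.
smooth_until_bimodal <- function(h) {
  y <- as.numeric(h)
  iter <- 0L
  while (!bimodal(y)) {
    y <- smooth3(y)
    iter <- iter + 1L
    if (iter > 10000L) return(NULL)
  }
  y
}

# Prewitt & Mendelsohn: midpoint of the two modes after smoothing.
th_intermodes <- function(h) {
  y <- smooth_until_bimodal(h)
  if (is.null(y)) {
    warning("histogram cannot be smoothed to bimodality; using Mean")
    return(th_mean(h))
  }
  n <- length(y)
  pk <- which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] > y[3:n])  # 0-based level = pk
  as.integer(floor(sum(pk) / 2))
}

# Minimum between the two modes after smoothing.
th_minimum <- function(h) {
  y <- smooth_until_bimodal(h)
  if (is.null(y)) {
    warning("histogram cannot be smoothed to bimodality; using Mean")
    return(th_mean(h))
  }
  for (i in 2:255) {
    if (y[i - 1L] > y[i] && y[i + 1L] >= y[i]) return(as.integer(i - 1L))
  }
  th_mean(h)
}

# Li & Tam: iterative minimum cross-entropy.
th_li <- function(h) {
  tot <- sum(h)
  mean_all <- sum(lvls * h) / tot
  new_t <- mean_all
  t_int <- as.integer(new_t + 0.5)
  repeat {
    old_t <- new_t
    t_int <- as.integer(old_t + 0.5)
    lo <- 0:t_int
    sum_lo <- sum(h[lo + 1L]); mean_lo <- if (sum_lo > 0) sum(lo * h[lo + 1L]) / sum_lo else 0
    if (t_int < 255L) {
      hi <- (t_int + 1L):255L
      sum_hi <- sum(h[hi + 1L]); mean_hi <- if (sum_hi > 0) sum(hi * h[hi + 1L]) / sum_hi else 0
    } else mean_hi <- 0
    if (mean_lo < 1e-10) mean_lo <- 1e-10   # log guard at the dark end
    if (mean_hi < 1e-10) mean_hi <- 1e-10
    denom <- log(mean_lo) - log(mean_hi)
    if (abs(denom) < 1e-12) break
    temp <- (mean_lo - mean_hi) / denom
    new_t <- if (temp < 0) as.integer(temp - 0.5) else as.integer(temp + 0.5)
    if (abs(new_t - old_t) <= 0.5) break
  }
  as.integer(t_int)
}

# Kapur, Sahoo & Wong: maximize the sum of background and foreground
# Shannon entropies.
th_maxentropy <- function(h) {
  p <- h / sum(h)
  P1 <- cumsum(p)
  first <- first_nonzero(h); last <- last_nonzero(h)
  best <- first; bestval <- -Inf
  for (t in first:last) {
    w0 <- P1[t + 1L]; w1 <- 1 - w0
    if (w0 < 1e-12 || w1 < 1e-12) next
    p0 <- p[1:(t + 1L)]; p0 <- p0[p0 > 0]
    hb <- -sum((p0 / w0) * log(p0 / w0))
    p1v <- if (t < 255L) p[(t + 2L):256L] else numeric(0)
    p1v <- p1v[p1v > 0]
    hw <- if (length(p1v)) -sum((p1v / w1) * log(p1v / w1)) else 0
    v <- hb + hw
    if (v > bestval) { bestval <- v; best <- t }
  }
  as.integer(best)
}

# Glasbey's "mean": floor of the histogram mean.
th_mean <- function(h) as.integer(floor(sum(lvls * h) / sum(h)))

# Kittler & Illingworth minimum-error thresholding, iterative form.
th_minerror <- function(h) {
  A <- cumsum(h)
  B <- cumsum(lvls * h)
  C <- cumsum(lvls^2 * h)
  At <- A[256L]; Bt <- B[256L]; Ct <- C[256L]
  t <- th_mean(h)
  prev <- -2L
  iter <- 0L
  while (t != prev) {
    iter <- iter + 1L
    if (iter > 10000L) { warning("MinError did not converge"); break }
    i <- t + 1L
    if (A[i] <= 0 || At - A[i] <= 0) { warning("MinError: degenerate class"); break }
    mu <- B[i] / A[i]
    nu <- (Bt - B[i]) / (At - A[i])
    pp <- A[i] / At
    q <- (At - A[i]) / At
    sigma2 <- C[i] / A[i] - mu^2
    tau2 <- (Ct - C[i]) / (At - A[i]) - nu^2
    if (sigma2 <= 0 || tau2 <= 0) { warning("MinError: zero class variance"); break }
    w0 <- 1 / sigma2 - 1 / tau2
    w1 <- mu / sigma2 - nu / tau2
    w2 <- mu^2 / sigma2 - nu^2 / tau2 + log10((sigma2 * q^2) / (tau2 * pp^2))
    sqterm <- w1^2 - w0 * w2
    if (sqterm < 0) { warning("MinError did not converge"); break }
    prev <- t
    temp <- (w1 + sqrt(sqterm)) / w0
    if (!is.finite(temp)) break
    t <- as.integer(floor(temp))
    if (t < 0L) t <- 0L
    if (t > 255L) t <- 255L
  }
  as.integer(t)
}

# Tsai: moment-preserving thresholding.
th_moments <- function(h) {
  p <- h / sum(h)
  m1 <- sum(lvls * p); m2 <- sum(lvls^2 * p); m3 <- sum(lvls^3 * p)
  cd <- m2 - m1^2
  if (abs(cd) < 1e-12) return(th_mean(h))
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (-m3 + m2 * m1) / cd
  disc <- c1^2 - 4 * c0
  if (disc < 0) return(th_mean(h))
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  if (abs(z1 - z0) < 1e-12) return(th_mean(h))
  p0 <- (z1 - m1) / (z1 - z0)           # target tail fraction below threshold
  cum <- cumsum(p)
  t <- which(cum > p0)[1L] - 1L
  if (is.na(t)) t <- 255L
  as.integer(t)
}

# Otsu: maximize between-class variance (cumulative-moment form; tie -> lower).
th_otsu <- function(h) {
  tot <- sum(h)
  p <- h / tot
  w0 <- cumsum(p)
  mu <- cumsum(lvls * p)
  mu_t <- mu[256L]
  w1 <- 1 - w0
  num <- (mu_t * w0 - mu)^2
  den <- w0 * w1
  sigma_b <- ifelse(den > 1e-12, num / den, -Inf)
  as.integer(which.max(sigma_b) - 1L)
}

# Doyle: threshold whose foreground fraction is closest to 50%.
th_percentile <- function(h, ptile = 0.5) {
  cum <- cumsum(h / sum(h))
  d <- abs(cum - ptile)
  as.integer(which.min(d) - 1L)
}

# Renyi-entropy maximizer for a given order; order 1 reduces to Kapur.
renyi_t <- function(p, P1, first, last, alpha) {
  best <- first; bestval <- -Inf
  for (t in first:last) {
    w0 <- P1[t + 1L]; w1 <- 1 - w0
    if (w0 < 1e-12 || w1 < 1e-12) next
    if (abs(alpha - 1) < 1e-9) {
      p0 <- p[1:(t + 1L)]; p0 <- p0[p0 > 0]
      hb <- -sum((p0 / w0) * log(p0 / w0))
      p1v <- if (t < 255L) p[(t + 2L):256L] else numeric(0); p1v <- p1v[p1v > 0]
      hw <- if (length(p1v)) -sum((p1v / w1) * log(p1v / w1)) else 0
      v <- hb + hw
    } else {
      s0 <- sum((p[1:(t + 1L)] / w0)^alpha)
      s1 <- if (t < 255L) sum((p[(t + 2L):256L] / w1)^alpha) else 0
      if (s0 <= 0 || s1 <= 0) next
      v <- log(s0) / (1 - alpha) + log(s1) / (1 - alpha)
    }
    if (v > bestval) { bestval <- v; best <- t }
  }
  best
}

# Sahoo, Wilkins & Yeager: combine Renyi-entropy thresholds of orders
# 1/2, 1 and 2 with closeness-dependent weights.
th_renyientropy <- function(h) {
  p <- h / sum(h)
  P1 <- cumsum(p)
  first <- first_nonzero(h); last <- last_nonzero(h)
  if (first == last) return(as.integer(first))
  ts <- sort(c(renyi_t(p, P1, first, last, 0.5),
               renyi_t(p, P1, first, last, 1.0),
               renyi_t(p, P1, first, last, 2.0)))
  t1 <- ts[1L]; t2 <- ts[2L]; t3 <- ts[3L]
  if (abs(t1 - t2) <= 5) {
    if (abs(t2 - t3) <= 5) { b <- c(1, 2, 1) } else { b <- c(0, 1, 3) }
  } else {
    if (abs(t2 - t3) <= 5) { b <- c(3, 1, 0) } else { b <- c(1, 2, 1) }
  }
  omega <- P1[t3 + 1L] - P1[t1 + 1L]
  opt <- t1 * (P1[t1 + 1L] + 0.25 * omega * b[1]) +
    0.25 * t2 * omega * b[2] +
    t3 * (1 - P1[t3 + 1L] + 0.25 * omega * b[3])
  as.integer(opt)
}

# Shanbhag: fuzzy-membership information measure; minimize |H_back - H_obj|.
th_shanbhag <- function(h) {
  p <- h / sum(h)
  P1 <- cumsum(p)                        # P1[i] = mass at levels 0..i-1
  P2 <- 1 - P1
  first <- first_nonzero(h); last <- last_nonzero(h)
  if (first == last) return(as.integer(first))
  best <- first; bestval <- Inf
  P1x <- c(0, P1)                        # P1x[i+1] = mass up to level i-1
  P2x <- c(P2, 0)                        # P2x[i+1] = mass above level i
  for (t in first:last) {
    w0 <- P1[t + 1L]; w1 <- P2[t + 1L]
    if (w0 < 1e-12 || w1 < 1e-12) next
    term_b <- 0.5 / w0
    ib <- 1:t
    arg_b <- 1 - term_b * P1x[ib + 1L]
    keep <- p[ib + 1L] > 0 & arg_b > 0
    ent_back <- -term_b * sum(p[ib + 1L][keep] * log(arg_b[keep]))
    term_o <- 0.5 / w1
    io <- if (t < 255L) (t + 1L):254L else integer(0)
    ent_obj <- 0
    if (length(io)) {
      arg_o <- 1 - term_o * P2x[io + 2L]
      keep <- p[io + 1L] > 0 & arg_o > 0
      ent_obj <- -term_o * sum(p[io + 1L][keep] * log(arg_o[keep]))
    }
    v <- abs(ent_back - ent_obj)
    if (v < bestval) { bestval <- v; best <- t }
  }
  as.integer(best)
}

# Zack, Rogers & Latt triangle method, platform geometry (flip so the longer
# tail is to the right, maximize distance from the peak-to-tail chord).
th_triangle <- function(h) {
  d <- as.numeric(h)
  mn <- first_nonzero(h); mx2 <- last_nonzero(h)
  if (mn > 0L) mn <- mn - 1L
  if (mx2 < 255L) mx2 <- mx2 + 1L
  peak <- which.max(d) - 1L
  inverted <- FALSE
  if ((peak - mn) < (mx2 - peak)) {      # longer tail on the right: flip it left
    inverted <- TRUE
    d <- rev(d)
    mn_new <- 255L - mx2
    peak <- 255L - peak
    mn <- mn_new
  }
  if (mn == peak) return(as.integer(if (inverted) 255L - mn else mn))
  nx <- d[peak + 1L]
  ny <- mn - peak
  dn <- sqrt(nx^2 + ny^2); nx <- nx / dn; ny <- ny / dn
  dconst <- nx * mn + ny * d[mn + 1L]
  split <- mn; split_dist <- 0
  for (i in (mn + 1L):peak) {
    newd <- nx * i + ny * d[i + 1L] - dconst
    if (newd > split_dist) { split <- i; split_dist <- newd }
  }
  split <- split - 1L
  as.integer(if (inverted) 255L - split else split)
}

# Yen: maximal correlation criterion.
th_yen <- function(h) {
  p <- h / sum(h)
  P1 <- cumsum(p)
  P1sq <- cumsum(p^2)
  tot_sq <- P1sq[256L]
  best <- 0L; bestval <- -Inf
  for (t in 0:255) {
    w0 <- P1[t + 1L]; w1 <- 1 - w0
    s0 <- P1sq[t + 1L]; s1 <- tot_sq - s0
    if (s0 <= 0 || s1 <= 0 || w0 <= 0 || w1 <= 0) next
    v <- -log(s0 * s1) + 2 * log(w0 * w1)
    if (v > bestval) { bestval <- v; best <- t }
  }
  as.integer(best)
}

#' Select a threshold automatically from a histogram
#'
#' Dispatches to one of the 17 algorithms (see \link{autothreshold}). A
#' degenerate histogram with all mass in one bin returns that bin's level
#' with a warning, for every method.
#'
#' @param hist Integer vector of 256 counts (from [histogram256()]).
#' @param method One of [threshold_methods()].
#' @return Integer threshold level in \code{[0, 255]}.
#' @export
auto_threshold <- function(hist, method = "Default") {
  if (length(hist) != 256L || any(hist < 0))
    stop("hist must be 256 non-negative counts")
  if (sum(hist) <= 0) stop("histogram is empty")
  method <- match.arg(method, threshold_methods())
  nz <- which(hist > 0)
  if (length(nz) == 1L) {
    warning("degenerate histogram: all pixels share value ", nz - 1L)
    return(as.integer(nz - 1L))
  }
  fn <- switch(method,
    Default = th_default, Huang = th_huang, Huang2 = th_huang2,
    Intermodes = th_intermodes, IsoData = th_isodata, Li = th_li,
    MaxEntropy = th_maxentropy, Mean = th_mean, MinError = th_minerror,
    Minimum = th_minimum, Moments = th_moments, Otsu = th_otsu,
    Percentile = th_percentile, RenyiEntropy = th_renyientropy,
    Shanbhag = th_shanbhag, Triangle = th_triangle, Yen = th_yen
  )
  t <- fn(as.numeric(hist))
  as.integer(min(255L, max(0L, t)))
}

#' Apply a threshold level to an image
#'
#' @param img Canonical 8-bit single-channel image.
#' @param t Threshold level in \code{[0, 255]}.
#' @param polarity \code{"dark_object"} selects pixels \code{<= t} (stained
#'   objects on a bright brightfield background); \code{"bright_object"}
#'   selects pixels \code{>= t} (fluorescent objects on a dark background).
#' @return Integer 0/1 mask matrix, same shape as \code{img}.
#' @export
apply_threshold <- function(img, t, polarity = c("dark_object", "bright_object")) {
  img <- assert_gray(img)
  polarity <- match.arg(polarity)
  if (t < 0 || t > 255) stop("threshold must lie in [0, 255]")
  m <- if (polarity == "dark_object") img <= t else img >= t
  mode(m) <- "integer"
  m
}

#' Offset a threshold level, clipped to the valid range
#'
#' The manual adjustment available for the signal threshold (nuclei
#' thresholding stays fully automatic).
#'
#' @param t Threshold level in \code{[0, 255]}.
#' @param offset Signed integer adjustment.
#' @return \code{clip(t + offset, 0, 255)} as integer.
#' @export
manual_offset <- function(t, offset) {
  if (t < 0 || t > 255) stop("threshold must lie in [0, 255]")
  as.integer(min(255L, max(0L, t + offset)))
}
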