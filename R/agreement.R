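#' Intraclass correlation, two-way model, absolute agreement
#'
#' ICC from the two-way ANOVA decomposition of an images x raters table
#' (the "random mixed model, absolute agreement" setting of SPSS). With
#' \code{MSR} the row (image) mean square, \code{MSC} the column (rater)
#' mean square and \code{MSE} the residual mean square:
#' single measures \code{ICC(A,1) = (MSR - MSE) /
#' (MSR + (k - 1) MSE + (k / n)(MSC - MSE))}; average measures
#' \code{ICC(A,k) = (MSR - MSE) / (MSR + (MSC - MSE) / n)}.
#'
#' @param table Numeric matrix or data frame, rows = images, columns =
#'   raters; no missing cells.
#' @param type \code{"single"} (default) or \code{"average"} measures.
#' @return The ICC. A table with zero total variance returns 1 by
#'   convention, with a warning.
#' @export
icc_absolute_agreement <- function(table, type = c("single", "average")) {
  type <- match.arg(type)
  m <- as.matrix(table)
  if (anyNA(m)) stop("rater table must have no missing cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 images and 2 raters")
  grand <- mean(m)
  if (all(abs(m - grand) < 1e-12)) {
    warning("zero total variance: ICC set to 1 by convention")
    return(1)
  }
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sst <- sum((m - grand)^2)
  mse <- (sst - k * sum((row_m - grand)^2) - n * sum((col_m - grand)^2)) /
    ((n - 1) * (k - 1))
  if (type == "single")
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  else
    (msr - mse) / (msr + (msc - mse) / n)
}

#' Pairwise agreement statistics between two score vectors
#'
#' Mean difference (\code{x - y}), its sample SD, the 95% confidence
#' interval of the mean difference (t-based), and the Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return List with \code{mean_diff}, \code{sd_diff}, \code{ci95}
#'   (length-2 vector) and \code{pearson_r} (\code{NA} if either input has
#'   zero variance).
#' @export
pair_stats <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired scores")
  d <- x - y
  md <- mean(d)
  sdd <- stats::sd(d)
  half <- stats::qt(0.975, n - 1) * sdd / sqrt(n)
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  list(mean_diff = md, sd_diff = sdd, ci95 = c(md - half, md + half),
       pearson_r = r)
}

#' Verbal reliability label for an ICC
#'
#' Above 0.9 is excellent reliability, above 0.75 (up to 0.9) good, and
#' anything at or below 0.75 falls short of good.
#'
#' @param icc ICC value.
#' @return \code{"excellent"}, \code{"good"} or \code{"below_good"}.
#' @export
reliability_label <- function(icc) {
  if (icc > 1 + 1e-9) stop("ICC cannot exceed 1")
  if (icc > 0.9) "excellent" else if (icc > 0.75) "good" else "below_good"
}

#' Calibrate the coverage threshold against rater consensus
#'
#' Re-analyzes every field at each candidate coverage threshold, compares
#' the program's percent-positive values with the human consensus via the
#' two-way absolute-agreement ICC, and selects the threshold with maximal
#' ICC (ties resolved toward the lower threshold). This is the sweep that
#' fixed the method's default of 0.80.
#'
#' @param fields List of per-field input lists; each element holds the
#'   [analyze_field()] image arguments for one field (e.g.
#'   \code{list(image = rgb)} or \code{list(nuclei = n8, signal = s8)}).
#' @param consensus Numeric vector of consensus percent-positive scores,
#'   one per field (typically the unweighted mean over included raters).
#' @param thresholds Candidate coverage thresholds to sweep.
#' @param config Base [quant_config()]; its \code{coverage_threshold} is
#'   replaced by each candidate in turn.
#' @return Object of class \code{nq_calibration}: data frame \code{curve}
#'   with columns \code{threshold}, \code{icc}; \code{best_threshold};
#'   \code{best_icc}; and the per-threshold program scores in
#'   \code{scores}.
#' @export
calibrate_coverage_threshold <- function(fields, consensus,
                                         thresholds = seq(0.1, 1, by = 0.1),
                                         config = quant_config()) {
  if (length(fields) < 2L) stop("calibration needs at least 2 fields")
  if (length(consensus) != length(fields))
    stop("consensus must align with fields")
  if (!length(thresholds)) stop("empty threshold sweep")
  scores <- matrix(NA_real_, length(fields), length(thresholds))
  for (ti in seq_along(thresholds)) {
    cfg <- config
    cfg$coverage_threshold <- thresholds[ti]
    for (fi in seq_along(fields)) {
      ans <- tryCatch(
        do.call(analyze_field, c(fields[[fi]], list(config = cfg))),
        error = function(e) stop("calibration error on field ", fi, ": ",
                                 conditionMessage(e), call. = FALSE))
      scores[fi, ti] <- ans$result$pct_positive
    }
  }
  iccs <- vapply(seq_along(thresholds), function(ti)
    icc_absolute_agreement(cbind(program = scores[, ti],
                                 consensus = consensus)), numeric(1))
  best <- which.max(iccs)                 # which.max takes the first maximum
  structure(list(
    curve = data.frame(threshold = thresholds, icc = iccs),
    best_threshold = thresholds[best],
    best_icc = iccs[best],
    scores = scores,
    consensus = consensus
  ), class = "nq_calibration")
}

#' @export
print.nq_calibration <- function(x, ...) {
  cat("Coverage-threshold calibration\n")
  print(x$curve, row.names = FALSE)
  cat(sprintf("best threshold: %.2f (ICC = %.4f, %s reliability)\n",
              x$best_threshold, x$best_icc,
              sub("_", "-", reliability_label(x$best_icc))))
  invisible(x)
}

#' @export
plot.nq_calibration <- function(x, ...) {
  graphics::plot(x$curve$threshold, x$curve$icc, type = "b", pch = 19,
                 xlab = "coverage threshold", ylab = "ICC vs consensus", ...)
  graphics::abline(v = x$best_threshold, lty = 2)
  invisible(x)
}

#' Read a rater score table from CSV
#'
#' Rows are images, columns are raters; a header row names the raters and
#' an optional first column of non-numeric values names the images.
#'
#' @param path CSV path.
#' @return Numeric matrix with image rownames and rater colnames.
#' @export
read_rater_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) && !is.numeric(df[[1L]])) {
    rn <- df[[1L]]; df <- df[, -1L, drop = FALSE]; rownames(df) <- rn
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("rater table must be numeric")
  if (any(m < 0 | m > 100, na.rm = TRUE))
    stop("rater scores must lie in [0, 100]")
  m
}
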