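#' Batch-process a directory of fields
#'
#' Processes every field in \code{input_dir} with one configuration and
#' collects the results. In \code{h_dab} mode every TIFF/PNG is one field;
#' in the two-image modes files pair by the filename convention
#' \code{<stem>_nuclei.<ext>} / \code{<stem>_signal.<ext>}. Fields are
#' processed independently in sorted filename order: one failing field is
#' recorded in the manifest and does not abort the batch.
#'
#' @param input_dir Directory of input images.
#' @param config A [quant_config()] object.
#' @param output_dir Where to write \code{fields.csv} (one row per field),
#'   \code{nuclei.csv} (one row per nucleus) and, when \code{overlays} is
#'   TRUE, one overlay PNG per field. \code{NULL} writes nothing.
#' @param overlays Write classification overlay PNGs.
#' @return Object of class \code{nq_batch}: \code{manifest} data frame
#'   (field, status, message plus the field summary columns) and
#'   \code{fields}, the per-field \code{nq_field} objects (NULL where
#'   failed).
#' @export
run_batch <- function(input_dir, config = quant_config(), output_dir = NULL,
                      overlays = FALSE) {
  files <- sort(list.files(input_dir, pattern = "\\.(tif|tiff|png)$",
                           ignore.case = TRUE))
  if (!length(files)) stop("empty batch: no TIFF/PNG images in ", input_dir)
  two_image <- config$mode != "h_dab"
  entries <- list()
  if (two_image) {
    stems <- unique(sub("_(nuclei|signal)\\.[^.]+$", "", files))
    for (s in sort(stems)) {
      nf <- files[grepl(paste0("^", s, "_nuclei\\."), files)]
      sf <- files[grepl(paste0("^", s, "_signal\\."), files)]
      if (length(nf) == 1L && length(sf) == 1L) {
        entries[[s]] <- list(nuclei = file.path(input_dir, nf),
                             signal = file.path(input_dir, sf))
      } else {
        entries[[s]] <- list(error = paste0(
          "unpairable field '", s, "': expected one *_nuclei and one *_signal image"))
      }
    }
  } else {
    for (f in files)
      entries[[sub("\\.[^.]+$", "", f)]] <- list(image = file.path(input_dir, f))
  }
  ids <- names(entries)
  fields <- vector("list", length(ids)); names(fields) <- ids
  rows <- vector("list", length(ids))
  nuc_tabs <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]; e <- entries[[id]]
    ans <- tryCatch({
      if (!is.null(e$error)) stop(e$error)
      args <- lapply(e, read_image)
      do.call(analyze_field, c(args, list(config = config)))
    }, error = function(err) err)
    if (inherits(ans, "error")) {
      rows[[i]] <- data.frame(field = id, status = "failed",
                              message = conditionMessage(ans),
                              n_nuclei = NA_integer_, n_positive = NA_integer_,
                              pct_positive = NA_real_, histoscore = NA_real_,
                              overall_score = NA_real_,
                              overall_category = NA_character_,
                              stringsAsFactors = FALSE)
    } else {
      fields[[id]] <- ans
      r <- ans$result
      rows[[i]] <- data.frame(field = id, status = "ok", message = "",
                              n_nuclei = r$n_nuclei, n_positive = r$n_positive,
                              pct_positive = r$pct_positive,
                              histoscore = r$histoscore,
                              overall_score = r$overall_score,
                              overall_category = r$overall_category,
                              stringsAsFactors = FALSE)
      tab <- regions_table(ans$regions)
      if (nrow(tab)) nuc_tabs[[id]] <- cbind(field = id, tab)
      if (!is.null(output_dir) && overlays) {
        dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
        write_overlay(ans$display, ans$regions,
                      file.path(output_dir, paste0(id, "_overlay.png")))
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(manifest, file.path(output_dir, "fields.csv"),
                     row.names = FALSE)
    nuc <- if (length(nuc_tabs)) do.call(rbind, nuc_tabs) else
      cbind(field = character(0), regions_table(list()))
    utils::write.csv(nuc, file.path(output_dir, "nuclei.csv"),
                     row.names = FALSE)
  }
  structure(list(manifest = manifest, fields = fields, config = config),
            class = "nq_batch")
}

#' @export
print.nq_batch <- function(x, ...) {
  ok <- sum(x$manifest$status == "ok")
  cat(sprintf("Batch: %d field(s), %d ok, %d failed\n",
              nrow(x$manifest), ok, nrow(x$manifest) - ok))
  print(x$manifest[, c("field", "status", "n_nuclei", "pct_positive")],
        row.names = FALSE)
  invisible(x)
}
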