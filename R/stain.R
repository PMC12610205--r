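#' Default H-DAB stain vectors
#'
#' Unit optical-density triplets for haematoxylin, DAB and a residual
#' complement, one stain per row. The defaults are the widely used
#' Ruifrok--Johnston H-DAB basis shipped with ImageJ/Fiji's colour
#' deconvolution: haematoxylin (0.650, 0.704, 0.286) and DAB
#' (0.268, 0.570, 0.776); the residual row is their normalized cross
#' product. Rows are renormalized to unit Euclidean length.
#'
#' @param hema,dab Length-3 numeric OD triplets (R, G, B).
#' @return A 3x3 matrix with rows \code{hema}, \code{dab}, \code{residual}.
#' @export
stain_vectors_hdab <- function(hema = c(0.650, 0.704, 0.286),
                               dab = c(0.268, 0.570, 0.776)) {
  stopifnot(length(hema) == 3L, length(dab) == 3L)
  res <- c(hema[2] * dab[3] - hema[3] * dab[2],
           hema[3] * dab[1] - hema[1] * dab[3],
           hema[1] * dab[2] - hema[2] * dab[1])
  m <- rbind(hema = hema / sqrt(sum(hema^2)),
             dab = dab / sqrt(sum(dab^2)),
             residual = res / sqrt(sum(res^2)))
  colnames(m) <- c("r", "g", "b")
  if (abs(det(m)) < 1e-8) stop("stain matrix is singular")
  m
}

#' RGB image to per-channel optical density
#'
#' Beer--Lambert optical density relative to white:
#' \code{OD = -log10(max(I, 1) / 255)} per channel. Intensity is clamped at 1
#' before the log so a zero pixel maps to the finite maximum
#' \code{log10(255)} rather than infinity.
#'
#' @param img Canonical 8-bit RGB image.
#' @return \code{h x w x 3} numeric array of optical densities.
#' @export
rgb_to_od <- function(img) {
  if (n_channels(img) != 3L) stop("rgb_to_od requires a 3-channel image")
  -log10(pmax(img, 1) / 255)
}

#' Separate an H-DAB image into haematoxylin and DAB channels
#'
#' Colour deconvolution: per pixel the OD vector is expressed in the stain
#' basis, negative concentrations are clipped to zero, and each stain channel
#' is re-exposed as an 8-bit pseudo-transmittance image
#' \code{round(255 * 10^(-c))} in which darker pixels carry more stain. The
#' semiquantitative intensity cut-offs (60/120 mean gray) are defined on this
#' scale.
#'
#' @param img Canonical 8-bit RGB image.
#' @param vectors 3x3 stain matrix from [stain_vectors_hdab()].
#' @return List with integer matrices \code{nuclei} (haematoxylin) and
#'   \code{dab}, plus the raw concentration arrays in \code{concentrations}.
#' @export
separate_h_dab <- function(img, vectors = stain_vectors_hdab()) {
  if (n_channels(img) != 3L) stop("separate_h_dab requires a 3-channel image")
  if (abs(det(vectors)) < 1e-8) stop("stain matrix is singular")
  h <- dim(img)[1]; w <- dim(img)[2]
  od <- rgb_to_od(img)
  odm <- matrix(od, ncol = 3L)            # pixels x channels
  conc <- odm %*% solve(vectors)          # pixels x stains
  conc[conc < 0] <- 0
  chan <- function(k) {
    m <- matrix(as.integer(pmin(255, pmax(0, round(255 * 10^(-conc[, k]))))), h, w)
    m
  }
  list(nuclei = chan(1L), dab = chan(2L),
       concentrations = array(conc, dim = c(h, w, 3L)))
}

#' Render an RGB image from stain concentration maps
#'
#' Forward Beer--Lambert model, the inverse of [separate_h_dab()]: per pixel
#' \code{OD = c_hema * v_hema + c_dab * v_dab} and
#' \code{RGB = round(255 * 10^(-OD))}. Used by the synthetic-field generator.
#'
#' @param c_hema,c_dab Numeric matrices of non-negative concentrations (OD
#'   units), same shape.
#' @param vectors 3x3 stain matrix.
#' @return Canonical 8-bit RGB array.
#' @export
render_from_concentrations <- function(c_hema, c_dab,
                                       vectors = stain_vectors_hdab()) {
  if (!identical(dim(c_hema), dim(c_dab)))
    stop("concentration maps must have the same shape")
  if (any(c_hema < 0) || any(c_dab < 0))
    stop("concentrations must be non-negative")
  h <- dim(c_hema)[1]; w <- dim(c_hema)[2]
  conc <- cbind(as.vector(c_hema), as.vector(c_dab), 0)
  od <- conc %*% vectors[1:3, , drop = FALSE]
  rgb <- 255 * 10^(-od)
  canonical8(array(rgb, dim = c(h, w, 3L)))
}
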