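#' Brain mask with a fixed pixel ordering
#'
#' Wraps a binary image into a mask object carrying the canonical pixel
#' ordering used by every pixel-by-time matrix in the package: masked pixels
#' are enumerated row-major over the grid (row 1 left to right, then row 2,
#' ...), and row `i` of any series matrix always refers to `pixel_index[i, ]`.
#'
#' @param image Logical or 0/1 numeric matrix; `TRUE`/1 marks analyzed pixels.
#' @return An object of class `"brain_mask"` with elements `image` (logical
#'   matrix), `pixel_index` (n x 2 integer matrix of (row, col) grid
#'   coordinates) and `n_pixels`.
#' @examples
#' m <- brain_mask(matrix(c(0, 1, 1, 0), 2, 2))
#' m$n_pixels
#' @export
brain_mask <- function(image) {
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  img <- matrix(as.logical(image), nrow(image), ncol(image))
  if (anyNA(img)) stop("mask image contains NA", call. = FALSE)
  if (sum(img) < 2L) stop("mask must contain at least 2 pixels", call. = FALSE)
  idx <- which(img, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]  # row-major order
  dimnames(idx) <- list(NULL, c("row", "col"))
  structure(
    list(image = img, pixel_index = idx, n_pixels = nrow(idx),
         shape = dim(img)),
    class = "brain_mask"
  )
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %d x %d grid, %d masked pixels (%.1f%%)\n",
              x$shape[1], x$shape[2], x$n_pixels,
              100 * x$n_pixels / prod(x$shape)))
  invisible(x)
}

#' Centered elliptical mask
#'
#' Default field-of-view emulating the dorsal-brain mask of widefield mouse
#' imaging: an ellipse centered on the grid whose area is close to
#' `fraction` of the grid.
#'
#' @param shape Integer vector `c(rows, cols)`.
#' @param fraction Target in-mask fraction of the grid, in (0, 1].
#' @return A [brain_mask()].
#' @export
ellipse_mask <- function(shape, fraction = 0.6) {
  if (length(shape) != 2L || any(shape < 2L))
    stop("`shape` must be two integers >= 2", call. = FALSE)
  if (fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  nr <- shape[1]; nc <- shape[2]
  # semi-axes proportional to the grid, scaled so pi*a*b = fraction*nr*nc
  s <- sqrt(fraction * nr * nc / (pi * (nr / 2) * (nc / 2)))
  a <- s * nr / 2; b <- s * nc / 2
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  rr <- matrix(seq_len(nr), nr, nc)
  ccm <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  img <- ((rr - cr) / a)^2 + ((ccm - cc) / b)^2 <= 1
  if (sum(img) < 2L) img[cbind(c(cr, cr), c(floor(cc), ceiling(cc)))] <- TRUE
  brain_mask(img)
}

# Paint a per-masked-pixel vector back onto the grid (NA off-mask).
mask_to_image <- function(mask, values) {
  stopifnot(inherits(mask, "brain_mask"), length(values) == mask$n_pixels)
  img <- matrix(NA_real_, mask$shape[1], mask$shape[2])
  img[mask$pixel_index] <- values
  img
}

same_mask <- function(a, b) {
  identical(a$shape, b$shape) && identical(a$pixel_index, b$pixel_index)
}
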