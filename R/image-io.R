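#' Read an image as a grayscale matrix
#'
#' Reads a PNG and returns a numeric matrix in `[0, 255]`. RGB(A) images are
#' converted to luminance (Rec. 601 weights) first; an alpha channel is
#' ignored.
#'
#' @param path PNG file path.
#' @return Numeric matrix (rows x cols) in `[0, 255]`.
#' @export
read_gray <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) {
    if (dim(px)[3] >= 3) {
      px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    } else {
      px <- px[, , 1]
    }
  }
  px * 255
}

#' Write a grayscale matrix as an 8-bit PNG
#'
#' @param img Numeric matrix in `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path) {
  png::writePNG(clamp255(img) / 255, path)
  invisible(path)
}

#' Bilinear resize of a grayscale matrix
#'
#' @param img Numeric matrix.
#' @param height,width Target size in pixels.
#' @return Resized matrix.
#' @export
resize_gray <- function(img, height, width = height) {
  if (nrow(img) == height && ncol(img) == width) return(img)
  out <- EBImage::resize(img, w = height, h = width)
  matrix(out, height, width)
}

#' Load a batch of images as a standardized tensor
#'
#' Reads each record's image, converts to grayscale, bilinearly resizes to
#' `size x size`, scales to `[0, 1]` and standardizes by `(x - mean) / sd`.
#' Unreadable files are skipped with a warning (never silently dropped from
#' the reported counts).
#'
#' @param records A manifest tibble (columns `path`, `label`) or a character
#'   vector of paths.
#' @param size Target side length in pixels (default 224).
#' @param mean,sd Standardization constants on the `[0, 1]` scale
#'   (defaults 0.5 / 0.5).
#' @param class_levels Label factor levels defining the class indices;
#'   defaults to the four tumor classes.
#' @return A list with `x` (array `n x size x size`), `y` (integer class
#'   indices, 1-based, or `NULL` when `records` has no labels), `paths`, and
#'   `n_skipped`.
#' @export
load_batch <- function(records, size = 224L, mean = 0.5, sd = 0.5,
                       class_levels = tumor_classes()) {
  if (is.character(records)) {
    records <- tibble::tibble(path = records, label = NA_character_)
  }
  n <- nrow(records)
  imgs <- vector("list", n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    img <- tryCatch(read_gray(records$path[i]), error = function(e) NULL)
    if (is.null(img)) next
    imgs[[i]] <- (resize_gray(img, size) / 255 - mean) / sd
    ok[i] <- TRUE
  }
  if (any(!ok)) {
    warning(sum(!ok), " unreadable image(s) skipped", call. = FALSE)
  }
  x <- array(0, dim = c(sum(ok), size, size))
  for (i in seq_along(which(ok))) x[i, , ] <- imgs[[which(ok)[i]]]
  y <- NULL
  if (!all(is.na(records$label))) {
    y <- as.integer(factor(records$label[ok], levels = class_levels))
  }
  list(x = x, y = y, paths = records$path[ok], n_skipped = sum(!ok))
}
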