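#' The four tumor classes
#'
#' Directory / label names, in the fixed order that defines class indices:
#' glioma, meningioma, pituitary, no_tumor.
#'
#' @return Character vector of length 4.
#' @export
tumor_classes <- function() c("glioma", "meningioma", "pituitary", "no_tumor")

#' Specification of a synthetic head phantom
#'
#' Describes one MRI-like phantom slice: an elliptical "head" on a dark
#' background carrying smooth low-contrast tissue texture, a class-dependent
#' lesion, a smooth multiplicative illumination gradient and additive noise.
#' The defaults emulate the troublesome properties of clinical slices (poor
#' contrast, brightness variation, noise) without any claim of radiological
#' realism: lesion geometry per class is invented purely to make the classes
#' separable.
#'
#' Class geometry: `glioma` (0) an irregular mid-size bright blob off-center;
#' `meningioma` (1) a rim-bright disc near the cortex; `pituitary` (2) a
#' small bright midline disc low in the head; `no_tumor` (3) no lesion.
#'
#' @param image_size Side length in pixels (default 64).
#' @param class_id Integer 0-3, indexing [tumor_classes()].
#' @param lesion_radius Lesion radius in pixels; `NULL` picks a class default.
#' @param lesion_delta Lesion intensity increment over tissue (default 80).
#' @param illumination Amplitude of the multiplicative illumination gradient
#'   (0 disables; default 0.3, i.e. +-30% across the image).
#' @param noise_sigma Additive Gaussian noise scale in gray levels
#'   (default 6).
#' @param contrast_window Intensity bounds of the tissue texture
#'   (default `c(90, 150)`, deliberately low-contrast).
#' @param seed Integer seed; the phantom is a deterministic function of the
#'   full spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 64L, class_id = 0L, lesion_radius = NULL,
                         lesion_delta = 80, illumination = 0.3, noise_sigma = 6,
                         contrast_window = c(90, 150), seed = 1L) {
  if (!class_id %in% 0:3) stop("class_id must be in 0..3", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (contrast_window[1] < 0 || contrast_window[2] > 255 ||
      contrast_window[1] >= contrast_window[2]) {
    stop("contrast_window must be an increasing pair within [0, 255]", call. = FALSE)
  }
  if (is.null(lesion_radius)) {
    lesion_radius <- c(image_size / 8, image_size / 7, image_size / 11, 0)[class_id + 1]
  }
  if (lesion_radius >= image_size / 2) {
    stop("lesion_radius must be below image_size / 2", call. = FALSE)
  }
  structure(list(image_size = as.integer(image_size), class_id = as.integer(class_id),
                 lesion_radius = lesion_radius, lesion_delta = lesion_delta,
                 illumination = illumination, noise_sigma = noise_sigma,
                 contrast_window = contrast_window, seed = as.integer(seed)),
            class = "phantom_spec")
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# smooth unit-scale random field via Gaussian-blurred white noise
smooth_field <- function(n, sigma) {
  z <- EBImage::gblur(matrix(stats::rnorm(n * n), n, n), sigma = sigma)
  rng <- range(z)
  if (diff(rng) < 1e-12) return(matrix(0.5, n, n))
  (z - rng[1]) / diff(rng)
}

#' Generate one synthetic head phantom
#'
#' Deterministically renders the phantom described by a [phantom_spec()]:
#' elliptical head mask, tissue texture confined to the contrast window,
#' class-dependent lesion, multiplicative illumination gradient, additive
#' noise, clamp to `[0, 255]`.
#'
#' @param spec A [phantom_spec()].
#' @return Numeric matrix `image_size x image_size` in `[0, 255]`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$image_size
  with_seed(spec$seed + 7919L * spec$class_id, {
    cx <- n / 2 + stats::runif(1, -1, 1)
    cy <- n / 2 + stats::runif(1, -1, 1)
    rx <- n * stats::runif(1, 0.40, 0.44)
    ry <- n * stats::runif(1, 0.33, 0.37)
    xs <- matrix(seq_len(n), n, n)          # row coordinate
    ys <- matrix(seq_len(n), n, n, byrow = TRUE)
    head <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1

    w <- spec$contrast_window
    tissue <- w[1] + (w[2] - w[1]) * smooth_field(n, sigma = n / 16)

    img <- matrix(8, n, n)                  # dark background
    img[head] <- tissue[head]

    r <- spec$lesion_radius
    delta <- spec$lesion_delta
    if (spec$class_id == 0L) {
      # glioma: irregular bright blob in the superior half
      lx <- cx - stats::runif(1, 0.08, 0.20) * n
      ly <- cy + stats::runif(1, -0.12, 0.12) * n
      ang <- atan2(ys - ly, xs - lx)
      wobble <- 1 + 0.35 * sin(3 * ang + stats::runif(1, 0, 2 * pi)) +
        0.2 * sin(5 * ang + stats::runif(1, 0, 2 * pi))
      les <- sqrt((xs - lx)^2 + (ys - ly)^2) <= r * wobble
      img[les & head] <- img[les & head] + delta
    } else if (spec$class_id == 1L) {
      # meningioma: bright rim with a dark core, abutting the cortex
      th <- stats::runif(1, 0, 2 * pi)
      lx <- cx + 0.50 * rx * cos(th)
      ly <- cy + 0.50 * ry * sin(th)
      d <- sqrt((xs - lx)^2 + (ys - ly)^2)
      rim <- d <= r & d >= 0.55 * r
      core <- d < 0.55 * r
      img[rim & head] <- img[rim & head] + 1.1 * delta
      img[core & head] <- img[core & head] - 0.5 * delta
    } else if (spec$class_id == 2L) {
      # pituitary: compact bright midline disc, low in the head
      lx <- cx + 0.45 * rx + stats::runif(1, -1, 1)
      ly <- cy + stats::runif(1, -0.03, 0.03) * n
      les <- sqrt((xs - lx)^2 + (ys - ly)^2) <= r
      img[les & head] <- img[les & head] + 1.3 * delta
    }

    if (spec$illumination > 0) {
      th <- stats::runif(1, 0, 2 * pi)
      ramp <- (cos(th) * (xs - n / 2) + sin(th) * (ys - n / 2)) / n  # [-0.5, 0.5]
      img <- img * (1 + spec$illumination * 2 * ramp)
    }
    if (spec$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(n * n, sd = spec$noise_sigma), n, n)
    }
    matrix(clamp255(img), n, n)
  })
}

#' Write a synthetic phantom dataset in class-folder layout
#'
#' Generates `n_per_class` phantoms for each of the four classes and writes
#' them as 8-bit grayscale PNGs under `root_dir/<class>/`, the layout
#' [build_manifest()] expects. Image sizes cycle through `sizes` so that
#' downstream resizing is exercised.
#'
#' @param n_per_class Images per class (>= 2).
#' @param root_dir Output directory; must be empty or absent unless
#'   `force = TRUE`.
#' @param seed Integer seed controlling every phantom.
#' @param sizes Integer vector of side lengths cycled across images.
#' @param ... Further arguments passed to [phantom_spec()] (e.g.
#'   `noise_sigma`, `illumination`).
#' @return `root_dir`, invisibly.
#' @export
generate_dataset <- function(n_per_class, root_dir, seed = 1L,
                             sizes = c(56L, 64L, 72L, 80L), force = FALSE, ...) {
  if (n_per_class < 2) stop("n_per_class must be >= 2", call. = FALSE)
  if (dir.exists(root_dir) && length(list.files(root_dir)) > 0 && !force) {
    stop("refusing to write into non-empty directory ", root_dir,
         " (use force = TRUE)", call. = FALSE)
  }
  classes <- tumor_classes()
  for (ci in seq_along(classes)) {
    dir.create(file.path(root_dir, classes[ci]), recursive = TRUE,
               showWarnings = FALSE)
    for (i in seq_len(n_per_class)) {
      sz <- sizes[(i - 1L) %% length(sizes) + 1L]
      sub_seed <- as.integer((as.numeric(seed) * 100003 + i) %% 2147483629)
      spec <- phantom_spec(image_size = sz, class_id = ci - 1L,
                           seed = sub_seed, ...)
      img <- generate_phantom(spec)
      write_gray(img, file.path(root_dir, classes[ci],
                                sprintf("%s_%04d.png", classes[ci], i)))
    }
  }
  invisible(root_dir)
}
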