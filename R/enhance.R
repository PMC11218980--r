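#' Parameters of the homomorphic emphasis filter
#'
#' The homomorphic filter models a pixel as the product of a slowly varying
#' illumination field and a reflectance field, takes logarithms to make the
#' product additive, and applies a Gaussian high-emphasis transfer function in
#' the frequency domain:
#' \deqn{H(u,v) = (\gamma_H - \gamma_L)\,\{1 - \exp[-c\,D^2(u,v)/D_0^2]\} + \gamma_L}
#' so that slow illumination (low frequencies) is attenuated towards
#' `gamma_low` while detail (high frequencies) is amplified towards
#' `gamma_high`.
#'
#' @param gamma_high High-frequency gain (dimensionless), must exceed
#'   `gamma_low`. Default 1.5.
#' @param gamma_low Low-frequency gain (dimensionless), must be positive.
#'   Default 0.5.
#' @param c Sharpness constant of the Gaussian transition. Default 1.
#' @param d0 Cutoff frequency, in centered frequency-plane index units.
#'   Default 40.
#' @return An object of class `hf_params`.
#' @export
#' @examples
#' p <- hf_params()
#' homomorphic_gain(0, p)   # gamma_low
#' homomorphic_gain(40, p)  # 0.5 + (1 - exp(-1))
hf_params <- function(gamma_high = 1.5, gamma_low = 0.5, c = 1, d0 = 40) {
  if (!is.numeric(gamma_high) || !is.numeric(gamma_low) ||
      gamma_low <= 0 || gamma_high <= gamma_low) {
    stop("invalid homomorphic filter gains: need gamma_high > gamma_low > 0",
         call. = FALSE)
  }
  if (c <= 0) stop("invalid homomorphic filter params: c must be > 0", call. = FALSE)
  if (d0 <= 0) stop("invalid homomorphic filter params: d0 must be > 0", call. = FALSE)
  structure(list(gamma_high = gamma_high, gamma_low = gamma_low, c = c, d0 = d0),
            class = "hf_params")
}

#' Homomorphic transfer function
#'
#' Evaluates the high-emphasis gain at frequency-plane distance `d` from the
#' spectrum center. Strictly increasing in `d`, bounded in
#' `[gamma_low, gamma_high)`.
#'
#' @param d Non-negative distance(s) from the centered spectrum origin;
#'   vectorized.
#' @param params An [hf_params()] object.
#' @return Gain value(s), same shape as `d`.
#' @export
homomorphic_gain <- function(d, params = hf_params()) {
  stopifnot(inherits(params, "hf_params"))
  if (any(d < 0)) stop("frequency distance d must be >= 0", call. = FALSE)
  with(params, (gamma_high - gamma_low) * (1 - exp(-c * d^2 / d0^2)) + gamma_low)
}

# validate a grayscale image matrix in [0, 255]
check_gray <- function(img, min_side = 8L) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("image must be a 2-D numeric matrix", call. = FALSE)
  }
  if (nrow(img) < min_side || ncol(img) < min_side) {
    stop("image must be at least ", min_side, "x", min_side, call. = FALSE)
  }
  if (!all(is.finite(img))) stop("image contains non-finite values", call. = FALSE)
  invisible(img)
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

# centered frequency distance grid for an n1 x n2 spectrum (unshifted layout)
freq_dist <- function(n1, n2) {
  d1 <- (0:(n1 - 1)); d1 <- pmin(d1, n1 - d1)
  d2 <- (0:(n2 - 1)); d2 <- pmin(d2, n2 - d2)
  sqrt(outer(d1^2, d2^2, `+`))
}

#' Homomorphic filtering of a grayscale image
#'
#' Takes `log(img + eps)`, applies the [homomorphic_gain()] transfer function
#' to the 2-D Fourier spectrum (distance measured from the centered spectrum
#' origin in index units), inverts the transform, exponentiates, and min-max
#' rescales to `[0, 255]`. The log guard `eps` makes zero-valued background
#' pixels (common in MRI) safe.
#'
#' @param img Numeric matrix in `[0, 255]`.
#' @param params An [hf_params()] object.
#' @param eps Log guard added before the logarithm. Default `1e-3`.
#' @param rescale If `TRUE` (default) rescale the result to `[0, 255]`; if
#'   `FALSE` return the raw exponentiated output (used e.g. to inspect the
#'   frequency response directly).
#' @param clip_quantile Robustness of the rescale: the quantile (per tail)
#'   clipped before the linear stretch to `[0, 255]`. The exponentiation
#'   step produces rare extreme pixels that would otherwise compress the
#'   whole intensity range; 0 gives a plain min-max stretch. Default 0.005.
#' @return Filtered matrix, same shape as `img`.
#' @export
homomorphic_filter <- function(img, params = hf_params(), eps = 1e-3,
                               rescale = TRUE, clip_quantile = 0.005) {
  check_gray(img)
  logi <- log(img + eps)
  spec <- stats::fft(logi)
  gain <- homomorphic_gain(freq_dist(nrow(img), ncol(img)), params)
  filt <- Re(stats::fft(spec * gain, inverse = TRUE)) / length(img)
  out <- exp(filt)
  if (!rescale) return(out)
  lims <- stats::quantile(out, c(clip_quantile, 1 - clip_quantile),
                          names = FALSE)
  if (diff(lims) < 1e-12) {
    # flat image: nothing to redistribute, return the clamped level
    return(matrix(clamp255(out[1]), nrow(img), ncol(img)))
  }
  matrix(clamp255((out - lims[1]) / diff(lims) * 255), nrow(img), ncol(img))
}

#' CLAHE parameters
#'
#' @param tile_rows,tile_cols Tile grid (default 8 x 8).
#' @param clip_factor Clip limit as a multiple of the mean bin height
#'   (`clip_limit = clip_factor * tile_pixels / n_bins`). Must be >= 1.
#'   Default 2.
#' @param n_bins Histogram bins (default 256).
#' @param redistribution_tol Absolute pixel-count tolerance at which the
#'   iterative clip-redistribute cycle stops. Default 0.5.
#' @return An object of class `clahe_params`.
#' @export
clahe_params <- function(tile_rows = 8L, tile_cols = 8L, clip_factor = 2,
                         n_bins = 256L, redistribution_tol = 0.5) {
  if (tile_rows < 1 || tile_cols < 1) stop("tile grid must be >= 1x1", call. = FALSE)
  if (clip_factor < 1) stop("clip_factor must be >= 1", call. = FALSE)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  if (redistribution_tol <= 0) stop("redistribution_tol must be > 0", call. = FALSE)
  structure(list(tile_rows = as.integer(tile_rows), tile_cols = as.integer(tile_cols),
                 clip_factor = clip_factor, n_bins = as.integer(n_bins),
                 redistribution_tol = redistribution_tol),
            class = "clahe_params")
}

#' Clip a histogram and redistribute the excess
#'
#' Bins above `clip_limit` are truncated and the removed mass is spread
#' uniformly over all bins; since the uniform share can push bins back over
#' the limit, the cycle repeats until the remaining excess falls below `tol`.
#' The total count is conserved exactly.
#'
#' @param hist Non-negative per-bin counts.
#' @param clip_limit Maximum bin height (count), > 0.
#' @param tol Stop when the clipped excess per cycle drops below this count.
#' @param max_iter Safety cap on cycles.
#' @return Redistributed counts, same length; no bin exceeds
#'   `clip_limit + tol`.
#' @export
#' @examples
#' clip_and_redistribute(c(8, 0, 0, 0), 2)  # converges to c(2, 2, 2, 2)
clip_and_redistribute <- function(hist, clip_limit, tol = 0.5, max_iter = 200L) {
  if (any(hist < 0)) stop("histogram counts must be >= 0", call. = FALSE)
  if (clip_limit <= 0) stop("clip_limit must be > 0", call. = FALSE)
  total <- sum(hist)
  n <- length(hist)
  if (clip_limit * n < total) {
    stop("clip_limit * n_bins (", clip_limit * n,
         ") is below the total count (", total,
         "): the histogram cannot fit under the limit", call. = FALSE)
  }
  h <- as.numeric(hist)
  for (i in seq_len(max_iter)) {
    excess <- sum(pmax(h - clip_limit, 0))
    if (excess < tol) break
    h <- pmin(h, clip_limit) + excess / n
  }
  h
}

# split 1..n into k contiguous tile index ranges of near-equal size
tile_breaks <- function(n, k) {
  edges <- floor(seq(0, n, length.out = k + 1))
  lapply(seq_len(k), function(i) (edges[i] + 1):edges[i + 1])
}

#' Contrast-limited adaptive histogram equalization
#'
#' Divides the image into `tile_rows x tile_cols` sub-blocks, computes each
#' block's gray-level histogram, limits it with [clip_and_redistribute()]
#' (clip limit `clip_factor * tile_pixels / n_bins`), equalizes through the
#' clipped histogram's cumulative mapping, and blends the per-tile mappings
#' bilinearly at every pixel.
#'
#' @param img Numeric matrix in `[0, 255]`.
#' @param params A [clahe_params()] object.
#' @return Equalized matrix in `[0, 255]`, same shape.
#' @export
clahe <- function(img, params = clahe_params()) {
  check_gray(img)
  nr <- nrow(img); nc <- ncol(img)
  tr <- params$tile_rows; tc <- params$tile_cols
  if (tr > nr || tc > nc) {
    stop("tile grid (", tr, "x", tc, ") larger than image (", nr, "x", nc, ")",
         call. = FALSE)
  }
  nb <- params$n_bins
  bin <- matrix(pmin(floor(clamp255(img) / 256 * nb), nb - 1L), nr, nc)  # 0-based

  rows <- tile_breaks(nr, tr)
  cols <- tile_breaks(nc, tc)
  # per-tile equalization mapping: bin -> output level in [0, 255]
  maps <- array(0, dim = c(tr, tc, nb))
  centers_r <- vapply(rows, function(ix) mean(range(ix)), numeric(1))
  centers_c <- vapply(cols, function(ix) mean(range(ix)), numeric(1))
  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      b <- bin[rows[[i]], cols[[j]]]
      s <- length(b)
      h <- tabulate(as.vector(b) + 1L, nbins = nb)
      cl <- params$clip_factor * s / nb
      h <- clip_and_redistribute(h, cl, params$redistribution_tol)
      maps[i, j, ] <- 255 * cumsum(h) / s
    }
  }

  # bilinear blend of the four surrounding tile mappings, clamped at borders
  interp_axis <- function(coord, centers, k) {
    lo <- findInterval(coord, centers)
    lo <- pmin(pmax(lo, 1L), max(k - 1L, 1L))
    hi <- pmin(lo + 1L, k)
    span <- centers[hi] - centers[lo]
    w_hi <- ifelse(span > 0, (coord - centers[lo]) / span, 0)
    w_hi <- pmin(pmax(w_hi, 0), 1)
    list(lo = lo, hi = hi, w_hi = w_hi)
  }
  ax_r <- interp_axis(seq_len(nr), centers_r, tr)
  ax_c <- interp_axis(seq_len(nc), centers_c, tc)

  ridx <- rep(seq_len(nr), times = nc)
  cidx <- rep(seq_len(nc), each = nr)
  bvec <- as.vector(bin) + 1L
  gather <- function(ti, tj) maps[cbind(ti[ridx], tj[cidx], bvec)]
  wr <- ax_r$w_hi[ridx]; wc <- ax_c$w_hi[cidx]
  out <- (1 - wr) * (1 - wc) * gather(ax_r$lo, ax_c$lo) +
         (1 - wr) * wc       * gather(ax_r$lo, ax_c$hi) +
         wr       * (1 - wc) * gather(ax_r$hi, ax_c$lo) +
         wr       * wc       * gather(ax_r$hi, ax_c$hi)
  matrix(clamp255(out), nr, nc)
}

#' Unsharp-masking parameters
#'
#' @param blur_sigma Standard deviation (pixels) of the Gaussian low-pass.
#'   Default 1.
#' @param amount Amplification of the high-frequency residual. Default 1.
#' @return An object of class `unsharp_params`.
#' @export
unsharp_params <- function(blur_sigma = 1, amount = 1) {
  if (blur_sigma <= 0) stop("blur_sigma must be > 0", call. = FALSE)
  if (amount < 0) stop("amount must be >= 0", call. = FALSE)
  structure(list(blur_sigma = blur_sigma, amount = amount), class = "unsharp_params")
}

#' Unsharp masking
#'
#' Sharpens by adding back an amplified high-frequency residual:
#' `clamp(img + amount * (img - gaussian_blur(img, blur_sigma)))`.
#'
#' @param img Numeric matrix in `[0, 255]`.
#' @param params An [unsharp_params()] object.
#' @return Sharpened matrix in `[0, 255]`, same shape.
#' @export
unsharp_mask <- function(img, params = unsharp_params()) {
  check_gray(img)
  if (params$amount == 0) return(img)
  low <- EBImage::gblur(img, sigma = params$blur_sigma)
  matrix(clamp255(img + params$amount * (img - low)), nrow(img), ncol(img))
}

#' Combined three-operator enhancement
#'
#' The augmentation operator used to double the dataset: homomorphic
#' filtering, then CLAHE, then unsharp masking.
#'
#' @param img Numeric matrix in `[0, 255]`.
#' @param hf,cl,um Parameter objects for the three stages.
#' @return Enhanced matrix in `[0, 255]`, same shape.
#' @export
combined_enhance <- function(img, hf = hf_params(), cl = clahe_params(),
                             um = unsharp_params()) {
  img |> homomorphic_filter(hf) |> clahe(cl) |> unsharp_mask(um)
}

#' Gray-level information entropy
#'
#' Shannon entropy (bits) of the 256-bin gray-level histogram, a proxy for
#' the richness of detail in an image. Bounded by `[0, log2(n_bins)]`; 8 bits
#' for a perfectly uniform 256-level histogram.
#'
#' @param img Numeric matrix in `[0, 255]`.
#' @param n_bins Histogram bins (default 256).
#' @return Entropy in bits.
#' @export
information_entropy <- function(img, n_bins = 256L) {
  check_gray(img, min_side = 1L)
  b <- pmin(floor(clamp255(img) / 256 * n_bins), n_bins - 1L)
  p <- tabulate(as.vector(b) + 1L, nbins = n_bins) / length(img)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Per-image entropy report for an enhancement run
#'
#' Applies [combined_enhance()] (or a subset of its stages) to every image in
#' a directory and tabulates the information entropy before and after, the
#' layout used to judge whether enhancement enriched image detail.
#'
#' @param paths Character vector of PNG paths.
#' @param ops Character subset of `c("hf", "clahe", "um")`, applied in that
#'   order.
#' @param hf,cl,um Stage parameters.
#' @return A tibble with columns `path`, `entropy_before`, `entropy_after`,
#'   `entropy_gain`.
#' @export
entropy_report <- function(paths, ops = c("hf", "clahe", "um"),
                           hf = hf_params(), cl = clahe_params(),
                           um = unsharp_params()) {
  ops <- match.arg(ops, several.ok = TRUE)
  purrr::map_dfr(paths, function(p) {
    img <- read_gray(p)
    out <- img
    if ("hf" %in% ops) out <- homomorphic_filter(out, hf)
    if ("clahe" %in% ops) out <- clahe(out, cl)
    if ("um" %in% ops) out <- unsharp_mask(out, um)
    tibble::tibble(path = p,
                   entropy_before = information_entropy(img),
                   entropy_after = information_entropy(out))
  }) |>
    dplyr::mutate(entropy_gain = .data$entropy_after - .data$entropy_before)
}
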