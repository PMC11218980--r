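#' Build a dataset manifest from a class-folder tree
#'
#' Scans `root_dir`, which must contain one subdirectory per tumor class
#' (see [tumor_classes()]), and returns one record per image file. Files
#' without a recognized image extension are skipped with a message.
#'
#' @param root_dir Directory with `glioma/`, `meningioma/`, `pituitary/`,
#'   `no_tumor/` subdirectories.
#' @param extensions Recognized image extensions.
#' @return A manifest tibble with columns `path`, `label`, `origin`
#'   (`"original"`), `split` (`"unassigned"`).
#' @export
build_manifest <- function(root_dir, extensions = c("png", "jpg", "jpeg")) {
  if (!dir.exists(root_dir)) stop("root directory not found: ", root_dir, call. = FALSE)
  classes <- tumor_classes()
  missing <- classes[!dir.exists(file.path(root_dir, classes))]
  if (length(missing)) {
    stop("missing class director", if (length(missing) > 1) "ies: " else "y: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  recs <- purrr::map_dfr(classes, function(cl) {
    files <- list.files(file.path(root_dir, cl), full.names = TRUE)
    keep <- grepl(paste0("\\.(", paste(extensions, collapse = "|"), ")$"),
                  files, ignore.case = TRUE)
    if (any(!keep)) {
      message(sum(!keep), " non-image file(s) skipped in ", cl)
    }
    tibble::tibble(path = files[keep], label = cl)
  })
  if (nrow(recs) == 0) stop("no images found under ", root_dir, call. = FALSE)
  recs |>
    dplyr::mutate(origin = "original", split = "unassigned")
}

#' Manifest skeleton from per-class counts
#'
#' Builds a manifest of placeholder records from per-class image counts, so
#' that the augmentation-doubling and stratified-split arithmetic can be
#' audited without the image files themselves (the published collection
#' reports 1621 / 1645 / 1757 / 2000 original slices per class).
#'
#' @param counts Named integer vector; names must be the four classes.
#' @return A manifest tibble (synthetic `path` entries, `origin = "original"`).
#' @export
#' @examples
#' m <- manifest_from_counts(c(glioma = 1621, meningioma = 1645,
#'                             pituitary = 1757, no_tumor = 2000))
#' nrow(m)  # 7023
manifest_from_counts <- function(counts) {
  classes <- tumor_classes()
  if (!setequal(names(counts), classes)) {
    stop("counts must be named by the four classes", call. = FALSE)
  }
  purrr::map_dfr(classes, function(cl) {
    tibble::tibble(path = sprintf("%s/%s_%05d.png", cl, cl, seq_len(counts[[cl]])),
                   label = cl)
  }) |>
    dplyr::mutate(origin = "original", split = "unassigned")
}

#' Double a dataset by enhancement augmentation
#'
#' For every original record, adds one enhanced twin with the same label and
#' `origin = "enhanced"`. When `out_dir` is given the enhanced image is
#' actually computed with [combined_enhance()] and written there (class
#' subfolders are created); with `out_dir = NULL` only the records are
#' produced, which is all the split arithmetic needs.
#'
#' @param manifest Manifest tibble, all records `origin = "original"`.
#' @param out_dir Directory for enhanced images, or `NULL` for records only.
#' @param hf,cl,um Enhancement stage parameters.
#' @return The doubled manifest (originals then enhanced twins).
#' @export
augment_manifest <- function(manifest, out_dir = NULL, hf = hf_params(),
                             cl = clahe_params(), um = unsharp_params()) {
  if (!all(manifest$origin == "original")) {
    stop("augment_manifest expects only original records", call. = FALSE)
  }
  enhanced <- manifest |>
    dplyr::mutate(origin = "enhanced",
                  path = sub("\\.([A-Za-z]+)$", "_enh.\\1", .data$path))
  if (!is.null(out_dir)) {
    enhanced$path <- file.path(out_dir, enhanced$label,
                               basename(enhanced$path))
    for (d in unique(enhanced$label)) {
      dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
    }
    for (i in seq_len(nrow(manifest))) {
      img <- tryCatch(read_gray(manifest$path[i]), error = function(e) NULL)
      if (is.null(img)) {
        stop("augmentation aborted: unreadable image ", manifest$path[i],
             " (", i - 1L, " enhanced images already written)", call. = FALSE)
      }
      write_gray(combined_enhance(img, hf, cl, um), enhanced$path[i])
    }
  }
  dplyr::bind_rows(manifest, enhanced)
}

# round-half-up to an integer (2593.6 -> 2594, 2811.2 -> 2811)
round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/test split
#'
#' Shuffles each class independently with the given seed and assigns
#' `round_half_up(train_fraction * n)` records to the training set, the rest
#' to the test set. The split runs over all records (originals and enhanced
#' twins alike), so a slice and its enhanced copy may land in different
#' folds; see the package vignette for the leakage caveat this carries.
#'
#' @param manifest Manifest tibble with every record `split = "unassigned"`.
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param seed Integer seed making the shuffle reproducible.
#' @return The manifest with `split` set to `"train"` or `"test"`.
#' @export
stratified_split <- function(manifest, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  if (!all(manifest$split == "unassigned")) {
    stop("manifest already has split assignments", call. = FALSE)
  }
  small <- manifest |> dplyr::count(.data$label) |> dplyr::filter(.data$n < 2)
  if (nrow(small)) {
    stop("class with fewer than 2 records: ",
         paste(small$label, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    manifest |>
      dplyr::group_by(.data$label) |>
      dplyr::group_modify(function(df, key) {
        n <- nrow(df)
        n_train <- round_half_up(train_fraction * n)
        ord <- sample.int(n)
        df$split <- "test"
        df$split[ord <= n_train] <- "train"
        df
      }) |>
      dplyr::ungroup() |>
      dplyr::select(dplyr::all_of(c("path", "label", "origin", "split")))
  })
}

#' Per-class split counts
#'
#' @param manifest A split manifest.
#' @return Tibble with per-class totals and train/test counts.
#' @export
split_counts <- function(manifest) {
  manifest |>
    dplyr::count(.data$label, .data$split) |>
    tidyr::pivot_wider(names_from = "split", values_from = "n",
                       values_fill = 0L) |>
    dplyr::mutate(total = rowSums(dplyr::pick(dplyr::where(is.numeric))))
}
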