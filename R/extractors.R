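#' Specify a pluggable image feature extractor
#'
#' Adapter around a pre-trained backbone that turns a directory of images
#' into a [feature_block()]. The backbone itself is supplied as a plain R
#' function (image array in, numeric vector out); the adapter reduces or
#' expands the backbone output to `target_dim` columns, since published
#' pipelines report pooled widths (512/1024) that differ from some
#' backbones' native output sizes. No backbone ships with this package: the
#' synthetic generator is the supported test path, and real deep features
#' are expected to be computed externally and loaded via
#' [read_feature_table()].
#'
#' @param backbone_id Character label, e.g. `"vgg16-like"`.
#' @param target_dim Output width of the block (e.g. 512 or 1024).
#' @param backbone Function mapping an image array (H x W or H x W x C,
#'   values in `[0, 1]`) to a numeric feature vector, or `NULL`.
#' @return An object of class `extractor_spec`.
#' @export
extractor_spec <- function(backbone_id, target_dim, backbone = NULL) {
  stopifnot(target_dim >= 1)
  if (!is.null(backbone)) stopifnot(is.function(backbone))
  structure(list(backbone_id = as.character(backbone_id),
                 target_dim = as.integer(target_dim), backbone = backbone),
            class = "extractor_spec")
}

# Reduce/expand a backbone output vector to target_dim: chunked mean
# pooling when longer, recycling when shorter, identity when equal.
pool_to_dim <- function(v, target_dim) {
  v <- as.numeric(v)
  if (length(v) == target_dim) return(v)
  if (length(v) > target_dim) {
    idx <- ceiling(seq_along(v) / (length(v) / target_dim))
    return(as.numeric(tapply(v, idx, mean)))
  }
  rep_len(v, target_dim)
}

#' Extract a feature block from a directory of images
#'
#' Reads every PNG in `image_dir` (sorted by name), runs `spec$backbone`
#' on each, pools to `target_dim`, and stacks the rows into a
#' [feature_block()]. Without a backbone function the extractor is
#' unavailable and errors with a pointer to the synthetic data path. JPEG
#' decoding is not bundled; convert to PNG or pass features directly.
#'
#' @param image_dir Directory containing `.png` images.
#' @param spec An [extractor_spec()] with a non-`NULL` backbone.
#' @return A [feature_block()] with one row per image; row names are the
#'   file names.
#' @export
extract_features <- function(image_dir, spec) {
  stopifnot(inherits(spec, "extractor_spec"))
  if (is.null(spec$backbone))
    stop("extraction unavailable: no backbone function configured; ",
         "use the synthetic generator (generate_dataset) or load ",
         "precomputed features with read_feature_table()")
  if (!requireNamespace("png", quietly = TRUE))
    stop("extraction unavailable: the 'png' package is required to decode images")
  files <- sort(list.files(image_dir, pattern = "\\.png$", full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0L) stop("no PNG images found in ", image_dir)
  rows <- lapply(files, function(f)
    pool_to_dim(spec$backbone(png::readPNG(f)), spec$target_dim))
  m <- do.call(rbind, rows)
  rownames(m) <- basename(files)
  feature_block(spec$backbone_id, m)
}

#' Toy backbone returning per-image mean intensities
#'
#' A stand-in backbone for exercising the extractor adapter without any
#' pre-trained network: it returns the overall mean pixel intensity followed
#' by per-channel means (for color images). Useful only for plumbing tests.
#'
#' @return A backbone function usable in [extractor_spec()].
#' @export
mock_pixel_mean_backbone <- function() {
  function(img) {
    if (length(dim(img)) == 3L) c(mean(img), apply(img, 3L, mean))
    else mean(img)
  }
}
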