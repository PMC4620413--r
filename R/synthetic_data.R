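# Synthetic stand-ins for the non-public CT-feature cohort: a Gaussian
# feature-table generator with the cohort's size and imbalance structure
# and a controllable class-separation knob, plus a toy texture front-end
# (smooth vs rough grayscale fields) with gray-level and box-counting
# fractal features.

#' Specification of a synthetic feature-table cohort
#'
#' The defaults mirror a small imbalanced CT cohort: 33 positives and 81
#' negatives, split 17/41 for training and 16/40 for testing.
#'
#' @param n_pos_train,n_neg_train,n_pos_test,n_neg_test class counts per
#'   split.
#' @param dims feature dimensionality.
#' @param separation distance between the class means in units of the
#'   within-class standard deviation; 0 makes the classes
#'   indistinguishable, 6 (the default) makes them cleanly separable.
#' @param seed integer seed.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_pos_train = 17L, n_neg_train = 41L,
                           n_pos_test = 16L, n_neg_test = 40L,
                           dims = 10L, separation = 6, seed = 1L) {
  if (!is.numeric(separation) || length(separation) != 1L ||
      is.na(separation) || separation < 0) {
    stopf("`separation` must be a single non-negative number")
  }
  structure(
    list(
      n_pos_train = check_count(n_pos_train, "n_pos_train"),
      n_neg_train = check_count(n_neg_train, "n_neg_train"),
      n_pos_test = check_count(n_pos_test, "n_pos_test"),
      n_neg_test = check_count(n_neg_test, "n_neg_test"),
      dims = check_count(dims, "dims"),
      separation = as.numeric(separation),
      seed = check_count(seed, "seed", min = -.Machine$integer.max)
    ),
    class = "synthetic_spec"
  )
}

#' Generate a train/test pair of Gaussian class-conditional datasets
#'
#' Features are multivariate normal with identity covariance: negatives
#' centred at the origin, positives at `separation * u` for the fixed unit
#' vector `u = (1, ..., 1) / sqrt(dims)`. Train and test are drawn
#' independently with the spec's class counts; the draw is deterministic
#' per seed.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `train` and `test`, both [svm_dataset()] objects.
#' @examples
#' sets <- generate_feature_dataset(synthetic_spec(seed = 42))
#' sets$train
#' @export
generate_feature_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  u <- rep(1, spec$dims) / sqrt(spec$dims)
  draw <- function(n_pos, n_neg) {
    n <- n_pos + n_neg
    x <- matrix(stats::rnorm(n * spec$dims), n, spec$dims)
    x[seq_len(n_pos), ] <- x[seq_len(n_pos), ] +
      matrix(spec$separation * u, n_pos, spec$dims, byrow = TRUE)
    svm_dataset(x, c(rep(1, n_pos), rep(-1, n_neg)))
  }
  with_seed(spec$seed, {
    list(
      train = draw(spec$n_pos_train, spec$n_neg_train),
      test = draw(spec$n_pos_test, spec$n_neg_test)
    )
  })
}

# Bilinear upscale of a coarse matrix to size x size (used for the smooth
# texture class).
bilinear_upscale <- function(m, size) {
  nr <- nrow(m)
  nc <- ncol(m)
  # sample source coordinates at pixel centres
  src_r <- (seq_len(size) - 0.5) / size * (nr - 1) + 1
  src_c <- (seq_len(size) - 0.5) / size * (nc - 1) + 1
  r0 <- pmin(floor(src_r), nr - 1)
  c0 <- pmin(floor(src_c), nc - 1)
  fr <- src_r - r0
  fc <- src_c - c0
  out <- matrix(0, size, size)
  for (j in seq_len(size)) {
    a <- m[cbind(r0, c0[j])] * (1 - fr) + m[cbind(r0 + 1, c0[j])] * fr
    b <- m[cbind(r0, c0[j] + 1)] * (1 - fr) + m[cbind(r0 + 1, c0[j] + 1)] * fr
    out[, j] <- a * (1 - fc[j]) + b * fc[j]
  }
  out
}

rescale_to_gray <- function(m) {
  rng <- range(m)
  if (rng[1] == rng[2]) return(matrix(128, nrow(m), ncol(m)))
  round(255 * (m - rng[1]) / (rng[2] - rng[1]))
}

#' Generate labeled toy texture images
#'
#' A stand-in front-end for grayscale texture classification: class -1 is
#' a smooth low-frequency field (coarse Gaussian noise bilinearly
#' upscaled), class +1 a rough high-frequency field (independent pixel
#' noise). Images are square 8-bit grayscale matrices with intensities in
#' 0..255.
#'
#' @param n_per_class images per class.
#' @param size image side length in pixels (>= 16).
#' @param seed integer seed.
#' @return A list with `images` (list of integer matrices) and `labels`
#'   (+1 rough / -1 smooth).
#' @export
generate_texture_images <- function(n_per_class, size = 128L, seed = 1L) {
  n_per_class <- check_count(n_per_class, "n_per_class")
  size <- check_count(size, "size", min = 16L)
  with_seed(seed, {
    smooth <- lapply(seq_len(n_per_class), function(i) {
      coarse <- matrix(stats::rnorm(16), 4, 4)
      rescale_to_gray(bilinear_upscale(coarse, size))
    })
    rough <- lapply(seq_len(n_per_class), function(i) {
      rescale_to_gray(matrix(stats::rnorm(size * size), size, size))
    })
    list(
      images = c(smooth, rough),
      labels = c(rep(-1, n_per_class), rep(1, n_per_class))
    )
  })
}

#' Box-counting fractal dimension of a binary mask
#'
#' Covers the mask with boxes of dyadic side lengths (1, 2, 4, ... up to
#' half the image side), counts boxes containing at least one foreground
#' pixel, and returns the least-squares slope of `log N(eps)` against
#' `log(1 / eps)`. A filled region has dimension near 2, a line near 1.
#'
#' @param mask logical (or 0/1) matrix; `TRUE` marks foreground.
#' @return The estimated dimension (a single number), or `NA` if the mask
#'   is empty.
#' @examples
#' box_counting_dimension(matrix(TRUE, 64, 64))  # ~2
#' @export
box_counting_dimension <- function(mask) {
  mask <- as.matrix(mask) != 0
  if (!any(mask)) return(NA_real_)
  side <- min(dim(mask))
  eps <- 2^(0:floor(log2(side / 2)))
  counts <- vapply(eps, function(e) {
    ri <- (row(mask)[mask] - 1L) %/% e
    ci <- (col(mask)[mask] - 1L) %/% e
    length(unique(ri * 1e9 + ci))
  }, numeric(1))
  stats::coef(stats::lm(log(counts) ~ log(1 / eps)))[[2]]
}

shannon_entropy_bits <- function(values) {
  tab <- tabulate(as.integer(values) + 1L, nbins = 256L)
  p <- tab[tab > 0] / sum(tab)
  -sum(p * log2(p))
}

#' Gray-level and fractal features of a grayscale image
#'
#' Returns four features: mean intensity, intensity standard deviation,
#' Shannon entropy of the 256-bin intensity histogram (in bits), and the
#' box-counting fractal dimension of the image binarized at its median
#' (foreground = strictly above the median). For a constant image the
#' binarization is degenerate; the dimension is then reported for the
#' full-support mask (close to 2) and flagged via the `"degenerate"`
#' attribute.
#'
#' @param image numeric matrix with intensities in `[0, 255]`.
#' @return Named numeric vector `mean`, `sd`, `entropy`, `fractal_dim`,
#'   with attribute `degenerate` (logical).
#' @export
extract_gray_fractal_features <- function(image) {
  image <- as.matrix(image)
  if (length(image) == 0) stopf("`image` must be non-empty")
  if (anyNA(image) || any(image < 0 | image > 255)) {
    stopf("intensities must lie in [0, 255]")
  }
  med <- stats::median(image)
  mask <- image > med
  degenerate <- !any(mask)
  if (degenerate) mask <- matrix(TRUE, nrow(image), ncol(image))
  out <- c(
    mean = mean(image),
    sd = stats::sd(as.numeric(image)),
    entropy = shannon_entropy_bits(round(image)),
    fractal_dim = box_counting_dimension(mask)
  )
  attr(out, "degenerate") <- degenerate
  out
}

#' Feature dataset from toy texture images
#'
#' Convenience wrapper: generates texture images and extracts the
#' gray/fractal features of each, yielding an [svm_dataset()] usable with
#' [tune_svm()].
#'
#' @inheritParams generate_texture_images
#' @return An [svm_dataset()] with 4 feature columns.
#' @export
texture_feature_dataset <- function(n_per_class, size = 64L, seed = 1L) {
  imgs <- generate_texture_images(n_per_class, size, seed)
  feats <- t(vapply(imgs$images,
                    function(im) unname(extract_gray_fractal_features(im)),
                    numeric(4)))
  colnames(feats) <- c("mean", "sd", "entropy", "fractal_dim")
  svm_dataset(feats, imgs$labels)
}
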