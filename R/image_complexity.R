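#' Extract the HSV value channel from an RGB image
#'
#' The value (V) component of the HSV colour space is the per-pixel maximum of
#' the red, green and blue channels, rescaled to `[0, 1]`. All complexity
#' computation in this package operates on this intensity band: it separates
#' brightness structure from hue and is robust for quantifying structural
#' complexity in vegetation scenes.
#'
#' @param img An RGB image: either a `height x width x 3` numeric array with
#'   channels in `[0, 1]` (the convention of [png::readPNG()] and friends) or
#'   with 8-bit integer channels in `[0, 255]`. A `height x width x 4` RGBA
#'   array is accepted; the alpha channel is ignored. A plain 2-D matrix is
#'   treated as already being an intensity grid and is rescaled if needed.
#' @return A `height x width` numeric matrix of intensities in `[0, 1]`.
#' @export
#' @examples
#' img <- array(c(1, 0, 0), dim = c(1, 1, 3)) # pure red
#' value_channel_from_rgb(img) # 1: V is hue-independent
value_channel_from_rgb <- function(img) {
  if (is.null(dim(img)) || any(dim(img)[1:2] < 1L)) {
    stop("empty image: no pixels to extract a value channel from")
  }
  if (length(dim(img)) == 2L) {
    v <- img
  } else if (length(dim(img)) == 3L && dim(img)[3] >= 3L) {
    v <- pmax(img[, , 1L], img[, , 2L], img[, , 3L])
  } else {
    stop("expected an RGB(A) array (h x w x 3/4) or an intensity matrix")
  }
  # 8-bit integer input is rescaled; float input is assumed already in [0,1]
  if (max(v) > 1) v <- v / 255
  if (min(v) < 0 || max(v) > 1) stop("channel values outside [0, 255]")
  matrix(as.numeric(v), nrow = dim(img)[1], ncol = dim(img)[2])
}

#' Quantize an intensity grid into M frequency bins
#'
#' Maps intensities in `[0, 1]` to integer bin indices `0 .. M-1` by
#' `min(floor(v * M), M - 1)`, so the closed top edge `v = 1` falls in the
#' last bin. The default `M = 256` preserves the native resolution of 8-bit
#' image channels; smaller `M` coarsens the alphabet, which is useful when
#' images are small relative to the number of possible neighborhood
#' configurations.
#'
#' @param field Numeric matrix of intensities in `[0, 1]`.
#' @param M Number of bins (`>= 1`).
#' @return An object of class `quantized_field`: an integer matrix of bin
#'   indices with attributes `M` and (optionally) `view`.
#' @param view Optional provenance label, e.g. `"N"` or `"TOP"`.
#' @export
quantize_intensities <- function(field, M = 256L, view = NULL) {
  if (!is.numeric(M) || length(M) != 1L || M < 1) stop("M must be a single integer >= 1")
  M <- as.integer(M)
  if (!is.matrix(field)) stop("field must be a matrix of intensities")
  if (anyNA(field) || min(field) < 0 || max(field) > 1) {
    stop("intensities must lie in [0, 1]")
  }
  q <- pmin(as.integer(floor(field * M)), M - 1L)
  q <- matrix(q, nrow = nrow(field), ncol = ncol(field))
  structure(q, M = M, view = view, class = c("quantized_field", class(q)))
}

#' Marginal and joint entropy of a quantized field
#'
#' Computes the two Shannon entropies that enter mean information gain, in
#' nats, from plug-in (empirical relative frequency) probabilities:
#' * `h_marginal`: entropy of the pixel-value distribution over all
#'   `height * width` pixels, ignoring location (aspatial heterogeneity);
#' * `h_joint`: entropy of the distribution of 2x2 pixel configurations over
#'   all `(height-1) * (width-1)` overlapping windows fully inside the image
#'   (spatial heterogeneity). No padding or wraparound is used.
#'
#' The convention `0 * log(0) = 0` applies throughout.
#'
#' @param qf A `quantized_field` from [quantize_intensities()], at least 2x2.
#' @return A list with `h_marginal`, `h_joint`, `n_pixels`, `n_windows`, and
#'   `n_configs` (number of distinct observed 2x2 configurations).
#' @export
entropy_components <- function(qf) {
  M <- attr(qf, "M")
  if (is.null(M)) stop("qf must be a quantized_field (see quantize_intensities)")
  h <- nrow(qf); w <- ncol(qf)
  if (h < 2L || w < 2L) stop("image must be at least 2x2 for joint entropy")

  counts <- tabulate(qf + 1L, nbins = M)
  p <- counts[counts > 0L] / (h * w)
  h_marginal <- -sum(p * log(p))

  # encode each 2x2 window (a b / c d) as a base-M integer; M^4 <= 2^53 for
  # M <= 256 so doubles hold the codes exactly
  a <- qf[-h, -w]; b <- qf[-h, -1L]; cc <- qf[-1L, -w]; d <- qf[-1L, -1L]
  code <- a + M * (b + M * (cc + M * as.numeric(d)))
  s <- sort(code)
  n <- length(s)
  last <- c(s[-1L] != s[-n], TRUE)
  cnt <- diff(c(0L, which(last)))
  pj <- cnt / n
  h_joint <- -sum(pj * log(pj))

  list(h_marginal = h_marginal, h_joint = h_joint,
       n_pixels = h * w, n_windows = n, n_configs = length(cnt))
}

#' Mean information gain (MIG) of a quantized image
#'
#' MIG is the normalized difference between the joint entropy of 2x2 pixel
#' neighborhoods and the marginal pixel entropy:
#' \deqn{MIG = \frac{H_{joint} - H_{marginal}}{\log(M^k / M)},\quad k = 4,}
#' which is 0 for a completely uniform image and approaches 1 for completely
#' random (iid) patterns. The normalization makes the value independent of
#' the logarithm base. No clamping is applied: on small images the plug-in
#' entropy estimates can push the value slightly outside `[0, 1]`.
#'
#' @param qf A `quantized_field` with configured bin count `M >= 2`.
#' @return An object of class `mig_result`: a list with `mig`, `h_marginal`,
#'   `h_joint`, `M`, and `k` (always 4 for the 2x2 neighborhood).
#' @export
#' @examples
#' qf <- quantize_intensities(matrix(0.5, 32, 32), M = 256)
#' mean_information_gain(qf)$mig # exactly 0 for a constant image
mean_information_gain <- function(qf) {
  M <- attr(qf, "M")
  if (is.null(M)) stop("qf must be a quantized_field (see quantize_intensities)")
  if (M < 2L) stop("M must be >= 2: the MIG denominator log(M^k/M) is zero for M = 1")
  ec <- entropy_components(qf)
  k <- 4L
  mig <- (ec$h_joint - ec$h_marginal) / ((k - 1) * log(M))
  structure(list(mig = mig, h_marginal = ec$h_marginal, h_joint = ec$h_joint,
                 M = M, k = k),
            class = "mig_result")
}

#' @export
print.mig_result <- function(x, ...) {
  cat(sprintf("MIG = %.4f  (H_joint = %.4f, H_marginal = %.4f nats; M = %d, k = %d)\n",
              x$mig, x$h_joint, x$h_marginal, x$M, x$k))
  invisible(x)
}

#' MIG of an RGB image in one step
#'
#' Convenience wrapper: value channel, quantization, MIG.
#'
#' @inheritParams value_channel_from_rgb
#' @inheritParams quantize_intensities
#' @return A `mig_result`.
#' @export
mig_from_rgb <- function(img, M = 256L) {
  mean_information_gain(quantize_intensities(value_channel_from_rgb(img), M = M))
}

.views_side <- c("N", "E", "S", "W")

#' Per-site MIG summary over the five-view photographic protocol
#'
#' Each sampling site is photographed five times from its centre: four side
#' views facing the cardinal directions and one view facing upwards at the
#' canopy. MIG is computed per image and combined into three site indices:
#' the mean over all five views (`mig_all`), the mean over the four side
#' views (`mig_sides`), and the top view alone (`mig_top`). By construction
#' `mig_all = (4 * mig_sides + mig_top) / 5`.
#'
#' @param images A named list of five RGB images (arrays or intensity
#'   matrices); names must be exactly `N`, `E`, `S`, `W`, `TOP`.
#' @param M Bin count passed to [quantize_intensities()].
#' @return A list with `mig_all`, `mig_sides`, `mig_top`, `per_view` (named
#'   numeric vector), `M` and `k`.
#' @export
site_mig_summary <- function(images, M = 256L) {
  required <- c(.views_side, "TOP")
  if (is.null(names(images))) stop("images must be a named list with views ", paste(required, collapse = ", "))
  missing <- setdiff(required, names(images))
  if (length(missing)) stop("missing view(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(images), required)
  if (length(extra)) stop("unexpected view(s): ", paste(extra, collapse = ", "))
  per_view <- vapply(required, function(v) mig_from_rgb(images[[v]], M = M)$mig, numeric(1))
  sides <- mean(per_view[.views_side])
  top <- per_view[["TOP"]]
  list(mig_all = (4 * sides + top) / 5, mig_sides = sides, mig_top = top,
       per_view = per_view, M = as.integer(M), k = 4L)
}

#' Read a photograph by format
#'
#' Dispatches on file extension to the PNG/TIFF/JPEG readers. Returned arrays
#' have channels in `[0, 1]`.
#'
#' @param path Path to a `.png`, `.tif(f)`, `.jpg` or `.jpeg` file.
#' @return Numeric array as returned by the format's reader.
#' @export
read_view_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext)
  )
}

#' Compute the site MIG table from an image manifest
#'
#' The manifest maps each site to its five photographs. Sites with unreadable
#' or missing images raise an error naming the site and view.
#'
#' @param manifest Data frame (or path to a CSV) with columns `site_id`,
#'   `view` (in `N`, `E`, `S`, `W`, `TOP`) and `path`.
#' @param M Bin count.
#' @param base_dir Optional directory that relative image paths are resolved
#'   against (defaults to the manifest's own directory when `manifest` is a
#'   path).
#' @return Data frame with one row per site: `site_id`, `mig_all`,
#'   `mig_sides`, `mig_top`, `M`, `k`.
#' @export
site_mig_table <- function(manifest, M = 256L, base_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  need <- c("site_id", "view", "path")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  rows <- lapply(split(manifest, manifest$site_id), function(mf) {
    imgs <- stats::setNames(vector("list", nrow(mf)), mf$view)
    for (i in seq_len(nrow(mf))) {
      p <- mf$path[i]
      if (!is.null(base_dir) && !file.exists(p)) p <- file.path(base_dir, mf$path[i])
      if (!file.exists(p)) {
        stop("site ", mf$site_id[1], ", view ", mf$view[i], ": image not found at ", mf$path[i])
      }
      imgs[[mf$view[i]]] <- read_view_image(p)
    }
    s <- site_mig_summary(imgs, M = M)
    data.frame(site_id = mf$site_id[1], mig_all = s$mig_all, mig_sides = s$mig_sides,
               mig_top = s$mig_top, M = s$M, k = s$k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$site_id), , drop = FALSE]
}
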