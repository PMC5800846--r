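#' Read a multi-page grayscale TIFF stack
#'
#' Loads a z-stack of 2-D grayscale slices (e.g. 2 um confocal sections)
#' into a numeric `y x x x z` array. Multi-channel pages are collapsed to
#' their first channel.
#'
#' @param path TIFF file path.
#' @return Numeric array with dimensions `(y, x, z)`, class `image_stack`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("stack not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  as_image_stack(array(unlist(pages), dim = c(dim(pages[[1]]), length(pages))))
}

#' Write an image stack as a multi-page TIFF
#'
#' Intensities are rescaled to `[0, 1]` for storage (16-bit); the scale
#' factor is lost, which is irrelevant for relative fluorescence work.
#'
#' @param stack `(y, x, z)` array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stack <- as_image_stack(stack)
  mx <- max(stack)
  if (mx <= 0) mx <- 1
  pages <- lapply(seq_len(dim(stack)[3]), function(z) stack[, , z] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Coerce to an image stack
#'
#' @param x Numeric matrix (treated as a single slice) or `(y, x, z)` array
#'   of finite, non-negative intensities.
#' @return The array with class `image_stack`.
#' @export
as_image_stack <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1))
  if (length(dim(x)) != 3 || dim(x)[3] < 1) stop("stack must be a (y, x, z) array with >= 1 slice")
  if (any(!is.finite(x)) || any(x < 0)) stop("intensities must be finite and >= 0")
  class(x) <- c("image_stack", class(array(0)))
  x
}

#' Maximum-intensity projection
#'
#' Collapses a z-stack to a single 2-D image by taking the per-pixel
#' maximum across slices — the standard merge used before soma counting.
#'
#' @param stack `(y, x, z)` array (or matrix).
#' @return Numeric `y x x` matrix.
#' @export
max_project <- function(stack) {
  stack <- as_image_stack(stack)
  out <- stack[, , 1]
  nz <- dim(stack)[3]
  if (nz > 1) for (z in 2:nz) out <- pmax(out, stack[, , z])
  out
}

# robust background level and spread: level = median of pixels at or below
# the given percentile (robust to sparse bright somata); spread = scaled MAD
# of the whole image (somata occupy far less than half the field, so the
# median absolute deviation still reflects the background noise)
.background_stats <- function(img, percentile = 0.5) {
  cut <- stats::quantile(img, percentile, names = FALSE)
  bg <- img[img <= cut]
  c(level = stats::median(bg), spread = stats::mad(img))
}

# 8-connected component labeling by iterative minimum-label propagation
.label_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  L <- matrix(Inf, ny, nx)
  L[mask] <- which(mask)
  pad_shift <- function(M, dy, dx) {
    out <- matrix(Inf, ny, nx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    out[ys, xs] <- M[ys - dy, xs - dx]
    out
  }
  repeat {
    Lnew <- L
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      Lnew <- pmin(Lnew, pad_shift(L, dy, dx))
    }
    Lnew[!mask] <- Inf
    if (identical(Lnew, L)) break
    L <- Lnew
  }
  lab <- matrix(0L, ny, nx)
  ids <- sort(unique(L[is.finite(L)]))
  lab[mask] <- match(L[mask], ids)
  lab
}

# local maxima of img within mask: pixel >= all 8 neighbours (after light
# 3x3 box smoothing to suppress single-pixel noise peaks)
.local_maxima <- function(img, mask) {
  ny <- nrow(img); nx <- ncol(img)
  pad <- function(M, dy, dx, fill = -Inf) {
    out <- matrix(fill, ny, nx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    out[ys, xs] <- M[ys - dy, xs - dx]
    out
  }
  sm <- matrix(0, ny, nx); cnt <- matrix(0, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    sm <- sm + pad(img, dy, dx, fill = 0)
    cnt <- cnt + pad(matrix(1, ny, nx), dy, dx, fill = 0)
  }
  sm <- sm / cnt
  is_max <- matrix(TRUE, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & (sm >= pad(sm, dy, dx))
  }
  which(is_max & mask, arr.ind = TRUE)
}

#' Detect fluorescent somata in a 2-D image
#'
#' Automated stand-in for manually drawn per-cell ROIs. The image is
#' thresholded at `background median + threshold_k * robust SD` (background
#' = pixels at or below the `background_percentile`), connected components
#' (8-connectivity) within `[min_area, max_area]` become candidate cells,
#' and components carrying two or more local intensity maxima separated by
#' more than `min_separation` pixels are split by nearest-maximum
#' assignment. ROIs are ordered by centroid (y, then x). A constant image
#' yields an empty list with a warning.
#'
#' @param image Numeric 2-D matrix (typically from [max_project()]).
#' @param threshold_k Threshold in robust-SD multiples above background (default 3).
#' @param background_percentile Fraction of pixels regarded as candidate
#'   background (default 0.5).
#' @param min_area,max_area Component area bounds in pixels.
#' @param min_separation Minimum distance (px) between maxima before a
#'   component is split.
#' @return List of class `cell_rois`: `rois` (data frame `id, centroid_y,
#'   centroid_x, area`), `labels` (integer matrix, 0 = background),
#'   `background` (level/spread), `threshold`.
#' @export
detect_cells <- function(image, threshold_k = 3, background_percentile = 0.5,
                         min_area = 9, max_area = Inf, min_separation = 8) {
  stopifnot(is.matrix(image))
  if (max(image) == min(image)) {
    warning("constant image: no cells detectable")
    return(structure(list(rois = data.frame(id = integer(), centroid_y = numeric(),
                                            centroid_x = numeric(), area = integer()),
                          labels = matrix(0L, nrow(image), ncol(image)),
                          background = c(level = unname(image[1]), spread = 0),
                          threshold = unname(image[1])),
                     class = "cell_rois"))
  }
  bg <- .background_stats(image, background_percentile)
  thr <- bg["level"] + threshold_k * bg["spread"]
  mask <- image > thr
  lab <- .label_components(mask)

  # split components holding >1 sufficiently separated local maxima
  if (max(lab) > 0 && is.finite(min_separation) && min_separation > 0) {
    mx <- .local_maxima(image, mask)
    if (nrow(mx) > 1) {
      newlab <- lab
      next_id <- max(lab)
      for (comp in seq_len(max(lab))) {
        in_comp <- lab[cbind(mx[, 1], mx[, 2])] == comp
        pts <- mx[in_comp, , drop = FALSE]
        if (nrow(pts) < 2) next
        # prominence filter: only maxima reaching half the component's peak
        # excess over threshold count as soma centers (tail noise does not)
        excess <- image[pts] - thr
        pts <- pts[excess >= 0.5 * max(excess), , drop = FALSE]
        if (nrow(pts) < 2) next
        # greedy merge: keep the brightest maximum within min_separation
        o <- order(-image[pts])
        pts <- pts[o, , drop = FALSE]
        keep <- rep(TRUE, nrow(pts))
        for (i in seq_len(nrow(pts))) {
          if (!keep[i]) next
          if (i < nrow(pts)) for (j in (i + 1):nrow(pts)) {
            if (keep[j] && sqrt(sum((pts[i, ] - pts[j, ])^2)) <= min_separation) keep[j] <- FALSE
          }
        }
        pts <- pts[keep, , drop = FALSE]
        if (nrow(pts) < 2) next
        px <- which(lab == comp, arr.ind = TRUE)
        d2 <- outer(px[, 1], pts[, 1], "-")^2 + outer(px[, 2], pts[, 2], "-")^2
        assign_to <- max.col(-d2, ties.method = "first")
        ids <- c(comp, next_id + seq_len(nrow(pts) - 1L))
        next_id <- next_id + nrow(pts) - 1L
        newlab[px] <- ids[assign_to]
      }
      lab <- newlab
    }
  }

  # area filter + deterministic ordering by centroid
  if (max(lab) > 0) {
    tab <- tabulate(lab[lab > 0])
    rois <- do.call(rbind, lapply(which(tab >= min_area & tab <= max_area), function(id) {
      px <- which(lab == id, arr.ind = TRUE)
      data.frame(old = id, centroid_y = mean(px[, 1]), centroid_x = mean(px[, 2]),
                 area = nrow(px))
    }))
  } else rois <- NULL
  out_lab <- matrix(0L, nrow(image), ncol(image))
  if (!is.null(rois) && nrow(rois)) {
    rois <- rois[order(rois$centroid_y, rois$centroid_x), , drop = FALSE]
    rois$id <- seq_len(nrow(rois))
    for (i in seq_len(nrow(rois))) out_lab[lab == rois$old[i]] <- rois$id[i]
    rois$old <- NULL
    rois <- rois[, c("id", "centroid_y", "centroid_x", "area")]
    rownames(rois) <- NULL
  } else {
    rois <- data.frame(id = integer(), centroid_y = numeric(),
                       centroid_x = numeric(), area = integer())
  }
  structure(list(rois = rois, labels = out_lab, background = bg,
                 threshold = unname(thr)),
            class = "cell_rois")
}

#' Import manually drawn ROIs from a label mask
#'
#' Escape hatch for reusing hand-drawn per-cell ROIs: a label image
#' (integer matrix, 0 = background, k = cell k) is converted to the same
#' `cell_rois` structure that [detect_cells()] produces, reordered by
#' centroid.
#'
#' @param mask Integer matrix of labels.
#' @param image Optional intensity image for background estimation.
#' @return A `cell_rois` object.
#' @export
rois_from_mask <- function(mask, image = NULL) {
  stopifnot(is.matrix(mask))
  ids <- sort(setdiff(unique(as.integer(mask)), 0L))
  rois <- do.call(rbind, lapply(ids, function(id) {
    px <- which(mask == id, arr.ind = TRUE)
    data.frame(old = id, centroid_y = mean(px[, 1]), centroid_x = mean(px[, 2]),
               area = nrow(px))
  }))
  bg <- if (!is.null(image)) .background_stats(image) else c(level = 0, spread = 0)
  out_lab <- matrix(0L, nrow(mask), ncol(mask))
  if (!is.null(rois)) {
    rois <- rois[order(rois$centroid_y, rois$centroid_x), , drop = FALSE]
    rois$id <- seq_len(nrow(rois))
    for (i in seq_len(nrow(rois))) out_lab[mask == rois$old[i]] <- rois$id[i]
    rois$old <- NULL
    rois <- rois[, c("id", "centroid_y", "centroid_x", "area")]
    rownames(rois) <- NULL
  } else {
    rois <- data.frame(id = integer(), centroid_y = numeric(),
                       centroid_x = numeric(), area = integer())
  }
  structure(list(rois = rois, labels = out_lab, background = bg, threshold = NA_real_),
            class = "cell_rois")
}

#' Per-cell fluorescence quantification
#'
#' For each ROI, sums the background-subtracted intensity (each pixel's
#' excess over the background level, clipped at 0 per pixel) and reports
#' both the integrated and the mean per-pixel value, plus the cell count.
#'
#' @param image Numeric 2-D matrix.
#' @param rois A `cell_rois` object over the same image.
#' @param background Background level; defaults to the level estimated at
#'   detection time (or from the image if unavailable). When quantifying a
#'   maximum projection of a noisy z-stack, pass the median of the full
#'   stack instead: the projection inflates background pixels by the
#'   maximum of the per-slice noise while soma pixels are dominated by
#'   their brightest slice, so a projection-based background over-subtracts.
#' @return List with `cells` (data frame `cell_id, area, mean_int,
#'   integrated_int`) and `count`.
#' @export
quantify_cells <- function(image, rois, background = NULL) {
  stopifnot(is.matrix(image), inherits(rois, "cell_rois"))
  if (!all(dim(rois$labels) == dim(image))) stop("ROI mask does not match image dimensions")
  if (is.null(background)) {
    background <- if (is.finite(rois$background["level"])) unname(rois$background["level"])
                  else unname(.background_stats(image)["level"])
  }
  n <- nrow(rois$rois)
  if (n == 0) return(list(cells = data.frame(cell_id = integer(), area = integer(),
                                             mean_int = numeric(), integrated_int = numeric()),
                          count = 0L))
  excess <- pmax(image - background, 0)
  cells <- do.call(rbind, lapply(seq_len(n), function(i) {
    px <- rois$labels == rois$rois$id[i]
    data.frame(cell_id = rois$rois$id[i], area = sum(px),
               mean_int = mean(excess[px]), integrated_int = sum(excess[px]))
  }))
  list(cells = cells, count = n)
}
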