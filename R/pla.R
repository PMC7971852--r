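#' Gaussian smoothing of a grayscale image
#'
#' Separable Gaussian convolution with edge replication; kernel radius is
#' `ceiling(3 * sigma)`.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return Smoothed matrix of the same dimensions.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_idx <- function(n) pmin(pmax(seq(1 - r, n + r), 1L), n)
  # rows
  pi <- pad_idx(nrow(img))
  tmp <- matrix(0, nrow(img), ncol(img))
  for (j in seq_along(k)) {
    tmp <- tmp + k[j] * img[pi[seq_len(nrow(img)) + j - 1L], , drop = FALSE]
  }
  # columns
  pj <- pad_idx(ncol(img))
  out <- matrix(0, nrow(img), ncol(img))
  for (j in seq_along(k)) {
    out <- out + k[j] * tmp[, pj[seq_len(ncol(img)) + j - 1L], drop = FALSE]
  }
  out
}

#' Local mean filter (adaptive-threshold neighbourhood)
#'
#' Mean over a square `window x window` neighbourhood; near the image
#' border the mean is taken over the in-bounds part of the window.
#' Computed with an integral image.
#'
#' @param img numeric matrix.
#' @param window odd neighbourhood size (> 1).
#' @return Matrix of local means.
#' @export
local_mean <- function(img, window) {
  if (window %% 2L == 0L || window <= 1L) {
    stop("adaptive window must be odd and > 1")
  }
  h <- nrow(img)
  w <- ncol(img)
  if (window >= h || window >= w) {
    stop("adaptive window must be smaller than the image")
  }
  r <- (window - 1L) %/% 2L
  ii <- rbind(0, cbind(0, apply(apply(img, 2, cumsum), 1, cumsum)))
  # ii is (w+1) x (h+1) after the double apply: index as ii[col+1, row+1]
  rows <- seq_len(h)
  cols <- seq_len(w)
  r1 <- pmax(rows - r, 1L)
  r2 <- pmin(rows + r, h)
  c1 <- pmax(cols - r, 1L)
  c2 <- pmin(cols + r, w)
  sums <- ii[c2 + 1L, r2 + 1L, drop = FALSE] -
    ii[c1, r2 + 1L, drop = FALSE] -
    ii[c2 + 1L, r1, drop = FALSE] + ii[c1, r1, drop = FALSE]
  counts <- outer(c2 - c1 + 1L, r2 - r1 + 1L)
  t(sums / counts)
}

#' Label connected components of a binary mask
#'
#' Classic two-pass labelling with union-find; 8-connectivity by default.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of component labels (0 = background) with the
#'   number of components in `attr(, "n_components")`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  h <- nrow(mask)
  w <- ncol(mask)
  labels <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union <- function(a, b) {
    ra <- find(a)
    rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  fg <- which(mask)
  for (idx in fg) {
    i <- (idx - 1L) %% h + 1L
    j <- (idx - 1L) %/% h + 1L
    nb <- integer(0)
    if (j > 1L && labels[i, j - 1L]) nb <- c(nb, labels[i, j - 1L])
    if (i > 1L && labels[i - 1L, j]) nb <- c(nb, labels[i - 1L, j])
    if (connectivity == 8L) {
      if (i > 1L && j > 1L && labels[i - 1L, j - 1L]) {
        nb <- c(nb, labels[i - 1L, j - 1L])
      }
      if (i > 1L && j < w && labels[i - 1L, j + 1L]) {
        nb <- c(nb, labels[i - 1L, j + 1L])
      }
    }
    if (length(nb) == 0L) {
      parent <- c(parent, length(parent) + 1L)
      labels[i, j] <- length(parent)
    } else {
      labels[i, j] <- min(nb)
      for (b in nb) union(labels[i, j], b)
    }
  }
  # second pass: resolve labels and compact them
  if (length(parent)) {
    roots <- vapply(seq_along(parent), find, integer(1))
    compact <- match(roots, sort(unique(roots)))
    labels[labels > 0L] <- compact[labels[labels > 0L]]
  }
  attr(labels, "n_components") <- length(unique(labels[labels > 0L]))
  labels
}

#' Count PLA spots in a micrograph
#'
#' The quantification pipeline for proximity-ligation-assay images:
#' grayscale conversion (3-channel arrays are combined by standard
#' luminance weighting), Gaussian smoothing, adaptive mean thresholding
#' (a pixel is foreground when its smoothed intensity exceeds the local
#' window mean by `adaptive_offset`), 8-connected component labelling,
#' and removal of components below `min_component_px` pixels. Each
#' surviving component is one nascent-protein spot.
#'
#' @param image numeric matrix, or an `h x w x 3` array.
#' @param gaussian_sigma smoothing sigma in pixels.
#' @param adaptive_window odd neighbourhood size for the local mean; must
#'   be held constant between control and experimental images.
#' @param adaptive_offset intensity offset above the local mean.
#' @param min_component_px minimum component size in pixels.
#' @param image_id identifier carried into the result.
#' @return An object of class `spot_count` (list with `image_id`,
#'   `n_components`, `parameters`, `labels`).
#' @export
count_spots <- function(image, gaussian_sigma = 1.5, adaptive_window = 31L,
                        adaptive_offset = 5, min_component_px = 2L,
                        image_id = NA_character_) {
  if (length(dim(image)) == 3L) {
    if (dim(image)[3] != 3L) stop("only 1- or 3-channel images supported")
    image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] +
      0.114 * image[, , 3]
  }
  if (!is.matrix(image) || length(image) == 0L) {
    stop("image must be a non-empty matrix")
  }
  sm <- gaussian_blur(image, gaussian_sigma)
  mask <- sm > local_mean(sm, adaptive_window) + adaptive_offset
  labels <- label_components(mask, 8L)
  sizes <- tabulate(labels[labels > 0L])
  n <- sum(sizes >= min_component_px)
  structure(list(image_id = image_id, n_components = n,
                 parameters = list(gaussian_sigma = gaussian_sigma,
                                   adaptive_window = adaptive_window,
                                   adaptive_offset = adaptive_offset,
                                   min_component_px = min_component_px),
                 labels = labels),
            class = "spot_count")
}

#' @export
print.spot_count <- function(x, ...) {
  cat(sprintf("spot_count %s: %d component(s)\n", x$image_id,
              x$n_components))
  invisible(x)
}

#' Average number of nascent-protein spots per cell
#'
#' @param result a `spot_count` (or its `n_components`).
#' @param n_cells number of cells in the image (> 0); 0 yields `NA` with
#'   a warning.
#' @return Spots per cell.
#' @export
dots_per_cell <- function(result, n_cells) {
  n <- if (inherits(result, "spot_count")) result$n_components else result
  if (n_cells == 0) {
    warning("n_cells is 0; dots per cell undefined", call. = FALSE)
    return(NA_real_)
  }
  n / n_cells
}

#' Count spots over a batch of images with shared parameters
#'
#' Enforces the analysis rule that the adaptive-threshold neighbourhood
#' (and all other parameters) are held constant between control and
#' experimental images: one parameter set is applied to the whole batch.
#'
#' @param images named list of image matrices.
#' @param n_cells named vector of cell counts per image (optional).
#' @param ... parameters passed to [count_spots()].
#' @return A `data.frame` with one row per image (`image_id`,
#'   `n_components`, and `dots_per_cell` when cell counts are given).
#' @export
count_spots_batch <- function(images, n_cells = NULL, ...) {
  res <- lapply(names(images), function(id)
    count_spots(images[[id]], ..., image_id = id))
  out <- data.frame(image_id = names(images),
                    n_components = vapply(res, `[[`, integer(1),
                                          "n_components"),
                    stringsAsFactors = FALSE)
  if (!is.null(n_cells)) {
    out$n_cells <- n_cells[out$image_id]
    out$dots_per_cell <- out$n_components / out$n_cells
  }
  out
}
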