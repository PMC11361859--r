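#' Phase-space-reconstruction configuration
#'
#' A 10-s segment is delay-embedded in two dimensions — the trajectory of
#' points `(x[t], x[t + delay])` — and the trajectory is rasterized into a
#' square occupancy grid (one image per segment).  The embedding dimension
#' is fixed at 2 because the downstream regressor consumes 2-D images.
#'
#' @param delay embedding delay in samples (default 10 = 20 ms at 500 Hz)
#' @param grid_size image side length (default 32)
#' @param normalize `"sum"` (entries sum to 1; model input default),
#'   `"max"` (max entry 1) or `"counts"` (raw occupancy counts)
#' @param bounds `"segment"` (per-segment min-max; makes the image invariant
#'   to amplitude scaling, appropriate because T:R is scale-free) or
#'   `"fixed"` (use `fixed_bounds`)
#' @param fixed_bounds length-2 `c(lo, hi)` amplitude bounds when
#'   `bounds = "fixed"`; out-of-range points fall into the edge bins
#' @return An object of class `psr_config`.
#' @export
psr_config <- function(delay = 10L, grid_size = 32L,
                       normalize = c("sum", "max", "counts"),
                       bounds = c("segment", "fixed"),
                       fixed_bounds = NULL) {
  normalize <- match.arg(normalize)
  bounds <- match.arg(bounds)
  stop_if_not(delay >= 1, "delay must be >= 1 sample")
  stop_if_not(grid_size >= 2, "grid_size must be >= 2")
  if (bounds == "fixed")
    stop_if_not(length(fixed_bounds) == 2 && fixed_bounds[2] > fixed_bounds[1],
                "fixed_bounds must be c(lo, hi) with hi > lo")
  structure(list(delay = as.integer(delay), grid_size = as.integer(grid_size),
                 normalize = normalize, bounds = bounds,
                 fixed_bounds = fixed_bounds),
            class = "psr_config")
}

#' Delay-embed a segment
#'
#' @param x an [ecg_segment] or numeric vector
#' @param config a [psr_config()] (only `delay` is used)
#' @return A two-column matrix of `(x[t], x[t + delay])` pairs, with
#'   `length(x) - delay` rows.
#' @export
psr_embed <- function(x, config = psr_config()) {
  s <- seg_samples(x)
  d <- config$delay
  if (length(s) <= d)
    stop("degenerate input: segment length must exceed the embedding delay",
         call. = FALSE)
  n <- length(s) - d
  cbind(x = s[seq_len(n)], y = s[seq_len(n) + d])
}

#' Rasterize an embedded trajectory into a PSR image
#'
#' Each trajectory point is assigned to exactly one cell of a
#' `grid_size` x `grid_size` occupancy grid (half-open bins, top edge
#' closed), then the grid is normalized per `config$normalize`.  A flat
#' (constant) segment has no amplitude range; its mass is assigned to cell
#' (1, 1) and the image is flagged low-quality.
#'
#' @param traj two-column matrix from [psr_embed()]
#' @param config a [psr_config()]
#' @param index,channel metadata carried on the image
#' @return An object of class `psr_image`: list with `grid` (matrix),
#'   `index`, `channel`, `normalize`, `flat`.
#' @export
psr_rasterize <- function(traj, config = psr_config(), index = NA_integer_,
                          channel = NA_character_) {
  stop_if_not(is.matrix(traj) && ncol(traj) == 2 && nrow(traj) >= 1,
              "trajectory must be a non-empty two-column matrix")
  g <- config$grid_size
  if (config$bounds == "fixed") {
    lo <- config$fixed_bounds[1]; hi <- config$fixed_bounds[2]
  } else {
    lo <- min(traj); hi <- max(traj)
  }
  flat <- !(hi > lo)
  grid <- matrix(0, g, g)
  if (flat) {
    grid[1, 1] <- nrow(traj)
  } else {
    ix <- pmax(1L, pmin(g, floor((traj[, 1] - lo) / (hi - lo) * g) + 1L))
    iy <- pmax(1L, pmin(g, floor((traj[, 2] - lo) / (hi - lo) * g) + 1L))
    counts <- tabulate((iy - 1L) * g + ix, nbins = g * g)
    grid <- matrix(as.numeric(counts), g, g)
  }
  grid <- switch(config$normalize,
                 counts = grid,
                 sum = grid / sum(grid),
                 max = grid / max(grid))
  structure(list(grid = grid, index = as.integer(index), channel = channel,
                 normalize = config$normalize, flat = flat),
            class = "psr_image")
}

#' @export
print.psr_image <- function(x, ...) {
  cat(sprintf("<psr_image> %dx%d (%s-normalized)%s, segment #%s (%s)\n",
              nrow(x$grid), ncol(x$grid), x$normalize,
              if (x$flat) " [flat segment]" else "",
              x$index, x$channel))
  invisible(x)
}

#' Convert one segment to its PSR image
#'
#' Conditions the segment ([preprocess_segment()]) and then embeds and
#' rasterizes it.  Deterministic: identical samples give identical images.
#'
#' @param segment an [ecg_segment]
#' @param filter_config a [filter_config()]; `NULL` skips conditioning
#' @param config a [psr_config()]
#' @return a [psr_rasterize()] image
#' @export
segment_to_image <- function(segment, filter_config = sicdscreen::filter_config(),
                             config = psr_config()) {
  if (!is.null(filter_config))
    segment <- preprocess_segment(segment, filter_config)
  psr_rasterize(psr_embed(segment, config), config,
                index = if (inherits(segment, "ecg_segment")) segment$index else NA_integer_,
                channel = if (inherits(segment, "ecg_segment")) segment$channel else NA_character_)
}

#' Convert many segments to PSR images
#'
#' @param segments a list of [ecg_segment] (one channel), or the per-channel
#'   list returned by [segment_record()]
#' @inheritParams segment_to_image
#' @return a list of `psr_image` (or a named list of such lists, mirroring
#'   the input structure)
#' @export
segments_to_images <- function(segments, filter_config = sicdscreen::filter_config(),
                               config = psr_config()) {
  if (length(segments) && is.list(segments[[1]]) &&
      !inherits(segments[[1]], "ecg_segment"))
    return(lapply(segments, segments_to_images, filter_config = filter_config,
                  config = config))
  lapply(segments, segment_to_image, filter_config = filter_config,
         config = config)
}

#' Flatten PSR images into a model-input matrix
#'
#' @param images list of `psr_image`
#' @return numeric matrix, one row per image, `grid_size^2` columns
#'   (column-major pixel order)
#' @export
images_to_matrix <- function(images) {
  stop_if_not(length(images) >= 1, "no images supplied")
  g <- nrow(images[[1]]$grid)
  X <- t(vapply(images, function(im) as.vector(im$grid), numeric(g * g)))
  attr(X, "grid_size") <- g
  X
}

#' Write / read a batch of PSR images
#'
#' Stores the image stack as an `n x g x g` array in an R serialization
#' file, with a plain-text CSV sidecar (`<path>.index.csv`) listing segment
#' index, channel and flat flag for each image.
#'
#' @param images list of `psr_image`
#' @param path output path for the array container
#' @return `path`, invisibly (for `write_psr_images`); a list of
#'   `psr_image` (for `read_psr_images`).
#' @export
write_psr_images <- function(images, path) {
  g <- nrow(images[[1]]$grid)
  arr <- array(0, dim = c(length(images), g, g))
  for (i in seq_along(images)) arr[i, , ] <- images[[i]]$grid
  attr(arr, "normalize") <- images[[1]]$normalize
  saveRDS(arr, path)
  idx <- data.frame(i = seq_along(images),
                    segment = vapply(images, function(x) x$index, integer(1)),
                    channel = vapply(images, function(x) x$channel, character(1)),
                    flat = vapply(images, function(x) x$flat, logical(1)))
  utils::write.csv(idx, paste0(path, ".index.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_psr_images
#' @export
read_psr_images <- function(path) {
  arr <- readRDS(path)
  idx <- utils::read.csv(paste0(path, ".index.csv"))
  lapply(seq_len(dim(arr)[1]), function(i) {
    structure(list(grid = arr[i, , ], index = idx$segment[i],
                   channel = idx$channel[i],
                   normalize = attr(arr, "normalize") %||% "sum",
                   flat = idx$flat[i]),
              class = "psr_image")
  })
}
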