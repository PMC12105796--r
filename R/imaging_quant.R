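# ROI-based quantification of two-channel confocal stacks: nuclear 3x3
# ROIs on the brightest plane, top-10-pixel terminal ROIs, whole-soma ROIs
# with area, maximal projection, twice-subtracted channel arithmetic and
# whole-image terminal intensity.  Stacks are plain numeric arrays indexed
# [z, y, x]; 2-D images are [y, x] matrices.

roi_measure <- function(kind, raw_mean, background, area = NA_real_,
                        clip = TRUE, bg_roi = NULL) {
  value <- raw_mean - background
  clipped <- FALSE
  if (value < 0 && clip) { value <- 0; clipped <- TRUE }
  structure(list(kind = kind, raw_mean = raw_mean, background = background,
                 value = value, area = area, clipped = clipped,
                 bg_roi = bg_roi),
            class = "roi_measure")
}

#' @export
print.roi_measure <- function(x, ...) {
  cat(sprintf("ROI measure [%s]: raw %.2f - background %.2f = %.2f%s%s\n",
              x$kind, x$raw_mean, x$background, x$value,
              if (x$clipped) " (clipped at 0)" else "",
              if (!is.na(x$area)) sprintf(", area %.2f um^2", x$area) else ""))
  invisible(x)
}

## Resolve the background argument: a number is a pre-measured grey value;
## NULL means "same-shape ROI translated away from the measured region".
## The first in-bounds axis-aligned translation by `offset_px` that does
## not overlap the ROI is used and its coordinates recorded for audit.
resolve_background <- function(img, roi_idx, background, offset_px = 10L) {
  if (!is.null(background)) {
    stopifnot(is.numeric(background), length(background) == 1L)
    return(list(value = background, roi = NULL))
  }
  dims <- dim(img)
  rc <- arrayInd(roi_idx, dims)
  for (off in list(c(offset_px, 0L), c(-offset_px, 0L),
                   c(0L, offset_px), c(0L, -offset_px))) {
    ry <- rc[, 1] + off[1]; rx <- rc[, 2] + off[2]
    if (any(ry < 1L | ry > dims[1] | rx < 1L | rx > dims[2])) next
    idx <- (rx - 1L) * dims[1] + ry
    if (any(idx %in% roi_idx)) next
    return(list(value = mean(img[idx]),
                roi = list(offset = off, idx = idx)))
  }
  stop("no in-bounds, non-overlapping background ROI found; ",
       "supply `background` explicitly")
}

#' Maximal projection of a z-stack
#'
#' Per-pixel maximum across the selected planes, the standard way of
#' overlaying the 8--10 confocal planes that contain the structures of
#' interest.
#'
#' @param stack Numeric array `[z, y, x]`.
#' @param z_range Plane indices to project (default: all).
#' @return A `[y, x]` matrix.
#' @export
max_project <- function(stack, z_range = seq_len(dim(stack)[1])) {
  stopifnot(length(dim(stack)) == 3L)
  if (length(z_range) == 0L) stop("empty z_range")
  if (any(z_range < 1L | z_range > dim(stack)[1]))
    stop("z_range outside the stack")
  apply(stack[z_range, , , drop = FALSE], c(2, 3), max)
}

#' Nuclear staining intensity from a 3x3 ROI on the brightest plane
#'
#' Around the given nucleus seed, the z-plane maximizing the mean
#' intensity of the 3x3 pixel neighbourhood is selected (searched within
#' `plane_search` planes of the seed's plane), and the measure is that
#' patch's mean grey value minus the background.
#'
#' @param stack Numeric array `[z, y, x]`.
#' @param nucleus_seed Integer `c(z, y, x)` voxel inside the nucleus.
#' @param background Pre-measured background grey value, or `NULL` to
#'   derive it from a same-shape ROI translated by `offset_px` pixels.
#' @param plane_search Half-width of the plane search window (default 3).
#' @param offset_px Background-ROI translation (pixels).
#' @param clip Clip negative background-subtracted values at 0.
#' @return A `roi_measure` with the selected plane in `$plane`.
#' @export
nuclear_intensity <- function(stack, nucleus_seed, background = NULL,
                              plane_search = 3L, offset_px = 10L,
                              clip = TRUE) {
  stopifnot(length(dim(stack)) == 3L, length(nucleus_seed) == 3L)
  dims <- dim(stack)
  z0 <- nucleus_seed[1]; y0 <- nucleus_seed[2]; x0 <- nucleus_seed[3]
  if (z0 < 1 || z0 > dims[1]) stop("seed plane outside the stack")
  if (y0 < 2 || y0 > dims[2] - 1 || x0 < 2 || x0 > dims[3] - 1)
    stop("seed at image border: 3x3 ROI does not fit")
  planes <- max(1L, z0 - plane_search):min(dims[1], z0 + plane_search)
  patch_mean <- vapply(planes, function(z)
    mean(stack[z, (y0 - 1):(y0 + 1), (x0 - 1):(x0 + 1)]), numeric(1))
  zbest <- planes[which.max(patch_mean)]
  img <- stack[zbest, , ]
  roi_idx <- as.integer(outer((y0 - 1):(y0 + 1),
                              ((x0 - 1):(x0 + 1) - 1L) * dims[2], "+"))
  bg <- resolve_background(img, roi_idx, background, offset_px)
  out <- roi_measure("nuclear3x3", max(patch_mean), bg$value,
                     clip = clip, bg_roi = bg$roi)
  out$plane <- zbest
  out
}

#' Terminal staining intensity from the 10 brightest pixels
#'
#' Within a rectangular region of the maximal projection, the measure is
#' the mean of the 10 highest pixel values minus the background.  Ties at
#' the 10th value are all included and the mean renormalized over the
#' pixels actually used (reported in `$n_used`, with a message).
#'
#' @param stack Numeric array `[z, y, x]` (projected internally) or an
#'   already-projected `[y, x]` matrix.
#' @param region List with `y = c(min, max)`, `x = c(min, max)` (pixel
#'   bounds, inclusive); at least 10 pixels.
#' @param background,offset_px,clip See [nuclear_intensity()].
#' @param n_top Number of brightest pixels (default 10).
#' @return A `roi_measure` with `$n_used`.
#' @export
top10_terminal_intensity <- function(stack, region, background = NULL,
                                     offset_px = 10L, clip = TRUE,
                                     n_top = 10L) {
  img <- if (length(dim(stack)) == 3L) max_project(stack) else stack
  dims <- dim(img)
  ys <- region$y[1]:region$y[2]; xs <- region$x[1]:region$x[2]
  if (any(ys < 1 | ys > dims[1] | xs < 1 | xs > dims[2]))
    stop("region outside the image")
  vals <- img[ys, xs, drop = FALSE]
  if (length(vals) < n_top)
    stop("region smaller than ", n_top, " pixels")
  sorted <- sort(as.numeric(vals), decreasing = TRUE)
  cutoff <- sorted[n_top]
  used <- sorted[sorted >= cutoff]
  if (length(used) > n_top)
    message("tie at the ", n_top, "th brightest pixel: using ",
            length(used), " pixels")
  roi_idx <- as.integer(outer(ys, (xs - 1L) * dims[1], "+"))
  bg <- resolve_background(img, roi_idx, background, offset_px)
  out <- roi_measure("top10", mean(used), bg$value, clip = clip,
                     bg_roi = bg$roi)
  out$n_used <- length(used)
  out
}

#' Whole-soma staining intensity and cell-body area
#'
#' The measure is the mean grey value over the soma mask on the maximal
#' projection minus the background; the area is the mask size converted to
#' square micrometres.
#'
#' @param stack Numeric array `[z, y, x]` or projected `[y, x]` matrix.
#' @param soma_mask Logical `[y, x]` matrix marking the cell body
#'   (non-empty).
#' @param background,offset_px,clip See [nuclear_intensity()].
#' @param pixel_size Pixel edge length in micrometres (default 0.537).
#' @return A `roi_measure` with `area` in um^2 and `$area_px`.
#' @export
soma_intensity_area <- function(stack, soma_mask, background = NULL,
                                offset_px = 10L, clip = TRUE,
                                pixel_size = 0.537) {
  img <- if (length(dim(stack)) == 3L) max_project(stack) else stack
  stopifnot(is.matrix(soma_mask), all(dim(soma_mask) == dim(img)))
  if (!any(soma_mask)) stop("empty soma mask")
  roi_idx <- which(soma_mask)
  bg <- resolve_background(img, roi_idx, background, offset_px)
  out <- roi_measure("soma", mean(img[roi_idx]), bg$value,
                     area = sum(soma_mask) * pixel_size^2,
                     clip = clip, bg_roi = bg$roi)
  out$area_px <- sum(soma_mask)
  out
}

#' Subtract the CRZ channel from the PDF channel
#'
#' Removes bleed-through of CRZ-neuron staining from a PDF image by
#' subtracting the CRZ channel `times` times (twice by default), clipping
#' at 0.  Residual soma or commissure staining that would be removed
#' manually in an interactive workflow is zeroed via the explicit
#' `manual_mask` argument, keeping the pipeline deterministic.
#'
#' @param pdf_img,crz_img Equal-shape `[y, x]` matrices.
#' @param times How many times to subtract (default 2).
#' @param manual_mask Optional logical matrix of pixels to zero.
#' @return The cleaned `[y, x]` matrix.
#' @export
subtract_crz_channel <- function(pdf_img, crz_img, times = 2,
                                 manual_mask = NULL) {
  if (!all(dim(pdf_img) == dim(crz_img))) stop("shape mismatch")
  out <- pmax(pdf_img - times * crz_img, 0)
  if (!is.null(manual_mask)) {
    stopifnot(all(dim(manual_mask) == dim(out)))
    out[manual_mask] <- 0
  }
  out
}

#' Whole-image terminal intensity after background subtraction
#'
#' After channel subtraction has blacked out everything except the
#' terminals, subtracting the background estimate and summing the whole
#' image measures the total terminal staining mass.
#'
#' @param projected `[y, x]` matrix (typically from
#'   [subtract_crz_channel()] of maximal projections).
#' @param background_estimate Grey value subtracted from every pixel
#'   before clipping at 0 and summing.
#' @return A `roi_measure` whose `value` is the summed intensity.
#' @export
whole_image_terminal_intensity <- function(projected, background_estimate = 0) {
  stopifnot(is.matrix(projected))
  total <- sum(pmax(projected - background_estimate, 0))
  out <- roi_measure("whole_image", total, 0, clip = FALSE)
  out$background <- background_estimate
  out
}

#' Write / read a z-stack as plain text
#'
#' Stacks are stored as a small text format (dimension header line, then
#' one whitespace-separated row per image row, planes concatenated) so
#' that synthetic image fixtures remain plain text.
#'
#' @param stack Numeric array `[z, y, x]`.
#' @param path File path.
#' @return `path` (write) or the array (read).
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3L)
  d <- dim(stack)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(d, collapse = " "), con)
  for (z in seq_len(d[1]))
    utils::write.table(stack[z, , ], con, row.names = FALSE,
                       col.names = FALSE, sep = " ")
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  d <- as.integer(strsplit(readLines(con, 1), " ")[[1]])
  stopifnot(length(d) == 3L)
  vals <- scan(con, quiet = TRUE)
  stopifnot(length(vals) == prod(d))
  out <- array(0, dim = d)
  m <- matrix(vals, ncol = d[3], byrow = TRUE)
  for (z in seq_len(d[1]))
    out[z, , ] <- m[(z - 1L) * d[2] + seq_len(d[2]), ]
  out
}
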