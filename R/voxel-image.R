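#' Calibrated multi-channel 3D intensity stack
#'
#' Container for a multi-channel 3D fluorescence image with physical voxel
#' calibration. Axis order is `(z, y, x)` everywhere in the package and all
#' physical quantities are in micrometres (um). Voxel index `i` (1-based)
#' spans the physical interval `[(i-1)*d, i*d)` along its axis, with centre
#' `(i-0.5)*d`, where `d` is the voxel size for that axis.
#'
#' @param data Numeric 4D array with dimensions `(channel, z, y, x)`, or a
#'   named list of 3D `(z, y, x)` arrays of identical shape. All intensities
#'   must be finite and non-negative.
#' @param voxel_size Numeric length-3 vector, um per voxel along `(z, y, x)`;
#'   strictly positive.
#' @param channel_labels Character vector of unique channel names. Required
#'   when `data` is an unnamed array; a typical set is
#'   `c("mrna", "nterm", "cterm", "reference")`.
#' @param cell_mask Optional logical 3D array of the spatial shape marking
#'   voxels inside the cell of interest; `NULL` means the whole volume.
#'
#' @return An object of class `voxel_image`: a list with elements `data`
#'   (4D array, channel-first), `voxel_size`, `channel_labels`, `cell_mask`.
#' @export
voxel_image <- function(data, voxel_size, channel_labels = NULL,
                        cell_mask = NULL) {
  if (is.list(data)) {
    if (is.null(channel_labels)) channel_labels <- names(data)
    shp <- dim(data[[1]])
    arr <- array(0, c(length(data), shp))
    for (i in seq_along(data)) {
      if (!identical(dim(data[[i]]), shp)) {
        stop("all channel arrays must share the same spatial shape")
      }
      arr[i, , , ] <- data[[i]]
    }
    data <- arr
  }
  if (length(dim(data)) != 4L) {
    stop("`data` must be a 4D (channel, z, y, x) array or list of 3D arrays")
  }
  if (is.null(channel_labels)) channel_labels <- dimnames(data)[[1]]
  if (is.null(channel_labels) || length(channel_labels) != dim(data)[1]) {
    stop("`channel_labels` must name every channel")
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("`voxel_size` must be 3 strictly positive values (z, y, x) in um")
  }
  if (!is.null(cell_mask)) {
    if (!identical(dim(cell_mask), dim(data)[2:4])) {
      stop("`cell_mask` shape must match the spatial shape of `data`")
    }
    storage.mode(cell_mask) <- "logical"
  }
  structure(
    list(data = data, voxel_size = voxel_size,
         channel_labels = as.character(channel_labels),
         cell_mask = cell_mask),
    class = "voxel_image"
  )
}

#' Extract one channel of a voxel image as a 3D array
#'
#' @param image A [voxel_image].
#' @param channel Channel name.
#' @return Numeric 3D `(z, y, x)` array.
#' @export
get_channel <- function(image, channel) {
  stopifnot(inherits(image, "voxel_image"))
  i <- match(channel, image$channel_labels)
  if (is.na(i)) {
    stop(sprintf("channel '%s' not found; available: %s", channel,
                 paste(image$channel_labels, collapse = ", ")))
  }
  ch <- image$data[i, , , , drop = TRUE]
  dim(ch) <- dim(image$data)[2:4]
  ch
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_image> %d channel(s) [%s], %d x %d x %d voxels (z,y,x)\n",
              d[1], paste(x$channel_labels, collapse = ", "), d[2], d[3], d[4]))
  cat(sprintf("  voxel size: %s um; extent: %s um%s\n",
              paste(format(x$voxel_size), collapse = " x "),
              paste(format(d[2:4] * x$voxel_size), collapse = " x "),
              if (is.null(x$cell_mask)) "" else "; cell mask present"))
  invisible(x)
}

# logical mask of voxels inside the cell (all TRUE when no mask was given)
image_mask <- function(image) {
  if (!is.null(image$cell_mask)) return(image$cell_mask)
  array(TRUE, dim(image$data)[2:4])
}

# physical (um) centre coordinates of voxel indices (matrix with cols z,y,x)
voxel_center_um <- function(idx, voxel_size) {
  sweep(idx - 0.5, 2, voxel_size, "*")
}

# voxel index (1-based integer) containing a physical position; clipped to bounds
um_to_voxel <- function(pos_um, voxel_size, shape) {
  idx <- floor(pos_um / voxel_size) + 1L
  pmin(pmax(idx, 1L), shape)
}
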