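## Pixel geometry and regions of interest.
##
## Grid convention (body-fixed): 32 x 32 image, row-major 0-based pixel
## indices. Row 0 = ventral (anterior) surface, row 31 = dorsal. Column 0 =
## the animal's RIGHT side. The electrode belt rotates with the animal, so
## masks never change with posture; only the gravity axis rotates.

## Body-frame pixel-center coordinates for every pixel of the grid.
## depth: cm from the ventral surface. lateral: cm from the midline,
## positive toward the animal's LEFT.
pixelCoords <- function(config) {
  g <- config$grid
  row <- rep(0:(g - 1L), each = g)
  col <- rep(0:(g - 1L), times = g)
  data.frame(pixel = row * g + col, row = row, col = col,
             depth = (row + 0.5) / g * config$ap_span,
             lateral = ((col + 0.5) / g - 0.5) * config$rl_span)
}

## Relative lung geometry (fractions of the grid): two ellipses centred at
## mid-depth, offset a quarter-width to each side.
.LUNG_CENTER_D <- 0.5
.LUNG_CENTER_X <- 0.24
.LUNG_SEMI_D <- 0.34
.LUNG_SEMI_X <- 0.16

#' Default two-lung ROI mask
#'
#' Builds the geometric elliptical two-lung mask on the EIT pixel grid and
#' labels every lung pixel with its ventral/dorsal half (split at mid-depth),
#' its left/right lung (split at the midline column) and its anatomical
#' quadrant (half x side). The quadrant partition refines the half partition
#' exactly. The mask is a declared geometric approximation (no
#' subject-specific segmentation) and can be replaced via
#' \code{\link{readRoiMask}}.
#'
#' @param grid grid side length; the supported EIT image is 32 x 32.
#' @return a \code{\linkS4class{ROIMask}}.
#' @export
defaultRoiMask <- function(grid = 32L) {
  grid <- as.integer(grid)
  stopifnot(grid >= 8L)
  row <- rep(0:(grid - 1L), each = grid)
  col <- rep(0:(grid - 1L), times = grid)
  fd <- (row + 0.5) / grid          # 0 ventral .. 1 dorsal
  fx <- (col + 0.5) / grid - 0.5    # <0 animal right, >0 animal left
  inLung <- function(cx)
    ((fd - .LUNG_CENTER_D) / .LUNG_SEMI_D)^2 +
      ((fx - cx) / .LUNG_SEMI_X)^2 <= 1
  left <- inLung(.LUNG_CENTER_X)
  right <- inLung(-.LUNG_CENTER_X)
  lung <- left | right
  half <- quadrant <- side <- rep(NA_character_, grid^2)
  ventral <- fd < 0.5
  half[lung] <- ifelse(ventral[lung], "ventral", "dorsal")
  side[lung] <- ifelse(right[lung], "right_lung", "left_lung")
  quadrant[lung] <- paste0(ifelse(ventral[lung], "upper_", "lower_"),
                           ifelse(right[lung], "right", "left"))
  new("ROIMask", grid = grid, lungMask = lung, half = half,
      quadrant = quadrant, side = side)
}

#' Region labels of a labelling scheme
#'
#' @param mask a \code{\linkS4class{ROIMask}}.
#' @param scheme "quadrant", "half", "side" or "lung".
#' @return character vector of region names in canonical order.
#' @export
roiRegions <- function(mask, scheme = c("quadrant", "half", "side", "lung")) {
  scheme <- match.arg(scheme)
  switch(scheme,
         quadrant = c("upper_right", "upper_left", "lower_right", "lower_left"),
         half = c("ventral", "dorsal"),
         side = c("right_lung", "left_lung"),
         lung = "lung")
}

#' Pixel indices (1-based columns of the frame matrix) of one region
#'
#' @param mask a \code{\linkS4class{ROIMask}}.
#' @param region a region name from any scheme, or "lung".
#' @return integer vector of 1-based pixel column indices.
#' @export
roiPixels <- function(mask, region = "lung") {
  lab <- switch(region,
                lung = mask@lungMask,
                ventral = , dorsal = mask@half == region,
                right_lung = , left_lung = mask@side == region,
                upper_right = , upper_left = , lower_right = ,
                lower_left = mask@quadrant == region,
                stop("unknown region: ", region))
  idx <- which(!is.na(lab) & lab)
  if (!length(idx)) stop("region '", region, "' contains no pixels")
  idx
}

#' Dependent lung of a lateral posture
#'
#' In "Lateral Left" the animal lies toward its left, making the LEFT lung
#' gravitationally dependent; symmetrically for "Lateral Right". Supine has
#' no dependent lung in this sense (the dependent region is the dorsal half
#' of both), so supine input is an error.
#'
#' @param post a \code{\link{posture}}.
#' @return "left_lung" or "right_lung".
#' @export
dependentLung <- function(post) {
  switch(post$label,
         lateral_left = "left_lung",
         lateral_right = "right_lung",
         stop("no dependent lung is defined for the supine posture"))
}

#' Gravitational depth of body-frame positions under a posture
#'
#' Projects body-fixed positions onto the gravity axis of the given posture
#' and returns depth below the least-dependent point of the set (cm). In
#' supine, gravity runs ventral to dorsal; a lateral tilt rotates the axis in
#' the frontal plane toward the dependent side.
#'
#' @param depth ventral-dorsal coordinates, cm.
#' @param lateral right-left coordinates (positive toward the animal's
#'   left), cm.
#' @param post a \code{\link{posture}}.
#' @return numeric vector of gravitational depths, minimum 0.
#' @export
gravitationalDepth <- function(depth, lateral, post) {
  th <- post$tilt * pi / 180
  sgn <- switch(post$label, supine = 0, lateral_left = 1, lateral_right = -1)
  proj <- depth * cos(th) + sgn * lateral * sin(th)
  proj - min(proj)
}

#' Write / read an ROI mask as JSON label arrays
#'
#' @param mask a \code{\linkS4class{ROIMask}}.
#' @param path file path.
#' @return \code{readRoiMask} returns a \code{\linkS4class{ROIMask}}.
#' @export
writeRoiMask <- function(mask, path) {
  jsonlite::write_json(
    list(grid = mask@grid, lungMask = mask@lungMask, half = mask@half,
         quadrant = mask@quadrant, side = mask@side),
    path, auto_unbox = TRUE, null = "null", na = "null", digits = NA)
  invisible(path)
}

#' @rdname writeRoiMask
#' @export
readRoiMask <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  asChr <- function(v) { v <- as.character(v); v[v == "NULL"] <- NA; v }
  new("ROIMask", grid = as.integer(j$grid), lungMask = as.logical(j$lungMask),
      half = asChr(j$half), quadrant = asChr(j$quadrant),
      side = asChr(j$side))
}
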