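## Binary morphology with a disc structuring element, used by the annotator
## simulator to model boundary error. Implemented by shifting the mask over
## the disc offsets; radii in this package are small (<= ~5 px) so the
## kernel has at most a few dozen offsets.

disc_offsets <- function(radius) {
  r <- as.integer(floor(radius))
  if (r <= 0) return(matrix(0L, 1, 2))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  as.matrix(g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE])
}

shift_matrix <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  sr <- max(1, 1 + dr):min(h, h + dr)
  sc <- max(1, 1 + dc):min(w, w + dc)
  if (length(sr) && length(sc)) out[sr, sc] <- m[sr - dr, sc - dc]
  out
}

#' Dilate a binary mask by a disc of the given radius
#' @param mask `binary_mask` or logical matrix.
#' @param radius disc radius in pixels (0 = identity).
#' @return a `binary_mask`.
#' @export
dilate_disc <- function(mask, radius) {
  m <- as_mask_matrix(mask)
  if (radius <= 0 || !any(m)) return(binary_mask(m))
  off <- disc_offsets(radius)
  out <- m
  for (i in seq_len(nrow(off)))
    if (off[i, 1] != 0 || off[i, 2] != 0)
      out <- out | shift_matrix(m, off[i, 1], off[i, 2])
  binary_mask(out)
}

#' Erode a binary mask by a disc of the given radius
#' @inheritParams dilate_disc
#' @return a `binary_mask`.
#' @export
erode_disc <- function(mask, radius) {
  m <- as_mask_matrix(mask)
  if (radius <= 0 || !any(m)) return(binary_mask(m))
  # erosion is dilation of the complement (disc kernel is symmetric)
  binary_mask(!as_mask_matrix(dilate_disc(!m, radius)))
}

# boundary band: pixels whose 1-dilation and 1-erosion disagree
boundary_band <- function(m) {
  as_mask_matrix(dilate_disc(m, 1)) & !as_mask_matrix(erode_disc(m, 1))
}

#' Paint a filled disc into a logical matrix
#' @param height,width frame size.
#' @param center_row,center_col 1-based center.
#' @param radius disc radius (>= 1).
#' @return logical matrix.
#' @keywords internal
disc_mask <- function(height, width, center_row, center_col, radius) {
  rr <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  (rr - center_row)^2 + (cc - center_col)^2 <= radius^2
}
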