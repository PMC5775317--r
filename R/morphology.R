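# 3D binary-image primitives: connected-component labelling with 6/18/26
# connectivity, ball dilation/erosion/closing. Grids in this package are
# small (tens of voxels per side), so frontier-based BFS in plain R is fast.

conn_offsets <- function(connectivity = 26L) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6"  = nz == 1,
                 "18" = nz >= 1 & rowSums(g != 0) <= 2,
                 "26" = nz >= 1)
  unname(g[keep, , drop = FALSE])
}

# linear indices of in-bounds neighbours of the voxels in `lin` (1-based)
neighbour_lin <- function(lin, dims, offs) {
  co <- arrayInd(lin, dims)
  n <- nrow(co); m <- nrow(offs)
  nb <- co[rep(seq_len(n), each = m), , drop = FALSE] +
    offs[rep(seq_len(m), times = n), , drop = FALSE]
  keep <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
    nb[, 2] >= 1 & nb[, 2] <= dims[2] &
    nb[, 3] >= 1 & nb[, 3] <= dims[3]
  nb <- nb[keep, , drop = FALSE]
  nb[, 1] + (nb[, 2] - 1L) * dims[1] + (nb[, 3] - 1L) * dims[1] * dims[2]
}

#' Label connected components of a 3D logical array
#'
#' @param member logical 3D array.
#' @param connectivity 6, 18 or 26 (face, edge or corner adjacency).
#' @return Integer array of the same shape; 0 = background, components
#'   numbered from 1 in first-encounter (column-major) order.
#' @export
label_components <- function(member, connectivity = 26L) {
  dims <- dim(member)
  stopifnot(length(dims) == 3L)
  offs <- conn_offsets(as.integer(connectivity))
  lab <- array(0L, dims)
  todo <- which(member)
  cur <- 0L
  for (s in todo) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      nb <- unique(neighbour_lin(frontier, dims, offs))
      nb <- nb[member[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

# offsets of a digital ball of given radius (voxel units, Euclidean)
ball_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  unname(g[rowSums(g^2) <= radius^2 + 1e-9, , drop = FALSE])
}

dilate_member <- function(member, radius) {
  if (radius <= 0) return(member)
  dims <- dim(member)
  offs <- ball_offsets(radius)
  out <- array(FALSE, dims)
  lin <- which(member)
  if (length(lin)) out[unique(neighbour_lin(lin, dims, offs))] <- TRUE
  out[lin] <- TRUE
  out
}

erode_member <- function(member, radius) {
  if (radius <= 0) return(member)
  # a voxel survives iff no background voxel lies within the ball
  # (out-of-bounds is treated as mask, so borders are not eroded inward)
  !dilate_member(!member, radius) & member
}

close_member <- function(member, radius) {
  if (radius <= 0) return(member)
  erode_member(dilate_member(member, radius), radius)
}

#' Dilate a binary mask by a ball
#'
#' @param mask a [binary_mask()].
#' @param radius_vox ball radius in voxels (Euclidean).
#' @return The dilated [binary_mask()].
#' @export
dilate_mask <- function(mask, radius_vox = 1) {
  stopifnot(inherits(mask, "binary_mask"))
  binary_mask(dilate_member(mask$member, radius_vox), mask$grid)
}
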