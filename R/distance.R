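#' Euclidean distance to the lesion
#'
#' Exact Euclidean distance transform (voxel centre to nearest lesion-voxel
#' centre) in millimetres, aware of anisotropic voxel sizes. Computed with
#' the separable lower-envelope algorithm of Felzenszwalb & Huttenlocher
#' applied along each axis in turn with the axis' physical spacing, which is
#' exact for point sites (iterated binary dilation, by contrast, only
#' approximates metric distance and degrades on anisotropic grids).
#'
#' @param lesion_mask logical 3D array; must contain at least one voxel.
#' @param grid a [vox_grid()] supplying voxel sizes.
#' @return numeric 3D array of distances in mm, 0 inside the lesion.
#' @export
distance_to_lesion <- function(lesion_mask, grid) {
  check_volume(lesion_mask, grid, "lesion_mask")
  if (!any(lesion_mask))
    stop("lesion mask is empty; perilesional distances are undefined",
         call. = FALSE)
  d2 <- array(ifelse(lesion_mask, 0, Inf), dim = grid$shape)
  for (axis in 1:3)
    d2 <- edt_pass(d2, axis, grid$voxel_mm[axis])
  sqrt(d2)
}

# One separable pass of the squared EDT along `axis` with spacing w (mm).
edt_pass <- function(d2, axis, w) {
  sh <- dim(d2)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(d2, perm), nrow = sh[axis])
  for (j in seq_len(ncol(m))) m[, j] <- edt_1d(m[, j], w)
  aperm(array(m, dim = sh[perm]), order(perm))
}

# 1D squared distance transform under f(i) with sample spacing w:
# out(i) = min_j f(j) + (w*(i-j))^2  (lower envelope of parabolas).
edt_1d <- function(f, w) {
  n <- length(f)
  finite <- which(is.finite(f))
  if (length(finite) == 0) return(f)
  v <- integer(n); z <- numeric(n + 1)
  k <- 1L
  v[1] <- finite[1]
  z[1] <- -Inf; z[2] <- Inf
  w2 <- w * w
  for (q in finite[-1]) {
    repeat {
      p <- v[k]
      s <- ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2 * w2 * (q - p))
      if (s <= z[k]) { k <- k - 1L } else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1] <- Inf
  }
  out <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1] < q) k <- k + 1L
    p <- v[k]
    out[q] <- w2 * (q - p)^2 + f[p]
  }
  out
}

#' Connected component of a binary mask containing a seed voxel
#'
#' 6-connectivity breadth-first flood fill; used to keep synthetic lesions
#' connected after masking to the brain and hemisphere.
#'
#' @param mask logical 3D array.
#' @param seed_index integer vector of length 3 (array index of the seed).
#' @return logical array: the component of `mask` containing the seed
#'   (all-FALSE if the seed voxel itself is FALSE).
#' @export
connected_component <- function(mask, seed_index) {
  sh <- dim(mask)
  out <- array(FALSE, dim = sh)
  si <- as.integer(seed_index)
  if (!mask[si[1], si[2], si[3]]) return(out)
  lin <- function(i) i[1] + (i[2] - 1L) * sh[1] + (i[3] - 1L) * sh[1] * sh[2]
  queue <- lin(si)
  out[queue] <- TRUE
  offsets <- c(-1L, 1L, -sh[1], sh[1], -sh[1] * sh[2], sh[1] * sh[2])
  # precompute array indices to guard against wrap-around at the faces
  while (length(queue) > 0) {
    cur <- queue
    queue <- integer(0)
    ai <- arrayInd(cur, sh)
    for (d in 1:6) {
      axis <- c(1L, 1L, 2L, 2L, 3L, 3L)[d]
      step <- c(-1L, 1L, -1L, 1L, -1L, 1L)[d]
      ok <- if (step < 0) ai[, axis] > 1L else ai[, axis] < sh[axis]
      nb <- cur[ok] + offsets[d]
      nb <- nb[mask[nb] & !out[nb]]
      if (length(nb)) {
        out[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
    queue <- unique(queue)
  }
  out
}
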