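#' Synthetic brain template with mirrored atlas ROIs
#'
#' Builds a mirror-symmetric synthetic head on the given grid: an ellipsoidal
#' brain with a CSF rim and central ventricles, smooth GM/WM/CSF probability
#' maps that sum to one inside the brain, and an atlas of axis-aligned
#' ellipsoidal ROIs placed in the left hemisphere and reflected to exact
#' right-hemisphere homologues. The first `n_roi_pairs` pairs are tagged as
#' perisylvian-analogue language ROIs, the remaining `n_control_rois` pairs
#' as control regions. ROI shapes are deliberately simple: the downstream
#' statistics are agnostic to anatomy, and exact mirror symmetry is what
#' makes laterality tests falsifiable.
#'
#' @param grid a [vox_grid()] (must be symmetric about the mid-sagittal
#'   plane, which the default `origin_mm` guarantees).
#' @param n_roi_pairs number of homologous language-ROI pairs (>= 1).
#' @param n_control_rois number of homologous control-ROI pairs.
#' @param seed integer seed (controls placement jitter).
#' @param roi_radius_mm ROI semi-axis length in mm.
#' @return list: `brain_mask` (logical), `tissue` (list gm/wm/csf),
#'   `atlas` (integer labels), `lookup` (data.frame label, name, hemisphere,
#'   class, homologue), `grid`.
#' @export
make_brain <- function(grid, n_roi_pairs = 4, n_control_rois = 2, seed = 1,
                       roi_radius_mm = 5) {
  stopifnot(n_roi_pairs >= 1, n_control_rois >= 0)
  co <- grid_coord_arrays(grid)
  extent <- grid$shape * grid$voxel_mm
  semi <- 0.46 * extent
  # ellipsoidal radial coordinate: 1 at the brain surface
  rho <- sqrt((co[[1]] / semi[1])^2 + (co[[2]] / semi[2])^2 +
                (co[[3]] / semi[3])^2)
  brain_mask <- rho <= 1

  # ventricles: small central ellipsoid, mirror-symmetric by construction
  vsemi <- c(0.22, 0.30, 0.18) * semi
  vent <- sqrt((co[[1]] / vsemi[1])^2 + (co[[2]] / vsemi[2])^2 +
                 (co[[3]] / vsemi[3])^2) <= 1

  # radial partition of unity: WM core, GM band, CSF rim
  ramp <- function(x, centre, width)  # keeps dim: array is pmin/pmax arg 1
    pmax(pmin((x - centre) / width + 0.5, 1), 0)
  a <- ramp(rho, 0.62, 0.10)   # 0 deep in WM -> 1 beyond the WM core
  b <- ramp(rho, 0.88, 0.08)   # 0 inside GM band -> 1 in the CSF rim
  wm <- (1 - a)
  gm <- a * (1 - b)
  csf <- a * b
  wm[!brain_mask] <- 0; gm[!brain_mask] <- 0; csf[!brain_mask] <- 0
  csf[vent & brain_mask] <- 1
  gm[vent] <- 0; wm[vent] <- 0
  tissue <- list(gm = gm, wm = wm, csf = csf)

  n_pairs <- n_roi_pairs + n_control_rois
  centres <- place_roi_centres(grid, rho, vent, n_pairs, roi_radius_mm, seed)
  atlas <- array(0L, dim = grid$shape)
  interior <- brain_mask & !vent & rho <= 0.95
  for (i in seq_len(n_pairs)) {
    ell <- (((co[[1]] - centres[i, 1]) / roi_radius_mm)^2 +
              ((co[[2]] - centres[i, 2]) / roi_radius_mm)^2 +
              ((co[[3]] - centres[i, 3]) / roi_radius_mm)^2) <= 1
    ell <- ell & interior
    if (!any(ell))
      stop("ROI ", i, " is empty after intersection with the brain; ",
           "grid too small for the requested ROI layout", call. = FALSE)
    if (any(atlas[ell] != 0))
      stop("ROI ", i, " overlaps a previously placed ROI", call. = FALSE)
    atlas[ell] <- i
  }
  # reflect left labels to right homologues
  right_atlas <- mirror_volume(atlas, grid)
  stopifnot(all(atlas[right_atlas != 0] == 0))
  atlas[right_atlas != 0] <- right_atlas[right_atlas != 0] + n_pairs

  cls <- c(rep("perisylvian", n_roi_pairs), rep("control", n_control_rois))
  nm <- c(sprintf("lang_%d", seq_len(n_roi_pairs)),
          if (n_control_rois > 0) sprintf("ctrl_%d", seq_len(n_control_rois)))
  lookup <- data.frame(
    label = c(seq_len(n_pairs), seq_len(n_pairs) + n_pairs),
    name = c(paste0(nm, "_L"), paste0(nm, "_R")),
    hemisphere = rep(c("L", "R"), each = n_pairs),
    class = rep(cls, 2),
    homologue = c(seq_len(n_pairs) + n_pairs, seq_len(n_pairs)),
    stringsAsFactors = FALSE)

  list(brain_mask = brain_mask, tissue = tissue, atlas = atlas,
       lookup = lookup, grid = grid)
}

# Deterministic maximin placement of ROI centres in the left hemisphere:
# candidates are interior voxel centres (a full ROI radius left of the
# midline, so mirrored homologues cannot overlap the originals); the first
# centre is the deepest candidate, each further centre maximizes its
# distance to those already placed (farthest-point packing), and a
# 2*radius + 1 voxel separation is enforced so ROIs stay disjoint. The seed
# only perturbs tie-breaking.
place_roi_centres <- function(grid, rho, vent, n_pairs, radius_mm, seed) {
  co <- grid_coord_arrays(grid)
  lr <- grid$lr_axis
  cand <- which(rho <= 0.85 & !vent &
                  co[[lr]] <= -(radius_mm + grid$voxel_mm[lr]))
  if (length(cand) == 0)
    stop("grid too small: no admissible left-hemisphere ROI centres",
         call. = FALSE)
  rng <- local_rng(seed)
  jitter <- rng$runif(length(cand)) * 1e-3
  pts <- cbind(co[[1]][cand], co[[2]][cand], co[[3]][cand])
  min_sep <- 2 * radius_mm + max(grid$voxel_mm)
  chosen <- matrix(NA_real_, nrow = n_pairs, ncol = 3)
  chosen[1, ] <- pts[which.min(rho[cand] + jitter), ]
  mind <- sqrt(colSums((t(pts) - chosen[1, ])^2))
  for (k in seq_len(n_pairs - 1)) {
    # prefer well-separated *and* interior points among those far enough
    score <- mind - jitter
    best <- which.max(score)
    if (mind[best] < min_sep)
      stop("grid too small to place ROI ", k + 1L, " of ", n_pairs,
           " disjoint left-hemisphere ROIs of radius ", radius_mm, " mm",
           call. = FALSE)
    chosen[k + 1, ] <- pts[best, ]
    mind <- pmin(mind, sqrt(colSums((t(pts) - pts[best, ])^2)))
  }
  chosen
}

#' Synthetic left-hemisphere lesion
#'
#' Places a roughly ellipsoidal lesion of the requested radius centred on
#' (a jittered version of) the centroid of a left-hemisphere ROI, clips it
#' to the brain and the left hemisphere, and keeps the connected component
#' containing the centre so the lesion is a single stroke-like blob.
#'
#' @param brain list from [make_brain()] (or any list with `brain_mask`,
#'   `atlas`, `lookup`, `grid`).
#' @param centre_roi label of a left-hemisphere ROI to centre the lesion on.
#' @param radius_mm lesion radius in mm; 0 gives an empty mask.
#' @param seed integer seed (centre jitter and per-axis eccentricity).
#' @return logical lesion mask.
#' @export
make_lesion <- function(brain, centre_roi, radius_mm, seed = 1) {
  grid <- brain$grid
  row <- brain$lookup[brain$lookup$label == centre_roi, ]
  if (nrow(row) != 1)
    stop("unknown ROI label ", centre_roi, call. = FALSE)
  if (row$hemisphere != "L")
    stop("lesion centre ROI ", centre_roi, " is not in the left hemisphere",
         call. = FALSE)
  empty <- array(FALSE, dim = grid$shape)
  if (radius_mm <= 0) return(empty)
  idx <- which(brain$atlas == centre_roi)
  ai <- arrayInd(idx, grid$shape)
  co <- grid_coords(grid)
  centre <- vapply(1:3, function(a) mean(co[[a]][ai[, a]]), numeric(1))
  rng <- local_rng(seed)
  centre <- centre + rng$runif(3, -1, 1) * grid$voxel_mm
  ax <- radius_mm * rng$runif(3, 0.85, 1.15)
  ca <- grid_coord_arrays(grid)
  ell <- (((ca[[1]] - centre[1]) / ax[1])^2 +
            ((ca[[2]] - centre[2]) / ax[2])^2 +
            ((ca[[3]] - centre[3]) / ax[3])^2) <= 1
  left <- hemisphere_masks(grid)$left
  lesion <- ell & brain$brain_mask & left
  if (!any(lesion)) return(empty)
  # seed voxel: nearest in-lesion voxel to the intended centre
  li <- which(lesion)
  lai <- arrayInd(li, grid$shape)
  w <- vapply(1:3, function(a) co[[a]][lai[, a]], numeric(nrow(lai)))
  if (is.null(dim(w))) w <- matrix(w, ncol = 3)
  d2c <- rowSums((w - matrix(centre, nrow(lai), 3, byrow = TRUE))^2)
  connected_component(lesion, lai[which.min(d2c), ])
}

# Small deterministic RNG wrapper: isolates synthetic-data draws from the
# caller's random stream.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed %% .Machine$integer.max))
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else rm(".Random.seed", envir = globalenv())
    s
  }
  draw <- function(fn, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else rm(".Random.seed", envir = globalenv())
    out
  }
  list(
    runif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max),
    rnorm = function(n, mean = 0, sd = 1) draw(stats::rnorm, n, mean, sd),
    rbinom = function(n, size, prob) draw(stats::rbinom, n, size, prob),
    sample = function(x, size, replace = FALSE) draw(base::sample, x, size, replace)
  )
}
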