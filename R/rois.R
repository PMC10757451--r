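#' Perilesional distance bands
#'
#' Builds the three perilesional ROIs as shells of tissue at (0,5], (5,10]
#' and (10,15] mm from the lesion boundary, using the exact Euclidean
#' distance transform rather than iterated dilation. Each band is then
#' intersected with the brain mask and the left hemisphere, and CSF voxels
#' are removed. The half-open intervals make the bands an exact partition of
#' the 0-15 mm shell before exclusions.
#'
#' @param lesion_mask logical 3D array (non-empty).
#' @param brain_mask logical 3D array.
#' @param tissue list with probability arrays `gm`, `wm`, `csf`.
#' @param grid a [vox_grid()].
#' @param breaks_mm outer edges of the bands (defaults 5, 10, 15 mm).
#' @param csf_threshold see [csf_exclusion_mask()].
#' @return list of logical arrays named `peri_0_5`, `peri_5_10`,
#'   `peri_10_15` (names derived from `breaks_mm`), with attribute
#'   `empty_bands` naming any band left empty after exclusions.
#' @export
perilesional_bands <- function(lesion_mask, brain_mask, tissue, grid,
                               breaks_mm = c(5, 10, 15),
                               csf_threshold = 0.5) {
  d <- distance_to_lesion(lesion_mask, grid)
  left <- hemisphere_masks(grid)$left
  keep <- brain_mask & left & !csf_exclusion_mask(tissue, csf_threshold) &
    !lesion_mask
  lo <- c(0, breaks_mm[-length(breaks_mm)])
  bands <- lapply(seq_along(breaks_mm), function(i)
    (d > lo[i]) & (d <= breaks_mm[i]) & keep)
  names(bands) <- sprintf("peri_%g_%g", lo, breaks_mm)
  empty <- names(bands)[!vapply(bands, any, logical(1))]
  if (length(empty))
    warning("perilesional band(s) empty after exclusions: ",
            paste(empty, collapse = ", "), call. = FALSE)
  attr(bands, "empty_bands") <- empty
  bands
}

#' CSF exclusion rule
#'
#' A voxel is excluded as cerebrospinal fluid when its CSF probability is at
#' least `threshold` and CSF is the most probable tissue there.
#'
#' @param tissue list with `gm`, `wm`, `csf` probability arrays.
#' @param threshold CSF probability cut-off (default 0.5).
#' @return logical array of voxels to exclude.
#' @export
csf_exclusion_mask <- function(tissue, threshold = 0.5) {
  (tissue$csf >= threshold) & (tissue$csf >= tissue$gm) &
    (tissue$csf >= tissue$wm)
}

#' Effective atlas ROI masks with exclusion rules and lesion load
#'
#' For every atlas label, removes lesioned voxels, CSF voxels and voxels
#' outside the brain mask from the original ROI, and computes the lesion
#' load as the percentage of the *original* ROI voxels covered by the
#' lesion. Control subjects pass `lesion_mask = NULL` (no lesion exclusion,
#' lesion load 0).
#'
#' @param atlas integer 3D array of ROI labels (0 = background).
#' @param lookup data.frame with columns `label`, `name`, `hemisphere`
#'   ("L"/"R"), `class` ("perisylvian"/"control"), `homologue` (label of the
#'   mirror ROI).
#' @param brain_mask logical 3D array.
#' @param tissue list with `gm`, `wm`, `csf` probability arrays.
#' @param lesion_mask logical 3D array or NULL.
#' @param csf_threshold passed to [csf_exclusion_mask()].
#' @return list with `masks` (named list of logical effective masks, one per
#'   label) and `table` (data.frame: roi, name, hemisphere, class,
#'   original_voxels, effective_voxels, lesion_load).
#' @export
prepare_atlas_rois <- function(atlas, lookup, brain_mask, tissue,
                               lesion_mask = NULL, csf_threshold = 0.5) {
  labels_present <- setdiff(sort(unique(as.integer(atlas))), 0L)
  unknown <- setdiff(labels_present, lookup$label)
  if (length(unknown))
    stop("atlas contains label(s) absent from the lookup table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  csf_out <- csf_exclusion_mask(tissue, csf_threshold)
  has_lesion <- !is.null(lesion_mask) && any(lesion_mask)
  masks <- list()
  rows <- lapply(seq_len(nrow(lookup)), function(i) {
    lab <- lookup$label[i]
    original <- atlas == lab
    n_orig <- sum(original)
    lesioned <- if (has_lesion) sum(original & lesion_mask) else 0L
    eff <- original & brain_mask & !csf_out
    if (has_lesion) eff <- eff & !lesion_mask
    masks[[as.character(lab)]] <<- eff
    data.frame(roi = lab, name = lookup$name[i],
               hemisphere = lookup$hemisphere[i], class = lookup$class[i],
               original_voxels = n_orig, effective_voxels = sum(eff),
               lesion_load = if (n_orig > 0) 100 * lesioned / n_orig else NA_real_)
  })
  tab <- do.call(rbind, rows)
  fully_gone <- tab$roi[tab$effective_voxels == 0]
  if (length(fully_gone))
    warning("ROI(s) with empty effective mask: ",
            paste(fully_gone, collapse = ", "), call. = FALSE)
  list(masks = masks, table = tab)
}
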