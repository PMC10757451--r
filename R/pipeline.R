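#' Write a cohort to disk
#'
#' One directory per subject with NIfTI-1 volumes (ASL 4D series, optional
#' M0, brain mask, GM/WM/CSF probability maps, lesion mask for patients)
#' plus shared `atlas.nii.gz`, `lookup.tsv`, `cohort.csv` and a JSON sidecar
#' with grid, acquisition parameters per subject and the generator seed.
#'
#' @param cohort bundle from [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- cohort$grid
  pix <- grid$voxel_mm
  wv <- function(vol, path) {
    img <- RNifti::asNifti(vol * 1)
    RNifti::pixdim(img) <- pix
    RNifti::writeNifti(img, path)
  }
  wv(cohort$atlas, file.path(out_dir, "atlas.nii.gz"))
  utils::write.table(cohort$lookup, file.path(out_dir, "lookup.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  acq_list <- list()
  for (s in cohort$subjects) {
    sd <- file.path(out_dir, s$id)
    dir.create(sd, showWarnings = FALSE)
    wv(s$asl, file.path(sd, "asl.nii.gz"))
    if (!is.null(s$m0)) wv(s$m0, file.path(sd, "m0.nii.gz"))
    wv(s$brain_mask, file.path(sd, "brain_mask.nii.gz"))
    wv(s$tissue$gm, file.path(sd, "gm.nii.gz"))
    wv(s$tissue$wm, file.path(sd, "wm.nii.gz"))
    wv(s$tissue$csf, file.path(sd, "csf.nii.gz"))
    if (!is.null(s$lesion)) wv(s$lesion, file.path(sd, "lesion.nii.gz"))
    acq_list[[s$id]] <- unclass(s$acq)
  }
  utils::write.csv(cohort$table, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(grid = list(shape = grid$shape, voxel_mm = grid$voxel_mm,
                     origin_mm = grid$origin_mm, lr_axis = grid$lr_axis),
         seed = cohort$seed, acq = acq_list),
    file.path(out_dir, "sidecar.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Validate and load a cohort directory
#'
#' Reads everything [write_cohort()] wrote, checks that all of a subject's
#' volumes share one grid, that lesion masks are binary, that the cohort
#' table has the required columns and that every ASL series has an even
#' number of volumes. All problems are collected and reported at once.
#'
#' @param dir cohort directory.
#' @return an in-memory cohort bundle (same shape as [simulate_cohort()]
#'   output, without ground truth).
#' @export
validate_and_load <- function(dir) {
  problems <- character(0)
  need <- function(path) {
    if (!file.exists(path)) {
      problems <<- c(problems, paste("missing file:", path))
      return(FALSE)
    }
    TRUE
  }
  if (!need(file.path(dir, "sidecar.json")) ||
      !need(file.path(dir, "cohort.csv")) ||
      !need(file.path(dir, "atlas.nii.gz")) ||
      !need(file.path(dir, "lookup.tsv")))
    stop("cohort directory invalid:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  side <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                              simplifyVector = TRUE)
  grid <- vox_grid(side$grid$shape, side$grid$voxel_mm,
                   side$grid$origin_mm, side$grid$lr_axis)
  tab <- utils::read.csv(file.path(dir, "cohort.csv"),
                         stringsAsFactors = FALSE)
  req_cols <- c("id", "group", "age", "sex", "months_post_onset", "site",
                "lesion_volume")
  miss <- setdiff(req_cols, names(tab))
  if (length(miss))
    problems <- c(problems, paste("cohort.csv missing column(s):",
                                  paste(miss, collapse = ", ")))
  lookup <- utils::read.delim(file.path(dir, "lookup.tsv"),
                              stringsAsFactors = FALSE)
  rv <- function(path) {
    v <- RNifti::readNifti(path)
    array(as.numeric(v), dim = dim(v))
  }
  atlas_raw <- rv(file.path(dir, "atlas.nii.gz"))
  atlas <- array(as.integer(round(atlas_raw)), dim = dim(atlas_raw))
  if (!identical(dim(atlas), as.integer(grid$shape)))
    problems <- c(problems, "atlas grid does not match sidecar grid")

  subjects <- list()
  for (i in seq_len(nrow(tab))) {
    id <- tab$id[i]
    sd <- file.path(dir, id)
    if (!dir.exists(sd)) {
      problems <- c(problems, paste("missing subject directory:", id))
      next
    }
    acq_raw <- side$acq[[id]]
    acq <- acq_params(alpha = acq_raw$alpha, t1_blood = acq_raw$t1_blood,
                      tau = acq_raw$tau, pld = acq_raw$pld,
                      lambda_p = acq_raw$lambda_p, m0_mode = acq_raw$m0_mode,
                      pair_order = acq_raw$pair_order)
    asl_img <- RNifti::readNifti(file.path(sd, "asl.nii.gz"))
    asl <- array(as.numeric(asl_img), dim = dim(asl_img))
    if (!identical(dim(asl)[1:3], as.integer(grid$shape)))
      problems <- c(problems, paste(id, ": ASL grid mismatch"))
    if (dim(asl)[4] %% 2 != 0)
      problems <- c(problems, paste(id, ": ASL series has an odd number of volumes"))
    m0 <- NULL
    if (acq$m0_mode == "separate_volume") {
      if (need(file.path(sd, "m0.nii.gz"))) m0 <- rv(file.path(sd, "m0.nii.gz"))
    }
    brain <- rv(file.path(sd, "brain_mask.nii.gz")) > 0.5
    tissue <- list(gm = rv(file.path(sd, "gm.nii.gz")),
                   wm = rv(file.path(sd, "wm.nii.gz")),
                   csf = rv(file.path(sd, "csf.nii.gz")))
    for (tn in names(tissue))
      if (!identical(dim(tissue[[tn]]), as.integer(grid$shape)))
        problems <- c(problems, paste(id, ":", tn, "grid mismatch"))
    lesion <- NULL
    lf <- file.path(sd, "lesion.nii.gz")
    if (file.exists(lf)) {
      lraw <- rv(lf)
      vals <- unique(as.vector(lraw))
      if (!all(vals %in% c(0, 1)))
        problems <- c(problems,
                      paste0(id, ": lesion mask in ", lf,
                             " is not binary (values ",
                             paste(utils::head(sort(vals), 5), collapse = ", "),
                             ")"))
      lesion <- lraw > 0.5
    }
    subjects[[i]] <- list(id = id, group = tab$group[i], site = tab$site[i],
                          acq = acq, asl = asl, m0 = m0, brain_mask = brain,
                          tissue = tissue, lesion = lesion)
  }
  if (length(problems))
    stop("cohort directory invalid:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  list(subjects = subjects, grid = grid, atlas = atlas, lookup = lookup,
       table = tab, seed = side$seed)
}

format_csv_num <- function(df) {
  for (nm in names(df))
    if (is.numeric(df[[nm]])) df[[nm]] <- signif(df[[nm]], 6)
  df
}

write_stage_csv <- function(df, path) {
  utils::write.csv(format_csv_num(df), path, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes quantification, ROI construction, perfusion metrics, group
#' comparisons (between-group per ROI, paired left/right, asymmetry,
#' lesioned-versus-spared, lesion-load correlations, perilesional band
#' comparisons), the partial-correlation grids and the lasso models, writing
#' every table as CSV plus a JSON provenance record. Stages needing both
#' groups or language scores are skipped, with the reason logged, when the
#' cohort lacks them.
#'
#' @param cohort in-memory cohort bundle ([simulate_cohort()] output or
#'   [validate_and_load()] result).
#' @param out_dir output directory for result tables.
#' @param family_alpha family-wise alpha.
#' @param gate_alpha cascade gate alpha.
#' @param csf_threshold CSF exclusion threshold.
#' @return list of all result tables (invisibly also written to
#'   `out_dir`).
#' @export
run_all <- function(cohort, out_dir = NULL, family_alpha = 0.05,
                    gate_alpha = 0.05, csf_threshold = 0.5) {
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  note("metrics: quantifying CBF and computing ROI summaries for ",
       length(cohort$subjects), " subjects")
  results$metrics <- stage("metrics", cohort_metrics(cohort, csf_threshold))
  results$asymmetry <- stage("metrics",
                             asymmetry_table(results$metrics, cohort$lookup))

  both_groups <- all(c("aphasia", "control") %in% cohort$table$group)
  if (both_groups) {
    note("group-compare: between-group cascade per ROI")
    results$group_comparison <- compare_groups_all_rois(
      results$metrics, cohort$lookup, family_alpha, gate_alpha)
    results$left_right <- compare_left_right(
      results$metrics, cohort$lookup, family_alpha, gate_alpha)
    results$asymmetry_tests <- compare_asymmetry(
      results$metrics, cohort$lookup, family_alpha, gate_alpha)
  } else {
    note("group-compare: skipped (need both groups)")
  }

  has_aphasia <- "aphasia" %in% cohort$table$group
  outcomes <- intersect(c("information_content", "fluency", "repetition",
                          "naming", "auditory_comprehension", "aq"),
                        names(cohort$table))
  has_scores <- has_aphasia && length(outcomes) > 0 &&
    any(is.finite(as.matrix(
      cohort$table[cohort$table$group == "aphasia", outcomes])))
  if (has_aphasia) {
    note("lesion analyses: lesion-load correlations and band comparisons")
    results$lesionload_correlations <- lesionload_correlations(
      results$metrics, cohort$lookup)
    results$perilesional <- compare_perilesional_bands(results$metrics,
                                                       gate_alpha)
  } else {
    note("lesion analyses: skipped (no aphasia group)")
  }
  if (has_scores) {
    note("correlate: partial-correlation grids (two covariate sets)")
    results$partial_correlations <- rbind(
      correlate_language(results$metrics, cohort$table, cohort$lookup,
                         "lesion_volume", outcomes,
                         family_alpha = family_alpha),
      correlate_language(results$metrics, cohort$table, cohort$lookup,
                         "lesion_volume_and_load", outcomes,
                         family_alpha = family_alpha))
    note("lasso: LOO-CV penalty selection per outcome")
    fits <- lapply(outcomes, function(o)
      fit_language_lasso(results$metrics, cohort$table, cohort$lookup, o))
    names(fits) <- outcomes
    results$lasso_fits <- fits
    results$lasso_table <- lasso_table(fits)
  } else {
    note("correlate/lasso: skipped (no language scores in cohort)")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in setdiff(names(results), "lasso_fits"))
      if (is.data.frame(results[[nm]]))
        write_stage_csv(results[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    jsonlite::write_json(
      list(package_version = as.character(utils::packageVersion("perfband")),
           seed = cohort$seed, family_alpha = family_alpha,
           gate_alpha = gate_alpha, csf_threshold = csf_threshold,
           n_subjects = length(cohort$subjects),
           stage_rows = lapply(Filter(is.data.frame, results), nrow),
           log = log_lines),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(results)
}
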