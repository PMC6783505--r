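#' Pipeline configuration
#'
#' Aggregates every tunable of the subject- and cohort-level pipeline so that
#' nothing is hard-coded: the fit configuration, the mask-morphology radii,
#' the rFW threshold, and the z-score clustering parameters. Radii are in
#' voxel units of the working grid.
#'
#' @param fit a [fw_fit_config()].
#' @param r_small GM/CSF guard-band dilation radius (voxels).
#' @param r_brain brain-mask erosion radius (voxels).
#' @param wmh_dilation WMH penumbra dilation radius (voxels).
#' @param threshold rFW threshold.
#' @param z_min inclusive z threshold for cluster maps.
#' @param min_cluster minimum surviving cluster size (voxels).
#' @param connectivity 6, 18 or 26.
#' @param b_tolerance,min_directions gradient-shell QA parameters, see
#'   [check_single_shell()].
#' @param se_type structuring-element shape for all morphology.
#' @param seed master seed; copied into the fit configuration.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(fit = fw_fit_config(),
                            r_small = 1, r_brain = 15, wmh_dilation = 2,
                            threshold = 0.1, z_min = 2, min_cluster = 10,
                            connectivity = 26,
                            b_tolerance = 50, min_directions = 41,
                            se_type = c("ball", "cube"), seed = 1L) {
  stopifnot(inherits(fit, "fw_fit_config"))
  if (any(c(r_small, r_brain, wmh_dilation) < 0)) stop("radii must be >= 0")
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must be in (0, 1)")
  fit$seed <- as.integer(seed)
  structure(list(fit = fit, r_small = r_small, r_brain = r_brain,
                 wmh_dilation = wmh_dilation, threshold = threshold,
                 z_min = z_min, min_cluster = min_cluster,
                 connectivity = as.integer(connectivity),
                 b_tolerance = b_tolerance, min_directions = min_directions,
                 se_type = match.arg(se_type), seed = as.integer(seed)),
            class = "pipeline_config")
}

# Internal: one QA check record.
.qa_check <- function(name, pass, messages = character(0), code = NULL) {
  list(name = name, pass = pass, messages = messages,
       code = if (pass) NULL else code)
}

#' Subject-level quality assurance
#'
#' Programmatic checks run before any fitting: single-shell gradient QA, grid
#' consistency of all volumes, and mask sanity (non-empty brain and WM).
#' Failing subjects are excluded from downstream statistics, each with a
#' machine-readable reason code.
#'
#' @param dwi a [dwi_series()].
#' @param tissues a [tissue_maps()].
#' @param config a [pipeline_config()].
#' @param subject_id identifier for the report.
#' @return list of class `qa_report` with `subject_id`, `pass`, `checks`,
#'   `reason_codes`.
#' @export
qa_subject <- function(dwi, tissues, config = pipeline_config(),
                       subject_id = "subject") {
  checks <- list()
  shell <- check_single_shell(dwi$gtab, b_tolerance = config$b_tolerance,
                              min_directions = config$min_directions)
  checks$shell <- .qa_check("gradient_shell", shell$pass, shell$messages,
                            code = "bad_gradient_shell")
  grid_ok <- tryCatch({
    assert_same_grid(dwi = dwi, wm = tissues$wm, gm = tissues$gm,
                     csf = tissues$csf, brain = tissues$brain,
                     wmh = tissues$wmh)
    TRUE
  }, error = function(e) conditionMessage(e))
  checks$grid <- .qa_check("grid_consistency", isTRUE(grid_ok),
                           if (!isTRUE(grid_ok)) grid_ok else character(0),
                           code = "grid_mismatch")
  mask_ok <- any(tissues$brain) && any(tissues$wm)
  checks$masks <- .qa_check("mask_sanity", mask_ok,
                            if (!mask_ok) "empty brain or WM mask" else character(0),
                            code = "empty_mask")
  codes <- unlist(lapply(checks, `[[`, "code"))
  structure(list(subject_id = subject_id,
                 pass = all(vapply(checks, `[[`, TRUE, "pass")),
                 checks = checks,
                 reason_codes = if (is.null(codes)) character(0) else codes),
            class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("<qa_report> %s: %s\n", x$subject_id,
              if (x$pass) "PASS" else paste("FAIL:", paste(x$reason_codes,
                                                           collapse = ", "))))
  invisible(x)
}

#' Run the full subject-level pipeline
#'
#' Reads the subject's DWI and masks, runs QA, fits the free-water model
#' inside the brain mask, builds the safe-WM and expanded-WMH masks, and
#' extracts the four metric records. Subjects failing QA are skipped and the
#' failure recorded; nothing stochastic happens outside `config$seed`, so
#' re-running with the same inputs reproduces the outputs.
#'
#' @param dwi_path,bval_path,bvec_path the DWI series and its gradient table.
#' @param wm_path,gm_path,csf_path,brain_path binary tissue and brain masks.
#' @param wmh_path optional WMH lesion mask (missing means no lesions).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, the FW maps
#'   ([write_freewater()]), the derived masks and `metrics.csv` are written
#'   there.
#' @param subject_id subject identifier.
#' @return list with `metrics` (data frame or `NULL` when excluded), `qa`
#'   (a [qa_subject()] report), `fit` (the `freewater_fit` or `NULL`).
#' @export
run_subject <- function(dwi_path, bval_path, bvec_path,
                        wm_path, gm_path, csf_path, brain_path,
                        wmh_path = NULL,
                        config = pipeline_config(), out_dir = NULL,
                        subject_id = "subject") {
  paths <- c(dwi_path, bval_path, bvec_path, wm_path, gm_path, csf_path,
             brain_path, wmh_path)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing input file(s): ",
                            paste(missing, collapse = ", "))
  dwi <- read_dwi(dwi_path, bval_path, bvec_path)
  wm <- read_volume(wm_path, as_mask = TRUE)
  gm <- read_volume(gm_path, as_mask = TRUE)
  csf <- read_volume(csf_path, as_mask = TRUE)
  brain <- read_volume(brain_path, as_mask = TRUE)
  wmh <- if (!is.null(wmh_path)) read_volume(wmh_path, as_mask = TRUE) else NULL
  tissues <- tissue_maps(wm, gm, csf, brain, wmh)
  qa <- qa_subject(dwi, tissues, config, subject_id)
  if (!qa$pass)
    return(list(metrics = NULL, qa = qa, fit = NULL))

  fit <- fit_freewater(dwi, mask = tissues$brain, config = config$fit,
                       keep_data = FALSE)
  wm_safe <- build_wm_safe(tissues, r_small = config$r_small,
                           r_brain = config$r_brain, se_type = config$se_type)
  wmh_exp <- expand_wmh(tissues$wmh, radius = config$wmh_dilation,
                        se_type = config$se_type)
  metrics <- subject_metrics(fit$f_map, tissues, wm_safe, wmh_exp,
                             threshold = config$threshold,
                             subject_id = subject_id)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_freewater(fit, out_dir, prefix = subject_id)
    write_volume(wm_safe, file.path(out_dir, paste0(subject_id, "_wm_safe.nii.gz")))
    write_volume(wmh_exp, file.path(out_dir, paste0(subject_id, "_wmh_expanded.nii.gz")))
    write_metrics_csv(metrics, file.path(out_dir, paste0(subject_id, "_metrics.csv")))
  }
  list(metrics = metrics, qa = qa, fit = fit)
}

#' Run the cohort-level analysis
#'
#' Joins subject metrics with demographics and produces the
#' group-comparison report (log-scale ANOVA + Tukey-Kramer per metric). When
#' spatially aligned FW volumes are supplied, also computes the z-score
#' cluster maps of each patient group against the reference (first) group:
#' each patient is z-scored voxelwise against the reference group's
#' mean/SD, the z-volumes are averaged within the patient group, thresholded
#' at `z >= z_min`, and only clusters of `min_cluster` or more voxels kept.
#'
#' @param metrics data frame of metric records (or path to a metrics CSV).
#' @param demographics data frame with subject_id/group/age/gender (or path
#'   to a CSV).
#' @param config a [pipeline_config()].
#' @param fw_volumes optional named list (by subject id) of aligned FW
#'   [scalar_volume()] objects for the cluster maps.
#' @param reference_group group used as z-score reference; defaults to the
#'   first group level (NC when present).
#' @param out_dir optional directory for `cohort_report.csv/.json` and
#'   cluster-map NIfTI/CSV outputs.
#' @return list with `report` ([cohort_report()]), `table`
#'   ([cohort_table()]), and `zmaps` (named list of [threshold_clusters()]
#'   results, or `NULL`).
#' @export
run_cohort <- function(metrics, demographics, config = pipeline_config(),
                       fw_volumes = NULL, reference_group = NULL,
                       out_dir = NULL) {
  if (is.character(metrics)) metrics <- read_metrics_csv(metrics)
  if (is.character(demographics)) {
    if (!file.exists(demographics)) stop("file not found: ", demographics)
    demographics <- utils::read.csv(demographics, stringsAsFactors = FALSE)
  }
  tab <- cohort_table(metrics, demographics)
  grp <- .group_factor(tab$group)
  if (nlevels(droplevels(grp)) < 2L)
    stop("cohort has a single group; nothing to compare")
  report <- cohort_report(tab)
  zmaps <- NULL
  if (!is.null(fw_volumes)) {
    if (is.null(names(fw_volumes)) ||
        !all(tab$subject_id %in% names(fw_volumes)))
      stop("'fw_volumes' must be a named list covering every subject")
    if (is.null(reference_group)) reference_group <- levels(grp)[1L]
    ref_ids <- tab$subject_id[tab$group == reference_group]
    ref <- group_reference(fw_volumes[ref_ids])
    zmaps <- list()
    for (g in setdiff(levels(droplevels(grp)), reference_group)) {
      ids <- tab$subject_id[tab$group == g]
      zs <- lapply(fw_volumes[ids], subject_zscore, ref = ref)
      zbar <- mean_zscore(zs)
      zmaps[[paste0(g, "_vs_", reference_group)]] <-
        threshold_clusters(zbar, z_min = config$z_min,
                           min_size = config$min_cluster,
                           connectivity = config$connectivity)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_report(report, file.path(out_dir, "cohort_report.csv"),
                        file.path(out_dir, "cohort_report.json"))
    for (nm in names(zmaps))
      write_cluster_map(zmaps[[nm]],
                        file.path(out_dir, paste0("clusters_", nm, ".nii.gz")),
                        file.path(out_dir, paste0("clusters_", nm, ".csv")))
  }
  list(report = report, table = tab, zmaps = zmaps)
}

#' End-to-end synthetic study: simulate, fit, measure, compare
#'
#' Generates the cohort one subject at a time (so memory stays flat), fits
#' the free-water model inside each subject's brain mask, extracts the
#' metric records, and returns everything needed for the cohort statistics
#' together with the ground-truth table. This is the package's power- and
#' validation-study driver.
#'
#' @param pspec a [phantom_spec()].
#' @param cspec a [cohort_spec()].
#' @param config a [pipeline_config()]; its radii must suit the phantom
#'   geometry (the brain erosion radius scales with the grid).
#' @param keep_fw also return each subject's fitted FW map (for z-score
#'   cluster maps); needs memory proportional to cohort size.
#' @return list with `metrics` (fitted metric records for all subjects),
#'   `demographics`, `truth` (ground-truth records), and optionally `fw`
#'   (named list of fitted FW maps).
#' @export
run_synthetic_cohort <- function(pspec, cspec, config = pipeline_config(),
                                 keep_fw = FALSE) {
  plan <- .cohort_plan(pspec, cspec)
  metrics <- vector("list", nrow(plan))
  truth <- vector("list", nrow(plan))
  fw <- if (keep_fw) stats::setNames(vector("list", nrow(plan)),
                                     plan$subject_id) else NULL
  for (i in seq_len(nrow(plan))) {
    ph <- make_phantom(.subject_spec(pspec, plan[i, ]))
    wm_safe <- build_wm_safe(ph$tissues, r_small = config$r_small,
                             r_brain = config$r_brain,
                             se_type = config$se_type)
    wmh_exp <- expand_wmh(ph$tissues$wmh, radius = config$wmh_dilation,
                          se_type = config$se_type)
    truth[[i]] <- subject_metrics(ph$true_f, ph$tissues, wm_safe, wmh_exp,
                                  threshold = config$threshold,
                                  subject_id = plan$subject_id[i])
    fit <- fit_freewater(ph$dwi, mask = ph$tissues$brain, config = config$fit,
                         keep_data = FALSE)
    metrics[[i]] <- subject_metrics(fit$f_map, ph$tissues, wm_safe, wmh_exp,
                                    threshold = config$threshold,
                                    subject_id = plan$subject_id[i])
    if (keep_fw) fw[[plan$subject_id[i]]] <- fit$f_map
  }
  list(metrics = do.call(rbind, metrics),
       demographics = plan[, c("subject_id", "group", "age", "gender")],
       truth = do.call(rbind, truth),
       fw = fw)
}
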