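#' Pipeline configuration
#'
#' @param registration [registration_config] shared by the rigid, intensity
#'   DIR and ROI stages.
#' @param blend_mm combined-CT seam blend width.
#' @param policy [art_policy] for the recommendation.
#' @param gamma [gamma_criteria] default criteria.
#' @return A list of class `adaptcheck_config`.
#' @export
adaptcheck_config <- function(registration = registration_config(),
                              blend_mm = 5, policy = art_policy(),
                              gamma = gamma_criteria()) {
  structure(list(registration = registration, blend_mm = blend_mm,
                 policy = policy, gamma = gamma),
            class = "adaptcheck_config")
}

.stage_error <- function(stage, manifest, parent) {
  stop(structure(class = c("adaptcheck_stage_error", "error", "condition"),
                 list(message = sprintf(
                   "stage '%s' failed: %s\ninputs manifest: %s",
                   stage, conditionMessage(parent),
                   paste(names(manifest), unlist(manifest), sep = "=",
                         collapse = ", ")),
                   call = NULL, stage = stage)))
}

# read inputs from a phantom case or a named list of file paths
.import_inputs <- function(case = NULL, paths = NULL) {
  if (!is.null(case)) {
    stopifnot(inherits(case, "phantom_case"))
    return(list(planning_ct = case$planning_ct, structures = case$structures,
                plan = case$plan, cbct = case$cbct,
                fraction_structures = case$fraction_structures,
                reference_dose = case$reference_dose,
                manifest = list(source = "phantom_case", seed = case$seed)))
  }
  need <- c("planning_ct", "structures", "plan", "cbct", "fraction_structures")
  manifest <- lapply(paths, function(p) p)
  for (k in need)
    if (is.null(paths[[k]]))
      stop("missing required input '", k, "'")
  ct <- read_image_series(paths$planning_ct, role = "planning_ct")
  list(planning_ct = ct,
       structures = read_structures(paths$structures, ct$grid),
       plan = read_plan(paths$plan),
       cbct = read_image_series(paths$cbct, role = "cbct"),
       fraction_structures = read_structures(paths$fraction_structures),
       reference_dose = if (!is.null(paths$reference_dose))
         read_dose(paths$reference_dose) else NULL,
       manifest = manifest)
}

# Registration stages shared by the full check and cohort studies:
# prealign + rigid, HU calibration, combined CT, intensity DIR + dpCT,
# label masks + ROI registration + target propagation.
.registration_stages <- function(ins, config = adaptcheck_config()) {
  ct <- ins$planning_ct
  log <- list()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  pre <- prealign(ct, ins$cbct, ins$plan$isocenter)
  rigid <- register_rigid(ct, ins$cbct, pre, config$registration)
  log$rigid_s <- tic() - t0
  t0 <- tic()
  # pulling the CT onto the CBCT grid needs the CBCT->CT mapping, i.e. the
  # inverse of the registered (CT -> CBCT) transform
  ct_aligned <- resample(ct, ins$cbct$grid, invert_rigid(rigid))
  sct <- calibrate_hu(ins$cbct, ct_aligned)
  combined <- build_combined_ct(ct, sct, rigid, blend_mm = config$blend_mm)
  log$combined_s <- tic() - t0
  t0 <- tic()
  dvf_dir <- register_bspline(combined, ct, config = config$registration)
  dpct <- make_deformed_ct(ct, dvf_dir, combined$grid)
  log$dir_s <- tic() - t0
  t0 <- tic()
  # fraction-day masks on the planning grid: influencers (and skin) come
  # from the supplied fraction-day segmentation, rigid organs from DIR
  # propagation of the planning contours
  infl <- names(ins$fraction_structures$masks)[
    ins$fraction_structures$roles == "influencer"]
  fov_ct <- attr(combined, "fov")
  frac_masks <- list(); frac_roles <- character(0)
  for (nm in infl) {
    m <- resample_mask(ins$fraction_structures$masks[[nm]],
                       ins$fraction_structures$grid, ct$grid, rigid)
    # fraction-day segmentation only exists inside the CBCT field of view;
    # outside it the planning delineation is used directly
    plan_m <- get_mask(ins$structures, nm)
    if (!is.null(plan_m)) m <- (m & fov_ct) | (plan_m & !fov_ct)
    frac_masks[[nm]] <- m
    frac_roles[nm] <- "influencer"
  }
  rigid_org <- names(ins$structures$masks)[ins$structures$roles == "rigid_organ"]
  for (nm in rigid_org) {
    frac_masks[[nm]] <- propagate_mask(ins$structures$masks[[nm]], ct$grid,
                                       dvf_dir)
    frac_roles[nm] <- "rigid_organ"
  }
  frac_ss <- structure_set(frac_masks, ct$grid, frac_roles)
  labels_plan <- build_label_mask(ins$structures)
  labels_frac <- build_label_mask(frac_ss)
  dvf_roi <- register_roi(labels_plan, labels_frac, config$registration)
  tnames <- names(ins$structures$masks)[ins$structures$roles == "target"]
  targets_plan <- structure_set(ins$structures$masks[tnames], ct$grid,
                                setNames(rep("target", length(tnames)), tnames))
  targets_frac <- propagate_targets(targets_plan, dvf_roi)
  log$roi_s <- tic() - t0
  all_masks <- c(frac_masks, targets_frac$masks)
  structures_fraction <- structure_set(
    all_masks, ct$grid,
    c(frac_roles, setNames(rep("target", length(targets_frac$masks)),
                           names(targets_frac$masks))))
  list(rigid = rigid, prealign = pre, sct = sct, combined = combined,
       dvf_dir = dvf_dir, dpct = dpct, dvf_roi = dvf_roi,
       targets_frac = targets_frac, structures_fraction = structures_fraction,
       labels_plan = labels_plan, labels_frac = labels_frac, log = log)
}

#' Run the full adaptive check on one fraction
#'
#' Executes the eight-step workflow: import; isocenter-prealigned rigid
#' registration and combined-CT construction; HU calibration (synthetic CT);
#' adoption of the fraction-day influencer segmentation; intensity DIR with
#' rigid-organ contour propagation and deformed-CT production; label-mask
#' ROI registration with CTV/PTV propagation; dose recomputation on the
#' deformed CT at the original plan's output; and dosimetric evaluation with
#' the replan recommendation.
#'
#' @param case a [phantom_case] (synthetic mode), or `NULL` when `paths`
#'   name the inputs on disk.
#' @param paths named list of input paths (`planning_ct`, `structures`,
#'   `plan`, `cbct`, `fraction_structures`, optional `reference_dose`).
#' @param out_dir when given, intermediates and the report are written here.
#' @param config an [adaptcheck_config].
#' @return A [fraction_report] with attributes `"stages"` (intermediate
#'   objects) and `"log"` (stage wall times, seconds).
#' @export
run_adaptive_check <- function(case = NULL, paths = NULL, out_dir = NULL,
                               config = adaptcheck_config()) {
  manifest <- list()
  ins <- tryCatch({
    ins <- .import_inputs(case, paths)
    manifest <- ins$manifest
    ins
  }, error = function(e) .stage_error("import", if (is.null(paths)) list(case = "case") else paths, e))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  reference_dose <- ins$reference_dose
  plan <- ins$plan
  if (is.null(reference_dose)) {
    reference_dose <- tryCatch(
      compute_plan_dose(ins$planning_ct, plan, normalization = "ptv_d98",
                        ptv_mask = get_mask(ins$structures, "PTV")),
      error = function(e) .stage_error("reference_dose", manifest, e))
    plan$output_factor <- attr(reference_dose, "output_factor")
  }
  if (is.null(plan$output_factor)) {
    # provided reference dose but no frozen output factor: recover it by
    # recomputing the reference normalization on the planning anatomy
    ref2 <- tryCatch(
      compute_plan_dose(ins$planning_ct, plan, normalization = "ptv_d98",
                        ptv_mask = get_mask(ins$structures, "PTV")),
      error = function(e) .stage_error("reference_dose", manifest, e))
    plan$output_factor <- attr(ref2, "output_factor")
  }
  stages <- tryCatch(.registration_stages(ins, config),
                     error = function(e) .stage_error("registration", manifest, e))
  if (!is.null(out_dir)) {
    write_volume(stages$sct, file.path(out_dir, "sct"))
    write_volume(stages$combined, file.path(out_dir, "combined_ct"))
    write_volume(stages$dpct, file.path(out_dir, "dpct"))
  }
  dose_fraction <- tryCatch(
    compute_plan_dose(stages$dpct, plan, normalization = "plan"),
    error = function(e) .stage_error("dose", manifest, e))
  report <- tryCatch(
    evaluate_fraction(dose_fraction, stages$structures_fraction,
                      reference_dose, ins$structures, plan),
    error = function(e) .stage_error("evaluate", manifest, e))
  report$recommendation <- art_recommendation(report, config$policy)
  stages$log$dose_s <- proc.time()[["elapsed"]] - t0
  if (!is.null(out_dir)) {
    write_volume(dose_fraction, file.path(out_dir, "dose_fraction"))
    write_report(report, file.path(out_dir, "report"))
  }
  attr(report, "stages") <- stages
  attr(report, "log") <- stages$log
  attr(report, "dose_fraction") <- dose_fraction
  report
}

#' Run a seeded synthetic cohort
#'
#' Generates `n_cases` phantom fractions, runs the registration stages on
#' each, and scores CTV/PTV propagation accuracy (DSC against the known
#' ground truth) for the three methods: rigid only, intensity DIR, and
#' structure-guided ROI registration.  With `dose = TRUE` the full dose
#' panel is computed per case.
#'
#' @param params [phantom_params].
#' @param n_cases number of fractions.
#' @param seed base seed; case `i` uses `seed + i - 1`.
#' @param dose also recompute and evaluate dose per case.
#' @param config [adaptcheck_config].
#' @param out_dir optional output directory for the summary CSVs.
#' @return A list: `dsc` (per case/structure/method), `dsc_summary`
#'   (mean and sd per structure/method), `metrics` (dose panel rows, when
#'   `dose`), `reports`.
#' @export
run_cohort <- function(params = phantom_params(), n_cases = 10L, seed = 1L,
                       dose = FALSE, config = adaptcheck_config(),
                       out_dir = NULL) {
  dsc_rows <- list()
  metric_rows <- list()
  reports <- list()
  for (i in seq_len(n_cases)) {
    case <- generate_case(params, seed = seed + i - 1L, compute_dose = dose)
    ins <- .import_inputs(case = case)
    st <- .registration_stages(ins, config)
    ctg <- case$planning_ct$grid
    for (tn in names(case$structures$masks)) {
      role <- case$structures$roles[[tn]]
      # ground truth in the rigid-aligned planning frame: the planning mask
      # pulled through the known deformation (no CBCT FOV truncation)
      gt <- propagate_mask(case$structures$masks[[tn]], ctg, case$true_dvf)
      est <- list(
        rigid = case$structures$masks[[tn]],
        dir = propagate_mask(case$structures$masks[[tn]], ctg, st$dvf_dir))
      if (role == "target") est$roi <- st$targets_frac$masks[[tn]]
      for (m in names(est))
        dsc_rows[[length(dsc_rows) + 1L]] <-
          data.frame(case = i, structure = tn, role = role, method = m,
                     dsc = dsc(est[[m]], gt), stringsAsFactors = FALSE)
    }
    if (dose) {
      rep_i <- run_adaptive_check(case = case, config = config)
      reports[[i]] <- rep_i
      mi <- rep_i$metrics
      mi$case <- i
      metric_rows[[length(metric_rows) + 1L]] <- mi
    }
  }
  dsc_df <- do.call(rbind, dsc_rows)
  agg <- aggregate(dsc ~ structure + method, dsc_df, function(v)
    c(mean = mean(v), sd = stats::sd(v)))
  dsc_summary <- data.frame(structure = agg$structure, method = agg$method,
                            mean = agg$dsc[, "mean"], sd = agg$dsc[, "sd"],
                            stringsAsFactors = FALSE)
  metrics <- if (length(metric_rows)) do.call(rbind, metric_rows) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(dsc_df, file.path(out_dir, "dsc.csv"), row.names = FALSE)
    write.csv(dsc_summary, file.path(out_dir, "dsc_summary.csv"),
              row.names = FALSE)
    if (!is.null(metrics))
      write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  }
  list(dsc = dsc_df, dsc_summary = dsc_summary, metrics = metrics,
       reports = reports)
}
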