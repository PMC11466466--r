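# Contour and dose evaluation: DSC, cumulative DVH, D_i / V_i / V_100%,
# the fraction report panel and the adaptive-replan recommendation.

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks are defined as DSC 1.0 (with a
#' warning), since nothing distinguishes them.
#'
#' @param a,b logical arrays on one grid.
#' @return Fraction in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("DSC requires masks on the same grid")
  na <- sum(a); nb <- sum(b)
  if (na == 0 && nb == 0) {
    warning("both masks empty; DSC defined as 1.0")
    return(1.0)
  }
  2 * sum(a & b) / (na + nb)
}

#' Cumulative dose-volume histogram
#'
#' For each bin edge `d`, the volume fraction of the structure receiving at
#' least `d` Gy.
#'
#' @param dose [dose_volume].
#' @param mask logical array on the dose grid; must be non-empty.
#' @param bin_width Gy (default 0.01).
#' @param structure structure name carried on the curve.
#' @return An object of class `dvh_curve` with `dose_bins`,
#'   `cumulative_volume`, `structure`, `prescription`.
#' @export
cumulative_dvh <- function(dose, mask, bin_width = 0.01, structure = "structure") {
  if (!all(dim(mask) == dose$grid$size))
    stop("mask and dose must share one grid")
  n <- sum(mask)
  if (n == 0) stop("empty mask for structure '", structure, "'")
  dv <- sort(dose$values[as.logical(mask)])
  top <- max(dv)
  bins <- seq(0, top + bin_width, by = bin_width)
  # volume fraction with dose >= d (1e-9 Gy guard against FP ties at edges)
  cv <- (n - findInterval(bins - 1e-9, dv)) / n
  structure(list(dose_bins = bins, cumulative_volume = cv,
                 structure = structure, prescription = dose$prescription),
            class = "dvh_curve")
}

#' Dose at volume (D_i)
#'
#' The largest dose received by at least `i`% of the structure volume,
#' linearly interpolated between DVH bins.
#'
#' @param dvh a [cumulative_dvh] curve.
#' @param i percent volume in (0, 100].
#' @return Gy.
#' @export
dose_at_volume <- function(dvh, i) {
  if (!length(dvh$dose_bins)) stop("empty DVH curve")
  if (i <= 0 || i > 100) stop("i must lie in (0, 100]")
  frac <- i / 100
  cv <- dvh$cumulative_volume
  bins <- dvh$dose_bins
  idx <- max(which(cv >= frac - 1e-12))
  if (idx == length(bins)) return(bins[idx])
  drop_ <- cv[idx] - cv[idx + 1]
  if (drop_ <= 0) return(bins[idx])
  bins[idx] + (cv[idx] - frac) / drop_ * (bins[idx + 1] - bins[idx])
}

#' Volume at dose (V_d, V_100%)
#'
#' @param dvh a [cumulative_dvh] curve.
#' @param d dose in Gy, or percent of prescription when
#'   `as_percent_of_prescription` is set.
#' @param as_percent_of_prescription interpret `d` as percent of the
#'   prescription attached to the curve (errors when none is).
#' @return Percent volume in `[0, 100]`.
#' @export
volume_at_dose <- function(dvh, d, as_percent_of_prescription = FALSE) {
  if (as_percent_of_prescription) {
    if (is.null(dvh$prescription))
      stop("V as percent of prescription requested but no prescription attached")
    d <- d / 100 * dvh$prescription
  }
  if (d < 0) stop("dose must be >= 0")
  bins <- dvh$dose_bins
  cv <- dvh$cumulative_volume
  if (d >= bins[length(bins)]) return(0)
  100 * approx(bins, cv, xout = d, rule = 2)$y
}

#' Gamma analysis criteria
#'
#' @param dose_tolerance percent of the global normalization (max of the
#'   reference dose).
#' @param dta distance-to-agreement in mm.
#' @param low_dose_threshold percent of normalization below which reference
#'   voxels are not evaluated.
#' @return A list of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_tolerance = 2, dta = 2, low_dose_threshold = 10) {
  if (any(c(dose_tolerance, dta, low_dose_threshold) <= 0))
    stop("all gamma criteria must be positive")
  structure(list(dose_tolerance = dose_tolerance, dta = dta,
                 low_dose_threshold = low_dose_threshold),
            class = "gamma_criteria")
}

#' 3D gamma pass rate
#'
#' Global-normalization gamma: for every reference voxel at or above the
#' low-dose threshold, the minimum over a search neighborhood (radius
#' 3 x DTA, trilinear interpolation at DTA/10 steps) of
#' `sqrt((dDose/tol)^2 + (dr/DTA)^2)`; a voxel passes when gamma <= 1.
#' The distance-sorted early break makes the neighborhood search exact.
#'
#' @param reference,evaluated [dose_volume]s; `evaluated` is resampled onto
#'   the reference grid if needed.
#' @param criteria [gamma_criteria].
#' @return Pass rate in percent, with attributes `"gamma"` (per-voxel gamma,
#'   NA where not evaluable) and `"n_evaluable"`.
#' @export
gamma_pass_rate <- function(reference, evaluated, criteria = gamma_criteria()) {
  if (!grid_equal(reference$grid, evaluated$grid, tol = 1e-6))
    evaluated <- resample(evaluated, reference$grid)
  norm <- max(reference$values)
  if (norm <= 0) stop("reference dose is empty; nothing to evaluate")
  tol_abs <- criteria$dose_tolerance / 100 * norm
  thresh_abs <- criteria$low_dose_threshold / 100 * norm
  step <- criteria$dta / 10
  reach <- 3 * criteria$dta
  s <- seq(-reach, reach, by = step)
  offs <- as.matrix(expand.grid(x = s, y = s, z = s))
  r2 <- rowSums(offs^2)
  keep <- r2 <= reach^2 + 1e-9
  offs <- offs[keep, , drop = FALSE]
  r2 <- r2[keep]
  ord <- order(r2)
  offs <- offs[ord, , drop = FALSE]
  rr <- r2[ord] / criteria$dta^2
  # physical offsets -> index offsets (orthonormal direction)
  off_idx <- sweep(offs %*% reference$grid$direction, 2L,
                   reference$grid$spacing, `/`)
  res <- gamma_cpp(reference$values, evaluated$values, reference$grid$size,
                   off_idx, rr, tol_abs, thresh_abs)
  if (res$n_evaluable == 0)
    stop("zero evaluable voxels above the low-dose threshold")
  out <- 100 * res$n_pass / res$n_evaluable
  attr(out, "gamma") <- res$gamma
  attr(out, "n_evaluable") <- res$n_evaluable
  out
}

#' Policy for the adaptive-replan recommendation
#'
#' Target rules are fixed clinical constraints (CTV V100% >= 99%,
#' PTV V100% >= 95%, CTV D99% and PTV D95% at least the prescription); the
#' OAR review margin is configurable because no published trigger rule
#' exists for the organs at risk.
#'
#' @param oar_delta percentage points of V-metric increase over the original
#'   plan that triggers a review.
#' @return A list of class `art_policy`.
#' @export
art_policy <- function(oar_delta = 5) {
  structure(list(oar_delta = oar_delta), class = "art_policy")
}

.panel_spec <- function() {
  data.frame(
    structure = c("CTV", "CTV", "PTV", "PTV", "bladder", "rectum",
                  "small_intestine", "bone_marrow", "femoral_head_l",
                  "femoral_head_r"),
    metric = c("V100%", "D99%", "V100%", "D95%", "V40Gy", "V40Gy", "V40Gy",
               "V10Gy", "V30Gy", "V30Gy"),
    stringsAsFactors = FALSE)
}

.panel_value <- function(dose, mask, metric, structure) {
  dvh <- cumulative_dvh(dose, mask, structure = structure)
  if (metric == "V100%") volume_at_dose(dvh, 100, TRUE)
  else if (grepl("^D", metric))
    dose_at_volume(dvh, as.numeric(sub("^D([0-9.]+)%$", "\\1", metric)))
  else volume_at_dose(dvh, as.numeric(sub("^V([0-9.]+)Gy$", "\\1", metric)))
}

#' Evaluate a fraction against the original plan
#'
#' Computes the dosimetric parameter panel (CTV V100%/D99%, PTV V100%/D95%,
#' bladder/rectum/bowel V40Gy, bone marrow V10Gy, femoral heads V30Gy) for
#' the original plan and the fraction recomputation, their deltas, and the
#' clinical target flags: CTV V100% < 99% fails, PTV V100% < 95% fails,
#' CTV D99% or PTV D95% below the prescription fails (pass exactly at the
#' boundary).  Missing targets are an error; missing OARs mark the metric
#' absent.
#'
#' @param dose_fraction fraction [dose_volume].
#' @param structures_fraction fraction-day [structure_set] (same grid as
#'   `dose_fraction`).
#' @param dose_original original-plan [dose_volume].
#' @param structures_original planning [structure_set].
#' @param plan [plan_info] (prescription).
#' @return An object of class `fraction_report`: `metrics` data frame
#'   (structure, metric, original, fraction, delta, flag), `prescription`,
#'   `target_pass` flags, `recommendation` (filled by
#'   [art_recommendation]).
#' @export
evaluate_fraction <- function(dose_fraction, structures_fraction,
                              dose_original, structures_original, plan) {
  rx <- plan$prescription_dose
  panel <- .panel_spec()
  tol <- 1e-6
  rows <- lapply(seq_len(nrow(panel)), function(r) {
    st <- panel$structure[r]; met <- panel$metric[r]
    m_orig <- get_mask(structures_original, st)
    m_frac <- get_mask(structures_fraction, st)
    is_target <- st %in% c("CTV", "PTV")
    if (is_target && (is.null(m_orig) || is.null(m_frac) ||
                      !any(m_orig) || !any(m_frac)))
      stop("missing target structure '", st, "'")
    if (is.null(m_orig) || is.null(m_frac) || !any(m_orig) || !any(m_frac))
      return(data.frame(structure = st, metric = met, original = NA_real_,
                        fraction = NA_real_, delta = NA_real_,
                        flag = "absent", stringsAsFactors = FALSE))
    vo <- .panel_value(dose_original, m_orig, met, st)
    vf <- .panel_value(dose_fraction, m_frac, met, st)
    flag <- "ok"
    if (is_target) {
      lim <- switch(paste(st, met),
                    "CTV V100%" = 99, "PTV V100%" = 95,
                    "CTV D99%" = rx, "PTV D95%" = rx)
      flag <- if (vf >= lim - tol) "pass" else "fail"
    }
    data.frame(structure = st, metric = met, original = vo, fraction = vf,
               delta = vf - vo, flag = flag, stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, rows)
  tp <- metrics$flag[metrics$structure %in% c("CTV", "PTV")]
  structure(list(metrics = metrics, prescription = rx,
                 target_pass = all(tp == "pass"),
                 recommendation = NULL),
            class = "fraction_report")
}

#' @export
print.fraction_report <- function(x, ...) {
  cat("Fraction report (prescription", x$prescription, "Gy)\n")
  print(x$metrics, row.names = FALSE, digits = 4)
  if (!is.null(x$recommendation))
    cat("Recommendation:", x$recommendation, "\n")
  invisible(x)
}

#' Adaptive-replan recommendation
#'
#' `adapt` when any target flag fails; `review` when any OAR V-metric
#' exceeds its original value by more than the policy margin; otherwise
#' `no_adaptation`.  Deterministic.
#'
#' @param report a [fraction_report].
#' @param policy an [art_policy].
#' @return `"no_adaptation"`, `"review"` or `"adapt"`.
#' @export
art_recommendation <- function(report, policy = art_policy()) {
  m <- report$metrics
  if (any(m$flag == "fail")) return("adapt")
  oar <- m[m$flag %in% c("ok", "absent") & grepl("^V", m$metric), ]
  deltas <- oar$delta[!is.na(oar$delta)]
  if (length(deltas) && any(deltas > policy$oar_delta)) return("review")
  "no_adaptation"
}

#' Write a fraction report to JSON and CSV
#'
#' Refuses NaN metrics (naming the offender); absent-structure NAs are
#' allowed.
#'
#' @param report a [fraction_report].
#' @param path_prefix output path without extension (`.json` and `.csv` are
#'   written).
#' @return `path_prefix`, invisibly.
#' @export
write_report <- function(report, path_prefix) {
  m <- report$metrics
  bad <- which(is.nan(m$original) | is.nan(m$fraction) | is.nan(m$delta))
  if (length(bad))
    stop("refusing to write NaN metric: ", m$structure[bad[1]], " ",
         m$metric[bad[1]])
  jsonlite::write_json(list(prescription = report$prescription,
                            target_pass = report$target_pass,
                            recommendation = report$recommendation,
                            metrics = m),
                       paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null")
  write.csv(m, paste0(path_prefix, ".csv"), row.names = FALSE)
  invisible(path_prefix)
}
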