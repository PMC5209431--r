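# Subject-level mobility metrics: R, VFPa, VFRa, VFAP and angle variants.

#' Left/right hemi-glottal ratio
#'
#' `R = left / right`. R > 1 indicates left-sided restriction (the left
#' hemi-space is the larger one during phonation when the left fold cannot
#' adduct); R < 1 the converse. Near-zero denominators yield `NA`
#' (an undefined-ratio flag) rather than an error, since a healthy glottis
#' can close completely during phonation.
#'
#' @param left,right hemi-areas (mm^2) or hemi-angles (deg).
#' @param eps guard threshold for the denominator: one pixel area
#'   (2.25 mm^2 at 1.5 mm spacing) for areas, 0.5 deg for angles.
#' @return `left / right`, or `NA` when undefined.
#' @export
lr_ratio <- function(left, right, eps = 2.25) {
  if (!is.finite(left) || !is.finite(right) || right <= eps) return(NA_real_)
  left / right
}

#' Asymmetry of the hemi-glottal ratio
#'
#' Magnitude of the deviation of R from unity, `|1 - R|`. Zero iff the two
#' hemi-spaces are equal. Note the laterality caveat: swapping sides maps
#' R to 1/R, and `|1 - R| != |1 - 1/R|` for R != 1, so the metric is not
#' invariant under left/right relabeling.
#'
#' @param r a ratio from [lr_ratio()].
#' @return `|1 - r|` (NA propagates).
#' @export
asymmetry <- function(r) {
  if (!is.finite(r)) return(NA_real_)
  abs(1 - r)
}

#' Abduction potential
#'
#' Percentage change in total glottal measure from respiration to
#' phonation: `100 * (resp - phon) / resp`. 100% means complete adduction,
#' 0% no change. A negative value (phonation larger than respiration) is
#' reported as-is with a warning.
#'
#' @param total_resp,total_phon total areas (mm^2) or summed angles (deg).
#' @param eps denominator guard, as in [lr_ratio()].
#' @return percent, or `NA` when the respiration total is below `eps`.
#' @export
vfap <- function(total_resp, total_phon, eps = 2.25) {
  if (!is.finite(total_resp) || !is.finite(total_phon) || total_resp <= eps)
    return(NA_real_)
  val <- 100 * (total_resp - total_phon) / total_resp
  if (val < 0)
    warning("negative abduction potential: phonation total exceeds respiration total")
  val
}

#' Metrics for one (subject, study, reader)
#'
#' Computes VFPa, VFRa and VFAP from period-mean hemi-areas
#' (mean-then-ratio) and the starred variants from period-mean
#' hemi-angles. Undefined components (closed glottis, invalid angles)
#' propagate as `NA` while the remaining metrics are still computed.
#'
#' @param resp,phon [period_summary()] objects for the respiration and
#'   phonation periods.
#' @param eps_area,eps_angle denominator guards (mm^2 / deg).
#' @return one-row data.frame with columns `vfpa`, `vfra`, `vfap`,
#'   `star_vfpa`, `star_vfra`, `star_vfap`.
#' @export
subject_metrics <- function(resp, phon, eps_area = 2.25, eps_angle = 0.5) {
  ang_total <- function(p)
    if (is.finite(p$mean_left_angle) && is.finite(p$mean_right_angle))
      p$mean_left_angle + p$mean_right_angle else NA_real_
  data.frame(
    vfpa = asymmetry(lr_ratio(phon$mean_left_area, phon$mean_right_area, eps_area)),
    vfra = asymmetry(lr_ratio(resp$mean_left_area, resp$mean_right_area, eps_area)),
    vfap = vfap(resp$total_area, phon$total_area, eps_area),
    star_vfpa = asymmetry(lr_ratio(phon$mean_left_angle, phon$mean_right_angle, eps_angle)),
    star_vfra = asymmetry(lr_ratio(resp$mean_left_angle, resp$mean_right_angle, eps_angle)),
    star_vfap = vfap(ang_total(resp), ang_total(phon), eps_angle)
  )
}

metric_names <- function() c("vfpa", "vfra", "vfap", "star_vfpa", "star_vfra", "star_vfap")

#' Per-frame ratio alternative (off by default in the pipeline)
#'
#' Ratio-then-mean variant: asymmetry computed per frame and then
#' averaged. Provided for sensitivity analysis; the pipeline default is
#' mean-then-ratio, which matches how period means feed the metrics. The
#' two agree when all frames are identical.
#'
#' @param lefts,rights per-frame hemi values.
#' @inheritParams lr_ratio
#' @return mean per-frame asymmetry over frames where the ratio is defined.
#' @export
framewise_asymmetry <- function(lefts, rights, eps = 2.25) {
  r <- mapply(function(l, rr) asymmetry(lr_ratio(l, rr, eps)), lefts, rights)
  if (all(!is.finite(r))) return(NA_real_)
  mean(r[is.finite(r)])
}

#' Metrics table from a frame-level measurement table
#'
#' Groups a measurement table (one row per frame) by subject, study and
#' reader, builds per-task period summaries, and computes
#' [subject_metrics()] for each group.
#'
#' @param measurements data.frame with columns `subject`, `study`,
#'   `reader`, `task`, `left_area`, `right_area`, `left_angle`,
#'   `right_angle` and logical validity columns `valid_left_area`, ...,
#'   `valid_right_angle` (missing validity columns are treated as
#'   finite-value validity).
#' @param eps_area,eps_angle denominator guards passed to [subject_metrics()].
#' @return data.frame, one row per (subject, study, reader).
#' @export
metrics_from_measurements <- function(measurements, eps_area = 2.25,
                                      eps_angle = 0.5) {
  m <- measurements
  for (q in c("left_area", "right_area", "left_angle", "right_angle")) {
    vq <- paste0("valid_", q)
    if (!vq %in% names(m)) m[[vq]] <- is.finite(m[[q]])
  }
  key <- interaction(m$subject, m$study, m$reader, drop = TRUE)
  rows <- lapply(split(m, key), function(g) {
    per <- lapply(c(respiration = "respiration", phonation = "phonation"),
                  function(tk) {
      gg <- g[g$task == tk, , drop = FALSE]
      if (nrow(gg) == 0) return(NULL)
      tryCatch(
        period_summary(lapply(seq_len(nrow(gg)), function(i) row_measurement(gg[i, ]))),
        error = function(e) NULL)
    })
    met <- if (is.null(per$respiration) || is.null(per$phonation)) {
      as.data.frame(setNames(as.list(rep(NA_real_, 6)), metric_names()))
    } else {
      subject_metrics(per$respiration, per$phonation, eps_area, eps_angle)
    }
    cbind(data.frame(subject = g$subject[1], study = g$study[1],
                     reader = g$reader[1]), met)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

# One measurement-table row -> hemi_measurement object.
row_measurement <- function(r) {
  structure(list(
    left_area = r$left_area, right_area = r$right_area,
    left_angle = r$left_angle, right_angle = r$right_angle,
    valid = c(left_area = isTRUE(r$valid_left_area),
              right_area = isTRUE(r$valid_right_area),
              left_angle = isTRUE(r$valid_left_angle),
              right_angle = isTRUE(r$valid_right_angle))),
    class = "hemi_measurement")
}
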