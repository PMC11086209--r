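# Plain-text interchange: per-trial stream CSVs plus a YAML manifest tying
# them together with task windows, questionnaire scores, manual scores and
# the posture clock offset.

#' Write a cohort to CSV streams plus a YAML manifest
#'
#' Writes one RR CSV (`t_unix,rr_ms`), one marker CSV
#' (`t_unix,marker_id,rx,ry,rz,tx,ty,tz,depth_m`) and one posture CSV
#' (`t_unix,landmark_id,x,y`) per trial under `dir`, a `trials.yaml`
#' manifest, and — for synthetic cohorts — a `ground_truth.csv`.
#'
#' @param cohort a `synthetic_cohort` or plain list of [trial_record()]s.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  trials <- if (inherits(cohort, "synthetic_cohort")) cohort$trials else cohort
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt_t <- function(x) sprintf("%.6f", x)  # microsecond epoch precision
  manifest <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    stem <- sprintf("trial%02d", i)
    rrf <- file.path(dir, paste0(stem, "_rr.csv"))
    utils::write.csv(data.frame(t_unix = fmt_t(tr$rr$t), rr_ms = tr$rr$rr_ms),
                     rrf, row.names = FALSE, quote = FALSE)
    mkf <- file.path(dir, paste0(stem, "_markers.csv"))
    mk <- as.data.frame(tr$markers)
    names(mk)[names(mk) == "t"] <- "t_unix"
    mk$t_unix <- fmt_t(mk$t_unix)
    utils::write.csv(mk, mkf, row.names = FALSE, quote = FALSE)
    pof <- file.path(dir, paste0(stem, "_posture.csv"))
    po <- as.data.frame(tr$posture)
    names(po)[names(po) == "t"] <- "t_unix"
    po$t_unix <- fmt_t(po$t_unix)
    utils::write.csv(po, pof, row.names = FALSE, quote = FALSE)
    list(subject_id = tr$subject_id, group = tr$group, task_id = tr$task_id,
         task_window = as.numeric(tr$task_window),
         rr = basename(rrf), markers = basename(mkf), posture = basename(pof),
         posture_offset_s = tr$posture_offset_s,
         tlx = lapply(tr$tlx, as.integer),
         manual = lapply(tr$manual, as.integer))
  })
  path <- file.path(dir, "trials.yaml")
  # full double precision: UNIX epochs must survive the round trip
  yaml::write_yaml(manifest, path, precision = 15)
  if (inherits(cohort, "synthetic_cohort"))
    utils::write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' Read a trial manifest back into trial records
#'
#' @param path path to a `trials.yaml` written by [write_cohort()] (or by
#'   hand, following the same layout).
#' @return A list of [trial_record()] objects.
#' @export
read_cohort <- function(path) {
  manifest <- yaml::read_yaml(path)
  dir <- dirname(path)
  lapply(manifest, function(m) {
    trial_record(
      subject_id = m$subject_id, group = m$group, task_id = m$task_id,
      task_window = as.numeric(m$task_window),
      rr = read_rr_csv(file.path(dir, m$rr)),
      markers = read_marker_csv(file.path(dir, m$markers)),
      posture = read_landmark_csv(file.path(dir, m$posture)),
      posture_offset_s = m$posture_offset_s,
      tlx = do.call(surg_tlx, m$tlx[c("mental", "physical", "temporal",
                                      "complexity", "situational_stress",
                                      "distractions")]),
      manual = m$manual)
  })
}

#' Write a stress-index result as JSON
#'
#' @param bsi a `bsi_result` from [baevsky_si()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_bsi_json <- function(bsi, path) {
  jsonlite::write_json(bsi[c("mo_s", "amo_pct", "mxdmn_s", "si")], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
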