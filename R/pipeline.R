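#' Score a cohort and emit results and charts in one pass
#'
#' The batch entry point behind the command-line tool: reads the cohort and
#' LMS reference, scores every row, writes `BMI_Results.csv`, detects
#' cross-sectional vs longitudinal mode from replicated IDs, and renders one
#' chart per sex present (so a mixed-sex batch yields two files per
#' requested format). Row-level problems become QC flags and warnings; only
#' unreadable inputs are fatal, and nothing is written until both inputs
#' have loaded.
#'
#' @param input Cohort file (CSV/xlsx/xls) or a data.frame already in
#'   [read_cohort()]'s output shape.
#' @param reference LMS reference file path or an
#'   [`lms_reference`][load_lms_reference] object.
#' @param outdir Output directory (created if needed).
#' @param formats Chart formats, subset of `c("pdf", "eps")`.
#' @param y_max,y_min Chart y-axis limits, kg/m^2.
#' @param percentiles Percentile curves to draw (default 5, 50, 85, 95; the
#'   120% and 140% of P95 severe-obesity curves are always added).
#' @param charts Set `FALSE` to skip chart rendering (results only).
#' @param results Set `FALSE` to skip the results CSV (charts only).
#' @param quiet Suppress the run log.
#' @return Invisibly, a list: `results` (scored data.frame), `mode`,
#'   `n_rows`, `n_flagged`, `prevalence`, `files` (paths written).
#' @export
run_pipeline <- function(input, reference, outdir = ".",
                         formats = "pdf", y_max = 60, y_min = 10,
                         percentiles = c(5, 50, 85, 95),
                         charts = TRUE, results = TRUE, quiet = FALSE) {
  formats <- match.arg(formats, c("pdf", "eps"), several.ok = TRUE)
  cohort <- if (is.data.frame(input)) as_cohort(input) else read_cohort(input)
  ref <- if (inherits(reference, "lms_reference")) {
    reference
  } else {
    load_lms_reference(reference)
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  scored <- compute_results(cohort, ref)
  mode <- detect_mode(scored$id)
  n_flagged <- sum(scored$qc_flags != "")
  say(sprintf("read %d row(s); %d flagged; mode: %s",
              nrow(scored), n_flagged, mode))
  prev <- if (any(!is.na(scored$weight_status))) {
    prevalence_summary(scored$weight_status)
  } else {
    NULL
  }
  if (!is.null(prev) && !quiet) {
    apply(prev$categories, 1, function(r) {
      say(sprintf("  %-24s %4s  (%.1f%%)", r[["status"]], r[["n"]],
                  100 * as.numeric(r[["proportion"]])))
    })
  }
  files <- character(0)
  if (results) {
    files <- c(files, write_results(scored, dir = outdir))
  }
  if (charts) {
    plottable <- scored[!is.na(scored$bmi_kgm2) & !is.na(scored$sex) &
                          scored$qc_flags == "", , drop = FALSE]
    for (sx in intersect(c("female", "male"), unique(plottable$sex))) {
      sub <- plottable[plottable$sex == sx, , drop = FALSE]
      if (!nrow(sub)) next
      crv <- build_curves(ref, sx, percentiles = percentiles)
      sub_mode <- detect_mode(sub$id)
      spec <- chart_spec(sx, mode = sub_mode, y_max = y_max, y_min = y_min)
      ch <- bmi_chart(sub, crv, spec)
      for (fmt in formats) {
        path <- file.path(outdir, default_output_name(sx, sub_mode, fmt))
        render_chart(ch, path)
        files <- c(files, path)
        say("wrote ", path)
      }
    }
  }
  invisible(list(results = scored, mode = mode, n_rows = nrow(scored),
                 n_flagged = n_flagged, prevalence = prev, files = files))
}
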