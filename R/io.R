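# CSV readers/writers for the pipeline's tabular interfaces. Times are
# integer days from the baseline scan; missing values are empty fields.

#' Read a long-format measurement table
#'
#' Validates and reads a CSV with columns `subject_id`, `day` (integer days
#' from the baseline scan) and `sod_mm` (sum of target-lesion diameters,
#' mm); an optional `arm` column is carried through. Malformed rows are
#' reported with their line numbers; a non-positive baseline or duplicate
#' (subject, day) pairs are errors naming the offending subject.
#'
#' @param path CSV path.
#' @return Data frame sorted by subject and day.
#' @export
read_measurements <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "day", "sod_mm")
  miss <- setdiff(req, names(m))
  if (length(miss) > 0L) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(m$day) | !is.finite(m$sod_mm) | m$sod_mm < 0)
  if (length(bad) > 0L) {
    stop("malformed measurement row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(m[, c("subject_id", "day")])
  if (any(dup)) {
    stop("duplicate (subject, day) for subject(s): ",
         paste(unique(m$subject_id[dup]), collapse = ", "), call. = FALSE)
  }
  base <- m[m$day == 0, , drop = FALSE]
  nobase <- setdiff(unique(m$subject_id), base$subject_id)
  if (length(nobase) > 0L) {
    stop("no baseline (day 0) row for subject(s): ",
         paste(nobase, collapse = ", "), call. = FALSE)
  }
  bad0 <- base$subject_id[base$sod_mm <= 0]
  if (length(bad0) > 0L) {
    stop("non-positive baseline SOD for subject(s): ",
         paste(bad0, collapse = ", "), call. = FALSE)
  }
  m[order(m$subject_id, m$day), , drop = FALSE]
}

#' Read a per-subject survival table
#'
#' CSV with `subject_id`, `os_days`, `os_event`, `pfs_days`, `pfs_event`
#' and optionally `arm`, `accrual_day`, `response_category`.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_survival <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "os_days", "os_event", "pfs_days", "pfs_event")
  miss <- setdiff(req, names(s))
  if (length(miss) > 0L) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!all(s$os_event %in% c(0, 1)) || !all(s$pfs_event %in% c(0, 1))) {
    stop("event indicators must be 0/1", call. = FALSE)
  }
  both <- s$pfs_days > s$os_days
  if (any(both)) {
    stop("pfs_days > os_days for subject(s): ",
         paste(s$subject_id[both], collapse = ", "), call. = FALSE)
  }
  s
}

write_csv_na <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
}

#' Write per-subject fit results
#'
#' @param results Data frame from [fit_cohort()].
#' @param path Output CSV path.
#' @export
write_results <- function(results, path) write_csv_na(results, path)

#' Write a cohort analysis report
#'
#' Emits the analysis as deterministic CSV tables under `outdir`:
#' classification counts, per-arm g summaries (with the 1e-2/day display
#' unit), pooled quartile KM and Cox tables for OS and PFS, and the per-arm
#' concordance table.
#'
#' @param analysis A `cohort_analysis` from [analyze_cohort()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(analysis, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(x, name) {
    p <- file.path(outdir, name)
    write_csv_na(x, p)
    paths <<- c(paths, p)
  }
  cnt <- analysis$counts
  cnt <- cbind(classification = rownames(cnt), cnt)
  put(cnt, "classification_counts.csv")
  gs <- analysis$arm_comparison$summary
  gs$mann_whitney_p <- analysis$arm_comparison$p_value
  put(gs, "g_by_arm.csv")
  put(analysis$km_os_pooled, "km_os_quartiles.csv")
  put(analysis$cox_os_pooled, "cox_os_quartiles.csv")
  put(analysis$km_pfs_pooled, "km_pfs_quartiles.csv")
  put(analysis$cox_pfs_pooled, "cox_pfs_quartiles.csv")
  conc <- do.call(rbind, lapply(names(analysis$concordance), function(a) {
    data.frame(arm = a, t(analysis$concordance[[a]]))
  }))
  put(conc, "concordance.csv")
  invisible(paths)
}
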