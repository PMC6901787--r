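#' @keywords internal
"_PACKAGE"

# Canonical delimited-text headers (comma-separated, UTF-8, "." decimal).
.peak_header <- c("rt1_s", "rt2_s", "mz", "area", "snr")
.peak_cols <- c("rt1", "rt2", "mz", "area", "snr")
.manifest_header <- c("subject_id", "group", "phase", "time_h",
                      "peaks_file", "background_file", "internal_standard_area")
.physio_header <- c("subject_id", "time_h", "pao2_mmHg", "fio2",
                    "paco2_mmHg", "ph", "hr_bpm", "rr_bpm")
.physio_cols <- c("subject_id", "time_h", "pao2", "fio2", "paco2", "ph", "hr", "rr")
.marker_header <- c("name", "quant_mz", "rt1_s", "rt2_s", "weight", "sign", "cutoff")

.read_csv_checked <- function(path, expected_header, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: '%s'", what, path), call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        strip.white = TRUE, fileEncoding = "UTF-8")
  got <- names(df)
  if (anyDuplicated(got)) {
    stop(sprintf("%s '%s': duplicate column(s): %s", what, path,
                 paste(unique(got[duplicated(got)]), collapse = ", ")),
         call. = FALSE)
  }
  missing <- setdiff(expected_header, got)
  if (length(missing)) {
    stop(sprintf("%s '%s': missing column(s): %s", what, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df[expected_header]
}

# Parse a character column as numeric; report offending file lines (header = line 1).
.numeric_col <- function(x, col, path, what) {
  x <- gsub("−", "-", x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !(is.na(x) | x == "NA"))
  if (length(bad)) {
    stop(sprintf("%s '%s': non-numeric value in column '%s' at line %s (e.g. '%s')",
                 what, path, col, paste(bad[seq_len(min(3, length(bad)))] + 1L,
                                        collapse = ", "), x[bad[1]]),
         call. = FALSE)
  }
  out
}

#' Construct a validated peak table
#'
#' A peak table holds one row per detected chromatographic feature of a GCxGC
#' run: first- and second-dimension retention times (seconds), the quant-ion
#' mass-to-charge ratio, the integrated area and the signal-to-noise ratio.
#'
#' @param rt1,rt2 First/second-dimension retention times in seconds (> 0).
#' @param mz Integer quant mass-to-charge ratio (>= 1).
#' @param area Non-negative integrated abundance (arbitrary units).
#' @param snr Non-negative signal-to-noise ratio.
#' @return A `data.frame` with columns `rt1`, `rt2`, `mz`, `area`, `snr`.
#' @examples
#' peak_table(rt1 = 171.3, rt2 = 1.2, mz = 78, area = 5000, snr = 900)
#' @export
peak_table <- function(rt1 = numeric(), rt2 = numeric(), mz = integer(),
                       area = numeric(), snr = numeric()) {
  df <- data.frame(rt1 = as.numeric(rt1), rt2 = as.numeric(rt2),
                   mz = as.integer(round(mz)), area = as.numeric(area),
                   snr = as.numeric(snr))
  validate_peaks(df)
}

#' @rdname peak_table
#' @param peaks A candidate peak `data.frame`.
#' @export
validate_peaks <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  missing <- setdiff(.peak_cols, names(peaks))
  if (length(missing)) {
    stop("peak table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(peaks)) {
    if (any(peaks$rt1 <= 0) || any(peaks$rt2 <= 0)) {
      stop("retention times must be positive", call. = FALSE)
    }
    if (any(peaks$area < 0)) stop("peak areas must be non-negative", call. = FALSE)
    if (any(peaks$snr < 0)) stop("peak snr must be non-negative", call. = FALSE)
    if (any(peaks$mz < 1) || any(peaks$mz != round(peaks$mz))) {
      stop("mz must be integer >= 1", call. = FALSE)
    }
  }
  peaks[.peak_cols]
}

#' Read and write peak tables
#'
#' Peak tables are CSV files with header `rt1_s,rt2_s,mz,area,snr`, one data
#' row per detected peak. Reading validates every cell and reports malformed
#' rows with their file line number; writing renders numbers at full precision
#' so that a write/read round trip reproduces the input exactly.
#'
#' @param path File path.
#' @return `read_peak_table()` returns a peak `data.frame` (see
#'   [peak_table()]), rows in file order; `write_peak_table()` invisibly
#'   returns `path`.
#' @seealso [peak_table()]
#' @export
read_peak_table <- function(path) {
  df <- .read_csv_checked(path, .peak_header, "peak table")
  out <- data.frame(
    rt1 = .numeric_col(df$rt1_s, "rt1_s", path, "peak table"),
    rt2 = .numeric_col(df$rt2_s, "rt2_s", path, "peak table"),
    mz = as.integer(round(.numeric_col(df$mz, "mz", path, "peak table"))),
    area = .numeric_col(df$area, "area", path, "peak table"),
    snr = .numeric_col(df$snr, "snr", path, "peak table"))
  validate_peaks(out)
}

# Full-precision, locale-independent number rendering for on-disk artifacts.
.fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  out
}

.write_csv_raw <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  quote_field <- function(x) {
    needs <- grepl('[",\n]', x)
    x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
    x
  }
  cells <- vapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) .fmt_num(col)
    else quote_field(as.character(col))
  }, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  lines <- c(paste(names(df), collapse = ","),
             if (nrow(df)) apply(cells, 1L, paste, collapse = ","))
  writeLines(lines, con, useBytes = TRUE)
}

#' @rdname read_peak_table
#' @param peaks Peak `data.frame` as returned by [peak_table()].
#' @export
write_peak_table <- function(peaks, path) {
  peaks <- validate_peaks(peaks)
  out <- data.frame(rt1_s = peaks$rt1, rt2_s = peaks$rt2, mz = peaks$mz,
                    area = peaks$area, snr = peaks$snr)
  .write_csv_raw(out, path)
  invisible(path)
}

#' Load a marker-parameter table
#'
#' A marker-parameter table specifies a WDA breath-score panel: one row per
#' marker compound with its quant m/z, retention coordinates, weight, sign and
#' abundance cutoff. The package ships a six-compound oxygen-exposure reference
#' panel (benzene and five methylated alkanes/alkenes) as
#' `system.file("extdata", "marker_params.csv", package = "breathscore")`,
#' which is loaded when `path` is `NULL`.
#'
#' The `sign` column accepts both the ASCII hyphen-minus and the Unicode minus
#' sign (U+2212) that typeset tables often carry.
#'
#' @param path CSV path with columns
#'   `name,quant_mz,rt1_s,rt2_s,weight,sign,cutoff`, or `NULL` for the
#'   packaged panel.
#' @return A `data.frame` with columns `name`, `quant_mz`, `rt1`, `rt2`,
#'   `weight`, `sign`, `cutoff`, in table order.
#' @examples
#' panel <- load_marker_params()
#' sum(panel$weight)
#' @export
load_marker_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "marker_params.csv", package = "breathscore")
  }
  df <- .read_csv_checked(path, .marker_header, "marker table")
  out <- data.frame(
    name = df$name,
    quant_mz = as.integer(round(.numeric_col(df$quant_mz, "quant_mz", path, "marker table"))),
    rt1 = .numeric_col(df$rt1_s, "rt1_s", path, "marker table"),
    rt2 = .numeric_col(df$rt2_s, "rt2_s", path, "marker table"),
    weight = .numeric_col(df$weight, "weight", path, "marker table"),
    sign = .numeric_col(df$sign, "sign", path, "marker table"),
    cutoff = .numeric_col(df$cutoff, "cutoff", path, "marker table"))
  if (any(!out$sign %in% c(-1, 1))) {
    stop(sprintf("marker table '%s': sign must be -1 or +1", path), call. = FALSE)
  }
  if (any(out$weight <= 0)) {
    stop(sprintf("marker table '%s': weights must be positive", path), call. = FALSE)
  }
  if (any(out$cutoff < 0)) {
    stop(sprintf("marker table '%s': cutoffs must be non-negative", path), call. = FALSE)
  }
  out
}

#' @rdname load_marker_params
#' @param markers Marker `data.frame` as returned by `load_marker_params()`.
#' @export
write_marker_params <- function(markers, path) {
  out <- data.frame(name = markers$name, quant_mz = as.integer(markers$quant_mz),
                    rt1_s = markers$rt1, rt2_s = markers$rt2,
                    weight = markers$weight, sign = markers$sign,
                    cutoff = markers$cutoff)
  .write_csv_raw(out, path)
  invisible(path)
}

#' Read a study manifest
#'
#' The manifest lists one row per breath sample: subject, treatment group
#' (`air` or `oxygen`), phase (`baseline` for collection times at or before
#' 0 h, `exposure` afterwards), collection time in hours relative to exposure
#' start, the peak-table file for the breath sample and its paired
#' breathing-circuit background sample, and the integrated area of the spiked
#' internal-standard (bromofluorobenzene) peak.
#'
#' A complete study contributes nine samples per subject (three baseline,
#' six exposure); subjects with a different count are retained with a warning
#' so that partially collected animals still flow through screening and
#' scoring. An unknown group label is a fatal error.
#'
#' @param path Manifest CSV path with header
#'   `subject_id,group,phase,time_h,peaks_file,background_file,internal_standard_area`.
#' @return A `data.frame` in file order with those columns (`time_h` and
#'   `internal_standard_area` numeric).
#' @export
read_manifest <- function(path) {
  df <- .read_csv_checked(path, .manifest_header, "manifest")
  out <- data.frame(
    subject_id = df$subject_id,
    group = df$group,
    phase = df$phase,
    time_h = .numeric_col(df$time_h, "time_h", path, "manifest"),
    peaks_file = df$peaks_file,
    background_file = df$background_file,
    internal_standard_area =
      .numeric_col(df$internal_standard_area, "internal_standard_area", path, "manifest"))
  bad_group <- setdiff(unique(out$group), c("air", "oxygen"))
  if (length(bad_group)) {
    stop(sprintf("manifest '%s': unknown group(s): %s", path,
                 paste(bad_group, collapse = ", ")), call. = FALSE)
  }
  bad_phase <- (out$time_h <= 0) != (out$phase == "baseline")
  if (any(bad_phase)) {
    stop(sprintf("manifest '%s': phase inconsistent with time_h at line %s",
                 path, paste(which(bad_phase)[1] + 1L)), call. = FALSE)
  }
  if (any(out$internal_standard_area <= 0)) {
    stop(sprintf("manifest '%s': internal_standard_area must be positive", path),
         call. = FALSE)
  }
  counts <- table(out$subject_id)
  off <- counts[counts != 9L]
  if (length(off)) {
    warning(sprintf("incomplete subject(s) retained: %s",
                    paste(sprintf("%s (%d samples)", names(off), as.integer(off)),
                          collapse = ", ")), call. = FALSE)
  }
  out
}

#' @rdname read_manifest
#' @param manifest Manifest `data.frame`.
#' @export
write_manifest <- function(manifest, path) {
  out <- data.frame(subject_id = manifest$subject_id, group = manifest$group,
                    phase = manifest$phase, time_h = manifest$time_h,
                    peaks_file = manifest$peaks_file,
                    background_file = manifest$background_file,
                    internal_standard_area = manifest$internal_standard_area)
  .write_csv_raw(out, path)
  invisible(path)
}

#' Read per-timepoint physiology records
#'
#' One row per subject and collection time: arterial blood gas values (PaO2,
#' FiO2, PaCO2, pH) and vital signs (heart rate, respiratory rate). The
#' oxygenation outcome used downstream is the P/F ratio `pao2 / fio2`
#' (see [pf_ratio()]).
#'
#' @param path Physiology CSV with header
#'   `subject_id,time_h,pao2_mmHg,fio2,paco2_mmHg,ph,hr_bpm,rr_bpm`.
#' @return A `data.frame` with columns `subject_id`, `time_h`, `pao2`, `fio2`,
#'   `paco2`, `ph`, `hr`, `rr`.
#' @export
read_physiology <- function(path) {
  df <- .read_csv_checked(path, .physio_header, "physiology")
  out <- data.frame(subject_id = df$subject_id)
  for (i in seq_along(.physio_cols)[-1]) {
    out[[.physio_cols[i]]] <-
      .numeric_col(df[[.physio_header[i]]], .physio_header[i], path, "physiology")
  }
  if (any(out$pao2 <= 0)) {
    stop(sprintf("physiology '%s': pao2 must be positive", path), call. = FALSE)
  }
  if (any(out$fio2 <= 0 | out$fio2 > 1)) {
    stop(sprintf("physiology '%s': fio2 must lie in (0, 1]", path), call. = FALSE)
  }
  out
}

#' @rdname read_physiology
#' @param physio Physiology `data.frame`.
#' @export
write_physiology <- function(physio, path) {
  out <- data.frame(subject_id = physio$subject_id, time_h = physio$time_h,
                    pao2_mmHg = physio$pao2, fio2 = physio$fio2,
                    paco2_mmHg = physio$paco2, ph = physio$ph,
                    hr_bpm = physio$hr, rr_bpm = physio$rr)
  .write_csv_raw(out, path)
  invisible(path)
}

#' Read or write a whole breath study directory
#'
#' A study directory is self-contained: `manifest.csv`, `physiology.csv`, one
#' peak-table CSV per breath sample and per background sample (under
#' `peaks/`), and, for simulated studies, the planted-marker ground truth
#' (`truth_markers.csv`, `truth_abundance.csv`) and the echoed generator
#' configuration (`config.yaml`).
#'
#' @param dir Study directory.
#' @return `read_study()` returns a `voc_study` object: a list with
#'   `manifest`, `samples` (a list of per-sample records, each holding `peaks`
#'   and `background` peak tables plus the manifest fields), `physio`, and, if
#'   present on disk, `truth`.
#' @seealso [simulate_study()], [build_feature_matrix()]
#' @export
read_study <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  physio <- read_physiology(file.path(dir, "physiology.csv"))
  samples <- stats::setNames(lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    list(subject_id = row$subject_id, group = row$group, phase = row$phase,
         time_h = row$time_h,
         peaks = read_peak_table(file.path(dir, row$peaks_file)),
         background = read_peak_table(file.path(dir, row$background_file)),
         internal_standard_area = row$internal_standard_area)
  }), sub("\\.csv$", "", basename(manifest$peaks_file)))
  truth <- NULL
  tm <- file.path(dir, "truth_markers.csv")
  if (file.exists(tm)) {
    markers <- utils::read.csv(tm)
    ab_path <- file.path(dir, "truth_abundance.csv")
    abundance <- if (file.exists(ab_path)) utils::read.csv(ab_path) else NULL
    truth <- list(markers = markers, abundance = abundance)
  }
  structure(list(manifest = manifest, samples = samples, physio = physio,
                 truth = truth, config = NULL),
            class = "voc_study")
}

#' @rdname read_study
#' @param study A `voc_study` object.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "voc_study"))
  dir.create(file.path(dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  manifest <- study$manifest
  for (i in seq_along(study$samples)) {
    s <- study$samples[[i]]
    write_peak_table(s$peaks, file.path(dir, manifest$peaks_file[i]))
    write_peak_table(s$background, file.path(dir, manifest$background_file[i]))
  }
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  write_physiology(study$physio, file.path(dir, "physiology.csv"))
  if (!is.null(study$truth)) {
    .write_csv_raw(study$truth$markers, file.path(dir, "truth_markers.csv"))
    if (!is.null(study$truth$abundance)) {
      .write_csv_raw(study$truth$abundance, file.path(dir, "truth_abundance.csv"))
    }
  }
  if (!is.null(study$config)) {
    cfg <- study$config
    cfg$pf_oxygen_path <- as.list(as.data.frame(cfg$pf_oxygen_path))
    yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' @export
print.voc_study <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("voc_study: %d subjects (%d air, %d oxygen), %d breath samples\n",
              length(unique(m$subject_id)),
              length(unique(m$subject_id[m$group == "air"])),
              length(unique(m$subject_id[m$group == "oxygen"])),
              nrow(m)))
  cat(sprintf("  collection times (h): %s\n",
              paste(sort(unique(m$time_h)), collapse = ", ")))
  if (!is.null(x$truth)) {
    cat(sprintf("  simulated; %d planted marker compound(s)\n",
                nrow(x$truth$markers)))
  }
  invisible(x)
}
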