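#' Convert mouse records to interchange tables
#'
#' Produces the three flat tables used for CSV interchange:
#' `measurements` (mouse_id, group, day, volume_cm3),
#' `necropsy` (mouse_id, day, weight_g, treatment_start_day) and
#' `pcr` (mouse_id, ctc_per20ng, organ, dtc_per60ng).
#'
#' @param records List of [mouse_record()] objects.
#' @return Named list of three data.frames.
#' @export
records_to_tables <- function(records) {
  meas <- do.call(rbind, lapply(records, function(r)
    data.frame(mouse_id = r$mouse_id, group = r$group, day = r$days,
               volume_cm3 = r$palpated_volumes, stringsAsFactors = FALSE)))
  necr <- do.call(rbind, lapply(records, function(r)
    data.frame(mouse_id = r$mouse_id, day = r$necropsy_day,
               weight_g = r$necropsy_weight,
               treatment_start_day = r$treatment_start_day %||% NA_real_,
               stringsAsFactors = FALSE)))
  pcr <- do.call(rbind, lapply(records, function(r) {
    organs <- if (length(r$dtc_counts)) names(r$dtc_counts) else NA_character_
    data.frame(mouse_id = r$mouse_id, ctc_per20ng = r$ctc_count,
               organ = organs,
               dtc_per60ng = if (length(r$dtc_counts)) unname(r$dtc_counts) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(measurements = meas, necropsy = necr, pcr = pcr)
}

#' Build mouse records from interchange tables
#'
#' Inverse of [records_to_tables()]; validates schemas and reports offending
#' rows.
#'
#' @param measurements,necropsy,pcr Data.frames with the columns described
#'   in [records_to_tables()].
#' @return List of [mouse_record()] objects.
#' @export
tables_to_records <- function(measurements, necropsy, pcr) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stopf("%s table lacks columns: %s", what,
                            paste(miss, collapse = ", "))
  }
  need(measurements, c("mouse_id", "group", "day", "volume_cm3"), "measurements")
  need(necropsy, c("mouse_id", "day", "weight_g"), "necropsy")
  need(pcr, c("mouse_id", "ctc_per20ng", "organ", "dtc_per60ng"), "pcr")
  ids <- unique(measurements$mouse_id)
  lapply(ids, function(id) {
    mi <- measurements[measurements$mouse_id == id, , drop = FALSE]
    mi <- mi[order(mi$day), , drop = FALSE]
    ni <- necropsy[necropsy$mouse_id == id, , drop = FALSE]
    if (nrow(ni) != 1L) stopf("necropsy table needs exactly one row for mouse %s", id)
    pi <- pcr[pcr$mouse_id == id, , drop = FALSE]
    dtc <- stats::setNames(pi$dtc_per60ng, pi$organ)
    dtc <- dtc[!is.na(names(dtc)) & !is.na(dtc)]
    tsd <- if ("treatment_start_day" %in% names(ni) && !is.na(ni$treatment_start_day))
      ni$treatment_start_day else NULL
    mouse_record(mouse_id = id, group = mi$group[1], days = mi$day,
                 palpated_volumes = mi$volume_cm3,
                 necropsy_weight = ni$weight_g, necropsy_day = ni$day,
                 ctc_count = if (nrow(pi)) pi$ctc_per20ng[1] else NA_real_,
                 dtc_counts = dtc, treatment_start_day = tsd)
  })
}

#' Write / read the interchange tables as CSV
#'
#' @param records List of [mouse_record()]s.
#' @param dir Output directory (created if needed).
#' @return `write_cohort_csv` invisibly returns the file paths;
#'   `read_cohort_csv` returns the records list.
#' @export
write_cohort_csv <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- records_to_tables(records)
  paths <- file.path(dir, paste0(names(tabs), ".csv"))
  for (i in seq_along(tabs))
    utils::write.csv(tabs[[i]], paths[i], row.names = FALSE)
  invisible(paths)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir) {
  tables_to_records(
    utils::read.csv(file.path(dir, "measurements.csv"), stringsAsFactors = FALSE),
    utils::read.csv(file.path(dir, "necropsy.csv"), stringsAsFactors = FALSE),
    utils::read.csv(file.path(dir, "pcr.csv"), stringsAsFactors = FALSE))
}

#' Read a treatment schedule from a YAML or JSON config file
#'
#' The file holds optional `chemo:` and `radio:` blocks with the fields of
#' [treatment_schedule()]. YAML needs the `yaml` package (present on a
#' standard install); JSON uses `jsonlite`.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A [treatment_schedule()].
#' @export
read_schedule <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("the yaml package is required to read YAML schedules")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  treatment_schedule(chemo = lst$chemo, radio = lst$radio)
}

#' Plain-text PPM (P3) image I/O
#'
#' Reads/writes the ASCII portable-pixmap format, the text-based
#' interchange used for small slide fixtures. `write_slide_ppm` stores the
#' pixel size in a comment so a round trip preserves it.
#'
#' @param image A [slide_image()].
#' @param path File path.
#' @param maxval Sample depth (default 255).
#' @return `read_slide_ppm` returns a [slide_image()].
#' @export
write_slide_ppm <- function(image, path, maxval = 255L) {
  stopifnot(inherits(image, "slide_image"))
  d <- dim(image$pixels)
  vals <- round(clamp(image$pixels, 0, 1) * maxval)
  # interleave channels pixel by pixel, row-major
  flat <- as.integer(aperm(vals, c(3, 2, 1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", sprintf("# mpp %.10g", image$pixel_size),
               sprintf("%d %d", d[2], d[1]), as.character(maxval)), con)
  writeLines(paste(flat, collapse = " "), con)
  invisible(path)
}

#' @rdname write_slide_ppm
#' @param pixel_size Microns per pixel; overrides any value stored in the
#'   file comment.
#' @export
read_slide_ppm <- function(path, pixel_size = NULL) {
  txt <- readLines(path)
  mpp <- NA_real_
  cm <- grep("^#", txt, value = TRUE)
  hit <- regmatches(cm, regexpr("mpp [0-9.eE+-]+", cm))
  if (length(hit)) mpp <- as.numeric(sub("mpp ", "", hit[[1]]))
  txt <- txt[!grepl("^#", txt)]
  if (txt[1] != "P3") stopf("not an ASCII PPM (P3) file")
  toks <- scan(text = paste(txt[-1], collapse = " "), quiet = TRUE)
  w <- toks[1]; h <- toks[2]; maxval <- toks[3]
  dat <- toks[-(1:3)] / maxval
  px <- aperm(array(dat, dim = c(3, w, h)), c(3, 2, 1))
  ps <- pixel_size %||% (if (is.na(mpp)) 1 else mpp)
  slide_image(px, pixel_size = ps)
}

#' PNG slide I/O (requires the png package)
#'
#' @param image A [slide_image()]; alpha is dropped on read.
#' @param path File path.
#' @param pixel_size Microns per pixel for the slide read from disk.
#' @return `read_slide_png` returns a [slide_image()].
#' @export
write_slide_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stopf("the png package is required for PNG output")
  png::writePNG(image$pixels, path)
  invisible(path)
}

#' @rdname write_slide_png
#' @export
read_slide_png <- function(path, pixel_size) {
  if (!requireNamespace("png", quietly = TRUE))
    stopf("the png package is required for PNG input")
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  slide_image(px, pixel_size = pixel_size)
}
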