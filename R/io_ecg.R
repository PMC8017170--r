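# MAT level-4 container -------------------------------------------------
#
# CPSC-style records ship as a MAT file holding one numeric matrix plus a
# plain-text header. The level-4 MAT layout (20-byte header, nul-terminated
# variable name, column-major doubles) is implemented directly; it is the
# oldest and simplest MAT dialect and is read by scipy.io and Octave alike.

write_mat_v4 <- function(mat, path, var_name = "val") {
  con <- file(path, "wb")
  on.exit(close(con))
  name <- c(utf8ToInt(var_name), 0L)
  # MOPT type code: little-endian (0), reserved (0), double (0), full (0)
  writeBin(as.integer(c(0L, nrow(mat), ncol(mat), 0L, length(name))),
           con, size = 4, endian = "little")
  writeBin(as.raw(name), con)
  writeBin(as.double(mat), con, size = 8, endian = "little")
  invisible(path)
}

read_mat_v4 <- function(path) {
  if (!file.exists(path))
    stop_ecgfb("ecgfb_io_error", "MAT file does not exist: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", 5, size = 4, endian = "little")
  if (length(hdr) < 5 || hdr[1] %% 10 != 0 || (hdr[1] %/% 10) %% 10 != 0)
    stop_ecgfb("ecgfb_format_error",
               "not a level-4 MAT file with a numeric double matrix: %s", path)
  if (hdr[2] < 1 || hdr[3] < 1)
    stop_ecgfb("ecgfb_format_error", "empty matrix in MAT file: %s", path)
  name_raw <- readBin(con, "raw", hdr[5])
  var_name <- rawToChar(name_raw[name_raw != as.raw(0)])
  n <- hdr[2] * hdr[3]
  x <- readBin(con, "double", n, size = 8, endian = "little")
  if (length(x) != n)
    stop_ecgfb("ecgfb_io_error", "truncated MAT file: %s", path)
  list(name = var_name, matrix = matrix(x, hdr[2], hdr[3]))
}

# Header dialect ---------------------------------------------------------
#
# Minimal line-oriented header in the spirit of WFDB .hea files:
#   <record_id> <n_leads> <fs> <n_samples>
#   #Dx: <comma-separated labels>      (absent when the label set is empty)
#   #Sex: <string>   #Age: <string>    (optional)

write_hea <- function(rec, path) {
  lines <- sprintf("%s %d %g %d", rec$record_id, n_leads(rec), rec$fs,
                   n_samples(rec))
  if (length(rec$labels))
    lines <- c(lines, paste0("#Dx: ", paste(rec$labels, collapse = ",")))
  if (!is.na(rec$sex)) lines <- c(lines, paste0("#Sex: ", rec$sex))
  if (!is.na(rec$age)) lines <- c(lines, paste0("#Age: ", rec$age))
  writeLines(lines, path)
  invisible(path)
}

read_hea <- function(path) {
  if (!file.exists(path))
    stop_ecgfb("ecgfb_io_error", "header file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines))
    stop_ecgfb("ecgfb_format_error", "empty header file: %s", path)
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(first) < 4)
    stop_ecgfb("ecgfb_format_error",
               "header first line needs 'id n_leads fs n_samples': %s", path)
  grab <- function(tag) {
    m <- grep(paste0("^#", tag, ":"), lines, value = TRUE)
    if (!length(m)) return(NA_character_)
    trimws(sub(paste0("^#", tag, ":"), "", m[1]))
  }
  dx <- grab("Dx")
  labels <- if (is.na(dx) || !nzchar(dx)) character()
            else trimws(strsplit(dx, ",")[[1]])
  list(record_id = first[1], n_leads = as.integer(first[2]),
       fs = as.numeric(first[3]), n_samples = as.integer(first[4]),
       labels = labels, sex = grab("Sex"), age = grab("Age"))
}

#' Read a CPSC-style MAT + header record pair
#'
#' The MAT file holds one numeric matrix; its on-disk orientation is
#' inferred (the longer axis is taken as samples — ECG records always have
#' far more samples than leads) unless `orientation` overrides it. Labels
#' come from the header's `#Dx:` line and are checked against the
#' vocabulary.
#'
#' @param mat_path Path to the MAT file.
#' @param header_path Path to the header file; defaults to `mat_path` with
#'   its extension replaced by `.hea`.
#' @param vocabulary Permitted class names (default [ecg_classes()]).
#' @param orientation One of `"auto"` (longer axis = samples),
#'   `"samples_rows"`, `"leads_rows"`.
#' @return An [ecg_record()].
#' @export
read_cpsc_record <- function(mat_path,
                             header_path = sub("\\.mat$", ".hea", mat_path),
                             vocabulary = ecg_classes(),
                             orientation = c("auto", "samples_rows",
                                             "leads_rows")) {
  orientation <- match.arg(orientation)
  m <- read_mat_v4(mat_path)$matrix
  h <- read_hea(header_path)
  flip <- switch(orientation,
                 auto = nrow(m) < ncol(m),
                 samples_rows = FALSE,
                 leads_rows = TRUE)
  if (flip) m <- t(m)
  if (!is.na(h$n_leads) && ncol(m) != h$n_leads)
    stop_ecgfb("ecgfb_format_error",
               "header declares %d leads but matrix has %d (record %s)",
               h$n_leads, ncol(m), h$record_id)
  ecg_record(m, fs = h$fs, record_id = h$record_id, labels = h$labels,
             vocabulary = vocabulary, sex = h$sex, age = h$age)
}

#' Write a record as a CPSC-style MAT + header pair
#'
#' `read_cpsc_record(write_record(r, dir))` reproduces the signal to
#' round-trip precision and the label set exactly.
#'
#' @param rec An [ecg_record()].
#' @param dir Output directory (created if needed).
#' @param orientation `"leads_rows"` (CPSC convention, default) or
#'   `"samples_rows"`.
#' @return Named character vector with the `mat` and `hea` paths.
#' @export
write_record <- function(rec, dir,
                         orientation = c("leads_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  validate_ecg_record(rec)
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop_ecgfb("ecgfb_io_error", "cannot create directory: %s", dir)
  mat_path <- file.path(dir, paste0(rec$record_id, ".mat"))
  hea_path <- file.path(dir, paste0(rec$record_id, ".hea"))
  m <- if (orientation == "leads_rows") t(rec$signal) else rec$signal
  write_mat_v4(m, mat_path)
  write_hea(rec, hea_path)
  c(mat = mat_path, hea = hea_path)
}

# Portable plain-text container ------------------------------------------

#' Write a record as a single portable text file
#'
#' Commented key-value header lines (`#id:`, `#fs:`, `#leads:`, `#labels:`)
#' followed by a samples x leads TSV body. Useful as a diff-able fixture
#' format; `ecgfb convert` translates between this and MAT + header.
#'
#' @param rec An [ecg_record()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_portable <- function(rec, path) {
  validate_ecg_record(rec)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#id: ", rec$record_id),
               paste0("#fs: ", rec$fs),
               paste0("#leads: ", paste(rec$lead_names, collapse = ",")),
               paste0("#labels: ", paste(rec$labels, collapse = ","))), con)
  utils::write.table(rec$signal, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a portable text record
#' @param path File written by [write_portable()].
#' @param vocabulary Permitted class names.
#' @return An [ecg_record()].
#' @export
read_portable <- function(path, vocabulary = ecg_classes()) {
  if (!file.exists(path))
    stop_ecgfb("ecgfb_io_error", "file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(lines, "#")
  grab <- function(tag) {
    m <- grep(paste0("^#", tag, ":"), lines[is_hdr], value = TRUE)
    if (!length(m)) NA_character_
    else trimws(sub(paste0("^#", tag, ":"), "", m[1]))
  }
  labels <- grab("labels")
  labels <- if (is.na(labels) || !nzchar(labels)) character()
            else trimws(strsplit(labels, ",")[[1]])
  sig <- as.matrix(utils::read.table(text = lines[!is_hdr], sep = "\t"))
  dimnames(sig) <- NULL
  ecg_record(sig, fs = as.numeric(grab("fs")), record_id = grab("id"),
             lead_names = trimws(strsplit(grab("leads"), ",")[[1]]),
             labels = labels, vocabulary = vocabulary)
}
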