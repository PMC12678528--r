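#' Load an ECG record from disk
#'
#' Supported formats:
#' * `csv` — header row of lead names, one row per sample, amplitudes in mV.
#'   The sampling rate is not part of the dialect and is supplied via `fs`.
#' * `wfdb` — a WFDB `.hea`/`.dat` pair (digital format 16); amplitudes are
#'   converted to millivolts using the per-signal gain and baseline.
#' * `hdf5` — a container with a tracing dataset shaped
#'   records x time x leads and an id dataset, plus an optional `scale`
#'   attribute on the tracing dataset (mV per unit). Matches the layout of
#'   large public tracing archives closely enough that `dialect` remaps
#'   dataset names for real files. Reading is delegated to the host Python
#'   (`h5py`) through a temporary binary exchange file.
#'
#' @param path File path (`.hea` file or bare record path for wfdb).
#' @param format One of `"wfdb"`, `"csv"`, `"hdf5"`.
#' @param record_id Record to extract (required for hdf5; otherwise the id
#'   stored with / derived from the file).
#' @param fs Sampling rate for formats that do not carry one (csv, hdf5).
#' @param dialect Named list overriding hdf5 dataset names:
#'   `tracings`, `ids`, and `lead_names`.
#' @return An [ecg_record()].
#' @export
load_record <- function(path, format = c("wfdb", "csv", "hdf5"),
                        record_id = NULL, fs = 500, dialect = list()) {
  format <- match.arg(format)
  switch(format,
         csv = read_record_csv(path, fs = fs, record_id = record_id),
         wfdb = read_record_wfdb(path, record_id = record_id),
         hdf5 = read_record_hdf5(path, record_id = record_id, fs = fs,
                                 dialect = dialect))
}

#' Write an ECG record to disk
#'
#' @param record An [ecg_record()].
#' @param path Output path (for wfdb, the base path without extension).
#' @param format `"csv"` (exact round-trip) or `"wfdb"` (amplitudes
#'   quantized to the ADC resolution implied by `gain`).
#' @param gain WFDB ADC gain in units per millivolt.
#' @export
write_record <- function(record, path, format = c("csv", "wfdb"),
                         gain = 1000) {
  format <- match.arg(format)
  switch(format,
         csv = write_record_csv(record, path),
         wfdb = write_record_wfdb(record, path, gain = gain))
  invisible(path)
}

read_record_csv <- function(path, fs = 500, record_id = NULL) {
  if (!file.exists(path))
    wmlr_stop(sprintf("file not found: %s", path), "wmlr_format_error")
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e)
                   wmlr_stop(sprintf("unreadable CSV '%s': %s",
                                     path, conditionMessage(e)),
                             "wmlr_format_error"))
  if (!ncol(df) || !all(vapply(df, is.numeric, logical(1))))
    wmlr_stop(sprintf("CSV '%s' has non-numeric columns", path),
              "wmlr_format_error")
  leads <- resolve_lead_names(names(df))
  id <- record_id %||% sub("\\.[^.]*$", "", basename(path))
  ecg_record(as.matrix(df), fs = fs, lead_names = leads, record_id = id)
}

write_record_csv <- function(record, path) {
  m <- record$samples
  # full "%.17g" precision so read-back reproduces doubles bit-exactly
  txt <- vapply(seq_len(nrow(m)), function(i)
    paste(sprintf("%.17g", m[i, ]), collapse = ","), character(1))
  writeLines(c(paste(record$lead_names, collapse = ","), txt), path)
  invisible(path)
}

# --- WFDB (digital format 16, little-endian, interleaved) -----------------

read_record_wfdb <- function(path, record_id = NULL) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea))
    wmlr_stop(sprintf("WFDB header not found: %s", hea), "wmlr_format_error")
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  head_tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(head_tok) < 4)
    wmlr_stop(sprintf("malformed WFDB header: %s", hea), "wmlr_format_error")
  nsig <- as.integer(head_tok[2])
  fs <- as.numeric(head_tok[3])
  nsamp <- as.integer(head_tok[4])
  sig <- lines[2:(1 + nsig)]
  gains <- numeric(nsig); base <- numeric(nsig); leads <- character(nsig)
  datfile <- character(nsig)
  for (i in seq_len(nsig)) {
    tok <- strsplit(trimws(sig[i]), "\\s+")[[1]]
    datfile[i] <- tok[1]
    if (as.integer(sub("[+:x].*$", "", tok[2])) != 16L)
      wmlr_stop("only WFDB digital format 16 is supported",
                "wmlr_format_error")
    gspec <- if (length(tok) >= 3) tok[3] else "200"
    g <- sub("\\(.*$", "", sub("/.*$", "", gspec))
    gains[i] <- as.numeric(g)
    if (gains[i] == 0) gains[i] <- 200  # WFDB default gain
    b <- regmatches(gspec, regexpr("\\(([-0-9]+)\\)", gspec))
    base[i] <- if (length(b)) as.numeric(gsub("[()]", "", b)) else 0
    leads[i] <- if (length(tok) >= 9) tok[length(tok)] else sprintf("S%d", i)
  }
  if (length(unique(datfile)) != 1L)
    wmlr_stop("multi-file WFDB records are not supported", "wmlr_format_error")
  dat <- file.path(dirname(hea), datfile[1])
  if (!file.exists(dat))
    wmlr_stop(sprintf("WFDB data file not found: %s", dat), "wmlr_format_error")
  raw <- readBin(dat, integer(), n = nsig * nsamp, size = 2,
                 signed = TRUE, endian = "little")
  if (length(raw) < nsig * nsamp)
    wmlr_stop(sprintf("WFDB data file truncated: %s", dat),
              "wmlr_format_error")
  adc <- matrix(raw, ncol = nsig, byrow = TRUE)
  mv <- sweep(sweep(adc, 2, base, "-"), 2, gains, "/")
  id <- record_id %||% sub("\\.hea$", "", basename(hea))
  ecg_record(mv, fs = fs, lead_names = resolve_lead_names(leads),
             record_id = id)
}

write_record_wfdb <- function(record, path, gain = 1000) {
  base <- sub("\\.hea$", "", path)
  nsig <- ncol(record$samples)
  nsamp <- nrow(record$samples)
  adc <- round(record$samples * gain)
  if (any(abs(adc) > 32767))
    wmlr_stop("amplitudes overflow 16-bit WFDB storage at this gain",
              "wmlr_value_error")
  datname <- paste0(basename(base), ".dat")
  hdr <- c(sprintf("%s %d %g %d", basename(base), nsig, record$fs, nsamp),
           sprintf("%s 16 %g(0)/mV 16 0 0 0 0 %s",
                   datname, gain, record$lead_names))
  writeLines(hdr, paste0(base, ".hea"))
  con <- file(file.path(dirname(base), datname), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(adc)), con, size = 2, endian = "little")
  invisible(base)
}

# --- HDF5 via the host Python/h5py -----------------------------------------

python_bin <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p))
    wmlr_stop("no python interpreter found for HDF5 access",
              "wmlr_format_error")
  p
}

run_python <- function(code) {
  script <- tempfile(fileext = ".py")
  writeLines(code, script)
  on.exit(unlink(script))
  out <- suppressWarnings(system2(python_bin(), script,
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0)
    wmlr_stop(paste("python HDF5 helper failed:",
                    paste(out, collapse = "\n")), "wmlr_format_error")
  out
}

hdf5_dialect <- function(dialect = list()) {
  d <- list(tracings = "tracings", ids = "exam_id",
            lead_names = c("I", "II", "III", "aVR", "aVL", "aVF",
                           "V1", "V2", "V3", "V4", "V5", "V6"))
  d[names(dialect)] <- dialect
  d
}

read_record_hdf5 <- function(path, record_id, fs = 500, dialect = list()) {
  if (is.null(record_id))
    wmlr_stop("record_id is required for HDF5 containers", "wmlr_value_error")
  if (!file.exists(path))
    wmlr_stop(sprintf("file not found: %s", path), "wmlr_format_error")
  d <- hdf5_dialect(dialect)
  bin <- tempfile(fileext = ".f64")
  on.exit(unlink(bin))
  code <- sprintf(
    'import h5py, numpy as np, sys
with h5py.File(%s, "r") as f:
    ids = np.asarray(f[%s]).astype(str)
    hits = np.nonzero(ids == %s)[0]
    if hits.size == 0:
        sys.stderr.write("record not in container"); sys.exit(3)
    ds = f[%s]
    x = np.asarray(ds[int(hits[0])], dtype=np.float64)
    scale = float(ds.attrs.get("scale", 1.0))
    (x * scale).tofile(%s)
    print(x.shape[0], x.shape[1])',
    deparse(path), deparse(d$ids), deparse(as.character(record_id)),
    deparse(d$tracings), deparse(bin))
  out <- tryCatch(run_python(code), wmlr_format_error = function(e) {
    if (grepl("record not in container", conditionMessage(e)))
      wmlr_stop(sprintf("record '%s' absent from HDF5 container", record_id),
                "wmlr_lookup_error")
    stop(e)
  })
  dims <- as.integer(strsplit(trimws(out[length(out)]), "\\s+")[[1]])
  x <- matrix(readBin(bin, double(), n = prod(dims)),
              nrow = dims[1], byrow = TRUE)
  ecg_record(x, fs = fs,
             lead_names = resolve_lead_names(d$lead_names[seq_len(dims[2])]),
             record_id = record_id)
}

#' Write a list of records to an HDF5 container
#'
#' Produces the same records x time x leads layout [load_record()] reads,
#' via the host Python/h5py. All records must share length and lead count.
#'
#' @param records List of [ecg_record()] objects.
#' @param path Output `.h5` path.
#' @param dialect As in [load_record()].
#' @export
write_cohort_hdf5 <- function(records, path, dialect = list()) {
  d <- hdf5_dialect(dialect)
  n <- length(records)
  nt <- nrow(records[[1]]$samples); nl <- ncol(records[[1]]$samples)
  bin <- tempfile(fileext = ".f64")
  ids <- tempfile(fileext = ".txt")
  on.exit(unlink(c(bin, ids)))
  con <- file(bin, "wb")
  for (r in records) {
    stopifnot(nrow(r$samples) == nt, ncol(r$samples) == nl)
    writeBin(as.vector(t(r$samples)), con)
  }
  close(con)
  writeLines(vapply(records, function(r) r$record_id, character(1)), ids)
  code <- sprintf(
    'import h5py, numpy as np
x = np.fromfile(%s, dtype=np.float64).reshape(%d, %d, %d)
ids = np.loadtxt(%s, dtype=str, ndmin=1)
with h5py.File(%s, "w") as f:
    ds = f.create_dataset(%s, data=x)
    ds.attrs["scale"] = 1.0
    f.create_dataset(%s, data=ids.astype("S"))',
    deparse(bin), n, nt, nl, deparse(ids), deparse(path),
    deparse(d$tracings), deparse(d$ids))
  run_python(code)
  invisible(path)
}

# --- Metadata table ---------------------------------------------------------

CONDITION_FLAGS <- c("1dAVb", "RBBB", "LBBB", "SB", "AF", "ST")

#' Read a record-metadata table
#'
#' Canonical columns: `patient_id`, `is_normal`, the six rhythm-condition
#' booleans (`1dAVb`, `RBBB`, `LBBB`, `SB`, `AF`, `ST`) and
#' `has_blank_lead`. `column_map` renames columns of real files onto the
#' canonical names, e.g. `c(patient_id = "patient_id", is_normal =
#' "normal_ecg")`.
#'
#' @param path CSV path.
#' @param column_map Named character vector: canonical -> source column.
#' @return A data.frame with the canonical columns.
#' @export
read_metadata_csv <- function(path, column_map = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  canon <- c("patient_id", "is_normal", CONDITION_FLAGS, "has_blank_lead")
  if (!is.null(column_map))
    for (k in names(column_map))
      names(df)[names(df) == column_map[[k]]] <- k
  missing <- setdiff(canon, names(df))
  if (length(missing))
    wmlr_stop(paste("metadata missing columns:",
                    paste(missing, collapse = ", ")), "wmlr_format_error")
  out <- df[canon]
  for (cc in setdiff(canon, "patient_id"))
    out[[cc]] <- as.logical(out[[cc]])
  out$patient_id <- as.character(out$patient_id)
  out
}
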