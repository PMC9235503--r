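#' @keywords internal
#' @useDynLib fpkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

#' Construct an MS/MS spectrum
#'
#' A spectrum is a peak list (m/z, relative intensity) plus acquisition
#' metadata, keyed to a 2D structure identity. Stereoisomers share a
#' `structure_key`: only atoms and connectivity matter for fragmentation, so
#' train/evaluation splits must be disjoint at this level, not at the level
#' of individual records.
#'
#' @param mz numeric vector of fragment m/z values in Da (positive).
#' @param intensity numeric vector of non-negative relative intensities.
#' @param precursor_mz precursor m/z in Da.
#' @param structure_key non-empty 2D structure identifier (e.g. the first,
#'   connectivity-only block of an InChIKey).
#' @param compound_id unique record identifier; defaults to `structure_key`.
#' @param adduct positive-mode adduct string, e.g. `"[M+H]+"`.
#' @param collision_energy collision energy: a single value, a
#'   comma-separated list (merged spectra) or `"ramp"`.
#' @param instrument instrument descriptor.
#' @param tolerance slack (Da) allowed for peaks above the precursor.
#' @return an object of class `fpkit_spectrum`. Peaks are stored sorted by
#'   ascending m/z.
#' @export
spectrum <- function(mz, intensity, precursor_mz, structure_key,
                     compound_id = structure_key, adduct = "[M+H]+",
                     collision_energy = NA_character_,
                     instrument = NA_character_, tolerance = 0.5) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (any(mz <= 0)) stop("all m/z values must be positive")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (!is.character(structure_key) || !nzchar(structure_key))
    stop("structure_key must be a non-empty string")
  if (length(mz) && any(mz > precursor_mz + tolerance))
    stop(sprintf("peak m/z %.4f exceeds precursor %.4f + tolerance",
                 max(mz), precursor_mz))
  ord <- order(mz)
  structure(
    list(mz = mz[ord], intensity = intensity[ord],
         precursor_mz = as.numeric(precursor_mz),
         adduct = adduct, collision_energy = as.character(collision_energy),
         instrument = instrument, structure_key = structure_key,
         compound_id = compound_id),
    class = "fpkit_spectrum")
}

#' @export
print.fpkit_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum %s> %d peaks, precursor %.4f Da, %s, structure %s\n",
              x$compound_id, length(x$mz), x$precursor_mz, x$adduct,
              x$structure_key))
  invisible(x)
}

n_peaks <- function(s) length(s$mz)

#' Read spectra from an MGF or MSP file
#'
#' Supports the Mascot generic format (`BEGIN IONS`/`END IONS` blocks with
#' `KEY=value` headers) and NIST-style MSP (`Name:` records with
#' `Num Peaks:`). Records without a precursor m/z (`PEPMASS`/`PrecursorMZ`)
#' are skipped with a warning; any other malformed line is an error naming
#' the line number.
#'
#' @param path file path.
#' @param format `"mgf"` or `"msp"`; default guesses from the extension.
#' @return list of [spectrum()] objects, peaks sorted by ascending m/z.
#' @export
read_spectra <- function(path, format = c("auto", "mgf", "msp")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "msp") "msp" else "mgf"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "mgf") parse_mgf(lines, path) else parse_msp(lines, path)
}

spectrum_from_fields <- function(fields, mz, intensity, path, lineno) {
  if (is.null(fields$precursor_mz) || is.na(fields$precursor_mz)) {
    warning(sprintf("%s: record ending at line %d has no precursor m/z; skipped",
                    path, lineno))
    return(NULL)
  }
  key <- fields$structure_key
  if (is.null(key) || !nzchar(key)) key <- fields$compound_id
  if (is.null(key) || !nzchar(key))
    stop(sprintf("%s: record ending at line %d lacks a structure identifier",
                 path, lineno))
  spectrum(mz, intensity,
           precursor_mz = fields$precursor_mz,
           structure_key = key,
           compound_id = if (!is.null(fields$compound_id)) fields$compound_id else key,
           adduct = if (!is.null(fields$adduct)) fields$adduct else "[M+H]+",
           collision_energy = if (!is.null(fields$collision_energy))
             fields$collision_energy else NA_character_,
           instrument = if (!is.null(fields$instrument))
             fields$instrument else NA_character_,
           tolerance = Inf)
}

parse_peak_line <- function(line, path, i) {
  parts <- strsplit(trimws(line), "[ \t]+")[[1]]
  vals <- suppressWarnings(as.numeric(parts[1:2]))
  if (length(parts) < 2 || anyNA(vals))
    stop(sprintf("%s: malformed peak line %d: '%s'", path, i, line))
  vals
}

parse_mgf <- function(lines, path) {
  out <- list()
  in_block <- FALSE
  fields <- list(); mz <- numeric(); intensity <- numeric()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (line == "BEGIN IONS") {
      if (in_block) stop(sprintf("%s: nested BEGIN IONS at line %d", path, i))
      in_block <- TRUE
      fields <- list(); mz <- numeric(); intensity <- numeric()
    } else if (line == "END IONS") {
      if (!in_block) stop(sprintf("%s: END IONS without BEGIN at line %d", path, i))
      in_block <- FALSE
      s <- spectrum_from_fields(fields, mz, intensity, path, i)
      if (!is.null(s)) out[[length(out) + 1L]] <- s
    } else if (in_block && grepl("=", line, fixed = TRUE)) {
      kv <- strsplit(line, "=", fixed = TRUE)[[1]]
      key <- toupper(kv[1]); val <- paste(kv[-1], collapse = "=")
      fields <- mgf_header_field(fields, key, val)
    } else if (in_block) {
      vals <- parse_peak_line(line, path, i)
      mz <- c(mz, vals[1]); intensity <- c(intensity, vals[2])
    } else {
      stop(sprintf("%s: content outside BEGIN IONS block at line %d", path, i))
    }
  }
  if (in_block) stop(path, ": unterminated BEGIN IONS block")
  out
}

mgf_header_field <- function(fields, key, val) {
  switch(key,
    PEPMASS = { fields$precursor_mz <-
      suppressWarnings(as.numeric(strsplit(val, "[ \t]+")[[1]][1])) },
    CHARGE = NULL,
    TITLE = { if (is.null(fields$compound_id)) fields$compound_id <- val },
    SPECTRUMID = ,
    COMPOUND_ID = { fields$compound_id <- val },
    STRUCTUREKEY = ,
    INCHIKEY2D = ,
    INCHIKEY = { fields$structure_key <- strsplit(val, "-")[[1]][1] },
    ADDUCT = ,
    PRECURSORTYPE = ,
    IONTYPE = { fields$adduct <- val },
    COLLISIONENERGY = ,
    COLLISION_ENERGY = { fields$collision_energy <- val },
    INSTRUMENT = ,
    SOURCE_INSTRUMENT = { fields$instrument <- val },
    NULL)
  fields
}

parse_msp <- function(lines, path) {
  out <- list()
  fields <- list(); mz <- numeric(); intensity <- numeric()
  npeaks <- NA_integer_; have_record <- FALSE
  flush <- function(i) {
    if (!have_record) return(invisible(NULL))
    s <- spectrum_from_fields(fields, mz, intensity, path, i)
    if (!is.null(s)) out[[length(out) + 1L]] <<- s
    fields <<- list(); mz <<- numeric(); intensity <<- numeric()
    npeaks <<- NA_integer_; have_record <<- FALSE
    invisible(NULL)
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) { flush(i); next }
    if (grepl("^Name:", line, ignore.case = TRUE)) {
      flush(i)
      have_record <- TRUE
      fields$compound_id <- trimws(sub("^Name:", "", line, ignore.case = TRUE))
    } else if (grepl(":", line, fixed = TRUE) && is.na(npeaks)) {
      kv <- strsplit(line, ":", fixed = TRUE)[[1]]
      key <- toupper(gsub("[ _]", "", kv[1]))
      val <- trimws(paste(kv[-1], collapse = ":"))
      switch(key,
        PRECURSORMZ = ,
        PEPMASS = { fields$precursor_mz <- suppressWarnings(as.numeric(val)) },
        PRECURSORTYPE = { fields$adduct <- val },
        INCHIKEY = { fields$structure_key <- strsplit(val, "-")[[1]][1] },
        COLLISIONENERGY = { fields$collision_energy <- val },
        INSTRUMENT = ,
        INSTRUMENTTYPE = { fields$instrument <- val },
        NUMPEAKS = { npeaks <- as.integer(val) },
        NULL)
    } else {
      if (!have_record)
        stop(sprintf("%s: peak data before any Name: record at line %d", path, i))
      vals <- parse_peak_line(line, path, i)
      mz <- c(mz, vals[1]); intensity <- c(intensity, vals[2])
    }
  }
  flush(length(lines))
  out
}

#' Write spectra to an MGF file
#'
#' @param spectra list of [spectrum()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", s$compound_id),
      paste0("PEPMASS=", format(s$precursor_mz, digits = 10)),
      paste0("STRUCTUREKEY=", s$structure_key),
      paste0("ADDUCT=", s$adduct),
      if (!is.na(s$collision_energy))
        paste0("COLLISIONENERGY=", s$collision_energy),
      if (!is.na(s$instrument)) paste0("INSTRUMENT=", s$instrument),
      sprintf("%.6f %.6g", s$mz, s$intensity),
      "END IONS", ""), con)
  }
  invisible(path)
}
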