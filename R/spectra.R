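# A Run is a tibble with one row per spectrum:
#   scan (int), ms_level (int), precursor_mz, precursor_charge (0 = unknown),
#   parent_scan (int, NA for MS1/MS2), selected_mz (MS3 only), activation,
#   orphan (MS3 whose parent is absent), peaks (list column of tibbles with
#   mz, intensity; strictly sorted ascending by mz).

#' Construct a spectrum row
#'
#' @param scan Integer scan id (unique within a run).
#' @param ms_level 1, 2 or 3.
#' @param mz,intensity Peak vectors; sorted by m/z on construction.
#' @param precursor_mz,precursor_charge Precursor info (levels 2-3);
#'   charge 0 means undetermined.
#' @param parent_scan Parent MS2 scan id (level 3).
#' @param selected_mz m/z of the MS2 fragment selected for MS3 (level 3).
#' @param activation Activation label (`"CID"`, `"HCD"`, `"stepped-HCD"`).
#' @return A one-row run tibble.
#' @export
spectrum_row <- function(scan, ms_level, mz, intensity,
                         precursor_mz = NA_real_, precursor_charge = 0L,
                         parent_scan = NA_integer_, selected_mz = NA_real_,
                         activation = NA_character_) {
  if (length(mz) != length(intensity)) rlang::abort("mz/intensity length mismatch")
  if (length(mz) && (any(mz <= 0) || any(intensity < 0))) {
    rlang::abort("peaks must have mz > 0 and intensity >= 0")
  }
  o <- order(mz)
  tibble::tibble(
    scan = as.integer(scan), ms_level = as.integer(ms_level),
    precursor_mz = precursor_mz, precursor_charge = as.integer(precursor_charge),
    parent_scan = as.integer(parent_scan), selected_mz = selected_mz,
    activation = activation, orphan = FALSE,
    peaks = list(tibble::tibble(mz = mz[o], intensity = intensity[o]))
  )
}

#' Assemble spectra into a run
#'
#' @param ... One-row spectrum tibbles from [spectrum_row()] (or already-bound
#'   run tibbles).
#' @param file,linker,replicate Optional per-run metadata recycled over rows.
#' @return A run tibble with resolved MS3 lineage; MS3 rows whose parent scan
#'   is absent are flagged `orphan` with a warning.
#' @export
as_run <- function(..., file = NA_character_, linker = NA_character_,
                   replicate = NA_character_) {
  run <- dplyr::bind_rows(...)
  if (nrow(run) && anyDuplicated(run$scan)) {
    rlang::abort("scan ids must be unique within a run")
  }
  run$file <- file
  run$linker <- linker
  run$replicate <- replicate
  resolve_lineage(run)
}

resolve_lineage <- function(run) {
  if (!nrow(run)) return(run)
  ms2_scans <- run$scan[run$ms_level == 2]
  is_ms3 <- run$ms_level == 3
  run$orphan <- is_ms3 & !(run$parent_scan %in% ms2_scans)
  if (any(run$orphan)) {
    rlang::warn(sprintf("%d MS3 spectra have no resolvable parent MS2 (flagged orphan)",
                        sum(run$orphan)))
  }
  run
}

#' Read an MS run from MGF or mzML
#'
#' @param path File path.
#' @param format `"mgf"`, `"mzml"`, or `"auto"` (by extension).
#' @param ... Passed to the format reader.
#' @return A run tibble (see [as_run()]); peak lists are sorted, MS3 lineage
#'   resolved.
#' @export
read_run <- function(path, format = c("auto", "mgf", "mzml"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "mgf"
  }
  switch(format, mgf = read_mgf(path, ...), mzml = read_mzml(path, ...))
}

# MGF has no native MS3 lineage; we encode it in TITLE with the grammar
#   scan=<n> level=<l> [parent=<m> selected_mz=<x>]
# and recover it on read.
#' Read an MGF file
#' @param path File path.
#' @return A run tibble.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("BEGIN IONS", lines, fixed = TRUE))) {
    rlang::abort(paste0("not a valid MGF file (no BEGIN IONS): ", path))
  }
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins)) {
    rlang::abort(paste0("malformed MGF (unbalanced BEGIN/END IONS): ", path))
  }
  rows <- purrr::map2(begins, ends, function(b, e) {
    block <- lines[(b + 1):(e - 1)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- block[is_kv]
    keys <- toupper(sub("=.*", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    title <- vals[match("TITLE", keys)]
    grab <- function(field) {
      m <- regmatches(title, regexpr(paste0(field, "=[-0-9.eE]+"), title))
      if (!length(m) || is.na(title)) NA_real_ else as.numeric(sub(".*=", "", m))
    }
    pepmass <- vals[match("PEPMASS", keys)]
    charge <- vals[match("CHARGE", keys)]
    peakl <- block[!is_kv & nzchar(trimws(block))]
    pk <- if (length(peakl)) {
      m <- do.call(rbind, strsplit(trimws(peakl), "[ \t]+"))
      list(mz = as.numeric(m[, 1]), intensity = as.numeric(m[, 2]))
    } else list(mz = numeric(), intensity = numeric())
    spectrum_row(
      scan = as.integer(grab("scan")),
      ms_level = if (is.na(grab("level"))) 2L else as.integer(grab("level")),
      mz = pk$mz, intensity = pk$intensity,
      precursor_mz = if (is.na(pepmass)) NA_real_ else
        as.numeric(strsplit(pepmass, "[ \t]+")[[1]][1]),
      precursor_charge = if (is.na(charge)) 0L else
        as.integer(sub("\\+$", "", charge)),
      parent_scan = as.integer(grab("parent")),
      selected_mz = grab("selected_mz"),
      activation = {
        m <- regmatches(title, regexpr("activation=[^ ]+", title))
        if (length(m) && !is.na(title)) sub(".*=", "", m) else NA_character_
      }
    )
  })
  run <- dplyr::bind_rows(rows)
  if (any(is.na(run$scan))) run$scan[is.na(run$scan)] <- seq_len(sum(is.na(run$scan)))
  run$file <- path
  run$linker <- NA_character_
  run$replicate <- NA_character_
  resolve_lineage(run)
}

#' Write a run to MGF
#'
#' MS3 lineage is encoded in the TITLE field with the grammar
#' `scan=<n> level=<l> parent=<m> selected_mz=<x> activation=<a>`; a read /
#' write round trip reproduces m/z to 1e-4 and intensities to 1e-3 relative.
#'
#' @param run A run tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mgf <- function(run, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(run))) {
    title <- sprintf("scan=%d level=%d", run$scan[i], run$ms_level[i])
    if (!is.na(run$parent_scan[i])) {
      title <- paste0(title, sprintf(" parent=%d", run$parent_scan[i]))
    }
    if (!is.na(run$selected_mz[i])) {
      title <- paste0(title, sprintf(" selected_mz=%.6f", run$selected_mz[i]))
    }
    if (!is.na(run$activation[i])) {
      title <- paste0(title, sprintf(" activation=%s", run$activation[i]))
    }
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", title), con)
    if (!is.na(run$precursor_mz[i])) {
      writeLines(sprintf("PEPMASS=%.6f", run$precursor_mz[i]), con)
    }
    if (!is.na(run$precursor_charge[i]) && run$precursor_charge[i] > 0) {
      writeLines(sprintf("CHARGE=%d+", run$precursor_charge[i]), con)
    }
    pk <- run$peaks[[i]]
    if (nrow(pk)) {
      writeLines(sprintf("%.5f %.4f", pk$mz, pk$intensity), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read an mzML file
#'
#' Uses the mzR backend; MS3 lineage is taken from the native precursor scan
#' references.
#'
#' @param path File path.
#' @return A run tibble.
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    rlang::abort("reading mzML requires the mzR package")
  }
  h <- NULL
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  h <- mzR::header(fh)
  if (!nrow(h)) rlang::abort(paste0("empty mzML file: ", path))
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  rows <- purrr::map(seq_len(nrow(h)), function(i) {
    spectrum_row(
      scan = h$acquisitionNum[i],
      ms_level = h$msLevel[i],
      mz = pk[[i]][, 1], intensity = pk[[i]][, 2],
      precursor_mz = if (h$msLevel[i] > 1) h$precursorMZ[i] else NA_real_,
      precursor_charge = if (h$msLevel[i] > 1 && !is.na(h$precursorCharge[i]))
        h$precursorCharge[i] else 0L,
      parent_scan = if (h$msLevel[i] == 3) h$precursorScanNum[i] else NA_integer_,
      selected_mz = if (h$msLevel[i] == 3) h$precursorMZ[i] else NA_real_
    )
  })
  run <- dplyr::bind_rows(rows)
  run$file <- path
  run$linker <- NA_character_
  run$replicate <- NA_character_
  resolve_lineage(run)
}

#' Select MS2 precursors by charge
#'
#' Keeps MS2 spectra whose precursor charge lies in the given closed range;
#' the default 4-8 mirrors the acquisition used for cross-linked peptides.
#' Spectra with undetermined charge (0) are always excluded.
#'
#' @param run A run tibble.
#' @param charge_range Length-2 integer vector `c(lo, hi)`.
#' @return The filtered run tibble (MS2 rows only).
#' @export
select_precursors <- function(run, charge_range = c(4L, 8L)) {
  dplyr::filter(run, .data$ms_level == 2L,
                .data$precursor_charge >= charge_range[1],
                .data$precursor_charge <= charge_range[2],
                .data$precursor_charge > 0L)
}
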