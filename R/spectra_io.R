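## Reading/writing spectra and PSM tables, and spectrum preprocessing.
## A "spectrum" is a plain list with fields `spectrum_id`, `mz`, `intensity`
## (parallel numeric vectors sorted by m/z); a spectrum collection is a named
## list of spectra keyed by spectrum_id.

new_spectrum <- function(id, mz, intensity) {
  o <- order(mz)
  list(spectrum_id = id, mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]))
}

#' Read MS/MS spectra from MGF or mzML
#'
#' Reads a peak-list file into a named list of spectra. Spectra are assumed to
#' be decharged and deisotoped, with all fragment ions at charge 1; peaks are
#' taken at face value. Scans with no peaks are skipped with a warning.
#'
#' @param path path to the spectrum file.
#' @param format `"mgf"` or `"mzml"`; defaults to the file extension.
#' @return a named list of spectra; each spectrum is a list with elements
#'   `spectrum_id`, `mz` and `intensity`, peaks sorted by ascending m/z.
#'   Spectrum ids are MGF `TITLE`s or mzML spectrum ids and must be unique.
#' @export
read_spectra <- function(path, format = c("auto", "mgf", "mzml")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mgf = "mgf", mzml = "mzml",
                     stop("cannot infer spectrum format from extension '", ext, "'"))
  }
  if (format == "mgf") read_mgf(path) else read_mzml(path)
}

#' @rdname read_spectra
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  b <- which(lines == "BEGIN IONS")
  e <- which(lines == "END IONS")
  if (length(b) != length(e) || any(e < b)) {
    stop("malformed MGF file '", path, "': unbalanced BEGIN IONS/END IONS")
  }
  out <- vector("list", length(b))
  keep <- logical(length(b))
  ids <- character(length(b))
  for (k in seq_along(b)) {
    chunk <- lines[seq.int(b[k] + 1L, e[k] - 1L)]
    chunk <- chunk[nzchar(chunk)]
    is_meta <- grepl("^[A-Za-z]", chunk)
    title <- sub("^TITLE=", "", grep("^TITLE=", chunk, value = TRUE))
    if (length(title) != 1L) {
      stop("MGF scan #", k, " in '", path, "' has no unique TITLE line")
    }
    pk <- chunk[!is_meta]
    if (!length(pk)) {
      warning("MGF scan '", title, "' has no peaks; skipped", call. = FALSE)
      next
    }
    parts <- strsplit(trimws(pk), "[ \t]+")
    mz <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 1L)))
    int <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
    if (anyNA(mz) || anyNA(int)) {
      stop("unparseable peak line in MGF scan '", title, "' of '", path, "'")
    }
    out[[k]] <- new_spectrum(title, mz, int)
    ids[k] <- title
    keep[k] <- TRUE
  }
  out <- out[keep]
  ids <- ids[keep]
  if (anyDuplicated(ids)) {
    stop("duplicate spectrum_id in '", path, "': ", ids[duplicated(ids)][1])
  }
  names(out) <- ids
  out
}

read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the 'mzR' package")
  }
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  warning("mzML peaks are used as-is: spectra are assumed decharged and ",
          "deisotoped with maximum fragment charge 1", call. = FALSE)
  ids <- as.character(hd$spectrumId)
  npk <- vapply(pk, nrow, integer(1))
  if (any(npk == 0L)) {
    warning("skipped ", sum(npk == 0L), " empty scan(s) in '", path, "'",
            call. = FALSE)
  }
  keep <- npk > 0L
  out <- Map(function(id, m) new_spectrum(id, m[, 1], m[, 2]), ids[keep], pk[keep])
  if (anyDuplicated(names(out))) {
    stop("duplicate spectrum_id in '", path, "'")
  }
  out
}

#' Write spectra as MGF
#'
#' Writes a spectrum collection as a minimal `BEGIN IONS`/`TITLE` MGF file.
#' m/z and intensity are printed with six decimals, so a write/read round trip
#' reproduces peaks to better than 1e-6 Da.
#'
#' @param spectra named list of spectra as returned by [read_spectra()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- vapply(spectra, function(s) {
    paste(c("BEGIN IONS",
            paste0("TITLE=", s$spectrum_id),
            sprintf("%.6f %.6f", s$mz, s$intensity),
            "END IONS"), collapse = "\n")
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}

#' Preprocess a spectrum
#'
#' Normalises intensities so that the base peak equals 100 and retains only
#' the `top_n` most intense peaks. Ties at the intensity cutoff are broken in
#' favour of lower m/z; the result is sorted by ascending m/z. The operation
#' is idempotent.
#'
#' @param s a spectrum (list with `mz`, `intensity`).
#' @param top_n maximum number of peaks to retain (default 150).
#' @return the preprocessed spectrum.
#' @export
preprocess_spectrum <- function(s, top_n = 150) {
  m <- length(s$mz)
  if (m == 0L) stop("cannot preprocess an empty spectrum")
  int <- s$intensity * (100 / max(s$intensity))
  if (m > top_n) {
    keep <- sort(order(-int, s$mz)[seq_len(top_n)])
    s$mz <- s$mz[keep]
    int <- int[keep]
  }
  s$intensity <- int
  s
}

## Default column mapping for the PSM table dialect. Values are the expected
## header names; the names are the internal field names.
psm_default_cols <- c(
  spectrum_id = "Spectrum",
  peptide     = "Peptide",
  mods        = "Assigned Modifications",
  charge      = "Charge",
  mass_shift  = "Delta Mass",
  evalue      = "Expectation"
)

#' Read a PSM table
#'
#' Reads a tab-separated table of peptide-spectrum matches from an open or
#' mass-offset search. The default schema expects the columns `Spectrum`,
#' `Peptide`, `Assigned Modifications`, `Charge`, `Delta Mass` and
#' `Expectation`; other headers can be supplied through `col_map`.
#'
#' Modification strings are comma-separated entries of the form
#' `"3S(79.9663)"` (1-based residue position, residue letter, mass delta) or
#' `"N-term(42.0106)"` / `"C-term(42.0106)"` for terminal modifications.
#'
#' @param path path to the TSV file.
#' @param col_map named character vector mapping internal field names
#'   (`spectrum_id`, `peptide`, `mods`, `charge`, `mass_shift`, `evalue`) to
#'   the file's header names; defaults to the schema above.
#' @param spectra optional spectrum collection; if given, a logical column
#'   `in_spectra` flags rows whose spectrum was loaded.
#' @return a data.frame with columns `spectrum_id`, `peptide`, `mods` (raw
#'   string), `var_mods` (list column of parsed `(pos, delta)` data.frames),
#'   `charge`, `mass_shift`, `evalue`, and optionally `in_spectra`.
#' @export
read_psm_table <- function(path, col_map = NULL, spectra = NULL) {
  cols <- psm_default_cols
  if (!is.null(col_map)) cols[names(col_map)] <- col_map
  tab <- read.delim(path, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  missing <- setdiff(unname(cols), names(tab))
  if (length(missing)) {
    stop("PSM table '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- data.frame(
    spectrum_id = tab[[cols["spectrum_id"]]],
    peptide = tab[[cols["peptide"]]],
    mods = tab[[cols["mods"]]],
    charge = as.integer(tab[[cols["charge"]]]),
    mass_shift = as.numeric(tab[[cols["mass_shift"]]]),
    evalue = as.numeric(tab[[cols["evalue"]]]),
    stringsAsFactors = FALSE
  )
  out$var_mods <- lapply(seq_len(nrow(out)), function(i) {
    tryCatch(parse_mod_string(out$mods[i], nchar(out$peptide[i])),
             error = function(e) {
               stop("row ", i, " of '", path, "': ", conditionMessage(e),
                    call. = FALSE)
             })
  })
  if (any(out$evalue < 0, na.rm = TRUE)) stop("negative expectation value in '", path, "'")
  if (!is.null(spectra)) {
    out$in_spectra <- out$spectrum_id %in% names(spectra)
    if (!all(out$in_spectra)) {
      warning(sum(!out$in_spectra), " PSM(s) reference no loaded spectrum",
              call. = FALSE)
    }
  }
  out
}

#' Parse an assigned-modifications string
#'
#' @param x modification string, e.g. `"3S(79.9663), N-term(42.0106)"`; empty
#'   strings and `NA` mean no variable modifications.
#' @param peptide_length length of the host peptide, used to validate residue
#'   positions.
#' @return a data.frame with character column `pos` (`"1"`..`"n"`, `"N-term"`,
#'   `"C-term"`) and numeric column `delta`.
#' @export
parse_mod_string <- function(x, peptide_length = Inf) {
  if (is.na(x) || !nzchar(trimws(x))) {
    return(data.frame(pos = character(), delta = numeric(),
                      stringsAsFactors = FALSE))
  }
  items <- trimws(strsplit(x, ",")[[1]])
  items <- items[nzchar(items)]
  pos <- character(length(items))
  delta <- numeric(length(items))
  for (i in seq_along(items)) {
    it <- items[i]
    m <- regmatches(it, regexec("^([0-9]+)[A-Z]\\((-?[0-9.]+)\\)$", it))[[1]]
    if (length(m) == 3L) {
      p <- as.integer(m[2])
      if (p < 1L || p > peptide_length) {
        stop("modification position ", p, " outside peptide in '", x, "'")
      }
      pos[i] <- m[2]
      delta[i] <- as.numeric(m[3])
      next
    }
    m <- regmatches(it, regexec("^(N-term|C-term)\\((-?[0-9.]+)\\)$", it))[[1]]
    if (length(m) == 3L) {
      pos[i] <- m[2]
      delta[i] <- as.numeric(m[3])
      next
    }
    stop("unparseable modification entry '", it, "'")
  }
  data.frame(pos = pos, delta = delta, stringsAsFactors = FALSE)
}

## Inverse of parse_mod_string, used by the synthetic generator/table writer.
format_mod_string <- function(var_mods, peptide = NULL) {
  if (is.null(var_mods) || nrow(var_mods) == 0L) return("")
  lab <- vapply(seq_len(nrow(var_mods)), function(i) {
    p <- var_mods$pos[i]
    if (p %in% c("N-term", "C-term")) {
      sprintf("%s(%.4f)", p, var_mods$delta[i])
    } else {
      aa <- if (is.null(peptide)) "X" else substr(peptide, as.integer(p), as.integer(p))
      sprintf("%s%s(%.4f)", p, aa, var_mods$delta[i])
    }
  }, character(1))
  paste(lab, collapse = ", ")
}

#' Write a PSM table
#'
#' Writes PSMs in the tab-separated dialect read by [read_psm_table()].
#'
#' @param psms PSM data.frame (columns `spectrum_id`, `peptide`, `mods`,
#'   `charge`, `mass_shift`, `evalue`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  out <- data.frame(
    Spectrum = psms$spectrum_id,
    Peptide = psms$peptide,
    `Assigned Modifications` = if (is.null(psms$mods)) "" else psms$mods,
    Charge = psms$charge,
    `Delta Mass` = sprintf("%.6f", psms$mass_shift),
    Expectation = sprintf("%.6g", psms$evalue),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a diagnostic feature report
#'
#' Writes validated features as a TSV with the standard report column set:
#' peak apex, ion type, mass, remainder propensity, delta mod mass, percent
#' PSMs (mod), percent PSMs (unmod), avg intensity (mod), avg intensity
#' (unmod), intensity fold change, E-value and AUC.
#'
#' @param features feature data.frame as produced by [mine_all()] (the
#'   `features` element of the report), or a `mine_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_report <- function(features, path) {
  if (inherits(features, "mine_report")) features <- features$features
  ion_type <- ifelse(features$feature_class == "diagnostic", "diagnostic",
              ifelse(features$feature_class == "peptide_remainder", "peptide",
                     features$ion_series))
  out <- data.frame(
    `peak apex` = sprintf("%.4f", features$bin_apex),
    `ion type` = ion_type,
    mass = sprintf("%.4f", features$mass),
    `remainder propensity` = ifelse(is.na(features$propensity), "",
                                    sprintf("%.2f", features$propensity)),
    `delta mod mass` = ifelse(is.na(features$delta_mod_mass), "",
                              sprintf("%.4f", features$delta_mod_mass)),
    `percent PSMs (mod)` = sprintf("%.2f", features$percent_mod),
    `percent PSMs (unmod)` = sprintf("%.2f", features$percent_unmod),
    `avg intensity (mod)` = sprintf("%.2f", features$avg_int_mod),
    `avg intensity (unmod)` = sprintf("%.2f", features$avg_int_unmod),
    `intensity fold change` = sprintf("%.2f", features$fold_change),
    `E-value` = sprintf("%.3g", features$e_value),
    AUC = sprintf("%.3f", features$auc),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a mass-shift summary table
#'
#' @param report a `mine_report` from [mine_all()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mass_shift_summary <- function(report, path) {
  write.table(report$summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
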