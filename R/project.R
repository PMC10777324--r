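#' Create an empty project workspace
#'
#' A project bundles spectra (raw FIDs and/or processed spectra with their
#' filter chains and analyzed ranges), molecules, assignment links between
#' signals and atoms, and an opaque display map, all serializable to a
#' single JSON document.
#'
#' @return an object of class `nmr_project` (schema version 1).
#' @export
new_project <- function() {
  structure(list(version = 1L, spectra = list(), molecules = list(),
                 assignments = list(), display = list(), extra = list()),
            class = "nmr_project")
}

#' Add a spectrum to a project
#' @param p an `nmr_project`.
#' @param raw optional [raw_fid()].
#' @param spectrum optional `spectrum1d`.
#' @param ranges optional list of ranges.
#' @param id identifier; default auto-numbered.
#' @return the project.
#' @export
project_add_spectrum <- function(p, raw = NULL, spectrum = NULL,
                                 ranges = list(), id = NULL) {
  stopifnot(inherits(p, "nmr_project"))
  if (is.null(id)) id <- sprintf("spectrum-%d", length(p$spectra) + 1L)
  p$spectra[[length(p$spectra) + 1L]] <-
    list(id = id, raw = raw, spectrum = spectrum, ranges = ranges)
  p
}

#' Add a molecule to a project
#' @param p an `nmr_project`.
#' @param mol a [parse_molfile()] molecule.
#' @param id identifier; default auto-numbered.
#' @return the project.
#' @export
project_add_molecule <- function(p, mol, id = NULL) {
  stopifnot(inherits(p, "nmr_project"), inherits(mol, "molecule"))
  if (is.null(id)) id <- sprintf("molecule-%d", length(p$molecules) + 1L)
  p$molecules[[length(p$molecules) + 1L]] <- list(id = id, molecule = mol)
  p
}

#' Link a signal to molecule atoms
#' @param p an `nmr_project`.
#' @param spectrum_id,molecule_id endpoint ids (must exist).
#' @param signal_id free-form signal identifier within the spectrum.
#' @param atom_indices integer atom indices into the molecule.
#' @return the project.
#' @export
project_add_assignment <- function(p, spectrum_id, signal_id, molecule_id,
                                   atom_indices) {
  stopifnot(inherits(p, "nmr_project"))
  p$assignments[[length(p$assignments) + 1L]] <-
    list(spectrum_id = spectrum_id, signal_id = signal_id,
         molecule_id = molecule_id, atom_indices = as.integer(atom_indices))
  p
}

b64_doubles <- function(x) jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                                         size = 8L,
                                                         endian = "little"))
unb64_doubles <- function(s) {
  r <- jsonlite::base64_dec(s)
  readBin(r, "double", n = length(r) %/% 8L, size = 8L, endian = "little")
}

serialize_fid <- function(fid) {
  if (is.null(fid)) return(NULL)
  list(data_real = b64_doubles(Re(fid$data)),
       data_imag = b64_doubles(Im(fid$data)),
       dtype = "float64le",
       sw_hz = fid$sw_hz, sfo1_mhz = fid$sfo1_mhz,
       nucleus = fid$nucleus, solvent = fid$solvent,
       group_delay_pts = fid$group_delay_pts,
       center_ppm = fid$center_ppm)
}

deserialize_fid <- function(x) {
  if (is.null(x)) return(NULL)
  raw_fid(complex(real = unb64_doubles(x$data_real),
                  imaginary = unb64_doubles(x$data_imag)),
          sw_hz = x$sw_hz, sfo1_mhz = x$sfo1_mhz, nucleus = x$nucleus,
          solvent = x$solvent, group_delay_pts = x$group_delay_pts,
          center_ppm = x$center_ppm)
}

serialize_chain <- function(chain) {
  lapply(chain, function(f)
    list(name = f$name, params = f$params, enabled = f$enabled))
}

deserialize_chain <- function(x) {
  lapply(x, function(f) filter_record(f$name, f$params, f$enabled))
}

serialize_spectrum <- function(spec) {
  if (is.null(spec)) return(NULL)
  list(data_real = b64_doubles(Re(spec$data)),
       data_imag = b64_doubles(Im(spec$data)),
       ppm_first = spec$ppm[1], ppm_last = spec$ppm[length(spec$ppm)],
       n_points = length(spec$data), dtype = "float64le",
       sw_hz = spec$sw_hz, sfo1_mhz = spec$sfo1_mhz,
       nucleus = spec$nucleus, solvent = spec$solvent,
       center_ppm = spec$center_ppm,
       chain = serialize_chain(spec$chain))
}

deserialize_spectrum <- function(x) {
  if (is.null(x)) return(NULL)
  new_spectrum1d(
    complex(real = unb64_doubles(x$data_real),
            imaginary = unb64_doubles(x$data_imag)),
    seq(x$ppm_first, x$ppm_last, length.out = x$n_points),
    x$sfo1_mhz, x$sw_hz, x$nucleus, x$solvent, x$center_ppm,
    deserialize_chain(x$chain))
}

serialize_ranges <- function(ranges) {
  lapply(ranges, function(rg) list(
    from_ppm = rg$from_ppm, to_ppm = rg$to_ppm,
    absolute_integral = rg$absolute_integral,
    relative_integral = rg$relative_integral,
    signals = lapply(rg$signals, function(s) list(
      delta_ppm = s$delta_ppm, multiplicity = s$multiplicity,
      j_hz = as.list(s$j_hz), intensity_sum = s$intensity_sum,
      assigned_atoms = as.list(s$assigned_atoms), n_h = s$n_h))))
}

deserialize_ranges <- function(x) {
  lapply(x, function(rg) {
    sig <- lapply(rg$signals, function(s) {
      out <- new_signal(s$delta_ppm, s$multiplicity,
                        as.numeric(unlist(s$j_hz)), s$intensity_sum)
      out$assigned_atoms <- as.integer(unlist(s$assigned_atoms))
      out$n_h <- s$n_h %||% NA_real_
      out
    })
    structure(list(from_ppm = rg$from_ppm, to_ppm = rg$to_ppm,
                   absolute_integral = rg$absolute_integral,
                   relative_integral = rg$relative_integral %||% NA_real_,
                   signals = sig), class = "nmr_range")
  })
}

validate_project <- function(p) {
  sp_ids <- vapply(p$spectra, function(s) s$id, character(1))
  mol_ids <- vapply(p$molecules, function(m) m$id, character(1))
  for (a in p$assignments) {
    if (!a$spectrum_id %in% sp_ids)
      stop("dangling assignment: unknown spectrum id ", a$spectrum_id)
    if (!a$molecule_id %in% mol_ids)
      stop("dangling assignment: unknown molecule id ", a$molecule_id)
    mol <- p$molecules[[match(a$molecule_id, mol_ids)]]$molecule
    if (any(a$atom_indices < 1 | a$atom_indices > nrow(mol$atoms)))
      stop("dangling assignment: atom index out of range for ", a$molecule_id)
  }
  invisible(TRUE)
}

#' Save a project to a JSON file
#'
#' One self-contained JSON document ("nmrkit project v1"): numeric arrays
#' are stored losslessly as base64-encoded little-endian IEEE 754 doubles
#' with a declared dtype, so `load_project(save_project(p))` reproduces
#' every float bit-for-bit, and saving again produces a byte-identical
#' file (fixed key order, fixed formatting).
#'
#' @param p an `nmr_project`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
save_project <- function(p, path) {
  stopifnot(inherits(p, "nmr_project"))
  validate_project(p)
  doc <- list(
    format = "nmrkit-project",
    version = p$version,
    spectra = lapply(p$spectra, function(s) list(
      id = s$id,
      raw = serialize_fid(s$raw),
      spectrum = serialize_spectrum(s$spectrum),
      ranges = serialize_ranges(s$ranges))),
    molecules = lapply(p$molecules, function(m) list(
      id = m$id, molfile = m$molecule$source_molfile)),
    assignments = p$assignments,
    display = p$display
  )
  doc <- c(doc, p$extra)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Load a project from a JSON file
#'
#' Unknown top-level keys are preserved and re-emitted on the next save.
#'
#' @param path a file written by [save_project()].
#' @return an `nmr_project`.
#' @export
load_project <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$version)) stop("unversioned project file")
  if (doc$version > 1) stop("incompatible project schema version ", doc$version)
  p <- new_project()
  p$version <- as.integer(doc$version)
  p$spectra <- lapply(doc$spectra %||% list(), function(s) list(
    id = s$id,
    raw = deserialize_fid(s$raw),
    spectrum = deserialize_spectrum(s$spectrum),
    ranges = deserialize_ranges(s$ranges %||% list())))
  p$molecules <- lapply(doc$molecules %||% list(), function(m) list(
    id = m$id, molecule = parse_molfile(m$molfile)))
  p$assignments <- lapply(doc$assignments %||% list(), function(a) list(
    spectrum_id = a$spectrum_id, signal_id = a$signal_id,
    molecule_id = a$molecule_id,
    atom_indices = as.integer(unlist(a$atom_indices))))
  p$display <- doc$display %||% list()
  known <- c("format", "version", "spectra", "molecules", "assignments",
             "display")
  p$extra <- doc[setdiff(names(doc), known)]
  p
}

#' Import any supported input as a project
#'
#' Dispatches by content sniffing, not extension: Bruker directories
#' (`acqus` + `fid`), JCAMP-DX documents (FID or spectrum blocks), V2000
#' molfiles, and nmrkit project JSON all become a project.
#'
#' @param path file or directory.
#' @return an `nmr_project`.
#' @export
import_any <- function(path) {
  if (dir.exists(path)) {
    if (file.exists(file.path(path, "acqus")) &&
        file.exists(file.path(path, "fid"))) {
      p <- new_project()
      return(project_add_spectrum(p, raw = read_bruker(path)))
    }
    stop("directory is not a Bruker dataset: ", path)
  }
  if (!file.exists(path)) stop("no such file: ", path)
  head_lines <- readLines(path, n = 20, warn = FALSE)
  txt <- paste(head_lines, collapse = "\n")
  if (grepl("##TITLE=", txt, fixed = TRUE)) {
    blocks <- parse_jcamp(path)
    p <- new_project()
    for (blk in blocks) {
      obj <- jcamp_block_to_object(blk)
      if (inherits(obj, "raw_fid"))
        p <- project_add_spectrum(p, raw = obj)
      else
        p <- project_add_spectrum(p, spectrum = obj)
    }
    return(p)
  }
  if (grepl("^\\s*\\{", txt)) {
    doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                    error = function(e) NULL)
    if (!is.null(doc) && identical(doc$format, "nmrkit-project"))
      return(load_project(path))
  }
  if (grepl("V2000", txt, fixed = TRUE)) {
    p <- new_project()
    return(project_add_molecule(p, parse_molfile(path)))
  }
  stop("unrecognized input: ", path,
       " (supported: Bruker directory, JCAMP-DX, V2000 molfile, ",
       "nmrkit project JSON)")
}
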