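#' Read a Bruker raw-data directory
#'
#' Reads `acqus` (JCAMP-like parameter file) and the binary `fid` from a
#' Bruker 1D acquisition directory.  The TD interleaved real/imaginary
#' values are assembled into `TD/2` complex points, decoded with the byte
#' order (`BYTORDA`) and data type (`DTYPA`: 0 = int32, 2 = float64) the
#' parameter file declares, and scaled by `2^NC` when an `NC` exponent is
#' present.  The digital-filter group delay (`GRPDLY`) is recorded on the
#' returned FID, not silently applied; [fourier_transform()] compensates it
#' as a first-order phase ramp of 360 degrees times the group delay across
#' the spectral width.
#'
#' @param directory path containing `acqus` and `fid`.
#' @return a [raw_fid()].
#' @export
read_bruker <- function(directory) {
  acqus_path <- file.path(directory, "acqus")
  fid_path <- file.path(directory, "fid")
  if (!file.exists(acqus_path)) stop("missing file: ", acqus_path)
  if (!file.exists(fid_path)) stop("missing file: ", fid_path)
  p <- parse_acqus(acqus_path)
  if (is.na(p$td) || p$td <= 0 || p$td %% 2 != 0)
    stop("acqus TD must be even and positive")
  if (is.na(p$sw_h) || p$sw_h <= 0) stop("acqus SW_h must be > 0")
  if (is.na(p$sfo1) || p$sfo1 <= 0) stop("acqus SFO1 must be > 0")
  size <- if (p$dtypa == 2) 8L else 4L
  what <- if (p$dtypa == 2) "double" else "integer"
  endian <- if (p$bytorda == 1) "big" else "little"
  nbytes <- file.info(fid_path)$size
  if (nbytes < p$td * size)
    stop(sprintf("fid holds %d bytes but TD=%d needs %d bytes",
                 nbytes, p$td, p$td * size))
  con <- file(fid_path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = what, n = p$td, size = size, endian = endian)
  v <- as.numeric(v) * 2^(p$nc %||% 0)
  re <- v[seq(1, p$td, by = 2)]
  im <- v[seq(2, p$td, by = 2)]
  raw_fid(complex(real = re, imaginary = im),
          sw_hz = p$sw_h, sfo1_mhz = p$sfo1,
          nucleus = p$nuc1 %||% "1H", solvent = p$solvent %||% "unknown",
          group_delay_pts = if (!is.na(p$grpdly) && p$grpdly > 0) p$grpdly else NULL,
          center_ppm = (p$o1 %||% 0) / p$sfo1)
}

parse_acqus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  getp <- function(name) {
    pat <- paste0("^##\\$", name, "= ?(.*)$")
    hit <- grep(pat, lines, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    sub(pat, "\\1", hit[1])
  }
  num <- function(name) suppressWarnings(as.numeric(getp(name)))
  strv <- function(name) {
    v <- getp(name)
    if (is.na(v)) return(NULL)
    gsub("[<>]", "", trimws(v))
  }
  list(
    td = as.integer(num("TD")),
    sw_h = num("SW_h"),
    sfo1 = num("SFO1"),
    o1 = {
      o <- num("O1"); if (is.na(o)) 0 else o
    },
    bytorda = {
      b <- num("BYTORDA"); if (is.na(b)) 0 else b
    },
    dtypa = {
      d <- num("DTYPA"); if (is.na(d)) 0 else d
    },
    grpdly = num("GRPDLY"),
    nc = {
      n <- num("NC"); if (is.na(n)) 0 else n
    },
    nuc1 = strv("NUC1"),
    solvent = strv("SOLVENT")
  )
}

#' Write a minimal Bruker fixture directory
#'
#' Writes an `acqus` parameter file and binary `fid` readable by
#' [read_bruker()].  `read_bruker(make_bruker_fixture(x))` recovers the
#' dwell time, observe frequency and complex data (within int32
#' quantization when storing as integers; a `2^NC` scaling exponent is
#' recorded so the decoded amplitude stays within 1e-6 of the input).
#'
#' @param directory output directory (created if needed).
#' @param fid a [raw_fid()].
#' @param data_type `"int32"` or `"float64"`.
#' @param byte_order `"little"` or `"big"`.
#' @return invisibly, `directory`.
#' @export
make_bruker_fixture <- function(directory, fid,
                                data_type = c("int32", "float64"),
                                byte_order = c("little", "big")) {
  stopifnot(inherits(fid, "raw_fid"))
  data_type <- match.arg(data_type)
  byte_order <- match.arg(byte_order)
  if (length(fid$data) == 0) stop("empty fid")
  ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("directory not writable: ", directory)
  v <- as.numeric(rbind(Re(fid$data), Im(fid$data)))   # interleave
  td <- length(v)
  nc <- 0
  if (data_type == "int32") {
    m <- max(abs(v))
    if (m > 0) nc <- ceiling(log2(m / 2^29))
    v <- round(v / 2^nc)
  }
  acqus <- c(
    "##TITLE= Parameter file",
    "##JCAMPDX= 5.0",
    "##DATA TYPE= Parameter Values",
    sprintf("##$TD= %d", td),
    sprintf("##$SW_h= %.10g", fid$sw_hz),
    sprintf("##$SFO1= %.10g", fid$sfo1_mhz),
    sprintf("##$O1= %.10g", fid$center_ppm * fid$sfo1_mhz),
    sprintf("##$BYTORDA= %d", if (byte_order == "big") 1L else 0L),
    sprintf("##$DTYPA= %d", if (data_type == "float64") 2L else 0L),
    sprintf("##$NC= %d", as.integer(nc)),
    if (!is.null(fid$group_delay_pts))
      sprintf("##$GRPDLY= %.10g", fid$group_delay_pts),
    sprintf("##$NUC1= <%s>", fid$nucleus),
    sprintf("##$SOLVENT= <%s>", fid$solvent),
    "##END="
  )
  writeLines(acqus, file.path(directory, "acqus"))
  con <- file(file.path(directory, "fid"), "wb")
  on.exit(close(con))
  if (data_type == "int32") {
    writeBin(as.integer(v), con, size = 4L, endian = byte_order)
  } else {
    writeBin(v, con, size = 8L, endian = byte_order)
  }
  invisible(directory)
}
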