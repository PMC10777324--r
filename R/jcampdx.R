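#' @name jcampdx
#' @title JCAMP-DX reading and writing
#' @description
#' JCAMP-DX is the ASCII exchange format the whole toolkit rests on.  The
#' reader covers the common denominator of 1D instrument exports:
#' `##XYDATA=(X++(Y..Y))` tables in AFFN (plain numbers) and ASDF compressed
#' form (SQZ, DIF, DUP digits, with DIF checkpoint verification), and
#' `##NTUPLES` blocks with separate real/imaginary pages for complex FIDs.
#' Compound (LINK) files yield one block per contained spectrum.  Unknown
#' and vendor-private (`##$FOO`) labels are preserved verbatim and passed
#' through untouched.
NULL

SQZ_POS <- c(`@` = 0, A = 1, B = 2, C = 3, D = 4, E = 5, F = 6, G = 7, H = 8, I = 9)
SQZ_NEG <- c(a = 1, b = 2, c = 3, d = 4, e = 5, f = 6, g = 7, h = 8, i = 9)
DIF_POS <- c(`%` = 0, J = 1, K = 2, L = 3, M = 4, N = 5, O = 6, P = 7, Q = 8, R = 9)
DIF_NEG <- c(j = 1, k = 2, l = 3, m = 4, n = 5, o = 6, p = 7, q = 8, r = 9)
DUP_DIG <- c(S = 1, T = 2, U = 3, V = 4, W = 5, X = 6, Y = 7, Z = 8, s = 9)

# tokenize one ASDF/AFFN data line into list(kind, value) tokens
asdf_tokens <- function(line, lineno) {
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  toks <- list()
  buf <- ""
  kind <- NULL      # "affn", "sqz", "dif", "dup"
  sign <- 1
  lead <- 0
  flush <- function() {
    if (is.null(kind)) return()
    if (buf == "" && kind == "affn")
      stop(sprintf("malformed numeric value at line %d", lineno))
    val <- if (buf == "") 0 else suppressWarnings(as.numeric(buf))
    if (is.na(val)) stop(sprintf("malformed numeric value at line %d", lineno))
    if (kind == "affn") {
      toks[[length(toks) + 1L]] <<- list(kind = "affn", value = sign * val)
    } else {
      # lead digit followed by plain digits: value = lead * 10^nd + digits
      full <- sign * (lead * 10^nchar(buf) + (if (buf == "") 0 else val))
      toks[[length(toks) + 1L]] <<- list(kind = kind, value = full)
    }
    buf <<- ""; kind <<- NULL; sign <<- 1; lead <<- 0
  }
  in_exp <- function() {
    !is.null(kind) && kind == "affn" && nchar(buf) > 0 &&
      substr(buf, nchar(buf), nchar(buf)) %in% c("E", "e")
  }
  for (ci in seq_along(chars)) {
    ch <- chars[ci]
    nxt <- if (ci < length(chars)) chars[ci + 1] else ""
    if (ch %in% c(" ", ",", "\t", ";")) {
      flush()
    } else if (ch %in% c("E", "e") && !is.null(kind) && kind == "affn" &&
               grepl("[0-9]$", buf) && nxt %in% c("+", "-")) {
      # AFFN exponent marker; a bare E before digits is the SQZ digit 5
      buf <- paste0(buf, ch)
    } else if (ch %in% c("+", "-") && in_exp()) {
      buf <- paste0(buf, ch)                     # exponent sign
    } else if (ch %in% c("+", "-")) {
      flush()
      kind <- "affn"; sign <- if (ch == "-") -1 else 1
    } else if (grepl("[0-9.]", ch)) {
      if (is.null(kind)) { kind <- "affn"; sign <- 1 }
      if (kind != "affn" && ch == ".")
        stop(sprintf("malformed numeric value at line %d", lineno))
      buf <- paste0(buf, ch)
    } else if (ch %in% names(SQZ_POS) || ch %in% names(SQZ_NEG)) {
      flush()
      kind <- "sqz"
      if (ch %in% names(SQZ_POS)) { sign <- 1; lead <- SQZ_POS[[ch]] }
      else { sign <- -1; lead <- SQZ_NEG[[ch]] }
    } else if (ch %in% names(DIF_POS) || ch %in% names(DIF_NEG)) {
      flush()
      kind <- "dif"
      if (ch %in% names(DIF_POS)) { sign <- 1; lead <- DIF_POS[[ch]] }
      else { sign <- -1; lead <- DIF_NEG[[ch]] }
    } else if (ch %in% names(DUP_DIG)) {
      flush()
      kind <- "dup"; sign <- 1; lead <- DUP_DIG[[ch]]
    } else if (ch == "?") {
      flush()
      toks[[length(toks) + 1L]] <- list(kind = "invalid", value = NA_real_)
    } else {
      stop(sprintf("unexpected character '%s' in data at line %d", ch, lineno))
    }
  }
  flush()
  toks
}

# decode (X++(Y..Y)) data lines into raw ordinate integers/values
decode_xydata <- function(lines, linenos) {
  y <- numeric(0)
  prev_dif <- FALSE
  for (li in seq_along(lines)) {
    line <- trimws(lines[[li]])
    if (line == "") next
    toks <- asdf_tokens(line, linenos[[li]])
    if (length(toks) < 2)
      stop(sprintf("data line with no ordinates at line %d", linenos[[li]]))
    if (toks[[1]]$kind != "affn")
      stop(sprintf("line must start with an AFFN abscissa at line %d", linenos[[li]]))
    first <- TRUE
    for (tk in toks[-1]) {
      if (tk$kind == "invalid")
        stop(sprintf("invalid '?' ordinate at line %d", linenos[[li]]))
      if (first && prev_dif) {
        # checkpoint: first ordinate repeats the last value of previous line
        if (tk$kind == "dif" || tk$kind == "dup")
          stop(sprintf("expected checkpoint ordinate at line %d", linenos[[li]]))
        if (length(y) == 0 || abs(tk$value - y[length(y)]) > 1e-9 * max(1, abs(tk$value)))
          stop(sprintf("DIF checkpoint mismatch at line %d", linenos[[li]]))
        first <- FALSE
        prev_dif <- FALSE
        next
      }
      first <- FALSE
      if (tk$kind == "dif") {
        if (length(y) == 0)
          stop(sprintf("DIF with no previous ordinate at line %d", linenos[[li]]))
        y <- c(y, y[length(y)] + tk$value)
        prev_dif <- TRUE
      } else if (tk$kind == "dup") {
        if (length(y) < 1 || (prev_dif && length(y) < 2))
          stop(sprintf("DUP with no previous ordinate at line %d", linenos[[li]]))
        rep_n <- tk$value - 1L
        if (prev_dif) {
          last_diff <- y[length(y)] - (if (length(y) >= 2) y[length(y) - 1] else 0)
          for (q in seq_len(rep_n)) y <- c(y, y[length(y)] + last_diff)
        } else {
          y <- c(y, rep(y[length(y)], rep_n))
        }
      } else {
        y <- c(y, tk$value)
        prev_dif <- FALSE
      }
    }
  }
  y
}

ldr_key <- function(label) {
  k <- toupper(gsub("[ _-]", "", label))
  k
}

# split text into LDR records: list(label, value, data_lines, linenos)
scan_ldrs <- function(lines) {
  idx <- grep("^##", lines)
  recs <- list()
  for (j in seq_along(idx)) {
    i <- idx[j]
    end <- if (j < length(idx)) idx[j + 1] - 1L else length(lines)
    m <- regmatches(lines[i], regexec("^##([^=]*)=(.*)$", lines[i]))[[1]]
    if (length(m) < 3) next
    label <- trimws(m[2])
    value <- trimws(m[3])
    body <- if (end > i) lines[(i + 1):end] else character(0)
    # drop comment-only lines
    keep <- !grepl("^\\$\\$", trimws(body))
    recs[[length(recs) + 1L]] <- list(label = label, value = value,
                                      data_lines = body[keep],
                                      linenos = ((i + 1):end)[keep],
                                      lineno = i)
  }
  recs
}

parse_block_recs <- function(recs) {
  ldrs <- list()
  title <- ""; data_type <- ""
  x_units <- ""; y_units <- ""
  xf <- 1; yf <- 1; firstx <- NA_real_; lastx <- NA_real_; np <- NA_integer_
  data <- NULL
  ntuples <- NULL
  i <- 1
  num <- function(v) suppressWarnings(as.numeric(v))
  while (i <= length(recs)) {
    r <- recs[[i]]
    key <- ldr_key(r$label)
    if (key == "TITLE") title <- r$value
    else if (key == "DATATYPE") data_type <- r$value
    else if (key == "XUNITS") x_units <- r$value
    else if (key == "YUNITS") y_units <- r$value
    else if (key == "XFACTOR") xf <- num(r$value)
    else if (key == "YFACTOR") yf <- num(r$value)
    else if (key == "FIRSTX") firstx <- num(r$value)
    else if (key == "LASTX") lastx <- num(r$value)
    else if (key == "NPOINTS") np <- as.integer(num(r$value))
    if (key == "PEAKTABLE")
      stop("unsupported JCAMP data class: PEAK TABLE")
    if (key == "XYDATA") {
      raw <- decode_xydata(r$data_lines, r$linenos)
      data <- raw * yf
      if (!is.na(np) && length(data) != np)
        stop(sprintf("##NPOINTS=%d but %d points decoded", np, length(data)))
    }
    if (key == "NTUPLES") {
      nt <- list(symbols = character(0), factors = numeric(0),
                 firsts = numeric(0), lasts = numeric(0), dims = integer(0),
                 pages = list())
      j <- i + 1
      while (j <= length(recs) && ldr_key(recs[[j]]$label) != "ENDNTUPLES" &&
             ldr_key(recs[[j]]$label) != "END") {
        rr <- recs[[j]]
        kk <- ldr_key(rr$label)
        splitcsv <- function(v) trimws(strsplit(v, ",")[[1]])
        if (kk == "SYMBOL") nt$symbols <- splitcsv(rr$value)
        else if (kk == "FACTOR") nt$factors <- num(splitcsv(rr$value))
        else if (kk == "FIRST") nt$firsts <- num(splitcsv(rr$value))
        else if (kk == "LAST") nt$lasts <- num(splitcsv(rr$value))
        else if (kk == "VARDIM") nt$dims <- as.integer(num(splitcsv(rr$value)))
        else if (kk == "DATATABLE") {
          sym <- if (grepl("R\\.\\.R", rr$value)) "R"
                 else if (grepl("I\\.\\.I", rr$value)) "I"
                 else if (grepl("Y\\.\\.Y", rr$value)) "Y"
                 else stop("unsupported DATA TABLE form: ", rr$value)
          raw <- decode_xydata(rr$data_lines, rr$linenos)
          nt$pages[[sym]] <- raw
        }
        j <- j + 1
      }
      ntuples <- nt
      i <- j
    }
    if (!key %in% c("XYDATA", "DATATABLE"))
      ldrs[[r$label]] <- r$value
    i <- i + 1
  }
  if (!is.null(ntuples)) {
    if (is.null(ntuples$pages$R) || is.null(ntuples$pages$I))
      stop("NTUPLES block without both R and I pages is unsupported")
    ix <- match("X", ntuples$symbols)
    ir <- match("R", ntuples$symbols)
    ii <- match("I", ntuples$symbols)
    fr <- if (!is.na(ir) && length(ntuples$factors) >= ir) ntuples$factors[ir] else 1
    fi <- if (!is.na(ii) && length(ntuples$factors) >= ii) ntuples$factors[ii] else 1
    data <- complex(real = ntuples$pages$R * fr,
                    imaginary = ntuples$pages$I * fi)
    yf <- fr
    if (!is.na(ix) && length(ntuples$firsts) >= ix) {
      firstx <- ntuples$firsts[ix]
      lastx <- ntuples$lasts[ix]
    }
    if (!is.na(ix) && length(ntuples$dims) >= ix) np <- ntuples$dims[ix]
    if (!is.na(np) && length(data) != np)
      stop(sprintf("##VAR_DIM=%d but %d points decoded", np, length(data)))
  }
  structure(list(
    title = title, data_type = data_type, ldrs = ldrs,
    x_units = x_units, y_units = y_units,
    y_factor = yf, x_factor = xf,
    x_first = firstx, x_last = lastx,
    n_points = if (!is.null(data)) length(data) else np,
    data = data
  ), class = "jcamp_block")
}

#' @export
print.jcamp_block <- function(x, ...) {
  cat(sprintf("<jcamp_block> '%s' (%s), %s points, x %s..%s %s\n",
              x$title, x$data_type,
              x$n_points %||% "?", format(x$x_first), format(x$x_last),
              x$x_units))
  invisible(x)
}

#' Parse a JCAMP-DX document
#'
#' @param text either the document as a character vector of lines (or a
#'   single string with embedded newlines), or a path to a file.
#' @return a list of `jcamp_block` objects, one per data block.  Compound
#'   (LINK) files yield all contained blocks, flattened.
#' @export
parse_jcamp <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  if (length(text) == 1) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- sub("\r$", "", text)
  text[1] <- sub("^\ufeff", "", text[1])
  if (!any(grepl("^##TITLE=", text)))
    stop("not a JCAMP-DX document: no ##TITLE= record")
  recs <- scan_ldrs(text)
  # split into TITLE..END blocks (LINK blocks contain nested TITLEs)
  blocks <- list()
  stack <- list()
  for (r in recs) {
    key <- ldr_key(r$label)
    if (key == "TITLE") {
      stack[[length(stack) + 1L]] <- list()
    }
    if (length(stack) == 0) next
    stack[[length(stack)]] <- c(stack[[length(stack)]], list(r))
    if (key == "END") {
      done <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      blk <- parse_block_recs(done)
      if (!grepl("LINK", toupper(blk$data_type)))
        blocks[[length(blocks) + 1L]] <- blk
    }
  }
  if (length(stack) > 0) {
    # unterminated outermost block: still parse it
    blk <- parse_block_recs(stack[[1]])
    if (!grepl("LINK", toupper(blk$data_type)))
      blocks[[length(blocks) + 1L]] <- blk
  }
  if (length(blocks) == 0) stop("no data blocks found")
  blocks
}

fmt_num <- function(x, digits = 10) {
  s <- format(x, digits = digits, scientific = FALSE, trim = TRUE)
  s
}

sqz_encode <- function(v) {
  neg <- v < 0
  d <- formatC(abs(v), format = "d")
  first <- substr(d, 1, 1)
  rest <- substr(d, 2, nchar(d))
  map <- if (neg) names(SQZ_NEG) else names(SQZ_POS)[-1]
  lead <- ifelse(first == "0", if (neg) "@" else "@",
                 map[as.integer(first)])
  paste0(lead, rest)
}

dif_encode <- function(v) {
  neg <- v < 0
  d <- formatC(abs(v), format = "d")
  first <- substr(d, 1, 1)
  rest <- substr(d, 2, nchar(d))
  posmap <- names(DIF_POS)
  negmap <- names(DIF_NEG)
  lead <- if (first == "0") "%" else if (neg) negmap[as.integer(first)] else posmap[as.integer(first) + 1L]
  paste0(lead, rest)
}

dup_encode <- function(n) {
  d <- formatC(n, format = "d")
  first <- substr(d, 1, 1)
  rest <- substr(d, 2, nchar(d))
  paste0(names(DUP_DIG)[as.integer(first)], rest)
}

#' Write a JCAMP-DX document
#'
#' Emits a JCAMP-DX 5.01 block in `(X++(Y..Y))` tabular form.  Real data
#' can be stored as AFFN (`compression = "none"`) or DIF/DUP compressed
#' ASDF with per-line checkpoints (`"dif_dup"`).  Complex data are written
#' as an NTUPLES block with separate real and imaginary pages (AFFN).
#' Ordinates are quantized by the Y factor, chosen so the maximum absolute
#' value maps near 2^15 unless the block supplies its own; the decoded
#' values therefore agree with the input within `y_factor / 2` per point.
#' Output is pure ASCII; vendor-private `##$` labels present in `ldrs` are
#' passed through verbatim.
#'
#' @param block a `jcamp_block` (as from [parse_jcamp()]), or a list with at
#'   least `title`, `data_type`, `x_first`, `x_last`, `data`.
#' @param compression `"none"` (AFFN) or `"dif_dup"`.
#' @return character vector of lines.
#' @export
write_jcamp <- function(block, compression = c("none", "dif_dup")) {
  compression <- match.arg(compression)
  if (is.null(block$data) || length(block$data) == 0)
    stop("block has no data")
  cplx <- is.complex(block$data)
  vals <- if (cplx) c(Re(block$data), Im(block$data)) else block$data
  if (any(!is.finite(vals))) stop("non-finite data values")
  n <- length(block$data)
  firstx <- block$x_first %||% 0
  lastx <- block$x_last %||% (n - 1)
  dx <- if (n > 1) (lastx - firstx) / (n - 1) else 0
  managed <- c("TITLE", "JCAMPDX", "DATATYPE", "XUNITS", "YUNITS", "XFACTOR",
               "YFACTOR", "FIRSTX", "LASTX", "NPOINTS", "FIRSTY", "XYDATA",
               "END", "NTUPLES", "ENDNTUPLES", "PAGE", "DATACLASS",
               "VARNAME", "SYMBOL", "VARTYPE", "VARFORM", "VARDIM", "UNITS",
               "FACTOR", "FIRST", "LAST", "NUMDIM")
  extra <- character(0)
  for (lab in names(block$ldrs %||% list())) {
    if (!ldr_key(lab) %in% managed)
      extra <- c(extra, sprintf("##%s=%s", lab, block$ldrs[[lab]]))
  }
  out <- c(
    sprintf("##TITLE=%s", block$title %||% ""),
    "##JCAMP-DX=5.01",
    sprintf("##DATA TYPE=%s", block$data_type %||% "NMR SPECTRUM"),
    extra
  )
  yfac_for <- function(y) {
    m <- max(abs(y))
    if (m == 0) 1 else m / 32000
  }
  if (!cplx) {
    yf <- yfac_for(block$data)
    ints <- round(block$data / yf)
    out <- c(out,
      sprintf("##XUNITS=%s", if (nzchar(block$x_units %||% "")) block$x_units else "HZ"),
      sprintf("##YUNITS=%s", if (nzchar(block$y_units %||% "")) block$y_units else "ARBITRARY UNITS"),
      "##XFACTOR=1",
      sprintf("##YFACTOR=%s", fmt_num(yf, 17)),
      sprintf("##FIRSTX=%s", fmt_num(firstx)),
      sprintf("##LASTX=%s", fmt_num(lastx)),
      sprintf("##NPOINTS=%d", n),
      sprintf("##FIRSTY=%s", fmt_num(ints[1] * yf, 17)),
      "##XYDATA=(X++(Y..Y))",
      encode_table(ints, firstx, dx, compression),
      "##END=")
  } else {
    yfr <- yfac_for(Re(block$data))
    yfi <- yfac_for(Im(block$data))
    ir <- round(Re(block$data) / yfr)
    ii <- round(Im(block$data) / yfi)
    out <- c(out,
      "##NUM DIM=1",
      sprintf("##NTUPLES=%s", block$data_type %||% "NMR FID"),
      "##VAR_NAME= TIME, FID/REAL, FID/IMAG",
      "##SYMBOL= X, R, I",
      "##VAR_TYPE= INDEPENDENT, DEPENDENT, DEPENDENT",
      "##VAR_FORM= AFFN, AFFN, AFFN",
      sprintf("##VAR_DIM= %d, %d, %d", n, n, n),
      sprintf("##UNITS= %s, ARBITRARY UNITS, ARBITRARY UNITS",
              if (nzchar(block$x_units %||% "")) block$x_units else "SECONDS"),
      sprintf("##FACTOR= 1, %s, %s", fmt_num(yfr, 17), fmt_num(yfi, 17)),
      sprintf("##FIRST= %s, %s, %s", fmt_num(firstx),
              fmt_num(ir[1] * yfr, 17), fmt_num(ii[1] * yfi, 17)),
      sprintf("##LAST= %s, %s, %s", fmt_num(lastx),
              fmt_num(ir[n] * yfr, 17), fmt_num(ii[n] * yfi, 17)),
      "##PAGE= N=1",
      "##DATA TABLE= (X++(R..R)), XYDATA",
      encode_table(ir, firstx, dx, "none"),
      "##PAGE= N=2",
      "##DATA TABLE= (X++(I..I)), XYDATA",
      encode_table(ii, firstx, dx, "none"),
      sprintf("##END NTUPLES=%s", block$data_type %||% "NMR FID"),
      "##END=")
  }
  out
}

# encode integer ordinates as (X++(Y..Y)) lines
encode_table <- function(ints, firstx, dx, compression, per_line = 8L) {
  n <- length(ints)
  lines <- character(0)
  if (compression == "none") {
    i <- 1L
    while (i <= n) {
      j <- min(n, i + per_line - 1L)
      x <- firstx + (i - 1L) * dx
      lines <- c(lines, paste(c(fmt_num(x), formatC(ints[i:j], format = "d")),
                              collapse = " "))
      i <- j + 1L
    }
  } else {
    # DIF/DUP with a checkpoint (SQZ repeat of last ordinate) starting
    # every line after the first
    i <- 1L
    first_line <- TRUE
    while (i <= n) {
      x <- firstx + (i - 1L) * dx
      parts <- fmt_num(x)
      if (first_line) {
        parts <- paste0(parts, sqz_encode(ints[i]))
        first_line <- FALSE
      } else {
        i <- i - 1L                       # checkpoint repeats previous point
        x <- firstx + (i - 1L) * dx
        parts <- paste0(fmt_num(x), sqz_encode(ints[i]))
      }
      count <- 0L
      pend_dif <- NA_integer_             # pending repeated difference
      pend_n <- 0L
      flushdup <- function() {
        if (pend_n > 0L) {
          parts <<- paste0(parts, dif_encode(pend_dif))
          if (pend_n > 1L) parts <<- paste0(parts, dup_encode(pend_n))
        }
        pend_dif <<- NA_integer_; pend_n <<- 0L
      }
      while (i < n && count < 64L) {
        d <- ints[i + 1L] - ints[i]
        if (!is.na(pend_dif) && d == pend_dif) {
          pend_n <- pend_n + 1L
        } else {
          flushdup()
          pend_dif <- d
          pend_n <- 1L
        }
        i <- i + 1L
        count <- count + 1L
      }
      flushdup()
      lines <- c(lines, parts)
      i <- i + 1L
    }
  }
  lines
}

# build a writable jcamp block from a spectrum1d (real part, ppm axis)
spectrum_to_jcamp_block <- function(spec, title = "spectrum") {
  structure(list(
    title = title,
    data_type = "NMR SPECTRUM",
    ldrs = list(
      `.OBSERVE FREQUENCY` = fmt_num(spec$sfo1_mhz, 12),
      `.OBSERVE NUCLEUS` = paste0("^", spec$nucleus),
      `.SOLVENT NAME` = spec$solvent,
      `$SWHZ` = fmt_num(spec$sw_hz, 12),
      `$CENTERPPM` = fmt_num(spec$center_ppm, 12)
    ),
    x_units = "PPM",
    y_units = "ARBITRARY UNITS",
    x_first = spec$ppm[1],
    x_last = spec$ppm[length(spec$ppm)],
    n_points = length(spec$data),
    data = Re(spec$data)
  ), class = "jcamp_block")
}

# build a writable jcamp block from a raw fid (complex, NTUPLES)
fid_to_jcamp_block <- function(fid, title = "fid") {
  n <- length(fid$data)
  structure(list(
    title = title,
    data_type = "NMR FID",
    ldrs = list(
      `.OBSERVE FREQUENCY` = fmt_num(fid$sfo1_mhz, 12),
      `.OBSERVE NUCLEUS` = paste0("^", fid$nucleus),
      `.SOLVENT NAME` = fid$solvent,
      `$SWHZ` = fmt_num(fid$sw_hz, 12),
      `$CENTERPPM` = fmt_num(fid$center_ppm, 12),
      `$GRPDLY` = fmt_num(fid$group_delay_pts %||% 0, 12)
    ),
    x_units = "SECONDS",
    y_units = "ARBITRARY UNITS",
    x_first = 0,
    x_last = (n - 1) * fid$dwell_s,
    n_points = n,
    data = fid$data
  ), class = "jcamp_block")
}

# interpret a parsed block as raw_fid or spectrum1d using its LDRs
jcamp_block_to_object <- function(blk) {
  ld <- blk$ldrs
  getld <- function(keys, default = NULL) {
    for (nm in names(ld)) if (ldr_key(nm) %in% keys) return(ld[[nm]])
    default
  }
  num <- function(v, default = NA_real_) {
    if (is.null(v)) return(default)
    suppressWarnings(as.numeric(gsub("[^0-9eE+.-]", "", v)))
  }
  sfo1 <- num(getld(c(".OBSERVEFREQUENCY", "$SFO1")))
  sw <- num(getld(c("$SWHZ", "$SWH")))
  center <- num(getld("$CENTERPPM"), 0)
  nuc <- getld(c(".OBSERVENUCLEUS", "$NUC1"), "1H")
  nuc <- gsub("[\\^<>]", "", nuc)
  solv <- getld(c(".SOLVENTNAME", "$SOLVENT"), "unknown")
  solv <- gsub("[<>]", "", solv)
  if (is.complex(blk$data)) {
    if (is.na(sw)) {
      dt <- (blk$x_last - blk$x_first) / (blk$n_points - 1)
      sw <- 1 / dt
    }
    if (is.na(sfo1)) stop("FID block lacks an observe frequency")
    gd <- num(getld("$GRPDLY"), 0)
    raw_fid(blk$data, sw_hz = sw, sfo1_mhz = sfo1, nucleus = nuc,
            solvent = solv, group_delay_pts = if (gd > 0) gd else NULL,
            center_ppm = center)
  } else {
    ppm <- seq(blk$x_first, blk$x_last, length.out = blk$n_points)
    if (ppm[1] < ppm[length(ppm)]) {   # normalize to descending
      ppm <- rev(ppm)
      blk$data <- rev(blk$data)
    }
    if (is.na(sfo1)) stop("spectrum block lacks an observe frequency")
    if (is.na(sw)) sw <- abs(blk$x_first - blk$x_last) * sfo1
    if (is.na(center) || center == 0) center <- mean(range(ppm))
    new_spectrum1d(complex(real = blk$data), ppm, sfo1, sw, nuc, solv, center)
  }
}
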