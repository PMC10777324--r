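# an independently written ASDF encoder, used as the oracle against the
# package's decoder: it encodes the whole series token by token and then
# chunks lines, unlike the package writer

SQZ_TABLE <- c("@", "A", "B", "C", "D", "E", "F", "G", "H", "I")
SQZ_TABLE_NEG <- c("", "a", "b", "c", "d", "e", "f", "g", "h", "i")
DIF_TABLE <- c("%", "J", "K", "L", "M", "N", "O", "P", "Q", "R")
DIF_TABLE_NEG <- c("", "j", "k", "l", "m", "n", "o", "p", "q", "r")
DUP_TABLE <- c("S", "T", "U", "V", "W", "X", "Y", "Z", "s")

pseudo_digit <- function(v, pos_tab, neg_tab) {
  s <- sprintf("%d", abs(v))
  first <- as.integer(substr(s, 1, 1))
  head <- if (v < 0) neg_tab[first + 1] else pos_tab[first + 1]
  paste0(head, substr(s, 2, nchar(s)))
}

oracle_sqz <- function(v) pseudo_digit(v, SQZ_TABLE, SQZ_TABLE_NEG)
oracle_dif <- function(v) pseudo_digit(v, DIF_TABLE, DIF_TABLE_NEG)
oracle_dup <- function(nrep) {
  s <- sprintf("%d", nrep)
  paste0(DUP_TABLE[as.integer(substr(s, 1, 1))], substr(s, 2, nchar(s)))
}

# encode integer ordinates as SQZ/DIF/DUP lines with checkpoints; x0/dx in
# abscissa units, per_line ordinates per row
oracle_encode_difdup <- function(ints, x0 = 0, dx = 1, per_line = 10L) {
  n <- length(ints)
  lines <- character(0)
  i <- 1L
  while (i <= n) {
    row <- paste0(format(x0 + (i - 1) * dx, scientific = FALSE, trim = TRUE),
                  oracle_sqz(ints[i]))
    count <- 0L
    j <- i
    toks <- character(0)
    diffs <- integer(0)
    while (j < n && count < per_line) {
      diffs <- c(diffs, ints[j + 1L] - ints[j])
      j <- j + 1L
      count <- count + 1L
    }
    # run-length compress the differences
    k <- 1L
    while (k <= length(diffs)) {
      run <- 1L
      while (k + run <= length(diffs) && diffs[k + run] == diffs[k])
        run <- run + 1L
      toks <- c(toks, oracle_dif(diffs[k]),
                if (run > 1L) oracle_dup(run))
      k <- k + run
    }
    lines <- c(lines, paste0(row, paste(toks, collapse = "")))
    i <- j
    if (i < n || (i == n && count > 0L)) {
      # next line begins with a checkpoint unless we are done
      if (i == n) break
      i <- i       # checkpoint row encodes the current last point again
    }
    if (count == 0L) break
  }
  lines
}

# wrap encoded ordinates into a complete single-block JCAMP document
oracle_jcamp_document <- function(ints, yfactor = 1, x0 = 0, dx = 1,
                                  per_line = 10L) {
  c("##TITLE=oracle fixture",
    "##JCAMP-DX=5.01",
    "##DATA TYPE=NMR SPECTRUM",
    "##XUNITS=HZ",
    "##YUNITS=ARBITRARY UNITS",
    "##XFACTOR=1",
    sprintf("##YFACTOR=%.17g", yfactor),
    sprintf("##FIRSTX=%.10g", x0),
    sprintf("##LASTX=%.10g", x0 + (length(ints) - 1) * dx),
    sprintf("##NPOINTS=%d", length(ints)),
    "##XYDATA=(X++(Y..Y))",
    oracle_encode_difdup(ints, x0, dx, per_line),
    "##END=")
}
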