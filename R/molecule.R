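#' Parse an MDL molfile (V2000)
#'
#' Reads the counts line, atom block (element, charge, isotope mass
#' difference, tetrahedral stereo parity) and bond block of a V2000
#' connection table; `M  CHG` and `M  ISO` property lines override the
#' atom-block fields.  Implicit hydrogens are filled in by the standard
#' valence model (C 4, N 3, O 2, halogens 1, S 2/4/6 minimal fit, P 3/5,
#' charge-adjusted).  V3000 files are rejected.
#'
#' @param text molfile text: a character vector of lines, a single string,
#'   or a path to a `.mol` file.
#' @return an object of class `molecule` with `atoms` (data.frame:
#'   `element`, `charge`, `isotope`, `parity`, `implicit_h`), `bonds`
#'   (data.frame: `a1`, `a2`, `order`, `stereo`) and `source_molfile`.
#' @export
parse_molfile <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  if (length(text) == 1) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- sub("\r$", "", text)
  if (any(grepl("V3000", text)))
    stop("V3000 molfiles are not supported (V2000 only)")
  counts_i <- grep("V2000", text)[1]
  if (is.na(counts_i)) {
    # some files omit the V2000 tag: counts line is line 4
    if (length(text) < 4) stop("no V2000 counts line found")
    counts_i <- 4L
  }
  cl <- text[counts_i]
  natoms <- suppressWarnings(as.integer(substr(cl, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(cl, 4, 6)))
  if (is.na(natoms) || is.na(nbonds))
    stop(sprintf("corrupt counts line at line %d", counts_i))
  atom_lines <- text[(counts_i + 1):(counts_i + natoms)]
  if (length(atom_lines) < natoms || any(is.na(atom_lines)))
    stop(sprintf("atom block truncated (expected %d atoms)", natoms))
  atoms <- data.frame(element = character(natoms), charge = 0L,
                      isotope = 0L, parity = 0L, implicit_h = 0L,
                      stringsAsFactors = FALSE)
  for (i in seq_len(natoms)) {
    f <- strsplit(trimws(atom_lines[i]), "\\s+")[[1]]
    if (length(f) < 4)
      stop(sprintf("corrupt atom line at line %d", counts_i + i))
    atoms$element[i] <- f[4]
    if (length(f) >= 6) {
      cc <- suppressWarnings(as.integer(f[6]))
      if (!is.na(cc) && cc > 0)
        atoms$charge[i] <- c(3L, 2L, 1L, 0L, -1L, -2L, -3L)[cc]
    }
    if (length(f) >= 7) {
      pp <- suppressWarnings(as.integer(f[7]))
      if (!is.na(pp) && pp %in% c(1L, 2L)) atoms$parity[i] <- pp
    }
    if (length(f) >= 5) {
      iso <- suppressWarnings(as.integer(f[5]))
      if (!is.na(iso)) atoms$isotope[i] <- iso
    }
  }
  bonds <- data.frame(a1 = integer(nbonds), a2 = integer(nbonds),
                      order = integer(nbonds), stereo = integer(nbonds))
  if (nbonds > 0) {
    bond_lines <- text[(counts_i + natoms + 1):(counts_i + natoms + nbonds)]
    if (length(bond_lines) < nbonds || any(is.na(bond_lines)))
      stop(sprintf("bond block truncated (expected %d bonds)", nbonds))
    for (i in seq_len(nbonds)) {
      ln <- bond_lines[i]
      # fixed-width first (handles >99 atom indices), whitespace fallback
      a1 <- suppressWarnings(as.integer(substr(ln, 1, 3)))
      a2 <- suppressWarnings(as.integer(substr(ln, 4, 6)))
      o <- suppressWarnings(as.integer(substr(ln, 7, 9)))
      st <- suppressWarnings(as.integer(substr(ln, 10, 12)))
      if (is.na(a1) || is.na(a2) || is.na(o)) {
        f <- strsplit(trimws(ln), "\\s+")[[1]]
        a1 <- as.integer(f[1]); a2 <- as.integer(f[2]); o <- as.integer(f[3])
        st <- if (length(f) >= 4) as.integer(f[4]) else 0L
      }
      if (is.na(a1) || is.na(a2) || a1 < 1 || a2 < 1 ||
          a1 > natoms || a2 > natoms)
        stop(sprintf("bond indices out of range at line %d",
                     counts_i + natoms + i))
      bonds[i, ] <- c(a1, a2, o, if (is.na(st)) 0L else st)
    }
  }
  # M CHG / M ISO override
  for (ln in grep("^M  (CHG|ISO)", text, value = TRUE)) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    cnt <- as.integer(f[3])
    for (k in seq_len(cnt)) {
      ai <- as.integer(f[2 + 2 * k])
      vv <- as.integer(f[3 + 2 * k])
      if (f[2] == "CHG") atoms$charge[ai] <- vv else atoms$isotope[ai] <- vv
    }
  }
  atoms$implicit_h <- implicit_h_counts(atoms, bonds)
  structure(list(atoms = atoms, bonds = bonds,
                 source_molfile = paste(text, collapse = "\n")),
            class = "molecule")
}

implicit_h_counts <- function(atoms, bonds) {
  n <- nrow(atoms)
  bsum <- rep(0L, n)
  for (i in seq_len(nrow(bonds))) {
    o <- bonds$order[i]
    if (o == 4L) o <- 1L          # aromatic flag: count minimally
    bsum[bonds$a1[i]] <- bsum[bonds$a1[i]] + o
    bsum[bonds$a2[i]] <- bsum[bonds$a2[i]] + o
  }
  vapply(seq_len(n), function(i) {
    el <- atoms$element[i]
    ch <- atoms$charge[i]
    val <- switch(el,
      C = 4L - abs(ch),
      N = 3L + ch,
      P = 3L + ch,
      O = 2L + ch,
      S = {
        cand <- c(2L, 4L, 6L) + ch
        cand <- cand[cand >= bsum[i]]
        if (length(cand)) min(cand) else bsum[i]
      },
      B = 3L,
      Si = 4L,
      H = 1L,
      F = , Cl = , Br = , I = max(0L, 1L - abs(ch)),
      0L)
    max(0L, as.integer(val) - bsum[i])
  }, integer(1))
}

#' Molecular formula in Hill order
#'
#' Carbon first, hydrogen second (including implicit hydrogens), remaining
#' elements alphabetical; without carbon, all elements alphabetical.
#'
#' @param mol a [parse_molfile()] molecule.
#' @return formula string such as `"C2H6O"`.
#' @export
molecular_formula <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  el <- mol$atoms$element
  counts <- table(el)
  h <- sum(mol$atoms$implicit_h) + sum(el == "H")
  counts <- counts[names(counts) != "H"]
  out <- character(0)
  fmt <- function(e, n) if (n == 1) e else paste0(e, n)
  if ("C" %in% names(counts)) {
    out <- c(out, fmt("C", counts[["C"]]))
    if (h > 0) out <- c(out, fmt("H", h))
    rest <- sort(names(counts)[names(counts) != "C"])
    for (e in rest) out <- c(out, fmt(e, counts[[e]]))
  } else {
    nm <- sort(unique(c(names(counts), if (h > 0) "H")))
    for (e in nm)
      out <- c(out, if (e == "H") fmt("H", h) else fmt(e, counts[[e]]))
  }
  paste(out, collapse = "")
}

# --- canonical form machinery ------------------------------------------

# heavy-atom invariant labels; bond orders enter as per-atom order sums so
# that alternating-bond (Kekule) ring forms compare equal
atom_invariants <- function(mol) {
  n <- nrow(mol$atoms)
  bsum <- rep(0, n)
  deg <- rep(0L, n)
  for (i in seq_len(nrow(mol$bonds))) {
    o <- mol$bonds$order[i]
    if (o == 4L) o <- 1.5
    bsum[mol$bonds$a1[i]] <- bsum[mol$bonds$a1[i]] + o
    bsum[mol$bonds$a2[i]] <- bsum[mol$bonds$a2[i]] + o
    deg[mol$bonds$a1[i]] <- deg[mol$bonds$a1[i]] + 1L
    deg[mol$bonds$a2[i]] <- deg[mol$bonds$a2[i]] + 1L
  }
  paste(mol$atoms$element, mol$atoms$charge, mol$atoms$isotope,
        mol$atoms$implicit_h, deg, bsum, sep = "|")
}

adjacency_list <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (i in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# iterative neighborhood (Weisfeiler-Lehman) color refinement
refine_colors <- function(adj, colors) {
  n <- length(colors)
  repeat {
    sig <- vapply(seq_len(n), function(i) {
      paste(colors[i],
            paste(sort(colors[adj[[i]]]), collapse = ","), sep = ";")
    }, character(1))
    new_colors <- as.integer(factor(sig, levels = sort(unique(sig))))
    if (identical(as.integer(factor(colors)), new_colors) ||
        length(unique(new_colors)) == length(unique(colors)) &&
        identical(order(new_colors), order(colors)))
      return(new_colors)
    if (length(unique(new_colors)) == length(unique(colors)))
      return(new_colors)
    colors <- new_colors
  }
}

# canonical labelings by individualization-refinement; returns all
# permutations (old index -> new label) whose encoding is minimal
canonical_perms <- function(mol, use_stereo, max_leaves = 5000L) {
  adj <- adjacency_list(mol)
  init <- as.integer(factor(atom_invariants(mol)))
  n <- nrow(mol$atoms)
  best <- NULL
  best_perms <- list()
  leaves <- 0L
  recurse <- function(colors) {
    if (leaves > max_leaves) return()
    colors <- refine_colors(adj, colors)
    if (length(unique(colors)) == n) {
      perm <- order(order(colors))      # old index -> new label
      enc <- encode_molecule(mol, perm, use_stereo)
      leaves <<- leaves + 1L
      if (is.null(best) || enc < best) {
        best <<- enc
        best_perms <<- list(perm)
      } else if (enc == best) {
        best_perms <<- c(best_perms, list(perm))
      }
      return()
    }
    tab <- table(colors)
    cls <- as.integer(names(tab)[tab > 1])
    target <- min(cls)
    members <- which(colors == target)
    for (m in members) {
      c2 <- colors
      c2[m] <- max(colors) + 1L
      recurse(c2)
    }
  }
  recurse(init)
  list(key = best, perms = best_perms, exhausted = leaves <= max_leaves)
}

# string encoding of the molecule under a given labeling
encode_molecule <- function(mol, perm, use_stereo) {
  n <- nrow(mol$atoms)
  inv_i <- order(perm)                  # new label -> old index
  at <- vapply(inv_i, function(i) {
    base <- paste0(mol$atoms$element[i],
                   if (mol$atoms$charge[i] != 0)
                     sprintf("%+d", mol$atoms$charge[i]) else "",
                   if (mol$atoms$isotope[i] != 0)
                     sprintf("[%d]", mol$atoms$isotope[i]) else "",
                   "H", mol$atoms$implicit_h[i])
    if (use_stereo && mol$atoms$parity[i] %in% c(1L, 2L)) {
      p <- transformed_parity(mol, i, perm)
      base <- paste0(base, "*", p)
    }
    base
  }, character(1))
  bd <- character(0)
  if (nrow(mol$bonds) > 0) {
    e1 <- pmin(perm[mol$bonds$a1], perm[mol$bonds$a2])
    e2 <- pmax(perm[mol$bonds$a1], perm[mol$bonds$a2])
    o <- order(e1, e2)
    bd <- sprintf("%d-%d", e1[o], e2[o])
  }
  paste(paste(at, collapse = ";"), paste(bd, collapse = ";"), sep = "/")
}

# tetrahedral parity transported through a relabeling: flip when the
# induced neighbor permutation is odd.  An implicit hydrogen counts as the
# highest-numbered neighbor in both numberings (molfile convention).
transformed_parity <- function(mol, i, perm) {
  nb <- sort(c(mol$bonds$a2[mol$bonds$a1 == i], mol$bonds$a1[mol$bonds$a2 == i]))
  keys_old <- as.numeric(nb)
  keys_new <- as.numeric(perm[nb])
  if (mol$atoms$implicit_h[i] > 0) {
    keys_old <- c(keys_old, Inf)
    keys_new <- c(keys_new, Inf)
  }
  old_rank <- order(keys_old)
  new_rank <- order(keys_new)
  # permutation mapping old neighbor order to new neighbor order
  p <- match(old_rank, new_rank)
  s <- perm_sign(p)
  if (s > 0) mol$atoms$parity[i] else 3L - mol$atoms$parity[i]
}

perm_sign <- function(p) {
  inv <- 0L
  n <- length(p)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) if (p[a] > p[b]) inv <- inv + 1L
  if (inv %% 2 == 0) 1L else -1L
}

#' Canonical structure key
#'
#' A text key invariant under atom renumbering and bond reordering,
#' computed by individualization-refinement canonical labeling.  The key
#' encodes elements, charges, isotopes, implicit hydrogen counts, per-atom
#' bond-order sums and the unordered connectivity, so Kekule forms of the
#' same aromatic ring compare equal; with `stereo = TRUE` tetrahedral
#' parity flags are transported through the relabeling (flipping with odd
#' neighbor permutations) and included.
#'
#' @param mol a [parse_molfile()] molecule.
#' @param stereo include tetrahedral parity (default TRUE).
#' @return the canonical key string.
#' @export
canonical_key <- function(mol, stereo = TRUE) {
  stopifnot(inherits(mol, "molecule"))
  canonical_perms(mol, use_stereo = stereo)$key
}

#' Compare a candidate structure against a solution
#'
#' @param candidate,solution [parse_molfile()] molecules.
#' @param stereo if `TRUE`, tetrahedral parity must also match.
#' @return `"correct"`, `"wrong_constitution"`, or `"wrong_stereo"`.
#' @export
check_answer <- function(candidate, solution, stereo = FALSE) {
  if (canonical_key(candidate, stereo = FALSE) !=
      canonical_key(solution, stereo = FALSE))
    return("wrong_constitution")
  if (stereo &&
      canonical_key(candidate, stereo = TRUE) !=
      canonical_key(solution, stereo = TRUE))
    return("wrong_stereo")
  "correct"
}

flip_parities <- function(mol) {
  p <- mol$atoms$parity
  mol$atoms$parity <- ifelse(p %in% c(1L, 2L), 3L - p, p)
  mol
}

# substitute one implicit H on atom i by an explicit marker atom and set
# the given parity at i (used by the diastereotopicity test)
substitute_h <- function(mol, i, parity) {
  stopifnot(mol$atoms$implicit_h[i] >= 1)
  mol$atoms <- rbind(mol$atoms, data.frame(
    element = "H", charge = 0L, isotope = 2L, parity = 0L, implicit_h = 0L))
  mol$bonds <- rbind(mol$bonds, data.frame(
    a1 = i, a2 = nrow(mol$atoms), order = 1L, stereo = 0L))
  mol$atoms$implicit_h[i] <- mol$atoms$implicit_h[i] - 1L
  mol$atoms$parity[i] <- parity
  mol
}

#' Hydrogen equivalence classes (topicity)
#'
#' Partitions all hydrogen positions (implicit and explicit) into
#' equivalence classes.  Constitutional equivalence comes from the
#' graph-automorphism orbits of the heavy-atom skeleton, obtained by
#' iterative neighborhood refinement with exact orbit verification via
#' enumeration of all canonical labelings (molecules up to 64 heavy atoms;
#' beyond that the refinement-only partition is returned, flagged
#' approximate).  A CH2 on a prochiral carbon is split into two classes
#' labeled `diastereotopic` when replacing either hydrogen by a marker
#' gives structures that are neither identical nor enantiomeric — the
#' substitution test, evaluated with stereo-aware canonical keys, so the
#' split happens only in the presence of a configured stereocenter.
#'
#' @param mol a [parse_molfile()] molecule.
#' @return object of class `h_classes`: list of classes, each with
#'   `positions` (data.frame `atom`, `h` index) and `topicity`
#'   (`"homotopic_or_equivalent"` or `"diastereotopic"`); attribute
#'   `approximate` is set when the exact orbit check was skipped.
#' @export
equivalent_hydrogens <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  n <- nrow(mol$atoms)
  approx_only <- n > 64
  if (!approx_only) {
    cp <- canonical_perms(mol, use_stereo = FALSE)
    approx_only <- !cp$exhausted
  }
  if (!approx_only && length(cp$perms) >= 1) {
    ref <- order(cp$perms[[1]])
    orbit_of <- seq_len(n)
    for (pp in cp$perms) {
      img <- ref[pp]                    # automorphism: old -> old
      for (a in seq_len(n)) {
        ra <- min(orbit_of[a], orbit_of[img[a]])
        orbit_of[orbit_of == orbit_of[a] | orbit_of == orbit_of[img[a]]] <- ra
      }
    }
  } else {
    adj <- adjacency_list(mol)
    cols <- refine_colors(adj, as.integer(factor(atom_invariants(mol))))
    orbit_of <- as.integer(factor(cols))
  }
  has_stereo <- any(mol$atoms$parity %in% c(1L, 2L))
  classes <- list()
  seen <- rep(FALSE, n)
  for (a in seq_len(n)) {
    nh <- mol$atoms$implicit_h[a] + 0L
    if (mol$atoms$element[a] == "H" || nh == 0 || seen[a]) next
    mates <- which(orbit_of == orbit_of[a] & mol$atoms$implicit_h > 0)
    seen[mates] <- TRUE
    split_pair <- FALSE
    if (nh == 2 && has_stereo && mol$atoms$element[a] == "C") {
      kA <- canonical_key(substitute_h(mol, a, 1L), stereo = TRUE)
      kB <- canonical_key(substitute_h(mol, a, 2L), stereo = TRUE)
      if (kA != kB) {
        kM <- canonical_key(flip_parities(substitute_h(mol, a, 1L)),
                            stereo = TRUE)
        if (kM != kB) split_pair <- TRUE
      }
    }
    if (split_pair) {
      for (hk in 1:2) {
        classes[[length(classes) + 1L]] <- list(
          positions = data.frame(atom = mates, h = hk),
          topicity = "diastereotopic")
      }
    } else {
      pos <- do.call(rbind, lapply(mates, function(m)
        data.frame(atom = m, h = seq_len(mol$atoms$implicit_h[m]))))
      classes[[length(classes) + 1L]] <- list(
        positions = pos, topicity = "homotopic_or_equivalent")
    }
  }
  # explicit H atoms grouped by their orbits
  hexp <- which(mol$atoms$element == "H")
  if (length(hexp)) {
    for (ob in unique(orbit_of[hexp])) {
      mem <- hexp[orbit_of[hexp] == ob]
      classes[[length(classes) + 1L]] <- list(
        positions = data.frame(atom = mem, h = 0L),
        topicity = "homotopic_or_equivalent")
    }
  }
  structure(classes, class = "h_classes",
            approximate = if (approx_only) TRUE else NULL)
}
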