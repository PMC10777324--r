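# molfile fixtures are built in code: a tiny V2000 writer, stock molecules,
# a renumbering utility and a brute-force automorphism oracle

make_molfile <- function(atoms, bonds, parities = NULL) {
  n <- length(atoms)
  m <- if (is.null(bonds)) 0L else nrow(bonds)
  lines <- c("synthetic structure", "  nmrkit test", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  for (i in seq_len(n)) {
    p <- if (!is.null(parities)) parities[i] else 0L
    lines <- c(lines, sprintf(
      "    0.0000    0.0000    0.0000 %-3s 0  0  %d  0  0  0  0  0  0  0  0  0",
      atoms[i], p))
  }
  for (k in seq_len(m))
    lines <- c(lines, sprintf("%3d%3d%3d  0",
                              bonds[k, 1], bonds[k, 2], bonds[k, 3]))
  c(lines, "M  END")
}

mol_ethanol <- function()
  make_molfile(c("C", "C", "O"), rbind(c(1, 2, 1), c(2, 3, 1)))

mol_dimethyl_ether <- function()
  make_molfile(c("C", "O", "C"), rbind(c(1, 2, 1), c(2, 3, 1)))

mol_benzene <- function(shift = 0) {
  # shift rotates the Kekule pattern
  ord <- rep(c(2L, 1L), 3)
  if (shift %% 2 == 1) ord <- rev(ord)
  make_molfile(rep("C", 6),
               cbind(1:6, c(2:6, 1), ord))
}

mol_water <- function() make_molfile("O", NULL)

mol_butan2ol <- function(parity) {
  # C1-C2(OH)-C3-C4 with a parity flag at C2
  make_molfile(c("C", "C", "C", "C", "O"),
               rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(2, 5, 1)),
               c(0L, parity, 0L, 0L, 0L))
}

mol_dimethoxybenzene <- function() {
  make_molfile(c(rep("C", 6), "O", "C", "O", "C"),
               rbind(c(1, 2, 2), c(2, 3, 1), c(3, 4, 2), c(4, 5, 1),
                     c(5, 6, 2), c(6, 1, 1),
                     c(1, 7, 1), c(7, 8, 1), c(4, 9, 1), c(9, 10, 1)))
}

# rebuild the molfile with atoms renumbered by `perm` (perm[i] = new index
# of old atom i).  Tetrahedral parity is defined relative to the atom
# numbering, so it flips whenever the induced permutation of a parity
# atom's neighbors (implicit H counted as the highest neighbor) is odd.
renumber_molfile <- function(lines, perm) {
  mol <- parse_molfile(lines)
  n <- nrow(mol$atoms)
  inv <- order(perm)
  parities <- mol$atoms$parity
  for (i in which(parities %in% c(1L, 2L))) {
    nb <- sort(c(mol$bonds$a2[mol$bonds$a1 == i],
                 mol$bonds$a1[mol$bonds$a2 == i]))
    old_key <- c(nb, if (mol$atoms$implicit_h[i] > 0) Inf)
    new_key <- c(perm[nb], if (mol$atoms$implicit_h[i] > 0) Inf)
    p <- match(order(old_key), order(new_key))
    inversions <- 0L
    for (a in seq_along(p)) for (b in seq_along(p))
      if (a < b && p[a] > p[b]) inversions <- inversions + 1L
    if (inversions %% 2 == 1L) parities[i] <- 3L - parities[i]
  }
  atoms <- mol$atoms$element[inv]
  parities <- parities[inv]
  bonds <- mol$bonds
  if (nrow(bonds)) {
    bonds <- cbind(perm[bonds$a1], perm[bonds$a2], bonds$order)
  } else bonds <- NULL
  make_molfile(atoms, bonds, parities)
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# brute-force automorphism orbits: permutations restricted to classes of
# equal (element, heavy degree), accepted when they preserve the unordered
# adjacency and per-atom bond-order sums
brute_force_h_orbits <- function(mol) {
  n <- nrow(mol$atoms)
  deg <- rep(0L, n); bsum <- rep(0, n)
  for (i in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]; o <- mol$bonds$order[i]
    deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
    bsum[a] <- bsum[a] + o; bsum[b] <- bsum[b] + o
  }
  cls <- paste(mol$atoms$element, deg, sep = "/")
  groups <- split(seq_len(n), cls)
  # cartesian product of within-group permutations
  group_perms <- lapply(groups, function(g) {
    lapply(all_perms(length(g)), function(p) g[p])
  })
  edge_key <- function(a1, a2) paste(pmin(a1, a2), pmax(a1, a2))
  base_edges <- sort(edge_key(mol$bonds$a1, mol$bonds$a2))
  orbit_of <- seq_len(n)
  combine <- function(gi, perm) {
    if (gi > length(group_perms)) {
      img <- perm
      if (!identical(sort(edge_key(img[mol$bonds$a1], img[mol$bonds$a2])),
                     base_edges)) return()
      if (any(abs(bsum[order(img)] - bsum) > 1e-9)) return()
      for (a in seq_len(n)) {
        ra <- min(orbit_of[a], orbit_of[img[a]])
        orbit_of[orbit_of %in% c(orbit_of[a], orbit_of[img[a]])] <<- ra
      }
      return()
    }
    for (gp in group_perms[[gi]]) {
      p2 <- perm
      p2[groups[[gi]]] <- gp
      combine(gi + 1L, p2)
    }
  }
  combine(1L, seq_len(n))
  orbit_of
}
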