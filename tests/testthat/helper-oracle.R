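# Independent brute-force oracles used to cross-check the package
# implementations. They deliberately take different algorithmic routes:
# ring perception by edge-deletion connectivity instead of bridge
# detection, one-atom-at-a-time pruning instead of vectorized rounds,
# and double-loop pair enumeration instead of matrix algebra.

# Atom/bond table of a molecule, via the backend's SDF conversion.
oracle_mol <- function(smiles) {
  sdfstr <- ChemmineOB::convertFormat("SMI", "SDF", source = paste0(smiles, " m\n"))
  con <- textConnection(sdfstr)
  on.exit(close(con))
  sdf <- suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(con)))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- as.matrix(ChemmineR::bondblock(sdf))
  list(sym = sub("_.*$", "", rownames(ab)),
       bonds = cbind(as.integer(bb[, 1]), as.integer(bb[, 2]),
                     as.integer(bb[, 3])))
}

# An edge lies on a cycle iff its endpoints stay connected after the
# edge is removed.
oracle_edge_on_cycle <- function(bonds, k, n) {
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(nrow(bonds))) {
    if (r == k) next
    a <- bonds[r, 1]; b <- bonds[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  src <- bonds[k, 1]; dst <- bonds[k, 2]
  seen <- rep(FALSE, n)
  stack <- src
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
  }
  seen[dst]
}

# Brute-force Bemis-Murcko framework: prune one terminal non-ring atom
# at a time until fixed point, then restore atoms multiply bonded to
# the remainder. Returns the canonical SMILES of the framework, or NA
# for acyclic molecules.
oracle_murcko <- function(smiles) {
  g <- oracle_mol(smiles)
  n <- length(g$sym)
  if (nrow(g$bonds) == 0) return(NA_character_)
  on_cycle <- vapply(seq_len(nrow(g$bonds)), function(k) {
    oracle_edge_on_cycle(g$bonds, k, n)
  }, logical(1))
  if (!any(on_cycle)) return(NA_character_)
  ring_atom <- rep(FALSE, n)
  ring_atom[unique(c(g$bonds[on_cycle, 1:2]))] <- TRUE
  keep <- rep(TRUE, n)
  repeat {
    deg <- rep(0L, n)
    for (r in seq_len(nrow(g$bonds))) {
      a <- g$bonds[r, 1]; b <- g$bonds[r, 2]
      if (keep[a] && keep[b]) { deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L }
    }
    victim <- which(keep & !ring_atom & deg == 1L)
    if (!length(victim)) break
    keep[victim[1]] <- FALSE
  }
  for (r in seq_len(nrow(g$bonds))) {
    if (g$bonds[r, 3] >= 2 && xor(keep[g$bonds[r, 1]], keep[g$bonds[r, 2]])) {
      keep[g$bonds[r, 1:2]] <- TRUE
    }
  }
  idx <- which(keep)
  remap <- integer(n); remap[idx] <- seq_along(idx)
  sel <- g$bonds[keep[g$bonds[, 1]] & keep[g$bonds[, 2]], , drop = FALSE]
  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    0, 0, 0, g$sym[idx])
  bond_lines <- sprintf("%3d%3d%3d  0  0  0  0",
                        remap[sel[, 1]], remap[sel[, 2]], sel[, 3])
  mol <- paste(c("frag", "  oracle", "",
                 sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                         length(idx), nrow(sel)),
                 atom_lines, bond_lines, "M  END", "$$$$"), collapse = "\n")
  out <- ChemmineOB::convertFormat("SDF", "CAN", source = paste0(mol, "\n"))
  strsplit(trimws(out), "[\t\n]")[[1]][1]
}

# Exhaustive pairwise Tanimoto by explicit double loop.
oracle_pairwise_tanimoto <- function(fp) {
  m <- nrow(fp)
  sims <- c()
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      a <- sum(fp[i, ]); b <- sum(fp[j, ]); cc <- sum(fp[i, ] & fp[j, ])
      sims <- c(sims, if (a + b - cc == 0) 1 else cc / (a + b - cc))
    }
  }
  sims
}

# A drug-like SMILES battery shared by several tests.
battery_smiles <- function() {
  c(
    "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "C1CCCCC1", "c1ccncc1",
    "c1ccccc1Cc1ccccc1", "CC(=O)c1ccccc1", "O=C1CCCCC1",
    "O=C(c1ccccc1)c1ccccc1", "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
    "OCC1OC(O)C(O)C(O)C1O", "C1CC2CCC1CC2", "c1ccc2[nH]ccc2c1",
    "CC(=O)Oc1ccccc1C(=O)O", "C=C1CCCCC1", "CC(=O)Nc1ccccc1",
    "O=C1Oc2ccccc2C=C1c1ccccc1", "CCN(CC)CCNC(=O)c1ccc(N)cc1",
    "c1ccc(cc1)C=Cc1ccccc1", "CN1CCC(CC1)c1ccccc1",
    "Oc1ccc2ccccc2c1", "CC1(C)CCCC1", "c1ccoc1", "C1CCNC1",
    "CC(=O)CCc1ccccc1"
  )
}

make_library <- function(smiles, ids = sprintf("M%03d", seq_along(smiles)),
                         ...) {
  tibble::tibble(id = ids, smiles = smiles, ...)
}

property_cols <- function() c("MW", "SlogP", "TPSA", "RB", "HBD", "HBA")
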