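# Light molecular-graph layer over ChemmineR SDF objects. Used for the
# operations the backend does not expose directly: Bemis-Murcko framework
# extraction and the rotatable-bond count. Hydrogens are implicit
# throughout (the backend writes heavy-atom-only molfiles).

sdf_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- as.matrix(ChemmineR::bondblock(sdf))
  n <- nrow(ab)
  sym <- sub("_.*$", "", rownames(ab))
  code <- if ("C5" %in% colnames(ab)) as.integer(ab[, "C5"]) else integer(n)
  # molfile charge codes: 0 none, 1..3 = +3..+1, 4 radical, 5..7 = -1..-3
  chg <- ifelse(code == 0L | code == 4L, 0L, 4L - code)
  list(
    n = n, sym = sym, chg = as.integer(chg),
    edges = cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L])),
    order = as.integer(bb[, 3L])
  )
}

# TRUE for bonds that lie on a cycle (non-bridge edges).
ring_edge_mask <- function(g) {
  ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
  if (igraph::vcount(ig) < g$n) {
    ig <- igraph::add_vertices(ig, g$n - igraph::vcount(ig))
  }
  mask <- rep(TRUE, nrow(g$edges))
  mask[as.integer(igraph::bridges(ig))] <- FALSE
  mask
}

# Atoms belonging to the Bemis-Murcko framework: ring systems plus the
# linkers between them (iterative pruning of terminal non-ring atoms),
# plus any atom attached to that core by a double or triple bond
# (exocyclic =O and friends, the usual framework convention). NULL when
# the molecule has no ring.
framework_atoms <- function(g) {
  ring_e <- ring_edge_mask(g)
  if (!any(ring_e)) return(NULL)
  ring_atom <- rep(FALSE, g$n)
  ring_atom[unique(as.vector(g$edges[ring_e, , drop = FALSE]))] <- TRUE
  keep <- rep(TRUE, g$n)
  repeat {
    live <- keep[g$edges[, 1L]] & keep[g$edges[, 2L]]
    deg <- tabulate(as.vector(g$edges[live, , drop = FALSE]), nbins = g$n)
    drop <- keep & !ring_atom & deg == 1L
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  for (k in which(g$order >= 2L)) {
    a <- g$edges[k, 1L]
    b <- g$edges[k, 2L]
    if (xor(keep[a], keep[b])) keep[c(a, b)] <- TRUE
  }
  keep
}

# Minimal V2000 molfile for an atom subset. Coordinates are zeroed: the
# consumer only re-perceives connectivity, so 2D layout (and with it E/Z
# bond stereo) is deliberately not carried into scaffolds.
build_molfile <- function(sym, chg, bonds, title) {
  n <- length(sym)
  m <- nrow(bonds)
  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    0, 0, 0, sym
  )
  bond_lines <- if (m > 0L) {
    sprintf("%3d%3d%3d  0  0  0  0", bonds[, 1L], bonds[, 2L], bonds[, 3L])
  } else {
    character(0)
  }
  ci <- which(chg != 0L)
  chg_lines <- if (length(ci)) {
    paste0("M  CHG", sprintf("%3d", length(ci)),
           paste0(sprintf("%4d%4d", ci, chg[ci]), collapse = ""))
  } else {
    character(0)
  }
  paste(c(title, "  npprofiler", "",
          sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m),
          atom_lines, bond_lines, chg_lines, "M  END", "$$$$"),
        collapse = "\n")
}

# Molfile text for the framework substructure of a molecular graph.
framework_molfile <- function(g, keep, title) {
  idx <- which(keep)
  remap <- integer(g$n)
  remap[idx] <- seq_along(idx)
  sel <- keep[g$edges[, 1L]] & keep[g$edges[, 2L]]
  bonds <- cbind(remap[g$edges[sel, 1L]], remap[g$edges[sel, 2L]],
                 g$order[sel])
  build_molfile(g$sym[idx], g$chg[idx], bonds, title)
}

# Ring presence test on a canonical SMILES: ring-closure labels are the
# only digits (or '%') outside bracket atoms.
smiles_has_ring <- function(smiles) {
  grepl("[0-9%]", gsub("\\[[^]]*\\]", "A", smiles))
}

# Rotatable bonds: single, non-ring bonds between two non-terminal heavy
# atoms, excluding amide C-N.
rotatable_bond_count <- function(g) {
  if (nrow(g$edges) < 3L) return(0L)
  ring_e <- ring_edge_mask(g)
  deg <- tabulate(as.vector(g$edges), nbins = g$n)
  rb <- 0L
  for (k in seq_len(nrow(g$edges))) {
    if (g$order[k] != 1L || ring_e[k]) next
    a <- g$edges[k, 1L]
    b <- g$edges[k, 2L]
    if (deg[a] < 2L || deg[b] < 2L) next
    if (is_amide_bond(g, a, b)) next
    rb <- rb + 1L
  }
  rb
}

is_amide_bond <- function(g, a, b) {
  for (p in list(c(a, b), c(b, a))) {
    if (g$sym[p[1L]] == "C" && g$sym[p[2L]] == "N") {
      dbl <- which((g$edges[, 1L] == p[1L] | g$edges[, 2L] == p[1L]) &
                     g$order == 2L)
      for (k in dbl) {
        other <- setdiff(g$edges[k, ], p[1L])
        if (any(g$sym[other] == "O")) return(TRUE)
      }
    }
  }
  FALSE
}
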