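# Featured heavy-atom protein graph: physicochemical vertex features from
# fixed per-residue atom-name tables, distance edges with a degree cap.

RESIDUE_CLASS <- c(
  ARG = "positive", LYS = "positive", HIS = "positive",
  ASP = "negative", GLU = "negative",
  SER = "polar", THR = "polar", ASN = "polar", GLN = "polar",
  CYS = "polar", TYR = "polar",
  ALA = "hydrophobic", GLY = "hydrophobic", ILE = "hydrophobic",
  LEU = "hydrophobic", MET = "hydrophobic", PHE = "hydrophobic",
  PRO = "hydrophobic", TRP = "hydrophobic", VAL = "hydrophobic"
)

# Side-chain hydrogen-bond donors / acceptors by residue and atom name.
DONOR_ATOMS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  TRP = "NE1", ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1",
  TYR = "OH", CYS = "SG"
)
ACCEPTOR_ATOMS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"),
  MET = "SD", CYS = "SG"  # thiol sulfur can accept an H-bond
)
AROMATIC_ATOMS <- list(
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)
CHARGED_ATOMS <- list(
  ARG = list(atoms = c("NE", "NH1", "NH2", "CZ"), sign = 1),
  LYS = list(atoms = "NZ", sign = 1),
  ASP = list(atoms = c("OD1", "OD2"), sign = -1),
  GLU = list(atoms = c("OE1", "OE2"), sign = -1)
)
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
FEATURE_ELEMENTS <- c("C", "N", "O", "S", "P")

#' Dimension of the per-atom feature vector
#' @return Integer feature width.
#' @export
atom_feature_dim <- function() 6L + 4L + 5L + 1L

#' Physicochemical features for protein heavy atoms
#'
#' A pure lookup on (residue_name, atom_name, element): element one-hot
#' (C, N, O, S, P, other), hydrogen-bond donor/acceptor flags (fixed
#' per-residue atom-name tables; backbone N donates, backbone O accepts),
#' aromatic-ring flag (His/Phe/Tyr/Trp ring atoms), backbone flag, residue
#' class one-hot (positive, negative, polar, hydrophobic, other) and formal
#' charge sign. Nonstandard residues get class "other" with element-default
#' flags.
#'
#' @param atoms Protein atom data.frame (as in a `pdna_complex`).
#' @return Numeric matrix, one row per atom, [atom_feature_dim()] columns.
#' @export
featurize_atoms <- function(atoms) {
  n <- nrow(atoms)
  F <- matrix(0, n, atom_feature_dim())
  colnames(F) <- c(paste0("el_", c(FEATURE_ELEMENTS, "other")),
                   "donor", "acceptor", "aromatic", "backbone",
                   paste0("class_", c("positive", "negative", "polar",
                                      "hydrophobic", "other")),
                   "charge_sign")
  el <- match(atoms$element, FEATURE_ELEMENTS)
  el[is.na(el)] <- 6L
  F[cbind(seq_len(n), el)] <- 1
  for (i in seq_len(n)) {
    res <- atoms$residue_name[i]
    nm <- atoms$atom_name[i]
    donor <- nm == "N" || nm %in% (DONOR_ATOMS[[res]] %||% character())
    acceptor <- nm %in% c("O", "OXT") ||
      nm %in% (ACCEPTOR_ATOMS[[res]] %||% character())
    if (!(res %in% names(RESIDUE_CLASS))) {
      # element defaults for unknown residues: N donates, O accepts
      donor <- atoms$element[i] == "N"
      acceptor <- atoms$element[i] == "O"
    }
    F[i, "donor"] <- as.numeric(donor)
    F[i, "acceptor"] <- as.numeric(acceptor)
    F[i, "aromatic"] <- as.numeric(nm %in% (AROMATIC_ATOMS[[res]] %||% character()))
    F[i, "backbone"] <- as.numeric(nm %in% BACKBONE_ATOMS &&
                                     res %in% names(RESIDUE_CLASS))
    cls <- RESIDUE_CLASS[res]
    cls <- if (is.na(cls)) "other" else cls
    F[i, paste0("class_", cls)] <- 1
    ch <- CHARGED_ATOMS[[res]]
    if (!is.null(ch) && nm %in% ch$atoms) F[i, "charge_sign"] <- ch$sign
  }
  F
}

#' Build the protein heavy-atom graph
#'
#' Undirected edges between atoms at distance `<= r_graph`; vertices whose
#' degree exceeds `max_degree` keep their nearest `max_degree` neighbours,
#' after which the edge set is re-symmetrized by union (an edge survives if
#' either endpoint kept it).
#'
#' @param atoms Protein atom data.frame.
#' @param r_graph Edge cutoff in Angstrom (default 4.0: covalent bonds plus
#'   close contacts).
#' @param max_degree Per-vertex neighbour cap before union symmetrization.
#' @return Object of class `protein_graph`: `atoms`, `features` (matrix),
#'   `edges` (m x 2 with i < j), `lengths` (Angstrom).
#' @export
build_protein_graph <- function(atoms, r_graph = 4.0, max_degree = 16L) {
  stopifnot(nrow(atoms) >= 1)
  X <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(X)
  edges <- matrix(integer(0), 0, 2)
  lens <- numeric(0)
  if (n >= 2) {
    d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * X %*% t(X)
    d2[d2 < 0] <- 0
    adj <- d2 <= r_graph^2 + 1e-9
    diag(adj) <- FALSE
    # degree cap: keep nearest max_degree per vertex, union symmetrize
    keep <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      if (length(nb) > max_degree) {
        nb <- nb[order(d2[i, nb])][seq_len(max_degree)]
      }
      keep[i, nb] <- TRUE
    }
    keep <- keep | t(keep)
    idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
    if (nrow(idx)) {
      edges <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      lens <- sqrt(d2[edges])
    }
  }
  colnames(edges) <- c("i", "j")
  structure(list(atoms = atoms, features = featurize_atoms(atoms),
                 edges = edges, lengths = lens,
                 r_graph = r_graph, max_degree = max_degree),
            class = "protein_graph")
}

#' @export
print.protein_graph <- function(x, ...) {
  cat("Protein graph:", nrow(x$atoms), "heavy atoms,",
      nrow(x$edges), "edges (r =", x$r_graph, "A)\n")
  invisible(x)
}

#' Dump a protein graph as an edge-list text file
#' @param graph A `protein_graph`.
#' @param path Output file (tab-separated i, j, length).
#' @export
write_graph_edges <- function(graph, path) {
  stopifnot(inherits(graph, "protein_graph"))
  utils::write.table(
    data.frame(i = graph$edges[, 1], j = graph$edges[, 2],
               length = graph$lengths),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
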