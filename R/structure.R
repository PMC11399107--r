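# Structure reading and the in-memory protein-DNA complex:
# heavy-atom cleanup, protein/DNA partition, Watson-Crick pairing.

PROTEIN_RESIDUES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                      "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                      "THR", "TRP", "TYR", "VAL", "MSE", "SEC", "PYL")

DNA_RESIDUES <- c(DA = "A", DC = "C", DG = "G", DT = "T",
                  A = "A", C = "C", G = "G", T = "T")

# Common chemically modified bases; explicitly rejected (scope is unmodified
# double-stranded DNA).
MODIFIED_BASES <- c("5CM", "5MC", "6MA", "6OG", "8OG", "BRU", "5IU", "5BU",
                    "DU", "UMS", "CBR", "5HC", "1MA", "7MG", "M1G", "2MG")

SOLVENT_IONS <- c("HOH", "WAT", "DOD", "DIS", "NA", "K", "MG", "CA", "ZN",
                  "CL", "MN", "FE", "CU", "NI", "CO", "CD", "SO4", "PO4",
                  "GOL", "EDO", "ACT")

SUGAR_RING_ATOMS <- c("C1'", "C2'", "C3'", "C4'", "O4'")

normalize_atom_name <- function(x) gsub("\\*", "'", trimws(x))

guess_element <- function(atom_name) {
  a <- gsub("[^A-Za-z]", "", atom_name)
  first <- toupper(substr(a, 1, 1))
  ifelse(first %in% c("C", "N", "O", "S", "P"), first, toupper(a))
}

# Standardize a bio3d atom table into the package's atom data.frame.
standardize_atoms <- function(at) {
  elesy <- toupper(trimws(at$elesy %||% ""))
  name <- normalize_atom_name(at$elety)
  elesy[is.na(elesy) | !nzchar(elesy)] <- guess_element(name[is.na(elesy) | !nzchar(elesy)])
  data.frame(
    atom_id = seq_len(nrow(at)),
    atom_name = name,
    element = elesy,
    residue_name = toupper(trimws(at$resid)),
    residue_index = as.integer(at$resno),
    insert = ifelse(is.na(at$insert) | at$insert == "", "", as.character(at$insert)),
    chain_id = ifelse(is.na(at$chain) | at$chain == "", " ", as.character(at$chain)),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt) | at$alt == "", "", as.character(at$alt)),
    stringsAsFactors = FALSE
  )
}

# Remove hydrogens/deuteriums, waters and small ions; resolve altlocs by
# highest occupancy (tie -> altloc "A", then first).
clean_atoms <- function(atoms) {
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  atoms <- atoms[!(atoms$residue_name %in% SOLVENT_IONS), , drop = FALSE]
  if (!nrow(atoms)) return(atoms)
  key <- paste(atoms$chain_id, atoms$residue_index, atoms$insert,
               atoms$residue_name, atoms$atom_name, sep = "|")
  if (anyDuplicated(key)) {
    ord <- order(key, -atoms$occupancy, atoms$altloc != "A", atoms$altloc)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain_id, atoms$residue_index,
                                     atoms$insert, atoms$residue_name,
                                     atoms$atom_name, sep = "|")), , drop = FALSE]
    atoms <- atoms[order(atoms$atom_id), , drop = FALSE]
  }
  atoms$atom_id <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  atoms
}

nucleotide_key <- function(chain, resno, insert) {
  paste0(chain, ":", resno, ifelse(nzchar(insert), insert, ""))
}

# Build nucleotide records (base letter, C1', glycosidic N, P, atoms) from
# the DNA partition of a cleaned atom table.
build_nucleotides <- function(dna_atoms) {
  if (!nrow(dna_atoms)) return(list())
  keys <- nucleotide_key(dna_atoms$chain_id, dna_atoms$residue_index, dna_atoms$insert)
  out <- list()
  for (k in unique(keys)) {
    sub <- dna_atoms[keys == k, , drop = FALSE]
    base <- unname(DNA_RESIDUES[sub$residue_name[1]])
    gly_name <- if (base %in% c("A", "G")) "N9" else "N1"
    c1 <- sub[sub$atom_name == "C1'", , drop = FALSE]
    gn <- sub[sub$atom_name == gly_name, , drop = FALSE]
    if (!nrow(c1) || !nrow(gn)) {
      stop("nucleotide ", k, " lacks C1' or glycosidic nitrogen (", gly_name, ")")
    }
    p <- sub[sub$atom_name == "P", , drop = FALSE]
    out[[k]] <- list(
      key = k,
      chain_id = sub$chain_id[1],
      residue_index = sub$residue_index[1],
      base = base,
      c1p = c(c1$x[1], c1$y[1], c1$z[1]),
      glyN = c(gn$x[1], gn$y[1], gn$z[1]),
      p = if (nrow(p)) c(p$x[1], p$y[1], p$z[1]) else NULL,
      atoms = sub
    )
  }
  out
}

complementary <- function(a, b) {
  (a == "A" && b == "T") || (a == "T" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G")
}

#' Detect Watson-Crick base pairs in a set of nucleotides
#'
#' Pairs nucleotides from different strands whose base labels are
#' complementary, whose C1'-C1' distance lies in \[9.0, 11.5\] Angstrom and
#' whose glycosidic nitrogens are within 4.0 Angstrom, each nucleotide used
#' at most once (greedy, closest glycosidic distance first). The longer
#' strand (tie: lexicographically smaller chain id) is taken as the Watson
#' strand and pairs are ordered 5'->3' along it (ascending author numbering),
#' giving 0-based `pair_index`.
#'
#' @param nucleotides List of nucleotide records as built internally by
#'   [parse_structure()] (each with `chain_id`, `residue_index`, `base`,
#'   `c1p`, `glyN`).
#' @return A data.frame with one row per pair: `pair_index`, `watson_key`,
#'   `crick_key`, `watson_base`, `watson_chain`, `crick_chain`.
#' @export
detect_base_pairs <- function(nucleotides) {
  if (length(nucleotides) < 8) {
    stop("need at least 8 nucleotides to detect a duplex")
  }
  chains <- vapply(nucleotides, `[[`, character(1), "chain_id")
  if (length(unique(chains)) < 2) {
    stop("need nucleotides on at least 2 strands")
  }
  n <- length(nucleotides)
  cand <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- nucleotides[[i]]; b <- nucleotides[[j]]
      if (a$chain_id == b$chain_id) next
      if (!complementary(a$base, b$base)) next
      dc1 <- vnorm(a$c1p - b$c1p)
      if (dc1 < 9.0 || dc1 > 11.5) next
      dgn <- vnorm(a$glyN - b$glyN)
      if (dgn > 4.0) next
      cand[[length(cand) + 1]] <- list(i = i, j = j, d = dgn)
    }
  }
  if (length(cand)) {
    cand <- cand[order(vapply(cand, `[[`, numeric(1), "d"))]
  }
  used <- rep(FALSE, n)
  pairs <- list()
  for (cc in cand) {
    if (used[cc$i] || used[cc$j]) next
    used[cc$i] <- used[cc$j] <- TRUE
    pairs[[length(pairs) + 1]] <- cc
  }
  if (length(pairs) < 4) {
    stop("no DNA duplex found: fewer than 4 Watson-Crick pairs detected")
  }
  # chain pair groups; more than one disconnected duplex is ambiguous
  cp <- vapply(pairs, function(p) {
    paste(sort(c(chains[p$i], chains[p$j])), collapse = "~")
  }, character(1))
  tab <- table(cp)
  major_groups <- names(tab)[tab >= 4]
  if (length(major_groups) > 1) {
    stop("ambiguous input: more than one DNA duplex candidate (chains ",
         paste(major_groups, collapse = ", "), ")")
  }
  keep <- cp == names(tab)[which.max(tab)]
  pairs <- pairs[keep]

  # Watson strand: more paired nucleotides, tie -> smaller chain id
  ch1 <- strsplit(names(tab)[which.max(tab)], "~")[[1]]
  count_in_chain <- vapply(ch1, function(ch) {
    sum(vapply(pairs, function(p) chains[p$i] == ch || chains[p$j] == ch,
               logical(1)) &
        TRUE)
  }, numeric(1))
  # strand length = number of nucleotides on the chain (not just paired)
  strand_len <- vapply(ch1, function(ch) sum(chains == ch), numeric(1))
  watson_chain <- if (strand_len[1] != strand_len[2]) {
    ch1[which.max(strand_len)]
  } else {
    sort(ch1)[1]
  }

  rows <- lapply(pairs, function(p) {
    a <- nucleotides[[p$i]]; b <- nucleotides[[p$j]]
    if (a$chain_id != watson_chain) { tmp <- a; a <- b; b <- tmp }
    data.frame(watson_key = a$key, crick_key = b$key,
               watson_base = a$base,
               watson_chain = a$chain_id, crick_chain = b$chain_id,
               watson_resno = a$residue_index,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$watson_resno), , drop = FALSE]
  df$pair_index <- seq_len(nrow(df)) - 1L
  rownames(df) <- NULL
  df[, c("pair_index", "watson_key", "crick_key", "watson_base",
         "watson_chain", "crick_chain")]
}

# Assemble a pdna_complex from a standardized, cleaned atom table.
complex_from_atoms <- function(atoms, source_id = "in-memory",
                               contact_cutoff = 5.0, require_protein = TRUE) {
  is_protein <- atoms$residue_name %in% PROTEIN_RESIDUES
  is_dna <- atoms$residue_name %in% names(DNA_RESIDUES)
  other <- !(is_protein | is_dna)
  if (any(other)) {
    res_other <- unique(atoms$residue_name[other])
    mod <- res_other[res_other %in% MODIFIED_BASES]
    if (!length(mod)) {
      # unknown residues carrying a sugar C1' look like modified nucleotides
      keys <- nucleotide_key(atoms$chain_id, atoms$residue_index, atoms$insert)
      for (rn in res_other) {
        sel <- atoms$residue_name == rn
        for (k in unique(keys[sel])) {
          nm <- atoms$atom_name[keys == k]
          if ("C1'" %in% nm && any(c("N1", "N9") %in% nm)) mod <- c(mod, rn)
        }
      }
    }
    if (length(mod)) {
      stop("unsupported chemistry: modified or non-standard nucleotide(s) ",
           paste(unique(mod), collapse = ", "),
           "; only unmodified A/C/G/T deoxyribonucleotides are accepted")
    }
    atoms <- atoms[!other, , drop = FALSE]  # drop remaining ligands
    is_protein <- atoms$residue_name %in% PROTEIN_RESIDUES
    is_dna <- atoms$residue_name %in% names(DNA_RESIDUES)
  }
  if (!any(is_dna)) stop("no DNA duplex found: structure has no DNA residues")
  if (require_protein && !any(is_protein)) {
    stop("no protein chains found in structure")
  }
  dna_atoms <- atoms[is_dna, , drop = FALSE]
  protein_atoms <- atoms[is_protein, , drop = FALSE]
  nucleotides <- build_nucleotides(dna_atoms)
  pairs <- detect_base_pairs(nucleotides)

  paired_keys <- c(pairs$watson_key, pairs$crick_key)
  unpaired <- setdiff(names(nucleotides), paired_keys)
  if (length(unpaired)) {
    # overhangs / unpaired nucleotides are excluded from the duplex
    nucleotides <- nucleotides[paired_keys]
    keep_keys <- nucleotide_key(dna_atoms$chain_id, dna_atoms$residue_index,
                                dna_atoms$insert) %in% paired_keys
    dna_atoms <- dna_atoms[keep_keys, , drop = FALSE]
  } else {
    nucleotides <- nucleotides[names(nucleotides)]
  }

  obj <- structure(list(
    protein_atoms = protein_atoms,
    dna_atoms = dna_atoms,
    nucleotides = nucleotides,
    pairs = pairs,
    n_pairs = nrow(pairs),
    dna_sequence = paste(pairs$watson_base, collapse = ""),
    source_id = source_id
  ), class = "pdna_complex")

  if (require_protein) {
    if (contact_count(obj, cutoff = contact_cutoff) < 1) {
      stop("no protein atoms within ", contact_cutoff,
           " Angstrom of the DNA: not an interface complex")
    }
  }
  obj
}

#' Parse a protein-DNA complex structure
#'
#' Reads a PDB or mmCIF file, removes hydrogens, waters, ions and altloc
#' duplicates (highest occupancy kept; first model only), partitions atoms
#' into protein and DNA by residue dictionary, and assembles the DNA duplex
#' via [detect_base_pairs()]. Chemically modified bases are rejected;
#' unpaired overhanging nucleotides are excluded from the duplex.
#'
#' @param path Structure file.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @param contact_cutoff Interface gate (Angstrom): at least one protein
#'   heavy atom must lie within this distance of a DNA heavy atom.
#' @return An object of class `pdna_complex` with elements `protein_atoms`,
#'   `dna_atoms`, `nucleotides`, `pairs`, `n_pairs`, `dna_sequence`,
#'   `source_id`.
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                            contact_cutoff = 5.0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  pdb <- tryCatch({
    if (format == "pdb") {
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    }
  }, error = function(e) {
    stop("failed to parse ", format, " file '", path, "': ",
         conditionMessage(e))
  })
  atoms <- clean_atoms(standardize_atoms(pdb$atom))
  if (!nrow(atoms)) stop("no heavy atoms found in ", path)
  complex_from_atoms(atoms, source_id = basename(path),
                     contact_cutoff = contact_cutoff)
}

#' @export
print.pdna_complex <- function(x, ...) {
  cat("Protein-DNA complex", sQuote(x$source_id), "\n")
  cat("  protein heavy atoms:", nrow(x$protein_atoms), "\n")
  cat("  duplex:", x$n_pairs, "base pairs, Watson sequence", x$dna_sequence, "\n")
  invisible(x)
}

#' Count protein-DNA atomic contacts
#'
#' Number of (protein heavy atom, DNA heavy atom) pairs at distance
#' `<= cutoff`.
#'
#' @param complex A [parse_structure()] result.
#' @param cutoff Distance cutoff in Angstrom (default 5.0).
#' @return Nonnegative integer.
#' @export
contact_count <- function(complex, cutoff = 5.0) {
  stopifnot(inherits(complex, "pdna_complex"))
  P <- as.matrix(complex$protein_atoms[, c("x", "y", "z")])
  D <- as.matrix(complex$dna_atoms[, c("x", "y", "z")])
  if (!nrow(P) || !nrow(D)) return(0L)
  d2 <- outer(rowSums(P^2), rowSums(D^2), "+") - 2 * P %*% t(D)
  sum(d2 <= cutoff^2 + 1e-9)
}

#' Write a complex to a PDB file
#'
#' Protein atoms first, then DNA atoms, sequential atom numbering; used for
#' synthetic fixtures and round-trip tests.
#'
#' @param complex A `pdna_complex`.
#' @param path Output file.
#' @export
write_complex_pdb <- function(complex, path) {
  stopifnot(inherits(complex, "pdna_complex"))
  at <- rbind(complex$protein_atoms, complex$dna_atoms)
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = at$residue_index,
                   resid = at$residue_name,
                   eleno = seq_len(nrow(at)),
                   elety = at$atom_name,
                   chain = at$chain_id,
                   o = at$occupancy,
                   b = rep(0, nrow(at)),
                   elesy = at$element)
  invisible(path)
}
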