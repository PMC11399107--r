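# Synthetic protein-DNA complexes with known ground-truth specificity:
# parametric B-DNA duplexes plus rule-bearing pseudo-residue probes docked
# at groove/backbone sites. Desk-scale stand-ins for curated corpora; the
# geometry is idealized and the "protein" is minimal, but every structure
# survives the full parse -> sym-helix -> graph -> predict pipeline.

#' Helical parameters of the generated B-DNA
#'
#' @param twist Helical twist, degrees per step.
#' @param rise Rise, Angstrom per step.
#' @param backbone_radius Phosphate radius, Angstrom.
#' @param minor_groove_phase Angular offset (degrees) between the two
#'   strands' phosphates measured across the minor groove.
#' @param coordinate_noise_sd Gaussian noise added to every coordinate
#'   (Angstrom).
#' @return List of class `helix_params`.
#' @export
helix_params <- function(twist = 36.0, rise = 3.4, backbone_radius = 9.4,
                         minor_groove_phase = 154, coordinate_noise_sd = 0.05) {
  stopifnot(twist > 20, twist < 45, rise > 2.5, rise < 4.5,
            backbone_radius > 0, coordinate_noise_sd >= 0)
  structure(list(twist = twist, rise = rise,
                 backbone_radius = backbone_radius,
                 minor_groove_phase = minor_groove_phase,
                 coordinate_noise_sd = coordinate_noise_sd),
            class = "helix_params")
}

# Local (base-pair frame) coordinates of one Watson nucleotide; the Crick
# mate is the y-mirror. Positions are base-label independent: sequence
# identity lives only in residue names and the glycosidic N name.
local_nucleotide_coords <- function(params) {
  phi <- deg2rad(180 - params$minor_groove_phase / 2)
  r <- params$backbone_radius
  list(
    P = c(r * cos(phi), r * sin(phi), 0),
    glyN = c(0, 1.5, 0),
    C5 = c(1.8, 1.0, 0),    # major-edge proxy
    C2 = c(-1.8, 1.0, 0),   # minor-edge proxy
    sugar = rbind(
      "C1'" = c(-2.0, 5.2, 0), "C2'" = c(-3.3, 5.9, -0.3),
      "C3'" = c(-3.0, 7.2, 0.2), "C4'" = c(-1.7, 7.3, 0.4),
      "O4'" = c(-1.2, 6.0, 0.3))
  )
}

rotz <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(ct, st, 0, -st, ct, 0, 0, 0, 1), 3, 3)
}

#' Generate an idealized B-DNA duplex
#'
#' Emits, per nucleotide, the phosphate, C1' and sugar-ring atoms, the
#' glycosidic nitrogen (N9 for purines, N1 for pyrimidines) and two
#' base-edge proxy atoms, at canonical cylindrical positions (strand 2
#' mirrored and phase-shifted, antiparallel residue numbering), plus seeded
#' Gaussian coordinate noise. The result parses through [parse_structure()]
#' machinery and pairs fully.
#'
#' @param sequence Watson-strand base string over ACGT, length 6 to 60.
#' @param params A [helix_params()].
#' @param seed RNG seed for the coordinate noise.
#' @return Standardized atom data.frame (chains A = Watson, B = Crick).
#' @export
make_bdna <- function(sequence, params = helix_params(), seed = 1) {
  sv <- strsplit(toupper(sequence), "")[[1]]
  if (!all(sv %in% BASES)) stop("sequence must be over A/C/G/T")
  N <- length(sv)
  if (N < 6 || N > 60) stop("sequence length must be in [6, 60]")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  loc <- local_nucleotide_coords(params)
  res3 <- c(A = "DA", C = "DC", G = "DG", T = "DT")
  rows <- list()
  emit <- function(chain, resno, base, R, zoff, mirror) {
    sgn <- if (mirror) -1 else 1
    add <- function(name, p, element) {
      p <- c(p[1], sgn * p[2], p[3])
      g <- R %*% p + c(0, 0, zoff)
      rows[[length(rows) + 1]] <<- data.frame(
        atom_name = name, element = element, residue_name = res3[[base]],
        residue_index = resno, chain_id = chain,
        x = g[1], y = g[2], z = g[3], stringsAsFactors = FALSE)
    }
    add("P", loc$P, "P")
    gly <- if (base %in% c("A", "G")) "N9" else "N1"
    add(gly, loc$glyN, "N")
    add("C5", loc$C5, "C")
    add("C2", loc$C2, "C")
    for (s in rownames(loc$sugar)) {
      add(s, loc$sugar[s, ], if (startsWith(s, "O")) "O" else "C")
    }
  }
  for (i in seq_len(N)) {
    R <- rotz(deg2rad((i - 1) * params$twist))
    zoff <- (i - 1) * params$rise
    emit("A", i, sv[i], R, zoff, mirror = FALSE)
    emit("B", N + 1 - i, comp[[sv[i]]], R, zoff, mirror = TRUE)
  }
  df <- do.call(rbind, rows)
  if (params$coordinate_noise_sd > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(3 * nrow(df),
                                                 sd = params$coordinate_noise_sd),
                                    ncol = 3))
    df$x <- df$x + noise[, 1]
    df$y <- df$y + noise[, 2]
    df$z <- df$z + noise[, 3]
  }
  df$insert <- ""
  df$occupancy <- 1
  df$altloc <- ""
  df$atom_id <- seq_len(nrow(df))
  df[, c("atom_id", "atom_name", "element", "residue_name", "residue_index",
         "insert", "chain_id", "x", "y", "z", "occupancy", "altloc")]
}

#' Probe placement rule
#'
#' A probe rule plants a 3-atom pseudo-residue of a given chemical class
#' near one helix point group of one pair, together with the base-column
#' preference it induces. Defaults mimic canonical readout chemistry: a
#' donor in the major groove favours G (the arginine-guanine bidentate
#' H-bond pattern), an acceptor favours A, a hydrophobic contact favours T
#' (methyl group); backbone (phosphate/sugar) rules induce a uniform column
#' but flag a narrowed minor groove.
#'
#' @param probe_class `"donor"`, `"acceptor"` or `"hydrophobic"`.
#' @param target_group `"major"`, `"minor"`, `"phosphate"` or `"sugar"`.
#' @param preferred_column Optional probability 4-vector (A, C, G, T)
#'   overriding the class default.
#' @return List of class `probe_rule`.
#' @export
probe_rule <- function(probe_class = c("donor", "acceptor", "hydrophobic"),
                       target_group = c("major", "minor", "phosphate", "sugar"),
                       preferred_column = NULL) {
  probe_class <- match.arg(probe_class)
  target_group <- match.arg(target_group)
  if (is.null(preferred_column)) {
    preferred_column <- if (target_group == "major") {
      switch(probe_class,
             donor = c(1, 1, 12, 1) / 15,
             acceptor = c(12, 1, 1, 1) / 15,
             hydrophobic = c(1, 1, 1, 12) / 15)
    } else {
      rep(0.25, 4)
    }
  }
  if (abs(sum(preferred_column) - 1) > 1e-6) {
    stop("preferred_column must sum to 1")
  }
  structure(list(probe_class = probe_class, target_group = target_group,
                 preferred_column = preferred_column,
                 narrow_groove = target_group %in% c("phosphate", "sugar")),
            class = "probe_rule")
}

PROBE_ATOMS <- list(
  donor = list(residue = "ARG", atoms = c("NH1", "NH2", "CZ"),
               elements = c("N", "N", "C")),
  acceptor = list(residue = "ASP", atoms = c("OD1", "OD2", "CG"),
                  elements = c("O", "O", "C")),
  hydrophobic = list(residue = "LEU", atoms = c("CD1", "CD2", "CG"),
                     elements = c("C", "C", "C"))
)

probe_atom_rows <- function(class, resno, center, axis, tangent, jitter) {
  spec_ <- PROBE_ATOMS[[class]]
  pos <- rbind(center,
               center + 1.3 * axis + jitter[1:3],
               center + 1.3 * tangent + jitter[4:6])
  data.frame(atom_name = spec_$atoms, element = spec_$elements,
             residue_name = spec_$residue, residue_index = resno,
             insert = "", chain_id = "P",
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             occupancy = 1, altloc = "", stringsAsFactors = FALSE)
}

#' Plant rule-bearing probes on a duplex
#'
#' For each (pair_index, rule), a 3-atom probe residue with the feature
#' profile of its class (named ARG/ASP/LEU so atom featurization applies
#' unmodified) is placed 2.8-3.2 Angstrom from a helix point of the targeted
#' group along its outward normal (seeded jitter; placement retried, then an
#' error, if two probes come within 2 Angstrom). The ground-truth PWM is
#' uniform everywhere except planted pairs, which take the rule's preferred
#' column. Backbone rules additionally narrow the groove locally by pulling
#' the neighbouring phosphates toward the axis.
#'
#' @param duplex Atom data.frame from [make_bdna()].
#' @param rules List of `list(pair_index = <0-based>, rule = probe_rule())`.
#' @param seed RNG seed for slot choice, distances and jitter.
#' @param n_decoys_far Far decoy atoms (hydrophobic, placed well outside the
#'   bipartite cutoff of every helix point).
#' @param n_decoys_inert In-range decoy atoms near backbone points of
#'   unplanted pairs, carrying no specificity rule.
#' @param source_id Identifier stored on the complex.
#' @return List of class `synthetic_datapoint`: `complex`, `truth_pwm`,
#'   `planted` (data.frame with probe atom ids), `decoy_atom_ids`.
#' @export
plant_probes <- function(duplex, rules, seed = 1, n_decoys_far = 0,
                         n_decoys_inert = 0, source_id = "synthetic") {
  pair_ix <- vapply(rules, function(r) as.integer(r$pair_index), integer(1))
  if (anyDuplicated(pair_ix)) stop("pair indices must be distinct")
  # local groove narrowing for backbone rules
  narrow_at <- pair_ix[vapply(rules, function(r) r$rule$narrow_groove,
                              logical(1))]
  if (length(narrow_at)) {
    N <- max(duplex$residue_index[duplex$chain_id == "A"])
    for (p in narrow_at) {
      for (dp_ in -1:1) {
        j <- p + dp_
        if (j < 0 || j >= N) next
        sel <- duplex$atom_name == "P" &
          ((duplex$chain_id == "A" & duplex$residue_index == j + 1) |
           (duplex$chain_id == "B" & duplex$residue_index == N - j))
        duplex$x[sel] <- duplex$x[sel] * 0.85
        duplex$y[sel] <- duplex$y[sel] * 0.85
      }
    }
  }
  dna_complex <- complex_from_atoms(duplex, source_id = source_id,
                                    require_protein = FALSE)
  helix <- build_sym_helix(dna_complex)
  n <- dna_complex$n_pairs
  if (any(pair_ix < 0 | pair_ix >= n)) stop("pair_index out of range")
  pts <- helix$points

  probe_rows <- list()
  decoy_rows <- list()
  planted <- list()
  placed_xyz <- matrix(numeric(0), 0, 3)
  resno <- 0L
  with_seed(child_seed(seed, 3L), {
    for (ri in seq_along(rules)) {
      rule <- rules[[ri]]$rule
      p <- pair_ix[ri]
      cand <- pts[pts$pair_index == p & pts$group == rule$target_group &
                    pts$present, , drop = FALSE]
      if (!nrow(cand)) stop("no present helix point for rule at pair ", p)
      ok <- FALSE
      for (attempt in seq_len(20)) {
        row <- cand[sample(nrow(cand), 1), ]
        nrm <- c(row$nx, row$ny, row$nz)
        axs <- c(row$ax, row$ay, row$az)
        tangent <- unitv(cross3(nrm, axs))
        center <- c(row$x, row$y, row$z) + stats::runif(1, 2.8, 3.2) * nrm
        jitter <- stats::rnorm(6, sd = 0.05)
        resno <- resno + 1L
        rows3 <- probe_atom_rows(rule$probe_class, resno, center, axs,
                                 tangent, jitter)
        xyz <- as.matrix(rows3[, c("x", "y", "z")])
        if (nrow(placed_xyz)) {
          d2 <- outer(rowSums(xyz^2), rowSums(placed_xyz^2), "+") -
            2 * xyz %*% t(placed_xyz)
          if (min(d2) < 4) { resno <- resno - 1L; next }  # < 2 A: retry
        }
        placed_xyz <- rbind(placed_xyz, xyz)
        probe_rows[[ri]] <- rows3
        planted[[ri]] <- data.frame(
          pair_index = p, probe_class = rule$probe_class,
          target_group = rule$target_group, residue_index = resno,
          stringsAsFactors = FALSE)
        ok <- TRUE
        break
      }
      if (!ok) stop("probe placement failed: overlapping probes at pair ", p)
    }
    # decoys
    zr <- range(helix$frames$origin[, 3])
    if (n_decoys_far > 0) {
      for (k in seq_len(n_decoys_far)) {
        ang <- stats::runif(1, 0, 2 * pi)
        pos <- c(25 * cos(ang), 25 * sin(ang), stats::runif(1, zr[1], zr[2]))
        resno <- resno + 1L
        decoy_rows[[length(decoy_rows) + 1]] <- data.frame(
          atom_name = "CD1", element = "C", residue_name = "LEU",
          residue_index = resno, insert = "", chain_id = "P",
          x = pos[1], y = pos[2], z = pos[3], occupancy = 1, altloc = "",
          stringsAsFactors = FALSE)
      }
    }
    if (n_decoys_inert > 0) {
      free_pairs <- setdiff(seq_len(n) - 1L, pair_ix)
      for (k in seq_len(n_decoys_inert)) {
        p <- if (length(free_pairs)) sample(free_pairs, 1) else sample(n, 1) - 1L
        cand <- pts[pts$pair_index == p & pts$group == "sugar" & pts$present, ,
                    drop = FALSE]
        row <- cand[sample(nrow(cand), 1), ]
        pos <- c(row$x, row$y, row$z) + 3.0 * c(row$nx, row$ny, row$nz)
        resno <- resno + 1L
        decoy_rows[[length(decoy_rows) + 1]] <- data.frame(
          atom_name = "CD1", element = "C", residue_name = "LEU",
          residue_index = resno, insert = "", chain_id = "P",
          x = pos[1], y = pos[2], z = pos[3], occupancy = 1, altloc = "",
          stringsAsFactors = FALSE)
      }
    }
  })
  protein_df <- do.call(rbind, c(probe_rows, decoy_rows))
  has_protein <- !is.null(protein_df) && nrow(protein_df) > 0
  all_atoms <- if (has_protein) {
    rbind(protein_df[, colnames(duplex)[-1], drop = FALSE],
          duplex[, colnames(duplex)[-1], drop = FALSE])
  } else {
    duplex[, colnames(duplex)[-1], drop = FALSE]
  }
  all_atoms$atom_id <- seq_len(nrow(all_atoms))
  all_atoms <- all_atoms[, c("atom_id", setdiff(colnames(all_atoms), "atom_id"))]
  complex <- complex_from_atoms(all_atoms, source_id = source_id,
                                require_protein = has_protein)

  planted_df <- if (length(planted)) do.call(rbind, planted) else
    data.frame(pair_index = integer(), probe_class = character(),
               target_group = character(), residue_index = integer())
  pa <- complex$protein_atoms
  planted_df$atom_ids <- I(lapply(planted_df$residue_index, function(rn) {
    pa$atom_id[pa$residue_index == rn]
  }))
  decoy_ids <- pa$atom_id[!(pa$residue_index %in% planted_df$residue_index)]

  truth <- matrix(0.25, n, 4)
  for (ri in seq_along(rules)) {
    truth[pair_ix[ri] + 1L, ] <- rules[[ri]]$rule$preferred_column
  }
  structure(list(complex = complex,
                 truth_pwm = pwm(truth, name = source_id),
                 planted = planted_df, decoy_atom_ids = decoy_ids),
            class = "synthetic_datapoint")
}

#' Generate a synthetic training corpus
#'
#' Seeded, reproducible corpus of probe-decorated duplexes. Duplex lengths,
#' rule counts and rule classes are sampled per complex; planted positions
#' of the (otherwise random) duplex sequence are set to the argmax base of
#' the planted column so that the frozen PWM-to-structure alignment recovers
#' the true correspondence. `group_label` is the sorted rule-class
#' signature, making [make_folds()] cluster-aware.
#'
#' @param n Number of complexes.
#' @param length_range Duplex length range (pairs).
#' @param rules_per_complex_range Range of planted rules per complex.
#' @param mixture Named sampling weights over rule classes; names are
#'   `"<class>@<group>"` tokens, defaults to the three major-groove classes
#'   in equal proportion.
#' @param params A [helix_params()].
#' @param seed RNG seed.
#' @return List of [specnet_datapoint()] objects, each additionally carrying
#'   `planted`, `truth_pwm` and `decoy_atom_ids`.
#' @export
generate_corpus <- function(n, length_range = c(10, 16),
                            rules_per_complex_range = c(1, 3),
                            mixture = c("donor@major" = 1, "acceptor@major" = 1,
                                        "hydrophobic@major" = 1),
                            params = helix_params(), seed = 1) {
  stopifnot(n >= 1)
  mixture <- mixture / sum(mixture)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    si <- child_seed(seed, i)
    dp <- with_seed(si, {
      L <- sample(length_range[1]:length_range[2], 1)
      nr <- sample(rules_per_complex_range[1]:rules_per_complex_range[2], 1)
      nr <- min(nr, max(1, L - 4))
      positions <- sample(2:(L - 3), nr)  # interior pairs, 0-based
      toks <- sample(names(mixture), nr, replace = TRUE, prob = mixture)
      sv <- sample(BASES, L, replace = TRUE)
      rules <- vector("list", nr)
      for (r in seq_len(nr)) {
        parts <- strsplit(toks[r], "@", fixed = TRUE)[[1]]
        rl <- probe_rule(parts[1], parts[2])
        rules[[r]] <- list(pair_index = positions[r], rule = rl)
        if (max(rl$preferred_column) > 0.3) {
          sv[positions[r] + 1] <- BASES[which.max(rl$preferred_column)]
        }
      }
      list(L = L, seq = paste(sv, collapse = ""), rules = rules,
           toks = toks)
    })
    duplex <- make_bdna(dp$seq, params = params, seed = child_seed(si, 7L))
    sdp <- plant_probes(duplex, dp$rules, seed = child_seed(si, 11L),
                        source_id = sprintf("synth_%04d", i))
    label <- paste(sort(dp$toks), collapse = "+")
    # truth PWMs span the whole duplex: demand full-coverage alignment so
    # the frozen correspondence is exact (offset 0, forward)
    point <- specnet_datapoint(sdp$complex, sdp$truth_pwm,
                               group_label = label,
                               min_overlap = sdp$complex$n_pairs,
                               id = sprintf("synth_%04d", i))
    point$planted <- sdp$planted
    point$truth_pwm <- sdp$truth_pwm
    point$decoy_atom_ids <- sdp$decoy_atom_ids
    out[[i]] <- point
  }
  out
}

#' Write a corpus to disk
#'
#' One PDB and one plain PWM file per datapoint plus a tab-separated
#' manifest mapping structure to truth to group label.
#'
#' @param corpus From [generate_corpus()].
#' @param dir Output directory (created).
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(corpus, function(dp) {
    pdb <- file.path(dir, paste0(dp$id, ".pdb"))
    pwmf <- file.path(dir, paste0(dp$id, ".pwm"))
    write_complex_pdb(dp$complex, pdb)
    write_pwm(dp$target_pwm, pwmf, format = "plain")
    planted <- if (!is.null(dp$planted) && nrow(dp$planted)) {
      paste(sprintf("%d|%s|%s", dp$planted$pair_index,
                    dp$planted$probe_class, dp$planted$target_group),
            collapse = ",")
    } else ""
    data.frame(id = dp$id, pdb = basename(pdb), pwm = basename(pwmf),
               group_label = dp$group_label, n_pairs = dp$complex$n_pairs,
               min_overlap = dp$alignment$overlap,
               planted = planted, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, "manifest.tsv"))
}

#' Reload a corpus written by [write_corpus()]
#'
#' @param dir Corpus directory containing `manifest.tsv`.
#' @return List of [specnet_datapoint()].
#' @export
read_corpus <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    cx <- parse_structure(file.path(dir, manifest$pdb[i]))
    tp <- read_pwm(file.path(dir, manifest$pwm[i]))
    mo <- manifest$min_overlap[i]
    if (is.null(mo) || is.na(mo)) mo <- 4
    dp <- specnet_datapoint(cx, tp, group_label = manifest$group_label[i],
                            min_overlap = mo, id = manifest$id[i])
    pl <- manifest$planted[i]
    if (!is.na(pl) && nzchar(pl)) {
      parts <- strsplit(strsplit(pl, ",")[[1]], "\\|")
      dp$planted <- data.frame(
        pair_index = as.integer(vapply(parts, `[`, character(1), 1)),
        probe_class = vapply(parts, `[`, character(1), 2),
        target_group = vapply(parts, `[`, character(1), 3),
        stringsAsFactors = FALSE)
    }
    dp
  })
}
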