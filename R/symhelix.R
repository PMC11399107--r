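# The symmetrized helix: per-base-pair reference frames, 11 grouped oriented
# points per pair (4 major + 3 minor base-edge sites, 2 phosphate, 2 sugar),
# and per-pair shape features. Base identity is removed by construction:
# base-edge point positions depend only on the frames, never on base labels.

GROUP_ORDER <- c("major", "minor", "phosphate", "sugar")
GROUP_SLOTS <- c(major = 4L, minor = 3L, phosphate = 2L, sugar = 2L)

#' Canonical base-edge point template
#'
#' Offsets (Angstrom, in base-pair frame coordinates: x toward the major
#' groove, y along the C1'-C1' axis, z along the local helix axis) of the
#' seven key interaction sites: four in the major groove and three in the
#' minor groove. The defaults mimic averaged Watson-Crick functional-group
#' positions and are configuration data, not code: pass an edited copy to
#' [build_sym_helix()] to change the schema.
#'
#' @return List with `major` (4 x 3) and `minor` (3 x 3) offset matrices.
#' @export
sym_helix_template <- function() {
  list(
    major = rbind(c(2.2, -2.4, 0), c(2.9, -0.8, 0),
                  c(2.9,  0.8, 0), c(2.2,  2.4, 0)),
    minor = rbind(c(-2.6, -1.6, 0), c(-3.0, 0, 0), c(-2.6, 1.6, 0))
  )
}

# Frame for one pair: origin at the glycosidic-nitrogen midpoint, y from
# Crick C1' toward Watson C1', z = local helix direction orthogonalized
# against y, x = y cross z pointing toward the major groove.
frame_for_pair <- function(w, c_, axis_hint) {
  origin <- (w$glyN + c_$glyN) / 2
  yv <- unitv(w$c1p - c_$c1p)
  z0 <- axis_hint - sum(axis_hint * yv) * yv
  if (vnorm(z0) < 1e-8) {
    stop("degenerate geometry: helix axis collinear with base-pair y axis")
  }
  zv <- unitv(z0)
  xv <- cross3(yv, zv)
  c1mid <- (w$c1p + c_$c1p) / 2
  s <- origin - c1mid
  if (vnorm(s) > 1e-8 && sum(xv * s) < 0) {
    zv <- -zv
    xv <- -xv
  }
  list(origin = origin, x = xv, y = yv, z = zv)
}

#' Compute base-pair reference frames for a complex
#'
#' One orthonormal right-handed frame per pair: origin at the midpoint of the
#' two glycosidic nitrogens, y axis from Crick C1' toward Watson C1', z axis
#' the local helix direction (from the previous pair origin to the next;
#' terminal pairs use their single neighbour; a single isolated pair falls
#' back to the global z direction orthogonalized against y), x = y x z
#' oriented toward the major groove.
#'
#' @param complex A `pdna_complex`.
#' @return List with `origin` (n x 3) and `axes` (3 x 3 x n; columns x, y, z).
#' @export
compute_frames <- function(complex) {
  stopifnot(inherits(complex, "pdna_complex"))
  pr <- complex$pairs
  n <- nrow(pr)
  W <- lapply(pr$watson_key, function(k) complex$nucleotides[[k]])
  C_ <- lapply(pr$crick_key, function(k) complex$nucleotides[[k]])
  origins0 <- t(vapply(seq_len(n), function(i) (W[[i]]$glyN + C_[[i]]$glyN) / 2,
                       numeric(3)))
  axes <- array(NA_real_, c(3, 3, n))
  origin <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    hint <- if (n == 1) {
      yv <- W[[i]]$c1p - C_[[i]]$c1p
      h <- c(0, 0, 1)
      if (vnorm(cross3(unitv(yv), h)) < 1e-6) h <- c(1, 0, 0)
      h
    } else if (i == 1) {
      origins0[2, ] - origins0[1, ]
    } else if (i == n) {
      origins0[n, ] - origins0[n - 1, ]
    } else {
      origins0[i + 1, ] - origins0[i - 1, ]
    }
    f <- frame_for_pair(W[[i]], C_[[i]], hint)
    origin[i, ] <- f$origin
    axes[, , i] <- cbind(f$x, f$y, f$z)
  }
  list(origin = origin, axes = axes)
}

sugar_centroid <- function(nuc) {
  sel <- nuc$atoms$atom_name %in% SUGAR_RING_ATOMS
  if (!any(sel)) return(NULL)
  colMeans(as.matrix(nuc$atoms[sel, c("x", "y", "z"), drop = FALSE]))
}

#' Build the symmetrized helix for a complex
#'
#' Replaces the DNA with grouped oriented points: per pair, 4 major-groove
#' and 3 minor-groove base-edge sites placed from the frame via the template
#' offsets, 2 phosphate points at the actual P atom positions (marked absent
#' when the 5' phosphate is missing) and 2 sugar points at the sugar-ring
#' centroids. Each point carries an outward normal (away from the frame
#' origin) and the local helix-axis direction. Point order is pair-major:
#' pair_index, then group (major, minor, phosphate, sugar), then slot.
#'
#' @param complex A `pdna_complex`.
#' @param template Base-edge offsets, see [sym_helix_template()].
#' @param seq_info If `TRUE`, attach the Watson-strand one-hot sequence
#'   features (see [attach_sequence()]).
#' @return Object of class `sym_helix`: `points` data.frame (pair_index,
#'   group, slot, x, y, z, nx, ny, nz, ax, ay, az, present), `frames`,
#'   `shape` (n x 4 matrix), `shape_z` (per-helix z-scored), `seq`
#'   (n x 4 one-hot or NULL), `n_pairs`.
#' @export
build_sym_helix <- function(complex, template = sym_helix_template(),
                            seq_info = FALSE) {
  stopifnot(inherits(complex, "pdna_complex"))
  frames <- compute_frames(complex)
  n <- complex$n_pairs
  pr <- complex$pairs
  rows <- vector("list", n * 11L)
  k <- 0L
  for (i in seq_len(n)) {
    O <- frames$origin[i, ]
    A <- frames$axes[, , i]
    zv <- A[, 3]
    add_point <- function(group, slot, pos, present = TRUE) {
      k <<- k + 1L
      if (present) {
        nrm <- pos - O
        nrm <- if (vnorm(nrm) > 1e-9) nrm / vnorm(nrm) else c(NA, NA, NA)
      } else {
        pos <- c(NA_real_, NA_real_, NA_real_)
        nrm <- c(NA_real_, NA_real_, NA_real_)
      }
      rows[[k]] <<- data.frame(
        pair_index = i - 1L, group = group, slot = slot,
        x = pos[1], y = pos[2], z = pos[3],
        nx = nrm[1], ny = nrm[2], nz = nrm[3],
        ax = zv[1], ay = zv[2], az = zv[3],
        present = present, stringsAsFactors = FALSE)
    }
    for (s in seq_len(4)) add_point("major", s, O + A %*% template$major[s, ])
    for (s in seq_len(3)) add_point("minor", s, O + A %*% template$minor[s, ])
    wnuc <- complex$nucleotides[[pr$watson_key[i]]]
    cnuc <- complex$nucleotides[[pr$crick_key[i]]]
    add_point("phosphate", 1, wnuc$p %||% O, present = !is.null(wnuc$p))
    add_point("phosphate", 2, cnuc$p %||% O, present = !is.null(cnuc$p))
    sw <- sugar_centroid(wnuc); sc <- sugar_centroid(cnuc)
    add_point("sugar", 1, sw %||% O, present = !is.null(sw))
    add_point("sugar", 2, sc %||% O, present = !is.null(sc))
  }
  points <- do.call(rbind, rows)
  helix <- structure(list(points = points, frames = frames,
                          shape = NULL, shape_z = NULL, seq = NULL,
                          n_pairs = n), class = "sym_helix")
  helix$shape <- compute_shape_features(helix)
  sz <- scale(helix$shape)
  sz[!is.finite(sz)] <- 0  # constant column -> zero after z-scoring
  helix$shape_z <- matrix(as.numeric(sz), n, 4,
                          dimnames = dimnames(helix$shape))
  if (seq_info) helix <- attach_sequence(helix, complex$dna_sequence)
  helix
}

#' @export
print.sym_helix <- function(x, ...) {
  cat("Symmetrized helix:", x$n_pairs, "pairs,",
      sum(x$points$present), "present points of", nrow(x$points), "\n")
  invisible(x)
}

#' Attach (or detach) sequence identity to a sym-helix
#'
#' Optionally reintroduces DNA sequence information: every point of pair i
#' carries the one-hot encoding of the Watson base at i. Pass `NULL` to
#' detach and return the sequence-agnostic helix.
#'
#' @param helix A `sym_helix`.
#' @param sequence Base string of length `n_pairs`, or `NULL`.
#' @return The helix with `seq` set (n x 4 one-hot matrix) or cleared.
#' @export
attach_sequence <- function(helix, sequence) {
  stopifnot(inherits(helix, "sym_helix"))
  if (is.null(sequence)) {
    helix["seq"] <- list(NULL)   # keep the slot, clear the value
    return(helix)
  }
  sv <- strsplit(toupper(sequence), "")[[1]]
  if (length(sv) != helix$n_pairs) {
    stop("sequence length ", length(sv), " does not match n_pairs ",
         helix$n_pairs)
  }
  if (!all(sv %in% BASES)) stop("sequence contains non-ACGT characters")
  onehot <- matrix(0, helix$n_pairs, 4, dimnames = list(NULL, BASES))
  onehot[cbind(seq_along(sv), match(sv, BASES))] <- 1
  helix$seq <- onehot
  helix
}

#' Per-pair DNA shape features
#'
#' Four features per pair: minor groove width (minimum cross-strand
#' phosphate-phosphate distance between the Watson phosphate of pair i and
#' the Crick phosphates of pairs i-4..i-2, minus 5.8 Angstrom for the two
#' phosphate radii, floored at 0), helical twist, rise and roll from the
#' relative transform between consecutive frames (assigned to the earlier
#' pair; the last pair copies its neighbour). Features that cannot be
#' computed (missing phosphates, chain ends) are imputed with the helix mean.
#'
#' @param helix A `sym_helix`.
#' @return n x 4 matrix with columns `minor_groove_width`, `twist`, `rise`,
#'   `roll`.
#' @export
compute_shape_features <- function(helix) {
  stopifnot(inherits(helix, "sym_helix"))
  n <- helix$n_pairs
  O <- helix$frames$origin
  A <- helix$frames$axes
  twist <- rise <- roll <- rep(NA_real_, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      xi <- A[, 1, i]; yi <- A[, 2, i]; zi <- A[, 3, i]
      xn <- A[, 1, i + 1]; zn <- A[, 3, i + 1]
      twist[i] <- rad2deg(atan2(sum(xn * yi), sum(xn * xi)))
      rise[i] <- sum((O[i + 1, ] - O[i, ]) * zi)
      roll[i] <- rad2deg(atan2(sum(zn * yi), sum(zn * zi)))
    }
    twist[n] <- twist[n - 1]; rise[n] <- rise[n - 1]; roll[n] <- roll[n - 1]
  }
  pts <- helix$points
  pw <- pts[pts$group == "phosphate" & pts$slot == 1, , drop = FALSE]
  pc <- pts[pts$group == "phosphate" & pts$slot == 2, , drop = FALSE]
  mgw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!pw$present[i]) next
    js <- (i - 4):(i - 2)
    js <- js[js >= 1]
    js <- js[pc$present[js]]
    if (!length(js)) next
    d <- sqrt((pw$x[i] - pc$x[js])^2 + (pw$y[i] - pc$y[js])^2 +
              (pw$z[i] - pc$z[js])^2)
    mgw[i] <- max(min(d) - 5.8, 0)
  }
  out <- cbind(minor_groove_width = mgw, twist = twist, rise = rise, roll = roll)
  for (j in seq_len(ncol(out))) {
    if (anyNA(out[, j])) {
      m <- mean(out[, j], na.rm = TRUE)
      out[is.na(out[, j]), j] <- if (is.finite(m)) m else 0
    }
  }
  out
}

#' Export a sym-helix as a point table
#'
#' One point per row: pair_index, group, slot, position and outward normal.
#'
#' @param helix A `sym_helix`.
#' @param path Output file (tab-separated).
#' @export
write_sym_helix <- function(helix, path) {
  stopifnot(inherits(helix, "sym_helix"))
  utils::write.table(
    helix$points[, c("pair_index", "group", "slot", "x", "y", "z",
                     "nx", "ny", "nz")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a sym-helix as PDB pseudo-atoms for visualization
#'
#' Groups are written as distinct residue names (MAJ, MIN, PHO, SUG) of
#' carbon pseudo-atoms, one residue per pair.
#'
#' @param helix A `sym_helix`.
#' @param path Output PDB file.
#' @export
write_sym_helix_pdb <- function(helix, path) {
  stopifnot(inherits(helix, "sym_helix"))
  pts <- helix$points[helix$points$present, , drop = FALSE]
  resid <- c(major = "MAJ", minor = "MIN", phosphate = "PHO",
             sugar = "SUG")[pts$group]
  xyz <- as.vector(t(as.matrix(pts[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = pts$pair_index + 1L, resid = resid,
                   eleno = seq_len(nrow(pts)),
                   elety = paste0("S", pts$slot),
                   chain = rep("H", nrow(pts)),
                   elesy = rep("C", nrow(pts)))
  invisible(path)
}
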