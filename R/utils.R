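# Small geometry / numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v, tol = 1e-10) {
  n <- vnorm(v)
  if (n < tol) stop("degenerate geometry: cannot normalize near-zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Random rigid transform (rotation + translation)
#'
#' Draws a uniformly random rotation (via QR of a Gaussian matrix, sign-fixed
#' to a proper rotation) and a random translation. Used in invariance tests.
#'
#' @param translation_scale Standard deviation (Angstrom) of the translation.
#' @return List with `R` (3x3 rotation) and `t` (length-3 translation).
#' @export
random_rigid_transform <- function(translation_scale = 20) {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = stats::rnorm(3, sd = translation_scale))
}

#' Apply a rigid transform to a complex structure
#'
#' Rotates and translates every atom coordinate; topology and labels are
#' untouched.
#'
#' @param complex A [parse_structure()] result.
#' @param transform A list with elements `R` and `t`, as produced by
#'   [random_rigid_transform()].
#' @return The transformed complex.
#' @export
transform_complex <- function(complex, transform) {
  stopifnot(inherits(complex, "pdna_complex"))
  tx <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(transform$R)
    xyz <- sweep(xyz, 2, -transform$t)  # adds t
    df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
    df
  }
  complex$protein_atoms <- tx(complex$protein_atoms)
  complex$dna_atoms <- tx(complex$dna_atoms)
  # rebuild nucleotide records so their anchor coordinates move too
  nucs <- build_nucleotides(complex$dna_atoms)
  complex$nucleotides <- nucs[names(complex$nucleotides)]
  complex
}

# Derive a child seed below 2^31 from a base seed and a stream tag.
# Double arithmetic keeps intermediates exact (< 2^53) and the result fits
# a 32-bit integer.
child_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) %% 2147483629 * 1009 +
                as.numeric(tag) * 7919) %% 2147483629)
}
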