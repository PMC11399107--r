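# Position weight matrices: container, file I/O, metrics, alignment.

BASES <- c("A", "C", "G", "T")

#' Position weight matrix
#'
#' A PWM is an N x 4 row-stochastic matrix over bases A, C, G, T: row i holds
#' the probabilities of the four bases at position i of the binding site.
#'
#' @param x Numeric N x 4 matrix (or object coercible to one); columns in
#'   A, C, G, T order.
#' @param name Optional identifier carried through I/O and reports.
#' @param normalize If `TRUE`, divide each row by its sum instead of
#'   insisting the input already lies on the simplex.
#' @return An object of class `pwm`.
#' @export
pwm <- function(x, name = NULL, normalize = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) != 4) stop("a PWM must have 4 columns (A, C, G, T)")
  storage.mode(x) <- "double"
  if (any(!is.finite(x)) || any(x < -1e-12)) {
    stop("PWM entries must be finite and nonnegative")
  }
  x[x < 0] <- 0
  if (normalize) {
    rs <- rowSums(x)
    if (any(rs <= 0)) stop("cannot normalize a PWM row that sums to 0")
    x <- x / rs
  }
  if (any(abs(rowSums(x) - 1) > 1e-6)) {
    stop("each PWM row must sum to 1 (within 1e-6); use normalize = TRUE for counts")
  }
  colnames(x) <- BASES
  rownames(x) <- NULL
  structure(x, class = c("pwm", "matrix"), name = name)
}

#' @export
print.pwm <- function(x, digits = 3, ...) {
  nm <- attr(x, "name")
  cat("PWM", if (!is.null(nm)) paste0("'", nm, "'"), "with", nrow(x), "positions\n")
  m <- unclass(x)
  attr(m, "name") <- NULL
  print(round(m, digits), ...)
  invisible(x)
}

is_pwm <- function(x) inherits(x, "pwm")

as_pwm_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "name") <- NULL
  m
}

#' Reverse complement of a PWM
#'
#' Rows are reversed and the A/T and C/G columns swapped, giving the motif as
#' read on the opposite strand. Involution: applying it twice restores the
#' original.
#'
#' @param x A [pwm()].
#' @return A `pwm`.
#' @export
reverse_complement <- function(x) {
  stopifnot(is_pwm(x))
  m <- as_pwm_matrix(x)
  m <- m[rev(seq_len(nrow(m))), c("T", "G", "C", "A"), drop = FALSE]
  pwm(m, name = attr(x, "name"))
}

check_same_length <- function(a, b) {
  if (nrow(a) != nrow(b)) {
    stop("PWMs differ in length (", nrow(a), " vs ", nrow(b), ")")
  }
}

#' Mean absolute error between two PWMs
#'
#' `MAE = (1/N) * sum_i sum_b |Y[i,b] - Ypred[i,b]|`: the inner sum runs over
#' the four bases and is not divided by 4, so a uniform column against a
#' one-hot column contributes 1.5.
#'
#' @param y,ypred PWMs of equal length.
#' @return Nonnegative scalar.
#' @export
pwm_mae <- function(y, ypred) {
  stopifnot(is_pwm(y), is_pwm(ypred))
  check_same_length(y, ypred)
  sum(abs(as_pwm_matrix(y) - as_pwm_matrix(ypred))) / nrow(y)
}

#' Root mean squared error between two PWMs
#'
#' `RMSE = sqrt((1/N) * sum_i sum_b (Y[i,b] - Ypred[i,b])^2)`, with the same
#' base-sum convention as [pwm_mae()].
#'
#' @inheritParams pwm_mae
#' @return Nonnegative scalar.
#' @export
pwm_rmse <- function(y, ypred) {
  stopifnot(is_pwm(y), is_pwm(ypred))
  check_same_length(y, ypred)
  sqrt(sum((as_pwm_matrix(y) - as_pwm_matrix(ypred))^2) / nrow(y))
}

#' Per-position information content
#'
#' `IC_i = 2 + sum_b p log2 p` bits, with `0 * log 0 := 0`: 0 for a uniform
#' column, 2 for a one-hot column.
#'
#' @param x A [pwm()].
#' @return Numeric vector, one value per position.
#' @export
information_content <- function(x) {
  stopifnot(is_pwm(x))
  m <- as_pwm_matrix(x)
  lg <- ifelse(m > 0, log2(m), 0)
  2 + rowSums(m * lg)
}

#' Ungapped local alignment of a PWM to a DNA sequence
#'
#' Scans every offset of the PWM along the sequence and its reverse
#' complement (the PWM itself is reverse-complemented for the reverse
#' strand), allowing partial overlaps down to `min_overlap`. The score of a
#' placement is the mean, over overlapping positions, of the PWM probability
#' of the sequence base. Ties are broken toward larger overlap, then the
#' forward strand, then the smallest offset.
#'
#' @param x A [pwm()].
#' @param seq DNA string over A/C/G/T.
#' @param min_overlap Smallest allowed overlap between PWM and sequence.
#' @return A list of class `pwm_alignment` with `offset` (0-based start of
#'   the possibly reverse-complemented PWM on the forward sequence; may be
#'   negative for overhanging placements), `strand`, `score`, `overlap`.
#' @export
align_pwm <- function(x, seq, min_overlap = 4) {
  stopifnot(is_pwm(x))
  seq <- toupper(seq)
  sv <- strsplit(seq, "")[[1]]
  if (!all(sv %in% BASES)) stop("sequence contains non-ACGT characters")
  S <- length(sv)
  if (S < min_overlap) stop("sequence shorter than min_overlap")
  L <- nrow(x)
  if (L < min_overlap) stop("PWM shorter than min_overlap")
  base_idx <- match(sv, BASES)

  best <- NULL
  for (strand in c("forward", "reverse")) {
    m <- if (strand == "forward") as_pwm_matrix(x) else
      as_pwm_matrix(reverse_complement(x))
    for (o in (min_overlap - L):(S - min_overlap)) {
      j0 <- max(0L, o)               # first covered seq position (0-based)
      j1 <- min(S, o + L) - 1L       # last covered seq position
      ov <- j1 - j0 + 1L
      if (ov < min_overlap) next
      jj <- j0:j1
      sc <- mean(m[cbind(jj - o + 1L, base_idx[jj + 1L])])
      cand <- list(offset = o, strand = strand, score = sc, overlap = ov)
      if (is.null(best) ||
          sc > best$score + 1e-12 ||
          (abs(sc - best$score) <= 1e-12 &&
           (ov > best$overlap ||
            (ov == best$overlap && best$strand == "reverse" && strand == "forward")))) {
        best <- cand
      }
    }
  }
  class(best) <- "pwm_alignment"
  best
}

#' @export
print.pwm_alignment <- function(x, ...) {
  cat(sprintf("PWM alignment: offset %d, %s strand, overlap %d, score %.4f\n",
              x$offset, x$strand, x$overlap, x$score))
  invisible(x)
}

#' Write a PWM to disk
#'
#' Two dialects are supported: `"plain"` (whitespace-separated N x 4
#' probability table with `#` comment lines) and `"jaspar"` (four labelled
#' count rows, probabilities scaled by 100).
#'
#' @param x A [pwm()].
#' @param path Output file.
#' @param format `"plain"` or `"jaspar"`.
#' @export
write_pwm <- function(x, path, format = c("plain", "jaspar")) {
  stopifnot(is_pwm(x))
  format <- match.arg(format)
  m <- as_pwm_matrix(x)
  nm <- attr(x, "name") %||% "pwm"
  if (format == "plain") {
    lines <- c(sprintf("# PWM %s", nm), "# A C G T",
               apply(m, 1, function(r) paste(sprintf("%.6f", r), collapse = "\t")))
  } else {
    counts <- round(m * 100, 4)
    lines <- c(paste0(">", nm),
               vapply(seq_along(BASES), function(b) {
                 sprintf("%s  [ %s ]", BASES[b],
                         paste(sprintf("%8.4f", counts[, b]), collapse = " "))
               }, character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a PWM from disk
#'
#' Auto-detects the dialect: a leading `>` marks a JASPAR-style block of four
#' labelled count rows, anything else is read as a plain N x 4 probability
#' table (with `#` comments). JASPAR counts are converted to probabilities
#' with a pseudocount added to every cell.
#'
#' @param path Input file.
#' @param format `"auto"`, `"plain"` or `"jaspar"`.
#' @param pseudocount Added to each JASPAR count cell before normalization.
#' @return A [pwm()].
#' @export
read_pwm <- function(path, format = c("auto", "plain", "jaspar"),
                     pseudocount = 0.5) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (format == "auto") {
    format <- if (length(lines) && startsWith(lines[[1]], ">")) "jaspar" else "plain"
  }
  if (format == "plain") {
    lines <- lines[!startsWith(lines, "#")]
    rows <- lapply(strsplit(lines, "\\s+"), as.numeric)
    m <- do.call(rbind, rows)
    if (any(abs(rowSums(m) - 1) > 1e-3)) {
      stop("plain PWM rows must be probabilities summing to 1")
    }
    # absorb the write precision (rows renormalized exactly)
    return(pwm(m, name = tools::file_path_sans_ext(basename(path)),
               normalize = TRUE))
  }
  nm <- sub("^>\\s*", "", lines[[1]])
  body <- lines[-1][1:4]
  vals <- lapply(body, function(ln) {
    lab <- sub("^([ACGT]).*", "\\1", ln)
    nums <- regmatches(ln, gregexpr("[0-9.eE+-]+", sub("^[ACGT]", "", ln)))[[1]]
    list(lab = lab, v = as.numeric(nums))
  })
  labs <- vapply(vals, `[[`, character(1), "lab")
  if (!setequal(labs, BASES)) stop("JASPAR block must have A, C, G, T rows")
  counts <- do.call(cbind, lapply(BASES, function(b) vals[[match(b, labs)]]$v))
  counts <- counts + pseudocount
  pwm(counts / rowSums(counts), name = nm)
}

#' Logo-ready table for a PWM
#'
#' One row per (position, base) with the probability and the position's
#' information content in bits, suitable for plotting sequence logos.
#'
#' @param x A [pwm()].
#' @return A data.frame with columns position (1-based), base, probability,
#'   bits.
#' @export
logo_table <- function(x) {
  stopifnot(is_pwm(x))
  m <- as_pwm_matrix(x)
  ic <- information_content(x)
  data.frame(
    position = rep(seq_len(nrow(m)), each = 4),
    base = rep(BASES, nrow(m)),
    probability = as.vector(t(m)),
    bits = rep(ic, each = 4),
    stringsAsFactors = FALSE
  )
}

#' @export
plot.pwm <- function(x, ...) {
  m <- t(as_pwm_matrix(x))
  graphics::barplot(m, beside = FALSE, names.arg = seq_len(ncol(m)),
                    col = c("#109648", "#255C99", "#F7B32B", "#D62839"),
                    xlab = "position", ylab = "probability",
                    legend.text = BASES, ...)
  invisible(x)
}

#' Uniform PWM of a given length
#'
#' @param n Number of positions.
#' @return A [pwm()] with every entry 0.25.
#' @export
uniform_pwm <- function(n) {
  pwm(matrix(0.25, n, 4), name = "uniform")
}
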