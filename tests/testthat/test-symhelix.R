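# Base-pair frames, sym-helix point construction, shape features.

test_that("frames are orthonormal, right-handed, with x toward the major groove", {
  cx <- clean_duplex_complex()
  fr <- compute_frames(cx)
  for (i in seq_len(cx$n_pairs)) {
    A <- fr$axes[, , i]
    expect_equal(t(A) %*% A, diag(3), tolerance = 1e-6, ignore_attr = TRUE)
    xv <- A[, 1]; yv <- A[, 2]; zv <- A[, 3]
    expect_equal(specnet:::cross3(xv, yv), zv, tolerance = 1e-6)
  }
})

test_that("a single isolated pair falls back to a well-defined frame", {
  cx <- clean_duplex_complex("ACGGTT")
  one <- cx
  one$pairs <- cx$pairs[1, , drop = FALSE]
  one$n_pairs <- 1L
  h <- build_sym_helix(one)
  expect_equal(nrow(h$points), 11)
  A <- h$frames$axes[, , 1]
  expect_equal(t(A) %*% A, diag(3), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("each pair carries 7 base-edge points (4 major + 3 minor) and 4 backbone points", {
  cx <- clean_duplex_complex("ACGGTT")
  one <- cx
  one$pairs <- cx$pairs[1, , drop = FALSE]
  one$n_pairs <- 1L
  h1 <- build_sym_helix(one)
  counts <- table(h1$points$group)
  expect_equal(as.integer(counts[c("major", "minor")]), c(4L, 3L))
  expect_equal(as.integer(counts["phosphate"] + counts["sugar"]), 4L)
  # N-pair duplex: 11 N points, group pattern conserved
  h <- build_sym_helix(cx)
  expect_equal(nrow(h$points), 11 * cx$n_pairs)
  tab <- table(h$points$group)
  expect_equal(as.integer(tab[c("major", "minor", "phosphate", "sugar")]),
               cx$n_pairs * c(4L, 3L, 2L, 2L))
})

test_that("a missing 5' phosphate yields an absent slot, not an imputed point", {
  d <- make_bdna("ACGGTTAC", seed = 2)
  d <- d[!(d$atom_name == "P" & d$chain_id == "A" & d$residue_index == 1), ]
  cx <- specnet:::complex_from_atoms(d, require_protein = FALSE)
  h <- build_sym_helix(cx)
  absent <- h$points[!h$points$present, ]
  expect_equal(nrow(absent), 1)
  expect_equal(absent$group, "phosphate")
  expect_equal(absent$pair_index, 0L)
})

test_that("sym-helix point positions are independent of base labels", {
  d <- make_bdna("ACGGTTACGTAC", seed = 7)
  # relabel bases on paper (A<->G, T<->C), coordinates untouched
  d2 <- d
  relab <- c(DA = "DG", DG = "DA", DT = "DC", DC = "DT")
  d2$residue_name <- unname(relab[d2$residue_name])
  gly <- d2$atom_name %in% c("N1", "N9")
  d2$atom_name[gly] <- ifelse(d2$residue_name[gly] %in% c("DA", "DG"),
                              "N9", "N1")
  h1 <- build_sym_helix(specnet:::complex_from_atoms(d, require_protein = FALSE))
  h2 <- build_sym_helix(specnet:::complex_from_atoms(d2, require_protein = FALSE))
  expect_identical(h1$points[, c("x", "y", "z", "nx", "ny", "nz")],
                   h2$points[, c("x", "y", "z", "nx", "ny", "nz")])
})

test_that("attach_sequence sets one-hots and detaching restores the original", {
  cx <- clean_duplex_complex("ACGTAC")
  h <- build_sym_helix(cx)
  h2 <- attach_sequence(h, "ACGTAC")
  expect_equal(h2$seq[1, ], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(h2$seq[3, ], c(A = 0, C = 0, G = 1, T = 0))
  expect_error(attach_sequence(h, "ACGT"), "does not match")
  h3 <- attach_sequence(h2, NULL)
  expect_equal(h3, h)
})

test_that("shape features recover the generator's twist and rise", {
  for (tw in c(34, 36)) {
    cx <- clean_duplex_complex("ACGGTTACGTAC", twist = tw)
    h <- build_sym_helix(cx)
    expect_equal(mean(h$shape[, "twist"]), tw, tolerance = 0.5)
    expect_equal(mean(h$shape[, "rise"]), 3.4, tolerance = 0.05)
  }
  # the 34 and 36 degree runs are clearly distinguishable
  h34 <- build_sym_helix(clean_duplex_complex("ACGGTTACGTAC", twist = 34))
  h36 <- build_sym_helix(clean_duplex_complex("ACGGTTACGTAC", twist = 36))
  expect_gt(abs(mean(h36$shape[, "twist"]) - mean(h34$shape[, "twist"])), 1)
})

test_that("shape features are invariant under rigid motion", {
  sdp <- std_complex()
  h1 <- build_sym_helix(sdp$complex)
  tr <- specnet:::with_seed(13, random_rigid_transform())
  h2 <- build_sym_helix(transform_complex(sdp$complex, tr))
  expect_equal(h2$shape, h1$shape, tolerance = 1e-6)
})

test_that("rigid motion transforms points and directions covariantly", {
  sdp <- std_complex()
  h1 <- build_sym_helix(sdp$complex)
  tr <- specnet:::with_seed(29, random_rigid_transform())
  h2 <- build_sym_helix(transform_complex(sdp$complex, tr))
  p1 <- as.matrix(h1$points[, c("x", "y", "z")]) %*% t(tr$R)
  p1 <- sweep(p1, 2, -tr$t)
  expect_equal(as.matrix(h2$points[, c("x", "y", "z")]), p1,
               tolerance = 1e-6, ignore_attr = TRUE)
  n1 <- as.matrix(h1$points[, c("nx", "ny", "nz")]) %*% t(tr$R)
  expect_equal(as.matrix(h2$points[, c("nx", "ny", "nz")]), n1,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("strand swap reverses pair order and exchanges backbone slots", {
  d <- make_bdna("ACGGTTACGTAC", seed = 7)
  d2 <- d
  d2$chain_id <- ifelse(d$chain_id == "A", "B", "A")
  h1 <- build_sym_helix(specnet:::complex_from_atoms(d, require_protein = FALSE))
  h2 <- build_sym_helix(specnet:::complex_from_atoms(d2, require_protein = FALSE))
  n <- h1$n_pairs
  # phosphate slot 1 (Watson) of pair i matches slot 2 (Crick) of pair n-1-i
  p1 <- h1$points[h1$points$group == "phosphate" & h1$points$slot == 1, ]
  p2 <- h2$points[h2$points$group == "phosphate" & h2$points$slot == 2, ]
  for (i in seq_len(n)) {
    expect_equal(unlist(p1[i, c("x", "y", "z")]),
                 unlist(p2[n + 1 - i, c("x", "y", "z")]), tolerance = 1e-9)
  }
  # same multiset of all present point positions
  m1 <- h1$points[h1$points$present, c("x", "y", "z")]
  m2 <- h2$points[h2$points$present, c("x", "y", "z")]
  expect_equal(m1[do.call(order, m1), ], m2[do.call(order, m2), ],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("sym-helix exports are written", {
  sdp <- std_complex()
  h <- build_sym_helix(sdp$complex)
  f1 <- tempfile(fileext = ".tsv")
  write_sym_helix(h, f1)
  tab <- read.delim(f1)
  expect_equal(nrow(tab), nrow(h$points))
  f2 <- tempfile(fileext = ".pdb")
  write_sym_helix_pdb(h, f2)
  expect_true(file.exists(f2))
})
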