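# Structure parsing, Watson-Crick pairing, contacts, round trips.

test_that("a synthetic complex round-trips through PDB within format precision", {
  sdp <- std_complex()
  f <- tempfile(fileext = ".pdb")
  write_complex_pdb(sdp$complex, f)
  cx2 <- parse_structure(f)
  expect_equal(cx2$n_pairs, 12)
  expect_equal(nrow(cx2$protein_atoms), nrow(sdp$complex$protein_atoms))
  expect_equal(nrow(cx2$dna_atoms), nrow(sdp$complex$dna_atoms))
  expect_equal(cx2$dna_sequence, sdp$complex$dna_sequence)
  a <- sdp$complex$dna_atoms; b <- cx2$dna_atoms
  ka <- order(a$chain_id, a$residue_index, a$atom_name)
  kb <- order(b$chain_id, b$residue_index, b$atom_name)
  expect_lt(max(abs(as.matrix(a[ka, c("x", "y", "z")]) -
                    as.matrix(b[kb, c("x", "y", "z")]))), 1e-3)
})

test_that("mmCIF input gives the same complex as PDB", {
  sdp <- std_complex()
  f <- tempfile(fileext = ".cif")
  write_min_cif(sdp$complex, f)
  cx <- suppressWarnings(parse_structure(f))
  expect_equal(cx$n_pairs, 12)
  expect_equal(cx$dna_sequence, sdp$complex$dna_sequence)
  expect_equal(nrow(cx$protein_atoms), nrow(sdp$complex$protein_atoms))
})

test_that("degenerate inputs are rejected with clear messages", {
  # protein only: write just the probe atoms
  sdp <- std_complex()
  protein_only <- sdp$complex
  protein_only$dna_atoms <- protein_only$dna_atoms[0, ]
  f <- tempfile(fileext = ".pdb")
  write_complex_pdb(protein_only, f)
  expect_error(parse_structure(f), "no DNA duplex found")
  expect_error(parse_structure(tempfile(fileext = ".pdb")), "not found")
  # modified base: 5-methylcytosine residue
  d <- make_bdna("ACGGTTACGTAC", seed = 7)
  d$residue_name[d$chain_id == "A" & d$residue_index == 2] <- "5CM"
  expect_error(specnet:::complex_from_atoms(d, require_protein = FALSE),
               "unsupported chemistry")
})

test_that("an ideal generated duplex pairs fully and in order", {
  cx <- clean_duplex_complex("ACGGTTACGT")
  expect_equal(cx$n_pairs, 10)
  expect_equal(cx$pairs$pair_index, 0:9)
  expect_equal(cx$dna_sequence, "ACGGTTACGT")
  # injective pairing
  keys <- c(cx$pairs$watson_key, cx$pairs$crick_key)
  expect_false(anyDuplicated(keys) > 0)
})

test_that("swapping the strands' chain records gives the same pair set", {
  d <- make_bdna("ACGGTTACGTAC", seed = 7)
  d2 <- d
  d2$chain_id <- ifelse(d$chain_id == "A", "B", "A")
  cx1 <- specnet:::complex_from_atoms(d, require_protein = FALSE)
  cx2 <- specnet:::complex_from_atoms(d2, require_protein = FALSE)
  expect_equal(cx2$n_pairs, cx1$n_pairs)
  # Watson/Crick roles swapped: the new Watson sequence is the reverse
  # complement of the old one
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  expect_equal(cx2$dna_sequence, rc(cx1$dna_sequence))
  # same C1' point set in space
  c1 <- function(cx) {
    m <- cx$dna_atoms[cx$dna_atoms$atom_name == "C1'", c("x", "y", "z")]
    m[do.call(order, m), ]
  }
  expect_equal(c1(cx1), c1(cx2), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("an unpaired overhanging nucleotide is excluded", {
  d <- make_bdna("ACGGTTACGTAC", seed = 7)
  d2 <- d[!(d$chain_id == "B" & d$residue_index == 1), ]  # drop last pair's mate
  cx <- specnet:::complex_from_atoms(d2, require_protein = FALSE)
  expect_equal(cx$n_pairs, 11)
})

test_that("pairing preconditions are enforced", {
  d <- make_bdna("ACGGTTACGTAC", seed = 1)
  nucs <- specnet:::build_nucleotides(d)
  expect_error(detect_base_pairs(nucs[1:6]), "at least 8")
  one_strand <- nucs[vapply(nucs, function(n) n$chain_id == "A", logical(1))]
  expect_error(detect_base_pairs(one_strand), "2 strands")
})

test_that("contact_count matches a brute-force distance scan", {
  sdp <- std_complex()
  cx <- sdp$complex
  P <- as.matrix(cx$protein_atoms[, c("x", "y", "z")])
  D <- as.matrix(cx$dna_atoms[, c("x", "y", "z")])
  brute <- function(cutoff) {
    n <- 0
    for (i in seq_len(nrow(P))) for (j in seq_len(nrow(D))) {
      if (sqrt(sum((P[i, ] - D[j, ])^2)) <= cutoff) n <- n + 1
    }
    n
  }
  for (cutoff in c(3, 5, 8)) {
    expect_equal(contact_count(cx, cutoff), brute(cutoff))
  }
  expect_gt(contact_count(cx, 5), 0)
  # far protein -> zero contacts
  far <- cx
  far$protein_atoms$x <- far$protein_atoms$x + 100
  expect_equal(contact_count(far, 5), 0)
  # an atom exactly on a DNA atom counts
  onsite <- cx
  onsite$protein_atoms[1, c("x", "y", "z")] <- cx$dna_atoms[1, c("x", "y", "z")]
  expect_gte(contact_count(onsite, 5), 1)
})

test_that("altloc duplicates resolve to the highest occupancy", {
  d <- make_bdna("ACGGTT", seed = 1)
  dup <- d[d$chain_id == "A" & d$residue_index == 1 & d$atom_name == "P", ]
  dup$x <- dup$x + 5
  dup$altloc <- "B"; dup$occupancy <- 0.9
  d$altloc[d$chain_id == "A" & d$residue_index == 1 & d$atom_name == "P"] <- "A"
  d$occupancy[d$chain_id == "A" & d$residue_index == 1 & d$atom_name == "P"] <- 0.4
  merged <- specnet:::clean_atoms(rbind(d, dup))
  kept <- merged[merged$chain_id == "A" & merged$residue_index == 1 &
                   merged$atom_name == "P", ]
  expect_equal(nrow(kept), 1)
  expect_equal(kept$occupancy, 0.9)
})
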