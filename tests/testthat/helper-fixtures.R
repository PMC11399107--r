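# Shared fixtures, built lazily once per test session. Everything is
# generated in code; nothing is read from disk except files the tests
# themselves write to tempdir().

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small network config used throughout the unit tests
tiny_config <- function(mode = "full", seed = 5) {
  specnet_config(mode = mode, embed_dim = 8, n_rbf = 6, conv1d_channels = 8,
                 n_protein_layers = 2, seed = seed)
}

# config used for the trained-model studies (documented in the vignette)
study_config <- function(mode = "full", seed = 5) {
  specnet_config(mode = mode, embed_dim = 16, n_rbf = 8,
                 conv1d_channels = 16, n_protein_layers = 2, seed = seed)
}

study_control <- function(epochs = 45, patience = 10) {
  specnet_control(lr = 0.03, batch_size = 8, epochs = epochs,
                  patience = patience)
}

# 12-bp duplex with one donor probe in the major groove of pair 5
std_complex <- function() {
  fixture("std_complex", function() {
    d <- make_bdna("ACGGTTACGTAC", seed = 7)
    plant_probes(d, list(list(pair_index = 5,
                              rule = probe_rule("donor", "major"))),
                 seed = 3, source_id = "std")
  })
}

# bare duplex (no protein), noise-free, for geometry tests
clean_duplex_complex <- function(sequence = "ACGGTTACGTAC", twist = 36,
                                 rise = 3.4) {
  d <- make_bdna(sequence, seed = 1,
                 params = helix_params(twist = twist, rise = rise,
                                       coordinate_noise_sd = 0))
  specnet:::complex_from_atoms(d, require_protein = FALSE,
                               source_id = "duplex")
}

# small trained fit shared by interpretation tests
trained_toy_fit <- function() {
  fixture("trained_toy_fit", function() {
    # include rule-inert backbone probes so backbone contacts are
    # in-distribution for the interpretation tests
    corpus <- generate_corpus(40, seed = 301,
                              mixture = c("donor@major" = 1,
                                          "acceptor@major" = 1,
                                          "hydrophobic@major" = 1,
                                          "hydrophobic@sugar" = 1))
    specnet(corpus, config = study_config(seed = 11),
            control = study_control(epochs = 30, patience = 8), seed = 77)
  })
}

# the cross-validation study corpus (acceptance-scale)
study_corpus <- function() {
  fixture("study_corpus", function() generate_corpus(300, seed = 2024))
}

# minimal mmCIF emitter (canonical RCSB atom_site column order); test-only
# plumbing - the package's own writer is PDB.
write_min_cif <- function(complex, path) {
  at <- rbind(complex$protein_atoms, complex$dna_atoms)
  lines <- c(
    "data_fixture", "#", "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
             "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
             "auth_comp_id", "auth_asym_id", "auth_atom_id",
             "pdbx_PDB_model_num")),
    sprintf("ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
            seq_len(nrow(at)), at$element, at$atom_name, at$residue_name,
            at$chain_id, at$residue_index, at$x, at$y, at$z,
            at$residue_index, at$residue_name, at$chain_id, at$atom_name),
    "#")
  writeLines(lines, path)
  invisible(path)
}

# random PWM generator for metric property tests
random_pwm <- function(n, seed) {
  m <- specnet:::with_seed(seed, matrix(stats::rexp(4 * n), n, 4))
  pwm(m / rowSums(m))
}
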