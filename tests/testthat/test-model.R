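# The geometric network: output contracts, invariances, gradients,
# checkpoints.

test_that("predictions are N x 4 row-stochastic matrices", {
  sdp <- std_complex()
  m <- specnet_model(tiny_config())
  pr <- predict_pwm(m, sdp$complex)
  expect_equal(dim(pr$pwm), c(12, 4))
  expect_true(all(abs(rowSums(pr$pwm) - 1) < 1e-6))
  expect_true(all(pr$pwm > 0 & pr$pwm < 1))
})

test_that("a zero-initialized head emits exactly uniform columns", {
  sdp <- std_complex()
  m <- specnet_model(tiny_config())
  pr <- predict_pwm(m, sdp$complex)
  expect_equal(unclass(pr$pwm), matrix(0.25, 12, 4), ignore_attr = TRUE)
})

test_that("prediction is invariant under rigid motion of the whole complex", {
  sdp <- std_complex()
  m <- specnet_model(tiny_config())
  # make outputs non-uniform so the check has teeth
  m$params$W_head <- specnet:::with_seed(8, matrix(rnorm(length(m$params$W_head), sd = 0.5),
                                                   nrow(m$params$W_head)))
  p0 <- predict_pwm(m, sdp$complex)$pwm
  for (s in 1:3) {
    tr <- specnet:::with_seed(s, random_rigid_transform())
    p1 <- predict_pwm(m, transform_complex(sdp$complex, tr))$pwm
    expect_equal(unclass(p1), unclass(p0), tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("masking atoms beyond the bipartite cutoff changes nothing", {
  sdp <- std_complex()
  m <- specnet_model(tiny_config())
  m$params$W_head <- specnet:::with_seed(9, matrix(rnorm(length(m$params$W_head), sd = 0.5),
                                                   nrow(m$params$W_head)))
  p0 <- predict_pwm(m, sdp$complex)
  # an id that exists nowhere near the helix (and a non-existent one)
  p1 <- predict_pwm(m, sdp$complex, mask = edge_mask(999999L))
  expect_identical(p0$logits, p1$logits)
  # masking every atom empties the bipartite graphs -> still valid simplex
  all_ids <- sdp$complex$protein_atoms$atom_id
  p2 <- predict_pwm(m, sdp$complex, mask = edge_mask(all_ids))
  expect_true(all(abs(rowSums(p2$pwm) - 1) < 1e-6))
})

test_that("prediction ignores base relabeling unless seqinfo mode is on", {
  d <- make_bdna("ACGGTTACGTAC", seed = 7)
  probe <- list(list(pair_index = 5, rule = probe_rule("donor", "major")))
  sdp <- plant_probes(d, probe, seed = 3)
  d2 <- d
  relab <- c(DA = "DG", DG = "DA", DT = "DC", DC = "DT")
  d2$residue_name <- unname(relab[d2$residue_name])
  gly <- d2$atom_name %in% c("N1", "N9")
  d2$atom_name[gly] <- ifelse(d2$residue_name[gly] %in% c("DA", "DG"),
                              "N9", "N1")
  sdp2 <- plant_probes(d2, probe, seed = 3)
  for (mode in c("full", "groove", "shape")) {
    m <- specnet_model(tiny_config(mode = mode))
    m$params$W_head <- specnet:::with_seed(4, matrix(rnorm(length(m$params$W_head), sd = 0.5),
                                                     nrow(m$params$W_head)))
    pa <- predict_pwm(m, sdp$complex)$pwm
    pb <- predict_pwm(m, sdp2$complex)$pwm
    expect_equal(unclass(pa), unclass(pb), ignore_attr = TRUE)
  }
  # seqinfo mode must depend on the labels
  m <- specnet_model(tiny_config(mode = "full_seqinfo"))
  m$params$W_head <- specnet:::with_seed(4, matrix(rnorm(length(m$params$W_head), sd = 0.5),
                                                   nrow(m$params$W_head)))
  pa <- predict_pwm(m, sdp$complex)$pwm
  pb <- predict_pwm(m, sdp2$complex)$pwm
  expect_gt(max(abs(pa - pb)), 1e-8)
})

test_that("mode-inactive blocks of the flattened features are zero", {
  sdp <- std_complex()
  ns <- asNamespace("specnet")
  for (mode in c("groove", "shape")) {
    cfg <- tiny_config(mode = mode)
    m <- specnet_model(cfg)
    inp <- ns$precompute_inputs(sdp$complex, cfg)
    fw <- ns$forward_specnet(m$params, inp, cfg, keep_cache = TRUE)
    Z <- fw$cache$Z
    d <- cfg$embed_dim
    blocks <- list(major = 0:3, minor = 4:6, phosphate = 7:8, sugar = 9:10)
    cols <- function(g) as.vector(outer(seq_len(2 * d), blocks[[g]] * 2 * d, "+"))
    if (mode == "groove") {
      expect_true(all(Z[, c(cols("phosphate"), cols("sugar"))] == 0))
      expect_equal(ncol(Z), 22 * d)        # no shape block at all
      expect_gt(sum(abs(Z[, cols("major")])), 0)
    } else {
      expect_true(all(Z[, c(cols("major"), cols("minor"))] == 0))
      expect_equal(ncol(Z), 22 * d + 4)    # shape block appended
      expect_gt(sum(abs(Z[, 22 * d + 1:4])), 0)
    }
  }
})

test_that("per-pair feature width is constant across pairs and runs", {
  ns <- asNamespace("specnet")
  cfg <- tiny_config()
  for (len in c("ACGGTTAC", "ACGGTTACGTACGGTT")) {
    d <- make_bdna(len, seed = 4)
    sdp <- plant_probes(d, list(list(pair_index = 3,
                                     rule = probe_rule("donor", "major"))),
                        seed = 5)
    inp <- ns$precompute_inputs(sdp$complex, cfg)
    m <- specnet_model(cfg)
    fw <- ns$forward_specnet(m$params, inp, cfg, keep_cache = TRUE)
    expect_equal(ncol(fw$cache$Z), ns$config_flat_width(cfg))
    expect_equal(nrow(fw$cache$Z), nchar(len))
  }
})

test_that("isolated vertices embed from their own features alone", {
  ns <- asNamespace("specnet")
  cfg <- tiny_config()
  m <- specnet_model(cfg)
  # far decoys are single-atom residues: isolated vertices with identical
  # features -> identical embeddings regardless of their positions
  d <- make_bdna("ACGGTTACGTAC", seed = 9)
  sdp <- plant_probes(d, list(list(pair_index = 5,
                                   rule = probe_rule("donor", "major"))),
                      seed = 6, n_decoys_far = 2)
  inp <- ns$precompute_inputs(sdp$complex, cfg)
  fw <- ns$forward_specnet(m$params, inp, cfg, keep_cache = TRUE)
  pa <- sdp$complex$protein_atoms
  iso <- which(pa$atom_id %in% sdp$decoy_atom_ids)
  expect_equal(length(iso), 2)
  H <- fw$cache$H_final
  expect_equal(H[iso[1], ], H[iso[2], ], tolerance = 1e-12)
  # and the connected probe atoms embed differently from the isolated ones
  probe_rows <- which(!(pa$atom_id %in% sdp$decoy_atom_ids))
  expect_gt(max(abs(H[probe_rows[1], ] - H[iso[1], ])), 1e-6)
})

test_that("analytic gradients match finite differences", {
  ns <- asNamespace("specnet")
  d <- make_bdna("ACGGTTACGT", seed = 1)
  sdp <- plant_probes(d, list(
    list(pair_index = 4, rule = probe_rule("donor", "major")),
    list(pair_index = 7, rule = probe_rule("acceptor", "major"))), seed = 2)
  cfg <- specnet_config(embed_dim = 4, n_rbf = 3, conv1d_channels = 5,
                        n_protein_layers = 2, seed = 3)
  params <- ns$init_params(cfg)
  params$W_head <- specnet:::with_seed(4, matrix(rnorm(length(params$W_head), sd = 0.3),
                                                 nrow(params$W_head)))
  params$b_head <- specnet:::with_seed(5, rnorm(4, sd = 0.1))
  inp <- ns$precompute_inputs(sdp$complex, cfg)
  tg <- matrix(0.25, 10, 4)
  tg[5, ] <- c(0.1, 0.1, 0.7, 0.1)
  tg[2, ] <- NA  # one uncovered flank column
  lossfn <- function(p) {
    fw <- ns$forward_specnet(p, inp, cfg)
    ns$loss_and_grad(fw$probs, tg, "l1")$value
  }
  fw <- ns$forward_specnet(params, inp, cfg, keep_cache = TRUE)
  lg <- ns$loss_and_grad(fw$probs, tg, "l1")
  g <- ns$backward_specnet(params, inp, cfg, fw$cache, lg$dlogits)
  eps <- 1e-6
  set.seed(1)
  for (nm in names(params)) {
    P <- params[[nm]]
    for (ii in sample(length(P), min(4, length(P)))) {
      p2 <- params; p2[[nm]][ii] <- p2[[nm]][ii] + eps
      p3 <- params; p3[[nm]][ii] <- p3[[nm]][ii] - eps
      num <- (lossfn(p2) - lossfn(p3)) / (2 * eps)
      expect_equal(g[[nm]][ii], num, tolerance = 1e-4)
    }
  }
})

test_that("prediction is deterministic for fixed seed and input", {
  sdp <- std_complex()
  m1 <- specnet_model(tiny_config(seed = 21))
  m2 <- specnet_model(tiny_config(seed = 21))
  expect_identical(m1$params, m2$params)
  p1 <- predict_pwm(m1, sdp$complex)
  p2 <- predict_pwm(m2, sdp$complex)
  expect_identical(p1$logits, p2$logits)
})

test_that("checkpoints round-trip and refuse version mismatches", {
  m <- specnet_model(tiny_config())
  f <- tempfile(fileext = ".ckpt")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$params, m$params)
  expect_equal(m2$config$mode, m$config$mode)
  bad <- readRDS(f)
  bad$version <- "someone-elses-format"
  saveRDS(bad, f)
  expect_error(load_model(f), "version mismatch")
})
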