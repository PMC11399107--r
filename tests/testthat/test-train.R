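# Folds, the covered-column loss, training, ensembling.

fake_points <- function(labels) {
  lapply(labels, function(l) list(group_label = l))
}

test_that("folds are cluster-aware, balanced and deterministic", {
  labs <- rep(paste0("g", 1:10), each = 3)
  ds <- fake_points(labs)
  folds <- make_folds(ds, k = 5, seed = 4)
  expect_equal(length(folds), 5)
  expect_equal(sort(unlist(folds)), seq_along(ds))
  # each fold gets exactly 2 of the 10 groups
  for (f in folds) {
    expect_equal(length(unique(labs[f])), 2)
  }
  # points sharing a label never split
  for (l in unique(labs)) {
    in_fold <- vapply(folds, function(f) any(labs[f] == l), logical(1))
    expect_equal(sum(in_fold), 1)
  }
  expect_identical(folds, make_folds(ds, k = 5, seed = 4))
  expect_false(identical(folds, make_folds(ds, k = 5, seed = 5)))
  expect_error(make_folds(fake_points(c("a", "b")), k = 5), "exceeds")
})

test_that("column_loss restricts the L1 metric to covered columns", {
  sdp <- std_complex()
  cx <- sdp$complex
  # full-coverage target equal to prediction -> 0
  dp <- specnet_datapoint(cx, sdp$truth_pwm, min_overlap = cx$n_pairs)
  expect_equal(column_loss(sdp$truth_pwm, dp), 0)
  # uniform prediction vs the planted one-column target: only pair 5 differs
  uni <- uniform_pwm(cx$n_pairs)
  expected <- sum(abs(c(1, 1, 12, 1) / 15 - 0.25)) / cx$n_pairs
  expect_equal(column_loss(uni, dp), expected)
  # equals pwm_mae on full coverage
  expect_equal(column_loss(uni, dp), pwm_mae(sdp$truth_pwm, uni))
  expect_error(column_loss(uniform_pwm(5), dp), "does not match")
})

test_that("a partially covering alignment compares the right columns", {
  cx <- std_complex()$complex
  # 6-column one-hot A target; place it via the real aligner on the
  # structure sequence, then verify against a hand loop
  onehot6 <- pwm(matrix(rep(c(1, 0, 0, 0), 6), 6, 4, byrow = TRUE))
  dp <- specnet_datapoint(cx, onehot6, min_overlap = 4)
  uni <- uniform_pwm(cx$n_pairs)
  al <- dp$alignment
  m <- if (al$strand == "forward") unclass(onehot6) else
    unclass(reverse_complement(onehot6))
  # hand loop over covered columns
  tot <- 0; ncov <- 0
  for (j in 0:(cx$n_pairs - 1)) {
    i <- j - al$offset + 1
    if (i >= 1 && i <= 6) {
      tot <- tot + sum(abs(0.25 - m[i, ]))
      ncov <- ncov + 1
    }
  }
  expect_equal(ncov, al$overlap)
  expect_equal(column_loss(uni, dp), tot / ncov)
  # uniform vs one-hot columns always cost 1.5 each
  expect_equal(column_loss(uni, dp), 1.5)
})

test_that("training reduces validation loss below the uniform baseline", {
  corpus <- generate_corpus(40, seed = 51)
  # analytic uniform baseline: mean covered-column loss of the flat guess
  base <- mean(vapply(corpus, function(dp) {
    column_loss(uniform_pwm(dp$complex$n_pairs), dp)
  }, numeric(1)))
  expect_gt(base, 0.1)  # planted columns make uniform imperfect
  fit <- specnet(corpus, config = study_config(seed = 31),
                 control = study_control(epochs = 25, patience = 25),
                 seed = 61)
  expect_lt(fit$best_val_loss, base * 0.6)
  expect_error(specnet(list(), config = study_config()), "empty")
})

test_that("training is reproducible under a fixed seed", {
  corpus <- generate_corpus(10, seed = 52)
  cfg <- tiny_config(seed = 7)
  ctl <- specnet_control(epochs = 3, lr = 0.02, batch_size = 4)
  f1 <- specnet(corpus, config = cfg, control = ctl, seed = 9)
  f2 <- specnet(corpus, config = cfg, control = ctl, seed = 9)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("ensemble prediction is the exact column-wise mean of members", {
  sdp <- std_complex()
  cx <- sdp$complex
  m1 <- specnet_model(tiny_config(seed = 1))
  m2 <- specnet_model(tiny_config(seed = 2))
  m2$params$W_head <- specnet:::with_seed(3, matrix(rnorm(length(m2$params$W_head), sd = 0.5),
                                                    nrow(m2$params$W_head)))
  # ensemble of one equals the member
  e1 <- ensemble_predict(list(m1), cx)
  expect_equal(unclass(e1), unclass(predict_pwm(m1, cx)$pwm),
               ignore_attr = TRUE)
  # ensemble of identical members equals any member
  e2 <- ensemble_predict(list(m2, m2), cx)
  expect_equal(unclass(e2), unclass(predict_pwm(m2, cx)$pwm),
               ignore_attr = TRUE)
  # mean of uniform and a non-uniform member, exact arithmetic
  pu <- unclass(predict_pwm(m1, cx)$pwm)   # uniform (zero head)
  pv <- unclass(predict_pwm(m2, cx)$pwm)
  e3 <- ensemble_predict(list(m1, m2), cx)
  expect_equal(unclass(e3), (pu + pv) / 2, ignore_attr = TRUE)
  expect_true(all(abs(rowSums(e3) - 1) < 1e-9))
  # closed form: uniform member + one-hot-like column
  half <- (matrix(0.25, 1, 4) + matrix(c(1, 0, 0, 0), 1, 4)) / 2
  expect_equal(half, matrix(c(0.625, 0.125, 0.125, 0.125), 1, 4))
})

test_that("residuals and evaluation tables are consistent", {
  corpus <- generate_corpus(6, seed = 53)
  fit <- list(model = specnet_model(tiny_config()),
              config = tiny_config())
  class(fit) <- "specnet"
  r <- residuals(fit, corpus)
  tab <- evaluate_corpus(fit, corpus)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$covered_loss, unname(r))
  expect_true(all(tab$align_strand == "forward"))
  expect_true(all(tab$align_offset == 0))
})
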