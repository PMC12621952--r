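test_that("within-class label smoothing has the exact arithmetic pattern", {
  oh_na <- replace(numeric(26), 22, 1)
  expect_identical(smooth_within_class(oh_na, 0), oh_na)
  y <- smooth_within_class(oh_na, 0.1)
  expect_equal(y[22], 0.925)
  expect_equal(unname(y[23:25]), rep(0.025, 3))
  expect_equal(sum(y[1:21]), 0)           # zero cross-class mass
  expect_equal(sum(y), 1)
  oh_p <- replace(numeric(26), 5, 1)
  yp <- smooth_within_class(oh_p, 0.1)
  expect_equal(yp[5], 0.9 + 0.1 / 20)
  expect_equal(sum(yp[22:26]), 0)
  # unknown tokens come back as the uniform over class canonicals
  expect_equal(smooth_within_class(replace(numeric(26), 26, 1))[22:25],
               rep(0.25, 4), ignore_attr = TRUE)
  expect_equal(smooth_within_class(replace(numeric(26), 21, 1))[1:20],
               rep(0.05, 20), ignore_attr = TRUE)
  expect_error(smooth_within_class(numeric(26)))
})

test_that("design targets supervise existing nucleic positions only", {
  helix <- make_protein_helix(8)
  tp <- build_design_targets(helix)
  expect_false(any(tp$mask))
  hair <- make_duplex("ACGUACGUAC", form = "A-RNA", double = FALSE)
  th <- build_design_targets(hair)
  expect_equal(sum(th$mask), 10)
  expect_true(all(abs(rowSums(th$y) - 1) < 1e-12))
  for (i in which(th$mask)) {
    expect_equal(sort(th$y[i, 22:25], decreasing = TRUE),
                 c(0.925, 0.025, 0.025, 0.025), ignore_attr = TRUE)
    expect_equal(sum(th$y[i, 1:21]), 0)
  }
  unk <- mark_unknown_base(hair, "A", 2L)
  tu <- build_design_targets(unk)
  i <- which(unk$residues$res_index == 2)
  expect_true(tu$mask[i])
  expect_equal(tu$y[i, 22:25], rep(0.25, 4), ignore_attr = TRUE)
})

test_that("specificity targets: nucleic-only complexes are fully uniform", {
  dx <- make_duplex("ACGTACGTAC")
  tg <- build_specificity_targets(dx, seed = 1)
  expect_false(tg$protein_dropped)
  expect_true(all(tg$mask))
  expect_equal(tg$y[, 22:25], matrix(0.25, 20, 4), ignore_attr = TRUE)
  expect_equal(rowSums(tg$y), rep(1, 20))
})

test_that("specificity targets: protein drop uniformizes everything", {
  fx <- make_interface_fixture(4.5)
  iface <- interface_mask(fx)
  # find seeds realizing both branches
  s_drop <- which(vapply(1:50, function(s)
    build_specificity_targets(fx, iface = iface, seed = s)$protein_dropped,
    TRUE))[1]
  s_keep <- which(vapply(1:50, function(s)
    !build_specificity_targets(fx, iface = iface, seed = s)$protein_dropped,
    TRUE))[1]
  dropped <- build_specificity_targets(fx, iface = iface, seed = s_drop)
  expect_true(dropped$protein_dropped)
  expect_false(any(dropped$complex$residues$polymer_class == "protein"))
  expect_equal(dropped$y[dropped$mask, 22:25],
               matrix(0.25, sum(dropped$mask), 4), ignore_attr = TRUE)
  kept <- build_specificity_targets(fx, iface = iface, seed = s_keep)
  expect_false(kept$protein_dropped)
  r <- kept$complex$residues
  # interface positions without a PPM carry the smoothed crystal base ...
  ifpos <- which(kept$mask & iface)
  expect_true(length(ifpos) > 0)
  for (i in ifpos) expect_equal(max(kept$y[i, ]), 0.925)
  # ... and non-interface positions are uniform
  nifpos <- which(kept$mask & !iface)
  for (i in nifpos)
    expect_equal(kept$y[i, 22:25], rep(0.25, 4), ignore_attr = TRUE)
})

test_that("specificity targets take aligned experimental PPM columns exactly", {
  fx <- make_interface_fixture(4.5)
  iface <- interface_mask(fx)
  s_keep <- which(vapply(1:50, function(s)
    !build_specificity_targets(fx, iface = iface, seed = s)$protein_dropped,
    TRUE))[1]
  key <- paste("A", 0, sep = "\r")
  aligned <- structure(list(map = setNames(list(
    list(column = c(0.7, 0.1, 0.1, 0.1), local_score = 2, ic = 5)), key)),
    class = "aligned_target_map")
  tg <- build_specificity_targets(fx, aligned = aligned, iface = iface,
                                  seed = s_keep)
  i <- which(fx$residues$chain_id == "A" & fx$residues$res_index == 0)
  expect_equal(tg$y[i, 22:25], c(0.7, 0.1, 0.1, 0.1), ignore_attr = TRUE)
  bad <- aligned
  bad$map[[key]]$column <- c(0.7, 0.1, 0.1, 0.2)
  expect_error(build_specificity_targets(fx, aligned = bad, iface = iface,
                                         seed = s_keep), "target error")
})

test_that("batch loss matches its closed forms and a scalar-loop oracle", {
  # all masks false -> 0
  lg <- matrix(0, 4, 26)
  t0 <- list(y = matrix(1 / 26, 4, 26), mask = rep(FALSE, 4))
  expect_equal(batch_loss(lg, t0), 0)
  # one masked residue, uniform 26-way prediction, unsmoothed one-hot
  t1 <- list(y = rbind(replace(numeric(26), 23, 1)), mask = TRUE)
  expect_equal(batch_loss(matrix(0, 1, 26), t1), log(26) / 6000)
  # doubling identical masked residues doubles the loss
  t2 <- list(y = rbind(t1$y, t1$y), mask = c(TRUE, TRUE))
  expect_equal(batch_loss(matrix(0, 2, 26), t2), 2 * log(26) / 6000)
  # scalar-loop oracle on random batches
  set.seed(42)
  for (rep_ in 1:5) {
    logits <- lapply(1:3, function(i) matrix(rnorm(8 * 26), 8, 26))
    targets <- lapply(1:3, function(i) {
      y <- t(vapply(sample(c(1:20, 22:25), 8, replace = TRUE),
                    nucmpnn:::.smoothed_token_target, numeric(26)))
      list(y = y, mask = runif(8) < 0.7)
    })
    expect_equal(batch_loss(logits, targets), loss_oracle(logits, targets),
                 tolerance = 1e-10)
  }
  expect_error(batch_loss(matrix(NA_real_, 1, 26), t1), "non-finite")
})

test_that("sampling weights follow the cluster-degree formula", {
  one <- make_duplex("ACGTA", double = FALSE)
  expect_equal(sampling_weight(one, c(A = 0)), 1)
  two <- make_duplex("ACGTA")
  expect_equal(sampling_weight(two, c(A = 1, B = 3)), 0.375)
  expect_lt(sampling_weight(two, c(A = 10, B = 30)),
            sampling_weight(two, c(A = 1, B = 3)))
  expect_equal(sampling_weight(two, c(A = 1e9, B = 1e9)), 0, tolerance = 1e-8)
  expect_error(sampling_weight(two, c(A = 1)), "missing cluster degree")
})

test_that("token-budget batching packs and never overflows", {
  singles <- replicate(20, list(tokens = 1, weight = 1), simplify = FALSE)
  b <- assemble_batches(singles, budget = 10, n_batches = 1, seed = 1)
  expect_length(b, 1)
  expect_length(b[[1]], 10)
  # random example sizes: every emitted batch total <= budget
  set.seed(7)
  ex <- lapply(1:30, function(i) list(tokens = sample(1:40, 1), weight = runif(1)))
  bs <- assemble_batches(ex, budget = 60, seed = 2)
  expect_true(length(bs) >= 1)
  for (bb in bs)
    expect_lte(sum(vapply(ex[bb], `[[`, 0, "tokens")), 60)
  expect_identical(assemble_batches(list(), budget = 10), list())
  # overweight examples are skipped with a warning
  heavy <- list(list(tokens = 100, weight = 1), list(tokens = 5, weight = 1))
  expect_warning(bh <- assemble_batches(heavy, budget = 10, n_batches = 1,
                                        seed = 3), "skipped")
  expect_true(all(unlist(bh) == 2))
})

test_that("weighted sampling respects example weights", {
  ex <- list(list(tokens = 1, weight = 1.0), list(tokens = 1, weight = 0.5))
  draws <- unlist(assemble_batches(ex, budget = 1, n_batches = 4000, seed = 9))
  frac1 <- mean(draws == 1)
  # expect 2/3 within ~4 binomial sigma
  expect_lt(abs(frac1 - 2 / 3), 4 * sqrt(2 / 9 / length(draws)))
})

test_that("analytic gradients match finite differences on a tiny model", {
  dx <- make_duplex("ACGT", double = FALSE)
  cfg <- model_config(hidden_dim = 8, n_encoder_layers = 1,
                      n_decoder_layers = 1, n_rbf = 3, dropout = 0, seed = 2)
  model <- init_model(cfg)
  g <- build_graph(dx, k = cfg$k_neighbors, n_rbf = cfg$n_rbf)
  tg <- build_design_targets(dx)
  out <- nucmpnn:::.example_loss_grads(model, g, tg, order_seed = 5)
  eps <- 1e-5
  paths <- list(
    c("out", "W"), c("edge_l", "W"), c("node_l2", "W"), c("tok_embed", "W"))
  set.seed(1)
  for (pth in paths) {
    W <- model$params[[pth[1]]][[pth[2]]]
    Ga <- out$grads[[pth[1]]][[pth[2]]]
    for (k in sample(length(W), 2)) {
      m1 <- model; m2 <- model
      m1$params[[pth[1]]][[pth[2]]][k] <- W[k] + eps
      m2$params[[pth[1]]][[pth[2]]][k] <- W[k] - eps
      l1 <- nucmpnn:::.example_loss_grads(m1, g, tg, order_seed = 5)$loss_sum
      l2 <- nucmpnn:::.example_loss_grads(m2, g, tg, order_seed = 5)$loss_sum
      num <- (l1 - l2) / (2 * eps) / 6000
      expect_equal(Ga[k], num, tolerance = 1e-5)
    }
  }
})

test_that("toy training is deterministic, clipped, and reduces the loss", {
  ds <- make_planted_dataset(4, length = 6, seed = 3)
  cfg <- model_config(hidden_dim = 12, n_encoder_layers = 1,
                      n_decoder_layers = 1, n_rbf = 4, dropout = 0, seed = 1)
  f1 <- train_toy(ds, cfg, steps = 8, budget = 12, seed = 5)
  f2 <- train_toy(ds, cfg, steps = 8, budget = 12, seed = 5)
  expect_equal(f1$losses, f2$losses, tolerance = 1e-10)
  expect_true(all(f1$grad_norms <= 1 + 1e-6))
  f3 <- train_toy(ds, cfg, steps = 60, budget = 12, seed = 5)
  expect_lt(mean(tail(f3$losses, 5)), mean(head(f3$losses, 5)))
})
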