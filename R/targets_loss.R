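# Training targets (within-class label smoothing, PPM substitution,
# specificity augmentations), the masked cross-entropy loss, cluster-degree
# sampling weights, token-budget batching, and the CPU training loop.

#' Label smoothing within polymer classes
#'
#' Redistributes a fraction `epsilon` of probability mass uniformly over the
#' canonical tokens of the residue's own polymer class (20 amino acids or 4
#' bases); mass outside the class is exactly zero. An unknown-token one-hot
#' is returned as the uniform distribution over its class canonicals.
#'
#' @param one_hot a valid 26-way token one-hot vector.
#' @param epsilon smoothing coefficient (default 0.1).
#' @return A 26-vector summing to 1.
#' @export
#' @examples
#' y <- smooth_within_class(replace(numeric(26), 22, 1))
#' y[22:25]  # 0.925, 0.025, 0.025, 0.025
smooth_within_class <- function(one_hot, epsilon = 0.1) {
  stopifnot(length(one_hot) == 26, sum(one_hot == 1) == 1,
            all(one_hot %in% c(0, 1)), epsilon >= 0, epsilon <= 1)
  tok <- which(one_hot == 1)
  canon <- if (tok <= 21L) .TOK_PROTEIN_CANONICAL else .TOK_NA_CANONICAL
  y <- numeric(26)
  if (!token_is_canonical(tok)) {
    y[canon] <- 1 / length(canon)
    return(y)
  }
  y[tok] <- 1 - epsilon
  y[canon] <- y[canon] + epsilon / length(canon)
  y
}

.smoothed_token_target <- function(token, epsilon = 0.1) {
  oh <- numeric(26)
  oh[token] <- 1
  smooth_within_class(oh, epsilon)
}

#' Design-model training targets
#'
#' The target at every existing nucleic acid position is the crystallographic
#' base as a within-class label-smoothed one-hot; protein positions are not
#' supervised (mask FALSE). Unknown bases get the uniform distribution over
#' the four canonical bases.
#'
#' @param complex a `nuc_complex`.
#' @param epsilon smoothing coefficient (default 0.1).
#' @return List with `y` (N x 26 target matrix) and `mask` (logical).
#' @export
build_design_targets <- function(complex, epsilon = 0.1) {
  r <- complex$residues
  n <- nrow(r)
  y <- t(vapply(r$token, .smoothed_token_target, numeric(26),
                epsilon = epsilon))
  mask <- r$polymer_class %in% c("DNA", "RNA") & r$exists
  list(y = y, mask = mask)
}

.drop_protein_chains <- function(complex) {
  r <- complex$residues
  keep_res <- r$polymer_class != "protein"
  rk <- paste(r$chain_id, r$res_index, sep = "\r")[keep_res]
  a <- complex$atoms
  a <- a[paste(a$chain_id, a$res_index, sep = "\r") %in% rk, ]
  a$is_sidechain <- NULL
  new_complex(a, resolution = complex$resolution, meta = complex$meta)
}

#' Specificity-model training targets with augmentations
#'
#' Implements the specificity supervision scheme: (i) nucleic-acid-only
#' complexes get the uniform PPM (0.25 each base) at every position; (ii)
#' protein-containing complexes have all protein chains dropped with
#' probability `drop_prob`, in which case every nucleic position is likewise
#' uniformized; (iii) otherwise, positions with an aligned experimental PPM
#' column take that column, interface positions without one take the
#' label-smoothed crystal base, and non-interface positions without one take
#' the uniform PPM.
#'
#' @param complex a `nuc_complex`.
#' @param aligned optional aligned target map from [merge_alignments()].
#' @param iface optional interface mask (computed at the default 5 Angstrom /
#'   48-neighbor settings when `NULL` and needed).
#' @param seed RNG seed for the protein-drop draw.
#' @param drop_prob protein-drop probability (default 0.5).
#' @param epsilon smoothing coefficient for crystal-base targets.
#' @return List with `y`, `mask`, `complex` (protein-dropped when drawn),
#'   and `protein_dropped` (logical).
#' @export
build_specificity_targets <- function(complex, aligned = NULL, iface = NULL,
                                      seed = NULL, drop_prob = 0.5,
                                      epsilon = 0.1) {
  r <- complex$residues
  n <- nrow(r)
  is_nuc <- r$polymer_class %in% c("DNA", "RNA")
  uniform4 <- function() { y <- numeric(26); y[.TOK_NA_CANONICAL] <- 0.25; y }
  has_protein <- any(r$polymer_class == "protein")
  dropped <- FALSE
  if (has_protein) {
    dropped <- with_seed(seed, stats::runif(1) < drop_prob)
  }
  if (!has_protein || dropped) {
    out_complex <- if (dropped) .drop_protein_chains(complex) else complex
    r2 <- out_complex$residues
    y <- matrix(0, nrow(r2), 26)
    mask <- r2$polymer_class %in% c("DNA", "RNA") & r2$exists
    y[mask, ] <- matrix(uniform4(), sum(mask), 26, byrow = TRUE)
    return(list(y = y, mask = mask, complex = out_complex,
                protein_dropped = dropped))
  }
  if (is.null(iface)) iface <- interface_mask(complex)
  y <- matrix(0, n, 26)
  mask <- is_nuc & r$exists
  key <- paste(r$chain_id, r$res_index, sep = "\r")
  for (i in which(mask)) {
    col <- if (!is.null(aligned)) aligned$map[[key[i]]]$column else NULL
    if (!is.null(col)) {
      if (abs(sum(col) - 1) > 1e-6)
        stop("target error: aligned PPM column does not sum to 1")
      y[i, .TOK_NA_CANONICAL] <- col
    } else if (iface[i]) {
      y[i, ] <- .smoothed_token_target(r$token[i], epsilon)
    } else {
      y[i, ] <- uniform4()
    }
  }
  list(y = y, mask = mask, complex = complex, protein_dropped = FALSE)
}

# ---- loss --------------------------------------------------------------------

.log_softmax <- function(logits) {
  m <- apply(logits, 1, max)
  z <- logits - m
  z - log(rowSums(exp(z)))
}

#' Masked cross-entropy training loss
#'
#' Computes (1/6000) * sum over examples and residues of
#' mask * sum_c(-y * log p), with p the full 26-way softmax of the logits.
#' The 1/6000 normalizer is the token budget of a batch and is fixed.
#'
#' @param logits a N x 26 logits matrix or a list of them (one per example).
#' @param targets matching target list(s) with elements `y` and `mask`
#'   (as from [build_design_targets()]).
#' @return Non-negative scalar loss.
#' @export
batch_loss <- function(logits, targets) {
  if (is.matrix(logits)) { logits <- list(logits); targets <- list(targets) }
  total <- 0
  for (b in seq_along(logits)) {
    if (any(!is.finite(logits[[b]]))) stop("training error: non-finite logits")
    lp <- .log_softmax(logits[[b]])
    ce <- -rowSums(targets[[b]]$y * lp)
    total <- total + sum(ce[targets[[b]]$mask])
  }
  total / 6000
}

#' Rarity-aware per-example sampling weight
#'
#' Computes (1/Nchains) * sum over chains of 1/(1 + d_i) where d_i is the
#' degree of the chain's sequence cluster; examples whose chains sit in rare
#' clusters are upweighted.
#'
#' @param complex a `nuc_complex`.
#' @param clusters named numeric vector: chain id -> cluster degree.
#' @return Positive sampling weight.
#' @export
sampling_weight <- function(complex, clusters) {
  cids <- complex$chains$chain_id
  if (!all(cids %in% names(clusters)))
    stop("missing cluster degree for chain(s): ",
         paste(setdiff(cids, names(clusters)), collapse = ","))
  d <- as.numeric(clusters[cids])
  if (any(d < 0)) stop("cluster degrees must be >= 0")
  mean(1 / (1 + d))
}

#' Token-budgeted weighted batching
#'
#' Examples are drawn by weighted sampling with replacement; a batch closes
#' when adding the next drawn example would exceed the token budget. An
#' epoch is defined as pool-size draws.
#'
#' @param examples list of examples, each with `tokens` (polymer residue
#'   count) and `weight` (sampling weight).
#' @param budget token budget per batch (default 6000).
#' @param n_batches stop after this many batches; `NULL` (default) stops
#'   after `length(examples)` draws (one epoch), emitting the final partial
#'   batch.
#' @param seed RNG seed.
#' @return List of integer vectors of example indices.
#' @export
assemble_batches <- function(examples, budget = 6000, n_batches = NULL,
                             seed = NULL) {
  if (length(examples) == 0) return(list())
  tokens <- vapply(examples, function(e) as.numeric(e$tokens), 0)
  weights <- vapply(examples, function(e) as.numeric(e$weight %||% 1), 0)
  usable <- tokens <= budget
  if (any(!usable)) {
    warning(sum(!usable), " example(s) exceed the token budget; skipped")
    weights[!usable] <- 0
  }
  if (!any(usable)) return(list())
  with_seed(seed, {
    batches <- list()
    cur <- integer(0); cur_tokens <- 0
    draws <- 0L
    max_draws <- if (is.null(n_batches)) length(examples) else Inf
    repeat {
      if (draws >= max_draws) break
      if (!is.null(n_batches) && length(batches) >= n_batches) break
      i <- sample.int(length(examples), 1, prob = weights)
      draws <- draws + 1L
      if (cur_tokens + tokens[i] > budget) {
        batches[[length(batches) + 1L]] <- cur
        cur <- integer(0); cur_tokens <- 0
        if (!is.null(n_batches) && length(batches) >= n_batches) break
      }
      cur <- c(cur, i)
      cur_tokens <- cur_tokens + tokens[i]
    }
    if (is.null(n_batches) && length(cur)) batches[[length(batches) + 1L]] <- cur
    batches
  })
}

# ---- full-model gradient ----------------------------------------------------

# One teacher-forced forward/backward pass on a single featurized example.
# Returns the (unnormalized-by-batch) loss contribution and a gradient tree
# matching the parameter structure.
.example_loss_grads <- function(model, graph, targets, order_seed,
                                train = TRUE) {
  cfg <- model$cfg
  params <- model$params
  r_tokens <- graph$tokens
  mask <- targets$mask & graph$node_mask
  enc_out <- .enc_forward(params, graph, cfg, train = train)
  free <- which(mask)
  ranks <- rep(0, graph$n_nodes)
  ord <- with_seed(order_seed, sample(free))
  ranks[ord] <- seq_along(ord)
  dec <- .dec_forward(params, graph, cfg, enc_out, r_tokens, ranks,
                      train = train)
  lp <- .log_softmax(dec$logits)
  loss_sum <- sum(-rowSums(targets$y * lp)[mask])
  # d loss / d logits (per the 1/6000-normalized batch loss)
  p <- exp(lp)
  dlogits <- (p - targets$y) * mask / 6000
  dec_b <- .dec_backward(params, graph, cfg, enc_out, dec$cache, dlogits)
  enc_g <- .enc_backward(params, graph, cfg, enc_out$cache, dec_b$dHenc,
                         dec_b$dHe)
  grads <- list(node_l1 = enc_g$node_l1, node_ln = enc_g$node_ln,
                node_l2 = enc_g$node_l2, edge_l = enc_g$edge_l,
                edge_ln = enc_g$edge_ln,
                tok_embed = .tok_embed_grad(dec_b$dS, r_tokens),
                out = dec_b$grads$out,
                enc = enc_g$enc, dec = dec_b$grads$dec)
  list(loss_sum = loss_sum, grads = grads)
}

#' Train a toy model on synthetic fixtures
#'
#' Runs the full loss / batching / augmentation stack at reduced scale on
#' CPU: token-budgeted weighted batches, teacher-forced random-order
#' decoding, coordinate noise, the 1/6000-normalized masked cross-entropy,
#' Adam (beta1 0.9, beta2 0.98, eps 1e-9) and gradient-norm clipping at 1.
#' Deterministic under `seed`.
#'
#' @param dataset a `planted_dataset` (or any list of `nuc_complex` in
#'   `$complexes`).
#' @param cfg model configuration.
#' @param steps optimizer steps.
#' @param lr Adam learning rate.
#' @param budget token budget per batch (toy scale defaults to 24).
#' @param noise_sigma training-time coordinate noise (default 0.1 Angstrom).
#' @param seed master seed for batching, noise, and decode orders.
#' @param target_recovery stop early once training-set sequence recovery
#'   reaches this value (`NULL` disables; recovery is checked every
#'   `check_every` steps).
#' @param check_every recovery check interval.
#' @return List with `model`, `losses`, `grad_norms` (post-clip gradient
#'   norms), `recovery` (last measured training recovery or `NA`), `steps_run`.
#' @export
train_toy <- function(dataset, cfg = model_config(hidden_dim = 64,
                                                  n_encoder_layers = 2,
                                                  n_decoder_layers = 2),
                      steps = 500, lr = 2e-3, budget = 24, noise_sigma = 0.1,
                      seed = 1, target_recovery = NULL, check_every = 25) {
  complexes <- dataset$complexes
  targets <- lapply(complexes, build_design_targets)
  examples <- lapply(complexes, function(cx)
    list(tokens = n_residues(cx), weight = 1))
  model <- init_model(cfg)
  opt <- adam_init(model$params, lr = lr)
  losses <- numeric(0)
  grad_norms <- numeric(0)
  recovery <- NA_real_
  steps_run <- 0L
  for (step in seq_len(steps)) {
    bseed <- derive_seed(seed, step)
    batch <- assemble_batches(examples, budget = budget, n_batches = 1,
                              seed = bseed)
    idx <- if (length(batch)) batch[[1]] else integer(0)
    if (!length(idx)) next
    total <- 0
    gacc <- NULL
    for (j in seq_along(idx)) {
      e <- idx[j]
      g <- build_graph(complexes[[e]], k = cfg$k_neighbors,
                       noise_sigma = noise_sigma,
                       seed = derive_seed(bseed, j), n_rbf = cfg$n_rbf)
      out <- .example_loss_grads(model, g, targets[[e]],
                                 order_seed = derive_seed(bseed, 1000 + j),
                                 train = FALSE)
      total <- total + out$loss_sum
      gacc <- if (is.null(gacc)) out$grads else tree_add(gacc, out$grads)
    }
    loss <- total / 6000
    if (!is.finite(loss))
      stop("training diverged: non-finite loss at step ", step)
    cl <- clip_grad_norm(gacc, 1)
    upd <- adam_step(model$params, cl$grads, opt)
    model$params <- upd$params
    opt <- upd$state
    losses <- c(losses, loss)
    grad_norms <- c(grad_norms, min(cl$norm, 1))
    steps_run <- step
    if (!is.null(target_recovery) && step %% check_every == 0) {
      recovery <- evaluate_recovery(model, dataset, seed = derive_seed(seed, -step))
      if (recovery >= target_recovery) break
    }
  }
  list(model = model, losses = losses, grad_norms = grad_norms,
       recovery = recovery, steps_run = steps_run)
}

#' Training-set sequence recovery of a model on a dataset
#'
#' Designs every existing nucleic position of every complex at a near-zero
#' temperature (per-step argmax) and reports the fraction matching the
#' native base.
#'
#' @param model a `nuc_model`.
#' @param dataset list with `$complexes` and `$sequences` (token vectors).
#' @param temperature sampling temperature (default 1e-3: argmax).
#' @param seed RNG seed for decode orders.
#' @return Fraction of positions recovered.
#' @export
evaluate_recovery <- function(model, dataset, temperature = 1e-3, seed = 1) {
  hits <- 0; tot <- 0
  for (e in seq_along(dataset$complexes)) {
    cx <- dataset$complexes[[e]]
    res <- sample_sequence(model, cx, temperature = temperature,
                           seed = derive_seed(seed, e))
    des <- res$designed
    hits <- hits + sum(res$tokens[des] == dataset$sequences[[e]][des])
    tot <- tot + sum(des)
  }
  hits / tot
}
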