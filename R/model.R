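# Encoder-decoder message-passing network over the unified residue graph,
# with a random-order autoregressive decoder supporting partial fixation.
#
# Messages flow along incoming edges (j -> i for j in kNN(i)) and are
# aggregated by mean over existing neighbors. The decoder mixes neighbor
# representations causally: an already-decoded (or fixed) neighbor exposes
# its decoder state plus its token embedding, a not-yet-decoded neighbor
# exposes its encoder state only.

#' Model configuration
#'
#' @param hidden_dim hidden width (default 128).
#' @param n_encoder_layers,n_decoder_layers encoder/decoder depth (default 3+3).
#' @param k_neighbors neighbors per node (default 32).
#' @param n_rbf radial basis bins per atom pair (default 16).
#' @param dropout dropout fraction applied to residual branches during
#'   training (default 0.1).
#' @param seed parameter-initialization seed.
#' @return A `nuc_model_config` list.
#' @export
model_config <- function(hidden_dim = 128, n_encoder_layers = 3,
                         n_decoder_layers = 3, k_neighbors = 32, n_rbf = 16,
                         dropout = 0.1, seed = 0L) {
  stopifnot(hidden_dim > 0, n_encoder_layers > 0, n_decoder_layers > 0,
            k_neighbors > 0, n_rbf > 0, dropout >= 0, dropout < 1)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 n_encoder_layers = as.integer(n_encoder_layers),
                 n_decoder_layers = as.integer(n_decoder_layers),
                 k_neighbors = as.integer(k_neighbors),
                 n_rbf = as.integer(n_rbf),
                 dropout = dropout, seed = as.integer(seed)),
            class = "nuc_model_config")
}

.edge_feature_dim <- function(cfg) 18L * 18L * cfg$n_rbf + 2L

#' Initialize a model
#'
#' Draws all parameters (Glorot-uniform weights, zero biases, unit
#' layer-norm gains) under the configuration seed.
#'
#' @param cfg a [model_config()].
#' @return A `nuc_model`: list with `cfg` and `params`.
#' @export
init_model <- function(cfg = model_config()) {
  H <- cfg$hidden_dim
  params <- with_seed(cfg$seed, {
    p <- list(
      node_l1 = nn_linear_init(4, H, bias = FALSE),
      node_ln = nn_ln_init(H),
      node_l2 = nn_linear_init(H, H),
      edge_l = nn_linear_init(.edge_feature_dim(cfg), H),
      edge_ln = nn_ln_init(H),
      tok_embed = nn_linear_init(26, H, bias = FALSE),
      out = nn_linear_init(H, 26),
      enc = vector("list", cfg$n_encoder_layers),
      dec = vector("list", cfg$n_decoder_layers))
    for (l in seq_len(cfg$n_encoder_layers))
      p$enc[[l]] <- list(msg = mlp3_init(3 * H, H), ln1 = nn_ln_init(H),
                         ffn = ffn_init(H), ln2 = nn_ln_init(H),
                         emsg = mlp3_init(3 * H, H), lne = nn_ln_init(H))
    for (l in seq_len(cfg$n_decoder_layers))
      p$dec[[l]] <- list(msg = mlp3_init(4 * H, H), ln1 = nn_ln_init(H),
                         ffn = ffn_init(H), ln2 = nn_ln_init(H))
    p
  })
  structure(list(cfg = cfg, params = params), class = "nuc_model")
}

#' @export
print.nuc_model <- function(x, ...) {
  cat("<nuc_model> hidden", x$cfg$hidden_dim, "| layers",
      x$cfg$n_encoder_layers, "+", x$cfg$n_decoder_layers, "| k",
      x$cfg$k_neighbors, "\n")
  invisible(x)
}

# ---- encoder ----------------------------------------------------------------

.enc_forward <- function(params, graph, cfg, train = FALSE) {
  n <- graph$n_nodes
  dst <- graph$edge_index[, 1]; src <- graph$edge_index[, 2]
  cnt <- graph$nbr_count
  cache <- list()
  # node embedding: one-hot -> bias-free linear -> LN -> linear(+bias)
  a1 <- graph$node_onehot %*% params$node_l1$W
  ln_n <- ln_fwd(a1, params$node_ln)
  Hn <- lin_fwd(ln_n$Y, params$node_l2)
  Hn[!graph$node_mask, ] <- 0
  # edge embedding
  ea <- lin_fwd(graph$edge_features, params$edge_l)
  ln_e <- ln_fwd(ea, params$edge_ln)
  He <- ln_e$Y
  cache$embed <- list(a1 = a1, ln_n = ln_n, ea = ea, ln_e = ln_e)
  cache$layers <- vector("list", cfg$n_encoder_layers)
  for (l in seq_len(cfg$n_encoder_layers)) {
    pl <- params$enc[[l]]
    lc <- list(H_in = Hn, E_in = He)
    Min <- cbind(Hn[dst, , drop = FALSE], Hn[src, , drop = FALSE], He)
    m <- mlp3_fwd(Min, pl$msg)
    A <- agg_mean_fwd(m$Y, dst, n, cnt)
    dp1 <- dropout_fwd(A, cfg$dropout, train)
    l1 <- ln_fwd(Hn + dp1$Y, pl$ln1)
    f <- ffn_fwd(l1$Y, pl$ffn)
    dp2 <- dropout_fwd(f$Y, cfg$dropout, train)
    l2 <- ln_fwd(l1$Y + dp2$Y, pl$ln2)
    Hn2 <- l2$Y
    Hn2[!graph$node_mask, ] <- 0
    Ein <- cbind(Hn2[dst, , drop = FALSE], Hn2[src, , drop = FALSE], He)
    em <- mlp3_fwd(Ein, pl$emsg)
    dpe <- dropout_fwd(em$Y, cfg$dropout, train)
    le <- ln_fwd(He + dpe$Y, pl$lne)
    lc <- c(lc, list(m = m, dp1 = dp1, l1 = l1, f = f, dp2 = dp2, l2 = l2,
                     em = em, dpe = dpe, le = le))
    cache$layers[[l]] <- lc
    Hn <- Hn2
    He <- le$Y
  }
  list(node_h = Hn, edge_h = He, cache = cache)
}

# backward through the encoder given gradients on final node/edge states
.enc_backward <- function(params, graph, cfg, cache, dHn, dHe) {
  n <- graph$n_nodes
  dst <- graph$edge_index[, 1]; src <- graph$edge_index[, 2]
  cnt <- graph$nbr_count
  g <- list(enc = vector("list", cfg$n_encoder_layers))
  for (l in rev(seq_len(cfg$n_encoder_layers))) {
    pl <- params$enc[[l]]
    lc <- cache$layers[[l]]
    # edge update backward
    ble <- ln_bwd(dHe, lc$le, pl$lne)
    dHe_res <- ble$dX
    dem <- dropout_bwd(dHe_res, lc$dpe$mask)
    bem <- mlp3_bwd(dem, lc$em, pl$emsg)
    H <- cfg$hidden_dim
    dHn2 <- dHn
    dHn2_e <- bem$dX[, 1:H, drop = FALSE]
    dHn2_src <- bem$dX[, (H + 1):(2 * H), drop = FALSE]
    dHe_in_e <- bem$dX[, (2 * H + 1):(3 * H), drop = FALSE]
    # scatter edge-side node grads back to nodes
    dHn2 <- dHn2 + rowsum_pad(dHn2_e, dst, n) + rowsum_pad(dHn2_src, src, n)
    dHn2[!graph$node_mask, ] <- 0
    dHe_acc <- dHe_res + dHe_in_e
    # node track backward
    bl2 <- ln_bwd(dHn2, lc$l2, pl$ln2)
    dff <- dropout_bwd(bl2$dX, lc$dp2$mask)
    bf <- ffn_bwd(dff, lc$f, pl$ffn)
    dl1 <- bl2$dX + bf$dX
    bl1 <- ln_bwd(dl1, lc$l1, pl$ln1)
    dA <- dropout_bwd(bl1$dX, lc$dp1$mask)
    dM <- agg_mean_bwd(dA, dst, cnt)
    bm <- mlp3_bwd(dM, lc$m, pl$msg)
    dHn_in <- bl1$dX +
      rowsum_pad(bm$dX[, 1:H, drop = FALSE], dst, n) +
      rowsum_pad(bm$dX[, (H + 1):(2 * H), drop = FALSE], src, n)
    dHe_in <- dHe_acc + bm$dX[, (2 * H + 1):(3 * H), drop = FALSE]
    g$enc[[l]] <- list(msg = bm$grad, ln1 = bl1$grad, ffn = bf$grad,
                       ln2 = bl2$grad, emsg = bem$grad, lne = ble$grad)
    dHn <- dHn_in
    dHe <- dHe_in
  }
  # embeddings backward
  emb <- cache$embed
  ble0 <- ln_bwd(dHe, emb$ln_e, params$edge_ln)
  bel <- lin_bwd(ble0$dX, graph$edge_features, params$edge_l, need_dx = FALSE)
  dHn[!graph$node_mask, ] <- 0
  bn2 <- lin_bwd(dHn, emb$ln_n$Y, params$node_l2)
  bln <- ln_bwd(bn2$dX, emb$ln_n, params$node_ln)
  bn1 <- lin_bwd(bln$dX, graph$node_onehot, params$node_l1, need_dx = FALSE)
  g$node_l1 <- bn1$grad
  g$node_ln <- bln$grad
  g$node_l2 <- bn2$grad
  g$edge_l <- bel$grad
  g$edge_ln <- ble0$grad
  g
}

rowsum_pad <- function(M, group, n) {
  out <- matrix(0, n, ncol(M))
  if (nrow(M)) {
    rs <- rowsum(M, group)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}

#' Run the encoder
#'
#' @param model a `nuc_model`.
#' @param graph a `nuc_graph` from [build_graph()].
#' @param train enable dropout.
#' @return List with `node_h` (N x H), `edge_h` (E x H) and a forward cache.
#' @export
encode <- function(model, graph, train = FALSE) {
  .enc_forward(model$params, graph, model$cfg, train = train)
}

# ---- decoder ----------------------------------------------------------------

# ranks: numeric vector; fixed context = 0, decoded free positions get their
# 1-based position in the decoding order, undecoded = Inf.
.dec_forward <- function(params, graph, cfg, enc_out, tokens_ctx, ranks,
                         train = FALSE) {
  n <- graph$n_nodes
  dst <- graph$edge_index[, 1]; src <- graph$edge_index[, 2]
  cnt <- graph$nbr_count
  H <- cfg$hidden_dim
  Henc <- enc_out$node_h
  He <- enc_out$edge_h
  tok <- tokens_ctx
  S <- matrix(0, n, H)
  known <- !is.na(tok)
  if (any(known)) S[known, ] <- params$tok_embed$W[tok[known], , drop = FALSE]
  vis <- as.numeric(ranks[src] < ranks[dst] & known[src] & graph$node_mask[src])
  cache <- list(S = S, vis = vis, known = known, layers = vector("list", cfg$n_decoder_layers))
  Hd <- Henc
  for (l in seq_len(cfg$n_decoder_layers)) {
    pl <- params$dec[[l]]
    U <- vis * Hd[src, , drop = FALSE] + (1 - vis) * Henc[src, , drop = FALSE]
    Min <- cbind(Hd[dst, , drop = FALSE], U, He, vis * S[src, , drop = FALSE])
    m <- mlp3_fwd(Min, pl$msg)
    A <- agg_mean_fwd(m$Y, dst, n, cnt)
    dp1 <- dropout_fwd(A, cfg$dropout, train)
    l1 <- ln_fwd(Hd + dp1$Y, pl$ln1)
    f <- ffn_fwd(l1$Y, pl$ffn)
    dp2 <- dropout_fwd(f$Y, cfg$dropout, train)
    l2 <- ln_fwd(l1$Y + dp2$Y, pl$ln2)
    cache$layers[[l]] <- list(H_in = Hd, m = m, dp1 = dp1, l1 = l1, f = f,
                              dp2 = dp2, l2 = l2)
    Hd <- l2$Y
    Hd[!graph$node_mask, ] <- 0
  }
  logits <- lin_fwd(Hd, params$out)
  cache$Hd_final <- Hd
  list(logits = logits, cache = cache)
}

.dec_backward <- function(params, graph, cfg, enc_out, cache, dlogits) {
  n <- graph$n_nodes
  dst <- graph$edge_index[, 1]; src <- graph$edge_index[, 2]
  cnt <- graph$nbr_count
  H <- cfg$hidden_dim
  Henc <- enc_out$node_h
  vis <- cache$vis
  S <- cache$S
  bout <- lin_bwd(dlogits, cache$Hd_final, params$out)
  dHd <- bout$dX
  dHenc <- matrix(0, n, H)
  dHe <- matrix(0, nrow(graph$edge_index), H)
  dS <- matrix(0, n, H)
  g <- list(dec = vector("list", cfg$n_decoder_layers), out = bout$grad)
  for (l in rev(seq_len(cfg$n_decoder_layers))) {
    pl <- params$dec[[l]]
    lc <- cache$layers[[l]]
    dHd[!graph$node_mask, ] <- 0
    bl2 <- ln_bwd(dHd, lc$l2, pl$ln2)
    dff <- dropout_bwd(bl2$dX, lc$dp2$mask)
    bf <- ffn_bwd(dff, lc$f, pl$ffn)
    dl1 <- bl2$dX + bf$dX
    bl1 <- ln_bwd(dl1, lc$l1, pl$ln1)
    dA <- dropout_bwd(bl1$dX, lc$dp1$mask)
    dM <- agg_mean_bwd(dA, dst, cnt)
    bm <- mlp3_bwd(dM, lc$m, pl$msg)
    dHd_in <- bl1$dX + rowsum_pad(bm$dX[, 1:H, drop = FALSE], dst, n)
    dU <- bm$dX[, (H + 1):(2 * H), drop = FALSE]
    dHe <- dHe + bm$dX[, (2 * H + 1):(3 * H), drop = FALSE]
    dSv <- bm$dX[, (3 * H + 1):(4 * H), drop = FALSE]
    dS <- dS + rowsum_pad(vis * dSv, src, n)
    dHd_in <- dHd_in + rowsum_pad(vis * dU, src, n)
    dHenc <- dHenc + rowsum_pad((1 - vis) * dU, src, n)
    g$dec[[l]] <- list(msg = bm$grad, ln1 = bl1$grad, ffn = bf$grad,
                       ln2 = bl2$grad)
    dHd <- dHd_in
  }
  dHenc <- dHenc + dHd  # initial decoder state was the encoder state
  list(grads = g, dHenc = dHenc, dHe = dHe, dS = dS)
}

.tok_embed_grad <- function(dS, tokens_ctx) {
  dW <- matrix(0, 26, ncol(dS))
  known <- which(!is.na(tokens_ctx))
  for (i in known) dW[tokens_ctx[i], ] <- dW[tokens_ctx[i], ] + dS[i, ]
  list(W = dW)
}

#' Conditional logits under a decoding order
#'
#' Teacher-forced decoder pass: the logits at each position depend only on
#' the structure, on fixed tokens, and on context tokens earlier in the
#' decoding order. `seq_context` supplies tokens; `NA` marks positions with
#' no sequence information.
#'
#' @param model a `nuc_model`.
#' @param graph a `nuc_graph`.
#' @param enc_out output of [encode()]; recomputed when `NULL`.
#' @param seq_context integer token vector (length N) with `NA` for unknown.
#' @param order integer vector of residue indices in decoding order; these
#'   positions are causally masked. Positions not in `order` with a token are
#'   fixed context (visible to everyone).
#' @return N x 26 logits matrix.
#' @export
decode_logits <- function(model, graph, seq_context, order,
                          enc_out = NULL) {
  if (any(!is.na(seq_context) & (seq_context < 1 | seq_context > 26)))
    stop("context token outside the 26-token alphabet")
  if (is.null(enc_out)) enc_out <- encode(model, graph)
  ranks <- rep(0, graph$n_nodes)
  ranks[is.na(seq_context)] <- Inf
  ranks[order] <- seq_along(order)
  out <- .dec_forward(model$params, graph, model$cfg, enc_out, seq_context,
                      ranks, train = FALSE)
  out$logits
}

# ---- sampling ----------------------------------------------------------------

.canonical_na_probs <- function(logit_row, temperature) {
  z <- logit_row[.TOK_NA_CANONICAL] / temperature
  z <- z - max(z)
  p <- exp(z)
  p / sum(p)
}

#' Sample nucleic acid sequences for a fixed backbone
#'
#' Free positions are decoded autoregressively in a uniformly random order;
#' at each step the 26-way logits are restricted to the four canonical
#' nucleic tokens and renormalized at the given temperature. Fixed positions
#' (everything outside `design_mask`, including all protein residues) echo
#' their input tokens and act as visible context.
#'
#' @param model a `nuc_model`.
#' @param complex a `nuc_complex`.
#' @param design_mask logical per-residue vector selecting positions to
#'   design; must select only existing nucleic residues. Default: all
#'   existing nucleic residues.
#' @param temperature sampling temperature (> 0; design default 0.1).
#' @param seed RNG seed governing both the decoding order and the sampling.
#' @param graph optionally, a prebuilt `nuc_graph`.
#' @return List with `tokens` (full per-residue token vector), `probs`
#'   (N x 4 canonical base probabilities used at each designed position's own
#'   decode step; NA rows elsewhere), `order`, and `designed` (logical).
#' @export
sample_sequence <- function(model, complex, design_mask = NULL,
                            temperature = 0.1, seed = NULL, graph = NULL) {
  r <- complex$residues
  n <- nrow(r)
  is_nuc <- r$polymer_class %in% c("DNA", "RNA")
  if (is.null(design_mask)) design_mask <- is_nuc & r$exists
  stopifnot(length(design_mask) == n, temperature > 0)
  if (any(design_mask & !is_nuc))
    stop("design_mask selects a protein residue; protein design is unsupported")
  if (any(design_mask & !r$exists))
    stop("design_mask selects a residue with missing backbone atoms")
  if (is.null(graph))
    graph <- build_graph(complex, k = model$cfg$k_neighbors,
                         n_rbf = model$cfg$n_rbf)
  enc_out <- encode(model, graph)
  tok <- r$token
  tok[design_mask] <- NA_integer_
  probs <- matrix(NA_real_, n, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  free <- which(design_mask)
  with_seed(seed, {
    order_free <- if (length(free)) sample(free) else integer(0)
    ranks <- rep(0, n)
    ranks[free] <- Inf
    for (t in seq_along(order_free)) {
      p_t <- order_free[t]
      out <- .dec_forward(model$params, graph, model$cfg, enc_out, tok, ranks)
      pr <- .canonical_na_probs(out$logits[p_t, ], temperature)
      choice <- sample.int(4, 1, prob = pr)
      tok[p_t] <- .TOK_NA_CANONICAL[choice]
      ranks[p_t] <- t
      probs[p_t, ] <- pr
    }
  })
  list(tokens = tok, probs = probs, order = if (length(free)) order_free else integer(0),
       designed = design_mask)
}

#' Predict a position probability matrix for the DNA of a complex
#'
#' Fixed-dock specificity inference: the DNA sequence is removed from the
#' model input (protein sequence/backbone and DNA backbone retained), random
#' autoregressive decoding is performed `n_samples` times at the given
#' temperature, and the canonical-base conditional probabilities recorded at
#' each position's own decode step are averaged into a predicted PPM.
#'
#' @param model a `nuc_model`.
#' @param complex a `nuc_complex` containing at least one DNA chain.
#' @param n_samples decoding runs (default 30).
#' @param temperature sampling temperature (default 0.6).
#' @param seed RNG seed.
#' @return Named list of `ppm` objects, one per DNA chain (rows = designed
#'   positions in residue order; every row sums to 1), with attribute
#'   `res_index` mapping rows to residue indices.
#' @export
predict_ppm <- function(model, complex, n_samples = 30, temperature = 0.6,
                        seed = NULL) {
  r <- complex$residues
  is_dna <- r$polymer_class == "DNA"
  if (!any(is_dna)) stop("complex contains no DNA chain")
  design_mask <- is_dna & r$exists
  graph <- build_graph(complex, k = model$cfg$k_neighbors,
                       n_rbf = model$cfg$n_rbf)
  acc <- matrix(0, nrow(r), 4)
  for (s in seq_len(n_samples)) {
    res <- sample_sequence(model, complex, design_mask,
                           temperature = temperature,
                           seed = if (is.null(seed)) NULL
                                  else derive_seed(seed, s),
                           graph = graph)
    acc[design_mask, ] <- acc[design_mask, ] + res$probs[design_mask, ]
  }
  acc <- acc / n_samples
  out <- list()
  for (cid in unique(r$chain_id[design_mask])) {
    rows <- which(design_mask & r$chain_id == cid)
    rows <- rows[order(r$res_index[rows])]
    m <- acc[rows, , drop = FALSE]
    colnames(m) <- c("A", "C", "G", "T")
    p <- new_ppm(m, source_id = paste0("predicted:", cid),
                 group_id = "predicted")
    attr(p, "res_index") <- r$res_index[rows]
    out[[cid]] <- p
  }
  out
}

# ---- persistence -------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Versioned parameter archive with the configuration embedded.
#'
#' @param model a `nuc_model`.
#' @param path file path (.rds).
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "nucmpnn-checkpoint", version = 1L,
               cfg = model$cfg, params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "nucmpnn-checkpoint"))
    stop("not a model checkpoint: ", path)
  structure(list(cfg = x$cfg, params = x$params), class = "nuc_model")
}

#' Write sequences as FASTA
#'
#' Nucleic tokens are spelled with T on DNA chains and U on RNA chains.
#'
#' @param sequences named character vector (names become record ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(sequences)) {
    writeLines(paste0(">", nm), con)
    writeLines(sequences[[nm]], con)
  }
  invisible(path)
}

#' Spell a complex's designed tokens as per-chain sequences
#' @param complex a `nuc_complex`.
#' @param tokens full per-residue token vector (e.g. from [sample_sequence()]).
#' @return Named character vector, one sequence per nucleic chain.
#' @export
tokens_to_sequences <- function(complex, tokens) {
  r <- complex$residues
  out <- character(0)
  for (cid in unique(r$chain_id)) {
    rows <- which(r$chain_id == cid)
    cls <- r$polymer_class[rows[1]]
    if (!cls %in% c("DNA", "RNA")) next
    rows <- rows[order(r$res_index[rows])]
    out[cid] <- paste(token_to_base(tokens[rows], cls), collapse = "")
  }
  out
}
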