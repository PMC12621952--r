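# Shared fixtures and small utilities for the test suite.

# tiny model configuration used by most model tests (fast on CPU)
tiny_cfg <- function(seed = 3L, hidden = 16L) {
  model_config(hidden_dim = hidden, n_encoder_layers = 2,
               n_decoder_layers = 2, n_rbf = 4, dropout = 0, seed = seed)
}

tiny_model <- function(seed = 3L, hidden = 16L) init_model(tiny_cfg(seed, hidden))

# apply a rigid motion (rotation R, translation t) to every atom
transform_complex <- function(complex, R = diag(3), t = c(0, 0, 0)) {
  a <- complex$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + t[1]
  a$y <- xyz[, 2] + t[2]
  a$z <- xyz[, 3] + t[3]
  a$is_sidechain <- NULL
  new_complex(a, resolution = complex$resolution, meta = complex$meta)
}

# rebuild a complex with its chains concatenated in reverse order
swap_chain_order <- function(complex) {
  a <- complex$atoms
  a$is_sidechain <- NULL
  cids <- unique(a$chain_id)
  parts <- lapply(rev(cids), function(cid) a[a$chain_id == cid, ])
  new_complex(do.call(rbind, parts), resolution = complex$resolution,
              meta = complex$meta)
}

# turn one residue of a complex into an unknown (non-canonical) base
mark_unknown_base <- function(complex, chain_id, res_index) {
  sel <- complex$residues$chain_id == chain_id &
    complex$residues$res_index == res_index
  complex$residues$token[sel] <- 26L
  complex$residues$res_name[sel] <- "XNA"
  complex
}

# brute-force all-pairs side-chain interface mask (oracle)
brute_interface_mask <- function(complex, cutoff = 5) {
  r <- complex$residues
  a <- complex$atoms[complex$atoms$is_sidechain, ]
  flag <- rep(FALSE, nrow(r))
  # exclude residues lacking their representative atom, as the mask does
  has_rep <- !is.na(representative_coords_test(complex)[, 1])
  for (i in seq_len(nrow(r))) {
    if (!has_rep[i]) next
    ai <- a[a$chain_id == r$chain_id[i] & a$res_index == r$res_index[i], ]
    if (!nrow(ai)) next
    for (j in seq_len(nrow(r))) {
      if (!has_rep[j]) next
      pi_ <- r$polymer_class[i]; pj_ <- r$polymer_class[j]
      opp <- (pi_ == "protein" && pj_ %in% c("DNA", "RNA")) ||
        (pi_ %in% c("DNA", "RNA") && pj_ == "protein")
      if (!opp) next
      aj <- a[a$chain_id == r$chain_id[j] & a$res_index == r$res_index[j], ]
      if (!nrow(aj)) next
      dmin <- sqrt(max(0, min(outer(rowSums(ai[, c("x", "y", "z")]^2),
                                    rowSums(aj[, c("x", "y", "z")]^2), "+") -
                                2 * as.matrix(ai[, c("x", "y", "z")]) %*%
                                  t(as.matrix(aj[, c("x", "y", "z")])))))
      if (dmin <= cutoff) { flag[i] <- TRUE; break }
    }
  }
  flag
}

representative_coords_test <- function(complex) {
  r <- complex$residues
  t(vapply(seq_len(nrow(r)), function(i) {
    nm <- if (r$polymer_class[i] == "protein") "CA" else "C1'"
    v <- get_atom_coord(complex, r$chain_id[i], r$res_index[i], nm)
    if (is.null(v)) rep(NA_real_, 3) else v
  }, numeric(3)))
}

# independent scalar-loop cross-entropy loss oracle
loss_oracle <- function(logits_list, targets_list) {
  total <- 0
  for (b in seq_along(logits_list)) {
    lg <- logits_list[[b]]
    y <- targets_list[[b]]$y
    mask <- targets_list[[b]]$mask
    for (i in seq_len(nrow(lg))) {
      if (!mask[i]) next
      p <- exp(lg[i, ] - max(lg[i, ]))
      p <- p / sum(p)
      for (c_ in 1:26) total <- total - y[i, c_] * log(p[c_])
    }
  }
  total / 6000
}

# exhaustive-enumeration alignment oracle (independent double loop)
align_oracle <- function(ppm, chain_tok, min_overlap = 5) {
  out <- list()
  for (orient in c("forward", "reverse_complement")) {
    m <- if (orient == "forward") unclass(ppm) else unclass(reverse_complement(ppm))
    L <- nrow(m); N <- length(chain_tok)
    for (off in (-(L - 1)):(N - 1)) {
      scores <- numeric(0); poss <- integer(0)
      for (row in 1:L) {
        pos <- off + row - 1
        if (pos < 0 || pos >= N) next
        tok <- chain_tok[pos + 1]
        if (is.na(tok) || tok == 26L) next
        oh <- numeric(4); oh[tok - 21L] <- 1
        col <- m[row, ]
        s <- if (stats::sd(col) < 1e-12) 0 else
          0.5 * (sum(log(col)) / log(0.25)) * stats::cor(col, oh)
        scores <- c(scores, s); poss <- c(poss, pos)
      }
      if (length(scores) < min_overlap) next
      out[[length(out) + 1L]] <- list(orientation = orient, offset = off,
                                      score = sum(scores),
                                      positions = poss,
                                      per_position_scores = scores)
    }
  }
  out
}

# independent minimum-RMSD oracle: Horn's closed-form quaternion method
# (optimizes over proper rotations, so it matches the no-reflection
# constraint of the package's SVD-based superposition)
quaternion_rmsd <- function(P, Q) {
  Pc <- scale(P, scale = FALSE); Qc <- scale(Q, scale = FALSE)
  S <- crossprod(Pc, Qc)
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],       S[3,1]-S[1,3],       S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],       S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  sqrt(max(0, sum(Pc^2) + sum(Qc^2) - 2 * lam) / nrow(P))
}

# random nucleic token chain with unknowns
random_chain_tokens <- function(n, p_unknown = 0.15) {
  toks <- sample(22:25, n, replace = TRUE)
  unk <- stats::runif(n) < p_unknown
  toks[unk] <- 26L
  toks
}
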