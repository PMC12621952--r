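# Minimal dense-layer toolkit with hand-written reverse-mode gradients.
# Everything operates on plain matrices; parameters live in nested lists.

nn_linear_init <- function(n_in, n_out, bias = TRUE) {
  s <- sqrt(6 / (n_in + n_out))
  W <- matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
  if (bias) list(W = W, b = rep(0, n_out)) else list(W = W)
}

nn_ln_init <- function(h) list(g = rep(1, h), b = rep(0, h))

lin_fwd <- function(X, p) {
  Y <- X %*% p$W
  if (!is.null(p$b)) Y <- sweep(Y, 2, p$b, "+")
  Y
}

# returns list(dX, grad = list(W, b))
lin_bwd <- function(dY, X, p, need_dx = TRUE) {
  g <- list(W = crossprod(X, dY))
  if (!is.null(p$b)) g$b <- colSums(dY)
  dX <- if (need_dx) dY %*% t(p$W) else NULL
  list(dX = dX, grad = g)
}

relu <- function(X) X * (X > 0)
relu_bwd <- function(dY, X) dY * (X > 0)

ln_fwd <- function(X, p, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- sweep(sweep(xhat, 2, p$g, "*"), 2, p$b, "+")
  list(Y = Y, xhat = xhat, inv = inv)
}

ln_bwd <- function(dY, cache, p) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2, p$g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dX = dX,
       grad = list(g = colSums(dY * xhat), b = colSums(dY)))
}

dropout_fwd <- function(X, p, train) {
  if (!train || p <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix(stats::rbinom(length(X), 1, 1 - p), nrow(X)) / (1 - p)
  list(Y = X * mask, mask = mask)
}

dropout_bwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask

# mean-aggregation of edge rows onto destination nodes
agg_mean_fwd <- function(M, dst, n, cnt) {
  A <- matrix(0, n, ncol(M))
  if (nrow(M)) {
    rs <- rowsum(M, dst)
    A[as.integer(rownames(rs)), ] <- rs
  }
  A / pmax(cnt, 1)
}

agg_mean_bwd <- function(dA, dst, cnt) {
  dAn <- dA / pmax(cnt, 1)
  dAn[dst, , drop = FALSE]
}

# three-layer message MLP (ReLU-ReLU-linear)
mlp3_init <- function(n_in, h) {
  list(l1 = nn_linear_init(n_in, h), l2 = nn_linear_init(h, h),
       l3 = nn_linear_init(h, h))
}

mlp3_fwd <- function(X, p) {
  a1 <- lin_fwd(X, p$l1); r1 <- relu(a1)
  a2 <- lin_fwd(r1, p$l2); r2 <- relu(a2)
  y <- lin_fwd(r2, p$l3)
  list(Y = y, X = X, a1 = a1, r1 = r1, a2 = a2, r2 = r2)
}

mlp3_bwd <- function(dY, cache, p, need_dx = TRUE) {
  b3 <- lin_bwd(dY, cache$r2, p$l3)
  d2 <- relu_bwd(b3$dX, cache$a2)
  b2 <- lin_bwd(d2, cache$r1, p$l2)
  d1 <- relu_bwd(b2$dX, cache$a1)
  b1 <- lin_bwd(d1, cache$X, p$l1, need_dx = need_dx)
  list(dX = b1$dX, grad = list(l1 = b1$grad, l2 = b2$grad, l3 = b3$grad))
}

# two-layer position-wise feed-forward
ffn_init <- function(h) list(l1 = nn_linear_init(h, 4 * h),
                             l2 = nn_linear_init(4 * h, h))

ffn_fwd <- function(X, p) {
  a1 <- lin_fwd(X, p$l1); r1 <- relu(a1)
  list(Y = lin_fwd(r1, p$l2), X = X, a1 = a1, r1 = r1)
}

ffn_bwd <- function(dY, cache, p) {
  b2 <- lin_bwd(dY, cache$r1, p$l2)
  d1 <- relu_bwd(b2$dX, cache$a1)
  b1 <- lin_bwd(d1, cache$X, p$l1)
  list(dX = b1$dX, grad = list(l1 = b1$grad, l2 = b2$grad))
}

# ---- parameter-tree utilities ----------------------------------------------

tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.list(t1)) {
    out <- vector("list", length(t1))
    names(out) <- names(t1)
    for (i in seq_along(t1))
      out[[i]] <- do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    out
  } else {
    do.call(f, trees)
  }
}

tree_zero <- function(tree) tree_map(function(x) x * 0, tree)

tree_add <- function(a, b) tree_map(`+`, a, b)

tree_sqnorm <- function(tree) {
  s <- 0
  rec <- function(t) {
    if (is.list(t)) lapply(t, rec) else s <<- s + sum(t * t)
    invisible(NULL)
  }
  rec(tree)
  s
}

#' Clip a gradient tree to a maximum global norm
#' @param grads nested list of numeric arrays.
#' @param max_norm maximum L2 norm (default 1).
#' @return List with `grads` (scaled tree) and `norm` (pre-clip norm).
#' @export
clip_grad_norm <- function(grads, max_norm = 1) {
  nrm <- sqrt(tree_sqnorm(grads))
  if (is.finite(nrm) && nrm > max_norm)
    grads <- tree_map(function(x) x * (max_norm / nrm), grads)
  list(grads = grads, norm = nrm)
}

#' Adam optimizer state
#' @param params parameter tree.
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam moments and stabilizer (defaults 0.9, 0.98,
#'   1e-9, the values used for training).
#' @return An optimizer state list.
#' @export
adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.98,
                      eps = 1e-9) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L,
       lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

#' One Adam update
#' @param params parameter tree.
#' @param grads matching gradient tree.
#' @param state state from [adam_init()].
#' @return List with updated `params` and `state`.
#' @export
adam_step <- function(params, grads, state) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) state$beta1 * m + (1 - state$beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) state$beta2 * v + (1 - state$beta2) * g * g,
                      state$v, grads)
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  params <- tree_map(function(p, m, v)
    p - state$lr * (m / bc1) / (sqrt(v / bc2) + state$eps),
    params, state$m, state$v)
  list(params = params, state = state)
}
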