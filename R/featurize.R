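# Unified residue graph: virtual atoms, k-nearest-neighbor topology, RBF
# distance edge features with existence masking, polymer-type node features,
# and training-time coordinate noise.

#' The 18 unified backbone atom slots
#'
#' Fixed ordered slot list shared by all polymer classes. Protein residues
#' populate N, CA, C, O and the virtual C-beta; DNA populates the phosphate
#' and sugar slots (all nucleic slots except O2'); RNA adds O2'. Both classes
#' get a virtual first side-chain atom (CBv for protein, Nv for nucleic).
#'
#' @return Character vector of length 18.
#' @export
backbone_slots <- function() {
  c("N", "CA", "C", "O", "CBv", "P", "OP1", "OP2", "O5'", "C5'", "C4'",
    "O4'", "C3'", "O3'", "C2'", "O2'", "C1'", "Nv")
}

.SLOTS <- c("N", "CA", "C", "O", "CBv", "P", "OP1", "OP2", "O5'", "C5'",
            "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'", "Nv")
.N_SLOTS <- 18L

#' Virtual C-beta position from backbone N, CA, C
#'
#' Ideal C-beta constructed from the local backbone frame with the
#' ProteinMPNN constants: with b = CA - N, c = C - CA, a = b x c,
#' CBv = -0.58273431 a + 0.56802827 b - 0.54067466 c + CA.
#'
#' @param n,ca,c backbone atom coordinates (length-3).
#' @return Length-3 coordinate. For degenerate (collinear) input the cross
#'   product vanishes; the function falls back to CA plus a unit offset and
#'   warns.
#' @export
virtual_cb <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- crossprod3(b, cc)
  if (vnorm(a) < 1e-8) {
    warning("collinear N/CA/C; virtual C-beta degenerate, using fallback")
    return(ca + c(1, 0, 0))
  }
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
}

#' Virtual nucleic side-chain nitrogen from the sugar atoms
#'
#' Placed 1.48 Angstrom from C1' along the bisector of the O4'-C1'-C2' angle,
#' pointing away from the sugar (toward the base): Nv = C1' +
#' 1.48 unit(2 C1' - O4' - C2').
#'
#' @param c1p,o4p,c2p sugar atom coordinates (length-3).
#' @return Length-3 coordinate.
#' @export
virtual_na_n <- function(c1p, o4p, c2p) {
  d <- 2 * c1p - o4p - c2p
  if (vnorm(d) < 1e-8) stop("degenerate sugar geometry: zero-length bisector")
  c1p + 1.48 * unit(d)
}

#' Gaussian radial basis expansion of a distance
#'
#' `n_rbf` Gaussian bins with centers uniformly spaced on \[2, 22\] Angstrom
#' and width equal to the bin spacing.
#'
#' @param d numeric vector of distances (Angstrom).
#' @param n_rbf number of bins (default 16).
#' @return `length(d) x n_rbf` matrix.
#' @export
rbf_expand <- function(d, n_rbf = 16) {
  mu <- seq(2, 22, length.out = n_rbf)
  sigma <- (22 - 2) / (n_rbf - 1)
  exp(-((matrix(d, length(d), n_rbf) -
           matrix(mu, length(d), n_rbf, byrow = TRUE)) / sigma)^2)
}

#' Training-time coordinate noise
#'
#' Adds i.i.d. isotropic Gaussian noise (per-coordinate standard deviation
#' `sigma`) to every atom coordinate; the training augmentation uses
#' `sigma = 0.1` Angstrom. Reproducible under `seed`.
#'
#' @param xyz N x 3 coordinate matrix.
#' @param sigma per-coordinate noise s.d. in Angstrom.
#' @param seed RNG seed.
#' @return Noised N x 3 matrix.
#' @export
apply_coordinate_noise <- function(xyz, sigma, seed = NULL) {
  if (sigma <= 0) return(xyz)
  xyz + with_seed(seed, matrix(stats::rnorm(length(xyz), sd = sigma),
                               nrow(xyz), 3))
}

# per-residue 18-slot coordinate/presence arrays
.slot_coords <- function(complex, noise_sigma = 0, seed = NULL) {
  r <- complex$residues
  a <- complex$atoms
  n <- nrow(r)
  ax <- as.matrix(a[, c("x", "y", "z")])
  if (noise_sigma > 0) ax <- apply_coordinate_noise(ax, noise_sigma, seed)
  X <- array(0, dim = c(n, .N_SLOTS, 3))
  P <- matrix(FALSE, n, .N_SLOTS)
  akey <- paste(a$chain_id, a$res_index, a$elety, sep = "\r")
  for (s in seq_len(.N_SLOTS)) {
    nm <- .SLOTS[s]
    if (nm %in% c("CBv", "Nv")) next
    m <- match(paste(r$chain_id, r$res_index, nm, sep = "\r"), akey)
    hit <- !is.na(m)
    P[hit, s] <- TRUE
    X[hit, s, ] <- ax[m[hit], , drop = FALSE]
  }
  s_cb <- match("CBv", .SLOTS); s_nv <- match("Nv", .SLOTS)
  for (i in seq_len(n)) {
    if (r$polymer_class[i] == "protein") {
      if (all(P[i, match(c("N", "CA", "C"), .SLOTS)])) {
        X[i, s_cb, ] <- virtual_cb(X[i, 1, ], X[i, 2, ], X[i, 3, ])
        P[i, s_cb] <- TRUE
      }
    } else {
      ic1 <- match("C1'", .SLOTS); io4 <- match("O4'", .SLOTS)
      ic2 <- match("C2'", .SLOTS)
      if (all(P[i, c(ic1, io4, ic2)])) {
        X[i, s_nv, ] <- virtual_na_n(X[i, ic1, ], X[i, io4, ], X[i, ic2, ])
        P[i, s_nv] <- TRUE
      }
    }
  }
  list(X = X, present = P)
}

.polymer_onehot <- function(polymer_class) {
  classes <- c("protein", "DNA", "RNA", "unknown")
  m <- match(polymer_class, classes)
  m[is.na(m)] <- 4L
  oh <- matrix(0, length(polymer_class), 4)
  oh[cbind(seq_along(m), m)] <- 1
  colnames(oh) <- classes
  oh
}

#' Build the residue graph for the network
#'
#' Steps: (1) optional i.i.d. Gaussian coordinate noise (training-time
#' augmentation) applied to every real atom before anything else; (2) virtual
#' atoms built from the (noised) coordinates; (3) k nearest existing residues
#' per node by representative-atom distance (C-alpha / C1'), ties broken by
#' lower residue index, self excluded; (4) per-edge RBF embeddings of all
#' 18 x 18 slot-pair distances, zeroed where either slot is absent, plus two
#' chain-relative features (same-chain flag, clipped signed sequence offset);
#' (5) polymer-type one-hot node features (embedded to the hidden dimension
#' inside the model).
#'
#' @param complex a `nuc_complex`.
#' @param k neighbors per node (default 32; capped at N-1).
#' @param noise_sigma coordinate noise s.d. in Angstrom (0 = off; training
#'   uses 0.1).
#' @param seed RNG seed for the noise.
#' @param n_rbf radial basis bins (default 16).
#' @return A `nuc_graph`: list with `node_onehot` (N x 4), `edge_index`
#'   (E x 2 matrix of (dst, src) residue indices), `edge_features`
#'   (E x (18*18*n_rbf + 2)), `node_mask` (exists flags), `nbr_count`,
#'   `coords`/`present` slot arrays and bookkeeping fields.
#' @export
build_graph <- function(complex, k = 32, noise_sigma = 0, seed = NULL,
                        n_rbf = 16) {
  r <- complex$residues
  n <- nrow(r)
  exists <- r$exists
  if (sum(exists) < 2) stop("graph requires at least 2 existing residues")
  sc <- .slot_coords(complex, noise_sigma = noise_sigma, seed = seed)
  X <- sc$X; P <- sc$present
  # representative atoms: CA for protein, C1' for nucleic
  rep_slot <- ifelse(r$polymer_class == "protein", match("CA", .SLOTS),
                     match("C1'", .SLOTS))
  rep_xyz <- t(vapply(seq_len(n), function(i) X[i, rep_slot[i], ], numeric(3)))
  ok <- exists & P[cbind(seq_len(n), rep_slot)]
  idx_ok <- which(ok)
  keff <- min(k, length(idx_ok) - 1L)
  dst <- integer(0); src <- integer(0)
  D <- as.matrix(stats::dist(rep_xyz[idx_ok, , drop = FALSE]))
  for (ii in seq_along(idx_ok)) {
    o <- order(D[ii, ], idx_ok)  # ties broken by lower residue index
    o <- o[idx_ok[o] != idx_ok[ii]]
    # neighbor order within the list is canonicalized by residue index:
    # aggregation is order-free and this keeps the edge layout stable under
    # rigid motions that perturb tied distances at floating-point level
    nb <- sort(idx_ok[utils::head(o, keff)])
    dst <- c(dst, rep(idx_ok[ii], length(nb)))
    src <- c(src, nb)
  }
  E <- length(dst)
  d_all <- matrix(0, E, .N_SLOTS * .N_SLOTS)
  pair_present <- matrix(FALSE, E, .N_SLOTS * .N_SLOTS)
  for (a_ in seq_len(.N_SLOTS)) {
    for (b_ in seq_len(.N_SLOTS)) {
      col <- (a_ - 1L) * .N_SLOTS + b_
      pres <- P[dst, a_] & P[src, b_]
      pair_present[, col] <- pres
      if (any(pres)) {
        diff <- X[dst[pres], a_, , drop = FALSE] - X[src[pres], b_, , drop = FALSE]
        d_all[pres, col] <- sqrt(rowSums(matrix(diff, sum(pres), 3)^2))
      }
    }
  }
  ef <- matrix(0, E, .N_SLOTS * .N_SLOTS * n_rbf)
  for (col in seq_len(.N_SLOTS * .N_SLOTS)) {
    pres <- pair_present[, col]
    if (!any(pres)) next
    ef[pres, ((col - 1L) * n_rbf + 1L):(col * n_rbf)] <-
      rbf_expand(d_all[pres, col], n_rbf)
  }
  same_chain <- as.numeric(r$chain_id[dst] == r$chain_id[src])
  rel <- ifelse(same_chain > 0, pmax(-32, pmin(32, r$res_index[src] -
                                                 r$res_index[dst])) / 32, 0)
  edge_features <- cbind(ef, same_chain, rel)
  structure(list(
    node_onehot = .polymer_onehot(r$polymer_class),
    edge_index = cbind(dst = dst, src = src),
    edge_features = edge_features,
    node_mask = ok,
    nbr_count = tabulate(dst, nbins = n),
    coords = X, present = P, rep_xyz = rep_xyz,
    n_rbf = n_rbf, k = keff, n_nodes = n,
    tokens = r$token, polymer_class = r$polymer_class,
    chain_id = r$chain_id, res_index = r$res_index),
    class = "nuc_graph")
}

#' @export
print.nuc_graph <- function(x, ...) {
  cat("<nuc_graph>", x$n_nodes, "nodes,", nrow(x$edge_index), "edges, k =",
      x$k, "\n")
  invisible(x)
}

#' Dump a graph as node and edge tables
#'
#' Debug/inspection helper: writes `<prefix>_nodes.tsv` and
#' `<prefix>_edges.tsv`.
#'
#' @param graph a `nuc_graph`.
#' @param prefix output path prefix.
#' @return The two paths, invisibly.
#' @export
dump_graph <- function(graph, prefix) {
  nodes <- data.frame(index = seq_len(graph$n_nodes),
                      chain_id = graph$chain_id,
                      res_index = graph$res_index,
                      polymer_class = graph$polymer_class,
                      exists = graph$node_mask,
                      nbr_count = graph$nbr_count)
  edges <- data.frame(dst = graph$edge_index[, 1], src = graph$edge_index[, 2],
                      dist = sqrt(rowSums((graph$rep_xyz[graph$edge_index[, 1], ,
                                                         drop = FALSE] -
                                             graph$rep_xyz[graph$edge_index[, 2], ,
                                                           drop = FALSE])^2)))
  np <- paste0(prefix, "_nodes.tsv"); ep <- paste0(prefix, "_edges.tsv")
  utils::write.table(nodes, np, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(edges, ep, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(np, ep))
}
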