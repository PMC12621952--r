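# Evaluation metrics: sequence recovery, PPM comparison (MAE and
# cross-entropy over the four bases), and C1'-RMSD with least-squares rigid
# superposition and overlap cropping.

#' Sequence recovery over designed positions
#'
#' The fraction of designed positions whose identity matches the native
#' residue.
#'
#' @param true_seq,designed_seq equal-length token (or letter) vectors.
#' @param designed_mask logical vector marking designed positions; default
#'   all.
#' @return Fraction in \[0, 1\].
#' @export
sequence_recovery <- function(true_seq, designed_seq,
                              designed_mask = rep(TRUE, length(true_seq))) {
  stopifnot(length(true_seq) == length(designed_seq),
            length(designed_mask) == length(true_seq))
  n <- sum(designed_mask)
  if (n == 0) stop("undefined metric: no designed positions")
  sum(true_seq[designed_mask] == designed_seq[designed_mask]) / n
}

.check_windows <- function(true_ppm, pred_ppm) {
  t_ <- as.matrix(unclass(true_ppm)); p_ <- as.matrix(unclass(pred_ppm))
  stopifnot(ncol(t_) == 4, ncol(p_) == 4)
  if (nrow(t_) != nrow(p_)) stop("PPM windows differ in length")
  if (nrow(t_) == 0) stop("undefined metric: empty PPM window")
  list(t = t_, p = p_)
}

#' Mean absolute error between aligned PPM windows
#'
#' Mean over positions of the L1 distance over the four bases (range
#' \[0, 2\] for probability rows).
#'
#' @param true_ppm,pred_ppm L x 4 probability matrices over the same
#'   positions.
#' @return Scalar MAE.
#' @export
ppm_mae <- function(true_ppm, pred_ppm) {
  w <- .check_windows(true_ppm, pred_ppm)
  mean(rowSums(abs(w$t - w$p)))
}

#' Cross-entropy between aligned PPM windows
#'
#' Mean over positions of -sum_c true * ln(pred); predicted entries are
#' floored at 1e-10 before the logarithm, mirroring the PPM epsilon
#' convention.
#'
#' @inheritParams ppm_mae
#' @param floor minimum predicted probability before the log.
#' @return Scalar cross-entropy (nats).
#' @export
ppm_cross_entropy <- function(true_ppm, pred_ppm, floor = 1e-10) {
  w <- .check_windows(true_ppm, pred_ppm)
  if (any(w$p < 0)) stop("negative predicted probabilities")
  mean(-rowSums(w$t * log(pmax(w$p, floor))))
}

# least-squares rigid superposition (rotation + translation, no reflection)
kabsch_superpose <- function(P, Q) {
  # returns P superposed onto Q
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  sweep(Pc %*% t(R), 2, cq, "+")
}

#' C1'-RMSD between native and model structures with overlap search
#'
#' When the two C1' traces differ in length, all contiguous placements of
#' the shorter along the longer are enumerated; for each, the overlapping
#' atoms are superposed by least-squares rigid fit (rotation + translation,
#' reflection excluded) and the RMSD computed; the minimum is returned with
#' its overlap. Equal lengths give the single full overlap.
#'
#' @param native,model N x 3 / M x 3 C1' coordinate matrices (>= 3 rows).
#' @return List with `rmsd`, `offset` (0-based placement of the shorter
#'   trace along the longer), `length` (overlap length), and `swapped`
#'   (TRUE when `model` was the longer input).
#' @export
c1_rmsd <- function(native, model) {
  native <- as.matrix(native); model <- as.matrix(model)
  stopifnot(ncol(native) == 3, ncol(model) == 3)
  if (nrow(native) < 3 || nrow(model) < 3)
    stop("need at least 3 C1' atoms in each structure")
  swapped <- nrow(model) > nrow(native)
  long <- if (swapped) model else native
  short <- if (swapped) native else model
  nl <- nrow(long); ns <- nrow(short)
  best <- NULL
  for (off in 0:(nl - ns)) {
    win <- long[(off + 1):(off + ns), , drop = FALSE]
    sup <- kabsch_superpose(short, win)
    rmsd <- sqrt(mean(rowSums((sup - win)^2)))
    if (is.null(best) || rmsd < best$rmsd)
      best <- list(rmsd = rmsd, offset = off, length = ns, swapped = swapped)
  }
  best
}

#' Crop a dot-bracket string, breaking severed pairs
#'
#' Utility for overlap cropping: positions outside `keep` are removed and
#' any base pair with exactly one partner cropped has its surviving partner
#' set to a loop (`.`). Pseudoknot bracket layers `()`, `[]`, `{}`, `<>` are
#' supported.
#'
#' @param dotbracket secondary structure string.
#' @param keep integer vector of 1-based positions to keep (must be
#'   contiguous).
#' @return The cropped dot-bracket string.
#' @export
crop_dotbracket <- function(dotbracket, keep) {
  ch <- strsplit(dotbracket, "")[[1]]
  n <- length(ch)
  stopifnot(all(keep >= 1 & keep <= n), all(diff(sort(keep)) == 1))
  keep <- sort(keep)
  partner <- rep(NA_integer_, n)
  openers <- c("(", "[", "{", "<"); closers <- c(")", "]", "}", ">")
  for (k in seq_along(openers)) {
    stack <- integer(0)
    for (i in seq_len(n)) {
      if (ch[i] == openers[k]) stack <- c(stack, i)
      else if (ch[i] == closers[k]) {
        if (!length(stack)) stop("unbalanced dot-bracket string")
        j <- stack[length(stack)]; stack <- stack[-length(stack)]
        partner[i] <- j; partner[j] <- i
      }
    }
    if (length(stack)) stop("unbalanced dot-bracket string")
  }
  out <- ch
  inside <- seq_len(n) %in% keep
  for (i in which(inside & !is.na(partner))) {
    if (!inside[partner[i]]) out[i] <- "."
  }
  paste(out[keep], collapse = "")
}

#' Extract the C1' coordinate trace of one nucleic chain
#'
#' @param complex a `nuc_complex`.
#' @param chain_id chain identifier.
#' @return L x 3 matrix in residue order (residues lacking C1' are skipped).
#' @export
c1_trace <- function(complex, chain_id) {
  r <- complex$residues[complex$residues$chain_id == chain_id, ]
  r <- r[order(r$res_index), ]
  rows <- lapply(r$res_index, function(i)
    get_atom_coord(complex, chain_id, i, "C1'"))
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}
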