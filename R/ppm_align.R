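# Position probability matrices: loading/normalization, reverse complement,
# information content, IC-weighted Pearson alignment to structure sequences,
# and conflict-resolved merging into per-complex target maps.

.BASES <- c("A", "C", "G", "T")

#' Construct a position probability matrix
#'
#' @param mat L x 4 matrix of per-position base probabilities, base order
#'   (A, C, G, T); each row must sum to 1 within 1e-6.
#' @param source_id motif identifier.
#' @param group_id experimentally-equivalent group identifier.
#' @return A `ppm` object.
#' @export
new_ppm <- function(mat, source_id = NA_character_, group_id = NA_character_) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == 4, nrow(mat) >= 1, all(mat >= 0))
  if (any(abs(rowSums(mat) - 1) > 1e-6))
    stop("PPM rows must sum to 1; normalize counts with normalize_ppm()")
  colnames(mat) <- .BASES
  structure(mat, class = c("ppm", "matrix"),
            source_id = source_id, group_id = group_id)
}

#' @export
print.ppm <- function(x, ...) {
  cat("<ppm>", nrow(x), "positions | source:", attr(x, "source_id"), "\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Normalize a count or probability matrix into a PPM
#'
#' Adds `epsilon` to all four entries of each position and renormalizes, so
#' every probability is strictly positive.
#'
#' @param raw L x 4 non-negative matrix (counts or probabilities).
#' @param epsilon pseudo-probability added to every entry (default 1e-10).
#' @inheritParams new_ppm
#' @return A `ppm`.
#' @export
normalize_ppm <- function(raw, epsilon = 1e-10, source_id = NA_character_,
                          group_id = NA_character_) {
  raw <- as.matrix(raw)
  if (any(raw < 0)) stop("PPM input contains negative entries")
  if (any(rowSums(raw) == 0)) stop("PPM input contains an all-zero position")
  raw <- raw + epsilon
  new_ppm(raw / rowSums(raw), source_id = source_id, group_id = group_id)
}

#' Reverse complement of a PPM
#'
#' Positions are reversed and within each position A/T and C/G probabilities
#' are swapped; applying twice is the identity.
#'
#' @param p a `ppm`.
#' @return A `ppm`.
#' @export
reverse_complement <- function(p) {
  m <- unclass(p)[rev(seq_len(nrow(p))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(m) <- .BASES
  structure(m, class = c("ppm", "matrix"),
            source_id = attr(p, "source_id"), group_id = attr(p, "group_id"))
}

#' Per-position information content
#'
#' IC = sum over the four bases of ln(P_c) / ln(0.25). Uniform positions give
#' exactly 4; the value grows as the position becomes more peaked (each term
#' ln(P)/ln(0.25) exceeds 1 for P < 0.25).
#'
#' @param column length-4 probability vector (epsilon-normalized, strictly
#'   positive).
#' @return Scalar information content.
#' @export
information_content <- function(column) {
  stopifnot(length(column) == 4)
  if (any(column <= 0))
    stop("information content requires strictly positive probabilities")
  sum(log(column)) / log(0.25)
}

#' Information-content-weighted Pearson correlation
#'
#' The alignment score between a PPM position and a one-hot base indicator:
#' 0.5 * IC(column) * PCC(column, onehot) over the four base channels. When
#' the column has zero variance (uniform), the PCC denominator vanishes and
#' the score is defined as 0.
#'
#' @param column length-4 probability vector.
#' @param onehot length-4 canonical base indicator.
#' @return Scalar score.
#' @export
ic_weighted_pcc <- function(column, onehot) {
  stopifnot(length(column) == 4, length(onehot) == 4)
  if (stats::sd(column) < 1e-12 || stats::sd(onehot) < 1e-12) return(0)
  0.5 * information_content(column) * stats::cor(column, onehot)
}

# one-hot (A,C,G,T) of a nucleic token; NULL for unknowns
.token_onehot4 <- function(token) {
  if (is.na(token) || token == .TOK_NA_UNK) return(NULL)
  v <- numeric(4)
  v[token - .TOK_NA_A + 1L] <- 1
  v
}

#' Align a PPM to a chain sequence at every qualifying offset
#'
#' Enumerates both orientations (forward and reverse complement) and every
#' overlap with at least `min_overlap` non-unknown sequence positions; each
#' alignment is scored as the sum of per-position IC-weighted PCC between
#' the PPM column and the one-hot structure base. Unknown sequence positions
#' are excluded from both the score and the overlap-length check.
#'
#' @param p a `ppm`.
#' @param chain_tokens integer nucleic token vector for the chain (unknown
#'   token allowed); RNA U is treated as T.
#' @param chain_id chain identifier recorded on results.
#' @param min_overlap minimum non-unknown overlap length (default 5).
#' @return List of alignment results, each a list with `chain_id`, `offset`
#'   (0-based chain position of PPM row 1), `orientation`, `score`,
#'   `positions` (0-based chain positions scored), `per_position_scores`,
#'   and `columns` (the oriented PPM).
#' @export
align_ppm_to_chain <- function(p, chain_tokens, chain_id = "A",
                               min_overlap = 5) {
  L <- nrow(p)
  N <- length(chain_tokens)
  onehots <- lapply(chain_tokens, .token_onehot4)
  results <- list()
  for (orientation in c("forward", "reverse_complement")) {
    m <- if (orientation == "forward") p else reverse_complement(p)
    for (offset in (-(L - 1L)):(N - 1L)) {
      rows <- seq_len(L)
      pos <- offset + rows - 1L          # 0-based chain positions
      keep <- pos >= 0L & pos < N
      rows <- rows[keep]; pos <- pos[keep]
      scored <- !vapply(onehots[pos + 1L], is.null, TRUE)
      if (sum(scored) < min_overlap) next
      sc_rows <- rows[scored]; sc_pos <- pos[scored]
      s <- vapply(seq_along(sc_rows), function(q)
        ic_weighted_pcc(m[sc_rows[q], ], onehots[[sc_pos[q] + 1L]]), 0)
      results[[length(results) + 1L]] <- list(
        chain_id = chain_id, offset = as.integer(offset),
        orientation = orientation, score = sum(s),
        positions = sc_pos, per_position_scores = s,
        rows = sc_rows, columns = m)
    }
  }
  results
}

#' Best-scoring alignments (ties retained)
#'
#' @param results list of alignment results (possibly across chains).
#' @return The maximal-score subset; ties are kept as multiple best
#'   alignments. Empty input gives an empty list.
#' @export
best_alignments <- function(results) {
  if (!length(results)) return(list())
  scores <- vapply(results, `[[`, 0, "score")
  results[scores == max(scores)]
}

#' Merge best alignments into a per-complex aligned target map
#'
#' Writes the aligned PPM columns of each group's best alignment(s) into a
#' global per-complex map. When two aligned columns land on the same
#' sequence position, the column with the higher per-position local score is
#' retained; at unknown sequence positions (where no local score exists)
#' the column with the higher information content wins. Groups are processed
#' in input order and earlier writes win exact ties.
#'
#' @param alignments_by_group list (one element per PPM group) of lists of
#'   best alignments from [best_alignments()]. Alignments may also carry
#'   columns over unknown positions: such positions get `local_score = NA`.
#' @param complex a `nuc_complex` (supplies chain sequences; unknown bases
#'   have no local score).
#' @return An `aligned_target_map`: list with `map` (keyed by
#'   `"chain\rres_index"`, each entry holding `column`, `local_score`, `ic`)
#'   and `n_positions`.
#' @export
merge_alignments <- function(alignments_by_group, complex) {
  map <- list()
  r <- complex$residues
  for (group in alignments_by_group) {
    for (al in group) {
      m <- al$columns
      rows <- seq_len(nrow(m))
      pos <- al$offset + rows - 1L
      chain_len <- sum(r$chain_id == al$chain_id)
      keep <- pos >= 0L & pos < chain_len
      rows <- rows[keep]; pos <- pos[keep]
      for (q in seq_along(rows)) {
        key <- paste(al$chain_id, pos[q], sep = "\r")
        tok <- r$token[r$chain_id == al$chain_id & r$res_index == pos[q]]
        known <- length(tok) == 1 && tok != .TOK_NA_UNK
        ls <- if (known) {
          oh <- .token_onehot4(tok)
          ic_weighted_pcc(m[rows[q], ], oh)
        } else NA_real_
        entry <- list(column = m[rows[q], ],
                      local_score = ls,
                      ic = information_content(m[rows[q], ]))
        old <- map[[key]]
        if (is.null(old)) {
          map[[key]] <- entry
        } else if (!is.na(ls) && !is.na(old$local_score)) {
          if (ls > old$local_score) map[[key]] <- entry
        } else {
          if (entry$ic > old$ic) map[[key]] <- entry
        }
      }
    }
  }
  structure(list(map = map, n_positions = length(map)),
            class = "aligned_target_map")
}

#' Pick one PPM from an experimentally-equivalent group
#'
#' Training samples uniformly among the group members each time an example
#' is loaded; evaluation deterministically takes the first.
#'
#' @param group non-empty list of `ppm` objects.
#' @param mode `"random"` (training) or `"first"` (evaluation).
#' @param seed RNG seed for random mode.
#' @return One `ppm`.
#' @export
select_group_ppm <- function(group, mode = c("random", "first"), seed = NULL) {
  mode <- match.arg(mode)
  if (!length(group)) stop("empty PPM group")
  if (mode == "first") return(group[[1L]])
  with_seed(seed, group[[sample.int(length(group), 1)]])
}

# ---- JASPAR-style I/O --------------------------------------------------------

#' Read a JASPAR-style matrix file
#'
#' Accepts the four-row `A [ ... ]` format (counts or probabilities) with an
#' optional `>identifier name` header; counts are normalized column-wise
#' before epsilon handling.
#'
#' @param path file path.
#' @return A `ppm` (source id from the header when present).
#' @export
read_jaspar <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  src <- NA_character_
  if (length(lines) && startsWith(lines[1], ">")) {
    src <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  rows <- lapply(.BASES, function(b) {
    ln <- grep(paste0("^", b, "\\b"), lines, value = TRUE)
    if (!length(ln)) stop("JASPAR parse error: missing row for base ", b)
    parts <- strsplit(gsub("[][]", " ", sub(paste0("^", b), "", ln[1])),
                      "\\s+")[[1]]
    as.numeric(parts[nzchar(parts)])
  })
  lens <- vapply(rows, length, 0L)
  if (length(unique(lens)) != 1) stop("JASPAR parse error: ragged rows")
  mat <- t(do.call(rbind, rows))  # L x 4
  colnames(mat) <- .BASES
  normalize_ppm(mat, source_id = src, group_id = src)
}

#' Write a PPM in JASPAR-style format
#'
#' @param p a `ppm`.
#' @param path output path.
#' @param digits significant digits for probabilities.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(p, path, digits = 6) {
  id <- attr(p, "source_id")
  hdr <- paste0(">", if (is.na(id)) "ppm" else id)
  body <- vapply(seq_len(4), function(ci) {
    paste0(.BASES[ci], "  [ ",
           paste(signif(unclass(p)[, ci], digits), collapse = " "), " ]")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Alignment results as a JSON report
#'
#' @param results list of alignment results.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_report <- function(results, path) {
  rep_ <- lapply(results, function(al)
    list(chain = al$chain_id, offset = al$offset,
         orientation = al$orientation, score = al$score,
         positions = al$positions, per_position_scores = al$per_position_scores))
  jsonlite::write_json(rep_, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
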