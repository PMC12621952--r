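test_that("normalization adds epsilon and renormalizes per position", {
  u <- normalize_ppm(matrix(rep(0.25, 4), 1))
  expect_equal(unclass(u)[1, ], rep(0.25, 4), ignore_attr = TRUE)
  counts <- normalize_ppm(matrix(c(7, 1, 1, 1), 1))
  expect_equal(unclass(counts)[1, ], c(0.7, 0.1, 0.1, 0.1),
               tolerance = 1e-9, ignore_attr = TRUE)
  oh <- normalize_ppm(matrix(c(1, 0, 0, 0), 1))
  expect_gt(oh[1, 1], 1 - 1e-9)
  expect_true(all(oh[1, 2:4] > 0))        # epsilon keeps all entries positive
  expect_error(normalize_ppm(matrix(c(-1, 1, 1, 1), 1)), "negative")
  expect_error(normalize_ppm(matrix(0, 1, 4)), "all-zero")
  expect_error(new_ppm(matrix(c(0.5, 0.2, 0.2, 0.2), 1)), "sum to 1")
})

test_that("reverse complement is an involution swapping A/T and C/G", {
  p <- make_synthetic_ppm(7, peakedness = 4, seed = 2)
  expect_equal(unclass(reverse_complement(reverse_complement(p))),
               unclass(p))
  u <- normalize_ppm(matrix(0.25, 3, 4))
  expect_equal(unclass(reverse_complement(u)), unclass(u))
  single <- normalize_ppm(matrix(c(0.7, 0.1, 0.1, 0.1), 1))
  rc <- reverse_complement(single)
  expect_equal(unclass(rc)[1, ], c(0.1, 0.1, 0.1, 0.7),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("information content follows the printed log-ratio formula", {
  expect_equal(information_content(rep(0.25, 4)), 4)
  expect_equal(information_content(c(0.97, 0.01, 0.01, 0.01)),
               (log(0.97) + 3 * log(0.01)) / log(0.25))
  expect_equal(information_content(c(0.97, 0.01, 0.01, 0.01)), 9.988,
               tolerance = 1e-3)
  oh <- normalize_ppm(matrix(c(1, 0, 0, 0), 1))[1, ]
  expect_equal(information_content(oh), 49.8, tolerance = 0.1)
  # invariant under channel permutation
  col <- c(0.5, 0.3, 0.15, 0.05)
  expect_equal(information_content(col), information_content(rev(col)))
  expect_error(information_content(c(0, 0.5, 0.25, 0.25)), "positive")
})

test_that("IC-weighted PCC handles matches, mismatches and degeneracy", {
  expect_identical(ic_weighted_pcc(rep(0.25, 4), c(1, 0, 0, 0)), 0)
  oh <- normalize_ppm(matrix(c(1, 0, 0, 0), 1))[1, ]
  expect_equal(ic_weighted_pcc(oh, c(1, 0, 0, 0)),
               0.5 * information_content(oh), tolerance = 1e-6)
  mm <- vapply(2:4, function(k) {
    v <- numeric(4); v[k] <- 1
    ic_weighted_pcc(oh, v)
  }, 0)
  expect_true(all(mm < 0))
  expect_equal(mm[1], mm[2])
  expect_equal(mm[2], mm[3])
})

test_that("alignment enumeration matches the exhaustive oracle exactly", {
  set.seed(11)
  for (trial in 1:12) {
    L <- sample(2:8, 1)
    N <- sample(5:12, 1)
    p <- make_synthetic_ppm(L, peakedness = runif(1, 0.5, 8), seed = trial)
    chain <- random_chain_tokens(N)
    mine <- align_ppm_to_chain(p, chain, min_overlap = 5)
    oracle <- align_oracle(p, chain, min_overlap = 5)
    expect_equal(length(mine), length(oracle))
    key <- function(x) paste(x$orientation, x$offset)
    mine <- mine[order(vapply(mine, key, ""))]
    oracle <- oracle[order(vapply(oracle, key, ""))]
    for (q in seq_along(mine)) {
      expect_identical(key(mine[[q]]), key(oracle[[q]]))
      expect_equal(mine[[q]]$score, oracle[[q]]$score)
      expect_equal(mine[[q]]$per_position_scores,
                   oracle[[q]]$per_position_scores)
      expect_equal(mine[[q]]$positions, oracle[[q]]$positions)
    }
  }
})

test_that("short chains yield no qualifying alignment", {
  p <- make_synthetic_ppm(6, seed = 1)
  expect_length(align_ppm_to_chain(p, base_to_token(c("A", "C", "G", "T"))), 0)
})

test_that("alignment scores mirror under reverse complementation of both", {
  set.seed(5)
  p <- make_synthetic_ppm(5, peakedness = 6, seed = 9)
  chain <- base_to_token(strsplit("TTACGTATT", "")[[1]])
  fwd <- align_ppm_to_chain(p, chain)
  # reverse-complement the chain and the PPM: the score multiset must match
  chain_rc <- rev(c(A = 25L, C = 24L, G = 23L, `T` = 22L)[
    c("A", "C", "G", "T")[chain - 21L]])
  names(chain_rc) <- NULL
  bwd <- align_ppm_to_chain(reverse_complement(p), chain_rc)
  expect_equal(sort(vapply(fwd, `[[`, 0, "score")),
               sort(vapply(bwd, `[[`, 0, "score")), tolerance = 1e-12)
  expect_equal(max(vapply(fwd, `[[`, 0, "score")),
               max(vapply(bwd, `[[`, 0, "score")), tolerance = 1e-12)
})

test_that("an embedded consensus aligns at its planted offset", {
  p <- make_synthetic_ppm(5, consensus = "ACGTA")
  chain <- base_to_token(strsplit("TTACGTATT", "")[[1]])
  best <- best_alignments(align_ppm_to_chain(p, chain))
  # the chain also contains the exact reverse complement TACGT at offset 1,
  # so two perfect alignments tie and both are retained
  expect_length(best, 2)
  keys <- vapply(best, function(b) paste(b$orientation, b$offset), "")
  expect_setequal(keys, c("forward 2", "reverse_complement 1"))
  # all five positions score 0.5*IC with PCC ~ 1
  ic <- information_content(unclass(p)[1, ])
  for (b in best) expect_equal(b$score, 5 * 0.5 * ic, tolerance = 1e-6)
})

test_that("merging resolves overlaps by local score, and by IC at unknowns", {
  dx <- make_duplex("ACGTACGTAC", double = FALSE)
  sharp <- unclass(make_synthetic_ppm(1, consensus = "A"))[1, ]  # peaked on A
  soft <- c(0.4, 0.2, 0.2, 0.2)
  # two fake alignments overlapping at position 3 (0-based), chain A
  al1 <- list(chain_id = "A", offset = 0L, orientation = "forward",
              columns = do.call(rbind, rep(list(soft), 4)), score = 1)
  al2 <- list(chain_id = "A", offset = 3L, orientation = "forward",
              columns = do.call(rbind, rep(list(sharp), 3)), score = 1)
  m <- merge_alignments(list(list(al1), list(al2)), dx)
  # position 3 holds base T (ACGT...) -> compare local scores there
  key3 <- paste("A", 3, sep = "\r")
  s_soft <- ic_weighted_pcc(soft, c(0, 0, 0, 1))
  s_sharp <- ic_weighted_pcc(sharp, c(0, 0, 0, 1))
  winner <- if (s_sharp > s_soft) sharp else soft
  expect_equal(m$map[[key3]]$column, winner, ignore_attr = TRUE,
               tolerance = 1e-9)
  # single alignment, no conflicts: map equals its columns
  m1 <- merge_alignments(list(list(al1)), dx)
  expect_equal(m1$n_positions, 4)
  for (j in 0:3)
    expect_equal(m1$map[[paste("A", j, sep = "\r")]]$column, soft,
                 ignore_attr = TRUE)
  # unknown sequence position: higher IC wins regardless of order
  unk <- mark_unknown_base(dx, "A", 3L)
  mu1 <- merge_alignments(list(list(al1), list(al2)), unk)
  mu2 <- merge_alignments(list(list(al2), list(al1)), unk)
  expect_equal(mu1$map[[key3]]$column, sharp, ignore_attr = TRUE,
               tolerance = 1e-9)  # sharp has higher IC
  expect_equal(mu2$map[[key3]]$column, sharp, ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("group selection is uniform in training and fixed in evaluation", {
  g1 <- list(make_synthetic_ppm(3, seed = 1))
  expect_identical(select_group_ppm(g1, "random", seed = 1)[, ], g1[[1]][, ])
  expect_identical(select_group_ppm(g1, "first")[, ], g1[[1]][, ])
  g3 <- lapply(1:3, function(i) make_synthetic_ppm(3, seed = i))
  expect_identical(select_group_ppm(g3, "first")[, ], g3[[1]][, ])
  picks <- vapply(1:2000, function(s)
    attr(select_group_ppm(g3, "random", seed = s), "source_id") == "synthetic" &&
      identical(select_group_ppm(g3, "random", seed = s)[1, ],
                g3[[1]][1, ]), TRUE)
  frac <- mean(picks)
  expect_lt(abs(frac - 1 / 3), 0.05)
  expect_error(select_group_ppm(list()), "empty")
})

test_that("JASPAR matrices round-trip through the reader and writer", {
  p <- make_synthetic_ppm(6, peakedness = 5, seed = 4)
  path <- tempfile(fileext = ".jaspar")
  write_jaspar(p, path)
  back <- read_jaspar(path)
  expect_lt(max(abs(unclass(p) - unclass(back))), 1e-5)
  # count-matrix dialect
  cpath <- tempfile()
  writeLines(c(">MA0000.1 test",
               "A [ 10  0  5 ]",
               "C [  0 10  5 ]",
               "G [  0  0  5 ]",
               "T [  0  0  5 ]"), cpath)
  cp <- read_jaspar(cpath)
  expect_equal(nrow(cp), 3)
  expect_equal(unname(unclass(cp)[1, 1]), 1, tolerance = 1e-8)
  expect_equal(unclass(cp)[3, ], rep(0.25, 4), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_equal(attr(cp, "source_id"), "MA0000.1 test")
})
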