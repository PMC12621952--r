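# Structure domain model: typed residues with named backbone atoms and
# occupancies, entry/residue filters, and the side-chain interface mask.

.BB_PROTEIN <- c("N", "CA", "C", "O")
.BB_DNA <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'",
             "C2'", "C1'")
.BB_RNA <- c(.BB_DNA, "O2'")
.VIRTUAL_ATOMS <- c("CBv", "Nv")

required_backbone <- function(polymer_class) {
  switch(polymer_class,
         protein = .BB_PROTEIN,
         DNA = .BB_DNA,
         RNA = .BB_RNA,
         stop("no backbone definition for class ", polymer_class))
}

.is_hydrogen <- function(elety) grepl("^[0-9]*H", elety)

#' Build a biopolymer complex from an atom table
#'
#' Classifies residues by polymer class (protein / DNA / RNA), assigns tokens
#' from the shared alphabet, marks side-chain atoms, and computes the
#' per-residue `exists` flag: a residue exists only if every required backbone
#' atom of its class is present with occupancy strictly above
#' `occupancy_threshold`. Atoms that belong to non-polymer residues (ligands,
#' waters) are dropped; hydrogens are ignored throughout.
#'
#' @param atoms data frame with columns `chain_id`, `res_index` (0-based
#'   position within chain), `res_name`, `elety` (PDB atom name), `x`, `y`,
#'   `z` (Angstrom) and `o` (occupancy in \[0,1\]).
#' @param resolution resolution in Angstrom, or `NA` when not reported.
#' @param meta list of entry metadata (e.g. `entry_id`, `method`).
#' @param occupancy_threshold occupancy above which an atom counts as present
#'   (strict inequality; default 0.8).
#' @param permissive_termini if `TRUE`, 5'-terminal nucleic residues are not
#'   required to carry P/OP1/OP2 to exist. Off by default: the strict reading
#'   of the occupancy rule covers all backbone atoms.
#' @return An object of class `nuc_complex` with elements `atoms` (atom
#'   table with `is_sidechain`), `residues` (per-residue table with
#'   `polymer_class`, `token`, `exists`), `chains`, `resolution`, `meta`.
#' @export
new_complex <- function(atoms, resolution = NA_real_, meta = list(),
                        occupancy_threshold = 0.8,
                        permissive_termini = FALSE) {
  stopifnot(is.data.frame(atoms),
            all(c("chain_id", "res_index", "res_name", "elety",
                  "x", "y", "z", "o") %in% names(atoms)))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  if (any(atoms$o < 0 | atoms$o > 1))
    stop("occupancy must lie in [0, 1]")
  atoms <- atoms[!.is_hydrogen(atoms$elety), , drop = FALSE]

  key <- paste(atoms$chain_id, atoms$res_index, sep = "\r")
  first <- !duplicated(key)
  res <- data.frame(chain_id = atoms$chain_id[first],
                    res_index = atoms$res_index[first],
                    res_name = atoms$res_name[first],
                    stringsAsFactors = FALSE)
  res_atoms <- split(atoms$elety, factor(key, levels = unique(key)))

  classify <- function(name, elety_set) {
    if (name %in% names(.AA3)) return(list(class = "protein", token = .AA3[[name]]))
    if (name %in% names(.DNA_RES)) return(list(class = "DNA", token = .DNA_RES[[name]]))
    if (name %in% names(.RNA_RES)) return(list(class = "RNA", token = .RNA_RES[[name]]))
    if ("C1'" %in% elety_set) {
      cls <- if ("O2'" %in% elety_set) "RNA" else "DNA"
      return(list(class = cls, token = .TOK_NA_UNK))
    }
    if (all(c("N", "CA", "C") %in% elety_set))
      return(list(class = "protein", token = .TOK_PROTEIN_UNK))
    list(class = "drop", token = NA_integer_)
  }
  cls <- mapply(classify, res$res_name, res_atoms, SIMPLIFY = FALSE)
  res$polymer_class <- vapply(cls, `[[`, "", "class")
  res$token <- vapply(cls, function(x) as.integer(x$token), 1L)

  keep <- res$polymer_class != "drop"
  res <- res[keep, , drop = FALSE]
  if (nrow(res) == 0L) stop("empty structure: no polymer residues found")
  atoms <- atoms[key %in% paste(res$chain_id, res$res_index, sep = "\r"), ,
                 drop = FALSE]
  rownames(res) <- NULL
  rownames(atoms) <- NULL

  # per-atom side-chain flag and per-residue existence
  akey <- paste(atoms$chain_id, atoms$res_index, sep = "\r")
  rkey <- paste(res$chain_id, res$res_index, sep = "\r")
  aclass <- res$polymer_class[match(akey, rkey)]
  in_bb <- (aclass == "protein" & atoms$elety %in% .BB_PROTEIN) |
    (aclass == "DNA" & atoms$elety %in% .BB_DNA) |
    (aclass == "RNA" & atoms$elety %in% .BB_RNA)
  atoms$is_sidechain <- !in_bb & !(atoms$elety %in% .VIRTUAL_ATOMS)

  chain_start <- stats::ave(res$res_index, res$chain_id, FUN = min)
  occ_ok <- atoms$o > occupancy_threshold
  present <- split(atoms$elety[occ_ok], factor(akey[occ_ok], levels = rkey))
  res$exists <- vapply(seq_len(nrow(res)), function(i) {
    need <- required_backbone(res$polymer_class[i])
    if (permissive_termini && res$polymer_class[i] != "protein" &&
        res$res_index[i] == chain_start[i])
      need <- setdiff(need, c("P", "OP1", "OP2"))
    all(need %in% present[[i]])
  }, TRUE)

  chains <- data.frame(chain_id = unique(res$chain_id), stringsAsFactors = FALSE)
  chains$polymer_class <- vapply(chains$chain_id, function(cid) {
    tab <- table(res$polymer_class[res$chain_id == cid])
    names(tab)[which.max(tab)]
  }, "")

  structure(list(atoms = atoms, residues = res, chains = chains,
                 resolution = resolution, meta = meta),
            class = "nuc_complex")
}

#' @export
print.nuc_complex <- function(x, ...) {
  cat("<nuc_complex>", nrow(x$chains), "chain(s),",
      nrow(x$residues), "residues,", nrow(x$atoms), "atoms\n")
  for (i in seq_len(nrow(x$chains))) {
    cid <- x$chains$chain_id[i]
    n <- sum(x$residues$chain_id == cid)
    cat("  chain", cid, paste0("[", x$chains$polymer_class[i], "]"), n,
        "residues\n")
  }
  invisible(x)
}

#' Number of polymer residues in a complex
#' @param complex a `nuc_complex`.
#' @return Integer count.
#' @export
n_residues <- function(complex) nrow(complex$residues)

#' Coordinates of one named atom of one residue
#' @param complex a `nuc_complex`.
#' @param chain_id chain identifier.
#' @param res_index 0-based residue index within the chain.
#' @param elety atom name.
#' @return Numeric length-3 vector, or `NULL` when absent.
#' @export
get_atom_coord <- function(complex, chain_id, res_index, elety) {
  a <- complex$atoms
  i <- which(a$chain_id == chain_id & a$res_index == res_index &
               a$elety == elety)
  if (length(i) == 0L) return(NULL)
  as.numeric(a[i[1L], c("x", "y", "z")])
}

#' Token sequence of one chain
#' @param complex a `nuc_complex`.
#' @param chain_id chain identifier.
#' @return Integer token vector ordered by residue index.
#' @export
chain_tokens <- function(complex, chain_id) {
  r <- complex$residues[complex$residues$chain_id == chain_id, ]
  r$token[order(r$res_index)]
}

# file parsing ---------------------------------------------------------------

.scan_header_resolution <- function(lines) {
  m <- grep("_refine\\.ls_d_res_high", lines, value = TRUE)
  if (length(m)) {
    v <- suppressWarnings(as.numeric(sub(".*_refine\\.ls_d_res_high\\s+", "", m[1])))
    if (is.finite(v)) return(v)
  }
  m <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
  if (length(m)) {
    tail_ <- sub(".*RESOLUTION\\.", "", m[1])
    v <- suppressWarnings(as.numeric(
      regmatches(tail_, regexpr("[0-9]+\\.?[0-9]*", tail_))))
    if (is.finite(v)) return(v)
  }
  NA_real_
}

.scan_header_method <- function(lines) {
  m <- grep("_exptl\\.method", lines, value = TRUE)
  if (length(m)) return(gsub("['\"]", "", sub(".*_exptl\\.method\\s+", "", m[1])))
  m <- grep("^EXPDTA", lines, value = TRUE)
  if (length(m)) return(trimws(sub("^EXPDTA", "", m[1])))
  NA_character_
}

#' Parse an mmCIF or PDB file into a complex
#'
#' Reads atom records (occupancy honored) through `bio3d`, keeps the
#' highest-occupancy alternate location per atom, drops hydrogens and
#' non-polymer residues, and types every residue by polymer class. Residue
#' indices are rebuilt 0-based and contiguous per chain in file order.
#' Non-canonical nucleic residues receive the unknown nucleic token.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"mmcif"` or `"pdb"`.
#' @inheritParams new_complex
#' @return A `nuc_complex`.
#' @export
parse_structure <- function(path, format = c("auto", "mmcif", "pdb"),
                            occupancy_threshold = 0.8,
                            permissive_termini = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    suppressWarnings(suppressMessages(
      if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)
      else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
    )),
    error = function(e) stop("unparseable ", format, " file: ", path, " (",
                             conditionMessage(e), ")"))
  at <- pdb$atom
  at$elety <- gsub('"', "", at$elety)
  at$o[is.na(at$o)] <- 1
  at$chain[is.na(at$chain)] <- "A"
  # highest-occupancy altloc per (chain, residue, atom name)
  ord <- order(-at$o)
  at <- at[ord, , drop = FALSE]
  dupkey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  at <- at[!duplicated(dupkey), , drop = FALSE]
  at <- at[order(as.integer(rownames(at))), , drop = FALSE]

  rid <- paste(at$chain, at$resno, at$insert, sep = "\r")
  rid_f <- factor(rid, levels = unique(rid))
  # 0-based contiguous index per chain, in file order
  idx_by_chain <- stats::ave(as.integer(rid_f), at$chain,
                             FUN = function(v) match(v, unique(v)) - 1L)
  atoms <- data.frame(chain_id = at$chain, res_index = idx_by_chain,
                      res_name = at$resid, elety = at$elety,
                      x = at$x, y = at$y, z = at$z, o = pmin(pmax(at$o, 0), 1),
                      stringsAsFactors = FALSE)
  lines <- readLines(path, warn = FALSE)
  new_complex(atoms,
              resolution = .scan_header_resolution(lines),
              meta = list(entry_id = sub("\\.[^.]*$", "", basename(path)),
                          method = .scan_header_method(lines)),
              occupancy_threshold = occupancy_threshold,
              permissive_termini = permissive_termini)
}

# minimal writers (sufficient for fixtures) ----------------------------------

.element_of <- function(elety) {
  e <- sub("^[0-9]*", "", elety)
  substr(e, 1, 1)
}

#' Write a complex to an mmCIF or PDB file
#'
#' A minimal writer covering atom records plus resolution/method headers;
#' sufficient to round-trip fixtures through [parse_structure()].
#'
#' @param complex a `nuc_complex`.
#' @param path output path.
#' @param format `"mmcif"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(complex, path, format = c("mmcif", "pdb")) {
  format <- match.arg(format)
  a <- complex$atoms
  r <- complex$residues
  # residue numbering for output: 1-based within chain
  resno <- a$res_index + 1L
  if (format == "mmcif") {
    hdr <- c(paste0("data_", complex$meta$entry_id %||% "fixture"), "#")
    if (!is.na(complex$resolution))
      hdr <- c(hdr, sprintf("_refine.ls_d_res_high %.3f", complex$resolution), "#")
    if (!is.null(complex$meta$method) && !is.na(complex$meta$method))
      hdr <- c(hdr, sprintf("_exptl.method '%s'", complex$meta$method), "#")
    cols <- c("group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
              "label_comp_id", "label_asym_id", "label_entity_id",
              "label_seq_id", "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
              "Cartn_z", "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
              "auth_seq_id", "auth_comp_id", "auth_asym_id", "auth_atom_id",
              "pdbx_PDB_model_num")
    name <- ifelse(grepl("'", a$elety), paste0('"', a$elety, '"'), a$elety)
    rows <- sprintf(
      "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f 0.00 ? %d %s %s %s 1",
      seq_len(nrow(a)), .element_of(a$elety), name, a$res_name, a$chain_id,
      resno, a$x, a$y, a$z, a$o, resno, a$res_name, a$chain_id, name)
    writeLines(c(hdr, "loop_", paste0("_atom_site.", cols), rows, "#"), path)
  } else {
    lines <- character(0)
    if (!is.na(complex$resolution))
      lines <- c(lines, sprintf(
        "REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", complex$resolution))
    if (!is.null(complex$meta$method) && !is.na(complex$meta$method))
      lines <- c(lines, paste0("EXPDTA    ", complex$meta$method))
    name4 <- ifelse(nchar(a$elety) >= 4, substr(a$elety, 1, 4),
                    sprintf(" %-3s", a$elety))
    rows <- sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    seq_len(nrow(a)), name4, a$res_name,
                    substr(a$chain_id, 1, 1), resno, a$x, a$y, a$z, a$o, 0,
                    .element_of(a$elety))
    writeLines(c(lines, rows, "END"), path)
  }
  invisible(path)
}

# filters ---------------------------------------------------------------------

#' Dataset- and evaluation-stage entry filters
#'
#' Dataset stage: heavy-atom count >= 100; resolution <= 3.5 Angstrom or
#' absent (NMR-like entries pass); the most frequent residue must not be UNK
#' occurring more than 20 times; at least one nucleic acid chain; at least one
#' nucleic residue with all backbone atoms above the occupancy threshold;
#' total polymer length <= 6000. When per-chain reference sequence lengths are
#' supplied, sequence coverage (existing residues / reference length, minimum
#' over chains) must reach 0.9; without references the coverage check passes.
#' Evaluation stage: 20 <= total polymer residues <= 1000.
#'
#' @param complex a `nuc_complex`.
#' @param stage `"dataset"` or `"evaluation"`.
#' @param reference_lengths optional named numeric vector of reference
#'   sequence lengths per chain id.
#' @return A list with `accept` (logical) and `reasons` (character vector of
#'   failed clauses, empty when accepted).
#' @export
entry_filter <- function(complex, stage = c("dataset", "evaluation"),
                         reference_lengths = NULL) {
  stage <- match.arg(stage)
  r <- complex$residues
  reasons <- character(0)
  n_total <- nrow(r)
  if (stage == "evaluation") {
    if (n_total < 20) reasons <- c(reasons, "fewer than 20 polymer residues")
    if (n_total > 1000) reasons <- c(reasons, "more than 1000 polymer residues")
  } else {
    heavy <- sum(!.is_hydrogen(complex$atoms$elety))
    if (heavy < 100) reasons <- c(reasons, "heavy-atom count < 100")
    if (!is.na(complex$resolution) && complex$resolution > 3.5)
      reasons <- c(reasons, "resolution > 3.5 A")
    tab <- sort(table(r$res_name), decreasing = TRUE)
    if (length(tab) && names(tab)[1] == "UNK" && tab[1] > 20)
      reasons <- c(reasons, "most frequent residue is UNK (> 20 occurrences)")
    is_na_res <- r$polymer_class %in% c("DNA", "RNA")
    if (!any(is_na_res)) reasons <- c(reasons, "no nucleic acid chain")
    if (!any(is_na_res & r$exists))
      reasons <- c(reasons, "no nucleic residue with full backbone occupancy")
    if (n_total > 6000) reasons <- c(reasons, "more than 6000 polymer residues")
    if (!is.null(reference_lengths)) {
      cov <- vapply(names(reference_lengths), function(cid) {
        sum(r$chain_id == cid & r$exists) / reference_lengths[[cid]]
      }, 0)
      if (length(cov) && min(cov) < 0.9)
        reasons <- c(reasons, "sequence coverage < 0.9")
    }
  }
  list(accept = length(reasons) == 0L, reasons = reasons, stage = stage)
}

# interface mask ---------------------------------------------------------------

.rep_atom_name <- function(polymer_class) {
  ifelse(polymer_class == "protein", "CA", "C1'")
}

# N x 3 matrix of representative-atom coordinates (NA rows when missing).
representative_coords <- function(complex) {
  r <- complex$residues
  a <- complex$atoms
  akey <- paste(a$chain_id, a$res_index, a$elety, sep = "\r")
  want <- paste(r$chain_id, r$res_index, .rep_atom_name(r$polymer_class),
                sep = "\r")
  m <- match(want, akey)
  cbind(a$x[m], a$y[m], a$z[m])
}

#' Side-chain interface mask between protein and nucleic acid residues
#'
#' A protein residue is flagged when any of its side-chain atoms lies within
#' `cutoff` of a side-chain atom of a nucleic residue among its `knn_limit`
#' nearest residues (representative atoms: C-alpha for protein, C1' for
#' nucleic acids), and symmetrically for nucleic residues. Residues lacking
#' their representative atom are excluded from the neighbor search and are
#' never flagged.
#'
#' @param complex a `nuc_complex`.
#' @param cutoff contact distance in Angstrom (default 5).
#' @param knn_limit number of nearest residues searched (default 48; `Inf`
#'   searches all pairs).
#' @return Logical vector aligned to `complex$residues`.
#' @export
interface_mask <- function(complex, cutoff = 5, knn_limit = 48) {
  r <- complex$residues
  n <- nrow(r)
  flag <- rep(FALSE, n)
  rep_xyz <- representative_coords(complex)
  ok <- stats::complete.cases(rep_xyz)
  if (sum(ok) < 2) return(flag)
  a <- complex$atoms[complex$atoms$is_sidechain, , drop = FALSE]
  if (nrow(a) == 0L) return(flag)
  akey <- paste(a$chain_id, a$res_index, sep = "\r")
  rkey <- paste(r$chain_id, r$res_index, sep = "\r")
  sc_by_res <- split(seq_len(nrow(a)), factor(akey, levels = rkey))
  is_prot <- r$polymer_class == "protein"
  is_nuc <- r$polymer_class %in% c("DNA", "RNA")
  idx_ok <- which(ok)
  d2 <- as.matrix(stats::dist(rep_xyz[idx_ok, , drop = FALSE]))
  for (ii in seq_along(idx_ok)) {
    i <- idx_ok[ii]
    sci <- sc_by_res[[rkey[i]]]
    if (length(sci) == 0L) next
    ord <- order(d2[ii, ])
    ord <- ord[ord != ii]
    if (is.finite(knn_limit)) ord <- utils::head(ord, knn_limit)
    nbr <- idx_ok[ord]
    opp <- if (is_prot[i]) nbr[is_nuc[nbr]] else if (is_nuc[i]) nbr[is_prot[nbr]] else integer(0)
    for (j in opp) {
      scj <- sc_by_res[[rkey[j]]]
      if (length(scj) == 0L) next
      pi <- as.matrix(a[sci, c("x", "y", "z")])
      pj <- as.matrix(a[scj, c("x", "y", "z")])
      dmin <- sqrt(max(0, min(outer(rowSums(pi^2), rowSums(pj^2), "+") -
                                2 * pi %*% t(pj))))
      if (dmin <= cutoff) { flag[i] <- TRUE; break }
    }
  }
  flag
}
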