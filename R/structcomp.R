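# Crystal-structure comparison.
#
# Atom records are parsed with bio3d; CRYST1 and REMARK 290 symmetry
# operators (given by the PDB in orthogonal-Angstrom space) are read
# directly from the file so that assemblies are bit-traceable to the
# deposited entry rather than to an embedded space-group library.

.identity_op <- function(op, tol = 1e-9) {
  all(abs(op[, 1:3] - diag(3)) < tol) && all(abs(op[, 4]) < tol)
}

#' Read a crystal structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), the CRYST1 unit cell and any
#' REMARK 290 crystallographic symmetry operators. Alternate locations
#' are resolved by keeping the highest-occupancy conformer (ties broken
#' toward the alphabetically first altloc).
#'
#' @param source path to a PDB-format file.
#' @param id identifier for the model; defaults to the file name.
#' @return an object of class `structure_model`: list with `id`,
#'   `atoms` (a data.frame in bio3d column layout), `cell` (lengths,
#'   angles, space group; `NULL` without CRYST1) and `symmetry` (list
#'   of 3x4 rotation|translation matrices in orthogonal Angstroms;
#'   empty without REMARK 290).
#' @export
read_structure <- function(source, id = sub("\\.pdb$", "", basename(source))) {
  lines <- readLines(source, warn = FALSE)
  atom_lines <- grep("^(ATOM  |HETATM)", lines)
  if (!length(atom_lines))
    stop("'", source, "' contains no ATOM/HETATM records")
  for (ln in atom_lines) {
    xyz <- substring(lines[ln], c(31, 39, 47), c(38, 46, 54))
    if (anyNA(suppressWarnings(as.numeric(xyz))))
      stop("malformed coordinate field at line ", ln, " of '", source, "'")
  }
  pdb <- bio3d::read.pdb(source, verbose = FALSE, rm.alt = FALSE)
  atoms <- pdb$atom
  # altloc resolution: best occupancy per (chain, resno, insert, atom name)
  alt <- atoms$alt
  alt[is.na(alt)] <- ""
  has_alt <- alt != ""
  if (any(has_alt)) {
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety,
                 sep = "|")
    keep <- rep(TRUE, nrow(atoms))
    for (k in unique(key[has_alt])) {
      idx <- which(key == k)
      if (length(idx) < 2L) next
      occ <- atoms$o[idx]
      occ[is.na(occ)] <- 0
      best <- idx[order(-occ, alt[idx])][1]
      keep[setdiff(idx, best)] <- FALSE
    }
    atoms <- atoms[keep, ]
  }
  rownames(atoms) <- NULL

  cell <- NULL
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr)) {
    cr <- cr[1]
    cell <- list(
      lengths = as.numeric(substring(cr, c(7, 16, 25), c(15, 24, 33))),
      angles = as.numeric(substring(cr, c(34, 41, 48), c(40, 47, 54))),
      spacegroup = trimws(substring(cr, 56, 66))
    )
  }

  sym <- list()
  smtry <- grep("^REMARK 290   SMTRY", lines, value = TRUE)
  if (length(smtry)) {
    rowno <- as.integer(substring(smtry, 19, 19))
    opno <- as.integer(substring(smtry, 20, 23))
    vals <- t(vapply(smtry, function(l)
      as.numeric(strsplit(trimws(substring(l, 24)), "\\s+")[[1]]),
      numeric(4), USE.NAMES = FALSE))
    for (k in sort(unique(opno))) {
      m <- matrix(NA_real_, 3, 4)
      for (r in 1:3) m[r, ] <- vals[which(opno == k & rowno == r)[1], ]
      if (anyNA(m)) stop("incomplete REMARK 290 operator ", k,
                         " in '", source, "'")
      sym[[k]] <- m
    }
  }

  structure(list(id = id, atoms = atoms, cell = cell, symmetry = sym),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  prot <- x$atoms[x$atoms$type == "ATOM", ]
  cat(sprintf("<structure_model> %s: %d atoms, chains %s, %d HETATM, %d symmetry op(s)%s\n",
              x$id, nrow(x$atoms),
              paste(unique(prot$chain), collapse = ""),
              sum(x$atoms$type == "HETATM"), length(x$symmetry),
              if (!is.null(x$cell))
                paste0(", space group ", x$cell$spacegroup) else ""))
  invisible(x)
}

#' Select C-alpha coordinates from a chain
#'
#' One CA per residue over an author-numbering range, with optional
#' excluded sub-ranges; residues missing a CA are skipped and reported
#' in the `missing` attribute.
#'
#' @param model a [read_structure()] model.
#' @param chain chain identifier.
#' @param range inclusive `c(start, end)` residue range (default: whole
#'   chain).
#' @param excluded list of `c(start, end)` ranges to drop.
#' @return an n x 3 coordinate matrix ordered by residue number, with
#'   attributes `resno` (residue numbers) and `missing` (residues in
#'   range lacking a CA).
#' @export
select_calpha <- function(model, chain, range = NULL, excluded = list()) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  sel <- at$type == "ATOM" & at$chain == chain & at$elety == "CA"
  if (!any(sel)) stop("chain '", chain, "' has no CA atoms")
  at <- at[sel, ]
  if (is.null(range)) range <- range(at$resno)
  keep <- at$resno >= range[1] & at$resno <= range[2]
  for (ex in excluded)
    keep <- keep & !(at$resno >= ex[1] & at$resno <= ex[2])
  at <- at[keep, ]
  if (nrow(at) == 0L) stop("empty CA selection")
  at <- at[order(at$resno), ]
  wanted <- setdiff(seq(range[1], range[2]), unlist(lapply(excluded,
    function(ex) seq(ex[1], ex[2]))))
  miss <- setdiff(wanted, at$resno)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rownames(xyz) <- at$resno
  attr(xyz, "resno") <- at$resno
  attr(xyz, "missing") <- miss
  xyz
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation `R` and translation `t` minimizing the sum
#' of squared distances between paired points `A[i,]` and
#' `R %*% B[i,] + t`, by centering and singular-value decomposition with
#' the determinant correction that excludes reflections.
#'
#' @param A,B n x 3 coordinate matrices with matched rows, n >= 3 and
#'   not collinear.
#' @return an object of class `superposition`: list with `rotation`
#'   (3x3, orthonormal, det +1), `translation` (length-3), `rmsd` (in
#'   the units of the coordinates), `n_atoms` and `paired_residues`
#'   (row labels of `A` if present).
#' @export
kabsch_superpose <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("coordinate sets differ in size")
  if (ncol(A) != 3L) stop("coordinates must be n x 3")
  n <- nrow(A)
  if (n < 3L) stop("need at least 3 paired atoms")
  if (anyNA(A) || anyNA(B) || any(!is.finite(A)) || any(!is.finite(B)))
    stop("coordinates must be finite")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  if (qr(Ac)$rank < 2L || qr(Bc)$rank < 2L)
    stop("degenerate (collinear) coordinate set")
  H <- crossprod(Bc, Ac)               # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tvec <- ca - as.vector(R %*% cb)
  resid <- Ac - Bc %*% t(R)
  rmsd <- sqrt(sum(resid^2) / n)
  structure(list(rotation = R, translation = tvec, rmsd = rmsd,
                 n_atoms = n, paired_residues = rownames(A)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d atoms, r.m.s.d. %.3f\n", x$n_atoms, x$rmsd))
  invisible(x)
}

#' Pairwise r.m.s.d. matrix of chain selections
#'
#' Superposes every unordered pair of entries over the residues common
#' to both selections and tabulates the r.m.s.d. values.
#'
#' @param entries list of entries, each a list with elements `model`
#'   (a [read_structure()] model), `chain`, and optionally `range`,
#'   `excluded` and `label`.
#' @return a symmetric labelled matrix of r.m.s.d. values (diagonal 0).
#' @export
rmsd_matrix <- function(entries) {
  if (length(entries) < 2L) stop("need at least 2 entries")
  sels <- lapply(entries, function(e)
    select_calpha(e$model, e$chain,
                  range = e$range, excluded = e$excluded %||% list()))
  labels <- vapply(seq_along(entries), function(i)
    entries[[i]]$label %||% paste0(entries[[i]]$model$id, ":",
                                   entries[[i]]$chain), character(1))
  n <- length(entries)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ri <- attr(sels[[i]], "resno"); rj <- attr(sels[[j]], "resno")
    common <- intersect(ri, rj)
    if (length(common) < 3L)
      stop("pair ", labels[i], " / ", labels[j],
           ": fewer than 3 common residues")
    sp <- kabsch_superpose(sels[[i]][match(common, ri), , drop = FALSE],
                           sels[[j]][match(common, rj), , drop = FALSE])
    m[i, j] <- m[j, i] <- sp$rmsd
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalized per-residue B-factor profile
#'
#' Per residue, the mean B-factor over backbone atoms; profiles are
#' averaged across the chains of the asymmetric unit (matched by
#' residue number) and normalized by their grand mean, so the profile
#' averages exactly 1 and is invariant to uniform B rescaling.
#'
#' @param model a [read_structure()] model.
#' @param atom_names backbone atom set (default N, CA, C, O).
#' @param chains chains to include (default: all protein chains).
#' @return an object of class `bfactor_profile`: data.frame with
#'   columns `resno` and `rel_b`, with attribute `averaged_over`.
#' @export
normalized_bfactor_profile <- function(model,
                                       atom_names = c("N", "CA", "C", "O"),
                                       chains = NULL) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  at <- at[at$type == "ATOM" & at$elety %in% atom_names, ]
  if (!is.null(chains)) at <- at[at$chain %in% chains, ]
  if (nrow(at) == 0L) stop("no backbone atoms in selection")
  if (all(is.na(at$b))) stop("no B-factors present")
  per_res <- stats::aggregate(b ~ chain + resno, data = at, FUN = mean)
  prof <- stats::aggregate(b ~ resno, data = per_res, FUN = mean)
  prof$rel_b <- prof$b / mean(prof$b)
  out <- data.frame(resno = prof$resno, rel_b = prof$rel_b)
  structure(out, class = c("bfactor_profile", "data.frame"),
            averaged_over = sort(unique(per_res$chain)))
}

#' Plot a B-factor profile
#'
#' @param x a [normalized_bfactor_profile()] result.
#' @param ... passed to [graphics::plot()].
#' @exportS3Method graphics::plot
plot.bfactor_profile <- function(x, ...) {
  graphics::plot(x$resno, x$rel_b, type = "l", xlab = "residue",
                 ylab = "relative backbone B-factor", ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Expand a model by crystallographic symmetry operators
#'
#' Applies each 3x4 rotation|translation operator (orthogonal-Angstrom
#' space, as in REMARK 290) to the selected chains. Identity operators
#' reproduce the input chains unchanged; each non-identity operator's
#' copies get primed chain ids (A -> A', A'', ...). Used to complete
#' the calsequestrin hexamer from its half-hexamer asymmetric unit.
#'
#' @param model a [read_structure()] model.
#' @param operators list of 3x4 matrices; defaults to the model's
#'   REMARK 290 operators.
#' @param chains chains to expand (default: all).
#' @return a new `structure_model` holding all transformed copies.
#' @export
expand_symmetry <- function(model, operators = model$symmetry,
                            chains = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (!length(operators))
    stop("no symmetry operators available; supply 3x4 orthogonal-space ",
         "matrices via `operators`")
  at <- model$atoms
  if (!is.null(chains)) at <- at[at$chain %in% chains, ]
  if (nrow(at) == 0L) stop("no atoms selected for expansion")
  copies <- list()
  n_nonid <- 0L
  for (k in seq_along(operators)) {
    op <- operators[[k]]
    if (!is.matrix(op) || !all(dim(op) == c(3, 4)))
      stop("operator ", k, " is not a 3x4 matrix")
    cp <- at
    if (.identity_op(op)) {
      # leave coordinates and chain ids untouched
    } else {
      n_nonid <- n_nonid + 1L
      xyz <- as.matrix(cp[, c("x", "y", "z")]) %*% t(op[, 1:3])
      xyz <- sweep(xyz, 2, op[, 4], "+")
      cp$x <- xyz[, 1]; cp$y <- xyz[, 2]; cp$z <- xyz[, 3]
      cp$chain <- paste0(cp$chain, strrep("'", n_nonid))
    }
    copies[[k]] <- cp
  }
  atoms <- do.call(rbind, copies)
  atoms$eleno <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  structure(list(id = paste0(model$id, "_assembly"), atoms = atoms,
                 cell = model$cell, symmetry = model$symmetry),
            class = "structure_model")
}

#' Count ions of an element in a model
#'
#' Counts HETATM atoms whose element symbol matches, optionally
#' restricted to chains and optionally occupancy-weighted. With
#' `element = "CA"` this counts crystallographic calcium ions.
#'
#' @param model a [read_structure()] model (or an [expand_symmetry()]
#'   assembly).
#' @param element element symbol (case-insensitive), default `"CA"`.
#' @param chains optional chain subset.
#' @param occupancy_weighted if `TRUE`, sum occupancies instead of
#'   counting atoms.
#' @return a count (numeric when occupancy-weighted).
#' @export
count_ions <- function(model, element = "CA", chains = NULL,
                       occupancy_weighted = FALSE) {
  stopifnot(inherits(model, "structure_model"))
  if (!is.character(element) || !nzchar(element))
    stop("element must be a non-empty symbol")
  at <- model$atoms
  at <- at[at$type == "HETATM", ]
  if (!is.null(chains)) at <- at[at$chain %in% chains, ]
  elesy <- toupper(trimws(at$elesy))
  elesy[is.na(elesy)] <- ""
  hit <- at[elesy == toupper(element), ]
  if (occupancy_weighted) {
    o <- hit$o
    o[is.na(o)] <- 1
    sum(o)
  } else {
    nrow(hit)
  }
}

#' Write a model back out as PDB
#'
#' Minimal ATOM/HETATM writer for assemblies; multi-character chain ids
#' produced by [expand_symmetry()] are remapped to single letters
#' (recorded in a remark).
#'
#' @param model a `structure_model`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  chains <- unique(at$chain)
  pool <- c(LETTERS, letters, 0:9)
  if (any(nchar(chains) > 1L) || length(chains) > length(pool)) {
    map <- stats::setNames(pool[seq_along(chains)], chains)
  } else {
    map <- stats::setNames(chains, chains)
  }
  lines <- character(0)
  if (any(map != names(map)))
    lines <- c(lines, paste0("REMARK 300 CHAIN MAP ",
                             paste(names(map), map, sep = "->",
                                   collapse = " ")))
  o <- at$o; o[is.na(o)] <- 1
  b <- at$b; b[is.na(b)] <- 0
  lines <- c(lines, sprintf(
    "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    at$type, seq_len(nrow(at)) %% 100000,
    ifelse(nchar(at$elety) < 4, paste0(" ", at$elety), at$elety),
    "", at$resid, map[at$chain], at$resno,
    ifelse(is.na(at$insert) | at$insert == "", " ", at$insert),
    at$x, at$y, at$z, o, b, toupper(trimws(at$elesy))), "END")
  writeLines(lines, path)
  invisible(path)
}
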