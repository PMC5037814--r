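# Pairwise sequence comparison.
#
# Global (end-to-end) affine-gap alignment with BLOSUM62 and percent
# identity/similarity in the Clustal convention: identities are
# identical columns, similarities additionally count substitutions
# within Clustal "strong" groups (the colon-marked pairs of an
# alignment printout). The percent denominator defaults to the length
# of the shorter sequence and is configurable, as published identity
# tables rarely state their convention.

.clustal_strong_groups <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK",
                            "MILV", "MILF", "HY", "FYW")

.check_protein <- function(x, what) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), .aa_alphabet)
  if (length(bad))
    stop("illegal residue(s) in ", what, ": ", paste(bad, collapse = ", "))
  invisible(x)
}

#' Global pairwise alignment
#'
#' Optimal end-to-end alignment under an affine gap model (gap of
#' length L costs `gap_open + L * gap_extend`).
#'
#' @param a,b amino-acid strings (standard 20 residues).
#' @param submat substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties (positive costs;
#'   defaults 10 and 0.5).
#' @param denominator convention for percentages: `"shorter"` (length
#'   of the shorter sequence, default), `"alignment"` (alignment
#'   length) or `"mean"` (mean sequence length).
#' @return an object of class `alignment_result`: list with
#'   `aligned_a`, `aligned_b` (gapped strings of equal length),
#'   `score`, `identity_pct`, `similarity_pct`.
#' @export
global_align <- function(a, b, submat = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5, denominator = "shorter") {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  a <- toupper(a); b <- toupper(b)
  .check_protein(a, "first sequence")
  .check_protein(b, "second sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend)
  aligned_a <- as.character(Biostrings::alignedPattern(aln))
  aligned_b <- as.character(Biostrings::alignedSubject(aln))
  pct <- identity_similarity(aligned_a, aligned_b,
                             denominator = denominator)
  structure(list(aligned_a = unname(aligned_a),
                 aligned_b = unname(aligned_b),
                 score = Biostrings::score(aln),
                 identity_pct = pct[["identity"]],
                 similarity_pct = pct[["similarity"]],
                 params = list(submat = submat, gap_open = gap_open,
                               gap_extend = gap_extend,
                               denominator = denominator)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment> score %.1f, identity %.2f%%, similarity %.2f%%\n",
              x$score, x$identity_pct, x$similarity_pct))
  invisible(x)
}

#' Percent identity and similarity of an alignment
#'
#' Identity counts identical non-gap columns; similarity additionally
#' counts substitutions within a conserved group (default: Clustal
#' strong groups, the colon convention).
#'
#' @param aligned_a,aligned_b gapped strings of equal length, or pass a
#'   single `alignment_result` as `aligned_a`.
#' @param groups character vector of conserved-substitution groups.
#' @param denominator `"shorter"`, `"alignment"` or `"mean"` (see
#'   [global_align()]).
#' @return named numeric vector `c(identity=, similarity=)` in percent.
#' @export
identity_similarity <- function(aligned_a, aligned_b = NULL,
                                groups = .clustal_strong_groups,
                                denominator = c("shorter", "alignment",
                                                "mean")) {
  denominator <- match.arg(denominator)
  if (inherits(aligned_a, "alignment_result")) {
    aligned_b <- aligned_a$aligned_b
    aligned_a <- aligned_a$aligned_a
  }
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) stop("aligned strings differ in length")
  nongap <- ca != "-" & cb != "-"
  ident <- nongap & ca == cb
  same_group <- nongap & !ident & mapply(function(x, y)
    any(vapply(groups, function(g)
      grepl(x, g, fixed = TRUE) && grepl(y, g, fixed = TRUE), logical(1))),
    ca, cb)
  den <- switch(denominator,
                shorter = min(sum(ca != "-"), sum(cb != "-")),
                alignment = length(ca),
                mean = mean(c(sum(ca != "-"), sum(cb != "-"))))
  c(identity = 100 * sum(ident) / den,
    similarity = 100 * (sum(ident) + sum(same_group)) / den)
}

#' Pairwise identity/similarity matrix
#'
#' All unordered pairs of records aligned with [global_align()];
#' diagonal (100, 100).
#'
#' @param records list of [sequence_record()]s (>= 2).
#' @param ... passed to [global_align()].
#' @return a list with symmetric labelled matrices `identity` and
#'   `similarity`, class `identity_matrix`.
#' @export
identity_matrix <- function(records, ...) {
  if (length(records) < 2L) stop("need at least 2 records")
  labels <- vapply(records, function(r) r$id, character(1))
  n <- length(records)
  id <- sim <- matrix(100, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    aln <- global_align(records[[i]]$residues, records[[j]]$residues, ...)
    id[i, j] <- id[j, i] <- aln$identity_pct
    sim[i, j] <- sim[j, i] <- aln$similarity_pct
  }
  structure(list(identity = id, similarity = sim),
            class = "identity_matrix")
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat("Percent identity (similarity):\n")
  n <- nrow(x$identity)
  out <- matrix(sprintf("%.2f (%.2f)", x$identity, x$similarity), n, n,
                dimnames = dimnames(x$identity))
  print(out, quote = FALSE)
  invisible(x)
}

#' Write an identity/similarity matrix as delimited text
#'
#' Tab-separated cells of the form `identity (similarity)`.
#'
#' @param x an [identity_matrix()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_identity_matrix <- function(x, path) {
  stopifnot(inherits(x, "identity_matrix"))
  n <- nrow(x$identity)
  cells <- matrix(sprintf("%.2f (%.2f)", x$identity, x$similarity), n, n,
                  dimnames = dimnames(x$identity))
  utils::write.table(cells, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Packaged calsequestrin PTM-site annotations
#'
#' Curated modification sites for mammalian calsequestrin isoforms in
#' mature-protein numbering: the conserved N-glycosylation sequon at
#' Asn316 and the C-terminal phosphoserines of the cardiac isoform.
#'
#' @return data.frame with columns `species`, `isoform`, `glyco_asn`,
#'   `phospho_sites` (comma-separated residue numbers; empty when
#'   unphosphorylated) and `note`.
#' @export
ptm_annotations <- function() {
  path <- system.file("extdata", "casq_ptm_sites.tsv",
                      package = "casqtools", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "",
                    quote = "")
}
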