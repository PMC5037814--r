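# FASTA input and in-silico CNBr fragmentation.
#
# CNBr cleaves C-terminal to methionine; the cleaved Met is converted to
# homoserine lactone (default) or homoserine. Positions are reported in
# mature-protein numbering: index in the loaded sequence minus
# `numbering_offset` (0 when the record already starts at the mature
# N-terminus; the length of the signal peptide when a precursor was
# loaded).

.aa_alphabet <- names(.residue_formulas)

#' Construct a protein sequence record
#'
#' @param id record identifier.
#' @param residues one-letter amino-acid string (standard 20 residues;
#'   lower case accepted and uppercased).
#' @param description free-text description.
#' @param numbering_offset residues to subtract from 1-based sequence
#'   indices to obtain mature-protein numbering (0 if the record starts
#'   at the mature N-terminus).
#' @return an object of class `sequence_record`.
#' @export
sequence_record <- function(id, residues, description = "",
                            numbering_offset = 0L) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("id must be a non-empty string")
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues))
    stop("residues must be a non-empty string")
  residues <- toupper(residues)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), .aa_alphabet)
  if (length(bad))
    stop("illegal residue character(s) in '", id, "': ",
         paste(bad, collapse = ", "))
  structure(list(id = id, description = description, residues = residues,
                 numbering_offset = as.integer(numbering_offset)),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s (%d aa%s)\n", x$id, nchar(x$residues),
              if (x$numbering_offset != 0)
                sprintf(", numbering offset %d", x$numbering_offset) else ""))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' @param source path to a FASTA file.
#' @param numbering_offset passed to each record (see
#'   [sequence_record()]).
#' @return a list of `sequence_record`s in file order.
#' @export
read_fasta <- function(source, numbering_offset = 0L) {
  set <- tryCatch(Biostrings::readAAStringSet(source),
                  error = function(e) stop("cannot read FASTA '", source,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA file '", source, "' contains no records")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mapply(function(id, desc, seq)
    sequence_record(id, seq, desc, numbering_offset),
    ids, descs, as.character(set), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' In-silico CNBr digestion
#'
#' Cuts the sequence C-terminal to every methionine. Fully cleaved
#' (0-missed) peptides tile the parent exactly; peptides with up to
#' `max_missed` internal Met are also emitted, each once. Every peptide
#' ending in Met carries the chosen homoserine C-terminal chemistry; the
#' parent's C-terminal peptide (unless it ends in Met) stays intact.
#'
#' @param record a [sequence_record()].
#' @param max_missed maximum number of internal (missed) Met cleavage
#'   points per peptide; default 1, reflecting routinely incomplete
#'   CNBr digests.
#' @param cterm_chem chemistry applied at cleaved Met termini:
#'   `"homoserine_lactone"` (the dominant CNBr product, default) or
#'   `"homoserine"`.
#' @return a data.frame with columns `parent_id`, `start`, `end`
#'   (mature numbering, 1-based inclusive), `sequence`, `cterm_chem`,
#'   `missed_cleavages`.
#' @export
cnbr_digest <- function(record, max_missed = 1L,
                        cterm_chem = c("homoserine_lactone", "homoserine")) {
  stopifnot(inherits(record, "sequence_record"))
  cterm_chem <- match.arg(cterm_chem)
  max_missed <- as.integer(max_missed)
  if (is.na(max_missed) || max_missed < 0L) stop("max_missed must be >= 0")
  chars <- strsplit(record$residues, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cuts <- which(chars == "M")              # cut after each of these
  bounds <- unique(c(0L, cuts, n))         # fragment boundaries
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  nfrag <- length(starts)
  out <- list()
  for (i in seq_len(nfrag)) {
    for (j in i:min(nfrag, i + max_missed)) {
      s <- starts[i]; e <- ends[j]
      seq <- substr(record$residues, s, e)
      ends_in_met <- chars[e] == "M"
      out[[length(out) + 1L]] <- data.frame(
        parent_id = record$id,
        start = s - record$numbering_offset,
        end = e - record$numbering_offset,
        sequence = seq,
        cterm_chem = if (ends_in_met) cterm_chem else "intact",
        missed_cleavages = j - i,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

.sequon_positions <- function(residues) {
  # N-X-S/T with X != P; returns 1-based Asn indices
  m <- gregexpr("(?=N[^P][ST])", residues, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Peptides covering an N-glycosylation sequon
#'
#' Returns the peptides whose span fully covers at least one N-X-S/T
#' motif (X != Pro) of the parent, annotated with the sequon's Asn
#' position in mature numbering (one row per peptide-sequon pair). In
#' calsequestrin the conserved sequon is Asn316-Val-Thr.
#'
#' @param peptides data.frame from [cnbr_digest()].
#' @param parent the parent [sequence_record()].
#' @return subset of `peptides` with an added `sequon_asn` column;
#'   zero rows when no sequon exists.
#' @export
find_sequon_peptides <- function(peptides, parent) {
  stopifnot(inherits(parent, "sequence_record"))
  asn_idx <- .sequon_positions(parent$residues)
  asn_mature <- asn_idx - parent$numbering_offset
  out <- list()
  for (k in seq_len(nrow(peptides))) {
    p <- peptides[k, ]
    covered <- asn_mature[asn_mature >= p$start & asn_mature + 2L <= p$end]
    for (a in covered) {
      row <- p
      row$sequon_asn <- a
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) {
    res <- peptides[0, ]
    res$sequon_asn <- integer(0)
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' The C-terminal peptide of a digest
#'
#' Returns the unique fully cleaved (0-missed) peptide whose end
#' coincides with the parent's C-terminus — the peptide that carries
#' calsequestrin's phosphorylatable acidic tail.
#'
#' @param peptides data.frame from [cnbr_digest()].
#' @param parent the parent [sequence_record()].
#' @return a one-row data.frame.
#' @export
cterminal_peptide <- function(peptides, parent) {
  stopifnot(inherits(parent, "sequence_record"))
  if (is.null(peptides) || nrow(peptides) == 0L)
    stop("empty peptide list")
  last <- nchar(parent$residues) - parent$numbering_offset
  hit <- peptides[peptides$end == last & peptides$missed_cleavages == 0L, ]
  if (nrow(hit) != 1L)
    stop("peptide list lacks a unique 0-missed C-terminal peptide")
  rownames(hit) <- NULL
  hit
}

#' Peptide mass table as delimited text
#'
#' Writes the digest table with neutral monoisotopic and average masses
#' appended, tab-separated.
#'
#' @param peptides data.frame from [cnbr_digest()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  peptides$mono_mass <- mapply(peptide_neutral_mass, peptides$sequence,
                               peptides$cterm_chem,
                               MoreArgs = list(scale = "monoisotopic"))
  peptides$avg_mass <- mapply(peptide_neutral_mass, peptides$sequence,
                              peptides$cterm_chem,
                              MoreArgs = list(scale = "average"))
  utils::write.table(peptides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
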