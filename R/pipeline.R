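# End-to-end PTM report.
#
# One call takes a FASTA file plus one or more peak lists and produces
# the full characterization for each spectrum: digest table, the
# sequon-bearing or C-terminal peptide, composition assignments,
# ladder series, the glycoform profile and a phosphoform summary.
# Reports are deterministic for identical configuration and inputs
# (no timestamps in the payload) and record the package version and
# the full effective configuration.

#' Build a run configuration
#'
#' @param fasta path to the FASTA file with the analyte sequence(s).
#' @param peaklists list of per-spectrum entries, each a list with
#'   `path` and optionally `polarity` (`"positive"`/`"negative"`),
#'   `charge`, `scale` (`"monoisotopic"`/`"average"`), `peptide`
#'   (`"sequon"` or `"cterm"`) and `label`.
#' @param max_missed missed cleavages for [cnbr_digest()].
#' @param tolerance,snr_threshold passed to [assign_compositions()].
#' @param comp_space composition grid (default
#'   [default_comp_space()]).
#' @param ladder_steps,ladder_tolerance passed to [detect_ladders()].
#' @param numbering_offset passed to [read_fasta()].
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(fasta, peaklists, max_missed = 1L,
                       tolerance = 1.0, snr_threshold = 1.0,
                       comp_space = default_comp_space(),
                       ladder_steps = c("hexose", "phosphoryl"),
                       ladder_tolerance = 0.5, numbering_offset = 0L) {
  if (!file.exists(fasta)) stop("FASTA file not found: ", fasta)
  if (!length(peaklists)) stop("at least one peak list is required")
  if (tolerance <= 0) stop("tolerance must be positive")
  if (snr_threshold < 0) stop("snr_threshold must be >= 0")
  peaklists <- lapply(seq_along(peaklists), function(i) {
    e <- peaklists[[i]]
    if (is.null(e$path)) stop("peak list entry ", i, " lacks a path")
    if (!file.exists(e$path)) stop("peak list not found: ", e$path)
    e$polarity <- e$polarity %||% "negative"
    e$charge <- e$charge %||% 1L
    e$scale <- .check_scale(e$scale %||% "monoisotopic")
    e$peptide <- match.arg(e$peptide %||% "sequon", c("sequon", "cterm"))
    e$label <- e$label %||% basename(e$path)
    e
  })
  structure(list(fasta = fasta, peaklists = peaklists,
                 max_missed = as.integer(max_missed),
                 tolerance = tolerance, snr_threshold = snr_threshold,
                 comp_space = comp_space, ladder_steps = ladder_steps,
                 ladder_tolerance = ladder_tolerance,
                 numbering_offset = as.integer(numbering_offset)),
            class = "run_config")
}

#' Run the full PTM characterization pipeline
#'
#' For each configured spectrum: digest the (first) FASTA record with
#' CNBr, pick the sequon-bearing or C-terminal peptide, assign
#' glycoform/phosphoform compositions, detect mass ladders, and
#' profile accepted glycoforms and phosphoforms.
#'
#' @param config a [run_config()].
#' @return an object of class `ptm_report`.
#' @export
run_ptm_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  records <- read_fasta(config$fasta,
                        numbering_offset = config$numbering_offset)
  record <- records[[1]]
  digest <- cnbr_digest(record, max_missed = config$max_missed)
  sequon_peps <- find_sequon_peptides(digest, record)
  spectra <- lapply(config$peaklists, function(e) {
    pl <- read_peaklist(e$path,
                        mode = ion_mode(e$polarity, e$charge),
                        scale = e$scale, label = e$label)
    pep <- if (e$peptide == "sequon") {
      if (nrow(sequon_peps) == 0L)
        stop("spectrum '", e$label,
             "': no sequon-bearing peptide in the digest")
      sp <- sequon_peps[sequon_peps$missed_cleavages ==
                          min(sequon_peps$missed_cleavages), ]
      sp[1, setdiff(names(sp), "sequon_asn")]
    } else {
      cterminal_peptide(digest, record)
    }
    asg <- assign_compositions(pl, pep, comp_space = config$comp_space,
                               tolerance = config$tolerance,
                               snr_threshold = config$snr_threshold)
    ladders <- detect_ladders(pl, steps = config$ladder_steps,
                              tolerance = config$ladder_tolerance)
    profile <- if (any(asg$accepted)) glycoform_profile(asg) else NULL
    list(label = e$label, peptide = pep, assignments = asg,
         ladders = ladders, profile = profile,
         phospho = phospho_summary(asg))
  })
  structure(list(
    version = as.character(utils::packageVersion("casqtools")),
    config = config, record_id = record$id, digest = digest,
    spectra = spectra
  ), class = "ptm_report")
}

#' @export
print.ptm_report <- function(x, ...) {
  cat(sprintf("PTM report for %s (casqtools %s)\n", x$record_id,
              x$version))
  cat(sprintf("  digest: %d peptides (max %d missed cleavages)\n",
              nrow(x$digest), x$config$max_missed))
  for (sp in x$spectra) {
    cat(sprintf("  spectrum %s: peptide %d-%d, %d/%d compositions accepted",
                sp$label, sp$peptide$start, sp$peptide$end,
                sum(sp$assignments$accepted), nrow(sp$assignments)))
    if (!is.null(sp$profile))
      cat(", major form ", format(sp$profile$major_form), sep = "")
    cat("\n")
    if (nrow(sp$phospho))
      cat("    phosphoforms: ",
          paste(sprintf("%dP (%.0f%%)", sp$phospho$n_phos,
                        100 * sp$phospho$fraction), collapse = ", "),
          "\n", sep = "")
  }
  invisible(x)
}

.report_payload <- function(report) {
  list(
    version = report$version,
    settings = list(
      fasta = report$config$fasta,
      max_missed = report$config$max_missed,
      tolerance = report$config$tolerance,
      snr_threshold = report$config$snr_threshold,
      ladder_steps = as.list(report$config$ladder_steps),
      ladder_tolerance = report$config$ladder_tolerance
    ),
    record = report$record_id,
    n_peptides = nrow(report$digest),
    spectra = lapply(report$spectra, function(sp) {
      list(
        label = sp$label,
        peptide = list(start = sp$peptide$start, end = sp$peptide$end,
                       sequence = sp$peptide$sequence,
                       cterm_chem = sp$peptide$cterm_chem),
        assignments = as.data.frame(sp$assignments),
        ladders = lapply(sp$ladders, function(l)
          list(step = l$step, base_peak_mz = l$base_peak_mz,
               member_mzs = l$member_mzs)),
        major_form = if (!is.null(sp$profile))
          format(sp$profile$major_form) else NULL,
        relative_heights = if (!is.null(sp$profile))
          sp$profile$table else NULL,
        phosphoforms = sp$phospho
      )
    })
  )
}

#' Write a PTM report to disk
#'
#' Emits `report.json` (machine-readable, deterministic for identical
#' inputs) and `report.txt` (the printed summary) into a directory.
#'
#' @param report a [run_ptm_report()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_ptm_report <- function(report, dir) {
  stopifnot(inherits(report, "ptm_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(.report_payload(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
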