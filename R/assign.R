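# Glycoform/phosphoform assignment of MALDI peak lists.
#
# The inference is deliberately simple and auditable: enumerate a finite
# composition space (HexNAc, Hex, phosphoryl counts), compute each
# composition's expected ion m/z from the peptide's neutral mass, match
# the nearest observed peak within a mass tolerance, and accept the
# assignment when the peak's signal-to-noise ratio exceeds a threshold
# (default: S/N > 1.0). Each observed peak is used at most once.

#' Construct a MALDI peak list
#'
#' @param mz numeric vector of m/z values (> 0).
#' @param intensity numeric vector of intensities (>= 0).
#' @param noise optional per-peak noise estimates (> 0); `NA` where
#'   unknown (fill with [estimate_snr()]).
#' @param mode an [ion_mode()]: polarity and charge the list was
#'   acquired in.
#' @param scale mass scale the m/z axis is read on: `"monoisotopic"`
#'   (reflector mode) or `"average"` (linear mode).
#' @param label free-text label for reports.
#' @return an object of class `peaklist`; peaks sorted by ascending m/z.
#' @export
peaklist <- function(mz, intensity, noise = NULL,
                     mode = ion_mode("positive"),
                     scale = "monoisotopic", label = "") {
  scale <- .check_scale(scale)
  if (!inherits(mode, "ion_mode")) stop("mode must be an ion_mode object")
  if (length(mz) == 0L) stop("peak list must be non-empty")
  if (length(intensity) != length(mz))
    stop("mz and intensity lengths differ")
  if (anyNA(mz) || anyNA(intensity))
    stop("non-numeric or missing mz/intensity values")
  if (any(mz <= 0)) stop("all mz values must be positive")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (is.null(noise)) noise <- rep(NA_real_, length(mz))
  if (length(noise) != length(mz)) stop("noise length differs from mz")
  if (any(!is.na(noise) & noise <= 0)) stop("noise values must be positive")
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]; noise <- noise[ord]
  if (any(diff(mz) < 1e-6))
    stop("duplicate mz values (within 1e-6)")
  structure(list(
    peaks = data.frame(mz = mz, intensity = intensity, noise = noise),
    mode = mode, scale = scale, label = label
  ), class = "peaklist")
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("<peaklist> %s: %d peaks, %.1f-%.1f m/z, %s %s (z=%d)\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              nrow(x$peaks), min(x$peaks$mz), max(x$peaks$mz),
              x$mode$polarity, x$scale, x$mode$charge))
  invisible(x)
}

#' Read a peak list from delimited text
#'
#' Expects a header with columns `mz`, `intensity` and optionally
#' `noise`; comma- or tab-separated.
#'
#' @param source file path.
#' @inheritParams peaklist
#' @return a [peaklist()].
#' @export
read_peaklist <- function(source, mode = ion_mode("positive"),
                          scale = "monoisotopic", label = source) {
  first <- readLines(source, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  df <- utils::read.table(source, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("mz", "intensity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("peak list '", source, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  for (col in intersect(c("mz", "intensity", "noise"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) && !anyNA(df[[col]]))
      stop("non-numeric values in column '", col, "' of '", source, "'")
    df[[col]] <- v
  }
  peaklist(df$mz, df$intensity,
           noise = if ("noise" %in% names(df)) df$noise else NULL,
           mode = mode, scale = scale, label = label)
}

#' Write a peak list as delimited text
#'
#' @param pl a [peaklist()].
#' @param path output path.
#' @param sep field separator (default comma).
#' @return the path, invisibly.
#' @export
write_peaklist <- function(pl, path, sep = ",") {
  stopifnot(inherits(pl, "peaklist"))
  df <- pl$peaks
  if (all(is.na(df$noise))) df$noise <- NULL
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Estimate per-peak noise and signal-to-noise ratios
#'
#' Where a peak has no explicit noise value, the noise is estimated as
#' the median intensity of the other peaks within `window/2` on either
#' side (falling back to all other peaks if that window is empty),
#' floored at a small positive epsilon. S/N = intensity / noise.
#'
#' @param pl a [peaklist()].
#' @param window full width, in Da, of the local median window.
#' @return the peak list with `noise` filled and an `snr` column added.
#' @export
estimate_snr <- function(pl, window = 200) {
  stopifnot(inherits(pl, "peaklist"))
  if (window <= 0) stop("window must be positive")
  pk <- pl$peaks
  need <- which(is.na(pk$noise))
  if (length(need) && nrow(pk) == 1L)
    stop("cannot estimate noise for a single-peak list without a noise column")
  eps <- 1e-9
  for (i in need) {
    others <- setdiff(which(abs(pk$mz - pk$mz[i]) <= window / 2), i)
    if (!length(others)) others <- setdiff(seq_len(nrow(pk)), i)
    pk$noise[i] <- max(stats::median(pk$intensity[others]), eps)
  }
  pk$snr <- pk$intensity / pk$noise
  pl$peaks <- pk
  pl
}

#' Default modification composition space
#'
#' The grid searched by [assign_compositions()]: HexNAc counts 0 and 2
#' (high-mannose glycans carry a GlcNAc2 core; 1 is searched optionally
#' for truncated forms), 0-9 mannoses, 0-3 phosphoryls.
#'
#' @param n_hexnac,n_hex,n_phos integer vectors of counts to combine.
#' @return a data.frame grid of compositions.
#' @export
default_comp_space <- function(n_hexnac = c(0L, 2L), n_hex = 0:9,
                               n_phos = 0:3) {
  g <- expand.grid(n_hexnac = n_hexnac, n_hex = n_hex, n_phos = n_phos,
                   KEEP.OUT.ATTRS = FALSE)
  # a glycan needs its core: drop hex > 0 with hexnac == 0
  g <- g[!(g$n_hexnac == 0L & g$n_hex > 0L), ]
  rownames(g) <- NULL
  g
}

.peptide_fields <- function(peptide) {
  if (is.character(peptide))
    return(list(sequence = peptide, cterm_chem = "intact",
                label = peptide))
  if (is.data.frame(peptide) && nrow(peptide) == 1L)
    return(list(sequence = peptide$sequence,
                cterm_chem = peptide$cterm_chem,
                label = sprintf("%s %d-%d", peptide$parent_id,
                                peptide$start, peptide$end)))
  stop("peptide must be a sequence string or a one-row digest table")
}

#' Assign glycoform/phosphoform compositions to a peak list
#'
#' For every composition in `comp_space`, the expected ion m/z is the
#' peptide's neutral mass plus the composition's mass delta, ionized per
#' the peak list's polarity/charge. The nearest observed peak within
#' `tolerance` yields an assignment; assignments are accepted when the
#' peak's S/N exceeds `snr_threshold` (strictly). Each observed peak is
#' matched at most once — ties are broken by smaller |error|, then fewer
#' total modifications, then lower theoretical m/z. Compositions whose
#' expected m/z coincide within 1e-6 are flagged ambiguous.
#'
#' @param pl a [peaklist()]; noise/S/N filled via [estimate_snr()] if
#'   absent.
#' @param peptide a one-row data.frame from [cnbr_digest()] or a plain
#'   sequence string (intact C-terminus).
#' @param comp_space data.frame of compositions (columns `n_hexnac`,
#'   `n_hex`, `n_phos`); default [default_comp_space()].
#' @param tolerance matching half-window in Da (default 1.0).
#' @param snr_threshold acceptance threshold; accepted iff S/N >
#'   threshold (default 1.0).
#' @param snr_window window passed to [estimate_snr()] when noise is
#'   missing.
#' @return an object of class `ptm_assignments`: a data.frame with one
#'   row per matched composition (`n_hexnac`, `n_hex`, `n_phos`,
#'   `theoretical_mz`, `observed_mz`, `error`, `intensity`, `snr`,
#'   `accepted`, `ambiguous`), with the search settings as attributes.
#' @export
assign_compositions <- function(pl, peptide, comp_space = default_comp_space(),
                                tolerance = 1.0, snr_threshold = 1.0,
                                snr_window = 200) {
  stopifnot(inherits(pl, "peaklist"))
  if (tolerance <= 0) stop("tolerance must be positive")
  pep <- .peptide_fields(peptide)
  if (!all(c("n_hexnac", "n_hex", "n_phos") %in% names(comp_space)))
    stop("comp_space needs columns n_hexnac, n_hex, n_phos")
  if (nrow(comp_space) > 0 &&
      any(comp_space$n_hexnac < 0 | comp_space$n_hex < 0 | comp_space$n_phos < 0))
    stop("composition counts must be non-negative")
  if (is.null(pl$peaks$snr) || anyNA(pl$peaks$noise))
    pl <- estimate_snr(pl, window = snr_window)
  empty <- data.frame(n_hexnac = integer(0), n_hex = integer(0),
                      n_phos = integer(0), theoretical_mz = numeric(0),
                      observed_mz = numeric(0), error = numeric(0),
                      intensity = numeric(0), snr = numeric(0),
                      accepted = logical(0), ambiguous = logical(0))
  make_result <- function(df) {
    structure(df, class = c("ptm_assignments", "data.frame"),
              peptide = pep$label, sequence = pep$sequence,
              scale = pl$scale, mode = pl$mode, tolerance = tolerance,
              snr_threshold = snr_threshold, peaklist_label = pl$label)
  }
  if (nrow(comp_space) == 0L) return(make_result(empty))

  base <- peptide_neutral_mass(pep$sequence, pep$cterm_chem, pl$scale)
  theo <- vapply(seq_len(nrow(comp_space)), function(k)
    ion_mz(base + modification_delta(
      mod_composition(comp_space$n_hexnac[k], comp_space$n_hex[k],
                      comp_space$n_phos[k]), pl$scale), pl$mode),
    numeric(1))
  nmods <- comp_space$n_hexnac + comp_space$n_hex + comp_space$n_phos

  # compositions indistinguishable at 1e-6 are ambiguous, not dropped
  ord_theo <- order(theo)
  amb <- logical(length(theo))
  if (length(theo) > 1) {
    close_pairs <- which(diff(theo[ord_theo]) < 1e-6)
    amb[ord_theo[close_pairs]] <- TRUE
    amb[ord_theo[close_pairs + 1L]] <- TRUE
  }

  # greedy one-peak-one-composition matching, best |error| first
  pk <- pl$peaks
  cand <- list()
  for (k in seq_along(theo)) {
    err <- pk$mz - theo[k]
    sel <- which(abs(err) <= tolerance)
    if (length(sel))
      cand[[length(cand) + 1L]] <- data.frame(
        comp = k, peak = sel, abserr = abs(err[sel]))
  }
  if (!length(cand)) return(make_result(empty))
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$abserr, nmods[cand$comp], theo[cand$comp]), ]
  comp_used <- logical(length(theo))
  peak_used <- logical(nrow(pk))
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    k <- cand$comp[r]; p <- cand$peak[r]
    if (comp_used[k] || peak_used[p]) next
    comp_used[k] <- TRUE; peak_used[p] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      n_hexnac = comp_space$n_hexnac[k], n_hex = comp_space$n_hex[k],
      n_phos = comp_space$n_phos[k], theoretical_mz = theo[k],
      observed_mz = pk$mz[p], error = pk$mz[p] - theo[k],
      intensity = pk$intensity[p], snr = pk$snr[p],
      accepted = pk$snr[p] > snr_threshold, ambiguous = amb[k])
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$theoretical_mz), ]
  rownames(df) <- NULL
  make_result(df)
}

#' @export
print.ptm_assignments <- function(x, ...) {
  cat(sprintf("PTM composition assignments for %s (%s, %s mode, tol %.2g Da, S/N > %.2g)\n",
              attr(x, "peptide"), attr(x, "scale"),
              attr(x, "mode")$polarity, attr(x, "tolerance"),
              attr(x, "snr_threshold")))
  if (nrow(x) == 0L) {
    cat("  no compositions matched\n")
    return(invisible(x))
  }
  print.data.frame(cbind(
    composition = vapply(seq_len(nrow(x)), function(i)
      format(mod_composition(x$n_hexnac[i], x$n_hex[i], x$n_phos[i])),
      character(1)),
    x[c("theoretical_mz", "observed_mz", "error", "snr", "accepted")]),
    digits = 6, row.names = FALSE)
  invisible(x)
}

#' @exportS3Method base::summary
summary.ptm_assignments <- function(object, ...) {
  acc <- object[object$accepted, , drop = FALSE]
  cat(sprintf("%d matched, %d accepted composition(s)\n",
              nrow(object), nrow(acc)))
  if (nrow(acc)) {
    cat("phosphoforms present:",
        paste(sort(unique(acc$n_phos)), collapse = ", "), "\n")
    cat("glycoforms present:",
        paste(vapply(which(acc$n_hexnac > 0), function(i)
          sprintf("GlcNAc%dMan%d", acc$n_hexnac[i], acc$n_hex[i]),
          character(1)), collapse = ", "), "\n")
  }
  invisible(object)
}

#' Plot assigned peaks over the spectrum
#'
#' Stick spectrum with accepted assignments marked and labelled by
#' composition.
#'
#' @param x a `ptm_assignments` object.
#' @param pl the [peaklist()] it was computed from.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @exportS3Method graphics::plot
plot.ptm_assignments <- function(x, pl, ...) {
  stopifnot(inherits(pl, "peaklist"))
  pk <- pl$peaks
  graphics::plot(pk$mz, pk$intensity, type = "h", xlab = "m/z",
                 ylab = "intensity", ...)
  acc <- x[x$accepted, , drop = FALSE]
  if (nrow(acc)) {
    graphics::points(acc$observed_mz, acc$intensity, col = "red", pch = 19)
    graphics::text(acc$observed_mz, acc$intensity,
                   labels = sprintf("(%d)", acc$n_hex),
                   pos = 3, col = "red", cex = 0.8)
  }
  invisible(x)
}

.step_masses <- function(scale) {
  c(hexose = formula_mass(.modification_formulas$hex, scale),
    hexnac = formula_mass(.modification_formulas$hexnac, scale),
    phosphoryl = formula_mass(.modification_formulas$phosphoryl, scale))
}

#' Detect mass-ladder series in a peak list
#'
#' Finds maximal chains of peaks whose successive m/z differences match
#' a step mass (hexose +162, HexNAc +203 or phosphoryl +80 on the
#' average scale) within a tolerance. Successive +162 peaks are the
#' signature of a high-mannose glycoform ladder; +80 spacings indicate
#' additional phosphoryl groups.
#'
#' @param pl a [peaklist()].
#' @param steps subset of `c("hexose", "hexnac", "phosphoryl")`.
#' @param tolerance matching half-window in Da.
#' @return a list of ladders, each a list with `step`, `step_mass`,
#'   `base_peak_mz` and `member_mzs` (ascending); only chains of length
#'   >= 2 are reported.
#' @export
detect_ladders <- function(pl, steps = c("hexose", "phosphoryl"),
                           tolerance = 0.5) {
  stopifnot(inherits(pl, "peaklist"))
  if (tolerance <= 0) stop("tolerance must be positive")
  steps <- match.arg(steps, c("hexose", "hexnac", "phosphoryl"),
                     several.ok = TRUE)
  mz <- pl$peaks$mz
  masses <- .step_masses(pl$scale)
  out <- list()
  for (s in steps) {
    step <- masses[[s]]
    succ <- rep(NA_integer_, length(mz))
    for (i in seq_along(mz)) {
      d <- abs(mz - (mz[i] + step))
      j <- which.min(d)
      if (length(j) && d[j] <= tolerance) succ[i] <- j
    }
    has_pred <- seq_along(mz) %in% succ
    for (start in which(!has_pred & !is.na(succ))) {
      chain <- start
      i <- start
      while (!is.na(succ[i])) {
        i <- succ[i]
        chain <- c(chain, i)
      }
      if (length(chain) >= 2L)
        out[[length(out) + 1L]] <- list(step = s, step_mass = step,
                                        base_peak_mz = mz[chain[1]],
                                        member_mzs = mz[chain])
    }
  }
  out
}

#' Relative-abundance profile of accepted glycoforms
#'
#' Peak-height fractions over the accepted assignments; the major form
#' is the composition with the largest fraction (ties broken toward
#' fewer total modifications).
#'
#' @param assignments a `ptm_assignments` object.
#' @return an object of class `glyco_profile`: list with `table` (a
#'   data.frame of compositions and `relative_height`) and `major_form`
#'   (a [mod_composition()]).
#' @export
glycoform_profile <- function(assignments) {
  acc <- assignments[assignments$accepted, , drop = FALSE]
  if (nrow(acc) == 0L) stop("no accepted assignments to profile")
  total <- sum(acc$intensity)
  acc$relative_height <- acc$intensity / total
  nmods <- acc$n_hexnac + acc$n_hex + acc$n_phos
  best <- order(-acc$relative_height, nmods)[1]
  tab <- acc[order(-acc$relative_height),
             c("n_hexnac", "n_hex", "n_phos", "observed_mz",
               "intensity", "relative_height")]
  rownames(tab) <- NULL
  structure(list(
    table = tab,
    major_form = mod_composition(acc$n_hexnac[best], acc$n_hex[best],
                                 acc$n_phos[best])
  ), class = "glyco_profile")
}

#' @export
print.glyco_profile <- function(x, ...) {
  cat("Glycoform/phosphoform profile (peak-height fractions)\n")
  df <- x$table
  df$composition <- vapply(seq_len(nrow(df)), function(i)
    format(mod_composition(df$n_hexnac[i], df$n_hex[i], df$n_phos[i])),
    character(1))
  print.data.frame(df[c("composition", "observed_mz", "relative_height")],
                   digits = 4, row.names = FALSE)
  cat("major form:", format(x$major_form), "\n")
  invisible(x)
}

#' Phosphoform summary of accepted assignments
#'
#' Which phosphoryl counts (0/1/2/...) are present among accepted
#' assignments, with their summed peak-height fractions.
#'
#' @param assignments a `ptm_assignments` object.
#' @return data.frame with columns `n_phos` and `fraction`.
#' @export
phospho_summary <- function(assignments) {
  acc <- assignments[assignments$accepted, , drop = FALSE]
  if (nrow(acc) == 0L)
    return(data.frame(n_phos = integer(0), fraction = numeric(0)))
  agg <- stats::aggregate(intensity ~ n_phos, data = acc, FUN = sum)
  data.frame(n_phos = agg$n_phos,
             fraction = agg$intensity / sum(agg$intensity))
}
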