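# Mass tables and m/z arithmetic.
#
# All masses are derived at load time from a single embedded atomic-mass
# table, so every downstream number is bit-reproducible and auditable back
# to six elemental constants per scale. Monoisotopic masses are the usual
# principal-isotope values; average masses use the conventional standard
# atomic weights that time-of-flight instruments report in linear mode.

# element -> c(monoisotopic, average), Da
.atomic_masses <- list(
  H = c(1.0078250319, 1.00794),
  C = c(12.0000000000, 12.0107),
  N = c(14.0030740052, 14.0067),
  O = c(15.9949146221, 15.9994),
  S = c(31.9720706900, 32.0650),
  P = c(30.9737615100, 30.973762)
)

# mass of a bare proton (H+), Da; not the H atom
.proton_mass <- 1.00727646688

# residue (amino acid minus water) elemental compositions
.residue_formulas <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

# CNBr converts a cleaved C-terminal Met to homoserine lactone (the
# dominant product) or, after ring opening, homoserine
.special_residue_formulas <- list(
  homoserine_lactone = c(C = 4, H = 5, N = 1, O = 1),
  homoserine         = c(C = 4, H = 7, N = 1, O = 2)
)

.modification_formulas <- list(
  hexnac     = c(C = 8, H = 13, N = 1, O = 5),  # N-acetylhexosamine residue
  hex        = c(C = 6, H = 10, O = 5),         # anhydro-hexose (mannose) residue
  phosphoryl = c(H = 1, P = 1, O = 3)           # HPO3
)

.water_formula <- c(H = 2, O = 1)

.mass_scales <- c("monoisotopic", "average")

.check_scale <- function(scale) {
  match.arg(scale, .mass_scales)
}

#' Mass of an elemental composition
#'
#' Sums the embedded atomic-mass table over a named vector of element
#' counts, on either mass scale.
#'
#' @param formula named integer vector of element counts, names in
#'   `H, C, N, O, S, P`.
#' @param scale `"monoisotopic"` or `"average"`.
#' @return mass in Da.
#' @examples
#' formula_mass(c(H = 2, O = 1))  # water
#' @export
formula_mass <- function(formula, scale = "monoisotopic") {
  scale <- .check_scale(scale)
  idx <- if (scale == "monoisotopic") 1L else 2L
  bad <- setdiff(names(formula), names(.atomic_masses))
  if (length(bad))
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  sum(vapply(names(formula),
             function(el) .atomic_masses[[el]][idx] * formula[[el]],
             numeric(1)))
}

#' Residue mass table
#'
#' Monoisotopic and average residue masses for the 20 standard amino
#' acids, plus homoserine lactone and homoserine (CNBr C-terminal
#' chemistry), water and the proton, all derived from the embedded
#' atomic-mass table.
#'
#' @return a list with elements `residues` (data.frame: residue, mono,
#'   avg), `water` (named numeric, both scales), `proton` (Da) and
#'   `special` (data.frame for the two homoserine forms).
#' @export
residue_mass_table <- function() {
  res <- data.frame(
    residue = names(.residue_formulas),
    mono = vapply(.residue_formulas, formula_mass, numeric(1),
                  scale = "monoisotopic"),
    avg = vapply(.residue_formulas, formula_mass, numeric(1),
                 scale = "average"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  special <- data.frame(
    residue = names(.special_residue_formulas),
    mono = vapply(.special_residue_formulas, formula_mass, numeric(1),
                  scale = "monoisotopic"),
    avg = vapply(.special_residue_formulas, formula_mass, numeric(1),
                 scale = "average"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(
    residues = res,
    water = c(monoisotopic = formula_mass(.water_formula, "monoisotopic"),
              average = formula_mass(.water_formula, "average")),
    proton = .proton_mass,
    special = special
  )
}

#' Export the residue mass table as delimited text
#'
#' Writes a tab-separated table (residue, mono, avg) including the
#' homoserine forms, water and proton rows, for external audit.
#'
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_mass_table <- function(path) {
  tab <- residue_mass_table()
  all <- rbind(tab$residues, tab$special,
               data.frame(residue = "water",
                          mono = tab$water[["monoisotopic"]],
                          avg = tab$water[["average"]]),
               data.frame(residue = "proton",
                          mono = tab$proton, avg = tab$proton))
  utils::write.table(format(all, digits = 12), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

.residue_mass <- function(code, scale) {
  idx <- if (scale == "monoisotopic") 1L else 2L
  f <- .residue_formulas[[code]]
  if (is.null(f)) return(NA_real_)
  formula_mass(f, scale)
}

#' Neutral mass of a peptide
#'
#' Sum of residue masses plus one water, with the C-terminal residue
#' optionally replaced by a homoserine form — the chemistry CNBr leaves
#' on peptides cleaved after methionine.
#'
#' @param sequence one-letter amino-acid string (standard 20 residues).
#' @param cterm_chem `"intact"`, `"homoserine_lactone"` or
#'   `"homoserine"`; the latter two are valid only when `sequence` ends
#'   in `M`, whose residue mass they replace.
#' @param scale `"monoisotopic"` or `"average"`.
#' @return neutral (uncharged) mass in Da.
#' @examples
#' peptide_neutral_mass("GGM", cterm_chem = "homoserine_lactone")
#' @export
peptide_neutral_mass <- function(sequence,
                                 cterm_chem = c("intact",
                                                "homoserine_lactone",
                                                "homoserine"),
                                 scale = "monoisotopic") {
  cterm_chem <- match.arg(cterm_chem)
  scale <- .check_scale(scale)
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("sequence must be a single non-empty string")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  known <- chars %in% names(.residue_formulas)
  if (!all(known)) {
    i <- which(!known)[1]
    stop(sprintf("unknown residue code '%s' at position %d", chars[i], i))
  }
  if (cterm_chem != "intact" && chars[length(chars)] != "M")
    stop("C-terminal homoserine chemistry requires the sequence to end in Met")
  masses <- vapply(chars, .residue_mass, numeric(1), scale = scale)
  if (cterm_chem != "intact")
    masses[length(masses)] <-
      formula_mass(.special_residue_formulas[[cterm_chem]], scale)
  sum(masses) + formula_mass(.water_formula, scale)
}

#' Glycan/phosphoryl composition
#'
#' A `(n_hexnac, n_hex, n_phos)` modification composition: counts of
#' N-acetylhexosamine, hexose (mannose) and phosphoryl (HPO3) groups.
#' The high-mannose glycans on calsequestrin are GlcNAc2Man_n, i.e.
#' `mod_composition(2, n)`.
#'
#' @param n_hexnac,n_hex,n_phos non-negative integer counts.
#' @return an object of class `mod_composition`.
#' @export
mod_composition <- function(n_hexnac = 0, n_hex = 0, n_phos = 0) {
  counts <- c(n_hexnac = n_hexnac, n_hex = n_hex, n_phos = n_phos)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("composition counts must be non-negative integers")
  counts <- stats::setNames(as.integer(counts),
                            c("n_hexnac", "n_hex", "n_phos"))
  structure(counts, class = "mod_composition")
}

#' @exportS3Method base::format
format.mod_composition <- function(x, ...) {
  sprintf("GlcNAc%dMan%d+%dP", x[["n_hexnac"]], x[["n_hex"]], x[["n_phos"]])
}

#' @export
print.mod_composition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Mass added by a modification composition
#'
#' Linear in each count: `n_hexnac * HexNAc + n_hex * Hex + n_phos *
#' HPO3`. On the average scale one hexose adds 162.14 Da and one
#' phosphoryl 79.98 Da — the 162 and 80 m/z spacings that identify
#' glycoform ladders and phosphopeptides in MALDI spectra.
#'
#' @param comp a [mod_composition()] (or numeric vector of the three
#'   counts).
#' @param scale `"monoisotopic"` or `"average"`.
#' @return mass delta in Da.
#' @export
modification_delta <- function(comp, scale = "monoisotopic") {
  scale <- .check_scale(scale)
  if (!inherits(comp, "mod_composition"))
    comp <- mod_composition(comp[[1]], comp[[2]], comp[[3]])
  comp[["n_hexnac"]] * formula_mass(.modification_formulas$hexnac, scale) +
    comp[["n_hex"]] * formula_mass(.modification_formulas$hex, scale) +
    comp[["n_phos"]] * formula_mass(.modification_formulas$phosphoryl, scale)
}

#' Ionization mode
#'
#' MALDI polarity and charge state. Analyte peaks are read as singly
#' charged by default; positive mode gives `[M+zH]z+`, negative
#' `[M-zH]z-`.
#'
#' @param polarity `"positive"` or `"negative"`.
#' @param charge integer >= 1.
#' @return an object of class `ion_mode`.
#' @export
ion_mode <- function(polarity = c("positive", "negative"), charge = 1L) {
  polarity <- match.arg(polarity)
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be an integer >= 1")
  structure(list(polarity = polarity, charge = charge), class = "ion_mode")
}

#' m/z of an ion from its neutral mass
#'
#' @param neutral_mass neutral mass in Da, > 0.
#' @param mode an [ion_mode()].
#' @return m/z value.
#' @examples
#' ion_mz(1000, ion_mode("positive"))
#' @export
ion_mz <- function(neutral_mass, mode = ion_mode("positive")) {
  if (!inherits(mode, "ion_mode")) stop("mode must be an ion_mode object")
  if (!is.numeric(neutral_mass) || any(neutral_mass <= 0))
    stop("neutral_mass must be positive")
  z <- mode$charge
  sign <- if (mode$polarity == "positive") 1 else -1
  (neutral_mass + sign * z * .proton_mass) / z
}
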