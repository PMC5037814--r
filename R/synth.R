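# Synthetic-data generators.
#
# These emulate the statistical structure the analysis assumes — CNBr
# cleavage points with geometric spacing, one glycosylation sequon, a
# serine-bearing C-terminal tail, spectra drawn from a ground-truth
# glycoform/phosphoform distribution with Gaussian mass error plus
# spurious sub-threshold peaks, and coordinate sets related by a known
# rigid motion plus isotropic perturbation. Every generator is
# bit-reproducible given its seed; generation leaves the caller's RNG
# state untouched.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.destroy_stray_sequons <- function(chars, protected_asn) {
  # mutate stray Asn to Gln until only the protected sequon remains
  for (iter in 1:200) {
    seq <- paste(chars, collapse = "")
    asns <- .sequon_positions(seq)
    stray <- setdiff(asns, protected_asn)
    if (!length(stray)) break
    chars[stray[1]] <- "Q"
  }
  chars
}

#' Simulate a protein sequence with CNBr-relevant features
#'
#' Random sequence with geometrically spaced methionines (independent
#' per-position probability `1/met_spacing`), optionally exactly one
#' N-X-S/T glycosylation sequon (X != P, planted 40 residues from the
#' C-terminus), and exactly `n_cterm_ser` serines in the final 30
#' residues of an otherwise acidic (Asp/Glu-enriched) tail — the
#' features of a calsequestrin-like substrate.
#'
#' @param length sequence length (>= 50 when a sequon is requested,
#'   else >= 20).
#' @param met_spacing mean residues between methionines.
#' @param include_sequon plant the single sequon?
#' @param n_cterm_ser number of serines in the final 30 residues.
#' @param seed integer seed.
#' @return a [sequence_record()].
#' @export
simulate_sequence <- function(length = 250L, met_spacing = 25,
                              include_sequon = TRUE, n_cterm_ser = 2L,
                              seed = 1L) {
  length <- as.integer(length)
  if (length < 20L) stop("length must be >= 20")
  if (include_sequon && length < 50L)
    stop("length must be >= 50 to fit the sequon upstream of the tail")
  if (n_cterm_ser < 0L || n_cterm_ser > 28L)
    stop("n_cterm_ser must be between 0 and 28")
  if (met_spacing <= 1) stop("met_spacing must exceed 1")
  .with_seed(seed, {
    non_met <- setdiff(.aa_alphabet, "M")
    chars <- ifelse(stats::runif(length) < 1 / met_spacing, "M",
                    sample(non_met, length, replace = TRUE))
    tail_start <- length - 29L
    protected <- integer(0)
    if (include_sequon) {
      asn <- length - 40L
      chars[asn:(asn + 2L)] <- c("N", "V", "T")
      protected <- asn
    }
    # acidic tail with exactly n_cterm_ser serines
    tail_idx <- tail_start:length
    chars[tail_idx][chars[tail_idx] %in% c("S", "T", "N")] <-
      sample(c("D", "E"), sum(chars[tail_idx] %in% c("S", "T", "N")),
             replace = TRUE)
    if (n_cterm_ser > 0L)
      chars[sample(tail_idx, n_cterm_ser)] <- "S"
    chars <- .destroy_stray_sequons(chars, protected)
    rec <- sequence_record(sprintf("synth_seq_%d", seed),
                           paste(chars, collapse = ""),
                           description = "simulated CNBr substrate")
    rec
  })
}

#' Ground truth for a simulated spectrum
#'
#' @param peptide a one-row digest table or plain sequence string.
#' @param abundances data.frame with columns `n_hexnac`, `n_hex`,
#'   `n_phos`, `abundance` (positive; normalized to sum to 1).
#' @param mass_error_sd Gaussian m/z error SD in Da (>= 0).
#' @param n_noise_peaks number of spurious peaks.
#' @param noise_mz_range `c(lo, hi)` m/z range for spurious peaks.
#' @param seed integer seed.
#' @return an object of class `spectrum_truth`.
#' @export
spectrum_truth <- function(peptide, abundances, mass_error_sd = 0,
                           n_noise_peaks = 0L,
                           noise_mz_range = c(2000, 5000), seed = 1L) {
  if (!all(c("n_hexnac", "n_hex", "n_phos", "abundance") %in%
           names(abundances)))
    stop("abundances needs columns n_hexnac, n_hex, n_phos, abundance")
  if (any(abundances$abundance <= 0))
    stop("abundances must be positive")
  if (mass_error_sd < 0) stop("mass_error_sd must be >= 0")
  abundances$abundance <- abundances$abundance / sum(abundances$abundance)
  structure(list(peptide = peptide, abundances = abundances,
                 mass_error_sd = mass_error_sd,
                 n_noise_peaks = as.integer(n_noise_peaks),
                 noise_mz_range = noise_mz_range, seed = as.integer(seed)),
            class = "spectrum_truth")
}

#' Simulate a MALDI peak list from a ground truth
#'
#' One peak per composition at its expected ion m/z plus Gaussian mass
#' error; intensities proportional to abundance with lognormal jitter
#' (sdlog 0.3) on a baseline of 1, so true peaks have S/N above 1 and
#' the uniformly scattered spurious peaks sit below it.
#'
#' @param truth a [spectrum_truth()].
#' @param mode an [ion_mode()].
#' @param scale mass scale of the m/z axis.
#' @return a [peaklist()] with a filled noise column.
#' @export
simulate_peaklist <- function(truth, mode = ion_mode("negative"),
                              scale = "monoisotopic") {
  stopifnot(inherits(truth, "spectrum_truth"))
  scale <- .check_scale(scale)
  pep <- .peptide_fields(truth$peptide)
  base <- peptide_neutral_mass(pep$sequence, pep$cterm_chem, scale)
  ab <- truth$abundances
  theo <- vapply(seq_len(nrow(ab)), function(k)
    ion_mz(base + modification_delta(
      mod_composition(ab$n_hexnac[k], ab$n_hex[k], ab$n_phos[k]), scale),
      mode), numeric(1))
  .with_seed(truth$seed, {
    mz <- theo + stats::rnorm(length(theo), 0, truth$mass_error_sd)
    intensity <- ab$abundance * 100 *
      stats::rlnorm(length(theo), 0, 0.3)
    if (truth$n_noise_peaks > 0L) {
      for (attempt in 1:50) {
        nmz <- stats::runif(truth$n_noise_peaks, truth$noise_mz_range[1],
                            truth$noise_mz_range[2])
        all_mz <- c(mz, nmz)
        if (all(diff(sort(all_mz)) > 1e-3)) break
      }
      mz <- c(mz, nmz)
      intensity <- c(intensity,
                     stats::runif(truth$n_noise_peaks, 0.1, 0.9))
    }
    peaklist(mz, intensity, noise = rep(1, length(mz)), mode = mode,
             scale = scale,
             label = sprintf("simulated (seed %d)", truth$seed))
  })
}

#' Uniformly random proper rotation matrix
#'
#' Drawn via a normalized Gaussian quaternion; uses the current RNG
#' state.
#'
#' @return a 3x3 orthonormal matrix with determinant +1.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Ground truth for a rigid-motion coordinate pair
#'
#' @param n_atoms number of points (>= 3).
#' @param rotation 3x3 proper rotation; `NULL` draws one at random.
#' @param translation length-3 vector; `NULL` draws uniform in
#'   `[-20, 20]` per axis.
#' @param perturbation_sd per-coordinate Gaussian SD in Angstroms.
#' @param seed integer seed.
#' @return an object of class `motion_truth`.
#' @export
motion_truth <- function(n_atoms = 100L, rotation = NULL,
                         translation = NULL, perturbation_sd = 0,
                         seed = 1L) {
  n_atoms <- as.integer(n_atoms)
  if (n_atoms < 3L) stop("n_atoms must be >= 3")
  if (perturbation_sd < 0) stop("perturbation_sd must be >= 0")
  if (!is.null(rotation)) {
    if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
        abs(det(rotation) - 1) > 1e-9)
      stop("rotation must be proper orthonormal")
  }
  structure(list(n_atoms = n_atoms, rotation = rotation,
                 translation = translation,
                 perturbation_sd = perturbation_sd,
                 seed = as.integer(seed)),
            class = "motion_truth")
}

#' Simulate a coordinate pair related by a known rigid motion
#'
#' `A` is uniform in a 50-Angstrom box; `B = R A + t` plus independent
#' Gaussian perturbation of each coordinate. [kabsch_superpose()] of
#' the pair recovers the motion, with expected r.m.s.d.
#' `perturbation_sd * sqrt(3)`.
#'
#' @param truth a [motion_truth()].
#' @return list with matrices `A`, `B` and the realized `rotation` and
#'   `translation`.
#' @export
simulate_coord_pair <- function(truth) {
  stopifnot(inherits(truth, "motion_truth"))
  .with_seed(truth$seed, {
    A <- matrix(stats::runif(truth$n_atoms * 3, 0, 50), ncol = 3)
    R <- truth$rotation %||% random_rotation()
    tvec <- truth$translation %||% stats::runif(3, -20, 20)
    B <- A %*% t(R) + matrix(tvec, truth$n_atoms, 3, byrow = TRUE)
    if (truth$perturbation_sd > 0)
      B <- B + matrix(stats::rnorm(length(B), 0, truth$perturbation_sd),
                      ncol = 3)
    list(A = A, B = B, rotation = R, translation = tvec)
  })
}
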