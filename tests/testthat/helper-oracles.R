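# Independent oracles used to check the implementation.

# Residue masses from an independent proteomics mass calculator
# (frozen values; monoisotopic and average scales), Da.
oracle_mono <- c(
  A = 71.03711, C = 103.00918, D = 115.02694, E = 129.04259,
  F = 147.06841, G = 57.02146, H = 137.05891, I = 113.08406,
  K = 128.09496, L = 113.08406, M = 131.04048, N = 114.04293,
  P = 97.05276, Q = 128.05858, R = 156.10111, S = 87.03203,
  T = 101.04768, V = 99.06841, W = 186.07931, Y = 163.06333)
oracle_avg <- c(
  A = 71.0780, C = 103.1428, D = 115.0876, E = 129.1142,
  F = 147.1742, G = 57.0514, H = 137.1395, I = 113.1579,
  K = 128.1725, L = 113.1579, M = 131.1960, N = 114.1028,
  P = 97.1154, Q = 128.1294, R = 156.1859, S = 87.0774,
  T = 101.1040, V = 99.1313, W = 186.2103, Y = 163.1736)
oracle_water <- c(mono = 18.01056, avg = 18.0153)
oracle_hex <- c(mono = 162.05282, avg = 162.1408)
oracle_hexnac <- c(mono = 203.07937, avg = 203.1928)
oracle_hpo3 <- c(mono = 79.96633, avg = 79.9799)
oracle_proton <- 1.00727646688

# Brute-force CNBr splitter: cut after every Met.
brute_cnbr_split <- function(seq) {
  m <- regmatches(seq, gregexpr("[^M]*M|[^M]+$", seq))[[1]]
  m[nzchar(m)]
}

# Horn's closed-form quaternion superposition: returns the optimal
# r.m.s.d. of rotating B onto A, independent of the SVD route.
horn_rmsd <- function(A, B) {
  n <- nrow(A)
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  S <- t(Bc) %*% Ac
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, sum(Ac^2) + sum(Bc^2) - 2 * lambda) / n)
}

# Memoized recursive global affine-gap alignment score: gap of length
# L costs open + L * extend, end gaps penalized. Independent of the
# aligner under test.
dp_align_score <- function(a, b, submat, gap_open = 10, gap_extend = 0.5) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -Inf
  # states: 1 = in match, 2 = gap in b (a consumed), 3 = gap in a
  memo <- array(NA_real_, dim = c(n + 1, m + 1, 3))
  score <- function(i, j, st) {
    if (i == 0 && j == 0)
      return(if (st == 1) 0 else NEG)
    v <- memo[i + 1, j + 1, st]
    if (!is.na(v)) return(v)
    v <- NEG
    if (st == 1 && i > 0 && j > 0) {
      s <- submat[ca[i], cb[j]]
      v <- s + max(score(i - 1, j - 1, 1), score(i - 1, j - 1, 2),
                   score(i - 1, j - 1, 3))
    } else if (st == 2 && i > 0) {
      v <- max(score(i - 1, j, 1) - gap_open - gap_extend,
               score(i - 1, j, 2) - gap_extend,
               score(i - 1, j, 3) - gap_open - gap_extend)
    } else if (st == 3 && j > 0) {
      v <- max(score(i, j - 1, 1) - gap_open - gap_extend,
               score(i, j - 1, 2) - gap_open - gap_extend,
               score(i, j - 1, 3) - gap_extend)
    }
    memo[i + 1, j + 1, st] <<- v
    v
  }
  max(score(n, m, 1), score(n, m, 2), score(n, m, 3))
}

random_protein <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
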