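#' @useDynLib phosphoseed, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical 20-letter amino-acid alphabet; this ORDER defines the rank used by
# every positional/compositional feature index in the package.
AA_ALPHABET <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

# Letters that are mapped to the unknown-residue placeholder X on input.
NONSTANDARD_AA <- c("B", "J", "O", "U", "Z", "*", ".", "-")

#' Alphabet rank of an amino acid
#'
#' Rank (1..20) of a residue in the canonical order `ARNDCQEGHILKMFPSTWYV`.
#' `X` and any unknown letter return `NA`.
#'
#' @param aa character vector of single residue letters.
#' @return integer vector of ranks.
#' @export
#' @examples
#' aa_rank(c("A", "R", "P"))  # 1 2 15
aa_rank <- function(aa) {
  match(aa, AA_ALPHABET)
}

# --- PAAC property scales (classic tables used by Chou's pseudo-AAC) --------
# Hydrophobicity (Tanford-style scale of the original PseAAC web server),
# hydrophilicity (Hopp-Woods), side-chain mass (Da).
PAAC_HYDROPHOBICITY <- c(
  A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29, Q = -0.85, E = -0.74,
  G = 0.48, H = -0.40, I = 1.38, L = 1.06, K = -1.50, M = 0.64, F = 1.19,
  P = 0.12, S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08
)
PAAC_HYDROPHILICITY <- c(
  A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0, Q = 0.2, E = 3.0,
  G = 0.0, H = -0.5, I = -1.8, L = -1.8, K = 3.0, M = -1.3, F = -2.5,
  P = 0.0, S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5
)
PAAC_SIDECHAIN_MASS <- c(
  A = 15, R = 101, N = 58, D = 59, C = 47, Q = 72, E = 73,
  G = 1, H = 82, I = 57, L = 57, K = 73, M = 75, F = 91,
  P = 42, S = 31, T = 45, W = 130, Y = 107, V = 43
)

# Standardize a property over the 20 residues (population sd, denominator 20),
# the normalization conventionally used before computing PAAC correlations.
.paac_normalize <- function(p) {
  p <- p[AA_ALPHABET]
  mu <- mean(p)
  sdev <- sqrt(sum((p - mu)^2) / 20)
  (p - mu) / sdev
}

# --- CTDC: 13 physicochemical properties, each a 3-group partition ----------
# Standard three-group partitions used by C/T/D composition descriptors:
# seven hydrophobicity scales, van der Waals volume, polarity, polarizability,
# charge, secondary structure and solvent accessibility.
CTDC_GROUPS <- list(
  hydrophobicity_PRAM900101 = c("RKEDQN",     "GASTPHY",          "CLVIMFW"),
  hydrophobicity_ARGP820101 = c("QSTNGDE",    "RAHCKMV",          "LYPFIW"),
  hydrophobicity_ZIMJ680101 = c("QNGSWTDERA", "HMCKV",            "LPFYI"),
  hydrophobicity_PONP930101 = c("KPDESNQT",   "GRHA",             "YMFWLCVI"),
  hydrophobicity_CASG920101 = c("KDEQPSRNTG", "AHYMLV",           "FIWC"),
  hydrophobicity_ENGD860101 = c("RDKENQHYP",  "SGTAW",            "CVLIMF"),
  hydrophobicity_FASG890101 = c("KERSQD",     "NTPG",             "AYHWVMFLIC"),
  normwaalsvolume           = c("GASTPDC",    "NVEQIL",           "MHKFRYW"),
  polarity                  = c("LIFWCMVY",   "PATGS",            "HQRKNED"),
  polarizability            = c("GASDT",      "CPNVEQIL",         "KMHFRYW"),
  charge                    = c("KR",         "ANCQGHILMFPSTWYV", "DE"),
  secondarystruct           = c("EALMQKRH",   "VIYCWFT",          "GNPSD"),
  solventaccess             = c("ALFCGIVW",   "RKQEND",           "MSPTHY")
)

# --- Residue-pair distance matrices for quasi-sequence-order ----------------

# Grantham (1974) property table: composition c, polarity p, volume v.
GRANTHAM_PROPERTIES <- data.frame(
  row.names = c("S","R","L","P","T","A","V","G","I","F",
                "Y","C","H","Q","N","K","D","E","M","W"),
  c = c(1.42, 0.65, 0.00, 0.39, 0.71, 0.00, 0.00, 0.74, 0.00, 0.00,
        0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0.00, 0.13),
  p = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
        6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
  v = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
        136, 55, 96, 85, 56, 119, 54, 83, 105, 170)
)

#' Grantham chemical distance matrix
#'
#' The 20x20 Grantham (1974) distance, computed from his published formula
#' `D = rho * sqrt(alpha (c_i - c_j)^2 + beta (p_i - p_j)^2 + gamma (v_i - v_j)^2)`
#' with alpha = 1.833, beta = 0.1018, gamma = 0.000399 and rho = 50.723
#' (scaling the mean distance to 100), over composition, polarity and volume.
#' Values agree with the published (rounded) table to within about one unit.
#'
#' @return numeric 20x20 symmetric matrix, rows/cols in alphabet order.
#' @export
grantham_matrix <- function() {
  pr <- GRANTHAM_PROPERTIES[AA_ALPHABET, ]
  d2 <- function(x) outer(x, x, "-")^2
  d <- 50.723 * sqrt(1.833 * d2(pr$c) + 0.1018 * d2(pr$p) + 0.000399 * d2(pr$v))
  dimnames(d) <- list(AA_ALPHABET, AA_ALPHABET)
  d
}

#' Physicochemical residue distance matrix
#'
#' A 20x20 distance built from the normalized hydrophobicity, hydrophilicity
#' and side-chain-mass scales: `d(i,j) = sqrt(mean of the three squared
#' normalized property differences)` (the square root of Chou's correlation
#' function). Used as the second quasi-sequence-order matrix alongside
#' [grantham_matrix()].
#'
#' @return numeric 20x20 symmetric matrix, rows/cols in alphabet order.
#' @export
hphys_matrix <- function() {
  h1 <- .paac_normalize(PAAC_HYDROPHOBICITY)
  h2 <- .paac_normalize(PAAC_HYDROPHILICITY)
  m  <- .paac_normalize(PAAC_SIDECHAIN_MASS)
  d <- sqrt((outer(h1, h1, "-")^2 + outer(h2, h2, "-")^2 + outer(m, m, "-")^2) / 3)
  dimnames(d) <- list(AA_ALPHABET, AA_ALPHABET)
  d
}
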