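# Physicochemical constant tables used by the feature extractors.
#
# Values follow the Biopython ProtParam reference tables: Kyte-Doolittle
# hydropathy, average amino-acid masses, the Guruprasad dipeptide instability
# weights (DIWV), and the Gill & von Hippel molar extinction coefficients.
# The isoelectric-point pKa set is the EMBOSS set. All tables are keyed by the
# 20 canonical one-letter codes in alphabetical order.

#' The 20 canonical amino-acid one-letter codes
#'
#' Alphabetical order; this order defines the canonical lexicographic
#' ordering of all amino-acid k-mer feature blocks.
#'
#' @format Character vector of length 20.
#' @export
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte & Doolittle hydropathy values (GRAVY = mean over residues)
KD_HYDROPATHY <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

# Average masses of the free amino acids (Da); residue mass = value - water.
AA_MASS_FREE <- c(
  A = 89.0932, C = 121.1582, D = 133.1027, E = 147.1293, F = 165.1891,
  G = 75.0666, H = 155.1546, I = 131.1729, K = 146.1876, L = 131.1729,
  M = 149.2113, N = 132.1179, P = 115.1305, Q = 146.1445, R = 174.2010,
  S = 105.0926, T = 119.1192, V = 117.1463, W = 204.2252, Y = 181.1885
)

WATER_MASS <- 18.0153

# Molar extinction coefficients at 280 nm (M^-1 cm^-1)
EXT_TRP <- 5500
EXT_TYR <- 1490
EXT_CYSTINE <- 125

# EMBOSS pKa set for the Henderson-Hasselbalch net-charge function.
PKA_POSITIVE <- c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
PKA_NEGATIVE <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

# Guruprasad dipeptide instability weights: DIWV[x, y] scores dipeptide "xy".
DIWV <- local({
  txt <- "
A  1     44.94 -7.49  1     1     1     -7.49  1     1     1     1     1     20.26  1     1     1     1     1     1     1
C  1     1     20.26  1     1     1     33.6   1     1     20.26 33.6  1     20.26 -6.54  1     1     33.6  -6.54 24.68  1
D  1     1     1      1    -6.54  1     1      1    -7.49  1     1     1     1     1    -6.54 20.26 -14.03  1     1     1
E  1     44.94 20.26 33.6   1     1    -6.54  20.26  1     1     1     1     20.26 20.26  1    20.26  1     1   -14.03  1
F  1     1     13.34  1     1     1     1      1   -14.03  1     1     1     20.26  1     1     1     1     1     1    33.601
G -7.49  1     1     -6.54  1    13.34  1     -7.49 -7.49  1     1    -7.49  1     1     1     1    -7.49  1    13.34 -7.49
H  1     1     1      1    -9.37 -9.37  1     44.94 24.68  1     1    24.68 -1.88  1     1     1    -6.54  1    -1.88 44.94
I  1     1     1     44.94  1     1    13.34   1    -7.49 20.26  1     1    -1.88  1     1     1     1    -7.49  1     1
K  1     1     1      1     1    -7.49  1     -7.49  1    -7.49 33.6   1    -6.54 24.64 33.6   1     1    -7.49  1     1
L  1     1     1      1     1     1     1      1    -7.49  1     1     1     20.26 33.6  20.26  1     1     1    24.68  1
M 13.34  1     1      1     1     1    58.28   1     1     1    -1.88  1     44.94 -6.54 -6.54 44.94 -1.88  1     1    24.68
N  1    -1.88  1      1   -14.03 -14.03 1     44.94 24.68  1     1     1    -1.88 -6.54  1     1    -7.49  1    -9.37  1
P 20.26 -6.54 -6.54  18.38 20.26  1     1      1     1     1    -6.54  1    20.26 20.26 -6.54 20.26  1    20.26 -1.88  1
Q  1    -6.54 20.26  20.26 -6.54  1     1      1     1     1     1     1    20.26 20.26  1    44.94  1    -6.54  1    -6.54
R  1     1     1      1     1    -7.49 20.26   1     1     1     1    13.34 20.26 20.26 58.28 44.94  1     1    58.28 -6.54
S  1    33.6   1     20.26  1     1     1      1     1     1     1     1    44.94 20.26 20.26 20.26  1     1     1     1
T  1     1     1     20.26 13.34 -7.49  1      1     1     1     1   -14.03  1    -6.54  1     1     1     1   -14.03  1
V  1     1    -14.03  1     1    -7.49  1      1    -1.88  1     1     1    20.26  1     1     1    -7.49  1     1    -6.54
W -14.03 1     1      1     1    -9.37 24.68   1     1    13.34 24.68 13.34  1     1     1     1   -14.03 -7.49  1     1
Y 24.68  1    24.68  -6.54  1    -7.49 13.34   1     1     1    44.94  1    13.34  1   -15.91   1    -7.49  1    -9.37 13.34"
  rows <- strsplit(trimws(strsplit(txt, "\n")[[1]]), "\\s+")
  rows <- rows[lengths(rows) > 0]
  m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(20)))
  # columns follow the same alphabetical residue order as the rows
  dimnames(m) <- list(vapply(rows, `[`, "", 1), vapply(rows, `[`, "", 1))
  m
})

#' Default 7-group side-chain alphabet
#'
#' A reduction of the 20 amino acids to seven chemical groups: aliphatic
#' (A,V,L,I), aromatic (F,W,Y), basic (K,R,H), acidic (D,E), polar
#' amide/hydroxyl (S,T,N,Q), sulfur-containing (C,M) and conformationally
#' special (G,P). Group symbols are the digits 1-7 so that k-mers over the
#' reduced alphabet sort lexicographically in a stable documented order.
#' Any total single-valued 7-group mapping preserves every dimensionality
#' invariant of the feature models; a different grouping table can be
#' supplied wherever a `side_chain_alphabet` argument is accepted.
#'
#' @param groups Named character vector mapping each of the 20 canonical
#'   letters to one of seven single-character group symbols. The default is
#'   the chemical partition above.
#' @return An object of class `side_chain_alphabet`: a list with elements
#'   `groups` (the mapping) and `symbols` (the 7 distinct group symbols,
#'   sorted).
#' @examples
#' alph <- side_chain_alphabet()
#' alph$groups[["K"]] == alph$groups[["R"]]  # both basic
#' @export
side_chain_alphabet <- function(groups = NULL) {
  if (is.null(groups)) {
    groups <- c(
      A = "1", V = "1", L = "1", I = "1",
      F = "2", W = "2", Y = "2",
      K = "3", R = "3", H = "3",
      D = "4", E = "4",
      S = "5", T = "5", N = "5", Q = "5",
      C = "6", M = "6",
      G = "7", P = "7"
    )
  }
  if (!all(AA_LETTERS %in% names(groups))) {
    stop("side-chain alphabet must map all 20 canonical amino-acid letters")
  }
  groups <- groups[AA_LETTERS]
  symbols <- sort(unique(unname(groups)))
  if (length(symbols) != 7L) {
    stop("side-chain alphabet must use exactly 7 distinct group symbols, got ",
         length(symbols))
  }
  if (any(nchar(symbols) != 1L)) stop("group symbols must be single characters")
  structure(list(groups = groups, symbols = symbols),
            class = "side_chain_alphabet")
}
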