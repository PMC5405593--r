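# Physicochemical constant tables (ExPASy ProtParam conventions).

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Average isotopic residue masses (Da); a peptide adds one water.
AA_MASS_AVG <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326)

MASS_WATER_AVG <- 18.01524

# Kyte-Doolittle hydropathy values (GRAVY is their arithmetic mean).
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# Bjellqvist pK values as used by ExPASy ProtParam.
PK_SIDECHAIN_NEG <- c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
PK_SIDECHAIN_POS <- c(H = 5.98, K = 10.00, R = 12.00)
PK_NTERM <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
              V = 7.44, E = 7.70)
PK_NTERM_DEFAULT <- 7.50
PK_CTERM <- c(D = 4.55, E = 4.75)
PK_CTERM_DEFAULT <- 3.55

# Guruprasad dipeptide instability weight values (DIWV); rows = first
# residue, columns = second. Unlisted pairs carry weight 1.
DIWV <- local({
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  v <- c(
    # A
    1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
    # C
    1, 1, 20.26, 1, 1, 1, 33.60, 1, 1, 20.26, 33.60, 1, 20.26, -6.54, 1, 1,
    33.60, -6.54, 24.68, 1,
    # D
    1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03,
    1, 1, 1,
    # E
    1, 44.94, 20.26, 33.60, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1,
    20.26, 1, 1, -14.03, 1,
    # F
    1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1,
    33.601,
    # G
    -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1,
    -7.49, 1, 13.34, -7.49,
    # H
    1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1,
    -6.54, 1, -1.88, 44.94,
    # I
    1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1,
    -7.49, 1, 1,
    # K
    1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.60, 1, -6.54, 24.64, 33.60,
    1, 1, -7.49, 1, 1,
    # L
    1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.60, 20.26, 1, 1, 1,
    24.68, 1,
    # M
    13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54,
    44.94, -1.88, 1, 1, 24.68,
    # N
    1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54,
    1, 1, -7.49, 1, -9.37, 1,
    # P
    20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26,
    -6.54, 20.26, 1, 20.26, -1.88, 1,
    # Q
    1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1,
    44.94, 1, -6.54, 1, -6.54,
    # R
    1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28,
    44.94, 1, 1, 58.28, -6.54,
    # S
    1, 33.60, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26,
    1, 1, 1, 1,
    # T
    1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1,
    1, -14.03, 1,
    # V
    1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49,
    1, 1, -6.54,
    # W
    -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1,
    -14.03, -7.49, 1, 1,
    # Y
    24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1,
    -15.91, 1, -7.49, 1, -9.37, 13.34)
  matrix(v, nrow = 20, byrow = TRUE, dimnames = list(aa, aa))
})

# Hydrophobic residues accepted at the zipper d register.
D_REGISTER_SET <- c("L", "I", "V", "M", "F")

# Charged residues used for the e/g charged-fraction statistics.
CHARGED_SET <- c("R", "K", "E", "D")

# Residues that make a g-e' pair "complete" (the repulsive lists of the
# dimerization lookup include Gln pairings, so Gln counts as chargeable).
CHARGEABLE_SET <- c("R", "K", "E", "D", "Q")
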