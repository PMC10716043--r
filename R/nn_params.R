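# Unified nearest-neighbour thermodynamic parameters for DNA duplexes.
#
# Watson-Crick propagation, initiation and symmetry terms follow the unified
# oligonucleotide parameter set (SantaLucia & Hicks 2004); internal
# single-mismatch stacks follow the Allawi/SantaLucia and Peyret mismatch
# series (G.T, G.A, C.T, A.C and like-with-like tables, including the
# published tandem-G.T entries). dH in kcal/mol, dS in cal/(mol K), 1 M NaCl
# reference; monovalent salt enters as an entropic correction (see
# duplex_thermo).
#
# Key convention: "XY/WZ" is the stack 5'-X Y-3' paired against 3'-W Z-5',
# i.e. pairs X.W and Y.Z. Each stack may be read from either strand; lookups
# try both readings.

.NN_WC <- list(
  "AA/TT" = c(-7.6, -21.3), "AT/TA" = c(-7.2, -20.4), "TA/AT" = c(-7.2, -21.3),
  "CA/GT" = c(-8.5, -22.7), "GT/CA" = c(-8.4, -22.4), "CT/GA" = c(-7.8, -21.0),
  "GA/CT" = c(-8.2, -22.2), "CG/GC" = c(-10.6, -27.2), "GC/CG" = c(-9.8, -24.4),
  "GG/CC" = c(-8.0, -19.9)
)

# duplex initiation, plus a penalty per terminal A.T pair and the
# symmetry correction for self-complementary duplexes
.NN_INIT     <- c(0.2, -5.7)
.NN_TERM_AT  <- c(2.2, 6.9)
.NN_SYM      <- c(0.0, -1.4)

.NN_MM <- list(
  # G.T mismatches (incl. tandem G.T entries)
  "AG/TT" = c(1.0, 0.9),   "AT/TG" = c(-2.5, -8.3), "CG/GT" = c(-4.1, -11.7),
  "CT/GG" = c(-2.8, -8.0), "GG/CT" = c(3.3, 10.4),  "GG/TT" = c(5.8, 16.3),
  "GT/CG" = c(-4.4, -12.3),"GT/TG" = c(4.1, 9.5),   "TG/AT" = c(-0.1, -1.7),
  "TG/GT" = c(-1.4, -6.2), "TT/AG" = c(-1.3, -5.3),
  # G.A mismatches
  "AA/TG" = c(-0.6, -2.3), "AG/TA" = c(-0.7, -2.3), "CA/GG" = c(-0.7, -2.3),
  "CG/GA" = c(-4.0, -13.2),"GA/CG" = c(-0.6, -1.0), "GG/CA" = c(0.5, 3.2),
  "TA/AG" = c(0.7, 0.7),   "TG/AA" = c(3.0, 7.4),
  # C.T mismatches
  "AC/TT" = c(0.7, 0.2),   "AT/TC" = c(-1.2, -6.2), "CC/GT" = c(-0.8, -4.5),
  "CT/GC" = c(-1.5, -6.1), "GC/CT" = c(2.3, 5.4),   "GT/CC" = c(5.2, 13.5),
  "TC/AT" = c(1.2, 0.7),   "TT/AC" = c(1.0, 0.7),
  # A.C mismatches
  "AA/TC" = c(2.3, 4.6),   "AC/TA" = c(5.3, 14.6),  "CA/GC" = c(1.9, 3.7),
  "CC/GA" = c(0.6, -0.6),  "GA/CC" = c(5.2, 14.2),  "GC/CA" = c(-0.7, -3.8),
  "TA/AC" = c(3.4, 8.0),   "TC/AA" = c(7.6, 20.2),
  # like-with-like (A.A, C.C, G.G, T.T)
  "AA/TA" = c(1.2, 1.7),   "CA/GA" = c(-0.9, -4.2), "GA/CA" = c(-2.9, -9.8),
  "TA/AA" = c(4.7, 12.9),
  "AC/TC" = c(0.0, -4.4),  "CC/GC" = c(-1.5, -7.2), "GC/CC" = c(3.6, 8.9),
  "TC/AC" = c(6.1, 16.4),
  "AG/TG" = c(-3.1, -9.5), "CG/GG" = c(-4.9, -15.3),"GG/CG" = c(-6.0, -15.8),
  "TG/AG" = c(1.6, 3.6),
  "AT/TT" = c(-2.7, -10.8),"CT/GT" = c(-5.0, -15.8),"GT/CT" = c(-2.2, -8.4),
  "TT/AT" = c(0.2, -1.5)
)

# Gas constant in cal/(mol K) and kcal/(mol K); the molar gas constant
# replaces the per-molecule Boltzmann constant for molar free energies.
.R_CAL  <- 1.9872
.R_KCAL <- 1.9872e-3

.BASES <- c("A", "C", "G", "T")

# Dense 16x16 stack lookup, indexed by pair codes p = 4*(top-1) + bottom
# (top base 5'->3', bottom base read 3'->5' opposite it, both 1..4).
# Stacks with no published value (both pairs mismatched, except the tandem
# G.T entries) contribute zero; such tandem runs are thereby scored as the
# sum of their flanking single-mismatch stacks.
.build_stack_tables <- function() {
  dH <- matrix(0, 16, 16)
  dS <- matrix(0, 16, 16)
  code <- function(top, bot) 4L * (match(top, .BASES) - 1L) + match(bot, .BASES)
  put <- function(key, val) {
    x1 <- substr(key, 1, 1); x2 <- substr(key, 2, 2)
    y1 <- substr(key, 4, 4); y2 <- substr(key, 5, 5)
    i <- code(x1, y1); j <- code(x2, y2)
    dH[i, j] <<- val[1]; dS[i, j] <<- val[2]
    # reading from the complementary strand: 5'-y2 y1-3' / 3'-x2 x1-5'
    i2 <- code(y2, x2); j2 <- code(y1, x1)
    dH[i2, j2] <<- val[1]; dS[i2, j2] <<- val[2]
  }
  for (k in names(.NN_WC)) put(k, .NN_WC[[k]])
  for (k in names(.NN_MM)) put(k, .NN_MM[[k]])
  list(dH = dH, dS = dS)
}

.nn_env <- new.env(parent = emptyenv())

.stack_tables <- function() {
  if (is.null(.nn_env$tabs)) .nn_env$tabs <- .build_stack_tables()
  .nn_env$tabs
}

.encode_seq <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], .BASES) - 1L
}

# Reference design constants (explicit stand-ins for the deployed strands;
# see reference_design() and the methods vignette for the calibration:
# the overlap duplex melts at 65 C at a 75 uM pool in 150 mM NaCl, and the
# adaptor melts >= 10 C above the hottest n = 4 overlap variant).
.REF_OVERLAP <- "GCCACAGTTGCGTC"
.REF_ADAPTOR <- "CGGACGCGACTCGCCGCCCG"
.REF_N_POSITIONS <- c(3L, 6L, 9L, 12L)
.REF_CODE_POSITIONS <- c(3L, 6L, 9L, 12L, 7L)
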