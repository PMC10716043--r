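# Independent oracles used to freeze expected values. These deliberately
# re-derive results through different code paths (string-keyed lookups,
# naive enumeration, numeric root-finding) than the package internals.

.o_bases <- c("A", "C", "G", "T")
.o_comp <- c(A = "T", C = "G", G = "C", T = "A")

o_revcomp <- function(s) {
  paste(rev(.o_comp[strsplit(s, "")[[1]]]), collapse = "")
}

# stack lookup by string key with both strand readings; NULL when
# unparameterised (tandem mismatches other than the published G.T ones)
o_stack <- function(x1, x2, y1, y2) {
  tabs <- c(dnagel:::.NN_WC, dnagel:::.NN_MM)
  k1 <- paste0(x1, x2, "/", y1, y2)
  k2 <- paste0(y2, y1, "/", x2, x1)
  if (!is.null(tabs[[k1]])) tabs[[k1]] else tabs[[k2]]
}

# Naive exhaustive MFE: every antiparallel register, every window with
# Watson-Crick ends, scored stack by stack.
o_mfe <- function(a, b, temp_C = 20, na_M = 0.15) {
  av <- strsplit(a, "")[[1]]; bv <- rev(strsplit(b, "")[[1]])
  la <- length(av); lb <- length(bv)
  tk <- temp_C + 273.15
  best <- 0
  for (s in (-(lb - 1)):(la - 1)) {
    i0 <- max(1, s + 1); i1 <- min(la, s + lb)
    w <- i1 - i0 + 1
    if (w < 2) next
    top <- av[i0:i1]; bot <- bv[(i0 - s):(i1 - s)]
    wc <- bot == .o_comp[top]
    for (i in seq_len(w - 1)) {
      if (!wc[i]) next
      for (j in (i + 1):w) {
        if (!wc[j]) next
        dH <- dnagel:::.NN_INIT[1]; dS <- dnagel:::.NN_INIT[2]
        for (k in i:(j - 1)) {
          v <- o_stack(top[k], top[k + 1], bot[k], bot[k + 1])
          if (!is.null(v)) { dH <- dH + v[1]; dS <- dS + v[2] }
        }
        for (e in c(i, j)) {
          if ((top[e] == "A" && bot[e] == "T") || (top[e] == "T" && bot[e] == "A")) {
            dH <- dH + dnagel:::.NN_TERM_AT[1]
            dS <- dS + dnagel:::.NN_TERM_AT[2]
          }
        }
        dS <- dS + 0.368 * (j - i) * log(na_M)
        g <- dH - tk * dS / 1000
        if (g < best) best <- g
      }
    }
  }
  best
}

# Exhaustive enumeration of splint assignments on one backbone: mean
# engaged-anchor fraction over all (2C)^m equally likely draws.
o_intra_enum <- function(m, C, mode = c("any", "mm")) {
  mode <- match.arg(mode)
  two_c <- 2L * C
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(two_c) - 1L), m)))
  frac <- apply(grid, 1, function(v) {
    if (mode == "any") {
      eng <- vapply(seq_along(v), function(i) {
        comp <- bitwXor(v[i], 1L)
        any(v[-i] == comp)
      }, logical(1))
      mean(eng)
    } else {
      tot <- 0L
      for (p in seq_len(C) - 1L) {
        tot <- tot + min(sum(v == 2L * p), sum(v == 2L * p + 1L))
      }
      2 * tot / m
    }
  })
  mean(frac)
}

# Two-state fraction bound of a non-self-complementary duplex at equal
# strand concentrations; root-find the temperature where it equals 0.5.
o_tm_root <- function(dH, dS, c_total) {
  frac <- function(tk) {
    K <- exp(-(dH * 1000 - tk * dS) / (1.9872 * tk))
    c0 <- c_total / 2
    # x = bound duplex: K = x / (c0 - x)^2
    x <- ((2 * K * c0 + 1) - sqrt((2 * K * c0 + 1)^2 - 4 * K^2 * c0^2)) / (2 * K)
    x / c0
  }
  stats::uniroot(function(tk) frac(tk) - 0.5, c(200, 450), tol = 1e-9)$root - 273.15
}

random_seq <- function(len) {
  paste(sample(.o_bases, len, replace = TRUE), collapse = "")
}
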