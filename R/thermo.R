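#' Thermodynamic conditions for hybridization predictions
#'
#' The default conditions match the study design for splint selectivity:
#' 20 degrees C, 150 mM NaCl and a 75 uM total splint pool (37.5 uM for
#' each splint strand before library expansion).
#'
#' @param temperature_C Temperature in degrees Celsius.
#' @param na_mM Monovalent sodium concentration in mM.
#' @param total_conc_uM Total strand concentration in uM.
#' @param rule How the pool is shared among explicit variants:
#'   \code{"equal_split"} divides the pool over all \eqn{2C} strands (used
#'   for melting predictions), \code{"fixed"} keeps every variant at its
#'   nominal pre-expansion concentration (used for selectivity).
#' @return Object of class \code{thermo_conditions} with fields in SI-ish
#'   units: \code{temperature} (K), \code{sodium} (mol/L),
#'   \code{total_strand_conc} (mol/L), \code{per_variant_conc_rule}.
#' @export
thermo_conditions <- function(temperature_C = 20, na_mM = 150,
                              total_conc_uM = 75,
                              rule = c("equal_split", "fixed")) {
  rule <- match.arg(rule)
  stopifnot(temperature_C > -273.15, na_mM > 0, total_conc_uM > 0)
  structure(list(temperature = temperature_C + 273.15,
                 sodium = na_mM * 1e-3,
                 total_strand_conc = total_conc_uM * 1e-6,
                 per_variant_conc_rule = rule),
            class = "thermo_conditions")
}

#' @export
print.thermo_conditions <- function(x, ...) {
  cat(sprintf("thermo conditions: %.1f C, %.0f mM Na+, %.2f uM total DNA (%s)\n",
              x$temperature - 273.15, x$sodium * 1e3,
              x$total_strand_conc * 1e6, x$per_variant_conc_rule))
  invisible(x)
}

# column pair codes of a full-length antiparallel alignment (1..16)
.pair_codes <- function(a, b) {
  ac <- .encode_seq(a)
  bc <- rev(.encode_seq(b))
  if (length(ac) != length(bc))
    stop("full-length duplex requires equal strand lengths", call. = FALSE)
  list(top = ac, bot = bc, code = 4L * ac + bc + 1L,
       wc = bc == 3L - ac)
}

#' Nearest-neighbour thermodynamics of a duplex
#'
#' Sums unified nearest-neighbour stack enthalpies and entropies (including
#' internal single-mismatch parameters) over the full-length antiparallel
#' alignment of \code{b} against \code{a}, adds duplex initiation and
#' terminal A.T penalties, applies the entropic monovalent-salt correction
#' \eqn{\Delta S \mathrel{+}= 0.368\, n_{stacks} \ln[Na^+]}, and evaluates
#' \eqn{\Delta G = \Delta H - T \Delta S / 1000} at the condition
#' temperature. Terminal mismatched columns are trimmed (treated as
#' neutral overhangs).
#'
#' @param a,b Explicit sequences, both 5'->3', equal length.
#' @param cond A \code{thermo_conditions} object.
#' @return Object of class \code{duplex_thermo}: \code{dH} (kcal/mol),
#'   \code{dS} (cal/mol/K, salt-corrected), \code{dG_at_T} (kcal/mol),
#'   \code{tm} (deg C at the condition's total strand concentration),
#'   \code{self_complementary}.
#' @examples
#' duplex_thermo("ACGTACGTAC", reverse_complement("ACGTACGTAC"))
#' @export
duplex_thermo <- function(a, b, cond = thermo_conditions()) {
  a <- .check_alphabet(a, allow_n = FALSE)
  b <- .check_alphabet(b, allow_n = FALSE)
  pc <- .pair_codes(a, b)
  keep <- which(pc$wc)
  if (length(keep) == 0L || length(pc$code) < 2L)
    stop("no nearest-neighbour stack defined (duplex shorter than 2 bp)",
         call. = FALSE)
  i0 <- keep[1]; i1 <- keep[length(keep)]
  if (i1 - i0 < 1L)
    stop("no nearest-neighbour stack defined (fewer than 2 paired positions)",
         call. = FALSE)
  tabs <- .stack_tables()
  idx <- cbind(pc$code[i0:(i1 - 1L)], pc$code[(i0 + 1L):i1])
  dH <- .NN_INIT[1] + sum(tabs$dH[idx])
  dS <- .NN_INIT[2] + sum(tabs$dS[idx])
  for (end in c(i0, i1)) {
    if ((pc$top[end] == 0L && pc$bot[end] == 3L) ||
        (pc$top[end] == 3L && pc$bot[end] == 0L)) {
      dH <- dH + .NN_TERM_AT[1]
      dS <- dS + .NN_TERM_AT[2]
    }
  }
  selfc <- identical(a, b) && identical(a, reverse_complement(a))
  if (selfc) dS <- dS + .NN_SYM[2]
  n_stacks <- i1 - i0
  dS <- dS + 0.368 * n_stacks * log(cond$sodium)
  dG <- dH - cond$temperature * dS / 1000
  tm <- if (dH < 0) {
    .tm_two_state(dH, dS, cond$total_strand_conc, selfc)
  } else NA_real_
  structure(list(dH = dH, dS = dS, dG_at_T = dG, tm = tm,
                 temperature = cond$temperature,
                 self_complementary = selfc, n_stacks = n_stacks),
            class = "duplex_thermo")
}

#' @export
print.duplex_thermo <- function(x, ...) {
  cat(sprintf("duplex: dH = %.2f kcal/mol, dS = %.2f cal/(mol K), dG(%.1f C) = %.2f kcal/mol",
              x$dH, x$dS, x$temperature - 273.15, x$dG_at_T))
  if (is.finite(x$tm)) cat(sprintf(", Tm = %.1f C", x$tm))
  cat("\n")
  invisible(x)
}

.tm_two_state <- function(dH, dS, c_total, self_complementary = FALSE) {
  x <- if (self_complementary) 1 else 4
  1000 * dH / (dS + .R_CAL * log(c_total / x)) - 273.15
}

#' Two-state melting temperature of a duplex
#'
#' \eqn{T_m = 1000 \Delta H / (\Delta S + R \ln(c_{total}/4)) - 273.15}
#' for a non-self-complementary duplex with both strands at equal
#' concentration (\eqn{c_{total}/1} when self-complementary);
#' \eqn{R = 1.9872} cal/(mol K). \code{dS} must already carry the salt
#' correction (as returned by \code{\link{duplex_thermo}}).
#'
#' @param thermo A \code{duplex_thermo} object.
#' @param c_total Total strand concentration in mol/L.
#' @param self_complementary Logical; defaults to the duplex's own flag.
#' @return Melting temperature in degrees C.
#' @export
melting_temperature <- function(thermo, c_total,
                                self_complementary = thermo$self_complementary) {
  if (!is.finite(thermo$dH) || thermo$dH >= 0)
    stop("dH >= 0: duplex has no two-state melting transition", call. = FALSE)
  stopifnot(c_total > 0)
  .tm_two_state(thermo$dH, thermo$dS, c_total, self_complementary)
}

#' Minimum free energy of an ungapped two-strand complex
#'
#' Scans every antiparallel register of \code{b} against \code{a} and every
#' sub-window whose ends are Watson-Crick pairs, scoring matched stacks and
#' internal mismatches with the unified nearest-neighbour tables (tandem
#' mismatches as the sum of their flanking single-mismatch stacks) and
#' treating unpaired overhangs as neutral. Returns 0 when no register is
#' stabilizing, so the value is the hybridization free energy relative to
#' the unbound state.
#'
#' @param a,b Explicit sequences 5'->3', lengths <= 32.
#' @param cond A \code{thermo_conditions} object.
#' @return MFE in kcal/mol (<= 0).
#' @export
mfe_duplex <- function(a, b, cond = thermo_conditions()) {
  a <- .check_alphabet(a, allow_n = FALSE)
  b <- .check_alphabet(b, allow_n = FALSE)
  if (nchar(a) > 32L || nchar(b) > 32L)
    stop("mfe_duplex supports strands up to 32 nt", call. = FALSE)
  tabs <- .stack_tables()
  .mfe_duplex_cpp(.encode_seq(a), .encode_seq(b), tabs$dH, tabs$dS,
                  cond$temperature, 0.368 * log(cond$sodium),
                  .NN_INIT, .NN_TERM_AT)
}

#' Pairwise MFE matrix of a crosslinker library
#'
#' \code{mfe[x, y] = mfe_duplex(forward_x, reverse_y)}: the diagonal holds
#' the intended splint pairs, off-diagonal entries the cross-talk between
#' non-partners.
#'
#' @param library A \code{crosslinker_library}.
#' @param cond A \code{thermo_conditions} object.
#' @param max_complexity Guard against accidental huge matrices
#'   (default 256, the deployed library range).
#' @return Object of class \code{energy_matrix}: \code{mfe} (kcal/mol,
#'   rows = forward pair_id, cols = reverse pair_id), \code{temperature}.
#' @export
mfe_matrix <- function(library, cond = thermo_conditions(),
                       max_complexity = 256L) {
  p <- library$pairs
  if (nrow(p) > max_complexity)
    stop(sprintf("library has %d pairs; raise max_complexity to proceed",
                 nrow(p)), call. = FALSE)
  bad <- p$pair_id[!grepl("^[ACGT]+$", p$forward) |
                   !grepl("^[ACGT]+$", p$reverse)]
  if (length(bad))
    stop(sprintf("non-explicit sequence in pair(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  tabs <- .stack_tables()
  fwd <- do.call(rbind, lapply(p$forward, .encode_seq))
  rev_ <- do.call(rbind, lapply(p$reverse, .encode_seq))
  m <- .mfe_matrix_cpp(fwd, rev_, tabs$dH, tabs$dS,
                       cond$temperature, 0.368 * log(cond$sodium),
                       .NN_INIT, .NN_TERM_AT)
  dimnames(m) <- list(p$pair_id, p$pair_id)
  structure(list(mfe = m, row_ids = p$pair_id, col_ids = p$pair_id,
                 temperature = cond$temperature),
            class = "energy_matrix")
}

#' @export
print.energy_matrix <- function(x, ...) {
  cat(sprintf("%dx%d MFE matrix (kcal/mol) at %.1f C; diagonal mean %.2f\n",
              nrow(x$mfe), ncol(x$mfe), x$temperature - 273.15,
              mean(diag(x$mfe))))
  invisible(x)
}

#' Boltzmann selectivity of splint pairing
#'
#' Converts an MFE matrix into pairing probabilities: each row is the
#' Boltzmann distribution of one forward splint over all reverse splints,
#' \eqn{B_{x,y} = e^{-MFE(x,y)/RT}} normalized per row
#' (\eqn{B^{norm}_{x,y} = B_{x,y} / \sum_y B_{x,y}}), with
#' \eqn{R = 1.987\times10^{-3}} kcal/(mol K). Rows are shifted by their
#' minimum MFE before exponentiation for numerical stability.
#'
#' @param E An \code{energy_matrix}.
#' @param cond A \code{thermo_conditions} object (supplies the temperature).
#' @return Object of class \code{selectivity_matrix}: \code{boltzmann}
#'   (unnormalized, at face value), \code{normalized} (rows sum to 1),
#'   \code{diagonal_min}.
#' @export
boltzmann_selectivity <- function(E, cond = thermo_conditions()) {
  mfe <- E$mfe
  if (!all(is.finite(mfe))) stop("MFE matrix has non-finite entries", call. = FALSE)
  rt <- .R_KCAL * cond$temperature
  shift <- apply(mfe, 1, min)
  w <- exp(-(mfe - shift) / rt)
  norm <- w / rowSums(w)
  dimnames(norm) <- dimnames(mfe)
  structure(list(boltzmann = exp(-mfe / rt), normalized = norm,
                 diagonal_min = min(diag(norm)),
                 temperature = cond$temperature),
            class = "selectivity_matrix")
}

#' @export
print.selectivity_matrix <- function(x, ...) {
  s <- selectivity_summary(x)
  cat(sprintf("%dx%d selectivity matrix: diagonal min %.4f, mean %.4f, worst off-diagonal %.4f\n",
              nrow(x$normalized), ncol(x$normalized),
              s$diagonal_min, s$diagonal_mean, s$worst_offdiagonal))
  invisible(x)
}

#' @export
plot.selectivity_matrix <- function(x, ...) {
  graphics::image(t(x$normalized)[, nrow(x$normalized):1],
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE,
                  main = "normalized Boltzmann pairing probability", ...)
  invisible(x)
}

#' Summary statistics of a selectivity matrix
#'
#' @param S A \code{selectivity_matrix}.
#' @return List with \code{diagonal_min}, \code{diagonal_mean},
#'   \code{worst_offdiagonal} (largest off-diagonal pairing probability).
#' @export
selectivity_summary <- function(S) {
  m <- S$normalized
  if (nrow(m) != ncol(m)) stop("selectivity matrix must be square", call. = FALSE)
  off <- m
  diag(off) <- -Inf
  list(diagonal_min = min(diag(m)),
       diagonal_mean = mean(diag(m)),
       worst_offdiagonal = if (nrow(m) > 1L) max(off) else 0)
}

#' Predicted matrix melting versus library complexity
#'
#' Under the equal-split rule a fixed total splint pool is shared over all
#' \eqn{2C} strands, so each intended overlap duplex sits at total pair
#' concentration \eqn{c_{total}/C} and its two-state melting temperature
#' drops as the library complexity grows. Returns the per-variant melting
#' temperatures of the library at its own dilution plus the melting trend
#' of a representative (median-stability) variant across
#' \eqn{C \in \{1, 4, 16, 64, 256\}}.
#'
#' @param library A \code{crosslinker_library}.
#' @param cond A \code{thermo_conditions} object.
#' @param c_splint_total Total splint strand pool in mol/L (default: the
#'   condition's total strand concentration).
#' @param trend_C Complexities for the trend report.
#' @return List: \code{per_variant} data.frame (pair_id, tm), \code{trend}
#'   data.frame (C, tm), \code{drop} = trend tm at min(C) minus at max(C).
#' @export
predicted_matrix_melting <- function(library, cond = thermo_conditions(),
                                     c_splint_total = cond$total_strand_conc,
                                     trend_C = c(1L, 4L, 16L, 64L, 256L)) {
  p <- library$pairs
  C <- library$complexity
  th <- lapply(seq_len(nrow(p)),
               function(i) duplex_thermo(p$forward[i], p$reverse[i], cond))
  tm_own <- vapply(th, function(t)
    melting_temperature(t, c_splint_total / C, FALSE), numeric(1))
  # representative: median-Tm variant at the library's own dilution
  rep_i <- order(tm_own)[ceiling(length(tm_own) / 2)]
  trend <- data.frame(
    C = as.integer(trend_C),
    tm = vapply(trend_C, function(cc)
      melting_temperature(th[[rep_i]], c_splint_total / cc, FALSE),
      numeric(1)))
  list(per_variant = data.frame(pair_id = p$pair_id, tm = tm_own),
       trend = trend,
       drop = trend$tm[which.min(trend$C)] - trend$tm[which.max(trend$C)])
}

#' Check the adaptor/overlap melting-temperature hierarchy
#'
#' The dual-splint design requires the adaptor domain (anchor binding, T1)
#' to melt well above every overlap variant (splint-splint pairing, T2) so
#' that a one-pot anneal binds adaptors first and overlaps second.
#'
#' @param adaptor Explicit adaptor sequence or \code{ambiguous_domain}.
#' @param overlap Overlap design (may contain N) or \code{ambiguous_domain}.
#' @param cond A \code{thermo_conditions} object.
#' @param min_gap Required separation T1 - T2 in degrees C (default 10).
#' @return List with \code{T1}, \code{T2} (max over overlap variants),
#'   \code{gap} and logical \code{pass}.
#' @export
domain_hierarchy <- function(adaptor, overlap, cond = thermo_conditions(),
                             min_gap = 10) {
  aseq <- if (inherits(adaptor, "ambiguous_domain")) adaptor$sequence else adaptor
  t1 <- duplex_thermo(aseq, reverse_complement(aseq), cond)$tm
  variants <- expand_ambiguous(overlap)
  t2 <- max(vapply(variants, function(v)
    duplex_thermo(v, reverse_complement(v), cond)$tm, numeric(1)))
  list(T1 = t1, T2 = t2, gap = t1 - t2, pass = (t1 - t2) >= min_gap)
}

#' Heat-activated crosslinker (HAC) design
#'
#' A blocking strand complementary to a contiguous sub-segment of the
#' overlap domain protects the splint from premature pairing; it must be
#' supplied in excess of the splint (the deployed recipe uses 2:1,
#' 80 uM blocker against 40 uM splint).
#'
#' @param overlap Explicit overlap sequence or \code{ambiguous_domain}.
#' @param blocking Explicit blocking-strand sequence.
#' @param blocking_conc,splint_conc Concentrations in mol/L.
#' @return Object of class \code{hac_design}.
#' @export
hac_design <- function(overlap, blocking, blocking_conc = 80e-6,
                       splint_conc = 40e-6) {
  oseq <- if (inherits(overlap, "ambiguous_domain")) overlap$sequence else
    .check_alphabet(overlap, allow_n = TRUE)
  blocking <- .check_alphabet(blocking, allow_n = FALSE)
  target <- reverse_complement(blocking)
  if (!grepl(target, oseq, fixed = TRUE))
    stop("blocking strand is not complementary to a contiguous segment of the overlap domain",
         call. = FALSE)
  if (blocking_conc < splint_conc)
    stop("blocking_conc must be >= splint_conc (blocker in excess)", call. = FALSE)
  structure(list(overlap = oseq, blocking = blocking, target = target,
                 blocking_conc = blocking_conc, splint_conc = splint_conc),
            class = "hac_design")
}

#' Blocking-strand occupancy versus temperature
#'
#' Two-state fraction of overlap domains bound by the blocking strand as a
#' function of temperature, at the stated strand concentrations
#' (competition with splint-splint pairing is ignored, so the curve is the
#' protection upper bound). The activation temperature is where the
#' occupancy crosses 0.5, i.e. the blocking duplex melting temperature at
#' these concentrations.
#'
#' @param hac A \code{hac_design}.
#' @param cond A \code{thermo_conditions} object (salt).
#' @param t_range Temperature sweep range in degrees C.
#' @param n Number of sweep points.
#' @return List: \code{curve} data.frame (temp_C, occupancy),
#'   \code{activation_temperature} (deg C, NA if no crossing in range),
#'   \code{heat_activatable} (occupancy > 0.99 at 4 C and < 0.5 at 37 C).
#' @export
blocking_occupancy <- function(hac, cond = thermo_conditions(),
                               t_range = c(0, 80), n = 161L) {
  b0 <- hac$blocking_conc; s0 <- hac$splint_conc
  temps <- seq(t_range[1], t_range[2], length.out = n)
  occ_at <- function(tC) {
    cc <- thermo_conditions(tC, cond$sodium * 1e3,
                            cond$total_strand_conc * 1e6)
    th <- duplex_thermo(hac$target, hac$blocking, cc)
    K <- exp(-th$dG_at_T / (.R_KCAL * cc$temperature))
    # K x^2 - (K(b0+s0)+1) x + K b0 s0 = 0, x = bound duplex conc
    bq <- K * (b0 + s0) + 1
    x <- (bq - sqrt(bq^2 - 4 * K^2 * b0 * s0)) / (2 * K)
    min(1, max(0, x / s0))
  }
  occ <- vapply(temps, occ_at, numeric(1))
  act <- NA_real_
  cross <- which(occ[-1] < 0.5 & occ[-n] >= 0.5)
  if (length(cross)) {
    f <- function(tC) occ_at(tC) - 0.5
    act <- stats::uniroot(f, c(temps[cross[1]], temps[cross[1] + 1L]),
                          tol = 1e-6)$root
  }
  list(curve = data.frame(temp_C = temps, occupancy = occ),
       activation_temperature = act,
       heat_activatable = isTRUE(occ_at(4) > 0.99 && occ_at(37) < 0.5))
}
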