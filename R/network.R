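#' Polymer backbone specification
#'
#' Describes a DNA-functionalized polymer: backbone molar mass, mean number
#' of anchor strands per backbone (m), and mass concentration in % (w/v)
#' (g per 100 mL). The molar anchor concentration is derived as
#' \code{mass_conc * 10 / backbone_mass * m} unless given explicitly;
#' the deployed recipes state the anchor equivalence directly (75 uM of
#' crosslinkers for 1% (w/v) of the 20-anchor backbone), so an explicit
#' \code{anchor_conc} overrides the derivation.
#'
#' @param backbone_mass Backbone molar mass in Da (default 3e6).
#' @param anchors_per_backbone Mean anchors per backbone, m.
#' @param mass_conc Mass concentration in % (w/v).
#' @param anchor_conc Optional explicit anchor concentration in mol/L.
#' @param rgd Logical flag for RGD-peptide-grafted derivatives (metadata).
#' @return Object of class \code{polymer_spec}.
#' @examples
#' p5 <- polymer_spec(anchors_per_backbone = 20, mass_conc = 1,
#'                    anchor_conc = 75e-6)
#' @export
polymer_spec <- function(backbone_mass = 3e6, anchors_per_backbone,
                         mass_conc = 1, anchor_conc = NULL, rgd = FALSE) {
  stopifnot(backbone_mass > 0, anchors_per_backbone > 0, mass_conc > 0)
  derived <- mass_conc * 10 / backbone_mass * anchors_per_backbone
  if (is.null(anchor_conc)) anchor_conc <- derived
  stopifnot(anchor_conc > 0)
  structure(list(backbone_mass = backbone_mass,
                 anchors_per_backbone = anchors_per_backbone,
                 mass_conc = mass_conc, anchor_conc = anchor_conc,
                 rgd = isTRUE(rgd)),
            class = "polymer_spec")
}

#' @export
print.polymer_spec <- function(x, ...) {
  cat(sprintf("polymer: %.2g Da backbone, m = %g anchors, %.2g%% (w/v), anchors %.3g uM%s\n",
              x$backbone_mass, x$anchors_per_backbone, x$mass_conc,
              x$anchor_conc * 1e6, if (x$rgd) " (RGD)" else ""))
  invisible(x)
}

#' Closed-form intramolecular-crosslink fraction (any-partner model)
#'
#' For a backbone with exactly \code{m} anchors, each carrying a splint
#' drawn uniformly from the \eqn{2C} library variants, the probability that
#' a given anchor's splint finds at least one complementary splint among
#' the other \eqn{m - 1} anchors of the same backbone is
#' \deqn{f = 1 - (1 - 1/(2C))^{m-1}.}
#' This is the worst-case (eligibility) count: it upper-bounds the pairing
#' fraction obtained when each anchor can engage at most one partner.
#'
#' @param m Anchors per backbone (>= 1).
#' @param C Library complexity (>= 1); vectorized over \code{C}.
#' @return Fraction in [0, 1].
#' @examples
#' intramolecular_fraction_analytic(3, 1)   # 0.75
#' intramolecular_fraction_analytic(3, 4)   # 15/64
#' @export
intramolecular_fraction_analytic <- function(m, C) {
  stopifnot(m >= 1, all(C >= 1))
  1 - (1 - 1 / (2 * C))^(m - 1)
}

#' Monte-Carlo partition of crosslinks on a single backbone
#'
#' Simulates \code{n_chains} backbones. Each carries a fixed or
#' Poisson-distributed number of anchors; every anchor binds a splint drawn
#' uniformly from the \eqn{2C} variants. Under \code{"any_partner"} an
#' anchor counts as intramolecularly engaged when any other anchor on the
#' chain carries the complementary variant (worst case); under
#' \code{"max_matching"} anchors engage pairwise, and the engaged count is
#' twice the maximum complementary matching
#' (\eqn{\sum_p \min(n^{fwd}_p, n^{rev}_p)}). Runs are bit-reproducible for
#' a given seed.
#'
#' @param m Mean anchors per backbone.
#' @param C Library complexity.
#' @param n_chains Number of simulated backbones.
#' @param partner_model \code{"max_matching"} (default) or
#'   \code{"any_partner"}.
#' @param anchor_model \code{"fixed"} (default) or \code{"poisson"}.
#' @param seed Integer seed (recorded in the result).
#' @return Object of class \code{crosslink_sim}:
#'   \code{intramolecular_fraction}, binomial 95% CI half-width
#'   \code{ci95}, and the echoed configuration.
#' @export
simulate_crosslink_partition <- function(m, C, n_chains = 1e5,
                                         partner_model = c("max_matching",
                                                           "any_partner"),
                                         anchor_model = c("fixed", "poisson"),
                                         seed = 1L) {
  partner_model <- match.arg(partner_model)
  anchor_model <- match.arg(anchor_model)
  stopifnot(C >= 1, n_chains >= 1, m >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  res <- .crosslink_sim_cpp(as.integer(m), as.integer(C),
                            as.integer(n_chains),
                            anchor_model == "poisson",
                            if (partner_model == "any_partner") 0L else 1L)
  p <- res$fraction
  ci <- if (res$n_anchors > 0) 1.96 * sqrt(p * (1 - p) / res$n_anchors) else NA_real_
  structure(list(intramolecular_fraction = p, ci95 = ci,
                 n_chains = as.integer(n_chains), n_anchors = res$n_anchors,
                 m = m, C = as.integer(C),
                 partner_model = partner_model, anchor_model = anchor_model,
                 seed = as.integer(seed)),
            class = "crosslink_sim")
}

#' @export
print.crosslink_sim <- function(x, ...) {
  cat(sprintf("intramolecular fraction %.4f +/- %.4f (m = %g, C = %d, %s/%s, %d chains, seed %d)\n",
              x$intramolecular_fraction, x$ci95, x$m, x$C,
              x$partner_model, x$anchor_model, x$n_chains, x$seed))
  invisible(x)
}

#' Minimal library complexity for intramolecular-crosslink suppression
#'
#' Sweeps the integer complexity grid upward and reports the smallest
#' \eqn{C} at which the intramolecular fraction drops to
#' \eqn{1 - suppression} or below (absolute interpretation: suppressing
#' 80% means a fraction of at most 20%). A relative interpretation
#' (fraction reduced to \eqn{(1-suppression)} of its \eqn{C = 1} value) is
#' available via \code{relative = TRUE}.
#'
#' @param m Mean anchors per backbone.
#' @param suppression Target suppression in (0, 1), e.g. 0.8.
#' @param partner_model,anchor_model,n_chains,seed Passed to
#'   \code{\link{simulate_crosslink_partition}}.
#' @param C_max Upper end of the integer grid (default 1024).
#' @param relative Use the relative interpretation (default FALSE).
#' @return List with \code{C_min_simulated}, \code{C_min_analytic}
#'   (any-partner closed form; NA under the relative rule with matching),
#'   \code{threshold}, and the model configuration.
#' @export
min_complexity_for_suppression <- function(m, suppression = 0.8,
                                           partner_model = c("max_matching",
                                                             "any_partner"),
                                           anchor_model = c("fixed", "poisson"),
                                           n_chains = 1e5, seed = 1L,
                                           C_max = 1024L, relative = FALSE) {
  partner_model <- match.arg(partner_model)
  anchor_model <- match.arg(anchor_model)
  stopifnot(suppression > 0, suppression < 1)
  base <- if (relative) {
    simulate_crosslink_partition(m, 1L, n_chains, partner_model,
                                 anchor_model, seed)$intramolecular_fraction
  } else 1
  threshold <- (1 - suppression) * base
  # analytic any-partner crossing on the same grid
  fa <- intramolecular_fraction_analytic(m, seq_len(C_max))
  thr_a <- (1 - suppression) * (if (relative) fa[1] else 1)
  hit_a <- which(fa <= thr_a)
  C_analytic <- if (length(hit_a)) hit_a[1] else NA_integer_
  C_sim <- NA_integer_
  for (C in seq_len(C_max)) {
    f <- simulate_crosslink_partition(m, C, n_chains, partner_model,
                                      anchor_model,
                                      seed + C)$intramolecular_fraction
    if (f <= threshold) { C_sim <- C; break }
  }
  if (is.na(C_sim))
    stop(sprintf("suppression target not reached on grid 1..%d (fraction %.3f at grid maximum)",
                 C_max, f), call. = FALSE)
  list(C_min_simulated = C_sim, C_min_analytic = C_analytic,
       threshold = threshold, suppression = suppression, m = m,
       partner_model = partner_model, anchor_model = anchor_model,
       n_chains = n_chains, relative = relative, seed = as.integer(seed))
}

# Physical constants (SI)
.KB <- 1.380649e-23   # J/K
.NA_AVOGADRO <- 6.02214076e23

#' Theoretical maximum shear modulus of an affine network
#'
#' Rubber elasticity for an affine network: \eqn{G' = \nu k_B T} with
#' \eqn{\nu} the crosslink number density. At full conversion every
#' crosslink consumes two anchor strands, so
#' \eqn{\nu_{max} = N_A \cdot c_{anchor} / 2} (per m^3) and
#' \eqn{G'_{max} = \nu_{max} k_B T}. A phantom-network normalization
#' (prefactor \eqn{1 - 2/\phi} for junction functionality \eqn{\phi = 4})
#' is available behind \code{model = "phantom"}.
#'
#' @param p A \code{polymer_spec} (supplies \code{anchor_conc} in mol/L).
#' @param T_K Temperature in kelvin.
#' @param model \code{"affine"} (default) or \code{"phantom"}.
#' @return Modulus in Pa.
#' @examples
#' p5 <- polymer_spec(anchors_per_backbone = 20, anchor_conc = 75e-6)
#' theoretical_max_modulus(p5, 293)  # ~91 Pa
#' @export
theoretical_max_modulus <- function(p, T_K = 293.15,
                                    model = c("affine", "phantom")) {
  model <- match.arg(model)
  if (is.null(p$anchor_conc) || !is.finite(p$anchor_conc))
    stop("anchor concentration unknown; supply anchor_conc in polymer_spec",
         call. = FALSE)
  stopifnot(T_K >= 0)
  nu <- .NA_AVOGADRO * p$anchor_conc * 1000 / 2  # crosslinks per m^3
  g <- nu * .KB * T_K
  if (model == "phantom") g <- g * (1 - 2 / 4)
  g
}

#' Crosslinking efficiency from the affine network model
#'
#' Inverts \eqn{G' = \nu k_B T}: the efficiency is the measured plateau
#' modulus over the theoretical maximum at full anchor conversion.
#'
#' @param g_measured Measured storage modulus in Pa (>= 0).
#' @param p A \code{polymer_spec}.
#' @param T_K Temperature in kelvin.
#' @param model Passed to \code{\link{theoretical_max_modulus}}.
#' @return Object of class \code{efficiency_estimate}: \code{g_measured},
#'   \code{g_max}, \code{efficiency}, \code{crosslink_density} (m^-3),
#'   \code{temperature}, and a \code{flag} when efficiency > 1.
#' @export
crosslink_efficiency <- function(g_measured, p, T_K = 293.15,
                                 model = c("affine", "phantom")) {
  stopifnot(all(g_measured >= 0))
  g_max <- theoretical_max_modulus(p, T_K, model)
  eff <- g_measured / g_max
  structure(list(g_measured = g_measured, g_max = g_max, efficiency = eff,
                 crosslink_density = g_max / (.KB * T_K),
                 temperature = T_K,
                 flag = if (any(eff > 1)) "efficiency exceeds 1 (measured modulus above affine limit)" else NULL),
            class = "efficiency_estimate")
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf("crosslinking efficiency %.3f (G' = %.3g Pa of %.3g Pa max at %.1f K)\n",
              x$efficiency[1], x$g_measured[1], x$g_max, x$temperature))
  if (!is.null(x$flag)) cat("note:", x$flag, "\n")
  invisible(x)
}

# nucleotide monophosphate residue masses (free acid), Da
.NT_MASS <- c(A = 313.21, C = 289.18, G = 329.21, T = 304.2)
.NT_MASS_AVG <- 325
.MASS_5PRIME_OH <- -61.96  # no 5' phosphate, free acid convention

#' Total DNA mass concentration of a strand mixture
#'
#' Sums \code{concentration x molecular mass} over strands. Mass comes from
#' base composition (free-acid convention, no 5' phosphate) when a sequence
#' is given, or from the 325 Da/nt average when only a length is known.
#'
#' @param strands data.frame with columns \code{conc} (mol/L) and either
#'   \code{sequence} or \code{length} (nt); or a list of such entries.
#' @return Mass concentration in g/L.
#' @examples
#' dna_mass_concentration(data.frame(length = 20, conc = 75e-6))  # ~0.49
#' @export
dna_mass_concentration <- function(strands) {
  if (is.list(strands) && !is.data.frame(strands))
    strands <- do.call(rbind, lapply(strands, as.data.frame))
  if (is.null(strands) || nrow(strands) == 0L) return(0)
  mass_one <- function(i) {
    if (!is.null(strands$sequence) && !is.na(strands$sequence[i]) &&
        nzchar(strands$sequence[i])) {
      s <- .check_alphabet(strands$sequence[i], allow_n = TRUE)
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      # N counts at the average of the four bases
      sum(ifelse(chars == "N", mean(.NT_MASS), .NT_MASS[chars]),
          na.rm = TRUE) + .MASS_5PRIME_OH
    } else {
      strands$length[i] * .NT_MASS_AVG
    }
  }
  sum(vapply(seq_len(nrow(strands)),
             function(i) strands$conc[i] * mass_one(i), numeric(1)))
}
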