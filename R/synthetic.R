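# Seeded generators for every input the analysis modules consume: library
# designs with a valid adaptor/overlap melting hierarchy, explicit
# distance-coded libraries, Maxwell relaxation traces, two-state melting
# sweeps and strain-cycling recovery traces. Each generator is
# deterministic for a given seed and carries its ground truth.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.random_seq <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

#' Generate a dual-splint library design
#'
#' Draws a random explicit adaptor and an overlap template with \code{n}
#' ambiguous positions placed uniformly, redrawing until the
#' adaptor/overlap melting hierarchy passes (adaptor Tm at least
#' \code{min_gap} above the hottest overlap variant).
#'
#' @param n_ambiguous Number of N positions in the overlap.
#' @param overlap_len,adaptor_len Domain lengths in nt.
#' @param gc_bounds GC-fraction targets \code{c(overlap, adaptor)}; the
#'   adaptor defaults to GC-rich so the hierarchy is satisfiable.
#' @param seed Integer seed.
#' @param cond Conditions for the hierarchy check.
#' @param min_gap Required T1 - T2 separation in deg C.
#' @param max_tries Redraw budget before giving up.
#' @return List: \code{overlap} and \code{adaptor}
#'   (\code{ambiguous_domain}s), \code{hierarchy}, \code{seed}.
#' @export
gen_library_design <- function(n_ambiguous = 2, overlap_len = 14,
                               adaptor_len = 20, gc_bounds = c(0.5, 0.7),
                               seed = 1L, cond = thermo_conditions(),
                               min_gap = 10, max_tries = 200L) {
  stopifnot(overlap_len >= n_ambiguous, n_ambiguous >= 0)
  .with_seed(seed, {
    for (i in seq_len(max_tries)) {
      ov <- strsplit(.random_seq(overlap_len, gc_bounds[1]), "", fixed = TRUE)[[1]]
      if (n_ambiguous > 0)
        ov[sample.int(overlap_len, n_ambiguous)] <- "N"
      ov <- paste(ov, collapse = "")
      ad <- .random_seq(adaptor_len, gc_bounds[2])
      h <- domain_hierarchy(ad, ov, cond, min_gap)
      if (isTRUE(h$pass)) {
        return(list(overlap = ambiguous_domain(ov, "overlap"),
                    adaptor = ambiguous_domain(ad, "adaptor"),
                    hierarchy = h, seed = as.integer(seed)))
      }
    }
    stop(sprintf("no design satisfying a %g C hierarchy in %d draws",
                 min_gap, max_tries), call. = FALSE)
  })
}

#' Reference dual-splint design
#'
#' A fixed design used as the package's stand-in for the deployed strands:
#' a 20-nt anchor/adaptor duplex and a 14-nt overlap whose perfect duplex
#' melts near 65 deg C at a 75 uM splint pool in 150 mM NaCl — the melting
#' point observed for the single-pair crosslinker matrix — with up to four
#' degenerate positions for libraries of 1 to 256 pairs. With 75 uM
#' anchors (one splint equivalent), the 20-nt anchor plus 34-nt splint
#' strands carry ~1.3 g/L of DNA at a 1% (w/v) 20-anchor backbone.
#'
#' @param n_ambiguous Number of overlap positions (0-4) made ambiguous.
#' @return List with \code{overlap}, \code{adaptor}
#'   (\code{ambiguous_domain}s) and \code{anchor} (explicit sequence, the
#'   adaptor's reverse complement).
#' @export
reference_design <- function(n_ambiguous = 2) {
  stopifnot(n_ambiguous >= 0, n_ambiguous <= 4)
  ov <- strsplit(.REF_OVERLAP, "", fixed = TRUE)[[1]]
  if (n_ambiguous > 0)
    ov[.REF_N_POSITIONS[seq_len(n_ambiguous)]] <- "N"
  list(overlap = ambiguous_domain(paste(ov, collapse = ""), "overlap"),
       adaptor = ambiguous_domain(.REF_ADAPTOR, "adaptor"),
       anchor = reverse_complement(.REF_ADAPTOR))
}

#' Generate an explicit splint library with guaranteed variant separation
#'
#' Builds \eqn{4^k} explicit overlap variants by varying \code{k} free
#' positions over A/C/G/T and writing a check digit (the sum of the free
#' digits mod 4) at one extra position, so any two variants differ at two
#' or more positions. Useful for studying selectivity with a minimum
#' inter-variant Hamming distance of 2, which a plain N-expansion (distance
#' 1) cannot provide.
#'
#' @param k Number of free positions (library size \eqn{4^k}, k = 0..4).
#' @param template Explicit overlap template (default: the reference
#'   overlap).
#' @param positions Indices of the k free positions plus the check
#'   position (length k + 1).
#' @param adaptor Explicit adaptor (default: the reference adaptor).
#' @return A \code{crosslinker_library} with \code{coded = TRUE} and
#'   attribute \code{min_distance = 2} (1 when k = 0... the single-member
#'   library trivially has no pair distance).
#' @export
gen_explicit_library <- function(k, template = .REF_OVERLAP,
                                 positions = .REF_CODE_POSITIONS,
                                 adaptor = .REF_ADAPTOR) {
  stopifnot(k >= 0, k <= length(positions) - 1L)
  chars <- strsplit(.check_alphabet(template), "", fixed = TRUE)[[1]]
  stopifnot(max(positions) <= length(chars))
  bases <- c("A", "C", "G", "T")
  free <- positions[seq_len(k)]
  check <- positions[length(positions)]
  total <- 4L^k
  fwd <- character(total)
  for (i in seq_len(total)) {
    code <- i - 1L
    digits <- integer(k)
    tmpl <- chars
    if (k > 0) for (j in k:1) {
      digits[j] <- code %% 4L
      tmpl[free[j]] <- bases[digits[j] + 1L]
      code <- code %/% 4L
    }
    tmpl[check] <- bases[sum(digits) %% 4L + 1L]
    fwd[i] <- paste(tmpl, collapse = "")
  }
  fwd <- sort(fwd, method = "radix")
  pairs <- data.frame(pair_id = seq_along(fwd), forward = fwd,
                      reverse = vapply(fwd, reverse_complement, character(1),
                                       USE.NAMES = FALSE),
                      stringsAsFactors = FALSE)
  lib <- new_crosslinker_library(
    design = ambiguous_domain(paste(chars, collapse = ""), "overlap"),
    adaptor = ambiguous_domain(adaptor, "adaptor"),
    pairs = pairs, complexity = total, coded = TRUE)
  attr(lib, "min_distance") <- if (k > 0) 2L else NA_integer_
  lib
}

#' Generate a Maxwell stress-relaxation trace with known ground truth
#'
#' \eqn{\sigma(t) = \sigma_0 e^{-t/\tau} +} Gaussian noise, truncated at 0.
#'
#' @param sigma0 Initial stress in Pa.
#' @param tau True relaxation time in s.
#' @param noise_sd Noise standard deviation in Pa.
#' @param t_max,dt Trace span and sampling step in s (t_max >= 3 tau
#'   recommended so the 1/e crossing is observed).
#' @param seed Integer seed.
#' @return A \code{relax_trace} with attributes \code{truth}
#'   (list sigma0, tau) and \code{seed}.
#' @export
gen_relaxation_trace <- function(sigma0 = 100, tau = 120, noise_sd = 2,
                                 t_max = 5 * tau, dt = tau / 50, seed = 1L) {
  stopifnot(tau > 0, sigma0 > 0, noise_sd >= 0)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  t <- seq(0, t_max, by = dt)
  s <- .with_seed(seed,
                  pmax(0, sigma0 * exp(-t / tau) + stats::rnorm(length(t), 0, noise_sd)))
  tr <- relax_trace(t, s)
  attr(tr, "truth") <- list(sigma0 = sigma0, tau = tau)
  attr(tr, "seed") <- as.integer(seed)
  tr
}

#' Generate a temperature sweep with a G'/G'' crossover at a known gel point
#'
#' \eqn{G'(T) = G_s (r + (1-r)\theta(T))} and
#' \eqn{G''(T) = G_s (r + (1-r)(1-\theta(T)))} with
#' \eqn{\theta(T) = 1/(1 + e^{(T - T_m)/w})}, a two-state sigmoid:
#' \eqn{\theta(T_m) = 0.5}, so the crossover sits exactly at
#' \code{tm_gel}. Optional multiplicative noise.
#'
#' @param tm_gel True gel melting point in deg C.
#' @param width Sigmoid width w in deg C.
#' @param g_solid Solid-plateau modulus in Pa.
#' @param g_liquid_ratio Liquid-phase floor as a fraction of
#'   \code{g_solid}.
#' @param t_range,dT Sweep range and step in deg C.
#' @param noise_rel Relative (multiplicative) noise sd; 0 disables.
#' @param seed Integer seed.
#' @return An \code{oscillatory_trace} (kind "temperature") with
#'   attributes \code{truth} and \code{seed}.
#' @export
gen_temp_sweep <- function(tm_gel = 60, width = 2.5, g_solid = 70,
                           g_liquid_ratio = 0.02, t_range = c(20, 80),
                           dT = 0.25, noise_rel = 0, seed = 1L) {
  stopifnot(width > 0, g_solid > 0, g_liquid_ratio >= 0, g_liquid_ratio < 1)
  T_ <- seq(t_range[1], t_range[2], by = dT)
  theta <- 1 / (1 + exp((T_ - tm_gel) / width))
  r <- g_liquid_ratio
  gp <- g_solid * (r + (1 - r) * theta)
  gpp <- g_solid * (r + (1 - r) * (1 - theta))
  if (noise_rel > 0) {
    noise <- .with_seed(seed, list(a = stats::rnorm(length(T_), 1, noise_rel),
                                   b = stats::rnorm(length(T_), 1, noise_rel)))
    gp <- gp * pmax(0.01, noise$a)
    gpp <- gpp * pmax(0.01, noise$b)
  }
  tr <- oscillatory_trace(T_, gp, gpp, kind = "temperature")
  attr(tr, "truth") <- list(tm_gel = tm_gel, width = width, g_solid = g_solid)
  attr(tr, "seed") <- as.integer(seed)
  tr
}

#' Generate a strain-cycling self-healing trace
#'
#' Alternating breaking (large strain: G' << G'', phase angle > 70 deg) and
#' healing periods; healing plateaus decay geometrically by
#' \code{loss_per_cycle} per cycle, emulating repeated breakage-recovery
#' runs.
#'
#' @param g0 Initial healed modulus in Pa.
#' @param loss_per_cycle Fractional stiffness loss per cycle in [0, 1).
#' @param n_cycles Number of breakage-healing cycles.
#' @param samples_per_period Samples within each period.
#' @param period_s Duration of each period in s.
#' @param noise_rel Relative noise sd; 0 disables.
#' @param seed Integer seed.
#' @return An \code{oscillatory_trace} (kind "time") with \code{cycle} and
#'   \code{period} labels and attributes \code{truth}, \code{seed}.
#' @export
gen_recovery_trace <- function(g0 = 70, loss_per_cycle = 0.005,
                               n_cycles = 10, samples_per_period = 30L,
                               period_s = 300, noise_rel = 0, seed = 1L) {
  stopifnot(loss_per_cycle >= 0, loss_per_cycle < 1, n_cycles >= 1)
  noise <- .with_seed(seed, stats::rnorm(2L * n_cycles * samples_per_period,
                                         1, max(noise_rel, 0)))
  if (noise_rel <= 0) noise <- rep(1, length(noise))
  rows <- vector("list", 2L * n_cycles)
  t0 <- 0
  k <- 0L
  for (cyc in seq_len(n_cycles)) {
    gh <- g0 * (1 - loss_per_cycle)^(cyc - 1L)
    tt <- t0 + seq_len(samples_per_period) * period_s / samples_per_period
    # breaking period: liquefied, G' << G'' (phase angle ~74 deg)
    rows[[k <- k + 1L]] <- data.frame(
      abscissa = tt, Gp_Pa = 0.05 * g0, Gpp_Pa = 0.05 * g0 * 3.49,
      cycle = cyc, period = "b")
    t0 <- max(tt)
    tt <- t0 + seq_len(samples_per_period) * period_s / samples_per_period
    # healing period: plateau restored minus the accumulated loss
    rows[[k <- k + 1L]] <- data.frame(
      abscissa = tt, Gp_Pa = gh, Gpp_Pa = gh * 0.05,
      cycle = cyc, period = "h")
    t0 <- max(tt)
  }
  df <- do.call(rbind, rows)
  i <- seq_len(nrow(df))
  tr <- oscillatory_trace(df$abscissa, df$Gp_Pa * noise[i],
                          df$Gpp_Pa * noise[i], kind = "time",
                          cycle = df$cycle, period = df$period)
  attr(tr, "truth") <- list(g0 = g0, loss_per_cycle = loss_per_cycle,
                            n_cycles = n_cycles,
                            recovery_pct = 100 * (1 - loss_per_cycle)^(n_cycles - 1L))
  attr(tr, "seed") <- as.integer(seed)
  tr
}
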