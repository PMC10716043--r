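#' Build a combinatorial crosslinker library (CCL)
#'
#' Expands a degenerate overlap design into its explicit splint pairs. Each
#' forward overlap variant is paired with its Watson-Crick reverse
#' complement, so every pair binds only its own partner; the library
#' complexity is \eqn{C = 4^n} for \eqn{n} ambiguous positions. All library
#' members share the same explicit adaptor domain, which binds the anchor
#' strands on the polymer backbone.
#'
#' @param overlap_design \code{ambiguous_domain} (role \code{"overlap"}),
#'   may contain \code{N}.
#' @param adaptor \code{ambiguous_domain} (role \code{"adaptor"}), explicit.
#' @param max_n Refuse designs with more ambiguous positions than this
#'   (default 8, i.e. 65,536 pairs) unless \code{allow_large = TRUE}.
#' @param allow_large Override the complexity guard.
#' @return Object of class \code{crosslinker_library}: fields \code{design},
#'   \code{adaptor}, \code{pairs} (data.frame \code{pair_id},
#'   \code{forward}, \code{reverse}) and \code{complexity}.
#' @examples
#' lib <- build_library(ambiguous_domain("GCGANNCTAGCGTA", "overlap"),
#'                      ambiguous_domain("GTAGCACTGACCGTGGTGAC", "adaptor"))
#' lib$complexity  # 16
#' @export
build_library <- function(overlap_design, adaptor, max_n = 8L,
                          allow_large = FALSE) {
  if (!inherits(overlap_design, "ambiguous_domain"))
    overlap_design <- ambiguous_domain(overlap_design, "overlap")
  if (!inherits(adaptor, "ambiguous_domain"))
    adaptor <- ambiguous_domain(adaptor, "adaptor")
  if (adaptor$n_ambiguous > 0L)
    stop("adaptor domain must be explicit (no N)", call. = FALSE)
  if (overlap_design$n_ambiguous > max_n && !allow_large) {
    stop(sprintf(paste0("design has %d ambiguous positions (%s pairs); ",
                        "set allow_large = TRUE to build anyway"),
                 overlap_design$n_ambiguous,
                 format(4^overlap_design$n_ambiguous, big.mark = ",")),
         call. = FALSE)
  }
  fwd <- expand_ambiguous(overlap_design)
  pairs <- data.frame(pair_id = seq_along(fwd),
                      forward = fwd,
                      reverse = vapply(fwd, reverse_complement, character(1),
                                       USE.NAMES = FALSE),
                      stringsAsFactors = FALSE)
  new_crosslinker_library(overlap_design, adaptor, pairs,
                          complexity = 4L^overlap_design$n_ambiguous)
}

new_crosslinker_library <- function(design, adaptor, pairs, complexity,
                                    coded = FALSE) {
  structure(list(design = design, adaptor = adaptor, pairs = pairs,
                 complexity = as.integer(complexity), coded = coded),
            class = "crosslinker_library")
}

#' @export
print.crosslinker_library <- function(x, ...) {
  cat(sprintf("CCL-%d crosslinker library (%d splint pairs)\n",
              x$complexity, nrow(x$pairs)))
  cat(sprintf("  overlap design: %s (%d N)\n",
              x$design$sequence, x$design$n_ambiguous))
  cat(sprintf("  adaptor:        %s\n", x$adaptor$sequence))
  if (isTRUE(x$coded))
    cat("  (distance-coded explicit library, not a plain N-expansion)\n")
  invisible(x)
}

#' @export
summary.crosslinker_library <- function(object, ...) {
  lens <- nchar(object$pairs$forward)
  out <- list(complexity = object$complexity,
              n_pairs = nrow(object$pairs),
              overlap_length = unique(lens),
              adaptor_length = nchar(object$adaptor$sequence),
              report = validate_design(object))
  class(out) <- "summary.crosslinker_library"
  out
}

#' @export
print.summary.crosslinker_library <- function(x, ...) {
  cat(sprintf("CCL-%d: %d pairs, overlap %s nt, adaptor %d nt\n",
              x$complexity, x$n_pairs,
              paste(x$overlap_length, collapse = "/"), x$adaptor_length))
  if (length(x$report)) {
    cat("validation failures:\n")
    for (msg in x$report) cat("  -", msg, "\n")
  } else cat("validation: clean\n")
  invisible(x)
}

#' Validate a crosslinker library
#'
#' Checks the structural invariants of the dual-splint architecture:
#' explicit alphabet in all pairs, reverse strands are true reverse
#' complements, no duplicated forward overlap, complexity arithmetic
#' (\eqn{4^n} for plain expansions), and an \code{N}-free adaptor.
#'
#' @param library A \code{crosslinker_library}.
#' @return Character vector of failure messages; empty when valid.
#' @export
validate_design <- function(library) {
  report <- character(0)
  p <- library$pairs
  ok_alpha <- grepl("^[ACGT]+$", p$forward) & grepl("^[ACGT]+$", p$reverse)
  if (!all(ok_alpha))
    report <- c(report, sprintf("non-explicit alphabet in pair(s): %s",
                                paste(p$pair_id[!ok_alpha], collapse = ", ")))
  rc <- vapply(p$forward[ok_alpha], reverse_complement, character(1),
               USE.NAMES = FALSE)
  bad_rc <- p$pair_id[ok_alpha][rc != p$reverse[ok_alpha]]
  if (length(bad_rc))
    report <- c(report, sprintf("reverse is not the reverse complement in pair(s): %s",
                                paste(bad_rc, collapse = ", ")))
  if (anyDuplicated(p$forward))
    report <- c(report, "duplicated forward overlap sequence(s)")
  if (nrow(p) != library$complexity)
    report <- c(report, sprintf("complexity %d != %d pairs present",
                                library$complexity, nrow(p)))
  if (!isTRUE(library$coded) &&
      library$complexity != 4L^library$design$n_ambiguous)
    report <- c(report, sprintf("complexity %d != 4^%d",
                                library$complexity,
                                library$design$n_ambiguous))
  if (.count_n(library$adaptor$sequence) > 0L)
    report <- c(report, "adaptor contains ambiguous base(s)")
  report
}
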