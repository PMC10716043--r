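#' Construct an ambiguous splint domain
#'
#' A domain is a short DNA sequence written 5'->3' over the alphabet
#' \code{A,C,G,T,N}. \code{N} marks a degenerate position at which an equal
#' mixture of the four bases is used during synthesis. Adaptor and blocking
#' domains must be explicit (no \code{N}); only the overlap domain may carry
#' degenerate positions.
#'
#' @param sequence Character scalar, the domain sequence (case-insensitive).
#' @param role One of \code{"overlap"}, \code{"adaptor"}, \code{"blocking"}.
#' @return An object of class \code{ambiguous_domain} with fields
#'   \code{sequence}, \code{n_ambiguous} and \code{role}.
#' @examples
#' ambiguous_domain("GCGANNCTAGCGTA", "overlap")
#' @export
ambiguous_domain <- function(sequence, role = c("overlap", "adaptor", "blocking")) {
  role <- match.arg(role)
  sequence <- .check_alphabet(sequence, allow_n = TRUE)
  n_amb <- .count_n(sequence)
  if (role != "overlap" && n_amb > 0L) {
    stop(sprintf("%s domains must be explicit; found %d ambiguous base(s)",
                 role, n_amb), call. = FALSE)
  }
  structure(list(sequence = sequence, n_ambiguous = n_amb, role = role),
            class = "ambiguous_domain")
}

#' @export
print.ambiguous_domain <- function(x, ...) {
  cat(sprintf("<%s domain> %s (%d nt, %d ambiguous)\n",
              x$role, x$sequence, nchar(x$sequence), x$n_ambiguous))
  invisible(x)
}

.count_n <- function(sequence) {
  sum(strsplit(sequence, "", fixed = TRUE)[[1]] == "N")
}

# Uppercase and validate; report the first offending position by index.
.check_alphabet <- function(sequence, allow_n = FALSE) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single character string", call. = FALSE)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop("sequence must have length >= 1", call. = FALSE)
  alpha <- if (allow_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% alpha))
  if (length(bad)) {
    stop(sprintf("invalid character '%s' at position %d (allowed: %s)",
                 chars[bad[1]], bad[1], paste(alpha, collapse = "")),
         call. = FALSE)
  }
  sequence
}

#' Expand ambiguous bases into all explicit sequences
#'
#' Replaces every \code{N} with each of A, C, G, T, producing all
#' \eqn{4^n} explicit variants of a degenerate design. The expansion order
#' is deterministic and lexicographic: A < C < G < T at each degenerate
#' position, with the leftmost \code{N} varying slowest, so that matrix row
#' and column indices are reproducible across runs.
#'
#' @param domain An \code{ambiguous_domain} or a character sequence.
#' @return Character vector of \eqn{4^n} distinct explicit sequences.
#' @examples
#' expand_ambiguous("ANT")   # AAT ACT AGT ATT
#' @export
expand_ambiguous <- function(domain) {
  seqc <- if (inherits(domain, "ambiguous_domain")) domain$sequence
          else .check_alphabet(domain, allow_n = TRUE)
  chars <- strsplit(seqc, "", fixed = TRUE)[[1]]
  npos <- which(chars == "N")
  if (!length(npos)) return(seqc)
  bases <- c("A", "C", "G", "T")
  n <- length(npos)
  total <- 4L^n
  out <- character(total)
  tmpl <- chars
  for (i in seq_len(total)) {
    # base-4 digits of i-1, leftmost N = most significant digit (varies slowest)
    code <- i - 1L
    for (k in n:1) {
      tmpl[npos[k]] <- bases[code %% 4L + 1L]
      code <- code %/% 4L
    }
    out[i] <- paste(tmpl, collapse = "")
  }
  out
}

#' Watson-Crick reverse complement of an explicit sequence
#'
#' @param seq Explicit sequence over \code{A,C,G,T} (no ambiguity codes).
#' @return The reverse complement, 5'->3'.
#' @examples
#' reverse_complement("AACG")  # "CGTT"
#' @export
reverse_complement <- function(seq) {
  seq <- .check_alphabet(seq, allow_n = FALSE)
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]),
                               collapse = ""))
}
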