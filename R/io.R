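# Plain-text interfaces: sequence CSV/FASTA, library CSV, rheometer CSV
# dialect, matrix TSV and JSON run manifests. Everything is diff-able text;
# no binary formats.

#' Read splint domains from CSV or FASTA
#'
#' CSV needs columns \code{name, role, sequence}; FASTA headers are taken
#' as \code{name} (role defaults to "overlap", or \code{"role=..."} in the
#' description). Lowercase bases are normalized to uppercase; ambiguous
#' bases (N) are preserved. Malformed records raise an error naming the
#' offending line or record.
#'
#' @param path File path; format inferred from extension
#'   (\code{.fa/.fasta} vs anything else = CSV) unless \code{format} given.
#' @param format \code{"auto"}, \code{"csv"} or \code{"fasta"}.
#' @return Named list of \code{ambiguous_domain} objects.
#' @export
read_sequences <- function(path, format = c("auto", "csv", "fasta")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(fa|fasta)$", path, ignore.case = TRUE)) "fasta" else "csv"
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    out <- list()
    for (i in seq_along(set)) {
      hdr <- names(set)[i]
      role <- if (grepl("role=", hdr)) sub(".*role=([a-z]+).*", "\\1", hdr) else "overlap"
      name <- sub("\\s.*$", "", hdr)
      seqc <- toupper(as.character(set[[i]]))
      dom <- tryCatch(ambiguous_domain(seqc, role),
                      error = function(e) stop(sprintf("record %d ('%s'): %s",
                                                       i, name, conditionMessage(e)),
                                               call. = FALSE))
      out[[name]] <- dom
    }
    return(out)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "role", "sequence")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(df))) {
    dom <- tryCatch(ambiguous_domain(df$sequence[i], df$role[i]),
                    error = function(e) stop(sprintf("line %d: %s", i + 1L,
                                                     conditionMessage(e)),
                                             call. = FALSE))
    out[[df$name[i]]] <- dom
  }
  out
}

#' Write / read an explicit splint library as CSV
#'
#' Columns \code{pair_id, forward, reverse}; the header carries no
#' metadata, so the design and adaptor travel separately (or via the run
#' manifest).
#'
#' @param library A \code{crosslinker_library}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_library <- function(library, path) {
  utils::write.csv(library$pairs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @param design,adaptor Optional domains to attach on read.
#' @export
read_library <- function(path, design = NULL, adaptor = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "forward", "reverse")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  if (is.null(design)) {
    # reconstruct a degenerate design: N where variants disagree
    chars <- do.call(rbind, strsplit(toupper(df$forward), "", fixed = TRUE))
    cons <- apply(chars, 2, function(col) if (length(unique(col)) == 1L) col[1] else "N")
    design <- ambiguous_domain(paste(cons, collapse = ""), "overlap")
  }
  if (is.null(adaptor)) adaptor <- ambiguous_domain("A", "adaptor")
  coded <- nrow(df) != 4L^design$n_ambiguous
  df$forward <- toupper(df$forward); df$reverse <- toupper(df$reverse)
  new_crosslinker_library(design, adaptor, df, complexity = nrow(df),
                          coded = coded)
}

#' Read a rheometer trace CSV
#'
#' Dialect: header row, decimal point, UTF-8; recognised columns among
#' \code{time_s, temp_C, stress_Pa, Gp_Pa, Gpp_Pa, strain_pct, cycle,
#' period}. Extra columns are ignored with a notice on stderr; missing
#' required columns raise an error naming them; non-monotone time stamps
#' are rejected.
#'
#' @param path CSV path.
#' @param kind \code{"relaxation"}, \code{"temperature"} or
#'   \code{"cycling"}.
#' @return A \code{relax_trace} or \code{oscillatory_trace}.
#' @export
read_rheo_csv <- function(path, kind = c("relaxation", "temperature", "cycling")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  known <- c("time_s", "temp_C", "stress_Pa", "Gp_Pa", "Gpp_Pa",
             "strain_pct", "cycle", "period")
  extra <- setdiff(names(df), known)
  if (length(extra))
    message(sprintf("read_rheo_csv: ignoring extra column(s): %s",
                    paste(extra, collapse = ", ")))
  need <- switch(kind,
                 relaxation = c("time_s", "stress_Pa"),
                 temperature = c("temp_C", "Gp_Pa", "Gpp_Pa"),
                 cycling = c("time_s", "Gp_Pa", "Gpp_Pa", "cycle", "period"))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  switch(kind,
         relaxation = relax_trace(df$time_s, df$stress_Pa,
                                  if ("strain_pct" %in% names(df)) df$strain_pct[1] else 15),
         temperature = oscillatory_trace(df$temp_C, df$Gp_Pa, df$Gpp_Pa,
                                         kind = "temperature"),
         cycling = oscillatory_trace(df$time_s, df$Gp_Pa, df$Gpp_Pa,
                                     kind = "time", cycle = df$cycle,
                                     period = df$period))
}

#' Write a trace in the rheometer CSV dialect
#'
#' @param trace A \code{relax_trace} or \code{oscillatory_trace}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_rheo_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  if (inherits(trace, "relax_trace")) {
    df$strain_pct <- attr(trace, "strain_pct")
  } else if (identical(attr(trace, "kind"), "temperature")) {
    names(df)[names(df) == "abscissa"] <- "temp_C"
  } else {
    names(df)[names(df) == "abscissa"] <- "time_s"
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read an energy or selectivity matrix as TSV
#'
#' Tab-separated with pair ids as row and column names.
#'
#' @param m An \code{energy_matrix}, \code{selectivity_matrix} or plain
#'   matrix.
#' @param path Output TSV path.
#' @param which For selectivity matrices, \code{"normalized"} (default) or
#'   \code{"boltzmann"}.
#' @return \code{path}, invisibly.
#' @export
write_matrix <- function(m, path, which = c("normalized", "boltzmann")) {
  which <- match.arg(which)
  x <- if (inherits(m, "energy_matrix")) m$mfe
       else if (inherits(m, "selectivity_matrix")) m[[which]]
       else m
  utils::write.table(x, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                              check.names = FALSE))
}

#' Write a machine-readable run manifest
#'
#' Records inputs, seeds and package version so a run can be reproduced
#' exactly.
#'
#' @param path Output JSON path.
#' @param inputs Named list of input descriptions (paths, parameters).
#' @param seed Integer seed(s) used.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(path, inputs = list(), seed = NA_integer_) {
  jsonlite::write_json(
    list(package = "dnagel",
         version = as.character(utils::packageVersion("dnagel")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         seed = seed, inputs = inputs),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Bundle a full analysis run configuration
#'
#' Collects the thermodynamic conditions, polymer specification, simulation
#' settings and file paths of one pipeline run; checks that referenced
#' inputs exist up front and carries everything the manifest needs.
#'
#' @param conditions A \code{thermo_conditions}.
#' @param polymer A \code{polymer_spec}.
#' @param sim Named list of simulation settings (m, C, n_chains, seed, ...).
#' @param paths Named list of input/output paths; inputs must exist.
#' @param log_level One of \code{"quiet"}, \code{"info"}, \code{"debug"}.
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(conditions = thermo_conditions(), polymer = NULL,
                       sim = list(), paths = list(),
                       log_level = c("info", "quiet", "debug")) {
  log_level <- match.arg(log_level)
  stopifnot(inherits(conditions, "thermo_conditions"))
  if (!is.null(polymer)) stopifnot(inherits(polymer, "polymer_spec"))
  inputs <- paths[grepl("^in", names(paths))]
  missing <- unlist(inputs)[!file.exists(unlist(inputs))]
  if (length(missing))
    stop(sprintf("input path(s) do not exist: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  structure(list(conditions = conditions, polymer = polymer, sim = sim,
                 paths = paths, log_level = log_level),
            class = "run_config")
}
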