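# Gaussian-dialect text I/O: input decks out, result logs in. A synthetic log
# writer mirrors the blocks the parser consumes so that write -> parse round
# trips are testable without an external engine.

.element_numbers <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15,
                      S = 16, Cl = 17, Br = 35, I = 53)

.symbol_from_z <- function(z) {
  sym <- names(.element_numbers)[match(z, .element_numbers)]
  if (anyNA(sym)) stop("unknown atomic number(s): ",
                       paste(z[is.na(sym)], collapse = ", "), call. = FALSE)
  sym
}

.route_line <- function(settings) {
  solv <- tolower(settings$solvation)
  sprintf("#P %s/%s opt freq scrf=(%s,solvent=%s)",
          settings$functional, settings$basis, solv, settings$solvent)
}

#' Write a Gaussian-dialect input deck
#'
#' Emits an optimize+frequencies input: route line with the functional, basis
#' and continuum-solvation keywords, a title card, the charge/multiplicity
#' line and the Cartesian coordinate block.
#'
#' @param structure An `atomic_structure`.
#' @param settings A [qm_settings()]; the functional must be one of
#'   [supported_functionals()].
#' @return The deck as a single character scalar.
#' @examples
#' cat(write_engine_input(build_species("water"), qm_settings("PBEPBE")))
#' @export
write_engine_input <- function(structure, settings) {
  validate_structure(structure)
  if (!settings$functional %in% supported_functionals()) {
    stop("unsupported functional '", settings$functional, "'; supported: ",
         paste(supported_functionals(), collapse = ", "), call. = FALSE)
  }
  title <- paste0(
    if (!is.na(structure$kind)) paste0("kind=", structure$kind, " ") else "",
    if (!is.na(structure$compound)) {
      paste0("compound=\"", structure$compound, "\" ")
    } else "",
    "generated input"
  )
  lines <- c(
    .route_line(settings),
    "",
    trimws(title),
    "",
    sprintf("%d %d", structure$charge, structure$multiplicity),
    sprintf("%-2s %14.8f %14.8f %14.8f", structure$elements,
            structure$coordinates[, 1], structure$coordinates[, 2],
            structure$coordinates[, 3]),
    ""
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

.split_log_lines <- function(text) {
  if (length(text) == 1L && grepl("[\r\n]", text)) {
    text <- gsub("\r\n?", "\n", text)
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  text
}

#' Parse a Gaussian-dialect result log
#'
#' Extracts, from the log text: the final thermochemistry ("Sum of electronic
#' and thermal Free Energies", last occurrence wins in multi-step logs), the
#' vibrational frequency block in printed order, the last orientation block as
#' the final geometry, the charge/multiplicity line, the normal-termination
#' flag and the elapsed wall time in minutes. Fields absent from the log stay
#' absent in the result (`NULL` structure/frequencies, `NA` wall time); a log
#' with no free-energy line is rejected. A file truncated before the
#' termination stamp yields `converged = FALSE` with whatever was parsed.
#' Parsing ignores trailing whitespace and line-ending style.
#'
#' @param text Log content: a single string or a character vector of lines.
#' @return A [qm_result()].
#' @seealso [read_gaussian_log()] to parse from a file path,
#'   [write_gaussian_log()] for the synthetic fixture writer.
#' @export
parse_gaussian_log <- function(text) {
  lines <- .split_log_lines(text)

  e_hits <- grep("Sum of electronic and thermal Free Energies", lines)
  if (length(e_hits) == 0L) {
    stop("no thermochemistry section ",
         "('Sum of electronic and thermal Free Energies' not found)",
         call. = FALSE)
  }
  energy <- as.numeric(sub(".*Free Energies=\\s*", "", lines[e_hits[length(e_hits)]]))

  freq_lines <- grep("^\\s*Frequencies\\s+--", lines, value = TRUE)
  frequencies <- if (length(freq_lines)) {
    as.numeric(unlist(lapply(freq_lines, function(l) {
      strsplit(trimws(sub(".*--", "", l)), "\\s+")[[1]]
    })))
  } else NULL

  cm <- grep("Charge\\s*=\\s*-?[0-9]+\\s+Multiplicity\\s*=", lines, value = TRUE)
  charge <- 0L; mult <- 1L
  if (length(cm)) {
    m <- regmatches(cm[1], regexec(
      "Charge\\s*=\\s*(-?[0-9]+)\\s+Multiplicity\\s*=\\s*([0-9]+)", cm[1]))[[1]]
    charge <- as.integer(m[2]); mult <- as.integer(m[3])
  }

  geo_hits <- grep("(Standard|Input) orientation:", lines)
  final_structure <- NULL
  if (length(geo_hits)) {
    start <- geo_hits[length(geo_hits)] + 5L # dashes, 2 header lines, dashes
    rows <- list()
    i <- start
    while (i <= length(lines) && !grepl("^\\s*-{10,}", lines[i])) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(f) >= 6L) rows[[length(rows) + 1L]] <- f
      i <- i + 1L
    }
    if (length(rows)) {
      tab <- do.call(rbind, rows)
      final_structure <- atomic_structure(
        elements = .symbol_from_z(as.integer(tab[, 2])),
        coordinates = apply(tab[, 4:6, drop = FALSE], 2, as.numeric),
        charge = charge, multiplicity = mult
      )
    }
  }

  converged <- any(grepl("Normal termination of Gaussian", lines))

  wall_time <- NA_real_
  t_hit <- grep("Elapsed time:", lines, value = TRUE)
  if (length(t_hit)) {
    m <- regmatches(t_hit[1], regexec(
      "([0-9]+)\\s+days\\s+([0-9]+)\\s+hours\\s+([0-9]+)\\s+minutes\\s+([0-9.]+)\\s+seconds",
      t_hit[1]))[[1]]
    if (length(m) == 5L) {
      v <- as.numeric(m[2:5])
      wall_time <- v[1] * 1440 + v[2] * 60 + v[3] + v[4] / 60
    }
  }

  qm_result(structure = final_structure, gibbs_free_energy = energy,
            frequencies = frequencies, converged = converged,
            wall_time = wall_time)
}

#' @rdname parse_gaussian_log
#' @param path Path to a log file.
#' @export
read_gaussian_log <- function(path) {
  parse_gaussian_log(readLines(path, warn = FALSE))
}

#' Write a synthetic Gaussian-dialect log
#'
#' Renders a [qm_result()] into the log blocks that [parse_gaussian_log()]
#' consumes: charge/multiplicity, an orientation table, the frequency block,
#' the final thermochemistry line (energy at six decimals, as engines print
#' it), the elapsed-time stamp and — for converged results — the normal
#' termination line. Intended for fixtures and for exercising the
#' log-directory ingestion path without an external engine; it is not an
#' engine output.
#'
#' @param result A `qm_result` whose `structure` is non-`NULL`.
#' @param settings A [qm_settings()] echoed into the route line.
#' @param path Optional file path; when given the log is also written there.
#' @return The log text as a single character scalar (invisibly when `path`
#'   is given).
#' @export
write_gaussian_log <- function(result, settings = qm_settings(), path = NULL) {
  st <- result$structure
  if (is.null(st)) stop("result carries no structure", call. = FALSE)
  validate_structure(st)
  z <- .element_numbers[st$elements]
  geo <- sprintf(" %6d %10d %11d    %11.6f %11.6f %11.6f",
                 seq_along(z), z, 0L,
                 st$coordinates[, 1], st$coordinates[, 2], st$coordinates[, 3])
  dash <- paste0(" ", strrep("-", 69))
  freq_block <- character(0)
  fr <- result$frequencies
  if (!is.null(fr) && length(fr)) {
    for (i in seq(1, length(fr), by = 3)) {
      chunk <- fr[i:min(i + 2, length(fr))]
      freq_block <- c(freq_block,
                      paste0(" Frequencies --  ",
                             paste(sprintf("%10.4f", chunk), collapse = " ")))
    }
  }
  wt <- if (is.na(result$wall_time)) 0 else result$wall_time
  days <- floor(wt / 1440); wt <- wt - days * 1440
  hours <- floor(wt / 60); wt <- wt - hours * 60
  mins <- floor(wt); secs <- (wt - mins) * 60
  lines <- c(
    " Entering Gaussian System",
    paste0(" ", .route_line(settings)),
    sprintf(" Charge = %2d Multiplicity = %d", st$charge, st$multiplicity),
    "                         Standard orientation:",
    dash,
    " Center     Atomic      Atomic             Coordinates (Angstroms)",
    " Number     Number       Type             X           Y           Z",
    dash,
    geo,
    dash,
    freq_block,
    sprintf(" Sum of electronic and thermal Free Energies=   %18.6f",
            result$gibbs_free_energy),
    sprintf(" Elapsed time: %7d days %2d hours %2d minutes %4.1f seconds.",
            days, hours, mins, secs),
    if (result$converged) " Normal termination of Gaussian 16" else NULL
  )
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}
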