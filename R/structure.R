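#' Atomic structures
#'
#' A light container for a molecular cluster: element symbols, Cartesian
#' coordinates in Angstrom, total charge, spin multiplicity, and an optional
#' per-atom role label marking the reaction center
#' (`carboxyl_C`, `carbonyl_O`, `hydroxyl_O`, `acidic_H`, `carboxylate_O1`,
#' `carboxylate_O2`, `water_O`, `water_H`, `ring_C_ipso`, `ring_C_ortho`).
#'
#' @param elements Character vector of element symbols.
#' @param coordinates Numeric n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param charge Integer total charge (elementary charges).
#' @param multiplicity Positive integer spin multiplicity.
#' @param roles Character vector of length n; `NA` for unlabeled atoms.
#' @param kind Optional species tag: one of `"acid"`, `"base"`, `"hydroxide"`,
#'   `"water"` for the four clusters of the dissociation reaction.
#' @param compound Optional compound name the structure belongs to.
#' @return An object of class `atomic_structure`.
#' @export
atomic_structure <- function(elements, coordinates, charge = 0L, multiplicity = 1L,
                             roles = NULL, kind = NA_character_,
                             compound = NA_character_) {
  coordinates <- matrix(as.numeric(coordinates), ncol = 3)
  elements <- as.character(elements)
  if (is.null(roles)) roles <- rep(NA_character_, length(elements))
  x <- structure(
    list(elements = elements, coordinates = coordinates,
         charge = as.integer(charge), multiplicity = as.integer(multiplicity),
         roles = as.character(roles), kind = kind, compound = compound),
    class = "atomic_structure"
  )
  validate_structure(x)
  x
}

#' @rdname atomic_structure
#' @param x An `atomic_structure`.
#' @export
validate_structure <- function(x) {
  stopifnot(inherits(x, "atomic_structure"))
  n <- length(x$elements)
  if (nrow(x$coordinates) != n || length(x$roles) != n) {
    stop("elements, coordinates and roles must agree in length", call. = FALSE)
  }
  if (!all(is.finite(x$coordinates))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (n > 1L) {
    dmin <- min(stats::dist(x$coordinates))
    if (dmin <= 0.5) {
      stop(sprintf("atoms closer than 0.5 Angstrom (min %.3f)", dmin), call. = FALSE)
    }
  }
  if (is.na(x$multiplicity) || x$multiplicity < 1L) {
    stop("multiplicity must be a positive integer", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.atomic_structure <- function(x, ...) {
  cat(sprintf("<atomic_structure> %d atoms, charge %+d, multiplicity %d\n",
              length(x$elements), x$charge, x$multiplicity))
  if (!is.na(x$kind)) cat("  kind:", x$kind, "\n")
  if (!is.na(x$compound)) cat("  compound:", x$compound, "\n")
  f <- structure_formula(x)
  cat("  formula:", paste0(names(f), f, collapse = " "), "\n")
  invisible(x)
}

#' Element counts of a structure
#'
#' @param x An `atomic_structure`.
#' @return Named integer vector of element counts (alphabetical order).
#' @export
structure_formula <- function(x) {
  tab <- table(x$elements)
  stats::setNames(as.integer(tab), names(tab))
}

.kv_line <- function(pairs) {
  paste(vapply(names(pairs), function(k) {
    v <- pairs[[k]]
    if (grepl("[[:space:]]", v)) v <- paste0("\"", v, "\"")
    paste0(k, "=", v)
  }, character(1)), collapse = " ")
}

#' Read and write XYZ files
#'
#' Standard XYZ layout: atom count, a comment line, then one
#' `element x y z` line per atom. The comment line carries the species tag,
#' charge and multiplicity as `key=value` pairs (quoted when the value
#' contains spaces), e.g. `kind=acid charge=0 mult=1 compound="Benzoic Acid"`.
#' Role labels are not serialized; [infer_roles()] recovers them from the
#' geometry.
#'
#' @param x An `atomic_structure`.
#' @param path File path.
#' @return `write_xyz()` returns `path` invisibly; `read_xyz()` returns an
#'   `atomic_structure`.
#' @export
write_xyz <- function(x, path) {
  validate_structure(x)
  kv <- list(charge = format(x$charge), mult = format(x$multiplicity))
  if (!is.na(x$kind)) kv <- c(list(kind = x$kind), kv)
  if (!is.na(x$compound)) kv$compound <- x$compound
  lines <- c(
    format(length(x$elements)),
    .kv_line(kv),
    sprintf("%-2s %14.8f %14.8f %14.8f", x$elements,
            x$coordinates[, 1], x$coordinates[, 2], x$coordinates[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 2L) {
    stop("malformed XYZ file: ", path, call. = FALSE)
  }
  comment <- lines[2]
  grab <- function(key, default) {
    m <- regmatches(comment,
                    regexec(paste0(key, "=(\"[^\"]*\"|[^[:space:]]+)"), comment))[[1]]
    if (length(m) < 2L) return(default)
    gsub("^\"|\"$", "", m[2])
  }
  fields <- do.call(rbind, strsplit(trimws(lines[3:(n + 2L)]), "[[:space:]]+"))
  atomic_structure(
    elements = fields[, 1],
    coordinates = apply(fields[, 2:4, drop = FALSE], 2, as.numeric),
    charge = as.integer(grab("charge", "0")),
    multiplicity = as.integer(grab("mult", "1")),
    kind = grab("kind", NA_character_),
    compound = grab("compound", NA_character_)
  )
}

# rigid-body helper: rotate about an arbitrary axis (Rodrigues), used by the
# cluster builder and handy for invariance checks
.rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rigidly transform a structure
#'
#' Applies a proper rotation (about an axis through the origin) followed by a
#' translation to every atom. Used to verify that geometric diagnostics are
#' frame-independent.
#'
#' @param x An `atomic_structure`.
#' @param axis Length-3 rotation axis (need not be normalized).
#' @param angle_deg Rotation angle in degrees.
#' @param translation Length-3 translation vector (Angstrom).
#' @return The transformed `atomic_structure`.
#' @export
transform_structure <- function(x, axis = c(0, 0, 1), angle_deg = 0,
                                translation = c(0, 0, 0)) {
  validate_structure(x)
  R <- .rotation_matrix(axis, angle_deg)
  x$coordinates <- sweep(x$coordinates %*% t(R), 2, translation, "+")
  x
}
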