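# Built-in panel: 11 substituted benzoic acids with experimental reference pKa
# (PubChem/NIH values). SMILES are stored in OpenBabel-canonical form so that
# the canonicalizing loader round-trips them unchanged. Substituent maps use
# ring numbering with the carboxyl carbon as position 1.

.builtin_panel <- local({
  sub <- function(p2 = "H", p3 = "H", p4 = "H", p6 = "H") {
    c(`2` = p2, `3` = p3, `4` = p4, `6` = p6)
  }
  list(
    list(name = "Benzoic Acid", smiles = "OC(=O)c1ccccc1",
         pka_ref = 4.20, substituents = sub()),
    list(name = "4-Cyanobenzoic Acid", smiles = "N#Cc1ccc(cc1)C(=O)O",
         pka_ref = 3.55, substituents = sub(p4 = "CN")),
    list(name = "2,6-Dimethylbenzoic Acid", smiles = "OC(=O)c1c(C)cccc1C",
         pka_ref = 3.24, substituents = sub(p2 = "CH3", p6 = "CH3")),
    list(name = "4-Bromobenzoic Acid", smiles = "OC(=O)c1ccc(cc1)Br",
         pka_ref = 3.96, substituents = sub(p4 = "Br")),
    list(name = "2-Bromobenzoic Acid", smiles = "OC(=O)c1ccccc1Br",
         pka_ref = 2.96, substituents = sub(p2 = "Br")),
    list(name = "2-Chlorobenzoic Acid", smiles = "OC(=O)c1ccccc1Cl",
         pka_ref = 2.96, substituents = sub(p2 = "Cl")),
    list(name = "3-Chlorobenzoic Acid", smiles = "Clc1cccc(c1)C(=O)O",
         pka_ref = 3.83, substituents = sub(p3 = "Cl")),
    list(name = "4-Chlorobenzoic Acid", smiles = "OC(=O)c1ccc(cc1)Cl",
         pka_ref = 3.99, substituents = sub(p4 = "Cl")),
    list(name = "2-Methoxybenzoic Acid", smiles = "COc1ccccc1C(=O)O",
         pka_ref = 4.09, substituents = sub(p2 = "OCH3")),
    list(name = "3-Methoxybenzoic Acid", smiles = "COc1cccc(c1)C(=O)O",
         pka_ref = 4.10, substituents = sub(p3 = "OCH3")),
    list(name = "4-Methoxybenzoic Acid", smiles = "COc1ccc(cc1)C(=O)O",
         pka_ref = 4.50, substituents = sub(p4 = "OCH3"))
  )
})

.compound_frame <- function(entries) {
  data.frame(
    name = vapply(entries, `[[`, character(1), "name"),
    smiles = vapply(entries, `[[`, character(1), "smiles"),
    pka_ref = vapply(entries, `[[`, numeric(1), "pka_ref"),
    substituents = I(lapply(entries, `[[`, "substituents")),
    stringsAsFactors = FALSE
  )
}

#' The built-in benzoic acid panel
#'
#' Eleven substituted benzoic acids — benzoic acid as the parent, plus cyano,
#' bromo, chloro, methoxy and 2,6-dimethyl derivatives probing inductive,
#' conjugative and "ortho" effects — with their experimental aqueous reference
#' pKa values (NIH/PubChem). The `substituents` list-column maps ring
#' positions 2, 3, 4, 6 (carboxyl carbon = position 1) to group labels in
#' `{H, CH3, Br, Cl, OCH3, CN}`.
#'
#' @return A data.frame with columns `name`, `smiles`, `pka_ref` and the
#'   list-column `substituents`; 11 rows in fixed panel order.
#' @examples
#' panel <- builtin_compounds()
#' panel[panel$name == "Benzoic Acid", "pka_ref"] # 4.20
#' @export
builtin_compounds <- function() .compound_frame(.builtin_panel)

.canonical_smiles <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", smiles),
    error = function(e) stop("unparsable SMILES '", smiles, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  out <- trimws(out)
  if (!nzchar(out)) stop("unparsable SMILES '", smiles, "'", call. = FALSE)
  out
}

.validate_smiles <- function(smiles, row = NA_integer_) {
  ok <- tryCatch({
    sdf <- ChemmineR::smiles2sdf(smiles)
    length(ChemmineR::atomblock(sdf[[1]])) > 0
  }, error = function(e) FALSE)
  if (!ok) {
    where <- if (is.na(row)) "" else paste0(" (row ", row, ")")
    stop("unparsable SMILES '", smiles, "'", where, call. = FALSE)
  }
  invisible(TRUE)
}

# substituent inference: user compounds whose canonical SMILES matches a
# built-in panel member inherit its map; anything else gets an empty map
.infer_substituents <- function(canonical) {
  builtin <- builtin_compounds()
  hit <- match(canonical, builtin$smiles)
  if (is.na(hit)) character(0) else builtin$substituents[[hit]]
}

#' Load a compound set from CSV
#'
#' Reads a UTF-8 CSV with columns `name`, `smiles`, `pka_ref` (dot decimal
#' separator). Every SMILES is validated and canonicalized through OpenBabel;
#' an unparsable SMILES aborts with the offending row. Substituent maps are
#' inferred when the canonical SMILES matches a built-in panel member and left
#' empty otherwise.
#'
#' @param path CSV file path.
#' @return A data.frame shaped like [builtin_compounds()].
#' @export
load_compounds <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("name", "smiles", "pka_ref")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) return(.compound_frame(list()))
  entries <- lapply(seq_len(nrow(raw)), function(i) {
    .validate_smiles(raw$smiles[i], row = i)
    can <- .canonical_smiles(raw$smiles[i])
    list(name = raw$name[i], smiles = can,
         pka_ref = as.numeric(raw$pka_ref[i]),
         substituents = .infer_substituents(can))
  })
  .compound_frame(entries)
}

#' Write a compound set to CSV
#'
#' Inverse of [load_compounds()]: columns `name`, `smiles`, `pka_ref`.
#'
#' @param compounds Data.frame shaped like [builtin_compounds()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_compounds <- function(compounds, path) {
  utils::write.csv(
    compounds[, c("name", "smiles", "pka_ref")], path,
    row.names = FALSE, quote = TRUE
  )
  invisible(path)
}

#' Count carboxylic acid groups in a SMILES
#'
#' A carboxyl group is a carbon with exactly one double-bonded oxygen and one
#' single-bonded hydroxyl oxygen (no further heavy neighbor on the latter).
#' The cluster builder only accepts monocarboxylic acids.
#'
#' @param smiles A SMILES string.
#' @return Integer count of carboxyl groups.
#' @export
count_carboxyl <- function(smiles) {
  .validate_smiles(smiles)
  sdf <- ChemmineR::smiles2sdf(smiles)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- gsub("_.*$", "", rownames(ab))
  deg <- function(i) sum(bb[, 1] == i | bb[, 2] == i)
  n_carboxyl <- 0L
  for (i in which(elem == "C")) {
    rows <- which(bb[, 1] == i | bb[, 2] == i)
    nbr <- ifelse(bb[rows, 1] == i, bb[rows, 2], bb[rows, 1])
    ord <- bb[rows, 3]
    o_nbr <- nbr[elem[nbr] == "O"]
    o_ord <- ord[elem[nbr] == "O"]
    if (length(o_nbr) == 2L && sort(o_ord)[1] == 1 && sort(o_ord)[2] == 2) {
      oh <- o_nbr[o_ord == 1]
      # hydroxyl O must have no heavy neighbor besides the carboxyl carbon
      if (deg(oh) == 1L) n_carboxyl <- n_carboxyl + 1L
    }
  }
  n_carboxyl
}

#' The published benchmark panel of calculated pKa values
#'
#' Calculated pKa for the 11-compound panel under six exchange-correlation
#' functionals (6-311+G(d,p), SMD water), as published. Two cells are
#' unusable in the source (a typographic corruption for
#' PBEPBE / 2,6-dimethylbenzoic acid and an out-of-trend entry for
#' TPSSTPSS / 4-methoxybenzoic acid) and are stored as `NA`; 64 of the 66
#' cells are clean.
#'
#' @return A data.frame with a `compound` column followed by one numeric
#'   column per functional, rows in panel order.
#' @seealso [mock_engine()], which back-derives engine energies from this
#'   table; [reference_costs()]; [reference_dihedrals()].
#' @export
reference_benchmark <- function() {
  data.frame(
    compound = builtin_compounds()$name,
    `CAM-B3LYP` = c(4.35, 3.32, 3.89, 4.00, 3.02, 3.24, 3.91, 3.98, 4.46, 4.54, 4.74),
    B3PW91     = c(3.83, 2.96, 3.39, 3.27, 3.86, 2.36, 3.62, 3.77, 4.20, 3.99, 4.76),
    PBE1PBE    = c(3.54, 2.68, 3.57, 3.65, 2.33, 2.36, 3.67, 3.91, 4.28, 4.00, 4.74),
    PBEPBE     = c(6.07, 4.93, NA,   5.94, 4.87, 3.96, 5.91, 6.20, 6.17, 6.21, 7.02),
    TPSSTPSS   = c(5.22, 4.22, 4.81, 4.77, 4.18, 3.23, 5.03, 5.30, 5.93, 5.37, NA),
    WB97XD     = c(2.94, 1.92, 2.04, 2.74, 1.62, 0.78, 2.59, 2.70, 2.83, 2.93, 3.62),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}

#' Functional labels in canonical benchmark order
#' @return Character vector of the six functional labels.
#' @export
benchmark_functionals <- function() {
  c("CAM-B3LYP", "B3PW91", "PBE1PBE", "PBEPBE", "TPSSTPSS", "WB97XD")
}

#' Published computational cost per conjugated pair
#'
#' Average wall time in minutes to optimize an acid/conjugate-base pair under
#' each functional (20 shared processors, fixed memory).
#'
#' @return Named numeric vector (minutes per pair), names as in
#'   [benchmark_functionals()].
#' @export
reference_costs <- function() {
  c(`CAM-B3LYP` = 52, B3PW91 = 35, PBE1PBE = 30, PBEPBE = 31,
    TPSSTPSS = 49, WB97XD = 51)
}

#' Published average carboxyl-ring dihedrals per acid/base pair
#'
#' Average twist (degrees) between the carboxyl(ate) moiety and the aromatic
#' ring over each acid/conjugate-base pair, per functional. Ortho-substituted
#' compounds (2,6-dimethyl, 2-bromo, 2-chloro, 2-methoxy) sit far from
#' planarity; all others are nearly coplanar.
#'
#' @return A data.frame with `compound` plus one numeric column per functional.
#' @export
reference_dihedrals <- function() {
  data.frame(
    compound = builtin_compounds()$name,
    `CAM-B3LYP` = c(0.32, 0.67, 67.03, 0.41, 68.30, 68.97, 0.49, 0.47, 35.76, 0.29, 0.28),
    B3PW91     = c(0.52, 0.52, 68.90, 0.56, 69.38, 67.085, 0.42, 0.63, 37.56, 0.02, 0.30),
    PBE1PBE    = c(0.36, 0.83, 66.86, 0.95, 67.55, 66.09, 0.31, 0.57, 33.64, 0.23, 0.23),
    PBEPBE     = c(0.44, 1.12, 69.07, 0.70, 69.80, 66.215, 0.36, 0.73, 36.30, 0.20, 0.40),
    TPSSTPSS   = c(0.39, 0.90, 63.76, 1.15, 67.36, 63.82, 0.28, 0.70, 31.91, 0.06, 0.20),
    WB97XD     = c(0.72, 0.99, 69.80, 0.67, 70.81, 70.30, 0.50, 0.65, 43.16, 0.48, 0.78),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}
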