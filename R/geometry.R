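# Reaction-center geometry diagnostics: the hydrogen-bond contacts a, b, c
# (acid) and a', a'' (base) around the carboxyl group, and the twist of the
# carboxyl moiety against the aromatic ring. Selection is role-driven, so the
# metrics are invariant under rigid-body transforms and atom reordering.

# single-bond covalent radii (Angstrom) for the bond-detection cutoff
.covalent_radii <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
                     F = 0.57, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20,
                     I = 1.39)

#' Interatomic distance
#'
#' Euclidean distance between the nuclear positions (bead centers) of two
#' atoms.
#'
#' @param structure An `atomic_structure`.
#' @param i,j Distinct atom indices.
#' @return Distance in Angstrom.
#' @export
atom_distance <- function(structure, i, j) {
  n <- length(structure$elements)
  if (!all(c(i, j) %in% seq_len(n))) {
    stop("atom index out of range 1..", n, call. = FALSE)
  }
  if (i == j) stop("`i` and `j` must differ", call. = FALSE)
  sqrt(sum((structure$coordinates[i, ] - structure$coordinates[j, ])^2))
}

# adjacency by covalent-radius cutoff (sum of radii x 1.2)
.bond_matrix <- function(structure) {
  r <- .covalent_radii[structure$elements]
  if (anyNA(r)) stop("no covalent radius for element(s): ",
                     paste(unique(structure$elements[is.na(r)]), collapse = ", "),
                     call. = FALSE)
  d <- as.matrix(stats::dist(structure$coordinates))
  cutoff <- 1.2 * outer(r, r, "+")
  bonded <- d < cutoff & d > 0
  diag(bonded) <- FALSE
  bonded
}

#' Infer reaction-center roles from a bare geometry
#'
#' Recovers the role labels on structures that carry none (e.g. geometries
#' parsed from engine logs): bonds are detected with a covalent-radius cutoff
#' (sum of radii times 1.2); water oxygens are O bonded to exactly two H and
#' nothing else; the carboxyl carbon is a C bonded to two non-water O; a
#' protonated oxygen identifies hydroxyl/acidic-H (acid), otherwise the two
#' oxygens are carboxylate (base, numbered by atom index); the ipso ring
#' carbon is the C neighbor of the carboxyl carbon and its C neighbors are
#' the ortho carbons.
#'
#' @param structure An `atomic_structure`.
#' @return The structure with `roles` (and `kind`, when derivable) filled in.
#' @export
infer_roles <- function(structure) {
  validate_structure(structure)
  n <- length(structure$elements)
  el <- structure$elements
  bonded <- .bond_matrix(structure)
  nbrs <- function(i) which(bonded[i, ])
  roles <- rep(NA_character_, n)

  for (i in which(el == "O")) {
    nb <- nbrs(i)
    if (length(nb) == 2L && all(el[nb] == "H")) {
      roles[i] <- "water_O"
      roles[nb] <- "water_H"
    }
  }

  cx <- NA_integer_
  for (i in which(el == "C")) {
    o_nb <- nbrs(i)[el[nbrs(i)] == "O" & is.na(roles[nbrs(i)])]
    if (length(o_nb) == 2L) { cx <- i; break }
  }
  if (!is.na(cx)) {
    roles[cx] <- "carboxyl_C"
    o_nb <- nbrs(cx)[el[nbrs(cx)] == "O"]
    protonated <- vapply(o_nb, function(o) any(el[nbrs(o)] == "H"), logical(1))
    if (any(protonated)) {
      oh <- o_nb[protonated][1]
      roles[oh] <- "hydroxyl_O"
      roles[o_nb[!protonated][1]] <- "carbonyl_O"
      roles[nbrs(oh)[el[nbrs(oh)] == "H"][1]] <- "acidic_H"
      if (is.na(structure$kind)) structure$kind <- "acid"
    } else {
      roles[sort(o_nb)[1]] <- "carboxylate_O1"
      roles[sort(o_nb)[2]] <- "carboxylate_O2"
      if (is.na(structure$kind)) structure$kind <- "base"
    }
    ipso <- nbrs(cx)[el[nbrs(cx)] == "C"]
    if (length(ipso) == 1L) {
      roles[ipso] <- "ring_C_ipso"
      ortho <- setdiff(nbrs(ipso)[el[nbrs(ipso)] == "C"], cx)
      roles[ortho] <- "ring_C_ortho"
    }
  }

  structure$roles <- roles
  structure
}

.roles_or_infer <- function(structure) {
  if (all(is.na(structure$roles))) infer_roles(structure) else structure
}

.role_idx <- function(structure, role) which(structure$roles == role)

.need_role <- function(structure, role, n = 1L) {
  idx <- .role_idx(structure, role)
  if (length(idx) < n) {
    stop("missing ", role, " role (need ", n, ", found ", length(idx), ")",
         call. = FALSE)
  }
  idx
}

# torsion angle p1-p2-p3-p4, signed, degrees
.torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Fold a torsion into the [0, 90] degree range
#'
#' The carboxyl twist is reported modulo the symmetry of the ring plane:
#' `f(x) = f(-x) = f(180 - x)`, mapping any angle into `[0, 90]`.
#'
#' @param deg Angle(s) in degrees.
#' @return Folded angle(s) in `[0, 90]`.
#' @export
fold_dihedral <- function(deg) {
  a <- abs(deg) %% 180
  ifelse(a > 90, 180 - a, a)
}

#' Carboxyl-ring twist angle
#'
#' The rotation of the carboxyl(ate) moiety against the aromatic ring plane,
#' measured as the four-atom torsion ortho-C / ipso-C / carboxyl-C /
#' carboxyl-O (the lower-index ortho carbon, and the carbonyl oxygen for
#' acids or the first carboxylate oxygen for bases) folded into `[0, 90]`
#' degrees. `method = "plane"` instead measures the angle between the C-O
#' direction and the ring plane's in-plane component, as a cross-check for
#' non-ideal ring geometries.
#'
#' @param structure An `atomic_structure`; roles are inferred when absent.
#' @param method `"torsion"` (default) or `"plane"`.
#' @return Twist angle in degrees, in `[0, 90]`.
#' @export
carboxyl_ring_dihedral <- function(structure, method = c("torsion", "plane")) {
  method <- match.arg(method)
  structure <- .roles_or_infer(structure)
  cx <- .need_role(structure, "carboxyl_C")[1]
  ipso <- .need_role(structure, "ring_C_ipso")[1]
  ortho <- sort(.need_role(structure, "ring_C_ortho"))[1]
  o_idx <- c(.role_idx(structure, "carbonyl_O"),
             .role_idx(structure, "carboxylate_O1"))
  if (length(o_idx) == 0L) {
    stop("missing carbonyl_O/carboxylate_O1 role", call. = FALSE)
  }
  xyz <- structure$coordinates
  if (method == "torsion") {
    return(fold_dihedral(.torsion(xyz[ortho, ], xyz[ipso, ], xyz[cx, ],
                                  xyz[o_idx[1], ])))
  }
  # plane variant: angle of the carboxyl C->O bond out of the ring plane
  ring_n <- .unit(.cross3(xyz[ortho, ] - xyz[ipso, ], xyz[cx, ] - xyz[ipso, ]))
  co <- .unit(xyz[o_idx[1], ] - xyz[cx, ])
  fold_dihedral(asin(abs(sum(co * ring_n))) * 180 / pi / 1) # out-of-plane angle
}

#' Reaction-center bond-length diagnostics
#'
#' For an acid cluster: `a` — the contact between the carbonyl oxygen and the
#' nearest water hydrogen; `b` — the contact between the acidic hydrogen and
#' the nearest water oxygen; `c` — the covalent O-H bond of the acid group.
#' For a conjugate-base cluster: `a_prime` and `a_second` — the minimum
#' water-H to carboxylate-O contact per water, with the two waters assigned
#' to the two oxygens by minimizing the total contact length (ties broken by
#' atom index). The carboxyl-ring twist is included in both cases.
#'
#' @param structure An `atomic_structure` with roles (inferred when absent).
#' @return A list of class `reaction_center_metrics`: `kind`, `lengths`
#'   (named numeric, Angstrom), `dihedral` (degrees in `[0, 90]`).
#' @export
reaction_center_metrics <- function(structure) {
  structure <- .roles_or_infer(structure)
  xyz <- structure$coordinates
  w_o <- .need_role(structure, "water_O", 2L)
  w_h <- .need_role(structure, "water_H", 4L)
  d <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))

  if (length(.role_idx(structure, "acidic_H"))) {
    oc <- .need_role(structure, "carbonyl_O")[1]
    oh <- .need_role(structure, "hydroxyl_O")[1]
    ha <- .need_role(structure, "acidic_H")[1]
    lengths <- c(
      a = min(vapply(w_h, d, numeric(1), i = oc)),
      b = min(vapply(w_o, d, numeric(1), i = ha)),
      c = d(oh, ha)
    )
    kind <- "acid"
  } else {
    o1 <- .need_role(structure, "carboxylate_O1")[1]
    o2 <- .need_role(structure, "carboxylate_O2")[1]
    # per water, its closest H-contact to each carboxylate O
    contact <- function(ow, o) {
      hs <- w_h[vapply(w_h, function(h) d(ow, h) < 1.2, logical(1))]
      min(vapply(hs, d, numeric(1), i = o))
    }
    c11 <- contact(w_o[1], o1); c12 <- contact(w_o[1], o2)
    c21 <- contact(w_o[2], o1); c22 <- contact(w_o[2], o2)
    # assign waters to oxygens minimizing total contact length; ties keep the
    # index order (water 1 -> O1)
    if (c11 + c22 <= c12 + c21) {
      lengths <- c(a_prime = c11, a_second = c22)
    } else {
      lengths <- c(a_prime = c21, a_second = c12)
    }
    kind <- "base"
  }
  out <- list(kind = kind, lengths = lengths,
              dihedral = carboxyl_ring_dihedral(structure))
  class(out) <- "reaction_center_metrics"
  out
}

#' @export
print.reaction_center_metrics <- function(x, ...) {
  cat(sprintf("<reaction_center_metrics> %s: %s; dihedral %.2f deg\n",
              x$kind,
              paste(sprintf("%s=%.3f", names(x$lengths), x$lengths),
                    collapse = " "),
              x$dihedral))
  invisible(x)
}

#' Average carboxyl twist over an acid/base pair
#'
#' Arithmetic mean of the (folded, absolute) dihedral of the acid and its
#' conjugate base — the per-pair summary used to compare functionals.
#'
#' @param acid_deg,base_deg Dihedrals in degrees, each in `[0, 90]`
#'   (vectorised).
#' @return Mean dihedral(s) in degrees.
#' @examples
#' pair_average_dihedral(60, 74) # 67
#' @export
pair_average_dihedral <- function(acid_deg, base_deg) {
  vals <- c(acid_deg, base_deg)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals < 0 | vals > 90)) {
    stop("dihedrals must lie in [0, 90] degrees", call. = FALSE)
  }
  (acid_deg + base_deg) / 2
}

#' Bond-length differences against a reference functional
#'
#' Tabulates, per compound and reaction-center contact, the signed difference
#' of each functional's bond length from the reference functional's value,
#' and flags differences whose magnitude exceeds 0.25 Angstrom as outliers
#' (the published envelope for this panel).
#'
#' @param lengths Long-format data.frame with columns `compound`,
#'   `functional`, `label`, `length` (Angstrom).
#' @param reference Reference functional label (default `"CAM-B3LYP"`); must
#'   be present for every compound/label.
#' @param flag_threshold Outlier threshold in Angstrom (default 0.25).
#' @return The input augmented with `delta` (functional minus reference) and
#'   logical `outlier`; the reference rows have `delta` identically zero.
#' @export
delta_length <- function(lengths, reference = "CAM-B3LYP",
                         flag_threshold = 0.25) {
  needed <- c("compound", "functional", "label", "length")
  if (!all(needed %in% names(lengths))) {
    stop("`lengths` needs columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  ref <- lengths[lengths$functional == reference, ]
  key <- function(d) paste(d$compound, d$label, sep = "\r")
  idx <- match(key(lengths), key(ref))
  if (anyNA(idx)) {
    bad <- unique(lengths$compound[is.na(idx)])
    stop("reference functional '", reference, "' missing for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  lengths$delta <- lengths$length - ref$length[idx]
  lengths$outlier <- abs(lengths$delta) > flag_threshold
  lengths
}
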