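# Analytic 3D templates for the species of the explicit dissociation reaction.
# Geometries are idealized starting guesses (regular aromatic ring, standard
# bond lengths, 1.85-Angstrom hydrogen-bond contacts) meant to be handed to a
# QM engine for optimization; construction is purely deterministic.

# template bond lengths (Angstrom) and angles (degrees)
.geom <- list(
  cc_ring = 1.39, ch_ring = 1.08, c_carboxyl = 1.48,
  co_double = 1.21, co_single = 1.34, co_carboxylate = 1.26,
  oh = 0.97, coh_angle = 106,
  c_methyl = 1.50, ch_methyl = 1.09, c_cl = 1.73, c_br = 1.89,
  c_cn = 1.43, cn_triple = 1.16, c_ome = 1.36, o_me = 1.43,
  hbond = 1.85, water_oh = 0.96, water_angle = 104.5,
  ortho_twist = 60
)

.unit <- function(v) v / sqrt(sum(v^2))

.perp_component <- function(v, ref) {
  p <- v - sum(v * ref) * ref
  n <- sqrt(sum(p^2))
  if (n < 1e-8) stop("degenerate frame in water placement", call. = FALSE)
  p / n
}

# one water molecule given its O position, the bisector/bond frame
.water_atoms <- function(o, dir1, dir2) {
  list(
    list(el = "O", xyz = o, role = "water_O"),
    list(el = "H", xyz = o + .geom$water_oh * dir1, role = "water_H"),
    list(el = "H", xyz = o + .geom$water_oh * dir2, role = "water_H")
  )
}

.resolve_compound <- function(compound) {
  if (is.character(compound) && length(compound) == 1L) {
    panel <- builtin_compounds()
    hit <- match(compound, panel$name)
    if (is.na(hit)) stop("unknown compound name '", compound, "'", call. = FALSE)
    return(panel[hit, , drop = FALSE])
  }
  if (is.data.frame(compound) && nrow(compound) == 1L) return(compound)
  stop("`compound` must be a compound name or a single-row compound data.frame",
       call. = FALSE)
}

# ring + carboxyl(ate) + substituents; the shared core of acid and base
.build_solute <- function(compound, ionized = FALSE) {
  cp <- .resolve_compound(compound)
  subs <- cp$substituents[[1]]
  if (length(subs) == 0L) {
    stop("cannot derive a 3D template for '", cp$name,
         "': no substituent pattern available", call. = FALSE)
  }
  g <- .geom
  atoms <- list()
  push <- function(el, xyz, role = NA_character_) {
    atoms[[length(atoms) + 1L]] <<- list(el = el, xyz = xyz, role = role)
  }

  theta <- (0:5) * 60 * pi / 180
  ring <- cbind(g$cc_ring * cos(theta), g$cc_ring * sin(theta), 0)
  radial <- cbind(cos(theta), sin(theta), 0)

  push("C", ring[1, ], "ring_C_ipso")
  for (k in 2:6) {
    role <- if (k %in% c(2L, 6L)) "ring_C_ortho" else NA_character_
    push("C", ring[k, ], role)
  }

  # carboxyl / carboxylate on position 1, initially in the ring plane
  ccx <- ring[1, ] + g$c_carboxyl * radial[1, ]
  dir_up <- c(cos(pi / 3), sin(pi / 3), 0)
  dir_dn <- c(cos(-pi / 3), sin(-pi / 3), 0)
  cx_start <- length(atoms) + 1L
  push("C", ccx, "carboxyl_C")
  if (ionized) {
    push("O", ccx + g$co_carboxylate * dir_up, "carboxylate_O1")
    push("O", ccx + g$co_carboxylate * dir_dn, "carboxylate_O2")
  } else {
    push("O", ccx + g$co_double * dir_up, "carbonyl_O")
    oh <- ccx + g$co_single * dir_dn
    push("O", oh, "hydroxyl_O")
    u <- .unit(ccx - oh)
    hdir <- as.vector(.rotation_matrix(c(0, 0, 1), -g$coh_angle) %*% u)
    push("H", oh + g$oh * hdir, "acidic_H")
  }
  cx_end <- length(atoms)

  # substituents / ring hydrogens on positions 2..6
  for (k in 2:6) {
    grp <- if (as.character(k) %in% names(subs)) subs[[as.character(k)]] else "H"
    d <- radial[k, ]
    p <- c(-sin(theta[k]), cos(theta[k]), 0) # in-plane perpendicular
    z <- c(0, 0, 1)
    base <- ring[k, ]
    if (grp == "H") {
      push("H", base + g$ch_ring * d)
    } else if (grp == "CH3") {
      cm <- base + g$c_methyl * d
      push("C", cm)
      for (phi in c(0, 120, 240) * pi / 180) {
        hd <- cos(70.5 * pi / 180) * d +
          sin(70.5 * pi / 180) * (cos(phi) * p + sin(phi) * z)
        push("H", cm + g$ch_methyl * hd)
      }
    } else if (grp == "Cl") {
      push("Cl", base + g$c_cl * d)
    } else if (grp == "Br") {
      push("Br", base + g$c_br * d)
    } else if (grp == "CN") {
      cc <- base + g$c_cn * d
      push("C", cc)
      push("N", cc + g$cn_triple * d)
    } else if (grp == "OCH3") {
      o <- base + g$c_ome * d
      push("O", o)
      bend <- if (theta[k] <= pi + 1e-9) 63 else -63 # fold away from carboxyl
      e <- as.vector(.rotation_matrix(z, bend) %*% d)
      cm <- o + g$o_me * e
      push("C", cm)
      pe <- .perp_component(p, e)
      for (phi in c(0, 120, 240) * pi / 180) {
        hd <- cos(70.5 * pi / 180) * e +
          sin(70.5 * pi / 180) * (cos(phi) * pe + sin(phi) * z)
        push("H", cm + g$ch_methyl * hd)
      }
    } else {
      stop("unsupported substituent group '", grp, "'", call. = FALSE)
    }
  }

  # ortho substituents force the carboxyl out of the ring plane in the guess
  ortho <- any(vapply(c("2", "6"), function(pos) {
    pos %in% names(subs) && subs[[pos]] != "H"
  }, logical(1)))
  if (ortho) {
    R <- .rotation_matrix(radial[1, ], g$ortho_twist)
    for (i in cx_start:cx_end) {
      atoms[[i]]$xyz <- ring[1, ] +
        as.vector(R %*% (atoms[[i]]$xyz - ring[1, ]))
    }
  }

  atomic_structure(
    elements = vapply(atoms, `[[`, character(1), "el"),
    coordinates = do.call(rbind, lapply(atoms, `[[`, "xyz")),
    charge = if (ionized) -1L else 0L, multiplicity = 1L,
    roles = vapply(atoms, `[[`, character(1), "role"),
    kind = if (ionized) "base" else "acid",
    compound = cp$name
  )
}

#' Deterministic 3D template for a panel compound
#'
#' Builds an idealized starting geometry for the neutral acid from the
#' compound's substituent pattern: a regular planar aromatic ring with
#' standard bond lengths, the carboxyl group in its syn rotamer, and a fixed
#' out-of-plane carboxyl twist when an ortho substituent is present (the
#' "ortho effect" anticipated in the guess). The construction is analytic, so
#' repeated calls are bitwise identical.
#'
#' @param compound A compound name from [builtin_compounds()] or a single-row
#'   compound data.frame with a non-empty substituent map.
#' @return An `atomic_structure` of the bare acid with reaction-center and
#'   ring roles labeled.
#' @examples
#' s <- embed_3d("Benzoic Acid")
#' range(s$coordinates[s$elements == "C", 3]) # ring is exactly planar
#' @export
embed_3d <- function(compound) .build_solute(compound, ionized = FALSE)

#' Place the two explicit waters at the reaction center
#'
#' For an acid solute, one water accepts a hydrogen bond from the acidic
#' proton (contact *b*) and one donates a hydrogen to the carbonyl oxygen
#' (contact *a*); for a carboxylate, each water donates one hydrogen to one
#' carboxylate oxygen (contacts *a'* and *a''*). All contacts are placed at
#' the template hydrogen-bond distance of 1.85 Angstrom with near-linear
#' donor-H-acceptor arrangements. Placement directions are derived from the
#' solute's own reaction-center atoms, so rigidly transforming the solute
#' rigidly transforms the solvated cluster.
#'
#' @param solute An `atomic_structure` with reaction-center roles (from
#'   [embed_3d()] or the ionized builder inside [build_species()]).
#' @param kind `"acid"` or `"base"`; defaults to the solute's own tag.
#' @return The solvated `atomic_structure` (solute atoms first, then the two
#'   waters) with `water_O`/`water_H` roles appended.
#' @export
solvate_reaction_center <- function(solute, kind = solute$kind) {
  validate_structure(solute)
  kind <- match.arg(kind, c("acid", "base"))
  g <- .geom
  xyz <- solute$coordinates
  at <- function(role) which(solute$roles == role)
  half <- g$water_angle / 2 * pi / 180
  waters <- list()

  if (kind == "acid") {
    need <- c("carboxyl_C", "carbonyl_O", "hydroxyl_O", "acidic_H")
    if (!all(vapply(need, function(r) length(at(r)) == 1L, logical(1)))) {
      stop("acid solute must carry roles ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    ccx <- xyz[at("carboxyl_C"), ]
    oc <- xyz[at("carbonyl_O"), ]
    oh <- xyz[at("hydroxyl_O"), ]
    ha <- xyz[at("acidic_H"), ]
    # water 1 accepts from the acidic H: contact b, linear O-H...O
    u <- .unit(ha - oh)
    ow1 <- ha + g$hbond * u
    p <- .perp_component(oc - ccx, u)
    waters <- c(waters, .water_atoms(
      ow1, cos(half) * u + sin(half) * p, cos(half) * u - sin(half) * p))
    # water 2 donates to the carbonyl O: contact a along the C=O direction
    v <- .unit(oc - ccx)
    hw2 <- oc + g$hbond * v
    ow2 <- hw2 + g$water_oh * v
    q <- .perp_component(.cross3(v, u), v)
    free <- cos(g$water_angle * pi / 180) * (-v) +
      sin(g$water_angle * pi / 180) * q
    waters <- c(waters, .water_atoms(ow2, .unit(hw2 - ow2), free))
  } else {
    o_idx <- c(at("carboxylate_O1"), at("carboxylate_O2"))
    if (length(o_idx) != 2L || length(at("carboxyl_C")) != 1L) {
      stop("base solute must carry roles carboxyl_C, carboxylate_O1, ",
           "carboxylate_O2", call. = FALSE)
    }
    ccx <- xyz[at("carboxyl_C"), ]
    v1 <- .unit(xyz[o_idx[1], ] - ccx)
    v2 <- .unit(xyz[o_idx[2], ] - ccx)
    n <- .unit(.cross3(v1, v2))
    vs <- list(v1, v2)
    for (k in 1:2) {
      v <- vs[[k]]
      oi <- xyz[o_idx[k], ]
      hw <- oi + g$hbond * v
      ow <- hw + g$water_oh * v
      q <- .perp_component(n, v)
      free <- cos(g$water_angle * pi / 180) * (-v) +
        sin(g$water_angle * pi / 180) * q
      waters <- c(waters, .water_atoms(ow, .unit(hw - ow), free))
    }
  }

  atomic_structure(
    elements = c(solute$elements, vapply(waters, `[[`, character(1), "el")),
    coordinates = rbind(xyz, do.call(rbind, lapply(waters, `[[`, "xyz"))),
    charge = solute$charge, multiplicity = solute$multiplicity,
    roles = c(solute$roles, vapply(waters, `[[`, character(1), "role")),
    kind = kind, compound = solute$compound
  )
}

# 3-vector cross product
.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.hydroxide_cluster <- function() {
  g <- .geom
  atoms <- list(
    list(el = "O", xyz = c(0, 0, 0), role = NA_character_),
    list(el = "H", xyz = c(0, 0, g$oh), role = NA_character_)
  )
  polar <- 110 * pi / 180
  for (az_deg in c(0, 150)) {
    az <- az_deg * pi / 180
    d <- c(sin(polar) * cos(az), sin(polar) * sin(az), cos(polar))
    hw <- g$hbond * d
    ow <- hw + g$water_oh * d
    t <- .unit(.cross3(d, c(0, 0, 1)))
    free <- cos(g$water_angle * pi / 180) * (-d) +
      sin(g$water_angle * pi / 180) * t
    atoms <- c(atoms, .water_atoms(ow, .unit(hw - ow), free))
  }
  atomic_structure(
    elements = vapply(atoms, `[[`, character(1), "el"),
    coordinates = do.call(rbind, lapply(atoms, `[[`, "xyz")),
    charge = -1L, multiplicity = 1L,
    roles = vapply(atoms, `[[`, character(1), "role"),
    kind = "hydroxide"
  )
}

.water_trimer <- function() {
  g <- .geom
  rc <- 2.8 / sqrt(3)
  az <- c(90, 210, 330) * pi / 180
  o <- cbind(rc * cos(az), rc * sin(az), 0)
  atoms <- list()
  for (i in 1:3) {
    nxt <- if (i == 3L) 1L else i + 1L
    b <- .unit(o[nxt, ] - o[i, ])
    free <- cos(g$water_angle * pi / 180) * b +
      sin(g$water_angle * pi / 180) * c(0, 0, 1)
    atoms <- c(atoms, .water_atoms(o[i, ], b, free))
  }
  atomic_structure(
    elements = vapply(atoms, `[[`, character(1), "el"),
    coordinates = do.call(rbind, lapply(atoms, `[[`, "xyz")),
    charge = 0L, multiplicity = 1L,
    roles = vapply(atoms, `[[`, character(1), "role"),
    kind = "water"
  )
}

#' Build a micro-solvated species of the dissociation reaction
#'
#' Constructs the initial structure of one of the four reaction species, each
#' carrying two explicit water molecules: the acid cluster
#' `RCO2H.(H2O)2` (neutral), the conjugate-base cluster `RCO2-.(H2O)2`
#' (charge -1), the hydroxide cluster `OH-.(H2O)2` (charge -1) and the water
#' trimer `H2O.(H2O)2` (neutral); all singlets. Acid and base require a
#' monocarboxylic compound; hydroxide and water are compound-independent.
#'
#' @param kind One of `"acid"`, `"base"`, `"hydroxide"`, `"water"`.
#' @param compound Compound name or single-row data.frame for acid/base;
#'   must be `NULL` for hydroxide/water.
#' @return An `atomic_structure` with reaction-center roles populated.
#' @examples
#' length(build_species("acid", "Benzoic Acid")$elements)  # 21 atoms
#' length(build_species("water")$elements)                 # 9 atoms
#' @export
build_species <- function(kind = c("acid", "base", "hydroxide", "water"),
                          compound = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("hydroxide", "water")) {
    if (!is.null(compound)) {
      stop("`compound` must be NULL for kind '", kind, "'", call. = FALSE)
    }
    return(if (kind == "hydroxide") .hydroxide_cluster() else .water_trimer())
  }
  if (is.null(compound)) {
    stop("kind '", kind, "' requires a compound", call. = FALSE)
  }
  cp <- .resolve_compound(compound)
  ncx <- count_carboxyl(cp$smiles)
  if (ncx != 1L) {
    stop("'", cp$name, "' has ", ncx,
         " carboxyl groups; only monocarboxylic acids are supported",
         call. = FALSE)
  }
  solute <- .build_solute(cp, ionized = (kind == "base"))
  solvate_reaction_center(solute, kind)
}
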