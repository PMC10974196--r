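test_that("atom distances match a brute-force table and survive rigid motion", {
  trimer <- build_species("water") # 9-atom fixture
  ref <- brute_force_distances(trimer)
  for (i in 1:8) {
    for (j in (i + 1):9) {
      expect_equal(atom_distance(trimer, i, j), ref[i, j], tolerance = 1e-12)
    }
  }
  two <- atomic_structure(c("O", "O"), rbind(c(0, 0, 0), c(0, 0, 2)))
  expect_equal(atom_distance(two, 1, 2), 2.0)

  set.seed(77)
  for (rep in 1:5) {
    moved <- random_rigid(trimer)
    expect_equal(atom_distance(moved, 2, 7), atom_distance(trimer, 2, 7),
                 tolerance = 1e-9)
  }
  expect_error(atom_distance(trimer, 1, 10), "out of range")
  expect_error(atom_distance(trimer, 3, 3), "differ")
})

test_that("carboxyl twist equals a constructed rotation and folds into [0, 90]", {
  s <- embed_3d("Benzoic Acid")
  expect_equal(carboxyl_ring_dihedral(s), 0, tolerance = 1e-9)
  cx_block <- which(s$roles %in% c("carbonyl_O", "hydroxyl_O", "acidic_H"))
  ipso <- s$coordinates[which(s$roles == "ring_C_ipso"), ]
  ccx <- s$coordinates[which(s$roles == "carboxyl_C"), ]
  for (angle in c(30, 67, 90, 123, 245)) {
    rotated <- rotate_atoms_about_bond(s, cx_block, ipso, ccx, angle)
    expect_equal(carboxyl_ring_dihedral(rotated), fold_dihedral(angle),
                 tolerance = 1e-6, info = paste("angle", angle))
  }
})

test_that("dihedral folding has the ring-plane symmetry f(x)=f(-x)=f(180-x)", {
  grid <- seq(-360, 360, by = 7.5)
  f <- fold_dihedral(grid)
  expect_true(all(f >= 0 & f <= 90))
  expect_equal(fold_dihedral(-grid), f)
  expect_equal(fold_dihedral(180 - grid), f)
})

test_that("pair averaging is the arithmetic mean with range checks", {
  expect_equal(pair_average_dihedral(0, 0), 0)
  expect_equal(pair_average_dihedral(60, 74), 67)
  for (x in c(0, 13.7, 45, 90)) expect_equal(pair_average_dihedral(x, x), x)
  expect_error(pair_average_dihedral(-1, 10), "\\[0, 90\\]")
  expect_error(pair_average_dihedral(10, 91), "\\[0, 90\\]")
})

test_that("reaction-center metrics are invariant to frame and atom order", {
  set.seed(99)
  for (kind in c("acid", "base")) {
    cl <- build_species(kind, "2-Methoxybenzoic Acid")
    m0 <- reaction_center_metrics(cl)
    moved <- random_rigid(cl)
    m1 <- reaction_center_metrics(moved)
    expect_equal(m1$lengths, m0$lengths, tolerance = 1e-9)
    expect_equal(m1$dihedral, m0$dihedral, tolerance = 1e-9)
    perm <- sample(length(cl$elements))
    shuffled <- atomic_structure(cl$elements[perm], cl$coordinates[perm, ],
                                 cl$charge, cl$multiplicity, cl$roles[perm],
                                 kind = cl$kind, compound = cl$compound)
    m2 <- reaction_center_metrics(shuffled)
    expect_equal(m2$lengths, m0$lengths, tolerance = 1e-9)
    expect_equal(m2$dihedral, m0$dihedral, tolerance = 1e-9)
  }
})

test_that("base contacts match brute-force enumeration of water/oxygen pairings", {
  for (nm in c("Benzoic Acid", "2-Bromobenzoic Acid")) {
    b <- build_species("base", nm)
    m <- reaction_center_metrics(b)
    xyz <- b$coordinates
    w_o <- which(b$roles == "water_O")
    w_h <- which(b$roles == "water_H")
    o12 <- c(which(b$roles == "carboxylate_O1"), which(b$roles == "carboxylate_O2"))
    d <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    contact <- function(ow, o) {
      mine <- w_h[vapply(w_h, function(h) d(ow, h) < 1.2, logical(1))]
      min(vapply(mine, function(h) d(h, o), numeric(1)))
    }
    # enumerate both water->oxygen assignments, keep the minimal total
    s1 <- contact(w_o[1], o12[1]) + contact(w_o[2], o12[2])
    s2 <- contact(w_o[1], o12[2]) + contact(w_o[2], o12[1])
    expect_equal(sort(unname(m$lengths)),
                 sort(if (s1 <= s2) c(contact(w_o[1], o12[1]), contact(w_o[2], o12[2]))
                      else c(contact(w_o[1], o12[2]), contact(w_o[2], o12[1]))),
                 tolerance = 1e-12)
  }
})

test_that("metrics demand the water roles", {
  bare <- embed_3d("Benzoic Acid")
  expect_error(reaction_center_metrics(bare), "water_O")
})

test_that("roles are recovered from a label-free geometry", {
  for (kind in c("acid", "base")) {
    cl <- build_species(kind, "Benzoic Acid")
    stripped <- atomic_structure(cl$elements, cl$coordinates, cl$charge,
                                 cl$multiplicity)
    inferred <- infer_roles(stripped)
    expect_equal(inferred$kind, kind)
    expect_equal(sum(inferred$roles == "water_O", na.rm = TRUE), 2L)
    expect_equal(sum(inferred$roles == "water_H", na.rm = TRUE), 4L)
    expect_equal(which(inferred$roles == "carboxyl_C"),
                 which(cl$roles == "carboxyl_C"))
    # metrics computed from inferred roles agree with the labeled original
    expect_equal(reaction_center_metrics(stripped)$lengths,
                 reaction_center_metrics(cl)$lengths, tolerance = 1e-9)
  }
})

test_that("delta-length reports signed differences and flags the 0.25 A envelope", {
  lengths <- data.frame(
    compound = rep("Benzoic Acid", 6),
    functional = rep(c("CAM-B3LYP", "TPSSTPSS"), each = 3),
    label = rep(c("a", "b", "c"), 2),
    length = c(1.80, 1.85, 0.98, 1.85, 2.15, 0.99)
  )
  rep_ <- delta_length(lengths)
  ref_rows <- rep_$functional == "CAM-B3LYP"
  expect_true(all(rep_$delta[ref_rows] == 0))
  expect_equal(rep_$delta[rep_$functional == "TPSSTPSS" & rep_$label == "a"],
               0.05, tolerance = 1e-12)
  expect_equal(rep_$outlier[rep_$functional == "TPSSTPSS"],
               c(FALSE, TRUE, FALSE))
  expect_error(delta_length(lengths[lengths$functional != "CAM-B3LYP", ]),
               "reference functional")
})
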