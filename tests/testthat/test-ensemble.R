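test_that("multi-model PDB files round-trip through read_ensemble", {
  base <- synthetic_ensemble_base(10)
  ens <- perturb_ensemble(base, 0.3, 5, seed = 101)
  path <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, path)
  back <- read_ensemble(path)
  expect_equal(n_models(back), 5L)
  expect_equal(nrow(back$atoms), nrow(ens$atoms))
  expect_equal(model_coords(back, 3), model_coords(ens, 3),
               tolerance = 1e-3)
})

test_that("m6A residues are recognised under their component codes", {
  at <- data.frame(chain = "B", resno = 3L, resname = "6MZ",
                   name = c("N1", "C6", "N6", "C10"))
  ens <- ensemble(matrix(rnorm(12), nrow = 1), at)
  expect_true(all(ens$atoms$resname == "M6A"))
  at$resname <- "6MA"
  ens2 <- ensemble(matrix(rnorm(12), nrow = 1), at)
  expect_true(all(ens2$atoms$resname == "M6A"))
  # and through the PDB reader
  path <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(ensemble(matrix(c(0, 0, 0, 1.4, 0, 0, 2.1, 1.1, 0,
                                       3.5, 1.2, 0), nrow = 1), at), path)
  back <- read_ensemble(path)
  expect_true(all(back$atoms$resname == "M6A"))
})

test_that("models with differing atom counts are rejected", {
  lines <- c("MODEL        1",
             "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
             "ATOM      2  CB  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
             "ENDMDL",
             "MODEL        2",
             "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
             "ENDMDL", "END")
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  expect_error(read_ensemble(path), "atom count")
})

test_that("selections resolve backbone and heavy atom classes", {
  at <- data.frame(chain = c("A", "A", "A", "A", "B", "B"),
                   resno = c(1L, 1L, 1L, 1L, 1L, 1L),
                   resname = c("ALA", "ALA", "ALA", "ALA", "A", "A"),
                   name = c("N", "CA", "CB", "H", "P", "N1"))
  ens <- ensemble(matrix(rnorm(18), nrow = 1), at)
  expect_equal(resolve_selection(ens, atom_selection("A", atom_class = "backbone")),
               c(1L, 2L))
  expect_equal(resolve_selection(ens, atom_selection("B", atom_class = "backbone")),
               5L)
  expect_equal(resolve_selection(ens, atom_selection(atom_class = "heavy")),
               c(1L, 2L, 3L, 5L, 6L))
  expect_error(resolve_selection(ens, atom_selection("C")), "empty")
})

test_that("identical models superpose trivially with zero RMSD", {
  base <- synthetic_ensemble_base(12)
  ens <- ensemble(base$xyz[rep(1, 6), ], base$atoms)
  sup <- superpose(ens, atom_selection(atom_class = "all"))
  st <- rmsd_to_mean(sup, atom_selection(atom_class = "all"))
  expect_equal(st$mean, 0, tolerance = 1e-8)
  expect_equal(model_coords(sup, 1), attr(sup, "mean_xyz"),
               tolerance = 1e-8)
})

test_that("rigid-body copies collapse to zero RMSD after superposition", {
  base <- synthetic_ensemble_base(12)
  ens <- perturb_ensemble(base, 0, 8, rigid = TRUE, seed = 111)
  raw <- rmsd_to_mean(ens, atom_selection(atom_class = "all"))
  expect_gt(raw$mean, 1)           # genuinely scattered before fitting
  sup <- superpose(ens, atom_selection(atom_class = "all"))
  st <- rmsd_to_mean(sup, atom_selection(atom_class = "all"))
  expect_equal(st$mean, 0, tolerance = 1e-6)
})

test_that("superposed pairwise RMSD agrees with the bio3d reference", {
  base <- synthetic_ensemble_base(15)
  ens <- perturb_ensemble(base, 0.4, 2, rigid = TRUE, seed = 112)
  sup <- superpose(ens, atom_selection(atom_class = "all"))
  # for two models each model's deviation from the mean is half the
  # pairwise deviation, so pairwise RMSD = 2 * RMSD-to-mean
  mine <- 2 * rmsd_to_mean(sup, atom_selection(atom_class = "all"))$mean
  ref <- bio3d::rmsd(ens$xyz[1, ], ens$xyz[2, ], fit = TRUE)
  expect_equal(mine, ref, tolerance = 1e-3)
})

test_that("reports are invariant under a global rigid motion of all models", {
  base <- synthetic_ensemble_base(12)
  ens <- perturb_ensemble(base, 0.3, 6, seed = 113)
  sup1 <- superpose(ens, atom_selection(atom_class = "all"))
  r1 <- rmsd_to_mean(sup1, atom_selection(atom_class = "all"))
  # rotate + translate every model identically
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- ens
  moved$xyz <- t(apply(ens$xyz, 1, function(v) {
    co <- matrix(v, ncol = 3, byrow = TRUE)
    as.vector(t(sweep(co %*% R, 2, c(4, -2, 7), "+")))
  }))
  r2 <- rmsd_to_mean(superpose(moved, atom_selection(atom_class = "all")),
                     atom_selection(atom_class = "all"))
  expect_equal(r2$per_model, r1$per_model, tolerance = 1e-6)
})

test_that("degenerate selections and too-small selections are rejected", {
  at <- data.frame(chain = "A", resno = 1:4, resname = "ALA", name = "CA")
  collinear <- cbind(1:4, 0, 0)
  ens <- ensemble(rbind(as.vector(t(collinear)),
                        as.vector(t(collinear + 0.1))), at)
  expect_error(superpose(ens, atom_selection(atom_class = "all")),
               "collinear")
})

test_that("heavy-atom RMSD is at least backbone RMSD on a realistic bundle", {
  base <- synthetic_ensemble_base(20)
  # side-chain-free base: emulate floppier periphery by inflating O atoms
  ens <- perturb_ensemble(base, 0.3, 10, seed = 114)
  o_idx <- which(ens$atoms$name == "O")
  cols <- as.vector(t(outer(o_idx, 1:3, function(i, k) 3 * (i - 1) + k)))
  set.seed(115)
  ens$xyz[, cols] <- ens$xyz[, cols] + rnorm(length(ens$xyz[, cols]), 0, 0.4)
  sup <- superpose(ens, atom_selection(atom_class = "backbone"))
  bb <- rmsd_to_mean(sup, atom_selection(atom_class = "backbone"))
  hv <- rmsd_to_mean(sup, atom_selection(atom_class = "heavy"))
  expect_gte(hv$mean, bb$mean)
})

test_that("restraint categories follow the residue-separation rules", {
  df <- data.frame(chain_a = c("A", "A", "A", "A", "A"),
                   res_a = c(1L, 1L, 1L, 1L, 5L),
                   atom_a = "HA",
                   chain_b = c("A", "A", "A", "A", "B"),
                   res_b = c(1L, 2L, 4L, 7L, 3L),
                   atom_b = "HB", upper = 5)
  counts <- classify_restraints(restraint_set(df))
  expect_equal(counts[["intraresidual"]], 1L)
  expect_equal(counts[["sequential"]], 1L)
  expect_equal(counts[["medium"]], 1L)
  expect_equal(counts[["long"]], 1L)
  expect_equal(counts[["intermolecular"]], 1L)
  expect_equal(counts[["total"]], 5L)
})

test_that("restraint counts partition the input", {
  set.seed(116)
  n <- 300
  df <- data.frame(chain_a = sample(c("A", "B"), n, TRUE),
                   res_a = sample(1:50, n, TRUE), atom_a = "H",
                   chain_b = sample(c("A", "B"), n, TRUE),
                   res_b = sample(1:50, n, TRUE), atom_b = "H",
                   upper = runif(n, 2, 6),
                   hbond = runif(n) < 0.1)
  counts <- classify_restraints(restraint_set(df))
  cats <- c("intraresidual", "sequential", "medium", "long",
            "hydrogen_bond", "intermolecular")
  expect_equal(sum(counts[cats]), n)
  expect_equal(counts[["total"]], n)
  empty <- classify_restraints(restraint_set(df[0, ]))
  expect_true(all(empty == 0L))
})

test_that("CYANA upl files parse with chain ranges and HB flags", {
  path <- tempfile(fileext = ".upl")
  writeLines(c("  1 MET  HA    2 ALA  H     4.50",
               "  3 SER  HB2 157 ADE  H2    5.00",
               " 10 THR  H    40 LEU  HD1   6.00",
               "  5 ALA  H     9 GLY  O     2.20  #HB",
               "# a comment line",
               ""), path)
  rs <- read_upl(path, chains = list(A = c(1, 156), B = c(157, 162)))
  expect_equal(nrow(rs), 4L)
  expect_equal(rs$chain_b, c("A", "B", "A", "A"))
  expect_equal(rs$hbond, c(FALSE, FALSE, FALSE, TRUE))
  counts <- classify_restraints(rs)
  expect_equal(counts[["intermolecular"]], 1L)
  expect_equal(counts[["hydrogen_bond"]], 1L)
  expect_equal(counts[["long"]], 1L)
  expect_equal(counts[["sequential"]], 1L)
  expect_error(read_upl(path, chains = list(A = c(1, 100))), "not covered")
})

test_that("NMR-STAR distance-constraint loops parse", {
  path <- tempfile(fileext = ".str")
  writeLines(c("data_test", "save_constraints", "loop_",
               "_Gen_dist_constraint.ID",
               "_Gen_dist_constraint.Entity_assembly_ID_1",
               "_Gen_dist_constraint.Comp_index_ID_1",
               "_Gen_dist_constraint.Atom_ID_1",
               "_Gen_dist_constraint.Entity_assembly_ID_2",
               "_Gen_dist_constraint.Comp_index_ID_2",
               "_Gen_dist_constraint.Atom_ID_2",
               "_Gen_dist_constraint.Distance_upper_bound_val",
               "1 1 10 HA 1 11 H 4.5",
               "2 1 10 HB 2 3 H2 5.0",
               "stop_", "save_"), path)
  rs <- read_star_restraints(path)
  expect_equal(nrow(rs), 2L)
  counts <- classify_restraints(rs)
  expect_equal(counts[["sequential"]], 1L)
  expect_equal(counts[["intermolecular"]], 1L)
})

test_that("constructed donor-acceptor geometries are detected as H-bonds", {
  # donor N (chain A) with H pointing at acceptor O (chain B) at 2.9 A
  at <- data.frame(chain = c("A", "A", "B"), resno = c(1L, 1L, 1L),
                   resname = c("ASN", "ASN", "A"),
                   name = c("ND2", "HD21", "O2"))
  xyz <- matrix(c(0, 0, 0,  1.0, 0, 0,  2.9, 0, 0), nrow = 1, byrow = TRUE)
  ens <- ensemble(xyz, at)
  rep1 <- find_contacts(ens)
  expect_equal(nrow(rep1$hbonds), 1L)
  expect_equal(rep1$hbonds$distance, 2.9)
  expect_equal(rep1$hbonds$angle, 180)
  # beyond the cutoff: nothing
  far <- ens
  far$xyz[1, 7] <- 6.0
  expect_equal(nrow(find_contacts(far)$hbonds), 0L)
  # bent geometry below the angle cutoff: nothing
  bent <- ens
  bent$xyz[1, 7:9] <- c(1.0, 2.5, 0)   # angle at H is 90 degrees
  expect_equal(nrow(find_contacts(bent)$hbonds), 0L)
})

test_that("hydrogen-free models need the distance-only fallback", {
  at <- data.frame(chain = c("A", "B"), resno = c(1L, 1L),
                   resname = c("THR", "M6A"), name = c("OG1", "N7"))
  ens <- ensemble(matrix(c(0, 0, 0, 3.0, 0, 0), nrow = 1), at)
  expect_error(find_contacts(ens), "no hydrogens")
  rep1 <- find_contacts(ens, fallback_distance_only = TRUE)
  expect_equal(nrow(rep1$hbonds), 2L)   # both atoms can act as donor
  expect_true(all(is.na(rep1$hbonds$angle)))
})

test_that("hydrophobic carbon contacts are reported across chains", {
  at <- data.frame(chain = c("A", "A", "B"), resno = c(442L, 442L, 3L),
                   resname = c("LEU", "LEU", "M6A"),
                   name = c("CD1", "CD2", "C10"))
  xyz <- matrix(c(0, 0, 0,  1.5, 0, 0,  4.0, 0, 0), nrow = 1, byrow = TRUE)
  ens <- ensemble(xyz, at)
  rep1 <- find_contacts(ens, fallback_distance_only = TRUE)
  expect_equal(nrow(rep1$hydrophobic), 2L)
  expect_true(all(rep1$hydrophobic$chain_a != rep1$hydrophobic$chain_b))
  # intra-chain pair CD1-CD2 excluded by interchain_only
  all_pairs <- find_contacts(ens, interchain_only = FALSE,
                             fallback_distance_only = TRUE)
  expect_equal(nrow(all_pairs$hydrophobic), 2L)  # same-residue pair still excluded
})

test_that("contact reports are invariant under a global rigid motion", {
  at <- data.frame(chain = c("A", "A", "B"), resno = c(1L, 1L, 1L),
                   resname = c("ASN", "ASN", "A"),
                   name = c("ND2", "HD21", "O2"))
  xyz <- matrix(c(0, 0, 0, 1.0, 0, 0, 2.9, 0.4, 0.2), nrow = 1)
  ens <- ensemble(xyz, at)
  th <- 1.2
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  co <- model_coords(ens, 1)
  moved <- ensemble(matrix(as.vector(t(sweep(co %*% R, 2, c(3, 1, -2), "+"))),
                           nrow = 1), at)
  a <- find_contacts(ens)$hbonds
  b <- find_contacts(moved)$hbonds
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$distance, b$distance, tolerance = 1e-8)
  expect_equal(a$angle, b$angle, tolerance = 1e-6)
})
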