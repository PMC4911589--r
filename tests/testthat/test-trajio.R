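# Structure/trajectory I/O and the selection grammar.

test_that("a bundle written to PDB re-reads with verbatim residue numbering", {
  bundle <- build_ideal_bundle()
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_structure(bundle$topology, bundle$frame, pdb)
  back <- read_structure(pdb)
  expect_identical(length(unique(back$topology$resid)), 35L)
  expect_identical(min(back$topology$resid), 42L)
  expect_identical(max(back$topology$resid), 76L)
  expect_identical(back$topology$resname, bundle$topology$resname)
  expect_identical(back$topology$name, bundle$topology$name)
  expect_equal(back$frame$xyz, bundle$frame$xyz, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("explicit element columns agree with name-based inference", {
  bundle <- build_ideal_bundle()
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_structure(bundle$topology, bundle$frame, pdb)
  back <- read_structure(pdb)
  expect_identical(toupper(back$topology$element),
                   toupper(infer_element(back$topology$name)))
})

test_that("GRO structures round-trip including the box line", {
  bundle <- build_ideal_bundle()
  fr <- make_frame(bundle$frame$xyz, box = c(8, 8, 6))
  gro <- withr::local_tempfile(fileext = ".gro")
  write_structure(bundle$topology, fr, gro)
  back <- read_structure(gro)
  expect_equal(back$frame$box, c(8, 8, 6), tolerance = 1e-5)
  expect_equal(back$frame$xyz, bundle$frame$xyz, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_identical(back$topology$resid, bundle$topology$resid)
})

test_that("element inference follows the documented two-letter rule", {
  expect_identical(infer_element(c("CA", "CB", "N", "OW", "HW1", "MO",
                                   "CL", "NE1", "CP1")),
                   c("C", "C", "N", "O", "H", "Mo", "Cl", "N", "C"))
})

test_that("trajectories round-trip through multi-model PDB with times", {
  run <- generate_trajectory(small_scenario(seed = 5), small_sheet())
  traj <- run$traj
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, pdb)
  back <- read_trajectory(traj$topology, pdb)
  expect_identical(n_frames(back), n_frames(traj))
  expect_equal(back$times_ps, traj$times_ps, tolerance = 1e-6)
  expect_lt(max(abs(back$frames[[5]] - traj$frames[[5]])), 1e-4 + 1e-12)
})

test_that("re-read trajectories reproduce analysis results (I/O transparency)", {
  run <- generate_trajectory(small_scenario(seed = 6), small_sheet())
  traj <- run$traj
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, pdb)
  back <- read_trajectory(traj$topology, pdb)
  top <- traj$topology
  sc <- select_atoms(top, "protein and sidechain and heavy")
  sh <- select_atoms(top, "sheet")
  for (i in c(1L, 10L, n_frames(traj))) {
    expect_identical(
      heavy_atom_contacts(traj_frame(back, i), sc, sh, rc = 0.6),
      heavy_atom_contacts(traj_frame(traj, i), sc, sh, rc = 0.6))
    expect_equal(helix_ratio(traj_frame(back, i), top, spans = helix_spans()),
                 helix_ratio(traj_frame(traj, i), top, spans = helix_spans()))
  }
  wat <- run$spec$shell_waters$resid[1]
  expect_identical(fss_water_count(traj_frame(back, 21), top, wat),
                   fss_water_count(traj_frame(traj, 21), top, wat))
})

test_that("stride subsets frames and times arithmetically", {
  run <- generate_trajectory(small_scenario(seed = 2), small_sheet())
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(run$traj, pdb)
  s2 <- read_trajectory(run$traj$topology, pdb, stride = 2L)
  expect_identical(n_frames(s2), 11L)
  expect_equal(s2$times_ps, run$traj$times_ps[seq(1, 21, 2)])
  s1 <- read_trajectory(run$traj$topology, pdb, stride = 1L)
  expect_equal(s1$times_ps, run$traj$times_ps)
})

test_that("trajectory loading rejects mismatches, reversed time and XTC", {
  run <- generate_trajectory(small_scenario(seed = 2), small_sheet())
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(run$traj, pdb)
  wrong_top <- topology(c("CA", "CB"), c(1L, 1L), "ALA")
  expect_error(read_trajectory(wrong_top, pdb), "[0-9]+ atoms")
  lines <- readLines(pdb)
  tl <- grep("^REMARK t=", lines)
  lines[tl] <- sprintf("REMARK t= %.6f", rev(run$traj$times_ps))
  rev_pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, rev_pdb)
  expect_error(read_trajectory(run$traj$topology, rev_pdb),
               "increasing")
  expect_error(read_trajectory(run$traj$topology, "traj.xtc"),
               "supported")
})

test_that("selection grammar matches the documented keyword semantics", {
  run <- generate_trajectory(small_scenario(seed = 3), small_sheet())
  top <- run$traj$topology
  h2 <- select_atoms(top, "resid 54-61")
  expect_identical(sort(unique(top$resid[h2])), 54:61)
  expect_length(select_atoms(top, "heavy and not heavy"), 0L)
  expect_identical(select_atoms(top, "protein and sidechain and heavy"),
                   which(top$protein & top$sidechain & top$heavy))
  expect_identical(select_atoms(top, "water or sheet"),
                   which(top$water | top$sheet))
  expect_identical(select_atoms(top, "resname TRP and heavy"),
                   which(top$resname == "TRP" & top$heavy))
  expect_identical(select_atoms(top, "not (protein or water)"),
                   which(!(top$protein | top$water)))
})

test_that("random selections equal a naive per-atom predicate oracle", {
  run <- generate_trajectory(small_scenario(seed = 4), small_sheet())
  top <- run$traj$topology
  flags <- c("protein", "water", "sheet", "heavy", "sidechain", "backbone")
  set.seed(99)
  for (i in 1:25) {
    f1 <- sample(flags, 1); f2 <- sample(flags, 1); f3 <- sample(flags, 1)
    op1 <- sample(c("and", "or"), 1); op2 <- sample(c("and", "or"), 1)
    neg <- sample(c("", "not "), 1)
    expr <- sprintf("%s%s %s (%s %s %s)", neg, f1, op1, f2, op2, f3)
    m1 <- top[[f1]]; m2 <- top[[f2]]; m3 <- top[[f3]]
    # naive predicate oracle with the grammar's precedence (not > and > or)
    inner <- if (op2 == "and") m2 & m3 else m2 | m3
    lhs <- if (neg == "not ") !m1 else m1
    want <- which(if (op1 == "and") lhs & inner else lhs | inner)
    expect_identical(select_atoms(top, expr), want, label = expr)
  }
})

test_that("selection conjunction is monotone and errors carry positions", {
  run <- generate_trajectory(small_scenario(seed = 4), small_sheet())
  top <- run$traj$topology
  base <- select_atoms(top, "protein")
  for (p in c("heavy", "sidechain", "resid 50-60", "resname LEU")) {
    refined <- select_atoms(top, paste("protein and", p))
    expect_true(all(refined %in% base))
  }
  expect_error(select_atoms(top, "protein znd heavy"), "position")
  expect_error(select_atoms(top, "resid abc"), "resid")
  expect_error(select_atoms(top, "(protein"), "')'")
})

test_that("loading is pure: two loads give identical topologies", {
  bundle <- build_ideal_bundle()
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_structure(bundle$topology, bundle$frame, pdb)
  expect_identical(read_structure(pdb), read_structure(pdb))
})
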