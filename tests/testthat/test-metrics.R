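# Structural observables against brute-force oracles and constructed
# boundary cases.

test_that("contact counting respects the cutoff boundary and far fields", {
  top <- topology(c("CA", "CB"), c(1L, 2L), c("ALA", "ALA"))
  near <- make_frame(rbind(c(0, 0, 0), c(0.59, 0, 0)))
  far <- make_frame(rbind(c(0, 0, 0), c(0.61, 0, 0)))
  expect_identical(heavy_atom_contacts(near, 1L, 2L, rc = 0.6), 1L)
  expect_identical(heavy_atom_contacts(far, 1L, 2L, rc = 0.6), 0L)
  shifted <- make_frame(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_identical(heavy_atom_contacts(shifted, 1L, 2L, rc = 0.6), 0L)
  expect_error(heavy_atom_contacts(near, 1:2, 2L), "disjoint")
})

test_that("contact counts equal the exhaustive double loop over 100 seeds", {
  for (seed in 1:100) {
    sys <- random_point_system(seed, n_a = 20, n_b = 25)
    fr <- make_frame(rbind(sys$a, sys$b))
    got <- heavy_atom_contacts(fr, 1:20, 21:45, rc = 0.5)
    want <- brute_contact_count(sys$a, sys$b, 0.5)
    expect_identical(got, as.integer(want))
    got_p <- heavy_atom_contacts(fr, 1:20, 21:45, rc = 0.5, pairs = TRUE)
    expect_identical(got_p, as.integer(brute_contact_count(sys$a, sys$b, 0.5,
                                                           pairs = TRUE)))
  }
})

test_that("contacts are invariant under joint rotation and translation", {
  sys <- random_point_system(7)
  fr <- make_frame(rbind(sys$a, sys$b))
  n0 <- heavy_atom_contacts(fr, 1:25, 26:55, rc = 0.5)
  rot <- nanoadsorb:::rotation_matrix(c(1, 2, 3), 1.1)
  moved <- make_frame(sweep(rbind(sys$a, sys$b) %*% t(rot), 2,
                            c(5, -3, 2), "+"))
  expect_identical(heavy_atom_contacts(moved, 1:25, 26:55, rc = 0.5), n0)
})

test_that("native-contact sets respect separation rules and match a residue-pair scan", {
  # two-residue peptide: minimum separation unreachable
  two <- list(topology = topology(c("CA", "CA"), c(1L, 2L),
                                  c("ALA", "ALA")),
              frame = make_frame(rbind(c(0, 0, 0), c(0.2, 0, 0))))
  expect_identical(nrow(native_contacts(two)), 0L)
  # extended chain: all pairs with sep >= 3 are beyond the cutoff
  ext <- build_ideal_bundle(phi = rep(-120, 35), psi = rep(120, 35))
  expect_identical(nrow(native_contacts(ext)), 0L)
  # ideal bundle against an exhaustive scan
  bundle <- build_ideal_bundle()
  ncs <- native_contacts(bundle, rc = 0.6, min_sep = 3L)
  expect_gt(nrow(ncs), 0L)
  expect_true(all(ncs$j - ncs$i >= 3L))
  top <- bundle$topology; xyz <- bundle$frame$xyz
  resids <- sort(unique(top$resid))
  want <- NULL
  for (i in resids) for (j in resids) {
    if (j - i < 3) next
    dmin <- brute_min_dist(xyz[top$resid == i & top$heavy, , drop = FALSE],
                           xyz[top$resid == j & top$heavy, , drop = FALSE])
    if (dmin <= 0.6) want <- rbind(want, c(i, j))
  }
  expect_equal(as.matrix(ncs[, c("i", "j")]), want, ignore_attr = TRUE)
})

test_that("Q is 1 at the reference, 0 when unfolded, and matches brute recounts", {
  bundle <- build_ideal_bundle()
  ncs <- native_contacts(bundle)
  expect_equal(q_fraction(bundle$frame, bundle$topology, ncs), 1.0)
  # fully extended: every native pair broken
  ext <- build_ideal_bundle(phi = rep(-120, 35), psi = rep(120, 35))
  expect_equal(q_fraction(ext$frame, ext$topology, ncs), 0.0)
  # partial melts against an independent recount
  for (m in c(0.25, 0.5, 0.75)) {
    fr <- melt_residues(bundle$frame, bundle$topology,
                        melt_residues_for_fraction(helix_spans(), m))
    got <- q_fraction(fr, bundle$topology, ncs)
    keep <- 0L
    for (k in seq_len(nrow(ncs))) {
      dmin <- brute_min_dist(
        fr$xyz[bundle$topology$resid == ncs$i[k] & bundle$topology$heavy, ,
               drop = FALSE],
        fr$xyz[bundle$topology$resid == ncs$j[k] & bundle$topology$heavy, ,
               drop = FALSE])
      if (dmin <= 0.6) keep <- keep + 1L
    }
    expect_equal(got, keep / nrow(ncs), tolerance = 1e-12)
  }
  expect_error(q_fraction(bundle$frame, bundle$topology, ncs[0, ]), "empty")
})

test_that("helix ratio is 1 for ideal helices, 0 for strands, 1-m for melts", {
  helix <- build_ideal_bundle(phi = rep(-57, 35), psi = rep(-47, 35))
  expect_equal(helix_ratio(helix$frame, helix$topology), 1.0)
  strand <- build_ideal_bundle(phi = rep(-120, 35), psi = rep(120, 35))
  expect_equal(helix_ratio(strand$frame, strand$topology), 0.0)
  bundle <- build_ideal_bundle()
  spans <- helix_spans()
  denom <- length(unlist(spans))
  for (m in c(0, 0.25, 0.5, 0.75, 1)) {
    melted <- melt_residues_for_fraction(spans, m)
    fr <- melt_residues(bundle$frame, bundle$topology, melted)
    got <- helix_ratio(fr, bundle$topology, spans = spans)
    expect_lte(abs(got - (1 - m)), 1 / denom + 1e-12)
    # exact value from an independent run-scan over programmed states
    span_all <- sort(unlist(spans))
    state <- !(span_all %in% melted)
    helical <- logical(length(span_all))
    i <- 1
    while (i <= length(span_all)) {
      if (!state[i]) { i <- i + 1; next }
      j <- i
      while (j < length(span_all) && state[j + 1] &&
             span_all[j + 1] == span_all[j] + 1) j <- j + 1
      if (j - i + 1 >= 4) helical[i:j] <- TRUE
      i <- j + 1
    }
    expect_equal(got, mean(helical), tolerance = 1e-12)
  }
})

test_that("hydrogen bonds follow the geometric criterion", {
  near <- water_pair_fixture(0.30)
  expect_identical(hbond_count(near$frame, near$topology), 1L)
  far <- water_pair_fixture(0.40)
  expect_identical(hbond_count(far$frame, far$topology), 0L)
  # bent geometry: distance fine, no H within the angle window
  bent <- water_pair_fixture(0.30)
  xyz <- bent$frame$xyz
  xyz[2, ] <- c(0, 0.0957, 0)  # donor H rotated 90 degrees away
  xyz[3, ] <- c(0, -0.0957, 0)
  xyz[5, ] <- c(0.30, 0.0957, 0)
  xyz[6, ] <- c(0.30, -0.0957, 0)
  expect_identical(hbond_count(make_frame(xyz), bent$topology), 0L)
})

test_that("hbond counts equal an exhaustive donor-acceptor scan without hydrogens", {
  set.seed(31)
  for (rep in 1:20) {
    n <- 15
    top <- topology(name = sample(c("N", "O"), n, replace = TRUE),
                    resid = seq_len(n), resname = "ALA")
    xyz <- matrix(runif(n * 3, 0, 1.2), n, 3)
    fr <- make_frame(xyz)
    got <- hbond_count(fr, top)
    want <- 0L
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (j - i <= 1) next  # adjacent residues excluded by the criterion
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= 0.35) want <- want + 1L
    }
    expect_identical(got, want)
  }
})

test_that("salt bridges and cation-pi stacking flip at their cutoffs", {
  sb_near <- salt_bridge_fixture(0.35)
  expect_true(salt_bridge(sb_near$frame, sb_near$topology, 1L, 2L))
  sb_far <- salt_bridge_fixture(0.45)
  expect_false(salt_bridge(sb_far$frame, sb_far$topology, 1L, 2L))
  expect_error(salt_bridge(sb_near$frame, sb_near$topology, 2L, 1L),
               "not basic")
  cp_near <- cation_pi_fixture(0.45)
  expect_true(cation_pi(cp_near$frame, cp_near$topology, 1L, 2L))
  cp_far <- cation_pi_fixture(0.55)
  expect_false(cation_pi(cp_far$frame, cp_far$topology, 1L, 2L))
  expect_error(cation_pi(cp_near$frame, cp_near$topology, 2L, 1L),
               "cation")
  # ring centroid equals the mean of ring atoms (oracle)
  ring_idx <- which(cp_near$topology$resid == 2L &
                      grepl("^C[GDEZ]", cp_near$topology$name))
  centroid <- colMeans(cp_near$frame$xyz[ring_idx, ])
  cz <- which(cp_near$topology$name == "CZ" & cp_near$topology$resid == 1L)
  d <- sqrt(sum((cp_near$frame$xyz[cz, ] - centroid)^2))
  expect_equal(d, 0.45, tolerance = 1e-12)
})

test_that("salt-bridge breakage frame matches a programmed separation", {
  # approach trajectory: carboxylate pulled away linearly; the detector
  # must flip exactly where the programmed distance crosses the cutoff
  dists <- seq(0.25, 0.60, by = 0.05)
  got <- vapply(dists, function(d) {
    fx <- salt_bridge_fixture(d)
    salt_bridge(fx$frame, fx$topology, 1L, 2L)
  }, TRUE)
  expect_identical(got, dists <= 0.4 + 1e-12)
})

test_that("hydrophobic fractions match set-membership recounts", {
  first_contact <- c("Arg-55", "Phe-58", "Asn-60", "Leu-61", "Leu-63",
                     "Trp-64")
  expect_equal(hydrophobic_fraction(first_contact), 200 / 3,
               tolerance = 1e-12)
  expect_identical(round(hydrophobic_fraction(first_contact)), 67)
  expect_equal(hydrophobic_fraction(rep("ASN", 6)), 0)
  set.seed(13)
  hydro <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO")
  all3 <- c("ALA", "ARG", "ASN", "ASP", "GLN", "GLU", "GLY", "HIS", "ILE",
            "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR",
            "VAL")
  for (i in 1:20) {
    res <- sample(all3, sample(3:15, 1), replace = TRUE)
    expect_equal(hydrophobic_fraction(res), 100 * mean(res %in% hydro))
  }
  expect_error(hydrophobic_fraction(c("ALA", "XXX")), "XXX")
})
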