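# Fixtures built in code: random point systems, micro structures with real
# atom names, tiny sheets and fast scenario specs. All randomness is
# seeded by the caller.

# Random two-group point system for pair-metric oracles.
random_point_system <- function(seed, n_a = 25, n_b = 30, spread = 1.5,
                                box = NULL) {
  set.seed(seed)
  list(a = matrix(runif(n_a * 3, 0, spread), n_a, 3),
       b = matrix(runif(n_b * 3, 0, spread), n_b, 3),
       box = box)
}

# Exhaustive double-loop distance oracle (no shared helper).
brute_min_dist <- function(a, b, box = NULL) {
  dmin <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      dv <- a[i, ] - b[j, ]
      if (!is.null(box)) dv <- dv - box * round(dv / box)
      d <- sqrt(sum(dv^2))
      if (d < dmin) dmin <- d
    }
  }
  dmin
}

brute_contact_count <- function(a, b, rc, box = NULL, pairs = FALSE) {
  n <- 0L
  for (i in seq_len(nrow(a))) {
    hit <- 0L
    for (j in seq_len(nrow(b))) {
      dv <- a[i, ] - b[j, ]
      if (!is.null(box)) dv <- dv - box * round(dv / box)
      if (sqrt(sum(dv^2)) <= rc) hit <- hit + 1L
    }
    n <- n + if (pairs) hit else as.integer(hit > 0)
  }
  n
}

# Two water molecules (O + 2 H each) with a given O-O distance; the donor
# H of the first water points straight at the second oxygen.
water_pair_fixture <- function(d_oo) {
  top <- topology(name = c("OW", "HW1", "HW2", "OW", "HW1", "HW2"),
                  resid = c(1L, 1L, 1L, 2L, 2L, 2L),
                  resname = "SOL")
  xyz <- rbind(c(0, 0, 0), c(0.0957, 0, 0), c(-0.024, 0.0927, 0),
               c(d_oo, 0, 0), c(d_oo + 0.024, 0.0927, 0),
               c(d_oo + 0.024, -0.0927, 0))
  list(topology = top, frame = make_frame(xyz))
}

# Arg/Asp pair with real charged-group atom names at a controlled minimum
# N-O distance.
salt_bridge_fixture <- function(d_no) {
  top <- topology(name = c("N", "CA", "C", "O", "NE", "NH1", "NH2",
                           "N", "CA", "C", "O", "OD1", "OD2"),
                  resid = c(rep(1L, 7), rep(2L, 6)),
                  resname = c(rep("ARG", 7), rep("ASP", 6)))
  xyz <- rbind(
    c(-0.5, 0, 1), c(-0.35, 0, 1), c(-0.2, 0, 1), c(-0.2, 0.12, 1),
    c(0, 0, 0), c(-0.11, 0.05, 0), c(-0.11, -0.05, 0),      # guanidinium N
    c(2, 0, 1), c(2.15, 0, 1), c(2.3, 0, 1), c(2.3, 0.12, 1),
    c(d_no, 0, 0), c(d_no + 0.22, 0, 0))  # nearest O exactly d_no from NE
  list(topology = top, frame = make_frame(xyz))
}

# Arg guanidinium carbon at a controlled distance from a Phe ring centroid.
cation_pi_fixture <- function(d) {
  ring <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  ring_xyz <- cbind(0.14 * cos(ang), 0.14 * sin(ang), 0)
  top <- topology(name = c("N", "CA", "C", "O", "CZ",
                           "N", "CA", "C", "O", ring),
                  resid = c(rep(1L, 5), rep(2L, 10)),
                  resname = c(rep("ARG", 5), rep("PHE", 10)))
  xyz <- rbind(c(1, 0, 2), c(1.15, 0, 2), c(1.3, 0, 2), c(1.3, 0.12, 2),
               c(0, 0, d),
               c(1, 1, 2), c(1.15, 1, 2), c(1.3, 1, 2), c(1.3, 1.12, 2),
               ring_xyz)
  list(topology = top, frame = make_frame(xyz))
}

# Small fast scenario for pipeline-level tests.
small_scenario <- function(seed = 1L, ...) {
  scenario_spec(n_frames = 21L, dt_ps = 500,
                onsets_ns = c("60" = 1, "55" = 3, "47" = 5, "64" = 7),
                melt_ns = c(helix2 = 4, helix3 = 8),
                shell_waters = data.frame(resid = c(64L, 55L),
                                          count = c(8L, 8L), radius = 0.42,
                                          count_final = c(3L, 5L),
                                          dewet_ns = c(8, 7)),
                seed = seed, ...)
}

small_sheet <- function() {
  build_monolayer(lattice_spec(nx = 21L, ny = 12L))
}

# Random scenario on a fixed grid for ground-truth recovery sweeps.
random_scenario <- function(seed) {
  set.seed(seed)
  resids <- 42:76
  seq3 <- as_residue_codes(hp35_sequence())
  eligible <- resids[seq3 != "GLY"]
  n_on <- sample(3:6, 1)
  onset_res <- sort(sample(eligible, n_on))
  times <- (0:20) * 0.5  # 21 frames at 500 ps
  onsets <- stats::setNames(sample(times[2:18], n_on, replace = TRUE),
                            onset_res)
  helices <- c("helix1", "helix2", "helix3")
  n_melt <- sample(0:3, 1)
  melt <- if (n_melt > 0) {
    stats::setNames(sample(times[4:19], n_melt), sample(helices, n_melt))
  } else numeric(0)
  wat_res <- sample(setdiff(eligible, NULL), 2)
  shell <- data.frame(resid = wat_res, count = sample(4:10, 2),
                      radius = 0.42,
                      count_final = sample(1:3, 2),
                      dewet_ns = sample(times[10:19], 2))
  scenario_spec(n_frames = 21L, dt_ps = 500, onsets_ns = onsets,
                melt_ns = melt, shell_waters = shell, seed = seed)
}
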