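# Hydration-shell counting, dewetting-slab counting, and adsorption
# kinetics.

# Residue with a sidechain plus a field of water oxygens at given positions.
waters_fixture <- function(water_xyz) {
  nw <- nrow(water_xyz)
  top <- topology(name = c("N", "CA", "C", "O", "CB", "CP1",
                           rep("OW", nw)),
                  resid = c(rep(5L, 6), 100L + seq_len(nw)),
                  resname = c(rep("LEU", 6), rep("SOL", nw)))
  xyz <- rbind(c(0, 0, 0.1), c(0.15, 0, 0.1), c(0.3, 0, 0.1),
               c(0.3, 0.12, 0.1), c(0.15, 0.15, 0.1), c(0.15, 0.28, 0.1),
               water_xyz)
  list(topology = top, frame = make_frame(xyz))
}

test_that("FSS counts partition by the cutoff and handle empty systems", {
  none <- waters_fixture(matrix(numeric(0), 0, 3))
  expect_identical(fss_water_count(none$frame, none$topology, 5L), 0L)
  # 3 waters at 0.3 nm from the sidechain, 2 at 0.6 nm
  cb <- c(0.15, 0.15, 0.1)
  w <- rbind(cb + c(0.3, 0, 0), cb + c(0, 0.3, 0), cb + c(0, 0, 0.3),
             cb + c(0.6, 0, 0), cb + c(0, 0, 0.6))
  fx <- waters_fixture(w)
  expect_identical(fss_water_count(fx$frame, fx$topology, 5L,
                                   rc_fss = 0.45), 3L)
})

test_that("glycine sidechains are rejected with a helpful message", {
  top <- topology(c("N", "CA", "C", "O", "OW"), c(1L, 1L, 1L, 1L, 9L),
                  c(rep("GLY", 4), "SOL"))
  fr <- make_frame(matrix(runif(15), 5, 3))
  expect_error(fss_water_count(fr, top, 1L), "all")
  expect_identical(fss_water_count(fr, top, 1L, rc_fss = 10, part = "all"),
                   1L)
})

test_that("FSS counts equal an exhaustive scan and grow with the cutoff", {
  set.seed(21)
  for (rep in 1:100) {
    w <- matrix(runif(3 * 25, -0.8, 1.2), 25, 3)
    fx <- waters_fixture(w)
    sc <- which(fx$topology$resid == 5L & fx$topology$sidechain)
    for (rc in c(0.3, 0.45)) {
      got <- fss_water_count(fx$frame, fx$topology, 5L, rc_fss = rc)
      want <- 0L
      for (i in seq_len(nrow(w))) {
        dmin <- Inf
        for (j in sc) {
          d <- sqrt(sum((w[i, ] - fx$frame$xyz[j, ])^2))
          dmin <- min(dmin, d)
        }
        if (dmin <= rc) want <- want + 1L
      }
      expect_identical(got, want)
    }
    # monotone in the shell radius
    counts <- vapply(c(0.3, 0.4, 0.5, 0.7),
                     function(rc) fss_water_count(fx$frame, fx$topology, 5L,
                                                  rc_fss = rc), 1L)
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("interfacial slab counts match a point-in-prism oracle", {
  # residue hovering 1 nm above a plane at z = 0
  top <- topology(name = c("N", "CA", "C", "O", "CB", rep("OW", 10)),
                  resid = c(rep(7L, 5), 200L + 1:10),
                  resname = c(rep("TRP", 5), rep("SOL", 10)))
  res_xyz <- rbind(c(1, 1, 1.0), c(1.15, 1, 1.05), c(1.3, 1, 1.0),
                   c(1.3, 1.12, 1.1), c(1.15, 1.15, 1.02))
  set.seed(3)
  inside <- cbind(runif(5, 0.8, 1.5), runif(5, 0.8, 1.35),
                  runif(5, 0.1, 0.9))
  outside <- rbind(cbind(runif(3, 3, 4), runif(3, 3, 4), runif(3, 0.1, 0.9)),
                   cbind(runif(2, 0.8, 1.5), runif(2, 0.8, 1.35),
                         runif(2, 1.5, 2)))
  fr <- make_frame(rbind(res_xyz, inside, outside))
  got <- interfacial_water_count(fr, top, 7L, sheet_top_z = 0, pad_xy = 0.3)
  expect_identical(got, 5L)
  # brute-force region test
  xr <- range(res_xyz[, 1]) + c(-0.3, 0.3)
  yr <- range(res_xyz[, 2]) + c(-0.3, 0.3)
  zl <- min(res_xyz[, 3])
  w <- rbind(inside, outside)
  want <- sum(w[, 1] >= xr[1] & w[, 1] <= xr[2] &
                w[, 2] >= yr[1] & w[, 2] <= yr[2] &
                w[, 3] > 0 & w[, 3] < zl)
  expect_identical(got, as.integer(want))
  # no waters in the slab
  empty <- make_frame(rbind(res_xyz, outside + 10))
  top2 <- topology(name = c("N", "CA", "C", "O", "CB", rep("OW", 5)),
                   resid = c(rep(7L, 5), 200L + 1:5),
                   resname = c(rep("TRP", 5), rep("SOL", 5)))
  expect_identical(interfacial_water_count(empty, top2, 7L, 0), 0L)
  # residue below the plane is a geometry violation
  expect_error(interfacial_water_count(fr, top, 7L, sheet_top_z = 2),
               "below")
})

test_that("first persistent contact times follow the definition", {
  t <- 0:9 / 2
  expect_true(is.na(first_contact_time(t, rep(0L, 10),
                                       persistence_k = 1)$onset_ns))
  s <- c(0, 0, 1, 1, 1, 1, 1, 0, 0, 0)
  expect_equal(first_contact_time(t, s, persistence_k = 5)$onset_ns, t[3])
  expect_equal(first_contact_time(t, s, persistence_k = 1)$onset_ns, t[3])
  # a grazing single-frame contact is ignored for k > 1
  g <- c(0, 1, 0, 0, 1, 1, 1, 1, 1, 1)
  expect_equal(first_contact_time(t, g, persistence_k = 1)$onset_ns, t[2])
  expect_equal(first_contact_time(t, g, persistence_k = 3)$onset_ns, t[5])
  expect_error(first_contact_time(numeric(0), numeric(0)), "empty")
})

test_that("onsets are monotone non-decreasing in the persistence requirement", {
  set.seed(44)
  t <- 0:29
  for (rep in 1:30) {
    s <- rbinom(30, 3, 0.3)
    onsets <- vapply(1:6, function(k) {
      first_contact_time(t, s, persistence_k = k)$onset_ns
    }, numeric(1))
    known <- !is.na(onsets)
    # once lost, never regained; while present, never earlier
    expect_true(all(diff(onsets[known]) >= 0))
    if (any(!known)) expect_true(all(which(!known) > max(which(known), 0)))
  }
})

test_that("anchoring order sorts helices by earliest onset with tie rules", {
  spans <- helix_spans()
  onsets <- data.frame(resid = c(45, 55, 60, 65),
                       onset_ns = c(7, 2, 3, 9))
  ord <- anchoring_order(onsets, spans)
  expect_identical(ord$helix, c(2L, 1L, 3L))
  # single contacting helix: the rest come last with NA
  single <- data.frame(resid = 57, onset_ns = 4)
  ord1 <- anchoring_order(single, spans)
  expect_identical(ord1$helix[1], 2L)
  expect_true(all(is.na(ord1$onset_ns[2:3])))
  # all tied: helix index breaks the tie
  tied <- data.frame(resid = c(45, 55, 65), onset_ns = c(1, 1, 1))
  expect_identical(anchoring_order(tied, spans)$helix, c(1L, 2L, 3L))
  none <- data.frame(resid = 45, onset_ns = NA_real_)
  expect_error(anchoring_order(none, spans), "onset")
})

test_that("adsorption-denaturation correlation matches the two-pass formula", {
  t <- 1:50
  contacts <- cumsum(rbinom(50, 2, 0.4))
  q <- 1 - 0.002 * contacts
  expect_equal(adsorption_denaturation_correlation(t, contacts, q = q), 1.0,
               tolerance = 1e-12)
  set.seed(17)
  for (rep in 1:20) {
    c2 <- rnorm(50)
    q2 <- rnorm(50)
    got <- adsorption_denaturation_correlation(t, c2, q = q2)
    loss <- 1 - q2
    want <- sum((c2 - mean(c2)) * (loss - mean(loss))) /
      sqrt(sum((c2 - mean(c2))^2) * sum((loss - mean(loss))^2))
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_warning(
    expect_true(is.na(adsorption_denaturation_correlation(t, rep(2, 50),
                                                          q = q))),
    "constant")
})
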