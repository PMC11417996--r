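# RDFs, coordination integrals, angular joint distribution, H-bonds.

test_that("the ideal-gas RDF is flat at 1 within Poisson shell noise", {
  tr <- make_ideal_gas(800, 30, n_frames = 4, seed = 7)
  rdf <- compute_rdf(tr, "IG", "IG", dr = 0.1, r_max = 10)
  sel <- rdf$r > 1
  expect_lt(abs(mean(rdf$g[sel]) - 1), 0.02)
  ## per-bin deviation consistent with Poisson counts: 4 sigma band
  rho <- 800 / 30^3
  expected_counts <- rdf$n_frames * rdf$n_a * rho *
    (4 / 3) * pi * ((rdf$r + 0.05)^3 - (rdf$r - 0.05)^3)
  z <- (rdf$counts[sel] - expected_counts[sel]) / sqrt(expected_counts[sel])
  expect_lt(max(abs(z)), 4.5)
})

test_that("two fixed particles give a single occupied bin at their separation", {
  box <- c(50, 50, 50)
  cfg <- md_config(box, rbind(c(10, 10, 10), c(10, 10, 13.27)),
                   c("A", "B"), c("A", "B"), 1:2, c("A", "B"))
  rdf <- compute_rdf(cfg, "A", "B", dr = 0.1, r_max = 20)
  occ <- which(rdf$counts > 0)
  expect_length(occ, 1L)
  expect_lt(abs(rdf$r[occ] - 3.27), 0.1)
})

test_that("coordination of g = 1 matches the analytic sphere to < 0.1%", {
  rho <- 0.0321
  r <- seq(0.01, 9.99, by = 0.02)
  rdf <- structure(list(r = r, g = rep(1, length(r)), rho = rho,
                        counts = rep(1, length(r)), n_frames = 1, n_a = 1,
                        dr = 0.02, sel_a = "g1", sel_b = "g1"), class = "rdf")
  for (a in c(2.5, 4.0, 6.0)) {
    expect_lt(abs(coordination_number(rdf, a) / ((4 / 3) * pi * a^3 * rho) - 1), 1e-3)
  }
  ## zero density -> zero coordination
  expect_equal(coordination_number(rdf, 4, rho = 0), 0)
  expect_error(coordination_number(rdf, 11), "beyond")
})

test_that("delta-shell fixtures recover k: histogram mass exactly, integral to quadrature", {
  for (k in c(4, 5.5)) {
    ds <- make_delta_shell(k, a = 2.8, n_centers = 64, seed = 2)
    rdf <- compute_rdf(ds, "C", "S", dr = 0.05, r_max = 6)
    ## pair-count oracle: brute-force count inside the shell / center
    f <- ds$frames[[1]]
    cnt <- brute_pair_count(f$xyz, f$box, which(f$type == "C"),
                            which(f$type == "S"), 4.0)
    expect_equal(cnt / 64, k)
    ## histogram mass inside r_min equals k per center exactly
    expect_equal(sum(rdf$counts[rdf$r < 4.0]) / 64, k)
    ## coordination integral agrees to quadrature accuracy
    expect_lt(abs(coordination_number(rdf, 4.0) - k), 5e-3)
    ## integrating below the shell radius gives zero
    expect_equal(coordination_number(rdf, 2.0), 0)
  }
})

test_that("auto-detected first minimum feeds the coordination wrappers", {
  ## shell of water oxygens around each hydroxide: HN = shell occupancy
  set.seed(31)
  oh <- hydroxide_template()
  n_oh <- 8; k <- 6
  spacing <- 18; side <- 2
  xyz <- NULL; site <- type <- mol_name <- character(0); mol_id <- integer(0)
  mol <- 0L
  for (i in seq_len(n_oh)) {
    cen <- ((c(i %% side, (i %/% side) %% side, i %/% side^2)) + 0.5) * spacing
    mol <- mol + 1L
    xyz <- rbind(xyz, place_template(oh, cen))
    site <- c(site, oh$sites$site); type <- c(type, oh$sites$type)
    mol_id <- c(mol_id, rep(mol, 2)); mol_name <- c(mol_name, rep("OHX", 2))
    u <- matrix(rnorm(3 * k), ncol = 3); u <- u / sqrt(rowSums(u^2))
    ## waters at radii spread over a narrow first shell
    rad <- 2.8 + runif(k, -0.15, 0.15)
    for (w in seq_len(k)) {
      mol <- mol + 1L
      xyz <- rbind(xyz, cen + u[w, ] * rad[w])
      site <- c(site, "OW"); type <- c(type, "O_w")
      mol_id <- c(mol_id, mol); mol_name <- c(mol_name, "SOL")
    }
  }
  box <- rep(side * spacing, 3)  # 8 cells of an 2x2x2 arrangement
  cfg <- md_config(box, xyz, site, type, mol_id, mol_name)
  tr <- md_traj(list(cfg))
  hn <- hydration_number(tr, dr = 0.05, r_max = 8)
  expect_equal(as.numeric(hn), k, tolerance = 0.02)
  expect_gt(attr(hn, "r_min"), 2.95)
  ## no hydroxide-hydroxide contacts: CIP_OH with explicit r_min is zero
  expect_equal(as.numeric(cip_oh(tr, r_min = 5, dr = 0.05, r_max = 8)), 0)
})

test_that("a single contact ion pair inside r_min gives CIP = 1", {
  ## one Na+ at contact with one hydroxide in a large cell
  oh <- hydroxide_template()
  xyz <- rbind(place_template(oh, c(20, 20, 20)), c(20, 20, 17.6))
  cfg <- md_config(c(40, 40, 40), xyz, c("O1", "H1", "NA"),
                   c("O_oh", "H_oh", "Na"), c(1L, 1L, 2L), c("OHX", "OHX", "NA"))
  val <- cip_pm(md_traj(list(cfg)), "NaOH", r_min = 3.5, dr = 0.05, r_max = 10)
  expect_equal(as.numeric(val), 1, tolerance = 1e-3)  # quadrature on a sharp peak
})

test_that("angular joint distribution places collinear and perpendicular waters correctly", {
  oh <- hydroxide_template()  # O at origin-offset, H along +z
  base <- c(10, 10, 10)
  mk <- function(wpos) {
    xyz <- rbind(place_template(oh, base), wpos)
    md_config(c(20, 20, 20), xyz, c("O1", "H1", "OW"), c("O_oh", "H_oh", "O_w"),
              c(1L, 1L, 2L), c("OHX", "OHX", "SOL"))
  }
  ## along the O-H axis: theta = 0
  aj0 <- angular_joint(md_traj(list(mk(base + c(0, 0, 3)))), r_max = 4, theta_bins = 36)
  idx <- which(aj0$p > 0, arr.ind = TRUE)
  expect_equal(sum(aj0$p), 1)
  expect_lt(aj0$theta[idx[1, 2]], 5)
  ## perpendicular at the oxygen: theta = 90
  aj90 <- angular_joint(md_traj(list(mk(base + c(3, 0, 0)))), r_max = 4, theta_bins = 36)
  idx90 <- which(aj90$p > 0, arr.ind = TRUE)
  ## 90 deg sits on a bin edge; either adjacent bin center is correct
  expect_lte(abs(aj90$theta[idx90[1, 2]] - 90), 2.5)
})

test_that("an isotropic shell has a sin(theta) marginal (solid-angle oracle)", {
  oh <- hydroxide_template()
  set.seed(42)
  nw <- 4000
  u <- matrix(rnorm(3 * nw), ncol = 3); u <- u / sqrt(rowSums(u^2))
  cen <- c(50, 50, 50)
  xyz <- rbind(place_template(oh, cen), sweep(u * 2.8, 2, cen, `+`))
  cfg <- md_config(c(100, 100, 100), xyz, c("O1", "H1", rep("OW", nw)),
                   c("O_oh", "H_oh", rep("O_w", nw)),
                   c(1L, 1L, seq_len(nw) + 1L), c("OHX", "OHX", rep("SOL", nw)))
  aj <- angular_joint(md_traj(list(cfg)), r_max = 4, theta_bins = 18)
  marg <- colSums(aj$p)
  edges <- seq(0, pi, length.out = 19)
  expected <- diff(-cos(edges)) / 2   # solid-angle fraction per theta bin
  expect_lt(max(abs(marg - expected)), 4 * sqrt(max(expected) / nw))
})

test_that("H-bond counting matches the brute-force geometric check in both conventions", {
  dg <- make_dimer_grid()
  for (conv in c("HOO", "OHO")) {
    hb <- count_hbonds(dg$config, r_cut = 3.5, angle_cut = 30, convention = conv)
    expect_identical(hb$n_hbonds,
                     brute_hbond_count(dg$config, 3.5, 30, conv))
  }
  ## analytic check against the construction table (HOO convention)
  hb <- count_hbonds(dg$config, r_cut = 3.5, angle_cut = 30)
  expect_identical(hb$n_hbonds, sum(dg$geometry$r <= 3.5 & dg$geometry$ang <= 30))
  ## distance cut: a linear dimer at 2.8 A binds, at 3.6 A it does not
  lin28 <- make_dimer_grid(distances = 2.8, angles = 0.0)
  expect_identical(count_hbonds(lin28$config, 3.5, 30)$n_hbonds, 1L)
  lin36 <- make_dimer_grid(distances = 3.6, angles = 0.0)
  expect_identical(count_hbonds(lin36$config, 3.5, 30)$n_hbonds, 0L)
  ## strong/weak split by the secondary distance threshold
  two <- make_dimer_grid(distances = c(2.8, 3.2), angles = 0.0)
  cls <- count_hbonds(two$config, 3.5, 30, strong_cut = 3.0)$bonds$class
  expect_setequal(cls, c("strong", "weak"))
})

test_that("structural estimators are invariant under rigid translation", {
  ## shell radius mid-bin (2.815 with dr = 0.05), so translation round-off
  ## cannot push distances across a bin edge
  ds <- make_delta_shell(4, a = 2.815, n_centers = 27, seed = 5)
  f <- ds$frames[[1]]
  f2 <- f; f2$xyz <- sweep(f2$xyz, 2, c(3.1, -4.2, 7.7), `+`)
  f2 <- wrap_config(f2)
  r1 <- compute_rdf(md_traj(list(f)), "C", "S", dr = 0.05, r_max = 6)
  r2 <- compute_rdf(md_traj(list(f2)), "C", "S", dr = 0.05, r_max = 6)
  expect_equal(r1$g, r2$g, tolerance = 1e-12)
})

test_that("empty selections are rejected by name", {
  tr <- make_ideal_gas(50, 20, seed = 1)
  expect_error(compute_rdf(tr, "nope", "IG", dr = 0.1, r_max = 8), "nope")
})
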