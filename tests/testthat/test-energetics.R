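# Pair-potential evaluation: analytic pair values, brute-force periodic
# oracles, finite-difference forces, Ewald correctness and invariances.

test_that("pair energy reproduces the analytic LJ landmarks and Coulomb law", {
  reg <- lj_only_registry(sigma = 3, eps_K = 50)
  ## LJ zero at r = sigma, minimum -eps at r = 2^(1/6) sigma
  expect_equal(pair_energy(reg, "X", "X", 3), 0, tolerance = 1e-12)
  eps_kJ <- 50 * hx_constants()$kB_kJmol
  expect_equal(pair_energy(reg, "X", "X", 2^(1 / 6) * 3), -eps_kJ, tolerance = 1e-12)
  ## two unit charges at 1 A: the Coulomb prefactor itself
  regq <- load_parameter_set(list(atom_types = list(
    Q = list(charge = 1, sigma = 1, epsilon_over_kB = 0, mass = 1))))
  ke_oracle <- (1.602176634e-19)^2 * 6.02214076e23 * 1e10 /
    (4 * pi * 8.8541878128e-12) / 1000
  expect_equal(pair_energy(regq, "Q", "Q", 1), ke_oracle, tolerance = 1e-12)
  expect_error(pair_energy(reg, "X", "X", 0), "> 0")
  expect_error(pair_energy(reg, "X", "Zz", 3), "Zz")
})

test_that("an isolated dimer matches pair_energy and a lone molecule has zero energy", {
  reg <- lj_only_registry()
  box <- c(60, 60, 60)
  mk <- function(xyz, nmol) md_config(box, xyz, rep("X", nrow(xyz)), rep("X", nrow(xyz)),
                                      nmol, rep("X", nrow(xyz)))
  dimer <- mk(rbind(c(10, 10, 10), c(13.2, 10, 10)), c(1L, 2L))
  e <- total_energy(dimer, reg, cutoff = 12, electrostatics = "cutoff",
                    tail_correction = FALSE)
  expect_equal(e$total, pair_energy(reg, "X", "X", 3.2), tolerance = 1e-12)
  ## intramolecular pairs carry no energy at all
  mono <- mk(rbind(c(10, 10, 10), c(13.2, 10, 10)), c(1L, 1L))
  expect_equal(total_energy(mono, reg, cutoff = 12, electrostatics = "cutoff",
                            tail_correction = FALSE)$total, 0)
})

test_that("minimum-image LJ sum plus tail equals the brute-force image sum", {
  set.seed(11)
  n <- 30
  box <- c(14, 12, 10)
  xyz <- cbind(runif(n) * box[1], runif(n) * box[2], runif(n) * box[3])
  reg <- lj_only_registry(sigma = 3, eps_K = 50)
  cfg <- md_config(box, xyz, rep("X", n), rep("X", n), seq_len(n), rep("X", n))
  e <- total_energy(cfg, reg, cutoff = 4.9, electrostatics = "cutoff")
  eb <- brute_lj_images(xyz, box, 3, 50 * hx_constants()$kB_kJmol, 1.5 * min(box))
  expect_lt(abs(e$total - eb), abs(e$lj_tail))
  expect_equal(e$total, e$lj + e$coulomb_real + e$coulomb_recip + e$lj_tail)
})

test_that("Ewald electrostatics reproduce the rocksalt Madelung constant", {
  rs <- rocksalt_config(n_cells = 4, a = 2)
  e <- total_energy(rs$config, rs$registry, cutoff = 4 * rs$a / 2 * 0.999,
                    electrostatics = "ewald")
  M <- -e$total / nrow(rs$config$xyz) * rs$a / hx_constants()$ke_kJmolA
  expect_equal(M, 1.747565 / 2, tolerance = 1e-5)
})

test_that("the Ewald total is flat over a range of splitting parameters", {
  cfg <- small_solution_box()
  reg <- default_parameter_set()
  rc <- min(cfg$box) / 2 * 0.99
  ## plateau over alpha*rc in [3.3, 4.5] (below 3.2 the real-space
  ## truncation erfc(alpha rc) is no longer negligible)
  es <- vapply(c(3.3, 3.6, 4.0, 4.5) / rc, function(al)
    total_energy(cfg, reg, cutoff = rc, electrostatics = "ewald", alpha = al)$total, 0)
  expect_lt(max(es) - min(es), 0.01)
})

test_that("forces are the analytic gradient (central-difference oracle)", {
  cfg <- small_solution_box()
  reg <- default_parameter_set()
  rc <- min(cfg$box) / 2 * 0.99
  h <- 1e-5
  for (mode in c("cutoff", "ewald")) {
    F <- forces(cfg, reg, cutoff = rc, electrostatics = mode)
    ## net force vanishes
    expect_lt(max(abs(colSums(F))), 1e-8)
    errs <- c()
    for (i in c(1L, 17L, 40L, 75L)) for (d in 1:3) {
      cp <- cfg; cp$xyz[i, d] <- cp$xyz[i, d] + h
      cm <- cfg; cm$xyz[i, d] <- cm$xyz[i, d] - h
      fd <- -(total_energy(cp, reg, rc, mode, tail_correction = FALSE)$total -
              total_energy(cm, reg, rc, mode, tail_correction = FALSE)$total) / (2 * h)
      errs <- c(errs, abs(fd - F[i, d]) / max(abs(fd), 1e-8))
    }
    expect_lt(max(errs), 1e-6)
  }
})

test_that("symmetric dimers feel equal and opposite forces; isolated molecules none", {
  reg <- lj_only_registry()
  box <- c(60, 60, 60)
  dimer <- md_config(box, rbind(c(10, 10, 10), c(13.2, 10, 10)),
                     c("X", "X"), c("X", "X"), c(1L, 2L), c("X", "X"))
  F <- forces(dimer, reg, cutoff = 12, electrostatics = "cutoff")
  expect_equal(F[1, ], -F[2, ], tolerance = 1e-12)
  mono <- md_config(box, rbind(c(10, 10, 10), c(13.2, 10, 10)),
                    c("X", "X"), c("X", "X"), c(1L, 1L), c("X", "X"))
  expect_equal(max(abs(forces(mono, reg, cutoff = 12, electrostatics = "cutoff"))), 0)
})

test_that("energy is invariant under rigid translation and molecule relabeling", {
  cfg <- small_solution_box()
  reg <- default_parameter_set()
  rc <- min(cfg$box) / 2 * 0.99
  e1 <- total_energy(cfg, reg, rc)$total
  sh <- cfg; sh$xyz <- sweep(sh$xyz, 2, c(1.3, -2.1, 0.7), `+`)
  e2 <- total_energy(wrap_config(sh), reg, rc)$total
  expect_equal(e2, e1, tolerance = 1e-10)

  ## swap the two first water molecules (identical species)
  i1 <- which(cfg$mol_id == 1L); i2 <- which(cfg$mol_id == 2L)
  sw <- cfg
  sw$xyz[c(i1, i2), ] <- cfg$xyz[c(i2, i1), ]
  e3 <- total_energy(sw, reg, rc)$total
  expect_equal(e3, e1, tolerance = 1e-10)
})

test_that("an oversized cutoff is rejected", {
  cfg <- small_solution_box()
  expect_error(total_energy(cfg, default_parameter_set(), cutoff = min(cfg$box)),
               "half the shortest box edge")
})
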