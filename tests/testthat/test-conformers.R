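test_that("freely jointed chains satisfy <L^2> = N_bonds * b^2", {
  chains <- generate_chain(101, count = 10000, seed = 5)
  L2 <- vapply(chains, function(cf) sum((cf$xyz[101, ] - cf$xyz[1, ])^2),
               numeric(1))
  expect_equal(length(chains), 10000)
  mc_se <- sd(L2) / sqrt(length(L2))
  expect_lt(abs(mean(L2) - 100 * 3.8^2), 3 * mc_se)
  # every bond has the configured length
  b <- sqrt(rowSums(diff(chains[[1]]$xyz)^2))
  expect_equal(b, rep(3.8, 100), tolerance = 1e-9)
})

test_that("FJC RMS Rg approaches the Gaussian closed form b*sqrt(N_bonds/6)", {
  chains <- generate_chain(500, count = 10000, seed = 6)
  rgs <- vapply(chains, conformer_rg, numeric(1))
  closed <- 3.8 * sqrt(499 / 6)
  expect_equal(sqrt(mean(rgs^2)), closed, tolerance = 0.02)
})

test_that("chain generation is deterministic under a fixed seed", {
  a <- generate_chain(80, 3, seed = 123)
  b <- generate_chain(80, 3, seed = 123)
  expect_identical(lapply(a, `[[`, "xyz"), lapply(b, `[[`, "xyz"))
  g1 <- generate_globule(60, 21, seed = 9)
  g2 <- generate_globule(60, 21, seed = 9)
  expect_identical(g1$xyz, g2$xyz)
  s1 <- generate_chain(60, 2, excluded_radius = 1.9, seed = 4)
  s2 <- generate_chain(60, 2, excluded_radius = 1.9, seed = 4)
  expect_identical(lapply(s1, `[[`, "xyz"), lapply(s2, `[[`, "xyz"))
})

test_that("self-avoiding chains respect the hard-sphere constraint and swell", {
  rex <- 1.9
  chains <- generate_chain(100, 5, excluded_radius = rex, seed = 31)
  for (cf in chains) {
    d <- as.matrix(dist(cf$xyz))
    nonbonded <- abs(row(d) - col(d)) > 1
    expect_gte(min(d[nonbonded]), 2 * rex - 1e-9)
  }
  # paired-seed comparison: excluded volume strictly expands the ensemble
  fjc <- generate_chain(200, 40, seed = 77)
  saw <- generate_chain(200, 40, excluded_radius = rex, seed = 77)
  expect_gt(mean(vapply(saw, conformer_rg, numeric(1))),
            mean(vapply(fjc, conformer_rg, numeric(1))))
})

test_that("self-avoiding ensembles scale with a Flory-type exponent", {
  ns <- c(50, 100, 200, 400)
  mean_rg <- vapply(ns, function(n) {
    chains <- generate_chain(n, 50, excluded_radius = 1.9, seed = 40 + n)
    mean(vapply(chains, conformer_rg, numeric(1)))
  }, numeric(1))
  nu <- coef(lm(log(mean_rg) ~ log(ns)))[[2]]
  expect_gt(nu, 0.56)
  expect_lt(nu, 0.64)
})

test_that("globule mimics hit the target Rg and the uniform-ball limit", {
  g <- generate_globule(400, 21.1, seed = 8)
  expect_equal(conformer_rg(g), 21.1, tolerance = 0.01)
  # regenerating at the realized ball radius is idempotent within 1%
  r_ball <- attr(g, "ball_radius")
  expect_equal(r_ball * sqrt(3 / 5), 21.1, tolerance = 0.1)
  # many-bead limit: Rg/R_ball -> sqrt(3/5)
  big <- generate_globule(1e5, 23.2379, seed = 3)
  expect_equal(conformer_rg(big) / attr(big, "ball_radius"), sqrt(3 / 5),
               tolerance = 0.01)
})

test_that("conformer_rg matches hand-computed cases", {
  two <- bead_conformer(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(conformer_rg(two), 5)
  one <- bead_conformer(matrix(c(3, -2, 7), 1))
  expect_equal(conformer_rg(one), 0)
  # weighted: all mass on one bead collapses Rg to zero
  wz <- bead_conformer(rbind(c(0, 0, 0), c(10, 0, 0)), weights = c(1, 0))
  expect_equal(conformer_rg(wz), 0)
  expect_error(conformer_rg(bead_conformer(rbind(c(0, 0, 0), c(1, 0, 0)),
                                           weights = c(0, 0))),
               class = "idpbiophys_invalid_input")
})

test_that("tethered complexes expand the chain and handle degenerate cases", {
  rg_cplx <- vapply(1:300, function(i)
    conformer_rg(assemble_complex(120, 60, 21, attachment_index = 120,
                                  seed = 900 + i)), numeric(1))
  rg_chain <- vapply(generate_chain(120, 300, seed = 901), conformer_rg,
                     numeric(1))
  expect_gt(mean(rg_cplx), mean(rg_chain))
  # zero-size domain degenerates to the bare chain
  bare <- assemble_complex(50, 0, 21, seed = 10)
  expect_equal(n_beads <- nrow(bare$xyz), 50)
  # attachment index validation
  expect_error(assemble_complex(50, 20, 21, attachment_index = 51),
               class = "idpbiophys_invalid_input")
  expect_error(assemble_complex(50, 20, 21, attachment_index = 0),
               class = "idpbiophys_invalid_input")
})

test_that("dense chains fail generation with an informative error", {
  expect_error(
    generate_chain(400, 1, bond_length = 3.8, excluded_radius = 1.89,
                   seed = 1, retry_cap = 50),
    class = "idpbiophys_generation_failure")
  err <- tryCatch(
    generate_chain(400, 1, bond_length = 3.8, excluded_radius = 1.89,
                   seed = 1, retry_cap = 50),
    error = function(e) conditionMessage(e))
  expect_match(err, "acceptance rate")
})

test_that("CA-only PDB round trip preserves coordinates and pools", {
  dir <- withr::local_tempdir()
  cf <- generate_chain(40, 1, seed = 2)[[1]]
  f <- file.path(dir, "conf.pdb")
  write_conformer_pdb(cf, f)
  back <- read_conformer_pdb(f)
  expect_equal(back$xyz, cf$xyz, tolerance = 1e-3)  # PDB has 3 decimals
  expect_equal(back$weights, cf$weights)
  pool <- generate_chain(25, 4, seed = 3)
  write_pool(pool, file.path(dir, "pool"))
  back_pool <- read_pool(file.path(dir, "pool"))
  expect_length(back_pool, 4)
  for (i in 1:4)
    expect_equal(back_pool[[i]]$xyz, pool[[i]]$xyz, tolerance = 1e-3)
})
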