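test_that("entropy ledgers validate keys and sum plainly", {
  host_tab <- cb8_reference("host")
  vals <- host_tab[match(c("S_HM_transvib", "S_HM_rovib", "S_HUA_transvib",
                           "S_HUA_rovib", "S_H_conf"), host_tab$component),
                   "H"]
  led <- entropy_ledger(
    species = "host",
    level = c("molecule", "molecule", "united_atom", "united_atom",
              "united_atom"),
    motion = c("translation", "rotation", "translation", "rotation",
               "translation"),
    minima = c(rep("vibrational", 4), "topographical"),
    value = vals)
  expect_equal(total_entropy(led), 965)
  # permutation invariance
  expect_equal(total_entropy(led[sample(nrow(led)), ]), 965)
  # empty ledger
  expect_equal(total_entropy(led[0, ]), 0)
  # duplicate key rejected
  expect_error(entropy_ledger(rep("host", 2), rep("molecule", 2),
                              rep("translation", 2), rep("vibrational", 2),
                              c(1, 2)), "duplicate")
  expect_error(entropy_ledger("host", "molecule", "sideways", "vibrational",
                              1), "invalid motion")
})

test_that("free energies recombine as G = E - TS", {
  sfe <- system_free_energy(energy = -100, entropy = 500, temperature = 300)
  expect_equal(sfe$G, sfe$E - sfe$T * sfe$S / 4184, tolerance = 1e-10)
})

test_that("binding free energy assembles the four-system difference", {
  mk <- function(E, S) system_free_energy(E, S, 300)
  # choose components so dH and TdS land on the published G1 values
  T_ <- 300
  S_c <- 5000; S_w <- 500; S_h <- 4800; S_g <- 700 + 1.3 * 4184 / T_
  b <- binding_free_energy(mk(-57.6, S_c), mk(-20, S_w),
                           mk(-30, S_h), mk(-40, S_g))
  expect_equal(b$dH, -7.6, tolerance = 1e-10)
  expect_equal(b$TdS, -1.3, tolerance = 1e-10)
  expect_equal(b$dG, -6.3, tolerance = 1e-10)
  expect_equal(b$dG, b$dH - b$TdS, tolerance = 1e-12)

  # all equal: no binding signal
  z <- binding_free_energy(mk(-5, 100), mk(-5, 100), mk(-5, 100), mk(-5, 100))
  expect_equal(z$dG, 0)

  # antisymmetry: swapping bound and unbound sides negates everything
  fwd <- binding_free_energy(mk(-57.6, S_c), mk(-20, S_w),
                             mk(-30, S_h), mk(-40, S_g))
  rev <- binding_free_energy(mk(-30, S_h), mk(-40, S_g),
                             mk(-57.6, S_c), mk(-20, S_w))
  expect_equal(rev$dG, -fwd$dG, tolerance = 1e-12)
  expect_equal(rev$dH, -fwd$dH, tolerance = 1e-12)
  expect_equal(rev$TdS, -fwd$TdS, tolerance = 1e-12)
})

test_that("SEM over replicates", {
  expect_equal(sem(c(1, 2, 3)), 1 / sqrt(3), tolerance = 1e-10)
  expect_equal(sem(c(2, 2, 2)), 0)
  expect_equal(sem(c(-6.0, -6.3, -6.6)), 0.1732, tolerance = 1e-3)
  expect_error(sem(5), "2 replicates")
  # invariant under a common shift
  set.seed(1)
  x <- rnorm(5)
  expect_equal(sem(x + 7), sem(x))
})

test_that("MAE against experiment", {
  expect_equal(mae(c(1, 2), c(1, 2)), 0)
  expect_equal(mae(0, 1), 1)
  expect_error(mae(1:3, 1:2), "length")
  set.seed(2)
  p <- rnorm(7); e <- rnorm(7)
  expect_equal(mae(p + 3, e + 3), mae(p, e))
  # the published CB8 series lands on 0.9 kcal/mol
  tab <- cb8_reference("binding")
  expect_equal(round(mae(tab$dG, tab$dG_expt), 1), 0.9)
})

test_that("energy drift regression", {
  flat <- data.frame(time = 0:99, energy = rep(5, 100))
  expect_equal(suppressWarnings(energy_drift(flat))$slope, 0,
               tolerance = 1e-12)
  line <- data.frame(time = 0:99, energy = 2 + 0.003 * (0:99))
  expect_equal(suppressWarnings(energy_drift(line))$slope, 3,
               tolerance = 1e-9)                                # per ns
  expect_error(energy_drift(data.frame(time = c(1, 1, 1),
                                       energy = c(1, 2, 3))), "constant")
  expect_error(energy_drift(data.frame(time = 1:2, energy = 1:2)), "3 points")

  # white noise: slope consistent with zero at 3 SE in >= 99% of runs
  hits <- 0
  for (s in 1:100) {
    set.seed(1000 + s)
    d <- energy_drift(data.frame(time = seq_len(1000),
                                 energy = rnorm(1000)))
    if (abs(d$slope) < 3 * d$slope_se) hits <- hits + 1
  }
  expect_gte(hits, 99)
})

test_that("energy series files parse and feed the drift check", {
  path <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c("# comment", "@ legend", "0 10.5", "100 10.6", "200 10.7"),
             path)
  es <- read_energy_series(path)
  expect_equal(nrow(es), 3L)
  # 0.1 kJ/mol per 100 ps is 1 kJ/mol per ns
  expect_equal(suppressWarnings(energy_drift(es))$slope, 1,
               tolerance = 1e-9)
})

test_that("replicate pooling and the protonation correction", {
  mk <- function(dH, TdS) list(dG = dH - TdS, dH = dH, TdS = TdS)
  res <- binding_result(list(mk(-14, -1.5), mk(-14.2, -1.8), mk(-13.8, -1.8)),
                        guest = "G5", expt = list(dG = -12.3))
  expect_equal(res$dG, res$dH - res$TdS, tolerance = 1e-12)
  expect_gte(res$dG_sem, 0)
  # the half-to-full protonation shift lowers TdS by 0.5 kB ln2 (in kcal)
  corr <- 300 * protonation_correction(0.5, 1) / 4184
  res_c <- binding_result(list(mk(-14, -1.5), mk(-14.2, -1.8),
                               mk(-13.8, -1.8)),
                          guest = "G5", protonation_TdS = corr)
  expect_equal(res_c$TdS, res$TdS + corr, tolerance = 1e-12)
  expect_equal(res_c$dG, res$dG - corr, tolerance = 1e-12)
})

test_that("report writes schema-stable tables", {
  mk <- function(dH, TdS) list(dG = dH - TdS, dH = dH, TdS = TdS)
  res <- binding_result(list(mk(-7.5, -1.2), mk(-7.7, -1.4)), guest = "G1",
                        expt = list(dG = -7.1, dH = -7.8, TdS = -0.8))
  led <- entropy_ledger("guest", "molecule", "translation", "vibrational", 62)
  bk <- water_bookkeeping(87.4, 24.3, 76.4, 2.4)
  dir <- withr::local_tempdir()
  files <- report(list(res), list(G1 = led), list(G1 = bk), dir = dir)
  expect_length(files, 3L)
  bt <- read.table(file.path(dir, "binding.tsv"), header = TRUE, sep = "\t",
                   comment.char = "#")
  expect_named(bt, c("guest", "dG", "dG_sem", "dH", "dH_sem", "TdS",
                     "TdS_sem", "dG_expt", "dH_expt", "TdS_expt"))
  lt <- read.table(file.path(dir, "entropy_components.tsv"), header = TRUE,
                   sep = "\t")
  expect_named(lt, c("system", "species", "level", "motion", "minima",
                     "value"))
  kt <- read.table(file.path(dir, "water_bookkeeping.tsv"), header = TRUE,
                   sep = "\t")
  expect_equal(kt$n_wb, 32.9)
  expect_error(report(list()), "no binding results")
})

test_that("solute ledger runs the full decomposition on a solvated system", {
  sys <- synthetic_solution(n_water = 16, n_frames = 20, seed = 31)
  led <- solute_entropy_ledger(sys, "GST.1", "guest")
  expect_s3_class(led, "mcc_ledger")
  # molecule + united-atom vibrational, positional, orientational, conf
  expect_gte(nrow(led), 6L)
  expect_true(all(is.finite(led$value)))
  pos <- led$value[led$level == "molecule" & led$motion == "translation" &
                     led$minima == "topographical"]
  expect_equal(pos, positional_entropy(1 / 55.5))
  expect_gt(total_entropy(led), 0)

  # bound guest: positional collapses to zero, orientational to the
  # symmetry-number ratio of the sigma = 16 host
  ledb <- solute_entropy_ledger(sys, "GST.1", "guest", bound = TRUE,
                                sigma_host = 16)
  topo <- ledb[ledb$minima == "topographical" & ledb$level == "molecule", ]
  expect_equal(topo$value[topo$motion == "translation"], 0)
  expect_equal(topo$value[topo$motion == "rotation"],
               orientational_entropy_bound(16, 1))

  # the host defines the reference frame: no positional/orientational rows
  ledh <- solute_entropy_ledger(sys, "GST.1", "host")
  expect_equal(nrow(ledh[ledh$minima == "topographical" &
                           ledh$level == "molecule", ]), 0L)
})
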