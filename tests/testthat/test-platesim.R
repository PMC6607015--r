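entry <- list(well = "A1", role = "compound")

test_that("total toxicity removes every cell", {
  p <- reduced_sim(fields_per_well = 2L, cells_per_field = 30)
  sw <- simulate_well(entry, compound_effect(toxicity_fraction = 1),
                      p, seed = 3)
  expect_equal(sw$truth$n_surviving, 0)
  expect_equal(nrow(sw$truth$cells), 0)
  # rendered fields contain background + noise only: nothing above the
  # background by more than noise excursions
  expect_lt(max(sw$images$fields[[1]][, , 1]), p$background + 8 * p$noise_sd)
})

test_that("survivor counts follow round(seeded * (1 - toxicity))", {
  p <- reduced_sim(fields_per_well = 2L, cells_per_field = 40)
  for (tox in c(0, 0.21, 0.5)) {
    sw <- simulate_well(entry, compound_effect(toxicity_fraction = tox),
                        p, seed = 17, render = FALSE)
    expect_equal(sw$truth$n_surviving,
                 round(sw$truth$n_seeded * (1 - tox)))
    expect_equal(nrow(sw$truth$cells), sw$truth$n_surviving)
  }
})

test_that("simulation is bit-identical under the same seed", {
  p <- reduced_sim(fields_per_well = 2L, cells_per_field = 25)
  a <- simulate_well(entry, compound_effect(1.7, 0.5), p, seed = 9)
  b <- simulate_well(entry, compound_effect(1.7, 0.5), p, seed = 9)
  expect_identical(a$images$fields, b$images$fields)
  expect_identical(a$truth, b$truth)
  c <- simulate_well(entry, compound_effect(1.7, 0.5), p, seed = 10)
  expect_false(identical(a$images$fields, c$images$fields))
})

test_that("ground truth is the same whether or not pixels are rendered", {
  p <- reduced_sim(fields_per_well = 2L, cells_per_field = 25)
  a <- simulate_well(entry, compound_effect(), p, seed = 5)
  b <- simulate_well(entry, compound_effect(), p, seed = 5, render = FALSE)
  expect_identical(a$truth, b$truth)
  expect_null(b$images)
})

test_that("invalid effect factors are rejected naming the field", {
  expect_error(compound_effect(lbpa_factor = -1), "lbpa_factor")
  expect_error(compound_effect(chol_factor = NaN), "chol_factor")
  expect_error(compound_effect(perinuclear_factor = 1.2),
               "perinuclear_factor")
  expect_error(compound_effect(toxicity_fraction = -0.1),
               "toxicity_fraction")
})

test_that("mean true per-cell LBPA intensity matches direct Monte-Carlo
          sampling of the generator distributions", {
  p <- sim_params()
  # independent oracle: draw per-cell totals straight from the stated
  # distributions, without any rendering or package simulation code
  set.seed(990)
  n <- 20000
  f <- rlnorm(n, -p$cell_cv^2 / 2, p$cell_cv)
  k <- rpois(n, p$endosomes_per_cell)
  sigma_px <- p$endosome_radius / p$pixel_size
  oracle <- vapply(seq_len(n), function(i) {
    if (k[i] == 0) return(0)
    sum(p$lbpa_spot_level * f[i] *
          rlnorm(k[i], -p$spot_cv^2 / 2, p$spot_cv)) * 2 * pi * sigma_px^2
  }, 0)
  truth <- unlist(lapply(1:6, function(s)
    simulate_well(entry, compound_effect(), p, seed = s,
                  render = FALSE)$truth$cells$lbpa_true))
  expect_gt(length(truth), 500)
  expect_lt(abs(mean(truth) / mean(oracle) - 1), 0.05)
  # and both agree with the closed-form moments
  mo <- lbpa_truth_moments(p)
  expect_lt(abs(mean(oracle) / mo$mean_cell - 1), 0.05)
  expect_lt(abs(sd(oracle) / sqrt(mo$var_cell) - 1), 0.05)
})

test_that("expected well-mean LBPA intensity is monotone in lbpa_factor", {
  p <- reduced_sim(fields_per_well = 1L, cells_per_field = 60)
  grid <- c(1, 1.5, 2, 3)
  means <- vapply(grid, function(lf) {
    mean(unlist(lapply(1:4, function(s)   # paired seeds across the grid
      simulate_well(entry, compound_effect(lbpa_factor = lf), p, seed = s,
                    render = FALSE)$truth$cells$lbpa_true)))
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("simulate_plate honours roles, skips empty wells and is
          order-independent", {
  lay <- default_plate_layout(c("A", "B"), n_rows = 2, n_cols = 4,
                              neg_col = 2, pos_col = 3)
  eff <- list(A = compound_effect(2), B = compound_effect())
  p <- sim_params(image_size = c(64L, 64L), pixel_size = 1,
                  fields_per_well = 1L, cells_per_field = 8)
  d <- simulate_plate(lay, eff, p, seed = 5)
  expect_setequal(names(d$wells), lay$well[lay$role != "empty"])
  expect_equal(sum(lay$role == "empty"), 2)

  perm <- lay[rev(seq_len(nrow(lay))), ]
  for (a in c("n_rows", "n_cols")) attr(perm, a) <- attr(lay, a)
  class(perm) <- class(lay)
  d2 <- simulate_plate(perm, eff, p, seed = 5)
  for (w in names(d$wells)) {
    expect_identical(d$wells[[w]]$images$fields, d2$wells[[w]]$images$fields)
    expect_identical(d$wells[[w]]$truth, d2$wells[[w]]$truth)
  }

  expect_error(simulate_plate(lay, eff["A"], p, seed = 1),
               "missing compound effect")
})

test_that("rendered intensities stay on the 12-bit scale", {
  p <- reduced_sim(fields_per_well = 1L, cells_per_field = 40)
  sw <- simulate_well(entry, compound_effect(lbpa_factor = 3,
                                             chol_factor = 3), p, seed = 2)
  for (f in sw$images$fields) {
    expect_gte(min(f), 0)
    expect_lte(max(f), p$max_intensity)
  }
})
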