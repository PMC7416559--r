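# Synthetic-data generators: exact ground truth, determinism, validation.

test_that("a single noiseless horizontal bar renders at its exact width", {
  sp <- fiber_image_spec(image_size = c(128, 128), n_fibers = 1,
                         diameter_mean = 5, diameter_sd = 0,
                         orientation_mu = 0, orientation_kappa = 1e6,
                         blur_sigma = 0, noise_sd = 0, seed = 3)
  sc <- generate_fiber_image(sp)
  m <- sc$ground_truth$true_mask
  expect_equal(sum(rowSums(m) > 0), 5)            # 5 rows thick
  expect_true(all(colSums(m) == 5))               # spans every column
  expect_equal(sc$ground_truth$true_porosity, 1 - 5 * 128 / (128 * 128))
  expect_equal(sc$ground_truth$true_porosity, mean(!m))
})

test_that("fiber generation is bitwise deterministic for a fixed seed", {
  sp <- fiber_image_spec(image_size = c(96, 96), n_fibers = 20, seed = 42)
  a <- generate_fiber_image(sp)
  b <- generate_fiber_image(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("isotropic orientation sampling has a small doubled-angle resultant", {
  sp <- fiber_image_spec(image_size = c(64, 64), n_fibers = 200,
                         orientation_kappa = 0, seed = 7)
  sc <- generate_fiber_image(sp)
  th <- sc$ground_truth$fibers$angle_deg * pi / 90
  R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  expect_lt(R, 0.15)
})

test_that("concentrated orientation sampling converges to the mean angle", {
  sp <- fiber_image_spec(image_size = c(64, 64), n_fibers = 500,
                         orientation_mu = 25, orientation_kappa = 50, seed = 5)
  sc <- generate_fiber_image(sp)
  expect_lt(abs(axial_mean(sc$ground_truth$fibers$angle_deg) - 25), 3)
  expect_true(all(sc$ground_truth$fibers$angle_deg >= -90 &
                  sc$ground_truth$fibers$angle_deg < 90))
})

test_that("porosity decreases as fibers are added", {
  poros <- sapply(c(10, 40, 160), function(nf) {
    sp <- fiber_image_spec(image_size = c(128, 128), n_fibers = nf, seed = 9)
    generate_fiber_image(sp)$ground_truth$true_porosity
  })
  expect_true(all(diff(poros) < 0))
})

test_that("fiber image spec validation names the offending field", {
  expect_error(fiber_image_spec(image_size = c(32, 32)), "image_size")
  expect_error(fiber_image_spec(diameter_mean = -1), "diameter_mean")
  expect_error(fiber_image_spec(fiber_intensity = 0.5,
                                background_intensity = 0.5),
               "fiber_intensity")
  expect_error(fiber_image_spec(noise_sd = -0.1), "noise_sd")
})

test_that("cell outlines are exact discretized ellipses", {
  circles <- generate_cell_outlines(3, elongation_mean = 1, seed = 1,
                                    radius_mean = 10)
  expect_length(circles, 3)
  v <- circles[[1]]$vertices
  x <- v[, 1]; y <- v[, 2]
  shoelace <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  expect_lt(abs(shoelace - pi * 100) / (pi * 100), 0.001)
  again <- generate_cell_outlines(3, elongation_mean = 1, seed = 1,
                                  radius_mean = 10)
  expect_identical(circles, again)

  ell <- generate_cell_outlines(1, elongation_mean = 2, seed = 2)[[1]]
  expect_equal(ell$truth$major / ell$truth$minor, 2)
  expect_identical(ell$truth$elongation, 2)
  expect_error(generate_cell_outlines(2, elongation_mean = 0.5),
               "elongation_mean")
})

test_that("Maxwell sweeps satisfy the analytic identities", {
  sw <- generate_rheology_sweep(maxwell_spec(modulus_scale = 100,
                                             relaxation_time = 1,
                                             frequency_grid = c(0.1, 1, 10)))
  expect_equal(sw$g_storage_pa[2], 50)   # G'(1/tau) = G/2
  expect_equal(sw$g_loss_pa[2], 50)
  expect_equal(sw$g_loss_pa[1] / sw$g_storage_pa[1], 10)  # 1/(wt) at wt=0.1
  expect_true(all(sw$g_storage_pa > 0 & sw$g_loss_pa > 0))
  expect_error(maxwell_spec(frequency_grid = c(2, 1)), "increasing")
  expect_error(maxwell_spec(frequency_grid = numeric(0)), "frequency_grid")
})

test_that("expression tables plant the promised fold changes", {
  sp <- expression_sim_spec(n_genes = 600, n_up = 10, n_down = 5,
                            effect_fold = 3, seed = 11)
  tab <- generate_expression_table(sp)
  expect_equal(sum(tab$planted == "up"), 10)
  expect_equal(sum(tab$planted == "down"), 5)
  expect_true(all(tab$fold_change[tab$planted == "up"] >= 3))
  expect_true(all(tab$fold_change[tab$planted == "down"] <= 1 / 3))
  expect_true(all(tab$biotype[tab$planted != "none"] == "protein_coding"))
  expect_identical(tab, generate_expression_table(sp))

  pc_only <- expression_sim_spec(n_genes = 100,
                                 biotype_proportions = c(protein_coding = 1),
                                 n_up = 5, n_down = 5, seed = 1)
  expect_true(all(generate_expression_table(pc_only)$biotype == "protein_coding"))
  expect_error(expression_sim_spec(n_genes = 10,
                                   biotype_proportions = c(protein_coding = 1),
                                   n_up = 6, n_down = 5),
               "protein-coding")
})

test_that("cytokine arrays record the exact normalized truth", {
  arr <- generate_cytokine_array(20, background = 2, reference = 20,
                                 seed = 3, noise_sd = 0)
  manual <- ((arr$spot1 + arr$spot2) / 2 - arr$background) / arr$reference
  expect_equal(manual, arr$true_level)
  expect_identical(arr, generate_cytokine_array(20, background = 2,
                                                reference = 20, seed = 3,
                                                noise_sd = 0))
  expect_error(generate_cytokine_array(5, reference = 0), "reference")
})
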