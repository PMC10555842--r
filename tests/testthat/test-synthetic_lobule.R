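test_that("lobule simulation is seed-deterministic with n_cells records", {
  a <- simulate_lobule(100, seed = 7, n_proteins = 30)
  b <- simulate_lobule(100, seed = 7, n_proteins = 30)
  expect_identical(a, b)
  expect_equal(nrow(a$cells), 100)
  expect_true(all(a$cells$area_um2 > 0))
  expect_true(all(a$cells$r_true >= 0 & a$cells$r_true <= 1))
  expect_true(all(a$cells$nuclear_fraction >= 0 &
                  a$cells$nuclear_fraction <= 1))
  expect_error(simulate_lobule(0), "n_cells")
})

test_that("default placement gives near-uniform relative distances", {
  truth <- simulate_lobule(2000, seed = 3, n_proteins = 5)
  ks <- suppressWarnings(ks.test(truth$cells$r_true, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("r_true agrees with the landmark-distance formula", {
  truth <- simulate_lobule(50, seed = 9, n_proteins = 5)
  d <- t(vapply(seq_len(50), function(i) {
    landmark_distances(c(truth$cells$centroid_x[i],
                         truth$cells$centroid_y[i]), truth$geometry)
  }, numeric(2)))
  expect_equal(truth$cells$r_true, relative_distance(d[, 1], d[, 2]))
  expect_equal(truth$cells$d_pv_um, unname(d[, 1]))
})

test_that("profile_value evaluates the piecewise zonation shapes", {
  flat <- list(shape_kind = "flat", baseline = 9, amplitude = 0)
  expect_equal(profile_value(flat, c(0, 0.3, 1)), rep(9, 3))
  hc <- list(shape_kind = "hockey_central", baseline = 10, amplitude = 4,
             r0 = 0.5, gamma = 1)
  expect_equal(profile_value(hc, 0.75), 12)
  # flat until the breakpoint
  expect_equal(profile_value(hc, c(0, 0.2, 0.5)), rep(10, 3))
  expect_equal(profile_value(hc, 1), 14)
  # the portal mirror image
  hp <- modifyList(hc, list(shape_kind = "hockey_portal"))
  expect_equal(profile_value(hp, 0.25), 12)
  expect_equal(profile_value(hp, c(1, 0.8, 0.5)), rep(10, 3))
  lin <- list(shape_kind = "linear_up", baseline = 8, amplitude = 2)
  expect_equal(profile_value(lin, 0.5), 9)
  expect_error(profile_value(hc, 1.5), "\\[0, 1\\]")
})

test_that("noise-free flat proteomes are constant up to the area term", {
  truth <- simulate_lobule(30, seed = 4, n_proteins = 10,
                           zonated_fraction = 0)
  pm <- simulate_proteome(truth, noise_sd = 0, missingness = NULL,
                          area_coef = 0, histone_coef = 0)
  vals <- pm_log2(pm)
  expect_true(all(apply(vals, 1, function(v) diff(range(v)) == 0)))
  expect_error(simulate_proteome(truth, noise_sd = -1), "noise_sd")
})

test_that("histone intensity couples linearly to nuclear fraction", {
  truth <- simulate_lobule(2, seed = 6, n_proteins = 8, zonated_fraction = 0)
  truth$cells$area_um2 <- c(600, 600)
  truth$cells$r_true <- c(0.5, 0.5)
  truth$cells$nuclear_fraction <- c(0, 0.5)
  pm <- simulate_proteome(truth, noise_sd = 0, missingness = NULL,
                          histone_coef = 2)
  m <- pm_log2(pm)
  hist_rows <- truth$profiles$is_histone
  expect_true(any(hist_rows))
  expect_equal(unname(m[hist_rows, 2] - m[hist_rows, 1]),
               rep(2 * 0.5, sum(hist_rows)))
  # non-histone proteins are unaffected
  expect_equal(unname(m[!hist_rows, 2]), unname(m[!hist_rows, 1]))
})

test_that("detected protein counts grow with shape area", {
  truth <- simulate_lobule(1000, seed = 8, n_proteins = 300)
  pm <- simulate_proteome(truth)
  counts <- colSums(!is.na(pm_log2(pm)))
  rho <- cor(counts, log(truth$cells$area_um2), method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("data completeness increases with protein intensity", {
  truth <- simulate_lobule(300, seed = 10, n_proteins = 400)
  pm <- simulate_proteome(truth)
  m <- pm_log2(pm)
  compl <- rowMeans(!is.na(m))
  med_int <- apply(m, 1, median, na.rm = TRUE)
  ok <- !is.na(med_int) & compl < 1
  expect_gt(cor(compl[ok], med_int[ok], method = "spearman"), 0.5)
})

test_that("simulated reports carry the three-channel mDIA design", {
  truth <- simulate_lobule(4, seed = 5, n_proteins = 5)
  pm <- simulate_proteome(truth, noise_sd = 0, missingness = NULL)
  sim <- simulate_report(pm, truth)
  by_run <- split(sim$report$Channel, sim$report$Run)
  for (ch in by_run) expect_setequal(unique(ch), c(0, 4, 8))
  # deterministic for a fixed truth
  sim2 <- simulate_report(pm, truth)
  expect_identical(sim$report, sim2$report)
  # single-fragment, noise-free ratio is exact
  one <- simulate_report(pm, truth, frag_per_precursor = 1,
                         n_precursors = 1, ratio_noise_sd = 0,
                         ref_run_noise_sd = 0, q_fail = 0)
  ref <- one$report[one$report$Channel == 0, ]
  tgt <- one$report[one$report$Channel == 4, ][1, ]
  r0 <- ref[ref$Run == tgt$Run & ref$Precursor.Id == tgt$Precursor.Id, ]
  got <- as.numeric(tgt$Fragment.Quant.Raw) / as.numeric(r0$Fragment.Quant.Raw)
  want <- one$ratios$true_ratio[one$ratios$run == tgt$Run &
                                one$ratios$channel == 4 &
                                one$ratios$precursor_id == tgt$Precursor.Id]
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("image channels encode the zonation axis", {
  truth <- simulate_lobule(2, seed = 2, n_proteins = 5)
  truth$cells$r_true <- c(0.05, 0.95)
  imgs0 <- simulate_images(truth, cell_noise_sd = 0, pixel_noise_sd = 0)
  expect_gt(mean(imgs0[[1]][, , 3]), mean(imgs0[[2]][, , 3]))  # E-cadherin
  expect_gt(mean(imgs0[[2]][, , 4]), mean(imgs0[[1]][, , 4]))  # Glul
  # determinism
  big <- simulate_lobule(20, seed = 12, n_proteins = 5)
  expect_identical(simulate_images(big), simulate_images(big))
  # Spearman correlation of the CV marker with r at default noise
  many <- simulate_lobule(500, seed = 14, n_proteins = 5)
  ch647 <- vapply(simulate_images(many), function(p) mean(p[, , 4]),
                  numeric(1))
  expect_gt(cor(ch647, many$cells$r_true, method = "spearman"), 0.8)
  expect_error(simulate_images(many, patch_size = 2), "patch_size")
})

test_that("landmarks outside the field are rejected", {
  expect_error(lobule_geometry(pv = rbind(c(-5, 0)), cv = rbind(c(1, 1)),
                               field_size = c(10, 10)), "inside")
  expect_error(lobule_geometry(pv = matrix(numeric(0), 0, 2)), "landmark")
})
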