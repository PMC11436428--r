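test_that("phantom generation is deterministic and exactly plateau-valued", {
  spec <- small_phantom_spec(noise_sigma = 0.2, seed = 99)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$labelmap, b$labelmap)

  # noiseless: every voxel is exactly background or a plateau value
  clean <- generate_phantom(small_phantom_spec())
  plateaus <- vapply(clean$spec$components, `[[`, numeric(1), "suv")
  expect_true(all(clean$volume$values %in% c(1.0, plateaus)))
  # label table covers the five device components plus the aorta
  expect_setequal(clean$label_table$component,
                  c(lvad_components(), "background_aorta"))
  # masks agree with the labelmap and are non-empty
  for (i in seq_len(nrow(clean$label_table))) {
    comp <- clean$label_table$component[i]
    expect_identical(clean$masks[[comp]]$indices,
                     which(clean$labelmap == clean$label_table$label[i]))
    expect_gt(length(clean$masks[[comp]]), 0L)
  }
})

test_that("segmentation reproduces the analytic phantom ground truth exactly", {
  ph <- generate_phantom(small_phantom_spec())
  seg <- segment_all(ph$volume, ph$masks)
  m <- merge(seg, ph$truth, by = c("component", "mode"),
             suffixes = c("_seg", "_truth"))
  expect_equal(nrow(m), 10L)
  expect_identical(as.integer(m$n_voxels_seg), as.integer(m$n_voxels_truth))
  expect_identical(m$mtv_cm3_seg, m$mtv_cm3_truth)
  expect_identical(m$tlg_seg, m$tlg_truth)
  expect_identical(m$suv_mean_seg_seg, m$suv_mean_seg_truth)

  # all plateaus at background level: absolute-rule MTV is zero everywhere
  cold <- vapply(lvad_components(), function(x) 1.0, numeric(1))
  ph0 <- generate_phantom(small_phantom_spec(
    components = default_phantom_components(hotspot_suv = cold)))
  expect_true(all(ph0$truth$mtv_cm3[ph0$truth$mode == "fixed_absolute"] == 0))
})

test_that("plateau voxel-count arithmetic drives MTV and TLG in the truth table", {
  ph <- generate_phantom(small_phantom_spec())
  vv <- voxel_volume(ph$volume)
  abs_truth <- ph$truth[ph$truth$mode == "fixed_absolute", ]
  for (i in seq_len(nrow(abs_truth))) {
    comp <- abs_truth$component[i]
    s <- ph$spec$components[[comp]]$suv
    n_comp <- length(ph$masks[[comp]])
    n_expect <- if (s >= 3.0) n_comp else 0L
    expect_equal(abs_truth$n_voxels[i], n_expect)
    expect_equal(abs_truth$mtv_cm3[i], n_expect * vv)
    expect_equal(abs_truth$tlg[i], n_expect * vv * (if (n_expect) s else 0))
  }
})

test_that("noisy phantoms reproduce MTV within 5% for hot plateaus", {
  hot <- c(driveline_exit = 7.0, driveline_subcutaneous = 6.5, pump = 8.0,
           inflow_cannula = 6.2, outflow_graft = 6.1)
  spec <- small_phantom_spec(
    components = default_phantom_components(hotspot_suv = hot),
    noise_sigma = 0.1, seed = 17)
  ph <- generate_phantom(spec)
  seg <- segment_all(ph$volume, ph$masks)
  abs_seg <- seg[seg$mode == "fixed_absolute", ]
  abs_truth <- ph$truth[ph$truth$mode == "fixed_absolute", ]
  for (comp in lvad_components()) {
    got <- abs_seg$mtv_cm3[abs_seg$component == comp]
    want <- abs_truth$mtv_cm3[abs_truth$component == comp]
    expect_lt(abs(got - want) / want, 0.05)
  }
})

test_that("phantom options: artifact rim stays off the masks; smoothing blurs edges", {
  rim <- generate_phantom(small_phantom_spec(
    artifact_rim = list(width = 6, suv = 2.75)))
  labelled <- unlist(lapply(rim$masks, function(m) m$indices))
  rim_voxels <- which(rim$volume$values == 2.75)
  expect_gt(length(rim_voxels), 0L)
  expect_length(intersect(rim_voxels, labelled), 0L)

  sm <- generate_phantom(small_phantom_spec(smoothing_fwhm = 6))
  clean <- generate_phantom(small_phantom_spec())
  # smoothing preserves deep-interior plateaus but not the edge voxels
  pump_vals <- sm$volume$values[sm$masks$pump$indices]
  expect_lt(min(pump_vals), max(clean$volume$values[clean$masks$pump$indices]))
  expect_equal(max(pump_vals), 5.0, tolerance = 1e-6)
})

test_that("geometry outside the grid is rejected", {
  comps <- default_phantom_components()
  expect_error(phantom_spec(shape = c(32, 32, 32), spacing = c(2, 2, 2),
                            components = comps),
               "geometry out of grid")
})

test_that("cohort generation hits its distribution targets", {
  spec <- cohort_spec(n_infected = 20000, n_noninfected = 20000, seed = 8)
  co <- generate_cohort(spec)
  expect_equal(nrow(co), 40000L)
  # sample medians near the median-targeted values (2% at this n)
  inf <- co[co$label == 1, ]
  non <- co[co$label == 0, ]
  expect_equal(median(inf$suv_max), 4.85, tolerance = 0.02)
  expect_equal(median(non$suv_max), 3.4, tolerance = 0.02)
  expect_equal(median(inf$lbr), 3.28, tolerance = 0.02)
  # mean/SD-targeted metrics recover their moments (looser: heavy tails)
  expect_equal(mean(inf$total_mtv_abs), 44.55, tolerance = 0.05)
  expect_equal(sd(non$total_mtv_rel), 12.76, tolerance = 0.05)
  # all metrics strictly positive
  mets <- unique(spec$targets$metric)
  expect_true(all(as.matrix(co[, mets]) > 0))
})

test_that("cohort dependence follows the shared-factor copula", {
  # rho = 0: independent columns
  co0 <- generate_cohort(cohort_spec(n_infected = 10000, n_noninfected = 2,
                                     rho = 0, seed = 3))
  inf0 <- co0[co0$label == 1, ]
  r0 <- cor(inf0$suv_max, inf0$total_mtv_abs, method = "spearman")
  expect_lt(abs(r0), 0.02)
  # rho = 0.5: pairwise rank correlation near the request
  co5 <- generate_cohort(cohort_spec(n_infected = 10000, n_noninfected = 2,
                                     rho = 0.5, seed = 3))
  inf5 <- co5[co5$label == 1, ]
  r5 <- cor(inf5$suv_max, inf5$suv_peak, method = "spearman")
  expect_equal(r5, 0.5, tolerance = 0.05)

  # determinism: same seed, identical table; different seed differs
  a <- generate_cohort(cohort_spec(seed = 4))
  b <- generate_cohort(cohort_spec(seed = 4))
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(cohort_spec(seed = 5))))
})

test_that("cohort targets run through diagnostics give plausible burden AUCs", {
  co <- generate_cohort(cohort_spec(n_infected = 300, n_noninfected = 300,
                                    seed = 21))
  auc_mtv <- roc_auc(co$total_mtv_abs, co$label)
  auc_tlg <- roc_auc(co$total_tlg_abs, co$label)
  expect_gt(auc_mtv, 0.6); expect_lt(auc_mtv, 0.95)
  expect_gt(auc_tlg, 0.6); expect_lt(auc_tlg, 0.95)
})

test_that("infeasible distribution targets are rejected", {
  bad <- cohort_targets()
  bad$q3[1] <- bad$q1[1]  # zero IQR
  expect_error(generate_cohort(cohort_spec(targets = bad)), "q1 < q3")
})
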