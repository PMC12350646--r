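test_that("compute_rates reproduces hand-computable fixtures exactly", {
  r <- compute_rates(1000, 2000, 1000)
  expect_equal(r$filling_rate_pct, 200)
  expect_equal(r$restoration_pct, 100)
  expect_equal(r$resorption_pct, 50)

  # cohort-mean volumes: ratio-of-means rates, which differ by
  # construction from averaging per-case rates (mean of ratios)
  r2 <- compute_rates(1505.2, 1982.7, 850.8)
  expect_equal(round(r2$filling_rate_pct, 1), 131.7)
  expect_equal(round(r2$restoration_pct, 1), 56.5)
  expect_equal(round(r2$resorption_pct, 1), 57.1)

  expect_equal(compute_rates(100, 80, 80)$resorption_pct, 0)
  expect_error(compute_rates(0, 100, 50), "cleft")
  expect_error(compute_rates(100, 0, 0), "graft")
  expect_error(compute_rates(100, 50, 60), "v_integrated")
})

test_that("case reports enforce the exact resorption identity", {
  r <- case_report("x", 500.25, 800.5, 300.125, 120)
  expect_equal(r$v_resorption_mm3, 800.5 - 300.125)
  expect_true(r$v_integrated_mm3 <= r$v_graft_mm3)
  expect_error(case_report("x", 500, 800, 900, 120), "exceed")
  expect_error(case_report("x", -1, 800, 300, 120), "nonnegative")
})

test_that("graft and integration volumes obey their Boolean definitions", {
  g <- fixture_geom(32, 0.5)
  sag <- plane(c(0, 0, 0), c(1, 0, 0))
  tb <- trim_box(c(-8, -8, -8), c(8, 8, 8))
  v0 <- ball_mask(g, radius = 4)
  graft_solid <- ball_mask(g, centre = c(3.5, 0, 0), radius = 2.5)
  v1 <- binary_mask(pmax(v0$voxels, graft_solid$voxels), g$spacing,
                    g$origin)

  # v1 == v0 gives a zero graft
  inp_same <- case_inputs(v0, v0, v0, sag, tb, smoothing_radius_mm = 0)
  expect_equal(compute_graft_volume(inp_same)$volume_mm3, 0)

  inp <- case_inputs(v0, v1, v0, sag, tb, smoothing_radius_mm = 0)
  graft <- compute_graft_volume(inp)
  # graft mask is disjoint from V0 by construction
  expect_equal(sum(graft$mask$voxels & v0$voxels), 0L)
  expect_equal(graft$volume_mm3,
               measure_volume(v1) - measure_volume(v0))

  # v2 covering the graft: zero resorption
  integ_full <- compute_integration(
    case_inputs(v0, v1, v1, sag, tb, smoothing_radius_mm = 0), graft$mask)
  expect_equal(integ_full$v_resorption_mm3, 0)
  expect_equal(integ_full$v_integrated_mm3, graft$volume_mm3)

  # v2 disjoint from the graft: everything resorbed
  integ_none <- compute_integration(
    case_inputs(v0, v1, v0, sag, tb, smoothing_radius_mm = 0), graft$mask)
  expect_equal(integ_none$v_integrated_mm3, 0)
  expect_equal(integ_none$v_resorption_mm3, graft$volume_mm3)
})

test_that("a trim box excluding the cleft region yields zero cleft volume", {
  ph <- generate_phantom(small_phantom_spec(seed = 61, noise_sd = 0,
                                            misalign_max_t_mm = 0,
                                            misalign_max_rot_deg = 0))
  cm <- ph$clean_masks
  far_box <- trim_box(c(-18, 2, -8), c(-10, 10, 8))  # contralateral side
  inp <- case_inputs(cm$v0, cm$v1, cm$v2, ph$config$sagittal_plane,
                     far_box, smoothing_radius_mm = 0)
  cleft <- compute_cleft_volume(inp)
  expect_lt(cleft$volume_mm3,
            0.01 * ph$truth$true_bone_volume_v0)
})

test_that("run_case runs from config + NIfTI files and flags missing data", {
  ph <- generate_phantom(small_phantom_spec(seed = 62))
  dir <- file.path(tempdir(), "case62")
  write_phantom_case(ph, dir)
  rep <- run_case(file.path(dir, "case.yaml"))
  tr <- ph$truth
  truth <- c(tr$true_cleft_volume, tr$true_graft_volume,
             tr$true_integrated_volume, tr$true_missing_volume)
  meas <- c(rep$v_cleft_mm3, rep$v_graft_mm3, rep$v_integrated_mm3,
            rep$v_missing_mm3)
  expect_true(all(abs(meas - truth) / truth < 0.05))
  expect_equal(rep$v_resorption_mm3,
               rep$v_graft_mm3 - rep$v_integrated_mm3)

  # missing follow-up volume: error names the timepoint
  cfg <- read_case_config(file.path(dir, "case.yaml"))
  cfg$volumes$v2 <- file.path(dir, "nonexistent.nii.gz")
  expect_error(run_case(cfg), "v2")
})

test_that("summarize_cohort matches hand-computed statistics on a printed fixture", {
  reports <- list(
    case_report("a", 1200, 1800, 900, 500, 150, 75, 50),
    case_report("b", 1500, 1950, 750, 800, 130, 50, 400 / 6.5),
    case_report("c", 1800, 2100, 600, 1100, 350 / 3, 100 / 3, 500 / 7))
  s <- summarize_cohort(reports)
  expect_equal(s$n, 3L)
  st <- s$stats
  expect_equal(st$mean[st$metric == "v_cleft_mm3"], 1500)
  expect_equal(st$sd[st$metric == "v_cleft_mm3"], 300)
  # independent arithmetic for the filling-vs-cleft correlation
  f <- c(150, 130, 350 / 3)
  v <- c(1200, 1500, 1800)
  r_hand <- sum((f - mean(f)) * (v - mean(v))) /
    sqrt(sum((f - mean(f))^2) * sum((v - mean(v))^2))
  expect_equal(s$correlations$r[s$correlations$pair == "filling_vs_cleft"],
               r_hand, tolerance = 1e-12)
  # p-values agree with the reference implementation
  ct <- cor.test(f, v)
  expect_equal(s$correlations$p[s$correlations$pair == "filling_vs_cleft"],
               unname(ct$p.value), tolerance = 1e-12)

  # sample mean and SD conventions: mean of {100, 200} is 150, SD 70.71
  two <- list(case_report("p", 100, 100, 50, 10, 100, 50, 50),
              case_report("q", 200, 100, 50, 10, 200, 50, 50))
  s2 <- suppressWarnings(summarize_cohort(two))
  expect_equal(s2$stats$mean[s2$stats$metric == "v_cleft_mm3"], 150)
  expect_equal(round(s2$stats$sd[s2$stats$metric == "v_cleft_mm3"], 2),
               70.71)

  # degenerate cohort: zero variance flags undefined correlations
  same <- list(case_report("u", 100, 120, 60, 10, 120, 60, 50),
               case_report("v", 100, 120, 60, 10, 120, 60, 50))
  w <- testthat::capture_warnings(s3 <- summarize_cohort(same))
  expect_true(all(grepl("zero variance", w)))
  expect_length(w, 3)  # one per correlation pair
  expect_true(all(is.nan(s3$correlations$r)))
  expect_error(summarize_cohort(list(case_report("w", 1, 1, 1, 1))),
               "at least 2")
})

test_that("restoration never exceeds filling in emitted reports", {
  co <- generate_cohort(12, seed = 63)
  reps <- cohort_truth_reports(co)
  for (r in reps) {
    expect_lte(r$restoration_pct, r$filling_rate_pct)
    expect_equal(r$v_resorption_mm3, r$v_graft_mm3 - r$v_integrated_mm3)
    expect_gte(r$v_integrated_mm3, 0)
    expect_lte(r$v_integrated_mm3, r$v_graft_mm3)
  }
})
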