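# Targeted quantification, total-concentration normalization and signed
# median fold changes.

test_that("noise-free forward-model inversion recovers ground truth", {
  eff <- default_effect_table()
  tab <- simulate_concentrations(study_design(), eff, cv = 0.1, seed = 1)
  v <- conc_values(tab)
  s <- render_spectrum(v[1, ], params = quiet_params(), seed = 1)
  q <- quantify_targeted(remove_water(s))
  truth <- v[1, names(q)]
  expect_equal(as.numeric(q), as.numeric(truth), tolerance = 0.01)
})

test_that("an all-zero spectrum yields all-missing coefficients", {
  s <- new_spectrum(default_ppm_axis(), rep(0, length(default_ppm_axis())))
  q <- quantify_targeted(s)
  expect_true(all(attr(q, "below_dl")))
})

test_that("a smooth baseline artifact barely perturbs the fit", {
  eff <- default_effect_table()
  tab <- simulate_concentrations(study_design(), eff, cv = 0.1, seed = 2)
  v <- conc_values(tab)
  s <- render_spectrum(v[2, ], params = render_params(drift_amplitude = 0), seed = 3)
  q0 <- quantify_targeted(remove_water(s))
  pert <- s
  pert$intensity <- s$intensity + 0.5 * sin(s$ppm / 3)   # slowly varying artifact
  pert <- baseline_correct(pert)
  q1 <- quantify_targeted(remove_water(pert))
  ok <- !attr(q0, "below_dl")
  expect_lt(max(abs(q1[ok] - q0[ok]) / q0[ok]), 0.1)
})

test_that("near-collinear templates are rejected as ill-conditioned", {
  lib <- list(
    a = new_metabolite_template("a", "C99991",
      data.frame(center = 1.5, relative_area = 1, linewidth = 0.004)),
    b = new_metabolite_template("b", "C99992",
      data.frame(center = 1.5001, relative_area = 1, linewidth = 0.004))
  )
  s <- render_spectrum(c(lactate = 1), params = quiet_params(), seed = 1)
  expect_error(quantify_targeted(s, library = lib),
               class = "hypoxiaNMR_ill_conditioned")
})

test_that("total-concentration normalization sums to 1 and is scale-free", {
  eff <- default_effect_table()
  tab <- simulate_concentrations(study_design(), eff, cv = 0.1, seed = 4)
  norm <- normalize_total(tab)
  v <- conc_values(norm)
  mask <- attr(norm, "missing_mask")
  sums <- vapply(seq_len(nrow(v)), function(i) sum(v[i, !mask[i, ]]), 0)
  expect_equal(sums, rep(1, nrow(v)), tolerance = 1e-9)

  # scaling a sample's raw values leaves its normalized row unchanged
  scaled <- tab
  mets <- colnames(v)
  scaled[3, mets] <- as.numeric(tab[3, mets]) * 3
  attr(scaled, "missing_mask") <- attr(tab, "missing_mask")
  norm2 <- normalize_total(scaled)
  expect_equal(as.numeric(conc_values(norm2)[3, ]), as.numeric(v[3, ]),
               tolerance = 1e-12)

  # single-metabolite sample normalizes to exactly 1
  single <- tab[, c("sample_id", "condition", "time_point", "replicate", "lactate")]
  class(single) <- class(tab)
  attr(single, "missing_mask") <- attr(tab, "missing_mask")[, "lactate", drop = FALSE]
  expect_equal(unname(conc_values(normalize_total(single))[, 1]),
               rep(1, nrow(single)))
})

test_that("fold changes follow the signed-ratio convention", {
  # 3 + 3 toy: hypoxia median exactly half the normoxia median
  tab <- data.frame(
    sample_id = sprintf("s%d", 1:6),
    condition = rep(c("hypoxia", "normoxia"), each = 3),
    time_point = "48h", replicate = rep(1:3, 2),
    a = c(1, 2, 3, 2, 4, 6),       # ratio 0.5 -> signed -2
    b = c(2, 4, 6, 1, 2, 3),       # ratio 2   -> signed +2
    d = c(1, 2, 3, 1, 2, 3)        # equal medians -> +1
  )
  class(tab) <- c("concentration_table", "data.frame")
  fc <- fold_changes(tab)
  expect_equal(fc$signed_ratio[fc$metabolite == "a"], -2)
  expect_equal(fc$log2_value[fc$metabolite == "a"], -1)
  expect_equal(fc$signed_ratio[fc$metabolite == "b"], 2)
  expect_equal(fc$signed_ratio[fc$metabolite == "d"], 1)
  expect_equal(fc$log2_value[fc$metabolite == "d"], 0)
  # internal consistency of the two representations
  expect_equal(fc$log2_value, sign(fc$signed_ratio) * log2(abs(fc$signed_ratio)))
})

test_that("fold changes are antisymmetric under group swap", {
  eff <- default_effect_table()
  for (seed in 1:5) {
    tab <- simulate_concentrations(study_design(), eff, cv = 0.1, seed = seed)
    fc <- fold_changes(tab)
    swapped <- tab
    swapped$condition <- ifelse(tab$condition == "hypoxia", "normoxia", "hypoxia")
    attr(swapped, "missing_mask") <- attr(tab, "missing_mask")
    fs <- fold_changes(swapped)
    ok <- !fc$missing
    expect_equal(fs$signed_ratio[ok], -fc$signed_ratio[ok], tolerance = 1e-12)
    expect_equal(fs$log2_value[ok], -fc$log2_value[ok], tolerance = 1e-12)
    expect_identical(fs$missing, fc$missing)
  }
})

test_that("log2 fold-change estimates recover the planted panel effects", {
  eff <- default_effect_table()
  errs <- matrix(NA_real_, 200, 17)
  truth <- eff$`48h`
  for (s in 1:200) {
    tab <- simulate_concentrations(study_design(time_points = "48h"), eff,
                                   cv = 0.1, seed = 10000 + s)
    fc <- fold_changes(tab)
    fc <- fc[match(eff$metabolite, fc$metabolite), ]
    errs[s, ] <- abs(fc$log2_value - sign(truth) * log2(abs(truth)))
  }
  mae <- colMeans(errs, na.rm = TRUE)
  names(mae) <- eff$metabolite
  expect_true(all(mae[!is.na(truth)] < 0.15))
})

test_that("heatmap matrix masks undetectable cells and round-trips CSV", {
  eff <- default_effect_table()
  tab <- simulate_concentrations(study_design(), eff, cv = 0.1, seed = 6)
  fc <- fold_changes(tab)
  m <- heatmap_matrix(fc)
  expect_true(attr(m, "missing_mask")["glucose", "48h"])
  expect_true(attr(m, "missing_mask")["pyruvate", "4h"])
  expect_true(is.na(m["glucose", "48h"]))

  # a +2 signed ratio maps to a cell value of exactly 1
  rec <- data.frame(metabolite = "lactate", time_point = "48h",
                    signed_ratio = 2, log2_value = 1, missing = FALSE)
  expect_equal(heatmap_matrix(rec)["lactate", "48h"], 1)

  f <- tempfile(fileext = ".csv")
  write_heatmap_matrix(m, f)
  back <- read_heatmap_matrix(f)
  expect_equal(unclass(back), unclass(m)[rownames(back), colnames(back)],
               tolerance = 1e-12, ignore_attr = TRUE)
})
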