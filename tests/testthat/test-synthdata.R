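# Synthetic study generator: effect table, concentration simulation,
# spectrum rendering, full-study assembly and the pathway fixture.

test_that("default effect table encodes the quoted panel effects", {
  eff <- default_effect_table()
  expect_setequal(eff$metabolite, panel_metabolites())
  expect_identical(effect_lookup(eff, "lactate", "48h"), 1.99)
  expect_identical(effect_lookup(eff, "pyruvate", "48h"), 1.80)
  expect_identical(effect_lookup(eff, "myo-inositol", "48h"), -4.29)
  expect_true(is.na(effect_lookup(eff, "glucose", "48h")))
  expect_true(is.na(effect_lookup(eff, "pyruvate", "4h")))
  expect_error(effect_lookup(eff, "citrate", "48h"), class = "hypoxiaNMR_not_in_panel")
  # magnitudes at least 1, effects strengthen with treatment duration
  expect_true(all(abs(eff[, c("4h", "24h", "48h")]) >= 1, na.rm = TRUE))
  ok <- !is.na(eff$`4h`) & !is.na(eff$`48h`) & eff$metabolite != "glucose"
  expect_true(all(abs(eff$`4h`[ok]) <= abs(eff$`48h`[ok])))
})

test_that("noise-free simulation reproduces configured fold ratios exactly", {
  eff <- default_effect_table()
  tab <- simulate_concentrations(study_design(), eff, cv = 0, seed = 1)
  v <- conc_values(tab)
  for (met in c("lactate", "glutamine", "myo-inositol")) {
    for (tp in c("24h", "48h")) {
      r <- effect_lookup(eff, met, tp)
      hyp <- tab$condition == "hypoxia" & tab$time_point == tp
      nor <- tab$condition == "normoxia" & tab$time_point == tp
      got <- median(v[hyp, met]) / median(v[nor, met])
      expect_equal(got, if (r >= 0) r else 1 / abs(r), tolerance = 1e-12)
    }
  }
  # undetectable entries land below the detection limit in both groups
  mask <- attr(tab, "missing_mask")
  expect_true(all(mask[tab$time_point == "48h", "glucose"]))
  expect_false(any(mask[tab$time_point == "48h", "lactate"]))
})

test_that("simulation is deterministic and unbiased in expectation", {
  eff <- default_effect_table()
  a <- simulate_concentrations(study_design(), eff, cv = 0.1, seed = 7)
  b <- simulate_concentrations(study_design(), eff, cv = 0.1, seed = 7)
  expect_identical(a, b)
  expect_error(simulate_concentrations(study_design(), eff, baseline = -1),
               class = "hypoxiaNMR_bad_baseline")

  # Monte-Carlo oracle: mean of per-replicate median ratios near +1.99
  des <- study_design(time_points = "48h")
  est <- vapply(1:200, function(s) {
    tab <- simulate_concentrations(des, eff, cv = 0.1, seed = s)
    v <- conc_values(tab)
    median(v[tab$condition == "hypoxia", "lactate"]) /
      median(v[tab$condition == "normoxia", "lactate"])
  }, 0)
  expect_lt(abs(mean(est) - 1.99) / 1.99, 0.05)
})

test_that("rendered spectra are additive and linear in concentration", {
  lib <- metabolite_library()
  p <- quiet_params()
  conc0 <- setNames(rep(0, length(lib)), names(lib))
  s0 <- render_spectrum(conc0, lib, p, seed = 1)
  # zero concentrations leave only the TMSP singlet and the water feature
  expect_equal(s0$intensity,
               0.3 * (2 / (pi * 0.003)) / (1 + (2 * s0$ppm / 0.003)^2) +
                 20 * dnorm(s0$ppm, 4.75, 0.07),
               tolerance = 1e-12)

  conc1 <- conc0; conc1["pyruvate"] <- 1
  conc2 <- conc0; conc2["pyruvate"] <- 2
  s1 <- render_spectrum(conc1, lib, p, seed = 1)
  s2 <- render_spectrum(conc2, lib, p, seed = 1)
  reg <- abs(s1$ppm - 2.368) < 0.05
  a1 <- sum((s1$intensity - s0$intensity)[reg])
  a2 <- sum((s2$intensity - s0$intensity)[reg])
  expect_equal(a2 / a1, 2, tolerance = 1e-9)
})

test_that("rendered singlet integral matches the closed-form Lorentzian area", {
  lib <- metabolite_library()
  p <- quiet_params(axis = seq(6, -0.5, by = -0.0005), tmsp_area = 0, water_area = 0)
  conc <- setNames(rep(0, length(lib)), names(lib))
  conc["pyruvate"] <- 2.5
  s <- render_spectrum(conc, lib, p, seed = 1)
  fwhm <- lib$pyruvate$peaks$linewidth[1]
  reg <- abs(s$ppm - 2.368) <= 10 * fwhm
  numeric_area <- sum(s$intensity[reg]) * 0.0005
  analytic <- 2.5 * (2 / pi) * atan(20)   # partial integral over +/- 10 FWHM
  expect_equal(numeric_area, analytic, tolerance = 0.01)
})

test_that("render rejects bad axes and unknown metabolites", {
  lib <- metabolite_library()
  conc <- c(lactate = 1)
  expect_error(render_spectrum(conc, lib, render_params(axis = seq(3, 0, by = -0.001))),
               class = "hypoxiaNMR_bad_axis")   # does not cover 4.4
  bad <- c(seq(10, 5, by = -0.01), seq(4.999, -0.5, by = -0.001))
  expect_error(render_spectrum(conc, lib, render_params(axis = bad)),
               class = "hypoxiaNMR_bad_axis")   # not uniform
  expect_error(render_spectrum(c(unknown = 1), lib), class = "hypoxiaNMR_no_template")
})

test_that("make_study yields the 54-sample design, deterministically", {
  st <- get_study1()
  expect_length(st$spectra, 54)
  counts <- table(st$truth$condition, st$truth$time_point)
  expect_true(all(counts == 9))
  # replicate determinism on a reduced design (byte-identical outputs)
  d <- study_design(n_per_group = 2, time_points = "48h")
  s1 <- make_study(seed = 11, design = d)
  s2 <- make_study(seed = 11, design = d)
  expect_identical(s1, s2)
})

test_that("spectrum text serialization round-trips", {
  st <- make_study(seed = 3, design = study_design(n_per_group = 1, time_points = "4h"))
  f <- tempfile(fileext = ".txt")
  write_spectrum(st$spectra[[1]], f)
  back <- read_spectrum(f)
  expect_equal(back$ppm, st$spectra[[1]]$ppm, tolerance = 1e-12)
  expect_equal(back$intensity, st$spectra[[1]]$intensity, tolerance = 1e-6)
  expect_identical(back$sample_id, st$spectra[[1]]$sample_id)
  expect_identical(back$condition, st$spectra[[1]]$condition)
})

test_that("pathway fixture reproduces the reference membership structure", {
  td <- file.path(tempdir(), "fixture-test")
  fx <- make_pathway_fixture(td)
  ref <- pathway_membership_reference()
  expect_length(fx$kgml_files, nrow(ref))
  expect_length(readLines(fx$gene_list), 66)

  recs <- parse_kgml(fx$kgml_files)
  panel <- read.delim(fx$panel)
  met <- unique(map_metabolites(panel, recs)$pathway_id)
  trans <- unique(suppressWarnings(
    map_genes(readLines(fx$gene_list), read_gene_map(fx$gene_map), recs))$pathway_id)
  expect_setequal(met, ref$pathway_id[ref$metabolome])
  expect_setequal(trans, ref$pathway_id[ref$transcriptome])

  # referential closure: every panel compound appears in some pathway file
  all_compounds <- unique(unlist(lapply(recs, `[[`, "compounds")))
  expect_true(all(panel$compound_id %in% all_compounds))
})
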