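# Generator determinism, degenerate noise settings, config validation,
# and small recovery checks against the ground-truth sidecars.

test_that("fixed seed gives identical outputs for every generator", {
  cfg <- generator_config(seed = 42, n_animals_per_group = 2,
                          flux = list(n_replicates = 1),
                          omics = list(n_proteins = 30L, n_up = 3L,
                                       n_down = 2L),
                          cage = list(duration_h = 50))
  for (gen in list(function(c) gen_flux_plate(c, "coupling-CI"),
                   gen_cage_trace, gen_abundance_table, gen_qpcr)) {
    a <- gen(cfg); b <- gen(cfg)
    expect_identical(a, b)
  }
  # different seeds differ
  cfg2 <- generator_config(seed = 43, n_animals_per_group = 2,
                           flux = list(n_replicates = 1))
  expect_false(identical(gen_flux_plate(cfg, "coupling-CI")$ticks,
                         gen_flux_plate(cfg2, "coupling-CI")$ticks))
})

test_that("generator substreams are independent of each other", {
  cfg <- generator_config(seed = 5, n_animals_per_group = 2,
                          flux = list(n_replicates = 1),
                          cage = list(duration_h = 50))
  tr1 <- gen_cage_trace(cfg)
  invisible(gen_flux_plate(cfg, "coupling-CII"))  # interleaved draw
  tr2 <- gen_cage_trace(cfg)
  expect_identical(tr1, tr2)
})

test_that("zero noise and zero drift reproduce phase means exactly", {
  cfg <- generator_config(seed = 1, n_animals_per_group = 2,
                          flux = list(noise_cv = 0, animal_cv = 0,
                                      drift_per_tick = 0, cs_cv = 0,
                                      n_replicates = 1))
  pl <- gen_flux_plate(cfg, "coupling-CI")
  truth <- attr(pl, "truth")
  for (g in c("Ctrl", "Cvs")) {
    wids <- pl$wells$well_id[pl$wells$group == g]
    tk <- pl$ticks[pl$ticks$well_id %in% wids, ]
    means <- truth$group_state_means[[g]]
    proto <- pl$protocol$phases
    for (i in seq_len(nrow(proto)))
      expect_true(all(tk$ocr_pmol_min[tk$phase == proto$phase[i]] ==
                        means[[proto$state[i]]]))
  }
})

test_that("within-phase drift tilts ticks linearly", {
  cfg <- generator_config(seed = 1, n_animals_per_group = 2,
                          flux = list(noise_cv = 0, animal_cv = 0,
                                      drift_per_tick = -2,
                                      n_replicates = 1))
  pl <- gen_flux_plate(cfg, "coupling-CI")
  v <- pl$ticks$ocr_pmol_min[pl$ticks$well_id == "W001" &
                               pl$ticks$phase == "adp"]
  expect_equal(diff(v), rep(-2, 2))
})

test_that("unknown assay kinds are rejected with the known protocols", {
  cfg <- generator_config(seed = 1)
  expect_error(gen_flux_plate(cfg, "glycolysis-stress"),
               "coupling-CI.*coupling-CII.*electron-flow")
})

test_that("cage trace respects the configured circadian contrast", {
  cfg <- generator_config(seed = 6, n_animals_per_group = 3)
  tr <- gen_cage_trace(cfg)
  expect_equal(nrow(tr$bins), 6 * 144)   # 72 h of 30-min bins
  ps <- circadian_phase_summary(tr)
  # configured dark EE above light EE for every animal
  wide <- reshape(ps[ps$phase != "total", c("animal_id", "phase", "ee")],
                  idvar = "animal_id", timevar = "phase",
                  direction = "wide")
  expect_true(all(wide$ee.dark > wide$ee.light))
})

test_that("flat cage settings at RER 1 give pure carbohydrate oxidation", {
  cfg <- generator_config(seed = 2, n_animals_per_group = 2,
    cage = list(sin_amplitude_frac = 0, noise_cv = 0, rer_sd = 0,
                rer_light = c(Ctrl = 1, Cvs = 1),
                rer_dark = c(Ctrl = 1, Cvs = 1)))
  d <- derive_metabolic_series(gen_cage_trace(cfg))
  expect_true(all(d$cho_mg_min > 0))
  expect_true(all(d$fao_mg_min == 0))
})

test_that("VCO2 is RER(t) times VO2(t) by construction", {
  cfg <- generator_config(seed = 3, n_animals_per_group = 2,
                          cage = list(rer_sd = 0))
  tr <- gen_cage_trace(cfg)
  d <- derive_metabolic_series(tr)
  expect_equal(unique(round(d$rer[d$phase == "light" &
                                    d$group == "Ctrl"], 10)), 0.93)
  expect_equal(unique(round(d$rer[d$phase == "dark" &
                                    d$group == "Cvs"], 10)), 0.91)
})

test_that("noise-free qPCR recovers the programmed ratio exactly", {
  cfg <- generator_config(seed = 4,
                          qpcr = list(replicate_sd = 0,
                                      true_ratio = c(Ctrl = 1, Cvs = 1)))
  mt <- mtdna_ratio(gen_qpcr(cfg))
  expect_equal(mt$ratio, rep(1, 10))
  cfg2 <- generator_config(seed = 4,
                           qpcr = list(replicate_sd = 0,
                                       true_ratio = c(Ctrl = 2, Cvs = 2)))
  rec <- gen_qpcr(cfg2)
  # one Ct per doubling: Nd1 exactly one cycle below Lpl per animal
  for (a in unique(rec$animal_id))
    expect_equal(mean(rec$ct[rec$animal_id == a & rec$gene == "Nd1"]),
                 mean(rec$ct[rec$animal_id == a & rec$gene == "Lpl"]) - 1)
})

test_that("noisy qPCR group means recover truth within 15%", {
  ratios <- sapply(1:60, function(s) {
    cfg <- generator_config(seed = s,
                            qpcr = list(replicate_sd = 0.2))
    mt <- mtdna_ratio(gen_qpcr(cfg))
    tapply(mt$ratio, mt$group, mean)
  })
  expect_lt(abs(mean(ratios["Ctrl", ]) - 1.0) / 1.0, 0.15)
  expect_lt(abs(mean(ratios["Cvs", ]) - 1.25) / 1.25, 0.15)
})

test_that("identical-sample abundance table yields no fold change", {
  cfg <- generator_config(seed = 9,
                          omics = list(n_proteins = 25L, n_up = 0L,
                                       n_down = 0L, log2_sd_within = 0))
  mat <- gen_abundance_table(cfg)
  de <- de_filter(mat, attr(mat, "groups"))
  expect_equal(de$table$fold_change, rep(1, 25))
  expect_false(any(de$table$significant))
})

test_that("null tables keep the raw-p false-positive rate near alpha", {
  ps <- unlist(lapply(1:100, function(s) {
    cfg <- generator_config(seed = s,
                            omics = list(n_proteins = 40L, n_up = 0L,
                                         n_down = 0L))
    mat <- gen_abundance_table(cfg)
    de_filter(mat, attr(mat, "groups"))$table$p
  }))
  expect_equal(mean(ps < 0.05), 0.05, tolerance = 0.25)
})

test_that("planted 2-fold proteins are recovered with high power", {
  cfg <- generator_config(seed = 10,
                          omics = list(n_proteins = 200L, n_up = 20L,
                                       n_down = 0L, fold_up = 2,
                                       log2_sd_within = 0.2))
  mat <- gen_abundance_table(cfg)
  truth <- attr(mat, "truth")
  de <- de_filter(mat, attr(mat, "groups"))
  hits <- sum(truth$up %in%
                de$table$protein_id[de$table$significant &
                                      de$table$direction == "up"])
  expect_gte(hits, 18L)
})

test_that("config validation rejects unphysical settings", {
  expect_error(generator_config(n_animals_per_group = 1), ">= 2")
  expect_error(generator_config(flux = list(noise_cv = -0.1)), ">= 0")
  expect_error(generator_config(omics = list(fold_up = 0)), "positive")
  expect_error(generator_config(qpcr = list(true_ratio = c(Ctrl = -1,
                                                           Cvs = 1))),
               "positive")
  expect_error(generator_config(flux = list(bogus = 1)), "unknown")
  expect_error({
    cfg <- generator_config(cage = list(bin_minutes = 50))
    gen_cage_trace(cfg)
  }, "divide")
})

test_that("sidecars are written as JSON and analysis ignores them", {
  cfg <- generator_config(seed = 12, n_animals_per_group = 2,
                          flux = list(n_replicates = 1))
  pl <- gen_flux_plate(cfg, "coupling-CI")
  f <- tempfile(fileext = ".json")
  write_truth_sidecar(pl, f)
  truth <- jsonlite::read_json(f)
  expect_equal(truth$kind, "flux_plate")
  expect_equal(truth$group_state_means$Cvs$state3, 67.5)
  expect_error(write_truth_sidecar(list(), f), "no ground-truth")
})
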