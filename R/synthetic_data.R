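# Seeded synthetic-data generators for all four input kinds (plate OCR
# traces, metabolic-cage traces, protein abundance tables, qPCR Ct
# tables), each with a ground-truth sidecar so downstream recovery can be
# scored without re-deriving truth. Analysis code never reads sidecars.

# Independent RNG substream per generator: substream seed derived from
# (master seed, generator name) so adding a generator does not shift the
# draws of the others.
substream_seed <- function(master, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(master) * 48271 + h) %% (2^31 - 1))
}

with_substream <- function(master, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(substream_seed(master, name))
  expr
}

default_flux_block <- function() {
  list(
    # per-group phase-mean OCR (pmol O2/min); magnitudes follow the study
    # conditions: CI state3 -55%, state2 -40%, state3u -42% in Cvs;
    # CII state2 -36%, state3 -56%, state3u -47%; leak (state4o) set so
    # Ctrl-CI couples above q_p, Ctrl-CII below q_p, Cvs-CII above q_p_ec.
    state_means = list(
      "coupling-CI" = list(
        Ctrl = c(state2 = 50, state3 = 150, state4o = 20,
                 state3u = 130, residual = 3),
        Cvs  = c(state2 = 30, state3 = 67.5, state4o = 8,
                 state3u = 75.4, residual = 3)),
      "coupling-CII" = list(
        Ctrl = c(state2 = 45, state3 = 120, state4o = 25,
                 state3u = 110, residual = 3),
        Cvs  = c(state2 = 28.8, state3 = 52.8, state4o = 2.6,
                 state3u = 58.3, residual = 3)),
      "electron-flow" = list(
        Ctrl = c(basal_uncoupled = 130, post_inhibition = 65,
                 post_stimulation = 120, post_antimycin = 5,
                 post_tmpd = 180),
        Cvs  = c(basal_uncoupled = 70.2, post_inhibition = 35,
                 post_stimulation = 30, post_antimycin = 5,
                 post_tmpd = 160))),
    noise_cv = 0.05,         # tick-level technical noise, CV
    animal_cv = 0.05,        # between-animal biological CV per state
    drift_per_tick = 0,      # additive pmol/min per tick within a phase
    state4o_shift = 0,       # additive shift of state4o means (negative
                             # values exercise the RCR offset rule)
    n_replicates = 3L,       # technical replicate wells per animal
    ticks_per_phase = 3L,
    protein_ug = 2.5, protein_cv = 0,
    cs_activity_mean = 1, cs_cv = 0.05)
}

default_cage_block <- function() {
  list(
    bw_g = c(Ctrl = 25, Cvs = 23), bw_cv = 0.04,
    # phase-level EE targets (ml/min/g^0.75) and RER; the square-wave
    # light/dark contrast carries the circadian structure, a small
    # sinusoid modulates within phases.
    ee_light = c(Ctrl = 6.2, Cvs = 6.0),
    ee_dark  = c(Ctrl = 8.2, Cvs = 6.6),
    rer_light = c(Ctrl = 0.93, Cvs = 0.87),
    rer_dark  = c(Ctrl = 0.97, Cvs = 0.91),
    sin_amplitude_frac = 0.05,
    noise_cv = 0.03,          # VO2 measurement noise, CV
    rer_sd = 0.02,            # per-bin RER noise (absolute)
    activity_light = c(Ctrl = 6, Cvs = 8),     # mean counts per bin
    activity_dark  = c(Ctrl = 16.5, Cvs = 26),
    food_g_per_day = c(Ctrl = 3.5, Cvs = 4.2), dark_food_frac = 0.7,
    light_onset = 6, phase_hours = 12, bin_minutes = 30,
    duration_h = 72, start = "2026-01-01T06:00:00",
    diet_kj_per_g = 12.9)
}

default_omics_block <- function() {
  list(n_proteins = 1090L, n_samples_per_group = 5L,
       log2_mean = 20, log2_sd_between = 1.5, log2_sd_within = 0.25,
       n_up = 73L, n_down = 13L, fold_up = 2.0, fold_down = 2.0)
}

default_qpcr_block <- function() {
  list(n_animals_per_group = 5L, n_replicates = 3L,
       ct_nuclear = 22, animal_sd = 0.3, replicate_sd = 0.15,
       true_ratio = c(Ctrl = 1.0, Cvs = 1.25))
}

#' Configuration for the synthetic-data generators
#'
#' Defaults encode the study conditions the analysis targets: 6 animals
#' per group in technical triplicate on the plate, 72 h of 30-min cage
#' bins starting at 06:00, 1090 quantified proteins with 73 up / 13 down
#' truly differential at 2-fold in 5 samples per group, and qPCR Ct
#' triplicates from 5 animals per group. Any block entry can be
#' overridden by passing a partial list.
#'
#' @param seed master seed; each generator derives its own substream
#'   from (seed, generator name).
#' @param n_animals_per_group animals per group (>= 2) for plate and
#'   cage data.
#' @param groups group labels; the second is the treated group.
#' @param flux,cage,omics,qpcr partial lists overriding the block
#'   defaults (see the package vignette for every field).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_animals_per_group = 6L,
                             groups = c("Ctrl", "Cvs"),
                             flux = list(), cage = list(),
                             omics = list(), qpcr = list()) {
  if (n_animals_per_group < 2L)
    stop("n_animals_per_group must be >= 2")
  if (length(groups) != 2L || anyDuplicated(groups))
    stop("exactly two distinct group labels required")
  merge_block <- function(defaults, user) {
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    defaults[names(user)] <- user
    defaults
  }
  cfg <- structure(list(seed = as.integer(seed),
                        n_animals_per_group = as.integer(n_animals_per_group),
                        groups = groups,
                        flux = merge_block(default_flux_block(), flux),
                        cage = merge_block(default_cage_block(), cage),
                        omics = merge_block(default_omics_block(), omics),
                        qpcr = merge_block(default_qpcr_block(), qpcr)),
                   class = "generator_config")
  for (cv in c(cfg$flux$noise_cv, cfg$flux$animal_cv, cfg$flux$protein_cv,
               cfg$flux$cs_cv, cfg$cage$noise_cv, cfg$cage$bw_cv))
    if (cv < 0) stop("coefficients of variation must be >= 0")
  if (cfg$omics$fold_up <= 0 || cfg$omics$fold_down <= 0)
    stop("fold-changes must be positive")
  if (any(cfg$qpcr$true_ratio <= 0)) stop("true ratios must be positive")
  cfg
}

#' Simulate a plate-format OCR assay
#'
#' One well per animal x technical replicate. Each well's tick series is
#' phase mean (group mean x per-animal biological effect) + linear
#' within-phase drift + Gaussian tick noise at the configured CV. The
#' true per-group state means are attached as a ground-truth sidecar
#' (attribute `"truth"`), never read by analysis code.
#'
#' @param config a [generator_config()].
#' @param assay_kind `"coupling-CI"`, `"coupling-CII"` or
#'   `"electron-flow"`.
#' @return a [plate_assay()] with attribute `"truth"`.
#' @export
gen_flux_plate <- function(config,
                           assay_kind = c("coupling-CI", "coupling-CII",
                                          "electron-flow")) {
  stopifnot(inherits(config, "generator_config"))
  fb <- config$flux
  known <- names(fb$state_means)
  if (!is.character(assay_kind) || !assay_kind[1L] %in% known)
    stop("unknown assay_kind '", assay_kind[1L], "'; known protocols: ",
         paste(known, collapse = ", "))
  assay_kind <- assay_kind[1L]
  proto <- injection_protocol(assay_kind,
                              ticks_per_phase = fb$ticks_per_phase)
  means <- fb$state_means[[assay_kind]]
  stopifnot(identical(names(means), config$groups) ||
              all(config$groups %in% names(means)))

  with_substream(config$seed, paste0("flux:", assay_kind), {
    wells <- list(); ticks <- list(); wi <- 0L
    for (g in config$groups) {
      gm <- means[[g]][proto$phases$state]
      if ("state4o" %in% names(gm))
        gm["state4o"] <- gm["state4o"] + fb$state4o_shift
      for (a in seq_len(config$n_animals_per_group)) {
        animal <- sprintf("%s_%02d", g, a)
        am <- gm * (1 + stats::rnorm(length(gm), 0, fb$animal_cv))
        for (r in seq_len(fb$n_replicates)) {
          wi <- wi + 1L
          wid <- sprintf("W%03d", wi)
          protein <- fb$protein_ug * (1 + stats::rnorm(1, 0, fb$protein_cv))
          cs <- fb$cs_activity_mean * (1 + stats::rnorm(1, 0, fb$cs_cv))
          wells[[wi]] <- data.frame(
            well_id = wid, animal_id = animal, group = g, replicate = r,
            protein_ug = protein, cs_activity = max(cs, 1e-6),
            stringsAsFactors = FALSE)
          tick_rows <- lapply(seq_len(nrow(proto$phases)), function(i) {
            ph <- proto$phases$phase[i]
            n_ticks <- proto$ticks_per_phase
            base <- am[proto$phases$state[i]]
            v <- base + fb$drift_per_tick * (seq_len(n_ticks) - 1L) +
              stats::rnorm(n_ticks, 0, fb$noise_cv * abs(base))
            data.frame(well_id = wid, phase = ph,
                       tick_index = seq_len(n_ticks),
                       time_min = (i - 1L) * n_ticks * 6 +
                         seq_len(n_ticks) * 6,
                       ocr_pmol_min = v, stringsAsFactors = FALSE)
          })
          ticks[[wi]] <- do.call(rbind, tick_rows)
        }
      }
    }
    plate <- plate_assay(do.call(rbind, wells), do.call(rbind, ticks),
                         proto)
    attr(plate, "truth") <- list(
      kind = "flux_plate", assay_kind = assay_kind,
      group_state_means = lapply(means, as.list),
      noise_cv = fb$noise_cv, animal_cv = fb$animal_cv,
      drift_per_tick = fb$drift_per_tick,
      state4o_shift = fb$state4o_shift,
      n_animals_per_group = config$n_animals_per_group,
      n_replicates = fb$n_replicates, seed = config$seed)
    plate
  })
}

#' Simulate a metabolic-cage trace
#'
#' Per-bin VO2 follows a square-wave light/dark contrast (phase-level EE
#' targets x bw^0.75) modulated by a within-phase sinusoid, with
#' multiplicative measurement noise; VCO2 = RER(t) * VO2(t) with a
#' phase-dependent RER plus per-bin noise. Activity counts are Poisson
#' per bin, food intake accumulates per bin with a dark-phase bias.
#'
#' @param config a [generator_config()].
#' @return a [cage_trace()] with attribute `"truth"`.
#' @export
gen_cage_trace <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cb <- config$cage
  if ((cb$phase_hours * 60) %% cb$bin_minutes != 0)
    stop("bin width must divide the light/dark period")
  if (cb$duration_h < 48 + 2 * cb$bin_minutes / 60)
    stop("duration must cover a full 48-h window plus margin")
  n_bins <- as.integer(cb$duration_h * 60 / cb$bin_minutes)
  t0 <- as.POSIXct(cb$start, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  stamps <- t0 + (seq_len(n_bins) - 1L) * cb$bin_minutes * 60
  hr <- as.numeric(format(stamps, "%H")) +
        as.numeric(format(stamps, "%M")) / 60
  in_light <- ((hr - cb$light_onset) %% (2 * cb$phase_hours)) <
    cb$phase_hours
  elapsed_h <- as.numeric(difftime(stamps, t0, units = "hours"))
  sinus <- sin(2 * pi * elapsed_h / 24)
  bins_per_day <- 24 * 60 / cb$bin_minutes

  with_substream(config$seed, "cage", {
    rows <- list(); i <- 0L
    for (g in config$groups) {
      for (a in seq_len(config$n_animals_per_group)) {
        i <- i + 1L
        animal <- sprintf("%s_%02d", g, a)
        bw <- cb$bw_g[[g]] * (1 + stats::rnorm(1, 0, cb$bw_cv))
        ee <- ifelse(in_light, cb$ee_light[[g]], cb$ee_dark[[g]])
        vo2 <- ee * bw^0.75 * (1 + cb$sin_amplitude_frac * sinus) *
          (1 + stats::rnorm(n_bins, 0, cb$noise_cv))
        vo2 <- pmax(vo2, 1e-6)
        rer <- ifelse(in_light, cb$rer_light[[g]], cb$rer_dark[[g]]) +
          stats::rnorm(n_bins, 0, cb$rer_sd)
        act_mean <- ifelse(in_light, cb$activity_light[[g]],
                           cb$activity_dark[[g]])
        food_rate <- cb$food_g_per_day[[g]] / bins_per_day *
          ifelse(in_light, 2 * (1 - cb$dark_food_frac),
                 2 * cb$dark_food_frac)
        rows[[i]] <- data.frame(
          animal_id = animal, group = g, timestamp = stamps,
          vo2_ml_min = vo2, vco2_ml_min = rer * vo2,
          activity_counts = stats::rpois(n_bins, act_mean),
          food_g = pmax(food_rate *
                          (1 + stats::rnorm(n_bins, 0, 0.2)), 0),
          bw_g = bw, stringsAsFactors = FALSE)
      }
    }
    trace <- cage_trace(do.call(rbind, rows),
                        light_onset = cb$light_onset,
                        phase_hours = cb$phase_hours)
    attr(trace, "truth") <- list(
      kind = "cage_trace",
      ee_light = as.list(cb$ee_light), ee_dark = as.list(cb$ee_dark),
      rer_light = as.list(cb$rer_light), rer_dark = as.list(cb$rer_dark),
      rer_total = as.list((unlist(cb$rer_light) +
                             unlist(cb$rer_dark)) / 2),
      food_g_per_day = as.list(cb$food_g_per_day),
      diet_kj_per_g = cb$diet_kj_per_g, seed = config$seed)
    trace
  })
}

#' Simulate a label-free protein abundance table
#'
#' Log-normal abundances: per-protein baseline log2 level drawn from a
#' between-protein normal, per-sample values with within-group Gaussian
#' log2 noise. The designated truly-differential proteins are shifted by
#' the configured fold-change in the treated group (up for the first
#' `n_up`, down for the next `n_down`). Truth sidecar lists the
#' designated sets.
#'
#' @param config a [generator_config()].
#' @return proteins x samples matrix (linear scale) with attributes
#'   `"groups"` (sample -> group) and `"truth"`.
#' @export
gen_abundance_table <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  ob <- config$omics
  if (ob$fold_up <= 0 || ob$fold_down <= 0)
    stop("fold-changes must be positive")
  if (ob$n_up + ob$n_down > ob$n_proteins)
    stop("designated DE set exceeds the protein universe")
  with_substream(config$seed, "omics", {
    ids <- sprintf("P%05d", seq_len(ob$n_proteins))
    samples <- c(sprintf("%s_s%d", config$groups[1L],
                         seq_len(ob$n_samples_per_group)),
                 sprintf("%s_s%d", config$groups[2L],
                         seq_len(ob$n_samples_per_group)))
    groups <- rep(config$groups, each = ob$n_samples_per_group)
    base <- stats::rnorm(ob$n_proteins, ob$log2_mean, ob$log2_sd_between)
    x <- matrix(stats::rnorm(ob$n_proteins * length(samples),
                             mean = base, sd = ob$log2_sd_within),
                nrow = ob$n_proteins, dimnames = list(ids, samples))
    up_ids <- ids[seq_len(ob$n_up)]
    down_ids <- ids[ob$n_up + seq_len(ob$n_down)]
    trt <- groups == config$groups[2L]
    x[up_ids, trt] <- x[up_ids, trt] + log2(ob$fold_up)
    x[down_ids, trt] <- x[down_ids, trt] - log2(ob$fold_down)
    mat <- 2^x
    attr(mat, "groups") <- stats::setNames(groups, samples)
    attr(mat, "truth") <- list(kind = "abundance_table",
                               up = up_ids, down = down_ids,
                               fold_up = ob$fold_up,
                               fold_down = ob$fold_down,
                               seed = config$seed)
    mat
  })
}

#' Simulate qPCR Ct triplicates for the mtDNA/nDNA ratio
#'
#' Per animal, the nuclear-gene Ct is drawn around the configured mean
#' (between-animal SD shifts both genes equally, so it cancels in the
#' ratio); the mitochondrial-gene Ct sits `log2(true ratio)` cycles
#' below it. Replicates add Gaussian noise.
#'
#' @param config a [generator_config()].
#' @return `qpcr_records` data frame with attribute `"truth"`.
#' @export
gen_qpcr <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  qb <- config$qpcr
  if (qb$n_replicates < 1L) stop("replicate count must be >= 1")
  with_substream(config$seed, "qpcr", {
    rows <- list(); i <- 0L
    for (g in config$groups) {
      for (a in seq_len(qb$n_animals_per_group)) {
        i <- i + 1L
        animal <- sprintf("%s_%02d", g, a)
        ct_n <- qb$ct_nuclear + stats::rnorm(1, 0, qb$animal_sd)
        ct_m <- ct_n - log2(qb$true_ratio[[g]])
        rows[[i]] <- data.frame(
          animal_id = animal, group = g,
          gene = rep(c("Nd1", "Lpl"), each = qb$n_replicates),
          replicate = rep(seq_len(qb$n_replicates), 2L),
          ct = c(ct_m + stats::rnorm(qb$n_replicates, 0, qb$replicate_sd),
                 ct_n + stats::rnorm(qb$n_replicates, 0, qb$replicate_sd)),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("qpcr_records", "data.frame")
    attr(out, "truth") <- list(kind = "qpcr",
                               true_ratio = as.list(qb$true_ratio),
                               seed = config$seed)
    out
  })
}

#' Write a generator's ground-truth sidecar to JSON
#'
#' Sidecars exist to score downstream recovery; analysis functions never
#' read them.
#'
#' @param obj an object produced by a `gen_*` function.
#' @param path output JSON path.
#' @export
write_truth_sidecar <- function(obj, path) {
  truth <- attr(obj, "truth")
  if (is.null(truth)) stop("object carries no ground-truth sidecar")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
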