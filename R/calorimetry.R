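# Indirect calorimetry: per-bin RER / energy expenditure / substrate
# oxidation from metabolic-cage gas exchange, summarized over a 48-h
# circadian window split into light and dark phases.

# Protein-free substrate-oxidation coefficients (g/min with VO2, VCO2 in
# L/min): CHO = 4.585*VCO2 - 3.2255*VO2 ; FAO = 1.6946*VO2 - 1.7012*VCO2.
OXIDATION_COEF <- c(cho_vco2 = 4.585, cho_vo2 = 3.2255,
                    fao_vo2 = 1.6946, fao_vco2 = 1.7012)

CAGE_COLUMNS <- c("animal_id", "group", "timestamp", "vo2_ml_min",
                  "vco2_ml_min", "activity_counts", "food_g", "bw_g")

#' Construct a cage trace from a bin table
#'
#' @param bins data frame with columns `animal_id, group, timestamp
#'   (POSIXct or ISO 8601), vo2_ml_min, vco2_ml_min, activity_counts,
#'   food_g, bw_g`; equally spaced bins per animal.
#' @param light_onset clock hour at which the light phase begins
#'   (default 6, i.e. 06:00).
#' @param phase_hours length of each of the light and dark phases
#'   (default 12).
#' @return object of class `cage_trace`.
#' @export
cage_trace <- function(bins, light_onset = 6, phase_hours = 12) {
  bins <- as.data.frame(bins)
  missing_cols <- setdiff(CAGE_COLUMNS, names(bins))
  if (length(missing_cols))
    stop("cage table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!inherits(bins$timestamp, "POSIXct"))
    bins$timestamp <- as.POSIXct(bins$timestamp, tz = "UTC",
                                 format = "%Y-%m-%dT%H:%M:%S")
  if (anyNA(bins$timestamp)) stop("unparseable timestamps in cage table")
  bins <- bins[order(bins$animal_id, bins$timestamp), ]
  for (a in unique(bins$animal_id)) {
    dt <- diff(as.numeric(bins$timestamp[bins$animal_id == a]))
    if (any(dt <= 0)) stop("timestamps not strictly increasing for ", a)
    if (length(unique(dt)) > 1L) stop("bins not equally spaced for ", a)
  }
  if (any(bins$vo2_ml_min < 0)) stop("negative VO2 in cage table")
  bin_minutes <- diff(as.numeric(bins$timestamp[
    bins$animal_id == bins$animal_id[1L]]))[1L] / 60
  if ((phase_hours * 60) %% bin_minutes != 0)
    stop("bin width (", bin_minutes, " min) does not divide the ",
         phase_hours, "-h light/dark phase")
  hr <- as.numeric(format(bins$timestamp, "%H")) +
        as.numeric(format(bins$timestamp, "%M")) / 60
  # ties at exact onset belong to light
  in_light <- ((hr - light_onset) %% (2 * phase_hours)) < phase_hours
  bins$phase <- ifelse(in_light, "light", "dark")
  rownames(bins) <- NULL
  structure(list(bins = bins, light_onset = light_onset,
                 phase_hours = phase_hours, bin_minutes = bin_minutes),
            class = "cage_trace")
}

#' Read a cage trace CSV
#' @param path CSV with the [cage_trace()] bin columns.
#' @inheritParams cage_trace
#' @export
read_cage_trace <- function(path, light_onset = 6, phase_hours = 12) {
  cage_trace(utils::read.csv(path, stringsAsFactors = FALSE),
             light_onset = light_onset, phase_hours = phase_hours)
}

#' Write a cage trace to CSV
#' @param trace a [cage_trace()]. @param path output path.
#' @export
write_cage_trace <- function(trace, path) {
  df <- trace$bins[, CAGE_COLUMNS]
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-bin metabolic series: RER, EE, CHO, FAO
#'
#' RER = VCO2/VO2. EE = VO2 normalized to metabolic body size,
#' VO2 / bw^0.75 (ml/min/g^0.75). Carbohydrate and fat oxidation use the
#' protein-free equations (VO2, VCO2 in L/min, output g/min, reported
#' here in mg/min):
#' CHO = 4.585 VCO2 - 3.2255 VO2, FAO = 1.6946 VO2 - 1.7012 VCO2.
#' Negative oxidation rates are clamped to zero with a per-bin flag; raw
#' values are retained in `cho_raw` / `fao_raw`. Bins with VO2 = 0 have
#' all derived values masked (`NA`) and are flagged, never dropped.
#'
#' @param trace a [cage_trace()].
#' @param bw body weight in g used for the metabolic-size exponent;
#'   default is each animal's mean recorded body weight.
#' @return the trace's bin table with added columns `rer`,
#'   `ee_ml_min_g075`, `cho_mg_min`, `fao_mg_min`, `cho_raw`, `fao_raw`,
#'   `clamped`, `masked`.
#' @export
derive_metabolic_series <- function(trace, bw = NULL) {
  stopifnot(inherits(trace, "cage_trace"))
  df <- trace$bins
  if (is.null(bw)) {
    bw_by <- tapply(df$bw_g, df$animal_id, mean)
    bw <- as.numeric(bw_by[as.character(df$animal_id)])
  } else {
    if (any(bw <= 0)) stop("bw must be positive")
    bw <- rep_len(bw, nrow(df))
  }
  vo2_l <- df$vo2_ml_min / 1000
  vco2_l <- df$vco2_ml_min / 1000
  masked <- df$vo2_ml_min == 0
  rer <- ifelse(masked, NA_real_, df$vco2_ml_min / df$vo2_ml_min)
  cho_raw <- 1000 * (OXIDATION_COEF["cho_vco2"] * vco2_l -
                     OXIDATION_COEF["cho_vo2"] * vo2_l)
  fao_raw <- 1000 * (OXIDATION_COEF["fao_vo2"] * vo2_l -
                     OXIDATION_COEF["fao_vco2"] * vco2_l)
  cho_raw[masked] <- fao_raw[masked] <- NA_real_
  df$rer <- rer
  df$ee_ml_min_g075 <- ifelse(masked, NA_real_, df$vo2_ml_min / bw^0.75)
  df$cho_raw <- unname(cho_raw)
  df$fao_raw <- unname(fao_raw)
  df$cho_mg_min <- pmax(df$cho_raw, 0)
  df$fao_mg_min <- pmax(df$fao_raw, 0)
  df$clamped <- !masked & (cho_raw < 0 | fao_raw < 0)
  df$masked <- masked
  df
}

#' Circadian phase summary over the first two complete light/dark cycles
#'
#' Selects exactly the window `[first light onset, + window_h)` from the
#' trace (default 48 h, two complete 12 h light + 12 h dark cycles) and
#' summarizes per animal per phase (light, dark, total): mean EE, RER,
#' CHO, FAO and summed activity. `total` is the duration-weighted
#' combination of the phases. RER means outside `[0.6, 1.3]` trigger a
#' warning.
#'
#' @param trace a [cage_trace()].
#' @param series optional [derive_metabolic_series()] output for the
#'   trace (recomputed if omitted).
#' @param window_h circadian window length in hours (default 48).
#' @return object of class `phase_summary`: data frame, one row per
#'   animal x phase, with attribute `window` (start, end).
#' @export
circadian_phase_summary <- function(trace, series = NULL, window_h = 48) {
  stopifnot(inherits(trace, "cage_trace"))
  if (is.null(series)) series <- derive_metabolic_series(trace)
  ts0 <- min(series$timestamp)
  # first bin at/after the configured light onset
  hr <- as.numeric(format(series$timestamp, "%H")) +
        as.numeric(format(series$timestamp, "%M")) / 60
  onset_idx <- which(series$phase == "light" &
                     ((hr - trace$light_onset) %% 24) <
                       trace$bin_minutes / 60)
  if (!length(onset_idx)) stop("no light-phase onset found in trace")
  start <- min(series$timestamp[onset_idx])
  end <- start + window_h * 3600
  avail_h <- as.numeric(difftime(max(series$timestamp), start,
                                 units = "hours")) +
             trace$bin_minutes / 60
  if (avail_h < window_h)
    stop("trace covers only ", round(avail_h, 1), " h after the first ",
         "light onset; ", window_h, " h required (short by ",
         round(window_h - avail_h, 1), " h)")
  win <- series[series$timestamp >= start & series$timestamp < end, ]

  summarize <- function(d, phase_label) {
    data.frame(phase = phase_label,
               n_bins = nrow(d),
               ee = mean(d$ee_ml_min_g075, na.rm = TRUE),
               rer = mean(d$rer, na.rm = TRUE),
               cho_mg_min = mean(d$cho_mg_min, na.rm = TRUE),
               fao_mg_min = mean(d$fao_mg_min, na.rm = TRUE),
               activity = sum(d$activity_counts),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(win, win$animal_id), function(d) {
    lt <- summarize(d[d$phase == "light", ], "light")
    dk <- summarize(d[d$phase == "dark", ], "dark")
    wl <- lt$n_bins / (lt$n_bins + dk$n_bins)
    tot <- data.frame(phase = "total", n_bins = lt$n_bins + dk$n_bins,
                      ee = wl * lt$ee + (1 - wl) * dk$ee,
                      rer = wl * lt$rer + (1 - wl) * dk$rer,
                      cho_mg_min = wl * lt$cho_mg_min + (1 - wl) * dk$cho_mg_min,
                      fao_mg_min = wl * lt$fao_mg_min + (1 - wl) * dk$fao_mg_min,
                      activity = lt$activity + dk$activity,
                      stringsAsFactors = FALSE)
    res <- rbind(lt, dk, tot)
    res$animal_id <- d$animal_id[1L]
    res$group <- d$group[1L]
    res
  }))
  rownames(out) <- NULL
  out <- out[, c("animal_id", "group", "phase", "n_bins", "ee", "rer",
                 "cho_mg_min", "fao_mg_min", "activity")]
  bad_rer <- !is.na(out$rer) & (out$rer < 0.6 | out$rer > 1.3)
  if (any(bad_rer))
    warning("phase-mean RER outside the [0.6, 1.3] sanity band for ",
            sum(bad_rer), " row(s)")
  attr(out, "window") <- c(start = start, end = end)
  class(out) <- c("phase_summary", "data.frame")
  out
}

#' Energy intake and weight change per convertible energy
#'
#' @param food_g per-bin (or per-measurement) food intake increments, g.
#' @param bw_before,bw_after body weight (g) at window start and end.
#' @param diet_kj_per_g metabolizable energy density of the diet, kJ/g.
#' @return list with `intake_kj`, `intake_kj_per_g_bw` (using the mean of
#'   before/after BW), `delta_bw_mg`, `mg_per_kj` (weight change per
#'   convertible energy; `NA` with a flag when intake is zero).
#' @export
intake_metrics <- function(food_g, bw_before, bw_after, diet_kj_per_g) {
  if (diet_kj_per_g <= 0) stop("diet energy density must be positive")
  intake_kj <- sum(food_g) * diet_kj_per_g
  delta_mg <- (bw_after - bw_before) * 1000
  mean_bw <- (bw_before + bw_after) / 2
  if (intake_kj == 0) {
    return(list(intake_kj = 0, intake_kj_per_g_bw = 0,
                delta_bw_mg = delta_mg, mg_per_kj = NA_real_,
                zero_intake = TRUE))
  }
  list(intake_kj = intake_kj,
       intake_kj_per_g_bw = intake_kj / mean_bw,
       delta_bw_mg = delta_mg,
       mg_per_kj = delta_mg / intake_kj,
       zero_intake = FALSE)
}
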