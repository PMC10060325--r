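# Hand-built miniature fixtures shared across test files.

# A coupling plate with fully specified tick values: `states` is a named
# list well_id -> named list phase -> numeric tick vector.
make_plate <- function(states,
                       meta = NULL,
                       protocol = injection_protocol("coupling-CI")) {
  wids <- names(states)
  if (is.null(meta))
    meta <- data.frame(well_id = wids,
                       animal_id = paste0("A", seq_along(wids)),
                       group = "Ctrl", replicate = 1L,
                       protein_ug = 2.5, cs_activity = 1,
                       stringsAsFactors = FALSE)
  ticks <- do.call(rbind, lapply(wids, function(w) {
    ph <- names(states[[w]])
    do.call(rbind, lapply(seq_along(ph), function(i) {
      v <- states[[w]][[i]]
      data.frame(well_id = w, phase = ph[i],
                 tick_index = seq_along(v),
                 time_min = (i - 1) * 100 + seq_along(v) * 6,
                 ocr_pmol_min = v, stringsAsFactors = FALSE)
    }))
  }))
  plate_assay(meta, ticks, protocol)
}

# default phases for a coupling plate, all ticks constant per state
coupling_phases <- function(state2 = 50, state3 = 150, state4o = 20,
                            state3u = 130, residual = 3, n = 3) {
  list(basal = rep(state2, max(n, 2)), adp = rep(state3, n),
       oligomycin = rep(state4o, n), fccp = rep(state3u, n),
       antimycin = rep(residual, n))
}

# a small cage bin table with explicit per-bin values
make_cage_bins <- function(vo2, rer, start = "2026-01-01T06:00:00",
                           animal = "A1", group = "Ctrl", bw = 25,
                           bin_minutes = 30) {
  n <- length(vo2)
  t0 <- as.POSIXct(start, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  data.frame(animal_id = animal, group = group,
             timestamp = t0 + (seq_len(n) - 1) * bin_minutes * 60,
             vo2_ml_min = vo2, vco2_ml_min = rer * vo2,
             activity_counts = 1L, food_g = 0.05, bw_g = bw,
             stringsAsFactors = FALSE)
}
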