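# Plate-format extracellular-flux (OCR) assay handling: injection
# protocols, plate parsing/validation, respiration-state extraction and
# protein / citrate-synthase normalization.

PLATE_COLUMNS <- c("well_id", "animal_id", "group", "replicate",
                   "assay_kind", "phase", "tick_index", "time_min",
                   "ocr_pmol_min", "protein_ug", "cs_activity")

#' Injection protocols for plate-based respirometry
#'
#' `"coupling-CI"` and `"coupling-CII"` run the classical coupling
#' sequence on complex I (pyruvate/malate + malonate) or complex II
#' (succinate + rotenone) substrates:
#' basal (state 2) -> ADP (state 3) -> oligomycin (state 4o) ->
#' FCCP (state 3u) -> antimycin A (residual).
#' `"electron-flow"` runs on FCCP-uncoupled mitochondria:
#' basal -> complex inhibitor -> complex substrate -> antimycin ->
#' TMPD/ascorbate.
#'
#' @param name one of `"coupling-CI"`, `"coupling-CII"`, `"electron-flow"`.
#' @param ticks_per_phase measurement cycles recorded per phase.
#' @param equilibration_cycles instrument mix/rest cycles before the first
#'   recorded basal measurement (excluded from all phases).
#' @return object of class `injection_protocol` with `name`, `phases`
#'   (data frame: phase, compound, state), `equilibration_cycles`.
#' @export
injection_protocol <- function(name = c("coupling-CI", "coupling-CII",
                                        "electron-flow"),
                               ticks_per_phase = 3L,
                               equilibration_cycles = 2L) {
  known <- c("coupling-CI", "coupling-CII", "electron-flow")
  if (!is.character(name) || !name[1L] %in% known)
    stop("unknown assay kind '", name[1L], "'; known protocols: ",
         paste(known, collapse = ", "))
  name <- name[1L]
  phases <- if (name == "electron-flow") {
    data.frame(
      phase = c("basal", "inhibitor", "substrate", "antimycin", "tmpd"),
      compound = c("FCCP (uncoupled basal)", "rotenone or malonate",
                   "pyruvate/malate or succinate", "antimycin A",
                   "TMPD/ascorbate"),
      state = c("basal_uncoupled", "post_inhibition", "post_stimulation",
                "post_antimycin", "post_tmpd"),
      stringsAsFactors = FALSE)
  } else {
    substrate <- if (name == "coupling-CI") "pyruvate/malate (+ malonate)"
                 else "succinate (+ rotenone)"
    data.frame(
      phase = c("basal", "adp", "oligomycin", "fccp", "antimycin"),
      compound = c(substrate, "ADP 2 mmol/l", "oligomycin 2 umol/l",
                   "FCCP 6 umol/l", "antimycin A 2 umol/l"),
      state = c("state2", "state3", "state4o", "state3u", "residual"),
      stringsAsFactors = FALSE)
  }
  structure(list(name = name, phases = phases,
                 ticks_per_phase = as.integer(ticks_per_phase),
                 equilibration_cycles = as.integer(equilibration_cycles)),
            class = "injection_protocol")
}

#' Construct a validated plate assay object
#'
#' @param wells data frame: `well_id`, `animal_id`, `group`, `replicate`,
#'   `protein_ug`, `cs_activity`.
#' @param ticks data frame: `well_id`, `phase`, `tick_index`, `time_min`,
#'   `ocr_pmol_min`.
#' @param protocol an [injection_protocol()].
#' @return object of class `plate_assay`.
#' @export
plate_assay <- function(wells, ticks, protocol) {
  stopifnot(inherits(protocol, "injection_protocol"))
  wells <- as.data.frame(wells)
  ticks <- as.data.frame(ticks)
  if (anyDuplicated(wells$well_id))
    stop("duplicate well_id in wells table")
  if (any(wells$protein_ug <= 0))
    stop("protein_ug must be positive for every well")
  if (any(wells$cs_activity <= 0))
    stop("cs_activity must be positive for every well")
  unknown <- setdiff(unique(ticks$phase), protocol$phases$phase)
  if (length(unknown))
    stop("unknown phase label(s) for protocol '", protocol$name, "': ",
         paste(unknown, collapse = ", "))
  key <- paste(ticks$well_id, ticks$phase, ticks$tick_index)
  if (anyDuplicated(key))
    stop("duplicate (well, phase, tick) rows: ",
         paste(which(duplicated(key))[1:min(3, sum(duplicated(key)))],
               collapse = ", "))
  # canonical ordering: protocol phase order, then tick index
  ticks$phase <- factor(ticks$phase, levels = protocol$phases$phase)
  ticks <- ticks[order(ticks$well_id, ticks$phase, ticks$tick_index), ]
  for (w in unique(ticks$well_id)) {
    tm <- ticks$time_min[ticks$well_id == w]
    if (any(diff(tm) <= 0))
      stop("tick times not strictly increasing within well ", w)
    missing_ph <- setdiff(protocol$phases$phase,
                          unique(as.character(ticks$phase[ticks$well_id == w])))
    if (length(missing_ph))
      stop("well ", w, " is missing phase(s): ",
           paste(missing_ph, collapse = ", "))
  }
  ticks$phase <- as.character(ticks$phase)
  rownames(wells) <- rownames(ticks) <- NULL
  structure(list(wells = wells, ticks = ticks, protocol = protocol),
            class = "plate_assay")
}

#' Read a plate assay from its flat CSV form
#'
#' Expected columns: `well_id, animal_id, group, replicate, assay_kind,
#' phase, tick_index, time_min, ocr_pmol_min, protein_ug, cs_activity`.
#' Row order does not matter; rows are keyed by (well, phase, tick).
#'
#' @param path CSV path.
#' @param protocol an [injection_protocol()]; defaults to the protocol
#'   named in the file's `assay_kind` column.
#' @return a [plate_assay()].
#' @export
read_plate <- function(path, protocol = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PLATE_COLUMNS, names(df))
  if (length(missing_cols))
    stop("plate file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  kinds <- unique(df$assay_kind)
  if (length(kinds) != 1L)
    stop("plate file mixes assay kinds: ", paste(kinds, collapse = ", "))
  if (is.null(protocol)) protocol <- injection_protocol(kinds)
  if (protocol$name != kinds)
    stop("file assay_kind '", kinds, "' does not match protocol '",
         protocol$name, "'")
  wells <- unique(df[, c("well_id", "animal_id", "group", "replicate",
                         "protein_ug", "cs_activity")])
  if (anyDuplicated(wells$well_id))
    stop("inconsistent well metadata across rows of the same well")
  ticks <- df[, c("well_id", "phase", "tick_index", "time_min",
                  "ocr_pmol_min")]
  plate_assay(wells, ticks, protocol)
}

#' Write a plate assay to its flat CSV form
#' @param plate a [plate_assay()].
#' @param path output CSV path.
#' @export
write_plate <- function(plate, path) {
  stopifnot(inherits(plate, "plate_assay"))
  df <- merge(plate$ticks, plate$wells, by = "well_id", sort = FALSE)
  df$assay_kind <- plate$protocol$name
  df <- df[order(df$well_id,
                 match(df$phase, plate$protocol$phases$phase),
                 df$tick_index), PLATE_COLUMNS]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract respiration states from a plate assay
#'
#' The basal state is the *second* basal-phase measurement (the first is
#' an equilibration check). Every other state is summarized by the phase
#' statistic: the mean of the phase's ticks (default) or the last tick.
#' Technical replicate wells of one animal are averaged after state
#' extraction, so downstream statistics run at n = animals.
#'
#' @param plate a [plate_assay()].
#' @param phase_stat `"mean"` or `"last"` for non-basal phases.
#' @param antimycin_correct subtract the post-antimycin (residual,
#'   non-mitochondrial) rate from the other states. Off by default.
#' @return object of class `respiration_states`: list with `states`
#'   (animal-level data frame), `well_states`, `assay_kind`, `phase_stat`,
#'   `normalized` flag and `normalization` record.
#' @export
extract_states <- function(plate, phase_stat = c("mean", "last"),
                           antimycin_correct = FALSE) {
  stopifnot(inherits(plate, "plate_assay"))
  phase_stat <- match.arg(phase_stat)
  proto <- plate$protocol
  ticks <- plate$ticks

  one_well <- function(w) {
    wt <- ticks[ticks$well_id == w, ]
    vals <- vapply(seq_len(nrow(proto$phases)), function(i) {
      ph <- proto$phases$phase[i]
      v <- wt$ocr_pmol_min[wt$phase == ph][order(wt$tick_index[wt$phase == ph])]
      if (!length(v)) stop("empty phase '", ph, "' in well ", w)
      if (ph == "basal") {
        if (length(v) < 2L)
          stop("well ", w, ": fewer than 2 basal ticks; the second basal ",
               "measurement defines the basal state")
        v[2L]
      } else if (phase_stat == "mean") mean(v) else v[length(v)]
    }, numeric(1))
    names(vals) <- proto$phases$state
    vals
  }

  ws <- t(vapply(plate$wells$well_id, one_well,
                 numeric(nrow(proto$phases))))
  well_states <- data.frame(plate$wells[, c("well_id", "animal_id",
                                            "group", "replicate")],
                            ws, row.names = NULL, check.names = FALSE)
  if (antimycin_correct) {
    resid_col <- if (proto$name == "electron-flow") "post_antimycin"
                 else "residual"
    st_cols <- setdiff(proto$phases$state, resid_col)
    well_states[st_cols] <- well_states[st_cols] - well_states[[resid_col]]
  }

  agg <- stats::aggregate(well_states[proto$phases$state],
                          by = list(animal_id = well_states$animal_id,
                                    group = well_states$group),
                          FUN = mean)
  agg <- agg[order(agg$group, agg$animal_id), ]
  rownames(agg) <- NULL
  structure(list(states = agg, well_states = well_states,
                 assay_kind = proto$name, phase_stat = phase_stat,
                 antimycin_corrected = antimycin_correct,
                 normalized = FALSE, normalization = character(0)),
            class = "respiration_states")
}

#' Normalize respiration states by protein load and citrate-synthase activity
#'
#' Each well's states are divided first by its relative protein load
#' (`protein_ug / reference_ug`) and then by its citrate-synthase
#' activity (a mitochondrial-content marker), after which technical
#' replicates are re-averaged per animal. The operation refuses to run
#' twice; the normalization chain is recorded in the result.
#'
#' @param states a non-normalized [extract_states()] result.
#' @param plate the plate the states came from (source of normalizers).
#' @param reference_ug reference protein load per well (default 2.5 ug).
#' @return a `respiration_states` object with `normalized = TRUE`.
#' @export
normalize_states <- function(states, plate, reference_ug = 2.5) {
  stopifnot(inherits(states, "respiration_states"),
            inherits(plate, "plate_assay"))
  if (states$normalized)
    stop("states are already normalized (double normalization refused)")
  if (reference_ug <= 0) stop("reference_ug must be positive")
  st_cols <- plate$protocol$phases$state
  ws <- states$well_states
  idx <- match(ws$well_id, plate$wells$well_id)
  protein <- plate$wells$protein_ug[idx]
  cs <- plate$wells$cs_activity[idx]
  if (any(protein <= 0) || any(cs <= 0))
    stop("nonpositive normalizer (protein_ug or cs_activity)")
  ws[st_cols] <- ws[st_cols] / (protein / reference_ug) / cs
  agg <- stats::aggregate(ws[st_cols],
                          by = list(animal_id = ws$animal_id,
                                    group = ws$group),
                          FUN = mean)
  agg <- agg[order(agg$group, agg$animal_id), ]
  rownames(agg) <- NULL
  states$states <- agg
  states$well_states <- ws
  states$normalized <- TRUE
  states$normalization <- c(states$normalization,
                            sprintf("protein/%g ug", reference_ug),
                            "cs_activity")
  states
}

#' Group summary of an electron-flow (or coupling) assay
#'
#' Per-state group means and the percent change of the treatment group
#' relative to the reference group, with the normality-gated group test
#' from [compare_groups()] per state.
#'
#' @param states a `respiration_states` object.
#' @param reference reference group label (default `"Ctrl"`).
#' @param treatment treatment group label (default the other group).
#' @return data frame with one row per state: group means, percent
#'   change `100 * (treatment - reference) / reference`, test name and p.
#' @export
electron_flow_summary <- function(states, reference = "Ctrl",
                                  treatment = NULL) {
  stopifnot(inherits(states, "respiration_states"))
  df <- states$states
  groups <- unique(df$group)
  if (!reference %in% groups)
    stop("reference group '", reference, "' absent from states")
  if (is.null(treatment)) treatment <- setdiff(groups, reference)[1L]
  if (is.na(treatment) || !treatment %in% groups)
    stop("treatment group absent from states")
  if (sum(df$group == reference) < 2L || sum(df$group == treatment) < 2L)
    stop("need >= 2 animals per group")
  st_cols <- setdiff(names(df), c("animal_id", "group"))
  rows <- lapply(st_cols, function(st) {
    ref <- df[[st]][df$group == reference]
    trt <- df[[st]][df$group == treatment]
    cmpr <- compare_groups(c(ref, trt),
                           rep(c(reference, treatment),
                               c(length(ref), length(trt))))
    data.frame(state = st,
               mean_ref = mean(ref), mean_trt = mean(trt),
               percent_change = 100 * (mean(trt) - mean(ref)) / mean(ref),
               test = cmpr$test_name, p = cmpr$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "reference") <- reference
  attr(out, "treatment") <- treatment
  out
}

#' @export
print.respiration_states <- function(x, ...) {
  cat("Respiration states (", x$assay_kind, "), ",
      nrow(x$states), " animals, phase stat = ", x$phase_stat,
      if (x$normalized) ", normalized by " else ", raw",
      if (x$normalized) paste(x$normalization, collapse = " then "),
      "\n", sep = "")
  print(utils::head(x$states))
  invisible(x)
}
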