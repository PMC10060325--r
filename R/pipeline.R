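# End-to-end orchestration: one YAML config drives simulate -> flux ->
# bioenergetics -> calorimetry -> omics -> statistics, with per-stage CSV
# outputs, a machine-readable JSON summary and a reproducibility
# manifest. Same config + seed => byte-identical summary.

DATA_KINDS <- c("flux_ci", "flux_cii", "cage", "abundance", "qpcr")

default_run_options <- function() {
  list(phase_stat = "mean", antimycin_correct = FALSE,
       epsilon = "auto", q_policy = "clamp",
       fold_threshold = 1.5, alpha = 0.05, ease_method = "ease",
       reference = "Ctrl", window_h = 48)
}

#' Build a pipeline run configuration
#'
#' Each data kind (`flux_ci`, `flux_cii`, `cage`, `abundance`, `qpcr`)
#' comes from exactly one source: a path in `inputs`, or the simulation
#' block. Configs round-trip losslessly through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param seed master seed for simulation.
#' @param simulate `NULL`, or a list of [generator_config()] arguments
#'   (excluding `seed`).
#' @param inputs named list of file paths per data kind; `pathways` may
#'   name a GMT file used for enrichment.
#' @param options module options overriding [default_run_options()].
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, simulate = list(), inputs = list(),
                       options = list()) {
  bad <- setdiff(names(inputs), c(DATA_KINDS, "pathways", "sample_map"))
  if (length(bad)) stop("unknown input kind(s): ",
                        paste(bad, collapse = ", "))
  opts <- default_run_options()
  unknown <- setdiff(names(options), names(opts))
  if (length(unknown)) stop("unknown option(s): ",
                            paste(unknown, collapse = ", "))
  opts[names(options)] <- options
  sim_on <- !is.null(simulate)
  for (kind in DATA_KINDS) {
    from_file <- kind %in% names(inputs)
    if (from_file && sim_on)
      stop("data kind '", kind, "' is configured from both an input ",
           "path and the simulation block; choose one")
    if (!from_file && !sim_on)
      stop("data kind '", kind, "' has neither an input path nor a ",
           "simulation block")
  }
  structure(list(seed = as.integer(seed), simulate = simulate,
                 inputs = inputs, options = opts),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`. @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  run_config(seed = raw$seed,
             simulate = raw$simulate,
             inputs = if (is.null(raw$inputs)) list() else raw$inputs,
             options = if (is.null(raw$options)) list() else raw$options)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

log_stage <- function(quiet, ...) if (!quiet) message("[mitothermics] ", ...)

round_df <- function(df, digits = 6) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Run the full analysis pipeline
#'
#' Stages: acquire data (simulate or read) -> respiration-state
#' extraction and normalization for the two coupling assays ->
#' RCR / coupling degree / optimal efficiency with set-point bands ->
#' circadian calorimetry summary -> differential abundance, enrichment
#' and mtDNA ratio -> normality-gated group statistics with BH
#' correction. Per-stage CSVs, `summary.json` and `manifest.json` are
#' written to `out_dir`.
#'
#' @param config a [run_config()] (or path to its YAML form).
#' @param out_dir output directory (created if needed).
#' @param quiet suppress stage log messages.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  opts <- config$options
  ref <- opts$reference
  summary <- list(seed = config$seed)

  gcfg <- NULL
  if (!is.null(config$simulate))
    gcfg <- do.call(generator_config,
                    c(list(seed = config$seed), config$simulate))

  get_plate <- function(kind, assay) {
    if (!is.null(config$inputs[[kind]]))
      read_plate(config$inputs[[kind]])
    else {
      plate <- gen_flux_plate(gcfg, assay)
      write_plate(plate, file.path(out_dir, paste0(kind, "_plate.csv")))
      write_truth_sidecar(plate,
                          file.path(out_dir, paste0(kind, "_truth.json")))
      plate
    }
  }

  epsilon <- if (identical(opts$epsilon, "auto")) NULL
             else as.numeric(opts$epsilon)

  # --- flux + bioenergetics, complex I and II coupling assays
  for (cx in c("flux_ci", "flux_cii")) {
    assay <- if (cx == "flux_ci") "coupling-CI" else "coupling-CII"
    log_stage(quiet, "stage flux/", assay)
    plate <- tryCatch(get_plate(cx, assay),
                      error = function(e) stop("stage flux(", assay,
                                               ") failed: ",
                                               conditionMessage(e)))
    st <- extract_states(plate, phase_stat = opts$phase_stat,
                         antimycin_correct = opts$antimycin_correct)
    st <- normalize_states(st, plate)
    utils::write.csv(round_df(st$states),
                     file.path(out_dir, paste0(cx, "_states.csv")),
                     row.names = FALSE, quote = FALSE)
    cpl <- thermodynamic_coupling(st$states$state3, st$states$state4o,
                                  sample = st$states$animal_id,
                                  epsilon = epsilon,
                                  q_policy = opts$q_policy)
    cpl$group <- st$states$group
    utils::write.csv(round_df(as.data.frame(cpl)),
                     file.path(out_dir, paste0(cx, "_coupling.csv")),
                     row.names = FALSE, quote = FALSE)
    efs <- electron_flow_summary(st, reference = ref)
    utils::write.csv(round_df(efs),
                     file.path(out_dir, paste0(cx, "_group_summary.csv")),
                     row.names = FALSE, quote = FALSE)
    eta_cmp <- compare_groups(cpl$eta_opt, cpl$group)
    grp_bands <- tapply(cpl$q, cpl$group, function(qv)
      classify_coupling(mean(qv)))
    summary[[cx]] <- list(
      assay_kind = assay,
      group_means = lapply(
        split(st$states[setdiff(names(st$states),
                                c("animal_id", "group"))],
              st$states$group),
        function(d) as.list(round(colMeans(d), 4))),
      percent_change = stats::setNames(
        as.list(round(efs$percent_change, 4)), efs$state),
      offset_applied = round(cpl$offset[1L], 6),
      q_group_means = lapply(tapply(cpl$q, cpl$group, mean), round, 6),
      q_bands = as.list(grp_bands),
      eta_opt_group_means = lapply(tapply(cpl$eta_opt, cpl$group, mean),
                                   round, 6),
      eta_opt_test = list(test = eta_cmp$test_name,
                          p = round(eta_cmp$p, 6)))
  }

  # --- calorimetry
  log_stage(quiet, "stage calorimetry")
  trace <- if (!is.null(config$inputs$cage))
    read_cage_trace(config$inputs$cage)
  else {
    tr <- gen_cage_trace(gcfg)
    write_cage_trace(tr, file.path(out_dir, "cage_trace.csv"))
    write_truth_sidecar(tr, file.path(out_dir, "cage_truth.json"))
    tr
  }
  series <- derive_metabolic_series(trace)
  phases <- circadian_phase_summary(trace, series,
                                    window_h = opts$window_h)
  utils::write.csv(round_df(as.data.frame(phases)),
                   file.path(out_dir, "phase_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  cal <- list()
  for (ph in c("light", "dark", "total")) {
    d <- phases[phases$phase == ph, ]
    cal[[ph]] <- list(
      ee = lapply(tapply(d$ee, d$group, mean), round, 4),
      rer = lapply(tapply(d$rer, d$group, mean), round, 4),
      cho_mg_min = lapply(tapply(d$cho_mg_min, d$group, mean), round, 4),
      fao_mg_min = lapply(tapply(d$fao_mg_min, d$group, mean), round, 4))
  }
  tot <- phases[phases$phase == "total", ]
  cal$tests <- list(
    ee = {
      cmpr <- compare_groups(tot$ee, tot$group)
      list(test = cmpr$test_name, p = round(cmpr$p, 6))
    },
    rer = {
      cmpr <- compare_groups(tot$rer, tot$group)
      list(test = cmpr$test_name, p = round(cmpr$p, 6))
    })
  summary$calorimetry <- cal

  # --- omics
  log_stage(quiet, "stage omics")
  if (!is.null(config$inputs$abundance)) {
    mat <- read_abundance(config$inputs$abundance)
    smap <- utils::read.csv(config$inputs$sample_map,
                            stringsAsFactors = FALSE)
    omics_groups <- stats::setNames(smap$group, smap$sample_id)[colnames(mat)]
  } else {
    mat <- gen_abundance_table(gcfg)
    omics_groups <- attr(mat, "groups")
    write_abundance(mat, file.path(out_dir, "abundance.tsv"))
    write_truth_sidecar(mat, file.path(out_dir, "abundance_truth.json"))
  }
  de <- de_filter(mat, omics_groups, fold_threshold = opts$fold_threshold,
                  alpha = opts$alpha, reference = ref)
  utils::write.csv(round_df(de$table),
                   file.path(out_dir, "de_results.csv"),
                   row.names = FALSE, quote = FALSE)
  summary$omics <- list(n_proteins = nrow(mat),
                        tested = unname(de$summary["tested"]),
                        up = unname(de$summary["up"]),
                        down = unname(de$summary["down"]))
  pathways <- if (!is.null(config$inputs$pathways))
    read_gmt(config$inputs$pathways) else NULL
  if (!is.null(pathways)) {
    enr <- enrich_pathways(
      de$table$protein_id[de$table$significant], pathways,
      rownames(mat), method = opts$ease_method)
    utils::write.csv(round_df(enr),
                     file.path(out_dir, "enrichment.csv"),
                     row.names = FALSE, quote = FALSE)
    summary$omics$enriched_q_lt_0.1 <- sum(enr$q < 0.1, na.rm = TRUE)
  }

  # --- qPCR mtDNA ratio
  log_stage(quiet, "stage qpcr")
  qrec <- if (!is.null(config$inputs$qpcr))
    read_qpcr(config$inputs$qpcr)
  else {
    qr <- gen_qpcr(gcfg)
    utils::write.csv(round_df(as.data.frame(qr)),
                     file.path(out_dir, "qpcr.csv"),
                     row.names = FALSE, quote = FALSE)
    write_truth_sidecar(qr, file.path(out_dir, "qpcr_truth.json"))
    qr
  }
  mt <- mtdna_ratio(qrec)
  utils::write.csv(round_df(mt), file.path(out_dir, "mtdna_ratio.csv"),
                   row.names = FALSE, quote = FALSE)
  mt_cmp <- compare_groups(mt$ratio, mt$group)
  summary$mtdna <- list(
    group_means = lapply(tapply(mt$ratio, mt$group, mean), round, 6),
    test = mt_cmp$test_name, p = round(mt_cmp$p, 6))

  # --- manifest + summary
  manifest <- list(package = "mitothermics",
                   version = as.character(utils::packageVersion("mitothermics")),
                   config_hash = config_hash(config),
                   seed = config$seed,
                   options = opts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_stage(quiet, "done: ", out_dir)
  invisible(summary)
}
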