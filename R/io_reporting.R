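# Table readers/writers, the end-to-end pipeline and the JSON report.
#
# All tables are comma-separated UTF-8 text with a mandatory header row and
# "." as decimal separator; undetermined cells are written as an explicit
# marker, never left empty.

intensity_columns <- c("ligand_id", "proton_id", "chemical_shift_ppm",
                       "condition", "saturation_time_s", "intensity_off",
                       "intensity_on", "overlap_flag")

#' Write saturation series to a delimited intensity table
#'
#' Serializes one or more experimental conditions (e.g. `reference`,
#' `probe:diazepam`) to the package's flat intensity-table schema: one row
#' per (proton, condition, saturation time).
#'
#' @param conditions named list: condition name -> list of
#'   [saturation_series()]. Condition names are `"reference"` or
#'   `"probe:<probe_id>"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_intensity_table()]
#' @export
write_intensity_table <- function(conditions, path) {
  if (!is.list(conditions) || is.null(names(conditions)) ||
      any(names(conditions) == ""))
    abort_invalid("conditions must be a named list of series lists")
  rows <- list()
  for (cond in names(conditions)) {
    for (s in conditions[[cond]]) {
      stopifnot(inherits(s, "saturation_series"))
      rows[[length(rows) + 1L]] <- data.frame(
        ligand_id = s$ligand_id, proton_id = s$proton_id,
        chemical_shift_ppm = s$chemical_shift, condition = cond,
        saturation_time_s = s$times, intensity_off = s$i0,
        intensity_on = s$istd, overlap_flag = s$overlap_flag,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an intensity table into saturation series
#'
#' Parses the flat schema written by [write_intensity_table()], validating
#' the header, cell types and key uniqueness; malformed rows are reported
#' with their line numbers. Series are returned sorted by saturation time
#' and grouped by condition. The ligand:protein ratio is not part of the
#' table and must be supplied (it comes from the sample composition).
#'
#' @param path input file path.
#' @param epsilon ligand:protein concentration ratio to attach, > 0.
#' @return Named list: condition -> list of [saturation_series()] keyed by
#'   proton_id.
#' @export
read_intensity_table <- function(path, epsilon) {
  if (!file.exists(path))
    stop_stdbind("stdbind_io_error", paste("file not found:", path))
  if (!is_scalar_number(epsilon) || epsilon <= 0)
    abort_invalid("epsilon must be a positive number")
  tab <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e)
      stop_stdbind("stdbind_schema_error",
                   paste("cannot parse table:", conditionMessage(e))))
  missing <- setdiff(intensity_columns, names(tab))
  if (length(missing))
    stop_stdbind("stdbind_schema_error",
                 paste("missing column(s):", paste(missing, collapse = ", ")))

  # line numbers: header is line 1
  lineno <- seq_len(nrow(tab)) + 1L
  bad <- integer(0)
  num <- list()
  for (col in c("chemical_shift_ppm", "saturation_time_s", "intensity_off",
                "intensity_on")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- union(bad, which(is.na(v) & !is.na(tab[[col]])))
    num[[col]] <- v
  }
  if (length(bad))
    stop_stdbind("stdbind_schema_error",
                 paste("non-numeric cell(s) at line(s):",
                       paste(sort(lineno[bad]), collapse = ", ")))
  key <- paste(tab$ligand_id, tab$proton_id, tab$condition,
               tab$saturation_time_s, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop_stdbind("stdbind_schema_error",
                 paste("duplicate (proton, condition, time) key(s) at line(s):",
                       paste(lineno[dup], collapse = ", ")))

  ov <- tolower(tab$overlap_flag) %in% c("true", "t", "1", "yes")
  out <- list()
  for (cond in unique(tab$condition)) {
    sel <- tab$condition == cond
    series <- list()
    for (pid in unique(tab$proton_id[sel])) {
      i <- which(sel & tab$proton_id == pid)
      i <- i[order(num$saturation_time_s[i])]
      series[[pid]] <- saturation_series(
        ligand_id = tab$ligand_id[i[1L]], proton_id = pid,
        chemical_shift = num$chemical_shift_ppm[i[1L]],
        times = num$saturation_time_s[i], i0 = num$intensity_off[i],
        istd = num$intensity_on[i], epsilon = epsilon,
        overlap_flag = any(ov[i]))
    }
    out[[cond]] <- series
  }
  out
}

#' Read / write dialysis concentration tables
#'
#' Tables with columns `sample_id, method, D_t, D_f, unit`. Concentrations
#' in ug/mL are converted to uM when a molar mass (g/mol) is supplied.
#'
#' @param path file path.
#' @param molar_mass optional molar mass (g/mol) to convert ug/mL to uM.
#' @return data frame with numeric `D_t`, `D_f`.
#' @export
read_dialysis_table <- function(path, molar_mass = NULL) {
  if (!file.exists(path))
    stop_stdbind("stdbind_io_error", paste("file not found:", path))
  tab <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "method", "D_t", "D_f", "unit")
  missing <- setdiff(req, names(tab))
  if (length(missing))
    stop_stdbind("stdbind_schema_error",
                 paste("missing column(s):", paste(missing, collapse = ", ")))
  if (!is.numeric(tab$D_t) || !is.numeric(tab$D_f))
    stop_stdbind("stdbind_schema_error", "D_t and D_f must be numeric")
  conv <- tab$unit == "ug/mL"
  if (any(conv)) {
    if (is.null(molar_mass))
      abort_invalid("table contains ug/mL rows; supply molar_mass (g/mol)")
    tab$D_t[conv] <- tab$D_t[conv] / molar_mass * 1000
    tab$D_f[conv] <- tab$D_f[conv] / molar_mass * 1000
    tab$unit[conv] <- "uM"
  }
  tab
}

#' @rdname read_dialysis_table
#' @param measurements data frame with the dialysis columns.
#' @export
write_dialysis_table <- function(measurements, path) {
  write.csv(measurements, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

default_config <- function() {
  list(
    seed = 1L,
    epsilon = 40,
    schedule = default_schedule(),
    noise = list(intensity_cv = 0.02, concentration_cv = 0.01),
    probe_sites = as.list(default_probe_sites()),
    ambiguity_threshold = 10,
    secondary_tolerance = 10,
    constrain_rate = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes fit -> epitope map -> competition -> site assignment ->
#' binding degree on either simulated data or input tables, collecting the
#' results into a single deterministic report. Stages are gated on the
#' configuration: an NMR stage runs when `simulate` or `intensity_table`
#' is present, the binding-degree stage when `dialysis` is present. A
#' failure in one stage is recorded in `report$errors` without aborting
#' the others.
#'
#' Configuration keys (YAML file or nested list; values shown are
#' defaults): `seed` (1), `epsilon` (40), `schedule` (0.5...6 s),
#' `noise: {intensity_cv: 0.02, concentration_cv: 0.01}`,
#' `probe_sites: {warfarin: site_I, diazepam: site_II}`,
#' `ambiguity_threshold` (10), `secondary_tolerance` (10). Input selection:
#' `simulate: {ligand: "3-CMC"|"4-CMC", probes: [diazepam, warfarin]}` or
#' `intensity_table: <path>`; `dialysis: {simulate: {n_replicates: 5,
#' methods: [ED, UF]}}` or `dialysis: {table: <path>, molar_mass: <g/mol>}`.
#'
#' @param config nested list or path to a YAML configuration file.
#' @return Object of class `analysis_report` (a nested list).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  report <- list(
    provenance = list(
      package = "stdbind",
      version = as.character(packageVersion("stdbind")),
      seed = cfg$seed,
      config = cfg),
    errors = list())

  noise <- noise_model(cfg$noise$intensity_cv, cfg$noise$concentration_cv)

  # mutable state shared with the stage closures (a promise evaluated inside
  # tryCatch cannot reach the function frame with `<<-`)
  state <- new.env(parent = emptyenv())
  state$errors <- list()
  state$truth <- NULL

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      state$errors[[name]] <- conditionMessage(e)
      NULL
    })
  }

  # --- NMR stage -----------------------------------------------------------
  conditions <- NULL
  if (!is.null(cfg$simulate)) {
    conditions <- run_stage("simulate", {
      tmpl <- switch(cfg$simulate$ligand %||% "3-CMC",
                     "3-CMC" = template_3cmc(), "4-CMC" = template_4cmc(),
                     abort_invalid("unknown ligand template"))
      probes <- cfg$simulate$probes %||% c("diazepam", "warfarin")
      conds <- list()
      ref_done <- FALSE
      truth_local <- list()
      for (i in seq_along(probes)) {
        p <- probes[[i]]
        site <- cfg$probe_sites[[p]] %||%
          abort_invalid(paste("no site mapping for probe", p))
        ds <- generate_competition_dataset(
          tmpl, default_competition_system(site), site,
          schedule = as.numeric(cfg$schedule), epsilon = cfg$epsilon,
          noise = noise, seed = cfg$seed + i)
        if (!ref_done) {
          conds$reference <- ds$reference
          ref_done <- TRUE
        }
        conds[[paste0("probe:", p)]] <- ds$with_probe
        truth_local[[p]] <- ds$truth
      }
      state$truth <- truth_local
      conds
    })
  } else if (!is.null(cfg$intensity_table)) {
    conditions <- run_stage("read_intensity_table",
                            read_intensity_table(cfg$intensity_table,
                                                 cfg$epsilon))
  }

  if (!is.null(conditions)) {
    nmr <- run_stage("fit_buildup", {
      if (is.null(conditions$reference))
        abort_invalid("no reference condition present")
      ref <- fit_buildup_set(conditions$reference)
      # competition refits share the reference build-up rate by default
      # (constrain_rate: false reverts to fully free refits)
      ref_for_probes <- if (isTRUE(cfg$constrain_rate)) ref else NULL
      fitsets <- list(reference = ref)
      for (cond in setdiff(names(conditions), "reference"))
        fitsets[[cond]] <- fit_buildup_set(conditions[[cond]],
                                           reference_fits = ref_for_probes)
      out <- list(fit_table = fits_table(ref$fits),
                  epitope_map = epitope_map(ref))
      probe_conds <- grep("^probe:", names(fitsets), value = TRUE)
      if (length(probe_conds) >= 1L) {
        entries <- do.call(rbind, lapply(probe_conds, function(pc) {
          attenuation_ratios(ref, fitsets[[pc]], sub("^probe:", "", pc))
        }))
        class(entries) <- c("competition_entries", "data.frame")
        out$competition_entries <- entries
        out$competition_table <- competition_table(entries)
        if (length(probe_conds) >= 2L)
          out$site_assignment <- assign_sites(
            entries, probe_sites = unlist(cfg$probe_sites),
            ambiguity_threshold = cfg$ambiguity_threshold,
            secondary_tolerance = cfg$secondary_tolerance)
      }
      if (!is.null(state$truth)) out$simulation_truth <- state$truth
      out
    })
    report$nmr <- nmr
  }

  # --- binding-degree stage ------------------------------------------------
  if (!is.null(cfg$dialysis)) {
    report$binding <- run_stage("binding_degree", {
      if (!is.null(cfg$dialysis$table)) {
        meas <- read_dialysis_table(cfg$dialysis$table,
                                    cfg$dialysis$molar_mass)
      } else {
        sim <- cfg$dialysis$simulate %||% list()
        methods <- unlist(sim$methods %||% c("ED", "UF"))
        nrep <- sim$n_replicates %||% 5
        sys <- default_dialysis_system()
        meas <- do.call(rbind, lapply(seq_along(methods), function(i)
          generate_dialysis_dataset(sys, nrep, noise,
                                    seed = cfg$seed + 100 + i,
                                    method = methods[i])$measurements))
      }
      list(measurements = meas, summary = summarize_binding_degree(meas))
    })
  }

  report$errors <- state$errors
  structure(report, class = "analysis_report")
}

#' Serialize an analysis report to JSON
#'
#' Deterministic JSON rendering of a pipeline report: fixed key order,
#' fixed numeric precision, data frames as row arrays. Running the same
#' configuration twice produces byte-identical files.
#'
#' @param report an `analysis_report` from [run_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = 12,
                           dataframe = "rows", na = "null", null = "null",
                           force = TRUE, pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("stdbind analysis report (seed", x$provenance$seed, ")\n")
  if (!is.null(x$nmr)) {
    cat(sprintf("  NMR: %d fitted protons\n", nrow(x$nmr$fit_table)))
    if (!is.null(x$nmr$site_assignment))
      cat(sprintf("  main site: %s (margin %.1f pp)\n",
                  x$nmr$site_assignment$main_site,
                  x$nmr$site_assignment$margin))
  }
  if (!is.null(x$binding)) {
    s <- x$binding$summary
    for (i in seq_len(nrow(s)))
      cat(sprintf("  binding degree (%s): %.1f +/- %.1f %% (n = %d)\n",
                  s$method[i], s$mean_percent[i], s$sd_percent[i], s$n[i]))
  }
  if (length(x$errors))
    cat("  stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
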