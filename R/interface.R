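#' Write effluent series to the package CSV dialect
#'
#' Columns: donor, compound, condition, channel, time_h, conc_nM, censored,
#' flow_out_uL_h. One file can hold any number of series.
#'
#' @param series_list list of [effluent_series()] (possibly nested lists).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_effluent_csv <- function(series_list, path) {
  flat <- list()
  collect <- function(x) {
    if (inherits(x, "effluent_series")) flat[[length(flat) + 1]] <<- x
    else if (is.list(x)) lapply(x, collect)
    invisible(NULL)
  }
  collect(series_list)
  rows <- do.call(rbind, lapply(flat, function(s)
    data.frame(donor = s$donor, compound = s$compound,
               condition = s$condition, channel = s$channel,
               time_h = s$samples$time_h, conc_nM = s$samples$conc_nM,
               censored = s$samples$censored, flow_out_uL_h = s$flow_out)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read effluent series from the package CSV dialect
#'
#' Validates the schema, rejects duplicate (donor, compound, condition,
#' channel, time) rows and non-monotone times, and groups rows back into
#' [effluent_series()] objects.
#'
#' @param path CSV path written by [write_effluent_csv()] (or compatible).
#' @return named list of [effluent_series()].
#' @export
load_effluent_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("donor", "compound", "condition", "channel", "time_h",
              "conc_nM", "censored", "flow_out_uL_h")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("effluent CSV is missing column(s): ", paste(missing, collapse = ", "))
  key <- interaction(df$donor, df$compound, df$condition, df$channel,
                     df$time_h, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (donor, compound, condition, channel, time) rows at row(s): ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "))
  groups <- split(df, interaction(df$donor, df$compound, df$condition,
                                  df$channel, drop = TRUE))
  out <- lapply(groups, function(g) {
    g <- g[order(g$time_h), ]
    effluent_series(donor = g$donor[1], compound = g$compound[1],
                    condition = g$condition[1], channel = g$channel[1],
                    time_h = g$time_h, conc_nM = g$conc_nM,
                    censored = g$censored, flow_out = g$flow_out_uL_h[1])
  })
  out
}

#' Write a plasma PK profile to CSV
#'
#' Columns: time_h, conc_nM, analyte, site, censored; optionally a
#' `conc_ng_mL` column when a molecular weight is supplied.
#'
#' @param profile a [pk_profile()].
#' @param path output CSV path.
#' @param mol_weight optional molecular weight for a mass-unit column.
#' @return `path`, invisibly.
#' @export
write_pk_csv <- function(profile, path, mol_weight = NULL) {
  df <- data.frame(time_h = profile$series$time_h,
                   conc_nM = profile$series$conc_nM,
                   analyte = profile$analyte, site = profile$site,
                   censored = profile$series$censored)
  if (!is.null(mol_weight))
    df$conc_ng_mL <- nM_to_ng_per_mL(df$conc_nM, mol_weight)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full in-vitro-to-in-vivo pipeline on a synthetic donor panel
#'
#' End-to-end orchestration with provenance: generate a synthetic donor
#' panel of effluent series, reduce each donor to clearances, scale active
#' secretion to the whole kidney, predict renal clearance per donor with
#' the mechanistic kidney model, simulate whole-body parent-metabolite
#' kinetics with the panel-mean renal clearance, manufacture synthetic
#' observations, and score the simulation by absolute average fold error.
#' Per-stage CSV/JSON artifacts and a YAML run manifest are written under
#' `output_dir`.
#'
#' @param n_donors donors in the synthetic panel.
#' @param seed integer seed governing all randomness.
#' @param output_dir directory for artifacts (created if needed); `NULL`
#'   skips writing.
#' @param dose parent [dose_regimen()].
#' @param horizon simulation horizon, h.
#' @param obs_cv noise CV of the synthetic observations.
#' @param truth_args extra arguments for [generate_donor_panel()].
#' @return list with `clearances` (per-donor table), `clr_table`,
#'   `simulation` ([simulate_parent_metabolite()] result), `aafe_parent`,
#'   `aafe_metabolite`, and `manifest`.
#' @export
run_full_pipeline <- function(n_donors = 3, seed = 1L, output_dir = NULL,
                              dose = dose_regimen(10, duration_h = 1 / 12),
                              horizon = 24, obs_cv = 0.2,
                              truth_args = list()) {
  panel <- do.call(generate_donor_panel,
                   c(list(n_donors = n_donors, seed = seed), truth_args))
  geometry <- device_geometry()
  reduced <- lapply(seq_along(panel), function(i) {
    arms <- generate_effluent_series(panel[[i]])
    cs <- reduce_donor(arms$control, arms$inhibitor, geometry,
                       nominal_conc = panel[[i]]$vascular_conc_in)
    cs$donor <- sprintf("donor%d", i)
    cs
  })
  cl_table <- do.call(rbind, lapply(reduced, function(cs)
    data.frame(donor = cs$donor,
               cl_app_transport = cs$cl_app_transport,
               cl_app_passive = cs$cl_app_passive,
               cl_int_active = cs$cl_int_active,
               papp_1e6_cm_s = cs$papp)))
  cl_table$cl_secretion_L_h <- scale_secretion(cl_table$cl_int_active)

  phys_k <- kidney_physiology()
  base <- morphine_renal_params()
  cl_table$clr_L_per_h <- vapply(seq_len(nrow(cl_table)), function(i) {
    drug <- base
    drug$papp <- cl_table$papp_1e6_cm_s[i]
    drug$secretion <- split_subsegments(cl_table$cl_secretion_L_h[i], 3)
    simulate_renal_clearance(drug, phys_k)
  }, numeric(1))

  clr_mean <- mean(cl_table$clr_L_per_h)
  parent <- morphine_model(clr = clr_mean)
  parent$renal$secretion <- split_subsegments(
    mean(cl_table$cl_secretion_L_h), 3)
  parent$renal$papp <- mean(cl_table$papp_1e6_cm_s)
  met <- m6g_model()
  sim <- simulate_parent_metabolite(parent, met, dose = dose,
                                    kidney_phys = phys_k, horizon = horizon)
  obs_times <- c(0.25, 0.5, 1, 2, 4, 6, 8, 12, 16, 24)
  obs_times <- obs_times[obs_times <= horizon]
  obs_p <- generate_clinical_pk(sim$parent,
                                obs_noise_model(obs_cv, obs_times, seed = seed + 101))
  obs_m <- generate_clinical_pk(sim$metabolite,
                                obs_noise_model(obs_cv, obs_times, seed = seed + 202))
  aafe_p <- aafe(sim$parent, obs_p)
  aafe_m <- aafe(sim$metabolite, obs_m)

  manifest <- list(
    package_version = as.character(utils::packageVersion("renalmps")),
    seed = seed, n_donors = n_donors,
    dose_mg = dose$amount_mg, horizon_h = horizon,
    clr_mean_L_h = clr_mean,
    aafe_parent = aafe_p$value, aafe_metabolite = aafe_m$value,
    timestamp = format(Sys.time(), tz = "UTC"))

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cl_table, file.path(output_dir, "donor_clearances.csv"),
                     row.names = FALSE)
    write_pk_csv(sim$parent, file.path(output_dir, "parent_profile.csv"),
                 mol_weight = parent$renal$mol_weight)
    write_pk_csv(sim$metabolite, file.path(output_dir, "metabolite_profile.csv"),
                 mol_weight = met$renal$mol_weight)
    jsonlite::write_json(
      list(parent = unclass(aafe_p), metabolite = unclass(aafe_m)),
      file.path(output_dir, "aafe_report.json"), auto_unbox = TRUE)
    yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
  }
  list(clearances = reduced, clr_table = cl_table, simulation = sim,
       aafe_parent = aafe_p, aafe_metabolite = aafe_m, manifest = manifest)
}
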