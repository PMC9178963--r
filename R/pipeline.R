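#' Process one fish's trace into traits, recovery and RMR rows
#'
#' Runs the full single-fish chain: MO2 series construction (segmentation,
#' slope fitting, background correction), trait derivation, recovery
#' kinetics and temperature-binned RMR. RMR uses only cycles recorded
#' after the detected end of EPOC; when EPOC never ends within the trial
#' the RMR table is empty.
#'
#' @param trace an [o2_trace].
#' @param mass_g,fork_length_mm fish morphometrics.
#' @param plan a [cycle_plan].
#' @param background a [background_model].
#' @param bin_width_c RMR temperature bin width, deg C.
#' @param spar optional smoothing parameter override for the recovery
#'   spline.
#' @param r2_floor minimum window r-squared (default 0, keep all).
#' @return A list with `series`, `traits`, `recovery`, `rmr`.
#' @export
process_trial <- function(trace, mass_g, fork_length_mm,
                          plan = cycle_plan(),
                          background = background_model(0, 0),
                          bin_width_c = 1, spar = NULL, r2_floor = 0) {
  series <- build_mo2_series(trace, plan, background,
                             mass_kg = mass_g / 1000, r2_floor = r2_floor)
  traits <- derive_traits(series, mass_g, fork_length_mm)
  rec <- recovery_metrics(series, traits$smr, traits$mmr,
                          traits$mmr_time_s, spar = spar)
  epoc_end_s <- if (isTRUE(rec$crossed_epoc)) {
    traits$mmr_time_s + rec$time_epoc_h * 3600
  } else {
    Inf
  }
  rmr <- if (is.finite(epoc_end_s)) {
    estimate_rmr(series, epoc_end_s, bin_width_c)
  } else {
    data.frame(fish_id = character(), temp_bin_c = numeric(),
               rmr = numeric(), n = integer())
  }
  traits$background_fraction <- attr(series, "background_fraction")
  list(series = series, traits = traits, recovery = rec, rmr = rmr)
}

#' Process a simulated cohort end to end
#'
#' Applies [process_trial()] to every fish in a [simulate_cohort()] result,
#' using each watershed's fitted empty-chamber background model. Per-fish
#' failures are captured and reported rather than aborting the run.
#'
#' @param cohort a `sim_cohort` with traces.
#' @param plan a [cycle_plan]; defaults to the cohort's design.
#' @param bin_width_c RMR bin width, deg C.
#' @param spar optional smoothing override.
#' @return A list with data frames `traits`, `recovery`, `rmr`, `ctmax`,
#'   `failures`, and the list of per-fish `series`.
#' @export
process_cohort <- function(cohort, plan = NULL, bin_width_c = 1,
                           spar = NULL) {
  if (is.null(cohort$traces)) {
    stop("cohort was simulated without traces", call. = FALSE)
  }
  if (is.null(plan)) {
    plan <- cycle_plan(cohort$scenario$design$measure_min,
                       cohort$scenario$design$flush_min)
  }
  traits <- list(); recov <- list(); rmr <- list(); fails <- list()
  series_list <- list()
  for (i in seq_len(nrow(cohort$metadata))) {
    md <- cohort$metadata[i, ]
    fid <- md$fish_id
    res <- tryCatch({
      bgm <- cohort$backgrounds[[md$watershed]]$model
      if (is.null(bgm)) bgm <- background_model(0, 0)
      process_trial(cohort$traces[[fid]], md$mass_g, md$fork_length_mm,
                    plan = plan, background = bgm,
                    bin_width_c = bin_width_c, spar = spar)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[fid]] <- data.frame(fish_id = fid,
                                 error = conditionMessage(res),
                                 stringsAsFactors = FALSE)
      next
    }
    keep <- intersect(c("watershed", "treatment", "mass_g",
                        "fork_length_mm", "treatment_temp_c"), names(md))
    tag <- intersect(c("watershed", "treatment"), names(md))
    traits[[fid]] <- cbind(res$traits, md[keep], row.names = NULL)
    recov[[fid]] <- cbind(res$recovery, md[tag], row.names = NULL)
    if (nrow(res$rmr) > 0) {
      rmr[[fid]] <- cbind(res$rmr, md[tag], row.names = NULL)
    }
    series_list[[fid]] <- res$series
  }
  ctmax <- if (length(cohort$ctmax) > 0) {
    do.call(rbind, lapply(cohort$ctmax, function(r) {
      data.frame(fish_id = r$fish_id, loe_temp_c = r$loe_temp_c,
                 loe_time_min = r$loe_time_min,
                 start_temp_c = r$start_temp_c,
                 ramp_rate_c_per_min = r$ramp_rate_c_per_min,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(fish_id = character(), loe_temp_c = numeric())
  }
  if (nrow(ctmax) > 0) {
    ctmax <- merge(ctmax,
                   cohort$metadata[c("fish_id", "watershed")], by = "fish_id")
  }
  bind <- function(l, template) if (length(l) > 0) {
    out <- do.call(rbind, unname(l)); rownames(out) <- NULL; out
  } else template
  list(traits = bind(traits, NULL),
       recovery = bind(recov, NULL),
       rmr = bind(rmr, data.frame()),
       ctmax = ctmax,
       failures = bind(fails, data.frame(fish_id = character(),
                                         error = character())),
       series = series_list)
}

#' Group statistics over a processed cohort
#'
#' Reproduces the study's comparison structure: Kruskal-Wallis (with
#' Dunn's post hoc where significant) of SMR, MMR, AAS, FAS and time to
#' 50% MMR across treatments within each watershed; one-way ANOVA of
#' mass, length and condition factor across watersheds; and the
#' log-linear RMR-temperature model with per-watershed intercepts.
#'
#' @param processed output of [process_cohort()].
#' @param adjustment Dunn adjustment method.
#' @param alpha significance level (default 0.05).
#' @return A list with `comparisons` (long data frame of test results),
#'   `pairwise` (Dunn tables), and `rmr_model` (an `rmr_model_fit`, or
#'   `NULL` when the RMR table is too small).
#' @export
cohort_stats <- function(processed, adjustment = "none", alpha = 0.05) {
  traits <- merge(processed$traits,
                  processed$recovery[c("fish_id", "time_mmr50_min")],
                  by = "fish_id")
  rows <- list(); pair <- list()
  for (w in unique(traits$watershed)) {
    tw <- traits[traits$watershed == w, ]
    for (trait in c("smr", "mmr", "aas", "fas", "time_mmr50_min")) {
      res <- tryCatch(compare_groups(tw, trait, "treatment", adjustment,
                                     alpha),
                      error = function(e) NULL)
      if (is.null(res)) next
      rows[[paste(w, trait)]] <- data.frame(
        scope = w, trait = trait, test = res$test$method,
        statistic = res$test$statistic, df = res$test$df[1],
        p_value = res$test$p_value, stringsAsFactors = FALSE)
      if (!is.null(res$pairwise)) pair[[paste(w, trait)]] <- res$pairwise
    }
  }
  for (trait in c("mass_g", "fork_length_mm", "condition_k")) {
    groups <- split(traits[[trait]], traits$watershed)
    res <- tryCatch(one_way_anova(groups), error = function(e) NULL)
    if (is.null(res)) next
    rows[[paste("all", trait)]] <- data.frame(
      scope = "all watersheds", trait = trait, test = res$method,
      statistic = res$statistic, df = res$df[1], p_value = res$p_value,
      stringsAsFactors = FALSE)
  }
  rmr_fit <- NULL
  if (!is.null(processed$rmr) && nrow(processed$rmr) >= 10 &&
      length(unique(processed$rmr$watershed)) >= 2) {
    rmr_fit <- fit_rmr_model(data.frame(rmr = processed$rmr$rmr,
                                        temp_c = processed$rmr$temp_bin_c,
                                        watershed = processed$rmr$watershed))
  }
  comp <- do.call(rbind, unname(rows))
  rownames(comp) <- NULL
  list(comparisons = comp, pairwise = pair, rmr_model = rmr_fit)
}

#' Default pipeline configuration
#'
#' @param mode `"simulate"` (default) or `"read-traces"`.
#' @param seed root RNG seed (mandatory in simulate mode).
#' @param ... overrides for any configuration field (see Details).
#' @details Fields: `watersheds`, `n_per_treatment`, `treatments`,
#'   `measure_min`, `flush_min`, `trim_s`, `sample_interval_s`,
#'   `noise_sd`, `bin_width_c`, `fas_threshold`, `adjustment`, `spar`,
#'   `write_traces`, and for read mode `metadata_csv` (a CSV with columns
#'   `fish_id`, `watershed`, `treatment`, `mass_g`, `fork_length_mm`,
#'   `chamber_volume_l`, `trace_path`).
#' @return A list of class `run_config`.
#' @export
default_config <- function(mode = "simulate", seed = 1, ...) {
  cfg <- list(mode = mode, seed = seed,
              watersheds = c("Alsea", "Siletz", "McKenzie", "N. Santiam"),
              n_per_treatment = 8,
              treatments = c("Ambient", "Max", "Climate"),
              measure_min = 6, flush_min = 4, trim_s = 0,
              sample_interval_s = 1, noise_sd = 0.02,
              bin_width_c = 1, fas_threshold = 3, adjustment = "none",
              spar = NULL, write_traces = FALSE, metadata_csv = NULL)
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified fields fall back to [default_config()] values.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(default_config, raw)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or ingest) -> MO2 series -> traits -> recovery ->
#' RMR -> thermal risk -> group statistics, writing plain-CSV tables and a
#' JSON manifest to `outdir`. In simulate mode a rerun with the identical
#' configuration is byte-identical.
#'
#' @param config a `run_config` (or path to a YAML file).
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with all tables plus `manifest`.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("run")) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  plan <- cycle_plan(config$measure_min, config$flush_min, config$trim_s)

  if (config$mode == "simulate") {
    if (is.null(config$seed)) stop("seed is mandatory in simulate mode",
                                   call. = FALSE)
    design <- trial_design(measure_min = config$measure_min,
                           flush_min = config$flush_min,
                           sample_interval_s = config$sample_interval_s,
                           noise_sd = config$noise_sd)
    scen <- default_scenario(watersheds = config$watersheds,
                             n_per_treatment = config$n_per_treatment,
                             treatments = config$treatments,
                             design = design)
    cohort <- simulate_cohort(scen, seed = config$seed)
    if (isTRUE(config$write_traces)) {
      tdir <- file.path(outdir, "traces")
      dir.create(tdir, showWarnings = FALSE)
      for (fid in names(cohort$traces)) {
        write_trace(cohort$traces[[fid]],
                    file.path(tdir, paste0(fid, ".csv")))
      }
    }
    utils::write.csv(cohort$metadata, file.path(outdir, "metadata.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$truth, file.path(outdir, "truth.csv"),
                     row.names = FALSE)
    processed <- process_cohort(cohort, plan, config$bin_width_c,
                                config$spar)
    context <- site_context()
  } else if (config$mode == "read-traces") {
    if (is.null(config$metadata_csv)) {
      stop("read-traces mode needs metadata_csv", call. = FALSE)
    }
    md <- utils::read.csv(config$metadata_csv, stringsAsFactors = FALSE)
    base <- dirname(config$metadata_csv)
    traces <- list()
    for (i in seq_len(nrow(md))) {
      p <- md$trace_path[i]
      if (!file.exists(p)) p <- file.path(base, md$trace_path[i])
      traces[[md$fish_id[i]]] <-
        read_trace(p, chamber_volume_l = md$chamber_volume_l[i],
                   fish_id = md$fish_id[i])
    }
    cohort <- list(metadata = md, traces = traces, ctmax = list(),
                   backgrounds = list(),
                   scenario = list(design = list(measure_min = plan$measure_min,
                                                 flush_min = plan$flush_min)))
    class(cohort) <- "sim_cohort"
    processed <- process_cohort(cohort, plan, config$bin_width_c,
                                config$spar)
    context <- tryCatch(site_context(), error = function(e) NULL)
  } else {
    stop("unknown mode: ", config$mode, call. = FALSE)
  }

  # intermediate tables are written before downstream stages consume them
  utils::write.csv(processed$traits, file.path(outdir, "traits.csv"),
                   row.names = FALSE)
  utils::write.csv(processed$recovery, file.path(outdir, "recovery.csv"),
                   row.names = FALSE)
  utils::write.csv(processed$rmr, file.path(outdir, "rmr.csv"),
                   row.names = FALSE)
  utils::write.csv(processed$failures, file.path(outdir, "failures.csv"),
                   row.names = FALSE)

  risk <- NULL
  if (!is.null(context) && nrow(processed$ctmax) > 0) {
    risk <- risk_metrics(processed$ctmax, processed$traits, context,
                         config$fas_threshold)
    utils::write.csv(risk, file.path(outdir, "risk.csv"), row.names = FALSE)
  }

  stats_out <- NULL
  if (!is.null(processed$traits) &&
      length(unique(processed$traits$treatment)) >= 2) {
    stats_out <- cohort_stats(processed, config$adjustment)
    utils::write.csv(stats_out$comparisons,
                     file.path(outdir, "stats.csv"), row.names = FALSE)
  }

  cfg_path <- file.path(outdir, "config.yaml")
  cfg_write <- config
  cfg_write$spar <- if (is.null(config$spar)) "gcv" else config$spar
  yaml::write_yaml(unclass(cfg_write), cfg_path)
  manifest <- list(package = "streamresp",
                   version = as.character(utils::packageVersion("streamresp")),
                   mode = config$mode, seed = config$seed,
                   config_hash = unname(tools::md5sum(cfg_path)),
                   n_fish = if (!is.null(processed$traits))
                     nrow(processed$traits) else 0L,
                   n_failures = nrow(processed$failures),
                   tables = list.files(outdir, pattern = "\\.csv$"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(traits = processed$traits, recovery = processed$recovery,
                 rmr = processed$rmr, ctmax = processed$ctmax,
                 risk = risk, stats = stats_out,
                 failures = processed$failures, manifest = manifest,
                 outdir = outdir))
}
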