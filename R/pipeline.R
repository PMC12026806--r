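# End-to-end virtual experiment: generate per-animal sessions for each
# condition, run the spectral / coupling / connectivity / behavior stages,
# quantify baseline and post-drug epochs, and fit the epoch x treatment
# repeated-measures designs.

#' Define a virtual experiment
#'
#' Defaults mirror the recording protocol: a 3600 s session before the
#' familiarization phase, injection after a 15 min baseline, and
#' quantification epochs at minutes 5-15 (baseline) and 50-60 (drug).
#' Smaller sessions (with proportionally placed epochs) are used for demos
#' and tests; epoch bounds are free parameters.
#'
#' @param n_animals Animals per virtual cohort; every animal is recorded
#'   under every condition (repeated measures).
#' @param conditions Conditions to simulate.
#' @param session_s Session length (s).
#' @param injection_s Injection time (s).
#' @param baseline_epoch,drug_epoch `c(start, end)` quantification epochs
#'   (s).
#' @param fs LFP sampling rate (Hz).
#' @param window_s Quantification window (s).
#' @param metrics Metric families to compute: any of `"power"`, `"pac"`,
#'   `"connectivity"`, `"mobility"`, `"behavior"`.
#' @param pac_roi_names ROIs (from [pac_rois()] presets) to quantify.
#' @param seed Master seed; per-session seeds are derived substreams, so
#'   adding an animal never changes another animal's data.
#' @return An `experiment_plan` list.
#' @export
experiment_plan <- function(n_animals = 2,
                            conditions = CONDITIONS,
                            session_s = 3600,
                            injection_s = 900,
                            baseline_epoch = c(300, 900),
                            drug_epoch = c(3000, 3600),
                            fs = 1000,
                            window_s = 60,
                            metrics = c("power", "pac", "connectivity",
                                        "mobility", "behavior"),
                            pac_roi_names = c("ca1_theta_hg", "ca1_delta_hf",
                                              "pl_delta_hg_wide"),
                            seed = 1L) {
  conditions <- match.arg(conditions, CONDITIONS, several.ok = TRUE)
  metrics <- match.arg(metrics, c("power", "pac", "connectivity",
                                  "mobility", "behavior"), several.ok = TRUE)
  if (baseline_epoch[2] > injection_s) {
    abort("baseline epoch must end at or before the injection")
  }
  if (drug_epoch[2] > session_s) abort("drug epoch exceeds the session")
  structure(list(n_animals = n_animals, conditions = conditions,
                 session_s = session_s, injection_s = injection_s,
                 baseline_epoch = baseline_epoch, drug_epoch = drug_epoch,
                 fs = fs, window_s = window_s, metrics = metrics,
                 pac_roi_names = pac_roi_names, seed = as.integer(seed)),
            class = "experiment_plan")
}

# windows (by index) fully inside an epoch
epoch_window_idx <- function(epoch, window_s, nwin) {
  starts <- (seq_len(nwin) - 1) * window_s
  which(starts >= epoch[1] & (starts + window_s) <= epoch[2])
}

# novel-object preference by condition and phase (synthetic conventions:
# impaired discrimination under sPCP + saline, partial STM / full LTM
# rescue by the drug)
condition_p_novel <- function(condition, phase) {
  key <- paste(condition, phase)
  switch(key,
    "healthy_saline STM" = 0.70, "healthy_drug STM" = 0.70,
    "spcp_saline STM" = 0.55,    "spcp_drug STM" = 0.62,
    "healthy_saline LTM" = 0.75, "healthy_drug LTM" = 0.75,
    "spcp_saline LTM" = 0.50,    "spcp_drug LTM" = 0.72,
    0.5)
}

analyze_session <- function(rec, plan) {
  fs <- rec$fs
  rows <- list()
  wlen_windows <- floor(ncol(rec$lfp) / (plan$window_s * fs))
  base_idx <- epoch_window_idx(plan$baseline_epoch, plan$window_s, wlen_windows)
  drug_idx <- epoch_window_idx(plan$drug_epoch, plan$window_s, wlen_windows)
  if (length(base_idx) < 2 || length(drug_idx) < 1) {
    abort("quantification epochs must cover at least 2 baseline windows and 1 drug window")
  }
  add <- function(metric, region, epoch, value) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      metric = metric, region = region, epoch = epoch, value = value)
  }

  if ("power" %in% plan$metrics) {
    for (region in rownames(rec$lfp)) {
      spec <- mt_spectrogram(rec$lfp[region, ], fs, window_s = plan$window_s)
      spec <- one_over_f_normalize(spec)
      for (b in c("delta", "theta", "low_gamma")) {
        bp <- band_power(spec, b)
        z <- zscore_to_baseline(bp$power, base_idx)
        add(paste0(b, "_z"), region, "baseline", mean(z[base_idx]))
        add(paste0(b, "_z"), region, "drug", mean(z[drug_idx]))
      }
    }
  }

  if ("pac" %in% plan$metrics) {
    rois <- dplyr::bind_rows(pac_rois("methods"), pac_rois("results"))
    rois <- rois[rois$roi %in% plan$pac_roi_names, ]
    grid <- pac_grid(window_s = plan$window_s)
    for (r in seq_len(nrow(rois))) {
      roi <- rois[r, ]
      x <- rec$lfp[roi$region, ]
      series <- pac_roi_series(x, fs, roi, grid)
      z <- zscore_to_baseline(series$mi, base_idx)
      add(paste0("pac_", roi$roi), roi$region, "baseline", mean(z[base_idx]))
      add(paste0("pac_", roi$roi), roi$region, "drug", mean(z[drug_idx]))
    }
  }

  if ("connectivity" %in% plan$metrics) {
    slice_ep <- function(ch, epoch) {
      rec$lfp[ch, (round(epoch[1] * fs) + 1):round(epoch[2] * fs)]
    }
    cb <- band_set("coherence")
    for (r in seq_len(nrow(cb))) {
      for (ep in c("baseline", "drug")) {
        epoch <- if (ep == "baseline") plan$baseline_epoch else plan$drug_epoch
        v <- wpli(slice_ep("CA1", epoch), slice_ep("PL", epoch), fs,
                  c(cb$lo[r], cb$hi[r]))
        add(paste0("wpli_", cb$band[r]), "CA1-PL", ep, v)
      }
    }
    db <- band_set("directionality")
    for (ep in c("baseline", "drug")) {
      epoch <- if (ep == "baseline") plan$baseline_epoch else plan$drug_epoch
      v <- psi(slice_ep("CA1", epoch), slice_ep("PL", epoch), fs,
               c(db$lo[1], db$hi[1]), epoch_len_s = plan$window_s)
      add("psi_theta", "CA1-PL", ep, v)
    }
  }

  if ("mobility" %in% plan$metrics) {
    mob <- acc_mobility(rec$acc, fs, bin_s = plan$window_s,
                        baseline_bins = base_idx)
    add("acc_ratio", "body", "baseline", mean(mob$ratio[base_idx]))
    add("acc_ratio", "body", "drug", mean(mob$ratio[drug_idx]))
  }

  dplyr::bind_rows(rows)
}

#' Run a virtual experiment
#'
#' For every animal and condition: generate a synthetic session from a
#' derived seed, compute the requested metric families quantified over the
#' baseline and drug epochs (power and coupling as baseline z-scores), and
#' fit the epoch x treatment repeated-measures designs within each health
#' state. Fully reproducible: the same plan and master seed give a
#' byte-identical report.
#'
#' @param plan An [experiment_plan()].
#' @param cfg_overrides Named list of [session_config()] arguments applied
#'   to every session (e.g. `list(noise_sd = 2)`).
#' @return An `experiment_report` list with `metrics` (long tibble:
#'   `animal`, `condition`, `metric`, `region`, `epoch`, `value`),
#'   `behavior` (per-animal DI table, if requested), `stats` (tidied
#'   rm-ANOVA tables), `seeds`, `plan`, `version`.
#' @export
run_experiment <- function(plan, cfg_overrides = list()) {
  stopifnot(inherits(plan, "experiment_plan"))
  metric_rows <- list()
  beh_rows <- list()
  seed_rows <- list()
  for (a in seq_len(plan$n_animals)) {
    for (ci in seq_along(plan$conditions)) {
      cond <- plan$conditions[ci]
      s <- derive_seed(plan$seed, a, ci)
      seed_rows[[length(seed_rows) + 1]] <- tibble::tibble(
        animal = a, condition = cond, seed = s)
      args <- c(list(duration_s = plan$session_s, fs_lfp = plan$fs,
                     condition = cond, injection_s = plan$injection_s,
                     seed = s), cfg_overrides)
      cfg <- do.call(session_config, args)
      rec <- tryCatch(gen_lfp_session(cfg), error = function(e) {
        abort(sprintf("stage 'synthgen' failed for animal %d / %s: %s",
                      a, cond, conditionMessage(e)))
      })
      m <- tryCatch(analyze_session(rec, plan), error = function(e) {
        abort(sprintf("stage 'analysis' failed for animal %d / %s: %s",
                      a, cond, conditionMessage(e)))
      })
      m$animal <- a
      m$condition <- cond
      metric_rows[[length(metric_rows) + 1]] <- m

      if ("behavior" %in% plan$metrics) {
        for (phase in c("STM", "LTM")) {
          vt <- gen_visit_table(30, condition_p_novel(cond, phase),
                                mean_visit_s = 1,
                                phase = phase,
                                seed = derive_seed(plan$seed, a, ci,
                                                   match(phase, c("STM", "LTM"))))
          es <- exploration_summary(vt)
          es$animal <- a
          es$condition <- cond
          beh_rows[[length(beh_rows) + 1]] <- es
        }
      }
    }
  }
  metrics <- dplyr::bind_rows(metric_rows) |>
    dplyr::relocate("animal", "condition")
  behavior <- if (length(beh_rows)) dplyr::bind_rows(beh_rows) else NULL

  # epoch x treatment designs within each health state (treatment sessions
  # are analyzed as the between factor, matching the biomarker design; the
  # session, animal x treatment, is the unit)
  stats_out <- list()
  pairs <- list(healthy = c("healthy_saline", "healthy_drug"),
                spcp = c("spcp_saline", "spcp_drug"))
  for (hs in names(pairs)) {
    conds <- intersect(pairs[[hs]], plan$conditions)
    if (length(conds) != 2 || plan$n_animals < 2) next
    dat <- metrics |>
      dplyr::filter(.data$condition %in% conds) |>
      dplyr::mutate(treatment = ifelse(grepl("drug$", .data$condition),
                                       "drug", "saline"),
                    session = paste(.data$animal, .data$treatment))
    cells <- unique(dat[, c("metric", "region")])
    for (k in seq_len(nrow(cells))) {
      sub <- dat[dat$metric == cells$metric[k] & dat$region == cells$region[k], ]
      fit <- tryCatch(
        rm_anova(sub, dv = "value", within = "epoch", unit = "session",
                 between = "treatment"),
        error = function(e) NULL)
      if (!is.null(fit)) {
        td <- tidy(fit)
        td$health_state <- hs
        td$metric <- cells$metric[k]
        td$region <- cells$region[k]
        stats_out[[length(stats_out) + 1]] <- td
      }
    }
  }
  structure(list(
    version = "1.0",
    plan = unclass(plan),
    metrics = metrics,
    behavior = behavior,
    stats = if (length(stats_out)) dplyr::bind_rows(stats_out) else NULL,
    seeds = dplyr::bind_rows(seed_rows)
  ), class = "experiment_report")
}

#' Condition-ordering study
#'
#' Replicated virtual sessions quantifying the two signatures of the sPCP
#' phenotype — CA1 delta z-power and CA1 delta-high-frequency coupling
#' (z-scored ROI MI) in the post-injection epoch — across conditions and
#' seeds. Under the default synthetic effects the medians order
#' spcp_saline > spcp_drug > healthy.
#'
#' @param n_seeds Number of replicate virtual animals per condition.
#' @param conditions Conditions to compare.
#' @param session_s Session length (s); the default 900 s keeps a 5-window
#'   post epoch after a 300 s injection with 4 baseline windows.
#' @param injection_s Injection time (s).
#' @param seed Master seed.
#' @return Tibble with `seed_rep`, `condition`, `delta_z`, `pac_z`.
#' @export
condition_ordering_study <- function(n_seeds = 20,
                                     conditions = c("healthy_saline",
                                                    "spcp_saline",
                                                    "spcp_drug"),
                                     session_s = 900,
                                     injection_s = 300,
                                     seed = 1L) {
  window_s <- 60
  nwin <- floor(session_s / window_s)
  base_idx <- epoch_window_idx(c(window_s, injection_s), window_s, nwin)
  drug_idx <- epoch_window_idx(c(session_s - 300, session_s), window_s, nwin)
  roi <- pac_rois("results")
  roi <- roi[roi$roi == "ca1_delta_hf", ]
  # coarse quantification grid restricted to the ROI (cheaper, same bands)
  grid <- pac_grid(phase_centers = 3:5, amp_centers = seq(150, 200, by = 10),
                   window_s = window_s)
  rows <- list()
  for (r in seq_len(n_seeds)) {
    for (ci in seq_along(conditions)) {
      cfg <- session_config(duration_s = session_s, condition = conditions[ci],
                            injection_s = injection_s,
                            seed = derive_seed(seed, r, ci))
      rec <- gen_lfp_session(cfg)
      spec <- one_over_f_normalize(
        mt_spectrogram(rec$lfp["CA1", ], rec$fs, window_s = window_s))
      dz <- zscore_to_baseline(band_power(spec, "delta")$power, base_idx)
      series <- pac_roi_series(rec$lfp["CA1", ], rec$fs, roi, grid)
      pz <- zscore_to_baseline(series$mi, base_idx)
      rows[[length(rows) + 1]] <- tibble::tibble(
        seed_rep = r, condition = conditions[ci],
        delta_z = mean(dz[drug_idx]), pac_z = mean(pz[drug_idx]))
    }
  }
  dplyr::bind_rows(rows)
}

#' Write an experiment report as JSON
#'
#' Floats are serialized at 12 significant digits; rerunning the same plan
#' and master seed produces a byte-identical file.
#'
#' @param report An `experiment_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "experiment_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = I(12), dataframe = "columns")
  invisible(path)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report v%s> %d animals x %d conditions, %d metric rows\n",
              x$version, x$plan$n_animals, length(x$plan$conditions),
              nrow(x$metrics)))
  invisible(x)
}
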