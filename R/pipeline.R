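# Study orchestration: one config object drives generation of a synthetic
# cohort, every analysis stage, and a summary reproducing the headline
# connectivity statistics.

#' Default study configuration
#'
#' @param seed master seed (required for any run; no silent
#'   nondeterminism).
#' @param out output directory.
#' @param cohort,quantal,mapping,puncta,timecourse,reproduction parameter
#'   blocks; see the defaults for the recognised fields.
#' @return list of class `ng2_study_config`.
#' @export
study_config <- function(
    seed = 1,
    out = tempfile("ng2study"),
    cohort = list(n_per_class = 25),
    quantal = list(n_sims = 10, n_sweeps = 150, q = -7.71, noise_sd = 1.5),
    mapping = list(n_maps = 4, n_interneurons = 30, p_near = 0.4),
    puncta = list(n_pv = 150, n_nonpv = 150),
    timecourse = list(n_cells_per_day = 25),
    reproduction = list(
      p_a = 0.43, p_b = 0.21, total_pairs = 147, total_connected = 38,
      chi2 = 6.93, ci_a = c(0.30, 0.57), ci_b = c(0.15, 0.27), level = 0.90
    )) {
  structure(
    list(seed = seed, out = out, cohort = cohort, quantal = quantal,
         mapping = mapping, puncta = puncta, timecourse = timecourse,
         reproduction = reproduction),
    class = "ng2_study_config"
  )
}

#' Validate a study configuration
#'
#' @param config an `ng2_study_config` (or plain list).
#' @return `TRUE` invisibly when valid; otherwise a character vector of
#'   error messages with class `ng2_config_errors` is returned. Unknown
#'   top-level keys produce warnings, not errors.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  known <- c("seed", "out", "cohort", "quantal", "mapping", "puncta",
             "timecourse", "reproduction")
  extra <- setdiff(names(config), known)
  if (length(extra)) {
    warning("unknown config keys ignored: ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  for (blk in setdiff(known, c("seed", "out"))) {
    if (is.null(config[[blk]])) errs <- c(errs, sprintf("missing block '%s'", blk))
  }
  if (is.null(config$seed) || !is.finite(config$seed)) {
    errs <- c(errs, "seed is required")
  }
  num_pos <- function(block, field) {
    v <- config[[block]][[field]]
    if (!is.null(config[[block]]) &&
        (is.null(v) || !is.numeric(v) || v <= 0)) {
      errs <<- c(errs, sprintf("%s$%s must be a positive number", block, field))
    }
  }
  num_pos("cohort", "n_per_class")
  num_pos("quantal", "n_sims")
  num_pos("quantal", "n_sweeps")
  num_pos("mapping", "n_maps")
  num_pos("puncta", "n_pv")
  num_pos("timecourse", "n_cells_per_day")
  if (length(errs)) return(structure(errs, class = "ng2_config_errors"))
  invisible(TRUE)
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full synthetic study
#'
#' Generates every synthetic input, runs all analysis stages, writes
#' per-stage CSV/JSON outputs plus a run log into `config$out`, and returns
#' the summary (also written as `summary.json`). Stage failures abort with
#' a diagnostic naming the stage. Re-running with the same config yields an
#' identical summary.
#'
#' @param config an `ng2_study_config`.
#' @return the summary list, invisibly.
#' @export
run_study <- function(config = study_config()) {
  val <- validate_config(config)
  if (!isTRUE(val)) {
    stop("invalid study config:\n  - ", paste(val, collapse = "\n  - "),
         call. = FALSE)
  }
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  summary <- list(seed = config$seed)

  # --- interneuron classification -------------------------------------
  coh <- stage("cohort", {
    df <- classify_cohort(config$cohort$n_per_class, seed = config$seed)
    utils::write.csv(df, file.path(config$out, "cohort_features.csv"),
                     row.names = FALSE)
    df
  })
  cm <- table(true = coh$true_label, called = coh$label)
  summary$classification <- list(
    n = nrow(coh),
    accuracy = mean(coh$label == coh$true_label),
    confusion = as.data.frame(cm)
  )

  # --- quantal analysis ------------------------------------------------
  qa <- stage("quantal", {
    qs <- config$quantal
    rows <- lapply(seq_len(qs$n_sims), function(i) {
      n_sites <- if (i %% 2 == 1) 1 else 2
      p <- if (n_sites == 1) {
        release_model_params(1, 0.6, 0.35, q = qs$q, noise_sd = qs$noise_sd,
                             n_sweeps = qs$n_sweeps)
      } else {
        release_model_params(2, 0.85, 0.4, q = qs$q, noise_sd = qs$noise_sd,
                             n_sweeps = qs$n_sweeps)
      }
      ps <- gen_paired_sweeps(p, seed = config$seed * 1000 + i)
      res <- classify_release_sites(detect_psc_all(ps))
      data.frame(
        sim = i, true_sites = n_sites, called_sites = res$n_sites,
        verdict = res$verdict, quantal_size = res$quantal_size,
        mean_nf1 = res$mean_nf1, p1 = res$p1, p2 = res$p2
      )
    })
    df <- do.call(rbind, rows)
    utils::write.csv(df, file.path(config$out, "quantal_results.csv"),
                     row.names = FALSE)
    df
  })
  summary$quantal <- list(
    n_sims = nrow(qa),
    recovery_rate = mean(qa$called_sites == qa$true_sites, na.rm = FALSE),
    mean_quantal_size = mean(qa$quantal_size[qa$true_sites == 1 &
                                               qa$called_sites %in% 1], na.rm = TRUE)
  )

  # --- puncta spatial statistics --------------------------------------
  pa <- stage("puncta", {
    cl <- gen_puncta_cloud(config$puncta$n_pv, config$puncta$n_nonpv,
                           seed = config$seed + 7)
    contacts <- classify_contacts(cl)
    utils::write.csv(contacts, file.path(config$out, "puncta_contacts.csv"),
                     row.names = FALSE)
    dd <- distance_distributions(contacts)
    dens <- shell_density_profile(cl)
    utils::write.csv(dens, file.path(config$out, "puncta_shell_density.csv"),
                     row.names = FALSE)
    list(dd = dd, dens = dens)
  })
  summary$puncta <- list(
    mean_distance_pv = pa$dd$mean_pv,
    mean_distance_nonpv = pa$dd$mean_nonpv,
    ks_p = pa$dd$ks$p.value
  )

  # --- connectivity mapping -------------------------------------------
  mp <- stage("mapping", {
    ms <- config$mapping
    maps <- lapply(seq_len(ms$n_maps), function(i) {
      fld <- gen_connectivity_field(
        field_params(n_interneurons = ms$n_interneurons, p_near = ms$p_near),
        seed = config$seed * 100 + i
      )
      map_from_field(fld, seed = config$seed * 100 + 50 + i)
    })
    prof <- distance_profile(maps)
    utils::write.csv(prof$bins, file.path(config$out, "distance_profile.csv"),
                     row.names = FALSE)
    prof
  })
  summary$mapping <- list(
    max_connected_distance = if (length(mp$connected_d)) max(mp$connected_d) else NA_real_,
    ks_p = if (!is.null(mp$ks)) mp$ks$p.value else NA_real_
  )

  # --- developmental time course --------------------------------------
  tc <- stage("timecourse", {
    rec <- gen_timecourse(timecourse_params(),
                          n_cells_per_day = config$timecourse$n_cells_per_day,
                          seed = config$seed + 13)
    utils::write.csv(rec, file.path(config$out, "timecourse_records.csv"),
                     row.names = FALSE)
    tab <- probability_by_group(rec, by = "day")
    utils::write.csv(tab, file.path(config$out, "timecourse_probabilities.csv"),
                     row.names = FALSE)
    corr10 <- with(rec[rec$day == 10, ],
                   pearson_correlation(na_density, spont_freq))
    list(tab = tab, corr10 = corr10)
  })
  summary$timecourse <- list(
    peak_day = tc$tab$day[which.max(tc$tab$p)],
    p_pn10 = tc$tab$p[tc$tab$day == 10],
    r_pn10 = tc$corr10$r
  )

  # --- printed-statistic reproduction ---------------------------------
  rep <- stage("reproduction", {
    rp <- config$reproduction
    tab <- reconstruct_contingency(rp$p_a, rp$p_b, rp$total_pairs,
                                   rp$total_connected, chi2 = rp$chi2,
                                   ci_a = rp$ci_a, ci_b = rp$ci_b,
                                   level = rp$level)
    chi <- pearson_chi2(tab)
    wa <- wilson_interval(tab[1, 1], sum(tab[1, ]), rp$level)
    wb <- wilson_interval(tab[2, 1], sum(tab[2, ]), rp$level)
    ov <- interval_overlap_test(wa, wb)
    list(table = tab, chi = chi, wa = wa, wb = wb, overlap = ov)
  })
  summary$reproduction <- list(
    table = as.data.frame(unclass(rep$table[, ])),
    chi2 = round_half_up(rep$chi$statistic),
    ci_a = round_half_up(c(rep$wa$lower, rep$wa$upper)),
    ci_b = round_half_up(c(rep$wb$lower, rep$wb$upper)),
    different = rep$overlap$different,
    alpha_bound = rep$overlap$alpha_bound
  )

  write_json_out(summary, file.path(config$out, "summary.json"))
  log_lines <- c(
    sprintf("ng2circuit run_study seed=%d", config$seed),
    sprintf("R version: %s", as.character(getRversion())),
    sprintf("stages: cohort quantal puncta mapping timecourse reproduction")
  )
  writeLines(log_lines, file.path(config$out, "run.log"))
  invisible(summary)
}
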