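# End-to-end orchestration: detect -> classify -> evoked / latency /
# spatial / kinematics analyses -> report.

.test_to_list <- function(tt) {
  if (is.null(tt)) return(NULL)
  out <- unclass(tt)
  out$n <- as.list(out$n)
  out
}

# First-task-saccade analysis table with a per-trial filter ledger.
# Filters (applied in order):
#   incorrect-outcome  : trial outcome != "correct"
#   no-task-saccade    : no saccade classified task-related (latency
#                        100-400 ms, duration < 75 ms) on the trial
#   excluded-electrode : stimulation trial on an excluded electrode
.build_task_table <- function(saccades, trials, exclusions) {
  n_in <- nrow(trials)
  ledger <- list(trials_in = n_in)
  ok <- trials$outcome == "correct"
  ledger$incorrect_outcome <- sum(!ok)
  t1 <- trials[ok, ]

  first <- saccades[saccades$first_task, ]
  has_task <- t1$trial_id %in% first$trial_id
  ledger$no_task_saccade <- sum(!has_task)
  t2 <- t1[has_task, ]

  drop_stim <- t2$stim == 1L & t2$electrode_id %in% exclusions$electrode_id
  ledger$excluded_electrode <- sum(drop_stim)
  t3 <- t2[!drop_stim, ]

  ledger$trials_kept <- nrow(t3)
  tab <- merge(t3, first, by = "trial_id")
  tab <- tab[order(tab$trial_id), ]
  rownames(tab) <- NULL
  list(table = tab, ledger = ledger)
}

#' Evoked-saccade analysis
#'
#' Summarizes, over stimulation trials, which electrodes evoke saccades
#' (at least 3 of 10 stimulation trials with an evoked-classified saccade)
#' and, restricted to electrodes evoking at *both* currents: (i) Fisher's
#' exact test of evoked frequency against current, (ii) a Harrison-Kanji
#' circular two-way ANOVA of evoked-saccade direction on electrode x
#' current, (iii) a linear two-way ANOVA of amplitude on electrode x
#' current, and (iv)-(vi) the same three analyses with currents pooled and
#' the task-instructed jump direction replacing current as second factor
#' (the control for task contamination of the evoked movement).
#'
#' @param saccades labelled saccade table ([classify_saccades()]).
#' @param trials trial metadata table.
#' @param electrode_map electrode map table.
#' @param n_perm permutations for the circular-ANOVA companion p-values.
#' @param seed seed for the permutation draws.
#' @return list: `summaries`, `dual_electrodes`, `empty` flag, and (when
#'   non-empty) `fisher_current`, `circ_anova_current`,
#'   `linear_anova_amplitude`, `fisher_instructed`,
#'   `circ_anova_instructed`, `linear_anova_instructed`.
#' @export
run_evoked_analysis <- function(saccades, trials, electrode_map,
                                n_perm = 999, seed = 1L) {
  summaries <- summarize_evoked(saccades, trials)
  out <- list(summaries = summaries, dual_electrodes = integer(0),
              empty = TRUE)
  if (nrow(summaries) == 0L) return(out)
  currents <- sort(unique(summaries$current_uA))
  inc <- summaries[summaries$included, ]
  dual <- if (length(currents) < 2L) integer(0) else
    Reduce(intersect, lapply(currents, function(cu)
      inc$electrode_id[inc$current_uA == cu]))
  out$dual_electrodes <- sort(dual)
  if (length(dual) == 0L) return(out)
  out$empty <- FALSE

  stim_trials <- trials[trials$stim == 1L & trials$electrode_id %in% dual, ]
  ev <- saccades[saccades$label == "evoked" &
                 saccades$trial_id %in% stim_trials$trial_id, ]
  ev <- ev[order(ev$trial_id, ev$onset_ms), ]
  ev <- ev[!duplicated(ev$trial_id), ]
  ev <- merge(ev, stim_trials[c("trial_id", "electrode_id", "current_uA",
                                "jump_dir")], by = "trial_id")

  lo <- min(currents); hi <- max(currents)
  n_ev <- function(sel_trials) {
    c(evoked = sum(sel_trials$trial_id %in% ev$trial_id),
      none = sum(!(sel_trials$trial_id %in% ev$trial_id)))
  }
  tab_cur <- rbind(n_ev(stim_trials[stim_trials$current_uA == lo, ]),
                   n_ev(stim_trials[stim_trials$current_uA == hi, ]))
  rownames(tab_cur) <- paste0(c(lo, hi), "uA")
  out$fisher_current <- .test_to_list(fisher_exact(tab_cur))
  out$fisher_current$table <- tab_cur

  safe_circ <- function(angles, fa, fb, seed_off) {
    tryCatch({
      r <- hk_circ_anova(angles, fa, fb, n_perm = n_perm,
                         seed = seed + seed_off)
      list(table = r$table, kappa_hat = r$kappa_hat, regime = r$regime,
           low_kappa_warning = r$low_kappa_warning, n = r$n)
    }, error = function(e) list(error = conditionMessage(e)),
       warning = function(w) {
         r <- suppressWarnings(hk_circ_anova(angles, fa, fb, n_perm = n_perm,
                                             seed = seed + seed_off))
         list(table = r$table, kappa_hat = r$kappa_hat, regime = r$regime,
              low_kappa_warning = r$low_kappa_warning, n = r$n)
       })
  }
  safe_lin <- function(y, fa, fb) {
    tryCatch(twoway_linear_anova(y, fa, fb),
             error = function(e) list(error = conditionMessage(e)))
  }

  out$circ_anova_current <- safe_circ(ev$direction_deg, ev$electrode_id,
                                      ev$current_uA, 1L)
  out$linear_anova_amplitude <- safe_lin(ev$amplitude_deg, ev$electrode_id,
                                         ev$current_uA)

  # instructed-direction controls (currents pooled)
  tab_dir <- rbind(n_ev(stim_trials[stim_trials$jump_dir == "contra", ]),
                   n_ev(stim_trials[stim_trials$jump_dir == "ipsi", ]))
  rownames(tab_dir) <- c("contra", "ipsi")
  out$fisher_instructed <- .test_to_list(fisher_exact(tab_dir))
  out$fisher_instructed$table <- tab_dir
  out$circ_anova_instructed <- safe_circ(ev$direction_deg, ev$electrode_id,
                                         ev$jump_dir, 2L)
  out$linear_anova_instructed <- safe_lin(ev$amplitude_deg, ev$electrode_id,
                                          ev$jump_dir)
  out
}

#' Latency analysis: baseline asymmetry and stimulation effects
#'
#' On the filtered first-task-saccade table: (i) the baseline contra-vs-
#' ipsiversive comparison on control trials (overall and within each block
#' current), and (ii) stimulation-vs-control comparisons separately per
#' saccade direction and current. The primary test is the pooled-variance
#' t-test on reciprocal-transformed latencies; the raw-scale t-test and
#' the Wilcoxon rank-sum test are reported as robustness companions. Mean
#' and median latency differences are always reported in milliseconds on
#' the raw scale (stim - control; baseline: ipsi - contra, so positive
#' values mean contraversive saccades lead).
#'
#' @param task_table filtered analysis table (internal; produced by
#'   [run_full()] from the saccade and trial tables).
#' @param transform test on reciprocal-transformed latencies (primary).
#' @return list with `baseline` (data.frame) and `conditions` (data.frame,
#'   one row per direction x current) plus the per-condition test details.
#' @export
run_latency_analysis <- function(task_table, transform = TRUE) {
  tab <- task_table
  ctrl <- tab[tab$stim == 0L, ]

  base_row <- function(label, sub) {
    co <- sub$latency_ms[sub$jump_dir == "contra"]
    ip <- sub$latency_ms[sub$jump_dir == "ipsi"]
    if (length(co) < 2L || length(ip) < 2L)
      return(data.frame(subset = label, n_contra = length(co),
                        n_ipsi = length(ip), advantage_ms = NA_real_,
                        median_advantage_ms = NA_real_, p = NA_real_,
                        p_raw = NA_real_, p_ranksum = NA_real_,
                        insufficient = TRUE))
    tt <- latency_test(ip, co, method = "t", transform = transform)
    tr <- latency_test(ip, co, method = "t", transform = FALSE)
    tw <- latency_test(ip, co, method = "ranksum", transform = FALSE)
    data.frame(subset = label, n_contra = length(co), n_ipsi = length(ip),
               advantage_ms = mean(ip) - mean(co),
               median_advantage_ms = median(ip) - median(co),
               p = tt$p_value, p_raw = tr$p_value, p_ranksum = tw$p_value,
               insufficient = FALSE)
  }
  currents <- sort(unique(tab$block_current_uA))
  baseline <- do.call(rbind, c(
    list(base_row("all", ctrl)),
    lapply(currents, function(cu)
      base_row(paste0(cu, "uA_blocks"), ctrl[ctrl$block_current_uA == cu, ]))))

  grid <- expand.grid(direction = c("contra", "ipsi"),
                      current_uA = currents, stringsAsFactors = FALSE)
  cond <- lapply(seq_len(nrow(grid)), function(i) {
    d <- grid$direction[i]; cu <- grid$current_uA[i]
    st <- tab$latency_ms[tab$stim == 1L & tab$jump_dir == d &
                         tab$block_current_uA == cu]
    ct <- tab$latency_ms[tab$stim == 0L & tab$jump_dir == d &
                         tab$block_current_uA == cu]
    if (length(st) < 2L || length(ct) < 2L)
      return(data.frame(direction = d, current_uA = cu,
                        n_stim = length(st), n_control = length(ct),
                        mean_diff_ms = NA_real_, median_diff_ms = NA_real_,
                        statistic = NA_real_, p = NA_real_,
                        p_raw = NA_real_, p_ranksum = NA_real_,
                        insufficient = TRUE))
    tt <- latency_test(st, ct, method = "t", transform = transform)
    tr <- latency_test(st, ct, method = "t", transform = FALSE)
    tw <- latency_test(st, ct, method = "ranksum", transform = FALSE)
    data.frame(direction = d, current_uA = cu,
               n_stim = length(st), n_control = length(ct),
               mean_diff_ms = tt$mean_diff_ms,
               median_diff_ms = tt$median_diff_ms,
               statistic = tt$statistic, p = tt$p_value,
               p_raw = tr$p_value, p_ranksum = tw$p_value,
               insufficient = FALSE)
  })
  conditions <- do.call(rbind, cond)
  rownames(baseline) <- rownames(conditions) <- NULL
  list(baseline = baseline, conditions = conditions,
       transform = transform)
}

#' Spatial (rostral/caudal) analysis of latency effects
#'
#' Restricted to blocks of the strongest current and their interleaved
#' control trials: per electrode and saccade direction, the mean
#' stimulation-trial latency is compared with the mean latency of the same
#' block's control trials. Per electrode group and direction a
#' paired-sample t-test across electrodes is run (four tests; Bonferroni
#' alpha 0.05/4 = 0.0125), and per direction the per-electrode effects of
#' the two groups are compared with a two-sample t-test.
#'
#' @param task_table filtered analysis table (see [run_full()]).
#' @param electrode_map electrode map table.
#' @param exclusions exclusion table from [flag_excluded_electrodes()].
#' @return list: `current_uA`, `per_electrode` (data.frame),
#'   `group_tests`, `between_tests`, `alpha_bonferroni`.
#' @export
run_spatial_analysis <- function(task_table, electrode_map, exclusions) {
  hi <- max(task_table$block_current_uA)
  tab <- task_table[task_table$block_current_uA == hi, ]
  keep_el <- setdiff(electrode_map$electrode_id[electrode_map$status == "ok"],
                     exclusions$electrode_id)
  tab <- tab[tab$electrode_id %in% keep_el, ]

  agg <- aggregate(latency_ms ~ electrode_id + jump_dir + stim, data = tab,
                   FUN = mean)
  n_agg <- aggregate(latency_ms ~ electrode_id + jump_dir + stim, data = tab,
                     FUN = length)
  names(n_agg)[4] <- "n"
  agg <- merge(agg, n_agg)
  wide <- merge(
    setNames(agg[agg$stim == 1L, c("electrode_id", "jump_dir",
                                   "latency_ms", "n")],
             c("electrode_id", "jump_dir", "mean_stim_ms", "n_stim")),
    setNames(agg[agg$stim == 0L, c("electrode_id", "jump_dir",
                                   "latency_ms", "n")],
             c("electrode_id", "jump_dir", "mean_control_ms", "n_control")),
    by = c("electrode_id", "jump_dir"))
  wide$effect_ms <- wide$mean_stim_ms - wide$mean_control_ms
  wide <- merge(wide, electrode_map[c("electrode_id", "group")],
                by = "electrode_id")
  wide <- wide[order(wide$jump_dir, wide$electrode_id), ]
  rownames(wide) <- NULL

  alpha <- bonferroni_alpha(0.05, 4L)
  gt <- expand.grid(group = c("caudal", "rostral"),
                    direction = c("contra", "ipsi"), stringsAsFactors = FALSE)
  group_tests <- do.call(rbind, lapply(seq_len(nrow(gt)), function(i) {
    sub <- wide[wide$group == gt$group[i] & wide$jump_dir == gt$direction[i], ]
    if (nrow(sub) < 2L)
      return(data.frame(group = gt$group[i], direction = gt$direction[i],
                        n_electrodes = nrow(sub), mean_effect_ms = NA_real_,
                        statistic = NA_real_, df = NA_real_, p = NA_real_,
                        significant = NA, insufficient = TRUE))
    tt <- latency_test(sub$mean_stim_ms, sub$mean_control_ms,
                       method = "t", paired = TRUE, transform = FALSE)
    data.frame(group = gt$group[i], direction = gt$direction[i],
               n_electrodes = nrow(sub), mean_effect_ms = mean(sub$effect_ms),
               statistic = tt$statistic, df = tt$df, p = tt$p_value,
               significant = tt$p_value < alpha, insufficient = FALSE)
  }))
  between_tests <- do.call(rbind, lapply(c("contra", "ipsi"), function(d) {
    ca <- wide$effect_ms[wide$group == "caudal" & wide$jump_dir == d]
    ro <- wide$effect_ms[wide$group == "rostral" & wide$jump_dir == d]
    if (length(ca) < 2L || length(ro) < 2L)
      return(data.frame(direction = d, n_caudal = length(ca),
                        n_rostral = length(ro),
                        mean_diff_ms = NA_real_, statistic = NA_real_,
                        df = NA_real_, p = NA_real_, insufficient = TRUE))
    tt <- latency_test(ca, ro, method = "t", transform = FALSE)
    data.frame(direction = d, n_caudal = length(ca), n_rostral = length(ro),
               mean_diff_ms = mean(ca) - mean(ro), statistic = tt$statistic,
               df = tt$df, p = tt$p_value, insufficient = FALSE)
  }))
  rownames(group_tests) <- rownames(between_tests) <- NULL
  list(current_uA = hi, per_electrode = wide, group_tests = group_tests,
       between_tests = between_tests, alpha_bonferroni = alpha)
}

#' Kinematics analysis: peak velocity, amplitude, endpoint accuracy
#'
#' Two-sample t-tests of stimulation against control trials on saccade
#' peak velocity, amplitude and Euclidean endpoint error, for each
#' direction x current combination, each direction pooled over currents,
#' and each current pooled over directions (eight tests per measure;
#' Bonferroni alpha 0.05/8), plus the fully pooled comparison. Mean
#' differences are reported in native units (deg/s or deg, stim -
#' control).
#'
#' @param task_table filtered analysis table (see [run_full()]).
#' @return list: `tests` (data.frame, one row per measure x subset),
#'   `alpha_bonferroni`, `n_family`.
#' @export
run_kinematics_analysis <- function(task_table) {
  tab <- task_table
  currents <- sort(unique(tab$block_current_uA))
  measures <- c(peak_velocity_deg_s = "peak_velocity_deg_s",
                amplitude_deg = "amplitude_deg",
                endpoint_error_deg = "endpoint_error_deg")
  subsets <- list()
  for (d in c("contra", "ipsi")) for (cu in currents)
    subsets[[paste(d, cu, sep = "_")]] <-
      list(dir = d, cur = cu, family = TRUE)
  for (d in c("contra", "ipsi"))
    subsets[[paste(d, "all", sep = "_")]] <-
      list(dir = d, cur = NA, family = TRUE)
  for (cu in currents)
    subsets[[paste("all", cu, sep = "_")]] <-
      list(dir = NA, cur = cu, family = TRUE)
  subsets[["all_all"]] <- list(dir = NA, cur = NA, family = FALSE)
  n_family <- sum(vapply(subsets, `[[`, logical(1), "family"))
  alpha <- bonferroni_alpha(0.05, n_family)

  rows <- list()
  for (m in names(measures)) {
    v <- tab[[measures[[m]]]]
    for (s in names(subsets)) {
      sel <- rep(TRUE, nrow(tab))
      if (!is.na(subsets[[s]]$dir)) sel <- sel & tab$jump_dir == subsets[[s]]$dir
      if (!is.na(subsets[[s]]$cur))
        sel <- sel & tab$block_current_uA == subsets[[s]]$cur
      st <- v[sel & tab$stim == 1L]; ct <- v[sel & tab$stim == 0L]
      st <- st[!is.na(st)]; ct <- ct[!is.na(ct)]
      if (length(st) < 2L || length(ct) < 2L) {
        rows[[paste(m, s)]] <- data.frame(
          measure = m, subset = s, n_stim = length(st),
          n_control = length(ct), mean_diff = NA_real_,
          statistic = NA_real_, df = NA_real_, p = NA_real_,
          in_family = subsets[[s]]$family, significant = NA,
          insufficient = TRUE)
        next
      }
      tt <- latency_test(st, ct, method = "t", transform = FALSE)
      rows[[paste(m, s)]] <- data.frame(
        measure = m, subset = s, n_stim = length(st), n_control = length(ct),
        mean_diff = tt$mean_diff_ms, statistic = tt$statistic, df = tt$df,
        p = tt$p_value, in_family = subsets[[s]]$family,
        significant = subsets[[s]]$family & tt$p_value < alpha,
        insufficient = FALSE)
    }
  }
  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL
  list(tests = tests, alpha_bonferroni = alpha, n_family = n_family)
}

#' Run the full analysis pipeline
#'
#' Either simulates a session from a [sim_config()] or consumes an
#' existing `stim_session` (simulated or read from CSV via
#' [read_session()]), then runs detection, classification, electrode
#' exclusion and the four analyses, and returns a structured report with a
#' trial filter ledger and a reproducibility manifest. With `out_dir` the
#' report is also written as `report.json` plus per-table CSVs.
#'
#' @param config a [sim_config()] (ignored when `session` is given).
#' @param session an existing `stim_session`.
#' @param seed simulation seed (defaults to `config$seed`).
#' @param v_threshold saccade velocity criterion, deg/s.
#' @param smooth_window_samples speed smoothing window, samples.
#' @param transform run latency tests on reciprocal-transformed values.
#' @param n_perm circular-ANOVA permutation count (0 disables).
#' @param out_dir optional output directory.
#' @return object of class `effect_report` (a nested list; see the
#'   individual `run_*_analysis()` functions for the section contents).
#' @export
run_full <- function(config = NULL, session = NULL, seed = NULL,
                     v_threshold = 100, smooth_window_samples = 15L,
                     transform = TRUE, n_perm = 999, out_dir = NULL) {
  if (is.null(session)) {
    if (is.null(config)) .stopf("provide either a config or a session")
    if (is.null(seed)) seed <- config$seed
    session <- simulate_session(config, seed = seed)
  }
  if (is.null(seed)) seed <- if (!is.null(session$seed)) session$seed else 0L
  saccades <- detect_session(session, v_threshold = v_threshold,
                             smooth_window_samples = smooth_window_samples)
  saccades <- classify_saccades(saccades, session$trials)

  evoked <- run_evoked_analysis(saccades, session$trials,
                                session$electrode_map,
                                n_perm = n_perm, seed = seed)
  exclusions <- flag_excluded_electrodes(evoked$summaries,
                                         session$electrode_map)
  built <- .build_task_table(saccades, session$trials, exclusions)
  latency <- run_latency_analysis(built$table, transform = transform)
  spatial <- run_spatial_analysis(built$table, session$electrode_map,
                                  exclusions)
  kinematics <- run_kinematics_analysis(built$table)

  report <- structure(list(
    manifest = list(seed = seed,
                    v_threshold = v_threshold,
                    smooth_window_samples = as.integer(smooth_window_samples),
                    transform = transform, n_perm = as.integer(n_perm),
                    n_trials = nrow(session$trials),
                    n_saccades_detected = nrow(saccades),
                    package_version =
                      as.character(packageVersion("stimsacc"))),
    filter_ledger = built$ledger,
    exclusions = exclusions,
    evoked = evoked,
    latency = latency,
    spatial = spatial,
    kinematics = kinematics), class = "effect_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.effect_report <- function(x, ...) {
  cat("Stimulation effect report\n")
  lg <- x$filter_ledger
  cat(sprintf("  trials: %d in, %d kept (incorrect %d, no task saccade %d, excluded electrode %d)\n",
              lg$trials_in, lg$trials_kept, lg$incorrect_outcome,
              lg$no_task_saccade, lg$excluded_electrode))
  if (isTRUE(x$evoked$empty)) {
    cat("  evoked section: empty (no electrode evokes at all currents)\n")
  } else {
    cat(sprintf("  evoked: %d dual-current evoking electrodes; Fisher current p = %.3g, OR = %.3g\n",
                length(x$evoked$dual_electrodes),
                x$evoked$fisher_current$p_value,
                x$evoked$fisher_current$odds_ratio))
  }
  b <- x$latency$baseline[x$latency$baseline$subset == "all", ]
  cat(sprintf("  baseline contra advantage: %.1f ms (median %.1f), p = %.3g\n",
              b$advantage_ms, b$median_advantage_ms, b$p))
  cc <- x$latency$conditions
  for (i in seq_len(nrow(cc)))
    cat(sprintf("  %6s @ %3g uA: stim - control = %+.1f ms (median %+.1f), p = %.3g (n = %d/%d)\n",
                cc$direction[i], cc$current_uA[i], cc$mean_diff_ms[i],
                cc$median_diff_ms[i], cc$p[i], cc$n_stim[i], cc$n_control[i]))
  gt <- x$spatial$group_tests
  for (i in seq_len(nrow(gt)))
    cat(sprintf("  spatial %7s/%6s: %+.1f ms, p = %.3g%s\n",
                gt$group[i], gt$direction[i], gt$mean_effect_ms[i], gt$p[i],
                ifelse(isTRUE(gt$significant[i]), " *", "")))
  kv <- x$kinematics$tests
  n_sig <- sum(kv$significant, na.rm = TRUE)
  cat(sprintf("  kinematics: %d of %d family tests significant at alpha = %.4g\n",
              n_sig, sum(kv$in_family), x$kinematics$alpha_bonferroni))
  invisible(x)
}

#' Write an effect report to disk
#'
#' Writes the machine-readable `report.json` plus per-table CSVs
#' (`latency_conditions.csv`, `latency_baseline.csv`,
#' `spatial_per_electrode.csv`, `spatial_group_tests.csv`,
#' `kinematics_tests.csv`, `evoked_summaries.csv`, `exclusions.csv`,
#' `filter_ledger.csv`).
#'
#' @param report an `effect_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "effect_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(.report_json_ready(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  write.csv(report$latency$conditions,
            file.path(dir, "latency_conditions.csv"), row.names = FALSE)
  write.csv(report$latency$baseline,
            file.path(dir, "latency_baseline.csv"), row.names = FALSE)
  write.csv(report$spatial$per_electrode,
            file.path(dir, "spatial_per_electrode.csv"), row.names = FALSE)
  write.csv(rbind(report$spatial$group_tests[
              c("group", "direction", "mean_effect_ms", "statistic", "df", "p")]),
            file.path(dir, "spatial_group_tests.csv"), row.names = FALSE)
  write.csv(report$kinematics$tests,
            file.path(dir, "kinematics_tests.csv"), row.names = FALSE)
  write.csv(report$evoked$summaries,
            file.path(dir, "evoked_summaries.csv"), row.names = FALSE)
  write.csv(report$exclusions, file.path(dir, "exclusions.csv"),
            row.names = FALSE)
  ledger <- data.frame(key = names(report$filter_ledger),
                       n = unlist(report$filter_ledger))
  write.csv(ledger, file.path(dir, "filter_ledger.csv"), row.names = FALSE)
  invisible(dir)
}

# strip classes/attributes that would make JSON serialization unstable
.report_json_ready <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    return(lapply(unclass(x), .report_json_ready))
  }
  if (is.data.frame(x)) {
    attr(x, "constant_response") <- NULL
    rownames(x) <- NULL
  }
  if (is.matrix(x)) x <- as.data.frame(x)
  x
}
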