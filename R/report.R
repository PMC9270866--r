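# Cohort-level analysis: per-pair summaries and the paired report.

#' Haemodynamic summary of one recording
#'
#' Beat-wise conventions (the acquisition report format does not fix
#' them): heart rate from the mean RR interval of the analysed beats,
#' LVP and RVP as the mean per-cycle peak, CVP as the mean per-cycle
#' mean.
#'
#' @param rec a `channel_recording`.
#' @param cycles its `cycle_landmarks` (computed if omitted).
#' @return named numeric: `hr_bpm`, `lvp_mmhg`, `rvp_mmhg`, `cvp_mmhg`.
#' @export
hemodynamics <- function(rec, cycles = NULL) {
  if (is.null(cycles)) cycles <- segment_cycles(rec)
  rr <- (cycles$next_ed - cycles$ed) / rec$sample_rate
  per_cycle <- function(x, f) {
    vapply(seq_len(nrow(cycles)), function(k)
      f(x[cycles$ed[k]:(cycles$next_ed[k] - 1)]), numeric(1))
  }
  c(hr_bpm = 60 / mean(rr),
    lvp_mmhg = mean(per_cycle(rec$lvp, max)),
    rvp_mmhg = mean(per_cycle(rec$rvp, max)),
    cvp_mmhg = mean(per_cycle(rec$cvp, mean)))
}

#' Full single-pair analysis
#'
#' Runs the standard pipeline on one Baseline/TRA recording pair:
#' cycle segmentation, n-beat averaging, end-diastolic geometry
#' (annular area, hull volume, regional CSA/ROC), haemodynamics and —
#' optionally — regional strain.
#'
#' @param baseline_rec,tra_rec `channel_recording`s of the two states.
#' @param layout the shared `crystal_layout`.
#' @param n_beats consecutive cycles to average (default 4).
#' @param levels subdivision levels for strain (default 2).
#' @param strain compute strain summaries (default TRUE; geometry-only
#'   runs are much faster for large simulation studies).
#' @return list: `geometry` ([geometry_summary()]), `hemo` (per-state
#'   haemodynamics), `beats` (the averaged beats) and, when requested,
#'   `strain` (per-state [cardiac_strain_timecourse()] regional means
#'   at ES) and `interventional` (ED + ES [interventional_strain()]
#'   regional aggregates).
#' @export
analyze_pair <- function(baseline_rec, tra_rec, layout = crystal_layout(),
                         n_beats = 4, levels = 2, strain = TRUE) {
  problems <- c(validate_layout(layout, baseline_rec),
                validate_layout(layout, tra_rec))
  if (length(problems)) stopf("layout/recording mismatch: %s",
                              paste(problems, collapse = "; "))
  run_state <- function(rec) {
    cyc <- segment_cycles(rec)
    list(cycles = cyc, beat = average_beats(rec, cyc, n = n_beats))
  }
  b <- run_state(baseline_rec); t_ <- run_state(tra_rec)
  out <- list(
    geometry = geometry_summary(b$beat, t_$beat, layout),
    hemo = rbind(baseline = hemodynamics(baseline_rec, b$cycles),
                 tra = hemodynamics(tra_rec, t_$cycles)),
    beats = list(baseline = b$beat, tra = t_$beat))
  if (strain) {
    tc_b <- cardiac_strain_timecourse(b$beat, layout, levels)
    tc_t <- cardiac_strain_timecourse(t_$beat, layout, levels)
    es_b <- which.min(abs(tc_b$grid - tc_b$es_phase))
    es_t <- which.min(abs(tc_t$grid - tc_t$es_phase))
    out$strain <- list(
      baseline = tc_b$regional[es_b, , ], tra = tc_t$regional[es_t, , ],
      timecourse = list(baseline = tc_b, tra = tc_t))
    out$interventional <- list(
      ED = regional_aggregate(
        interventional_strain(b$beat, t_$beat, layout, "ED", levels)),
      ES = regional_aggregate(
        interventional_strain(b$beat, t_$beat, layout, "ES", levels)))
  }
  out
}

#' Paired cohort report
#'
#' Mirrors a two-state summary table across recordings: per variable
#' the mean and SD in each state, the paired-t and exact Wilcoxon
#' p-values, and a Shapiro-Wilk normality flag on the paired
#' differences. Variables cover annular area (and percent reduction),
#' hull volume, regional CSA and ROC, and the haemodynamic channels;
#' strain rows are included when the pair analyses carry them.
#'
#' @param pair_analyses list of [analyze_pair()] results, one per
#'   recording pair (>= 2).
#' @return data.frame of class `cohort_report`: one row per variable
#'   with `mean_baseline`, `sd_baseline`, `mean_tra`, `sd_tra`,
#'   `p_t`, `p_wilcoxon`, `normal_diff`; attribute
#'   `taa_reduction_pct` holds the per-pair reduction mean and SD.
#' @export
build_report <- function(pair_analyses) {
  if (length(pair_analyses) < 2) stopf("need >= 2 recording pairs")
  geo_var <- pair_analyses[[1]]$geometry$variable
  get_geo <- function(pa, col) stats::setNames(pa$geometry[[col]], geo_var)
  vars <- list()
  for (v in geo_var)
    vars[[v]] <- vapply(pair_analyses, function(pa)
      c(get_geo(pa, "baseline")[v], get_geo(pa, "tra")[v]), numeric(2))
  for (h in colnames(pair_analyses[[1]]$hemo))
    vars[[h]] <- vapply(pair_analyses, function(pa)
      c(pa$hemo["baseline", h], pa$hemo["tra", h]), numeric(2))
  have_strain <- all(vapply(pair_analyses, function(pa)
    !is.null(pa$strain), logical(1)))
  if (have_strain) {
    for (reg in c("basal", "mid")) for (cp in c("E_cc", "E_ll", "areal")) {
      key <- sprintf("strain_es_%s_%s", reg, cp)
      vars[[key]] <- vapply(pair_analyses, function(pa)
        c(pa$strain$baseline[reg, cp], pa$strain$tra[reg, cp]), numeric(2))
    }
  }
  rows <- lapply(names(vars), function(v) {
    bx <- vars[[v]][1, ]; tx <- vars[[v]][2, ]
    tt <- tryCatch(paired_t_test(bx, tx), error = function(e) NULL)
    wt <- tryCatch(wilcoxon_signed_rank(bx, tx), error = function(e) NULL)
    nm <- tryCatch(shapiro_wilk(bx - tx)$p_value > 0.05,
                   error = function(e) NA)
    data.frame(variable = v,
               mean_baseline = mean(bx), sd_baseline = stats::sd(bx),
               mean_tra = mean(tx), sd_tra = stats::sd(tx),
               p_t = if (is.null(tt)) NA_real_ else tt$p_value,
               p_wilcoxon = if (is.null(wt)) NA_real_ else wt$p_value,
               normal_diff = nm)
  })
  out <- do.call(rbind, rows)
  red <- vapply(pair_analyses, function(pa)
    attr(pa$geometry, "taa_reduction_pct"), numeric(1))
  attr(out, "taa_reduction_pct") <- c(mean = mean(red), sd = stats::sd(red))
  attr(out, "n_pairs") <- length(pair_analyses)
  class(out) <- c("cohort_report", "data.frame")
  out
}

#' @export
print.cohort_report <- function(x, digits = 3, ...) {
  cat(sprintf("Paired cohort report (n = %d pairs), Baseline vs TRA\n",
              attr(x, "n_pairs")))
  df <- x
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits)
  print.data.frame(df, row.names = FALSE)
  red <- attr(x, "taa_reduction_pct")
  cat(sprintf("Annular area reduction: %.1f +/- %.1f %% (per-pair mean +/- SD)\n",
              red["mean"], red["sd"]))
  invisible(x)
}
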