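# Efficacy and safety read-outs computed from recorded trajectories.
# All metrics are pure functions of the saved records.

#' Clot lysis completion time
#'
#' First recorded time at which the binding-site concentration of every
#' clot cell has fallen to or below `threshold_fraction` of its initial
#' value. Resolution equals the recording cadence of the run.
#'
#' @param result A `"lysis_result"`.
#' @param threshold_fraction Residual site fraction counted as lysed
#'   (default from the configuration, 0.05).
#' @return Lysis time in s, or `NA` (attribute `"incomplete" = TRUE`) if
#'   the clot is not lysed by the end of the record.
#' @export
lysis_time <- function(result,
                       threshold_fraction =
                         default_config()$metrics$lysis_threshold) {
  cells <- which(result$in_clot)
  init <- result$n_total_init[cells]
  frac <- sweep(result$n_total[, cells, drop = FALSE], 2, init, "/")
  worst <- apply(frac, 1, max)  # slowest cell at each time
  idx <- which(worst <= threshold_fraction)
  if (!length(idx)) {
    return(structure(NA_real_, incomplete = TRUE))
  }
  result$times[idx[1L]]
}

#' Lysis activation time at a monitoring position
#'
#' First time the binding-site concentration at the cell nearest
#' `x_monitor` drops below `(1 - drop_fraction)` of its initial value,
#' i.e. the moment measurable degradation starts at that depth.
#'
#' @param result A `"lysis_result"`.
#' @param x_monitor Monitoring position, m (default from the clot
#'   configuration; 5 mm in the shipped defaults).
#' @param drop_fraction Fractional site loss marking activation.
#' @return Activation time in s, or `NA` if never reached.
#' @export
activation_time <- function(result, x_monitor = result$clot$x_monitor,
                            drop_fraction =
                              default_config()$metrics$activation_drop) {
  cell <- which.min(abs(result$x - x_monitor))
  crossing_time(result$times, result$n_total[, cell],
                (1 - drop_fraction) * result$n_total_init[cell])
}

# interpolated first downward crossing of `series` through `level`
crossing_time <- function(times, series, level) {
  idx <- which(series <= level)
  if (!length(idx)) return(structure(NA_real_, incomplete = TRUE))
  i <- idx[1L]
  if (i == 1L) return(times[1L])
  v0 <- series[i - 1L]; v1 <- series[i]
  if (v0 <= v1) return(times[i])
  times[i - 1L] + (v0 - level) / (v0 - v1) * (times[i] - times[i - 1L])
}

#' Duration of front lysis at the inlet face
#'
#' Time between lysis activation at the first clot cell (fractional site
#' loss `drop_fraction`) and that cell reaching the lysis threshold.
#' Measures how quickly the front face dissolves once attack has begun.
#'
#' @param result A `"lysis_result"`.
#' @param threshold_fraction Residual fraction counted as lysed.
#' @param drop_fraction Fractional loss marking activation.
#' @return Duration in s, or `NA` if the face never fully lyses.
#' @export
front_lysis_duration <- function(result,
                                 threshold_fraction =
                                   default_config()$metrics$lysis_threshold,
                                 drop_fraction =
                                   default_config()$metrics$activation_drop) {
  cell <- which(result$in_clot)[1L]
  init <- result$n_total_init[cell]
  series <- result$n_total[, cell]
  t_act <- crossing_time(result$times, series, (1 - drop_fraction) * init)
  t_lys <- crossing_time(result$times, series, threshold_fraction * init)
  if (is.na(t_act) || is.na(t_lys)) return(structure(NA_real_,
                                                     incomplete = TRUE))
  t_lys - t_act
}

#' Systemic drug exposure (area under the curve)
#'
#' Trapezoidal integral of the central-compartment drug concentration.
#'
#' @param traj A `"systemic_trajectory"`.
#' @return AUC in uM s.
#' @export
exposure_auc <- function(traj) {
  if (!nrow(traj)) stop("empty trajectory")
  t <- traj$time; y <- traj$Cc
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Safety read-outs: fibrinogen depletion and PAI-1 resistance
#'
#' Systemic fibrinogen nadir (absolute and as a fraction of baseline; low
#' fibrinogen is the proxy for intracranial-haemorrhage risk), minimum
#' systemic PAI-1 (higher retained PAI-1 indicates better inhibition
#' resistance), and the spatial-mean free PAI-1 in the clot at lysis
#' completion (or at the end of the record if lysis is incomplete).
#'
#' @param traj A `"systemic_trajectory"`.
#' @param result A `"lysis_result"` from the same scenario.
#' @param threshold_fraction Lysis threshold used to time the clot PAI-1
#'   read-out.
#' @return Named list: `fbg_nadir_systemic`, `fbg_nadir_fraction`,
#'   `pai_min_systemic`, `pai_at_lysis_clot` (all uM except the fraction).
#' @export
safety_profile <- function(traj, result,
                           threshold_fraction =
                             default_config()$metrics$lysis_threshold) {
  fbg0 <- traj$FBG[1L]
  fbg_nadir <- min(traj$FBG)
  t_lys <- lysis_time(result, threshold_fraction)
  t_ref <- if (is.na(t_lys)) utils::tail(result$times, 1) else t_lys
  i_ref <- which.min(abs(result$times - t_ref))
  pai_clot <- mean(result$C[i_ref, "PAI", result$in_clot])
  list(fbg_nadir_systemic = fbg_nadir,
       fbg_nadir_fraction = fbg_nadir / fbg0,
       pai_min_systemic = min(traj$PAI),
       pai_at_lysis_clot = pai_clot)
}

#' Assemble the full therapy report for one drug scenario
#'
#' @param traj A `"systemic_trajectory"`.
#' @param result A `"lysis_result"`.
#' @param threshold_fraction Lysis threshold.
#' @param drop_fraction Activation fractional drop.
#' @return A list of class `"therapy_report"` with lysis time, activation
#'   time, front lysis duration, drug exposure AUC and the safety profile.
#' @export
therapy_report <- function(traj, result,
                           threshold_fraction =
                             default_config()$metrics$lysis_threshold,
                           drop_fraction =
                             default_config()$metrics$activation_drop) {
  safety <- safety_profile(traj, result, threshold_fraction)
  t_lys <- lysis_time(result, threshold_fraction)
  t_act <- activation_time(result, drop_fraction = drop_fraction)
  rep <- c(list(drug = result$drug,
                lysis_time = as.numeric(t_lys),
                incomplete = is.na(t_lys),
                activation_time = as.numeric(t_act),
                front_lysis_duration =
                  as.numeric(front_lysis_duration(result,
                                                  threshold_fraction,
                                                  drop_fraction)),
                auc_drug_exposure = exposure_auc(traj)),
           safety)
  class(rep) <- c("therapy_report", "list")
  rep
}

#' Cross-drug comparison table
#'
#' Collects therapy reports into one table and ranks the drugs on the four
#' comparison axes: lysis time and activation time (ascending; faster is
#' better), fibrinogen nadir (descending; higher retained fibrinogen means
#' lower haemorrhage risk) and minimum systemic PAI-1 (descending; more
#' retained PAI-1 means better inhibition resistance). Rankings are
#' independent of input order.
#'
#' @param reports List of `"therapy_report"`s.
#' @return A list of class `"comparison_table"`: data.frame `table` plus,
#'   when two or more drugs are present, named ranking vectors (best
#'   first) in `rankings`.
#' @export
compare_drugs <- function(reports) {
  if (!length(reports)) stop("no reports supplied")
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(drug = r$drug,
               lysis_time_min = r$lysis_time / 60,
               activation_time_min = r$activation_time / 60,
               front_lysis_duration_min = r$front_lysis_duration / 60,
               auc_drug_exposure = r$auc_drug_exposure,
               fbg_nadir_systemic = r$fbg_nadir_systemic,
               fbg_nadir_fraction = r$fbg_nadir_fraction,
               pai_min_systemic = r$pai_min_systemic,
               pai_at_lysis_clot = r$pai_at_lysis_clot)
  }))
  tab <- tab[order(tab$drug), , drop = FALSE]
  rownames(tab) <- NULL
  rankings <- NULL
  if (nrow(tab) >= 2L) {
    rankings <- list(
      lysis_time = tab$drug[order(tab$lysis_time_min)],
      activation_time = tab$drug[order(tab$activation_time_min)],
      fbg_safety = tab$drug[order(-tab$fbg_nadir_systemic)],
      pai_resistance = tab$drug[order(-tab$pai_min_systemic)]
    )
  }
  structure(list(table = tab, rankings = rankings),
            class = c("comparison_table", "list"))
}

#' @export
print.therapy_report <- function(x, ...) {
  cat("<therapy_report>", x$drug, "\n")
  fmt_min <- function(v) if (is.na(v)) "incomplete" else
    sprintf("%.1f min", v / 60)
  cat("  lysis time:          ", fmt_min(x$lysis_time), "\n")
  cat("  activation time:     ", fmt_min(x$activation_time), "\n")
  cat("  front lysis duration:", fmt_min(x$front_lysis_duration), "\n")
  cat(sprintf("  drug exposure AUC:    %.3g uM s\n", x$auc_drug_exposure))
  cat(sprintf("  FBG nadir:            %.3g uM (%.1f%% of baseline)\n",
              x$fbg_nadir_systemic, 100 * x$fbg_nadir_fraction))
  cat(sprintf("  PAI-1 min (plasma):   %.3g uM\n", x$pai_min_systemic))
  invisible(x)
}

#' @export
print.comparison_table <- function(x, ...) {
  print(x$table, digits = 3)
  if (!is.null(x$rankings)) {
    cat("\nRankings (best first):\n")
    for (nm in names(x$rankings)) {
      cat(" ", nm, ":", paste(x$rankings[[nm]], collapse = " < "), "\n")
    }
  }
  invisible(x)
}
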