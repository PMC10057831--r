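# Scenario assembly, end-to-end runs and figure generation.

#' Build a simulation scenario
#'
#' Resolves a drug name, regimen, patient, clot and solver settings into a
#' single validated object that fully determines a run.
#'
#' @param drug Drug name (one of [drug_names()]) or a `"drug_parameters"`
#'   list.
#' @param config Scenario configuration, default [default_config()].
#' @param regimen Optional custom [regimen()]; defaults to the drug's
#'   built-in regimen.
#' @param patient A [patient()].
#' @param clot A [clot_config()].
#' @param t_end Simulation horizon, s.
#' @return A list of class `"scenario"`.
#' @export
scenario <- function(drug, config = default_config(), regimen = NULL,
                     patient = thrombosim::patient(config$patient$body_weight),
                     clot = clot_config(config), t_end = 10800) {
  dp <- if (inherits(drug, "drug_parameters")) drug else
    builtin_drug(drug, config)
  reg <- if (is.null(regimen)) builtin_regimen(dp$name, patient, config) else
    regimen
  if (t_end <= 0) stop("t_end must be positive")
  sc <- list(drug = dp, regimen = reg, patient = patient, clot = clot,
             config = config, t_end = t_end)
  class(sc) <- c("scenario", "list")
  sc
}

#' Run a scenario end to end
#'
#' Systemic PK-PD integration, then the local clot simulation driven by
#' the systemic inlet, then the therapy report. Optionally writes the
#' standard run directory (resolved `scenario.yaml`, `systemic.csv`,
#' `clot.csv`, `report.json`, `log.txt`). The whole pipeline is
#' deterministic: identical scenarios produce identical outputs.
#'
#' @param sc A [scenario()].
#' @param dir Optional output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return A list with `systemic` (trajectory), `lysis` (space-time
#'   record) and `report` (therapy report).
#' @export
run_scenario <- function(sc, dir = NULL, quiet = TRUE) {
  stopifnot(inherits(sc, "scenario"))
  cfg <- sc$config
  say <- function(...) if (!quiet) message(...)
  say("simulating systemic PK-PD for ", sc$drug$name)
  traj <- simulate_systemic(sc$drug, sc$regimen,
                            builtin_proteins(cfg), sc$patient,
                            t_end = sc$t_end,
                            dt_out = cfg$solver$dt_out_systemic,
                            kin = plasma_kinetics(cfg),
                            rtol = cfg$solver$rtol, atol = cfg$solver$atol)
  say("simulating local clot lysis")
  lys <- simulate_lysis(sc$drug, traj, sc$clot, sc$t_end, cfg)
  rep <- therapy_report(traj, lys,
                        threshold_fraction = cfg$metrics$lysis_threshold,
                        drop_fraction = cfg$metrics$activation_drop)
  out <- list(systemic = traj, lysis = lys, report = rep)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    resolved <- unclass(cfg)
    resolved$scenario <- list(
      drug = sc$drug$name, t_end = sc$t_end,
      body_weight = sc$patient$body_weight,
      regimen = lapply(sc$regimen$segments, unclass))
    write_config(structure(resolved, class = class(cfg)),
                 file.path(dir, "scenario.yaml"))
    write_systemic_csv(traj, file.path(dir, "systemic.csv"))
    write_lysis_csv(lys, file.path(dir, "clot.csv"))
    jsonlite::write_json(rep[!vapply(rep, is.na, TRUE)],
                         file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(c(paste("thrombosim run:", sc$drug$name),
                 paste("t_end:", sc$t_end, "s"),
                 paste("grid cells:", cfg$solver$n_cells),
                 paste("outer dt:", cfg$solver$dt, "s"),
                 utils::capture.output(print(rep))),
               file.path(dir, "log.txt"))
  }
  out
}

#' Render standard figures for a completed run
#'
#' Produces PNG figures from a run directory written by [run_scenario()]:
#' systemic drug and protein profiles, the binding-site space-time map and
#' the free-drug space-time map.
#'
#' @param dir Run directory containing `systemic.csv` and `clot.csv`.
#' @return Character vector of figure paths, invisibly.
#' @export
plot_results <- function(dir) {
  sys_csv <- file.path(dir, "systemic.csv")
  clot_csv <- file.path(dir, "clot.csv")
  if (!file.exists(sys_csv) || !file.exists(clot_csv)) {
    stop("run directory ", dir, " is missing systemic.csv / clot.csv; ",
         "run run_scenario(sc, dir = ...) first")
  }
  figdir <- file.path(dir, "figures")
  if (!dir.exists(figdir)) dir.create(figdir)
  sys <- utils::read.csv(sys_csv)
  clot <- utils::read.csv(clot_csv)
  paths <- character(0)

  draw <- function(name, fun) {
    p <- file.path(figdir, name)
    grDevices::png(p, width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    fun()
    paths <<- c(paths, p)
  }

  drug_c <- sys[sys$species == "drug" & sys$compartment == "central", ]
  draw("systemic_drug.png", function() {
    graphics::plot(drug_c$time / 60, drug_c$concentration, type = "l",
                   xlab = "time (min)", ylab = "drug (uM)",
                   main = "Central-compartment drug concentration")
  })
  draw("systemic_proteins.png", function() {
    prot <- sys[!sys$species %in% "drug", ]
    sp <- split(prot, prot$species)
    # floor at a display epsilon: plasmin starts at exactly zero
    graphics::matplot(sp[[1]]$time / 60,
                      sapply(sp, function(d) pmax(d$concentration, 1e-12)),
                      type = "l", lty = 1, log = "y",
                      xlab = "time (min)", ylab = "concentration (uM)",
                      main = "Systemic fibrinolytic proteins")
    graphics::legend("bottomleft", legend = names(sp), lty = 1,
                     col = seq_along(sp))
  })
  heat <- function(df, title) {
    tt <- sort(unique(df$time)); xx <- sort(unique(df$x))
    z <- matrix(df$value[order(df$time, df$x)], nrow = length(xx))
    graphics::image(tt / 60, xx * 1000, t(z),
                    xlab = "time (min)", ylab = "x (mm)", main = title,
                    xlim = c(0, max(tt) / 60), ylim = range(xx * 1000),
                    col = grDevices::hcl.colors(64, "viridis"))
  }
  draw("clot_sites.png", function()
    heat(clot[clot$species == "n_total", ], "Binding sites n_total (uM)"))
  draw("clot_drug.png", function()
    heat(clot[clot$species == "drug", ], "Free drug in clot (uM)"))
  invisible(paths)
}

#' Run and compare several drugs under their standard regimens
#'
#' @param drugs Drug names (default all four presets).
#' @param config Scenario configuration.
#' @param t_end Simulation horizon, s.
#' @param quiet Suppress progress messages.
#' @return A `"comparison_table"` (attribute `"runs"` keeps the full run
#'   objects).
#' @export
compare_presets <- function(drugs = drug_names(),
                            config = default_config(), t_end = 10800,
                            quiet = TRUE) {
  runs <- lapply(drugs, function(d) {
    run_scenario(scenario(d, config, t_end = t_end), quiet = quiet)
  })
  names(runs) <- drugs
  cmp <- compare_drugs(lapply(runs, `[[`, "report"))
  attr(cmp, "runs") <- runs
  cmp
}
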