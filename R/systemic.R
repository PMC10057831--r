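SYSTEMIC_STATES <- c("Cc", "Cp", PROTEIN_SPECIES)

#' Plasma-phase plasminogen activation rate
#'
#' Michaelis-Menten conversion of plasminogen to plasmin by a plasminogen
#' activator: `kcat * C_PA * C_PLG / (KM + C_PLG)`. The activator acts
#' catalytically and is not consumed.
#'
#' @param C_PA Activator concentration, uM.
#' @param C_PLG Plasminogen concentration, uM.
#' @param drug A `"drug_parameters"` list.
#' @return Rate of plasmin generation, uM/s.
#' @export
plasma_activation_rate <- function(C_PA, C_PLG, drug) {
  if (any(C_PA < 0) || any(C_PLG < 0)) stop("concentrations must be >= 0")
  drug$kcat_plasma * C_PA * C_PLG / (drug$KM_plasma + C_PLG)
}

#' PAI-1 inhibition rate
#'
#' Bilinear second-order inactivation of the activator by PAI-1:
#' `kPAI * C_PA * C_PAI`. Drug and inhibitor are consumed 1:1.
#'
#' @param C_PA Activator concentration, uM.
#' @param C_PAI PAI-1 concentration, uM.
#' @param drug A `"drug_parameters"` list.
#' @return Rate, uM/s.
#' @export
pai_inhibition_rate <- function(C_PA, C_PAI, drug) {
  if (any(C_PA < 0) || any(C_PAI < 0)) stop("concentrations must be >= 0")
  drug$kPAI * C_PA * C_PAI
}

#' Time derivatives of the systemic state
#'
#' Right-hand side of the coupled two-compartment PK model and plasma-phase
#' fibrinolysis network. State order: drug central (`Cc`), drug peripheral
#' (`Cp`), then PLG, PLS, AP, MG, FBG, PAI. The central-compartment balance
#' carries the infusion source `IV/(Vc*Mw)`, first-order elimination,
#' inter-compartment exchange, endogenous secretion (alteplase/urokinase
#' only) and PAI-1 inhibition; each protein carries homeostatic turnover
#' plus its reaction terms.
#'
#' @param t Time, s.
#' @param state Named numeric vector of the 8 state variables, uM.
#' @param drug A `"drug_parameters"` list.
#' @param reg A [regimen()].
#' @param proteins Protein table from [builtin_proteins()].
#' @param pat A [patient()].
#' @param kin Plasma kinetics from [plasma_kinetics()].
#' @return Named numeric vector of derivatives, uM/s.
#' @export
systemic_rhs <- function(t, state, drug, reg, proteins, pat, kin) {
  if (any(state < 0)) {
    stop("negative systemic state at t = ", t, ": ",
         paste(sprintf("%s=%.3e", names(state), state), collapse = " "))
  }
  Cc <- state[["Cc"]]; Cp <- state[["Cp"]]
  PLG <- state[["PLG"]]; PLS <- state[["PLS"]]
  AP <- state[["AP"]]; MG <- state[["MG"]]
  FBG <- state[["FBG"]]; PAI <- state[["PAI"]]

  Vc <- drug$Vc_per_kg * pat$body_weight
  source_uM <- iv_rate(reg, t) * 1000 / (Vc * drug$Mw)

  r_act <- plasma_activation_rate(Cc, PLG, drug)
  r_pai <- pai_inhibition_rate(Cc, PAI, drug)
  r_ap <- kin$k_AP * PLS * AP
  r_mg <- kin$k_MG * PLS * MG
  r_fbg <- kin$k_FBG * PLS * FBG

  S_PA <- if (drug$endogenous_secretion) drug$kel * drug$C0 else 0

  kel <- stats::setNames(proteins$kel_i, proteins$species)
  S <- stats::setNames(proteins$S_i, proteins$species)

  c(
    Cc = source_uM - drug$kel * Cc - drug$kcp * Cc + drug$kpc * Cp +
      S_PA - r_pai,
    Cp = drug$kcp * Cc - drug$kpc * Cp,
    PLG = -kel[["PLG"]] * PLG + S[["PLG"]] - r_act,
    PLS = -kel[["PLS"]] * PLS + S[["PLS"]] + r_act - r_ap - r_mg,
    AP = -kel[["AP"]] * AP + S[["AP"]] - r_ap,
    MG = -kel[["MG"]] * MG + S[["MG"]] - r_mg,
    FBG = -kel[["FBG"]] * FBG + S[["FBG"]] - r_fbg,
    PAI = -kel[["PAI"]] * PAI + S[["PAI"]] - r_pai
  )
}

#' Baseline (drug-free) systemic state
#'
#' @param drug A `"drug_parameters"` list.
#' @param proteins Protein table from [builtin_proteins()].
#' @return Named state vector at the homeostatic steady state.
#' @export
systemic_baseline <- function(drug, proteins) {
  st <- c(Cc = drug$C0, Cp = 0,
          stats::setNames(proteins$C_init, proteins$species))
  # endogenous drug distributes between compartments at baseline
  if (drug$C0 > 0) st[["Cp"]] <- drug$C0 * drug$kcp / drug$kpc
  st[SYSTEMIC_STATES]
}

#' Simulate the systemic PK-PD model
#'
#' Stiff adaptive integration (lsoda) of the two-compartment drug PK
#' coupled to the plasma fibrinolysis network. Integration restarts at
#' every infusion-segment boundary so the discontinuous infusion rate is
#' never smoothed across a jump.
#'
#' @param drug A `"drug_parameters"` list.
#' @param reg A [regimen()].
#' @param proteins Protein table, default [builtin_proteins()].
#' @param pat A [patient()].
#' @param t_end Simulation horizon, s.
#' @param dt_out Output sampling interval, s.
#' @param kin Plasma kinetics, default [plasma_kinetics()].
#' @param rtol,atol Integrator tolerances. The absolute floor defaults to
#'   1e-12 uM; PAI-1 traverses many orders of magnitude and must not be
#'   truncated.
#' @return A data.frame of class `"systemic_trajectory"` with columns
#'   `time`, `Cc`, `Cp`, `PLG`, `PLS`, `AP`, `MG`, `FBG`, `PAI`.
#' @export
simulate_systemic <- function(drug, reg, proteins = builtin_proteins(),
                              pat = patient(), t_end, dt_out = 5,
                              kin = plasma_kinetics(),
                              rtol = 1e-8, atol = 1e-12) {
  if (t_end <= 0) stop("t_end must be positive")
  breaks <- regimen_breaks(reg)
  breaks <- c(breaks[breaks < t_end], t_end)
  breaks <- sort(unique(c(0, breaks)))

  rhs <- function(t, y, parms) {
    y <- pmax(y, 0)  # guard round-off undershoot only
    names(y) <- SYSTEMIC_STATES
    list(systemic_rhs(t, y, drug, reg, proteins, pat, kin))
  }

  state <- systemic_baseline(drug, proteins)
  rows <- list(c(time = 0, state))
  for (i in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1L]
    times <- unique(c(t0, seq(t0, t1, by = dt_out), t1))
    times <- times[times >= t0 & times <= t1]
    if (length(times) < 2L) times <- c(t0, t1)
    sol <- deSolve::lsoda(y = state, times = times, func = rhs,
                          parms = NULL, rtol = rtol, atol = atol,
                          maxsteps = 50000)
    if (attr(sol, "istate")[1L] < 0) {
      stop("systemic integration failed near t = ",
           utils::tail(sol[, "time"], 1), " s; last state: ",
           paste(sprintf("%.3e", utils::tail(sol, 1)[-1]), collapse = " "))
    }
    sol_mat <- unname(as.matrix(sol))
    for (j in 2:nrow(sol_mat)) {
      rows[[length(rows) + 1L]] <- stats::setNames(
        sol_mat[j, ], c("time", SYSTEMIC_STATES))
    }
    state <- pmax(sol_mat[nrow(sol_mat), -1L], 0)
    names(state) <- SYSTEMIC_STATES
  }
  traj <- as.data.frame(do.call(rbind, rows))
  traj <- traj[!duplicated(traj$time), , drop = FALSE]
  rownames(traj) <- NULL
  structure(traj,
            class = c("systemic_trajectory", "data.frame"),
            drug = drug$name, body_weight = pat$body_weight)
}

#' Write a systemic trajectory as tidy long-format CSV
#'
#' @param traj A `"systemic_trajectory"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_systemic_csv <- function(traj, path) {
  species <- setdiff(names(traj), "time")
  long <- do.call(rbind, lapply(species, function(s) {
    data.frame(time = traj$time,
               compartment = if (s == "Cp") "peripheral" else "central",
               species = if (s %in% c("Cc", "Cp")) "drug" else s,
               concentration = traj[[s]])
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
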