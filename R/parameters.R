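.thrombosim_env <- new.env(parent = emptyenv())

PROTEIN_SPECIES <- c("PLG", "PLS", "AP", "MG", "FBG", "PAI")

#' Names of the built-in thrombolytic drugs
#'
#' @return Character vector of the four supported plasminogen activators.
#' @export
drug_names <- function() {
  c("alteplase", "tenecteplase", "reteplase", "urokinase")
}

#' Load the default scenario configuration
#'
#' Reads the packaged `defaults.yaml`, the single source of every constant
#' used by the simulator: published drug-specific kinetic and PK parameters,
#' and the calibration surface (plasma fibrinolytic-protein levels and
#' kinetics, clot micro-structure, solver settings). The parsed list is
#' cached for the session.
#'
#' @param path Optional path to an alternative YAML configuration file.
#' @return A nested list with class `"thrombosim_config"`.
#' @export
default_config <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.thrombosim_env$config)) {
      return(.thrombosim_env$config)
    }
    path <- system.file("extdata", "defaults.yaml", package = "thrombosim")
    if (!nzchar(path)) {
      stop("packaged defaults.yaml not found; is thrombosim installed?")
    }
    cfg <- read_config(path)
    .thrombosim_env$config <- cfg
    return(cfg)
  }
  read_config(path)
}

#' Read a scenario configuration file
#'
#' @param path Path to a YAML file following the documented schema
#'   (`schema_version` 1).
#' @return A `"thrombosim_config"` list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema_version) || cfg$schema_version != 1) {
    stop("unsupported or missing schema_version in ", path,
         " (expected 1)")
  }
  for (section in c("patient", "drugs", "proteins", "plasma_kinetics",
                    "clot", "binding", "metrics", "solver")) {
    if (is.null(cfg[[section]])) {
      stop("configuration is missing section '", section, "'")
    }
  }
  class(cfg) <- c("thrombosim_config", "list")
  cfg
}

#' Write a scenario configuration file
#'
#' Serialization keeps full double precision so that a write/read round trip
#' reproduces every field exactly.
#'
#' @param config A `"thrombosim_config"` list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path,
                   precision = 17L, handlers = list(
                     logical = function(x) {
                       result <- ifelse(x, "true", "false")
                       class(result) <- "verbatim"
                       result
                     }))
  invisible(path)
}

#' Kinetic and pharmacokinetic parameters of a built-in drug
#'
#' Assembles the full parameter set for one plasminogen activator in the
#' internal unit system (uM, s): plasma-phase Michaelis-Menten activation
#' constants, PAI-1 inhibition rate, two-compartment PK constants, and
#' clot-phase fibrin binding and catalysis constants. Urokinase carries no
#' fibrin affinity, so its adsorption constants are zero and its dissociation
#' constant is absent (`NA`).
#'
#' @param name One of [drug_names()].
#' @param config Scenario configuration, defaults to [default_config()].
#' @return A list of class `"drug_parameters"`.
#' @export
builtin_drug <- function(name, config = default_config()) {
  if (length(name) != 1L || !name %in% drug_names()) {
    stop("unknown drug '", paste(name, collapse = ","),
         "'; valid names: ", paste(drug_names(), collapse = ", "))
  }
  raw <- config$drugs[[name]]
  dp <- list(
    name = name,
    C0 = raw$C0_nM * 1e-3,   # nM -> uM
    KM_plasma = raw$KM_plasma,
    kcat_plasma = raw$kcat_plasma,
    kPAI = raw$kPAI,
    kel = raw$kel,
    kcp = raw$kcp,
    kpc = raw$kpc,
    Vc_per_kg = raw$Vc_per_kg,
    Mw = raw$Mw,
    ka = raw$ka,
    kd_off = raw$kd_off,
    Kd = if (isTRUE(raw$fibrin_binding)) raw$kd_off / raw$ka else NA_real_,
    KM_clot = raw$KM_clot,
    kcat_clot = raw$kcat_clot,
    fibrin_binding = isTRUE(raw$fibrin_binding),
    endogenous_secretion = isTRUE(raw$endogenous_secretion)
  )
  class(dp) <- c("drug_parameters", "list")
  validate_drug(dp)
  dp
}

#' Validate a drug parameter set
#'
#' Checks positivity of rate constants, consistency of the fibrin binding
#' flags (no binding implies zero adsorption/desorption and an absent Kd),
#' and that engineered variants carry no endogenous baseline.
#'
#' @param dp A `"drug_parameters"` list.
#' @return `dp`, invisibly; stops on violation.
#' @export
validate_drug <- function(dp) {
  rates <- c(dp$kcat_plasma, dp$kPAI, dp$kel, dp$kcp, dp$kpc,
             dp$ka, dp$kd_off, dp$kcat_clot)
  if (any(rates < 0)) stop("drug '", dp$name, "': negative rate constant")
  if (dp$KM_plasma <= 0 || dp$KM_clot <= 0) {
    stop("drug '", dp$name, "': Michaelis constants must be positive")
  }
  if (dp$Vc_per_kg <= 0 || dp$Mw <= 0) {
    stop("drug '", dp$name, "': Vc_per_kg and Mw must be positive")
  }
  if (!dp$fibrin_binding) {
    if (dp$ka != 0 || dp$kd_off != 0 || !is.na(dp$Kd)) {
      stop("drug '", dp$name,
           "': non-binding drug must have ka = kd_off = 0 and absent Kd")
    }
  } else {
    if (abs(dp$Kd - dp$kd_off / dp$ka) / dp$Kd >= 1e-9) {
      stop("drug '", dp$name, "': Kd inconsistent with kd_off/ka")
    }
  }
  if (!dp$endogenous_secretion && dp$C0 != 0) {
    stop("drug '", dp$name,
         "': engineered variants have no endogenous baseline (C0 must be 0)")
  }
  invisible(dp)
}

#' Systemic fibrinolytic protein parameters
#'
#' Returns initial plasma concentrations and turnover constants for the six
#' fibrinolytic proteins (plasminogen, plasmin, alpha2-antiplasmin,
#' alpha2-macroglobulin, fibrinogen, PAI-1). Secretion rates are derived
#' from homeostasis, `S_i = kel_i * C_init`, so the drug-free plasma is at
#' steady state.
#'
#' @param config Scenario configuration.
#' @return A data.frame with columns `species`, `C_init`, `kel_i`, `S_i`.
#' @export
builtin_proteins <- function(config = default_config()) {
  pr <- config$proteins
  stopifnot(all(PROTEIN_SPECIES %in% names(pr)))
  out <- data.frame(
    species = PROTEIN_SPECIES,
    C_init = vapply(PROTEIN_SPECIES, function(s) pr[[s]]$C_init, 0),
    kel_i = vapply(PROTEIN_SPECIES, function(s) pr[[s]]$kel_i, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (any(out$C_init < 0) || any(out$kel_i < 0)) {
    stop("protein concentrations and turnover constants must be >= 0")
  }
  out$S_i <- out$kel_i * out$C_init
  out
}

#' Clot geometry and micro-structure configuration
#'
#' @param config Scenario configuration.
#' @param ... Named overrides for individual fields (e.g. `n_total_init`).
#' @return A list of class `"clot_config"`.
#' @export
clot_config <- function(config = default_config(), ...) {
  cl <- config$clot
  overrides <- list(...)
  cl[names(overrides)] <- overrides
  if (cl$epsilon_clot <= 0 || cl$epsilon_clot >= 1) {
    stop("epsilon_clot must lie strictly in (0, 1)")
  }
  positive <- c("L_clot", "fiber_radius", "n_total_init", "mu", "D_i",
                "kdeg", "gamma")
  for (f in positive) {
    if (cl[[f]] <= 0) stop("clot field '", f, "' must be positive")
  }
  if (cl$dp_per_length < 0) stop("dp_per_length must be >= 0")
  if (cl$x_monitor < 0 || cl$x_monitor > cl$L_clot) {
    stop("x_monitor must lie within [0, L_clot]")
  }
  class(cl) <- c("clot_config", "list")
  cl
}

#' Patient description
#'
#' @param body_weight Body weight in kg (default 80).
#' @return A list of class `"patient"`.
#' @export
patient <- function(body_weight = 80) {
  if (body_weight <= 0) stop("body_weight must be positive")
  structure(list(body_weight = body_weight), class = c("patient", "list"))
}

#' Convert an administered drug mass to a plasma concentration
#'
#' Divides a mass in mg by the molar mass and the central-compartment
#' distribution volume: `1000 * mg / (Mw * Vc_per_kg * body_weight)` in uM.
#'
#' @param mass_mg Drug mass, mg (scalar or vector, `>= 0`).
#' @param drug A `"drug_parameters"` list.
#' @param patient A `"patient"` list.
#' @return Concentration in uM.
#' @export
mg_to_concentration <- function(mass_mg, drug, patient) {
  if (any(mass_mg < 0)) stop("mass_mg must be >= 0")
  1000 * mass_mg / (drug$Mw * drug$Vc_per_kg * patient$body_weight)
}

#' Plasma-phase reaction constants
#'
#' Second-order mass-action constants for plasmin inhibition by
#' alpha2-antiplasmin and alpha2-macroglobulin and for plasmin-mediated
#' fibrinogen degradation, shared by the systemic and local models.
#'
#' @param config Scenario configuration.
#' @return Named list with `k_AP`, `k_MG`, `k_FBG` (1/(uM s)).
#' @export
plasma_kinetics <- function(config = default_config()) {
  kin <- config$plasma_kinetics
  stopifnot(all(c("k_AP", "k_MG", "k_FBG") %in% names(kin)),
            kin$k_AP >= 0, kin$k_MG >= 0, kin$k_FBG >= 0)
  kin
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat("<drug_parameters>", x$name, "\n")
  cat(sprintf("  plasma: KM = %g uM, kcat = %g 1/s, kPAI = %g 1/(uM s)\n",
              x$KM_plasma, x$kcat_plasma, x$kPAI))
  cat(sprintf("  PK: kel = %g, kcp = %g, kpc = %g 1/s; Vc = %g L/kg; Mw = %g\n",
              x$kel, x$kcp, x$kpc, x$Vc_per_kg, x$Mw))
  if (x$fibrin_binding) {
    cat(sprintf("  clot: ka = %g, kd = %g (Kd = %g uM), KM = %g, kcat = %g\n",
                x$ka, x$kd_off, x$Kd, x$KM_clot, x$kcat_clot))
  } else {
    cat(sprintf("  clot: no fibrin binding; KM = %g uM, kcat = %g 1/s\n",
                x$KM_clot, x$kcat_clot))
  }
  invisible(x)
}
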