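# Shared fixtures. Coupled-model runs are expensive; cache them once per
# test session and reuse across test files.

.fixture_env <- new.env(parent = emptyenv())

fast_config <- function(...) {
  cfg <- default_config()
  overrides <- list(...)
  for (nm in names(overrides)) {
    path <- strsplit(nm, "\\.")[[1]]
    cfg[[path]] <- overrides[[nm]]
  }
  cfg
}

# coarse but complete coupled run, memoized
coupled_run <- function(drug_name, t_end = 3600, n_cells = 25, dt = 1) {
  key <- paste(drug_name, t_end, n_cells, dt, sep = "_")
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  cfg <- default_config()
  pat <- patient(cfg$patient$body_weight)
  dp <- builtin_drug(drug_name, cfg)
  reg <- builtin_regimen(drug_name, pat)
  traj <- simulate_systemic(dp, reg, builtin_proteins(cfg), pat,
                            t_end = t_end, kin = plasma_kinetics(cfg))
  lys <- simulate_lysis(dp, traj, clot_config(cfg), t_end, cfg,
                        n_cells = n_cells, dt = dt,
                        stop_on_lysis = TRUE, stop_fraction = 0.004)
  out <- list(traj = traj, lys = lys)
  .fixture_env[[key]] <- out
  out
}

# synthetic lysis record with prescribed site dynamics, for metric tests
synthetic_lysis_record <- function(times, n_total_mat, x = NULL,
                                   clot = clot_config()) {
  nx <- ncol(n_total_mat)
  if (is.null(x)) x <- (seq_len(nx) - 0.5) * clot$L_clot / nx
  C <- array(0, c(length(times), 7, nx),
             dimnames = list(NULL,
                             c("drug", "PLG", "PLS", "AP", "MG", "FBG",
                               "PAI"), NULL))
  structure(list(times = times, x = x, C = C,
                 b = array(0, c(length(times), 3, nx)),
                 n_total = n_total_mat,
                 epsilon = 1 - (1 - clot$epsilon_clot) *
                   sweep(n_total_mat, 2, n_total_mat[1, ], "/"),
                 U = rep(0, length(times)),
                 in_clot = rep(TRUE, nx),
                 n_total_init = n_total_mat[1, ],
                 drug = "synthetic", clot = clot, t_end = max(times)),
            class = c("lysis_result", "list"))
}

# helper: minimal hand-built field for transport-only experiments
bare_field <- function(n = 50, dx = 2e-4, eps = 1, U = 1e-5,
                       C0 = NULL) {
  C <- matrix(0, 7, n, dimnames = list(
    c("drug", "PLG", "PLS", "AP", "MG", "FBG", "PAI"), NULL))
  if (!is.null(C0)) C <- C0
  structure(list(x = (seq_len(n) - 0.5) * dx, dx = dx, C = C,
                 b = matrix(0, 3, n,
                            dimnames = list(c("drug", "PLG", "PLS"), NULL)),
                 n_total = rep(0, n), n_total_init = rep(0, n),
                 epsilon = rep(eps, n), epsilon_clot = 0.6,
                 in_clot = rep(TRUE, n), U = U),
            class = c("clot_field", "list"))
}

zero_inlet <- stats::setNames(rep(0, 7),
                              c("drug", "PLG", "PLS", "AP", "MG", "FBG",
                                "PAI"))

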