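test_that("Davis permeability is monotone, scales with fiber radius, and
          matches a hand evaluation", {
  expect_lt(davis_permeability(0.6, 1e-7), davis_permeability(0.9, 1e-7))
  expect_equal(davis_permeability(0.8, 2e-7),
               4 * davis_permeability(0.8, 1e-7))
  # hand evaluation at eps = 0.75, r = 100 nm:
  # k = (1e-7)^2 / (16 * 0.25^1.5 * (1 + 56 * 0.25^3)) = 2.6667e-15
  expect_equal(davis_permeability(0.75, 1e-7),
               1e-14 / (16 * 0.125 * (1 + 56 * 0.015625)),
               tolerance = 1e-12)
  expect_error(davis_permeability(1, 1e-7), "epsilon")
  expect_error(davis_permeability(0, 1e-7), "epsilon")
})

test_that("Darcy velocity responds linearly to pressure and inversely to
          viscosity", {
  expect_identical(darcy_velocity(1e-13, 1.5e-3, 0), 0)
  expect_equal(darcy_velocity(1e-13, 3e-3, 2e5),
               darcy_velocity(1e-13, 1.5e-3, 2e5) / 2)
})

test_that("series permeability composes cells like resistances", {
  rf <- 1e-6
  eps <- c(0.6, 0.8)
  k1 <- davis_permeability(0.6, rf); k2 <- davis_permeability(0.8, rf)
  expect_equal(series_permeability(eps, rf), 2 / (1 / k1 + 1 / k2))
  # a fully lysed cell contributes negligible resistance
  k_half <- series_permeability(c(0.6, 1), rf)
  expect_gt(k_half, 1.9 * k1)
})

test_that("transport-only step conserves mass to 1e-8 per species", {
  set.seed(11)
  fld <- bare_field(n = 40, eps = 0.7, U = 2e-5)
  fld$C[] <- runif(length(fld$C), 0, 5)
  inlet <- stats::setNames(runif(7, 0, 3), rownames(fld$C))
  for (i in 1:5) {
    fld <- step_transport(fld, inlet, dt = 1, D = 5e-11)
    resid <- attr(fld, "mass_balance")
    scale <- max(1, max(fld$C))
    expect_lt(max(abs(resid)) / scale, 1e-8)
  }
})

test_that("a step profile advects at the Darcy pore velocity with mass
          conserved to 1e-9", {
  U <- 2e-5
  fld <- bare_field(n = 100, dx = 1e-4, eps = 1, U = U)
  fld$C["drug", 1:20] <- 1   # step profile
  mass0 <- sum(fld$C["drug", ]) * fld$dx
  t_total <- 200
  inflow <- 0
  for (i in 1:40) fld <- step_transport(fld, zero_inlet, t_total / 40, D = 0)
  mass1 <- sum(fld$C["drug", ]) * fld$dx
  expect_equal(mass1, mass0, tolerance = 1e-9)
  # centre of mass moved by U * t (eps = 1, no outflow reached)
  com0 <- (20 * 1e-4) / 2 + 0.5e-4 * 0  # initial centre of the block
  com0 <- sum(fld$x[1:20]) / 20
  com1 <- sum(fld$x * fld$C["drug", ]) / sum(fld$C["drug", ])
  expect_equal(com1 - com0, U * t_total, tolerance = 0.02 * U * t_total)
})

test_that("pure diffusion spreads a pulse with variance growth 2Dt", {
  D <- 2e-9   # large enough to dominate numerical diffusion
  fld <- bare_field(n = 201, dx = 1e-4, eps = 1, U = 0)
  mid <- 101
  # narrow Gaussian initial pulse, far from both boundaries
  sigma0 <- 4e-4
  fld$C["drug", ] <- exp(-(fld$x - fld$x[mid])^2 / (2 * sigma0^2))
  mass0 <- sum(fld$C["drug", ]) * fld$dx
  t_total <- 20
  for (i in 1:20) fld <- step_transport(fld, zero_inlet, 1, D = D)
  w <- fld$C["drug", ] / sum(fld$C["drug", ])
  mu <- sum(w * fld$x)
  var1 <- sum(w * (fld$x - mu)^2)
  expect_equal(var1, sigma0^2 + 2 * D * t_total,
               tolerance = 0.01 * (sigma0^2 + 2 * D * t_total))
  expect_equal(sum(fld$C["drug", ]) * fld$dx, mass0, tolerance = 1e-9)
})

test_that("zero inlet, zero initial state, no reactions stays zero", {
  fld <- bare_field(n = 30, eps = 0.7, U = 1e-5)
  for (i in 1:10) fld <- step_transport(fld, zero_inlet, 1, D = 5e-11)
  expect_identical(max(abs(fld$C)), 0)
})

test_that("binding rates honour the urokinase no-affinity special case", {
  uro <- builtin_drug("urokinase")
  clot <- clot_config()
  bind <- default_config()$binding
  rt <- binding_rates(C_drug = 0.02, C_PLG = 2, C_PLS = 0.1, C_PAI = 1e-3,
                      b_drug = 0, b_PLG = 0.3, b_PLS = 0.05,
                      n_free = 3, drug = uro, clot = clot, bind = bind)
  expect_identical(rt$ads_drug, 0)
  # plasmin generation driven by the free drug concentration
  KM_eff <- uro$KM_clot * (1 - clot$epsilon_clot)
  expect_equal(rt$gen_PLS, 2.6 * 0.02 * 0.3 / (KM_eff + 0.3))
  # no bound plasminogen, no generation
  rt0 <- binding_rates(0.02, 2, 0.1, 1e-3, 0, 0, 0.05, 3, uro, clot, bind)
  expect_identical(rt0$gen_PLS, 0)
})

test_that("with catalysis off, bound/free drug settles at the Langmuir
          equilibrium implied by Kd", {
  for (dn in c("alteplase", "tenecteplase", "reteplase")) {
    dp <- builtin_drug(dn)
    dp$kcat_clot <- 0          # no catalysis
    cfg <- default_config()
    # no site loss, no clot-resident inhibitor: pure adsorption kinetics
    clot <- clot_config(cfg, kdeg = 1e-12, PAI_clot_init = 0,
                        n_total_init = 1)
    C_in <- 0.2
    traj <- structure(data.frame(time = c(0, 9000), Cc = C_in, Cp = 0,
                                 PLG = 0, PLS = 0, AP = 0, MG = 0,
                                 FBG = 0, PAI = 0),
                      class = c("systemic_trajectory", "data.frame"))
    lys <- simulate_lysis(dp, traj, clot, t_end = 9000, cfg,
                          n_cells = 6, dt = 2, output_dt = 400)
    i <- length(lys$times)
    C_f <- lys$C[i, "drug", 1]
    b_f <- lys$b[i, "drug", 1]
    n_free <- lys$n_total[i, 1] - sum(lys$b[i, , 1])
    # r = 0  =>  b / (C * n_free) = 1 / Kd
    expect_equal(unname(b_f / (C_f * n_free)), 1 / dp$Kd,
                 tolerance = 1e-3,
                 info = dn)
  }
})

test_that("site degradation follows the linear closed form and floors at
          zero", {
  clot <- clot_config()
  expect_identical(degrade_sites(5, 0, clot, 100), 5)
  # constant plasmin: slope is exactly -kdeg * gamma * n_PLS
  n1 <- degrade_sites(5, 0.2, clot, 10)
  expect_equal(5 - n1, clot$kdeg * clot$gamma * 0.2 * 10)
  expect_identical(degrade_sites(1e-9, 50, clot, 1e6), 0)
  expect_error(degrade_sites(-1, 0, clot, 1), "non-negative")
})

test_that("porosity closure interpolates between intact clot and open
          lumen", {
  expect_equal(porosity_from_sites(5, 5, 0.6), 0.6)
  expect_equal(porosity_from_sites(0, 5, 0.6), 1)
  expect_equal(porosity_from_sites(2.5, 5, 0.6), 0.8)
})

test_that("coupled run invariants hold: sites non-increasing, bound cap,
          non-negativity, no bound urokinase", {
  for (dn in c("alteplase", "urokinase")) {
    run <- coupled_run(dn, t_end = 1200, n_cells = 12, dt = 2)
    lys <- run$lys
    expect_true(all(lys$C >= 0) && all(lys$b >= 0), info = dn)
    expect_true(all(diff(lys$n_total) <= 1e-12), info = dn)
    bound_sum <- apply(lys$b, c(1, 3), sum)
    expect_true(all(bound_sum <= lys$n_total + 1e-9), info = dn)
    expect_true(all(lys$epsilon >= lys$clot$epsilon_clot - 1e-12 &
                      lys$epsilon <= 1 + 1e-12), info = dn)
  }
  uro <- coupled_run("urokinase", t_end = 1200, n_cells = 12, dt = 2)
  expect_identical(max(uro$lys$b[, "drug", ]), 0)
})

test_that("a drug-free inlet leaves the binding sites untouched", {
  dp <- builtin_drug("alteplase")
  cfg <- default_config()
  base <- stats::setNames(builtin_proteins(cfg)$C_init,
                          builtin_proteins(cfg)$species)
  traj <- structure(data.frame(time = c(0, 7200), Cc = 0, Cp = 0,
                               PLG = base[["PLG"]], PLS = 0,
                               AP = base[["AP"]], MG = base[["MG"]],
                               FBG = base[["FBG"]], PAI = base[["PAI"]]),
                    class = c("systemic_trajectory", "data.frame"))
  lys <- simulate_lysis(dp, traj, clot_config(cfg), t_end = 7200, cfg,
                        n_cells = 10, dt = 5, output_dt = 600)
  final <- lys$n_total[length(lys$times), ]
  # the endogenous activator baseline (C0, sub-nM) causes at most a
  # parts-per-thousand site loss over two hours
  expect_equal(final, lys$n_total[1, ], tolerance = 1e-3)
  expect_true(is.na(lysis_time(lys)))
})

test_that("doubling the inlet drug concentration never slows lysis", {
  for (dn in c("alteplase", "urokinase")) {
    run <- coupled_run(dn, t_end = 3600, n_cells = 12, dt = 2)
    cfg <- default_config()
    dp <- builtin_drug(dn, cfg)
    lys2 <- simulate_lysis(dp, run$traj, clot_config(cfg), 3600, cfg,
                           n_cells = 12, dt = 2, stop_on_lysis = TRUE,
                           stop_fraction = 0.004, inlet_scale = 2)
    t1 <- lysis_time(run$lys)
    t2 <- lysis_time(lys2)
    if (is.na(t1)) {
      succeed()  # baseline did not complete within the window
    } else {
      expect_false(is.na(t2), info = dn)
      expect_lte(t2, t1 * 1.001, expected.label = dn)
    }
  }
})
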