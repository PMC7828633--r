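test_that("plasma forcing follows the closed-form infusion solution", {
  reg <- dose_regimen()
  expect_equal(plasma_concentration(0, reg), 0)
  # end of a 15-min, 1 g infusion with CL 297 L/h and V 108 L
  expect_equal(plasma_concentration(15, reg), 6.695871, tolerance = 1e-6)
  # washout is mono-exponential with k = CL/V
  k <- (297 / 108) / 60
  expect_equal(plasma_concentration(100, reg),
               plasma_concentration(15, reg) * exp(-k * 85),
               tolerance = 1e-12)
  # AUC to infinity equals Dose/CL = 202.0 mg min/L
  t <- seq(0, 600, by = 1)
  expect_equal(auc_infinity(plasma_concentration(t, reg), t)$auc_inf,
               1000 / (297000 / 60) * 1000, tolerance = 1e-3)
  expect_error(dose_regimen(dose_g = 0), "positive")
})

test_that("the assembled system is Metzler and mass-conservative", {
  phys <- default_physiology()
  drug <- panel_drugs()[["morphine"]]
  sys <- build_system(drug, phys,
                      build_clearances(drug, phys, af = af_passive))
  K <- sys$K
  expect_equal(dim(K), c(8, 8))
  off <- K - diag(diag(K))
  expect_true(all(off >= 0))                  # non-negative couplings
  expect_true(all(diag(K) < 0))
  # column sums equal minus the loss to plasma: nothing else leaves
  expect_equal(colSums(K), -sys$loss)
  # a missing clearance is an assembly error
  cl <- build_clearances(drug, phys, af = af_passive)
  cl$bbb_para <- NULL
  expect_error(build_system(drug, phys, cl), "bbb_para")
})

test_that("with only the blood flow connected, MV tracks plasma and the rest stays empty", {
  phys <- default_physiology()
  drug <- panel_drugs()[["caffeine"]]
  cl <- build_clearances(drug, phys, af = af_passive)
  for (f in setdiff(names(cl), c("q_cbf", "af"))) cl[[f]] <- 0
  sim <- simulate_cns(build_system(drug, phys, cl), auto_extend = FALSE)
  others <- setdiff(colnames(sim$conc), c("plasma", "brain_MV"))
  expect_true(all(sim$conc[, others] == 0))
  # MV equilibrates fast (k = Q/V ~ 15/min): it shadows plasma closely
  late <- sim$time > 30
  expect_equal(sim$conc[late, "brain_MV"], sim$conc[late, "plasma"],
               tolerance = 5e-3)
})

test_that("simulations conserve mass and scale linearly with dose", {
  drug <- panel_drugs()[["thiopental"]]
  sim <- simulate_drug(drug, af = af_passive)
  expect_lt(sim$diagnostics$mass_balance_error, 1e-6)
  expect_true(all(sim$conc >= 0))
  expect_true(all(diff(sim$time) > 0))
  # doubling the dose doubles every trace (to solver tolerance)
  sim2 <- simulate_drug(drug, af = af_passive,
                        regimen = dose_regimen(dose_g = 2))
  expect_equal(sim2$conc, 2 * sim$conc, tolerance = 1e-5)
})

test_that("ECF profiles peak once, inside the horizon", {
  sim <- simulate_drug(panel_drugs()[["caffeine"]], af = af_passive)
  tr <- sim$conc[, "brain_ECF"]
  i <- which.max(tr)
  expect_gt(i, 1)
  expect_lt(i, length(tr))
  # single interior maximum: rises before, decays after
  expect_true(all(diff(tr[1:i]) > 0))
  expect_true(all(diff(tr[i:length(tr)]) < 0))
})

test_that("simulated AUC ratios agree with the flux-balance closed form", {
  phys <- default_physiology()
  for (nm in c("caffeine", "gabapentin", "thiopental")) {
    d <- panel_drugs()[[nm]]
    cl <- build_clearances(d, phys, af = af_passive)
    expected <- steady_state_kpuu(cl$bbb_para, cl$bbb_in, cl$bbb_ef,
                                  cl$q_ecf_bulk)
    sim <- simulate_drug(d, af = af_passive)
    expect_equal(
      kpuu(sim$conc[, "brain_ECF"], sim$conc[, "brain_MV"], sim$time),
      expected, tolerance = 0.02, label = nm)
  }
})

test_that("pH partitioning sets the cell and lysosome AUC ratios", {
  phys <- default_physiology()
  morphine <- panel_drugs()[["morphine"]]
  ion <- morphine$ionization
  sim <- simulate_drug(morphine, af = af_passive)
  expect_true(sim$diagnostics$extended)  # slow cell equilibration
  # Kp_uu,cell equals the unionized-fraction ratio ECF/ICF (oracle 1.9804)
  expect_equal(
    kpuu(sim$conc[, "brain_ICF"], sim$conc[, "brain_ECF"], sim$time),
    fraction_unionized(ion, phys$pH_ECF) /
      fraction_unionized(ion, phys$pH_ICF),
    tolerance = 0.01)
  # lysosome/ICF AUC ratio likewise equals fu(pH_ICF)/fu(pH_LYS):
  # a base is trapped in the acidic lysosome
  expect_equal(
    kpuu(sim$conc[, "lysosome"], sim$conc[, "brain_ICF"], sim$time),
    fraction_unionized(ion, phys$pH_ICF) /
      fraction_unionized(ion, phys$pH_LYS),
    tolerance = 0.01)
})

test_that("neutral drugs are bitwise insensitive to pH scenarios", {
  caffeine <- panel_drugs()[["caffeine"]]
  ref <- simulate_drug(caffeine)
  for (scn in c("pH_ECF_low", "pH_ECF_high", "pH_ICF_low", "pH_ICF_high")) {
    alt <- simulate_drug(caffeine, scenario = default_scenarios()[[scn]])
    expect_identical(alt$conc, ref$conc, label = scn)
  }
})

test_that("tidy trace export round-trips through CSV", {
  sim <- simulate_drug(panel_drugs()[["caffeine"]], af = af_passive)
  df <- as.data.frame(sim)
  expect_named(df, c("time", "compartment", "conc"))
  expect_equal(nrow(df), length(sim$time) * ncol(sim$conc))
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  back <- utils::read.csv(f)
  expect_equal(back$conc, df$conc, tolerance = 1e-12)
  ecf <- back[back$compartment == "brain_ECF", ]
  expect_equal(ecf$conc, unname(sim$conc[, "brain_ECF"]),
               tolerance = 1e-12)
})
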