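test_that("the standard scenario set is the reference plus ten perturbations", {
  scns <- default_scenarios()
  expect_length(scns, 11)
  expect_equal(scns[["reference"]]$mode, "reference")
  expect_equal(scns[["pH_ECF_low"]]$mode, "absolute")
  expect_equal(scns[["pH_ECF_low"]]$value, 5)
  expect_equal(scns[["pH_ECF_high"]]$value, 8)
  expect_equal(scns[["pH_ICF_low"]]$value, 6)
  expect_equal(scns[["pH_ICF_high"]]$value, 7.6)
  expect_equal(scns[["para_radius_high"]]$value, 5)
  expect_equal(scns[["para_radius_low"]]$value, 0.5)
  expect_equal(scns[["CBF_low"]]$value, 0.7)
  expect_equal(scns[["V_ECF_high"]]$value, 1.5)
  vapply(scns[-1], function(s) s$mode, character(1)) |>
    unique() |>
    setdiff(c("multiplier", "absolute")) |>
    expect_length(0)
})

test_that("applying a scenario changes exactly one parameter", {
  phys <- default_physiology()
  scns <- default_scenarios()
  expect_identical(apply_scenario(phys, scns[["reference"]]), phys)

  p <- apply_scenario(phys, scns[["CBF_low"]])
  expect_equal(p$Q_CBF, 482.3)
  expect_equal(unclass(p)[names(p) != "Q_CBF"],
               unclass(phys)[names(phys) != "Q_CBF"])

  p <- apply_scenario(phys, scns[["V_ECF_high"]])
  expect_equal(p$V_ECF, 379.5)
  expect_equal(p$V_ICF, phys$V_ICF)        # ICF untouched
  expect_equal(p$Q_ECF_bulk, phys$Q_ECF_bulk)
  expect_equal(p$SA_BBB, phys$SA_BBB)

  p <- apply_scenario(phys, scns[["pH_ECF_low"]])
  expect_equal(p$pH_ECF, 5)

  # a perturbation that breaks an invariant is refused with the violation
  bad <- scenario("bad", "Q_CBF", "multiplier", 1e-12)
  p2 <- phys
  p2$Q_CBF <- 0.1
  expect_error(apply_scenario(p2, scenario("neg", "V_ECF", "multiplier", 1)),
               NA)
  expect_error(scenario("neg", "V_ECF", "multiplier", -1), "positive")
  expect_error(scenario("abs_vol", "V_ECF", "absolute", 100), "pH")
})

test_that("the what-if grid is deterministic with a zero reference column", {
  drugs <- panel_drugs()[c("caffeine", "thiopental", "morphine")]
  g1 <- run_whatif_grid(drugs,
                        default_scenarios()[c("reference", "CBF_low",
                                              "pH_ECF_high")])
  g2 <- run_whatif_grid(drugs,
                        default_scenarios()[c("reference", "CBF_low",
                                              "pH_ECF_high")])
  expect_identical(g1$summary, g2$summary)
  ref_col <- g1$heatmap[g1$heatmap$scenario == "reference", "log2fc"]
  expect_true(all(ref_col == 0))
  expect_true(all(is.finite(g1$heatmap$log2fc)))
  # a grid without the reference is refused
  expect_error(run_whatif_grid(drugs, default_scenarios()[2:3]),
               "reference")
})

test_that("neutral drugs produce an all-zero pH row in the heatmap", {
  g <- run_whatif_grid(panel_drugs()[["levetiracetam"]],
                       default_scenarios()[c("reference", "pH_ECF_low",
                                             "pH_ECF_high", "pH_ICF_low")])
  ph_cells <- g$heatmap[g$heatmap$scenario != "reference", "log2fc"]
  expect_true(all(ph_cells == 0))
})

test_that("pH perturbations move acidic and basic exposure in opposite directions", {
  scns <- default_scenarios()
  acid <- panel_drugs()[["thiopental"]]
  base <- panel_drugs()[["morphine"]]
  auc_ecf <- function(drug, scn = NULL) {
    pk_summary(simulate_drug(drug, scenario = scn))$AUC_0_T[1]
  }
  # raising pH_ECF increases acidic exposure, lowers basic; vice versa at 5
  expect_gt(auc_ecf(acid, scns[["pH_ECF_high"]]), auc_ecf(acid))
  expect_lt(auc_ecf(acid, scns[["pH_ECF_low"]]), auc_ecf(acid))
  expect_lt(auc_ecf(base, scns[["pH_ECF_high"]]), auc_ecf(base))
  expect_gt(auc_ecf(base, scns[["pH_ECF_low"]]), auc_ecf(base))
})

test_that("the same pH directions hold on an ionizable virtual panel", {
  panel <- generate_virtual_drugs(virtual_drug_spec(
    n = 6, seed = 7, class_mix = c(acid = 0.5, base = 0.5, neutral = 0,
                                   zwitterion = 0),
    pka_range = c(4, 8.5), pkb_range = c(4, 9)))
  scns <- default_scenarios()
  for (d in panel) {
    ref <- pk_summary(simulate_drug(d))$AUC_0_T[1]
    hi <- pk_summary(simulate_drug(d,
                                   scenario = scns[["pH_ECF_high"]]))$AUC_0_T[1]
    if (d$ionization$ion_class == "acid") {
      expect_gt(hi, ref, label = d$name)
    } else {
      expect_lt(hi, ref, label = d$name)
    }
  }
})

test_that("widened pores pull every panel Kp_uu,BBB toward unity", {
  s <- full_grid()$summary
  ecf <- s[s$compartment == "brain_ECF", ]
  ref <- ecf[ecf$scenario == "reference", c("drug", "Kpuu_BBB")]
  wide <- ecf[ecf$scenario == "para_radius_high", c("drug", "Kpuu_BBB")]
  m <- merge(ref, wide, by = "drug", suffixes = c("_ref", "_wide"))
  expect_true(all(abs(1 - m$Kpuu_BBB_wide) < abs(1 - m$Kpuu_BBB_ref)))
})
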