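test_that("interventions graft the declared machinery onto a new net", {
  cancer <- build_model("cancer_hyperglycemia")
  hash_before <- net_hash(cancer)

  sh <- apply_intervention(cancer, intervention("shrna"))
  expect_true(all(c("shrna") %in% sh$places$id))
  expect_true("shrna_degradation" %in% sh$transitions$id)

  bz <- apply_intervention(cancer, intervention("bzx"))
  expect_true(all(c("bzx", "ogt_bzx_complex") %in% bz$places$id))
  # the complex is inert: nothing consumes it
  expect_false(any(bz$arcs$source == "ogt_bzx_complex"))
  # binding conserves ogt + complex against the base net's ogt row
  C_base <- incidence_matrix(cancer)
  C_bz <- incidence_matrix(bz)
  combined <- C_bz["ogt", ] + C_bz["ogt_bzx_complex", ]
  expect_equal(combined[colnames(C_base)], C_base["ogt", ])
  expect_equal(unname(combined["bzx_binding"]), 0)

  met <- apply_intervention(cancer, intervention("metformin"))
  inh <- met$arcs[met$arcs$arc_type == "inhibitory", ]
  new_inh <- nrow(inh) - sum(cancer$arcs$arc_type == "inhibitory")
  expect_identical(new_inh, 1L)
  expect_identical(inh$target[nrow(inh)], "survival_signal")
  expect_identical(inh$source[nrow(inh)], "metformin")

  # immutability of the base net throughout
  expect_identical(net_hash(cancer), hash_before)

  # every perturbed net still validates
  for (net in list(sh, bz, met)) {
    expect_identical(nrow(validate_net(net)), 0L, info = net$name)
  }
})

test_that("interventions demand their target elements", {
  toy <- cycle_net()
  expect_error(apply_intervention(toy, intervention("shrna")),
               class = "ogtpn_missing_target")
  expect_error(apply_intervention(toy, intervention("bzx")),
               class = "ogtpn_missing_target")
  expect_error(apply_intervention(toy, intervention("metformin")),
               class = "ogtpn_missing_target")
  expect_error(intervention("shrna", dose = -1),
               class = "ogtpn_intervention_error")
  expect_error(intervention("prayer"))
})

test_that("zero-dose interventions reproduce baseline trajectories", {
  s <- fast_settings()
  base <- simulate_net(build_model("cancer_hyperglycemia"), s)
  for (kind in c("shrna", "bzx", "metformin")) {
    net <- apply_intervention(build_model("cancer_hyperglycemia"),
                              intervention(kind, dose = 0))
    traj <- simulate_net(net, s)
    for (p in c("ogt", "cell_survival", "akt_active")) {
      expect_lt(abs(readout(traj, p) - readout(base, p)), 1e-6,
                label = paste(kind, p))
    }
  }
})

test_that("plans fold interventions order-independently", {
  cancer <- build_model("cancer_hyperglycemia")
  expect_identical(net_hash(apply_plan(cancer, list())), net_hash(cancer))

  ab <- apply_plan(cancer, list(intervention("shrna"), intervention("bzx")))
  ba <- apply_plan(cancer, list(intervention("bzx"), intervention("shrna")))
  ab$name <- ba$name <- "combo"
  expect_identical(net_hash(ab), net_hash(ba))

  bm <- apply_plan(cancer, list(intervention("bzx"),
                                intervention("metformin")))
  expect_true("ogt_bzx_complex" %in% bm$places$id)
  expect_true(any(bm$arcs$arc_type == "inhibitory" &
                    bm$arcs$source == "metformin"))

  expect_error(apply_plan(cancer, list(intervention("bzx"),
                                       intervention("bzx"))),
               class = "ogtpn_intervention_error")
})

test_that("metformin leaves everything but proliferation untouched", {
  s <- fast_settings()
  base <- simulate_net(build_model("cancer_hyperglycemia"), s)
  met <- simulate_net(apply_intervention(build_model("cancer_hyperglycemia"),
                                         intervention("metformin")), s)
  for (p in c("ogt", "akt_active", "glut4_membrane", "irs1_active")) {
    expect_lt(max(abs(met$markings[, p] - base$markings[, p])), 1e-6,
              label = p)
  }
  expect_lt(readout(met, "cell_survival"), readout(base, "cell_survival"))
})

test_that("dose sweeps are ordered and monotone where the gate dictates", {
  # degenerate sweep
  sw <- dose_sweep("cancer_hyperglycemia", list(intervention("bzx")),
                   "bzx", 10, "ogt", fast_settings())
  expect_identical(nrow(sw), 1L)

  # toy net: inhibitor gating a source; readout non-increasing in dose
  s <- sim_settings(t_end = 5, n_points = 51)
  vals <- vapply(c(0, 1, 2, 4, 8), function(d) {
    net <- gated_net(i0 = d, w = 2)
    readout(simulate_net(net, s), "P", "final")
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-9))

  expect_error(dose_sweep("cancer_hyperglycemia",
                          list(intervention("bzx")), "metformin",
                          c(1, 2), "ogt"),
               class = "ogtpn_intervention_error")
  expect_error(dose_sweep("cancer_hyperglycemia",
                          list(intervention("bzx")), "bzx",
                          numeric(0), "ogt"),
               class = "ogtpn_intervention_error")
})
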