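test_that("transition rates follow the mass-action law with gating", {
  # source transition fires at its rate constant
  net <- petri_net(
    places = data.frame(id = "A"),
    transitions = data.frame(id = "src", rate_constant = 2, kind = "source"),
    arcs = data.frame(source = "src", target = "A", weight = 1,
                      arc_type = "standard"))
  expect_equal(transition_rate(net, c(A = 7), "src"), 2)

  # empty input place is absorbing
  expect_equal(transition_rate(chain_net(), c(A = 0, B = 1), "T"), 0)

  # kinetic order equals arc weight: k * m^w
  net <- petri_net(
    places = data.frame(id = c("A", "B")),
    transitions = data.frame(id = "T", rate_constant = 0.5),
    arcs = data.frame(source = c("A", "T"), target = c("T", "B"),
                      weight = c(2, 1), arc_type = "standard"))
  expect_equal(transition_rate(net, c(A = 2, B = 0), "T"), 0.5 * 2^2)

  # hard gate closes at inhibitor marking >= weight
  hard <- sim_settings(hard_gate = TRUE)
  expect_equal(transition_rate(gated_net(i0 = 5, w = 1), c(I = 5, P = 0),
                               "T", hard), 0)
  expect_equal(transition_rate(gated_net(i0 = 0, w = 1), c(I = 0, P = 0),
                               "T", hard), 2)

  # smooth gate halves the rate exactly at m = w
  expect_equal(transition_rate(gated_net(w = 2), c(I = 2, P = 0), "T"), 1)

  expect_error(transition_rate(chain_net(), c(A = 1, B = 0), "nope"),
               class = "ogtpn_unknown_transition")
})

test_that("increasing an inhibitor's tokens never increases a gated rate", {
  for (w in c(0.5, 1, 3)) {
    for (hard in c(FALSE, TRUE)) {
      s <- sim_settings(hard_gate = hard)
      tokens <- seq(0, 10, by = 0.5)
      rates <- vapply(tokens, function(i0) {
        transition_rate(gated_net(i0 = i0, w = w), c(I = i0, P = 0), "T", s)
      }, numeric(1))
      expect_true(all(diff(rates) <= 1e-12),
                  info = sprintf("w=%g hard=%s", w, hard))
    }
  }
})

test_that("ode right-hand side is the incidence-weighted rate vector", {
  expect_equal(ode_rhs(chain_net(), c(A = 1, B = 0)), c(A = -1, B = 1))

  # conservation identity on a closed net
  net <- cycle_net()
  x <- p_invariants(net)[1, ]
  for (m in list(c(A = 2, B = 1), c(A = 0.3, B = 4))) {
    expect_equal(sum(x * ode_rhs(net, m)), 0)
  }

  # finite-difference agreement with the independent Euler oracle
  for (seed in 1:10) {
    net <- random_net(5, 5, seed)
    m0 <- initial_marking(net)
    h <- 1e-6
    m1 <- euler_oracle(net, t_end = h, h = h)
    expect_equal(ode_rhs(net, m0), (m1 - m0) / h, tolerance = 1e-4,
                 info = paste("seed", seed))
  }
})

test_that("simulation reproduces closed forms and first-order limits", {
  # two-point grid at tiny horizon: forward-Euler limit
  net <- cycle_net()
  t_end <- 1e-5
  traj <- simulate_net(net, sim_settings(t_end = t_end, n_points = 2))
  m0 <- initial_marking(net)
  expect_equal(unname(traj$markings[1, ]), unname(m0))
  expect_equal(traj$markings[2, ], m0 + t_end * ode_rhs(net, m0),
               tolerance = 1e-6)

  # linear decay: m(t) = exp(-k t)
  for (k in c(1, 0.3)) {
    traj <- simulate_net(decay_net(k = k),
                         sim_settings(t_end = 10, n_points = 101))
    for (t in c(1, 5, 10)) {
      i <- which(abs(traj$times - t) < 1e-9)
      expect_lt(abs(traj$markings[i, "A"] - exp(-k * t)), 1e-6)
    }
  }
})

test_that("trajectories are deterministic, nonnegative and conservative", {
  net <- build_model("cancer_hyperglycemia")
  s <- fast_settings()
  t1 <- simulate_net(net, s)
  t2 <- simulate_net(net, s)
  expect_identical(t1$markings, t2$markings)
  expect_true(all(t1$markings >= 0))

  # weighted token sums along trajectories stay constant for p-invariants
  for (nname in all_variants()) {
    vnet <- build_model(nname)
    inv <- p_invariants(vnet)
    traj <- simulate_net(vnet, s)
    for (i in seq_len(nrow(inv))) {
      sums <- traj$markings %*% inv[i, colnames(traj$markings)]
      expect_lt(max(abs(sums - sums[1])), 1e-6, label = nname)
    }
  }
})

test_that("adaptive integration agrees with the fixed-step oracle", {
  # spot check here; the full 50-net screen runs in the acceptance suite
  for (seed in 1:5) {
    net <- random_net(5, 5, seed)
    traj <- simulate_net(net, sim_settings(t_end = 1, n_points = 2))
    m_euler <- euler_oracle(net, t_end = 1, h = 1e-4)
    expect_lt(max(abs(traj$markings[2, ] - m_euler)), 1e-3,
              label = paste("seed", seed))
  }
})

test_that("readout summarises trajectories per mode", {
  const_traj <- structure(
    list(times = 0:10, markings = matrix(3, 11, 1,
                                         dimnames = list(NULL, "A")),
         net_name = "const"),
    class = "pn_trajectory")
  for (mode in c("final", "mean_tail", "max")) {
    expect_equal(readout(const_traj, "A", mode), 3)
  }

  # monotone increasing: max equals final
  inc <- const_traj
  inc$markings[, 1] <- seq(0, 1, length.out = 11)
  expect_equal(readout(inc, "A", "max"), readout(inc, "A", "final"))

  # decaying exponential over a long horizon: tail means are tiny
  traj <- simulate_net(decay_net(k = 1),
                       sim_settings(t_end = 10, n_points = 201))
  expect_lt(readout(traj, "A", "mean_tail"),
            readout(traj, "A", "final") + 1e-3)
  expect_lt(readout(traj, "A", "final"), 1e-3)

  expect_error(readout(traj, "nope"), class = "ogtpn_unknown_place")
})

test_that("trajectory CSV export round-trips on the standard header", {
  traj <- simulate_net(cycle_net(), sim_settings(t_end = 1, n_points = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  back <- utils::read.csv(path)
  expect_identical(names(back), c("time", "A", "B"))
  expect_equal(back$A, unname(traj$markings[, "A"]), tolerance = 1e-12)
})
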