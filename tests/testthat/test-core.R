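test_that("validator reports definitional structure violations as data", {
  # place -> place arc
  net <- petri_net(
    places = data.frame(id = c("A", "B")),
    transitions = data.frame(id = "T", rate_constant = 1),
    arcs = data.frame(source = "A", target = "B", weight = 1,
                      arc_type = "standard"))
  v <- validate_net(net)
  expect_true("non-bipartite arc" %in% v$rule)

  # inhibitory arc transition -> place
  net <- petri_net(
    places = data.frame(id = "A"),
    transitions = data.frame(id = "T", rate_constant = 1),
    arcs = data.frame(source = "T", target = "A", weight = 1,
                      arc_type = "inhibitory"))
  expect_true("inhibitory arc direction" %in% validate_net(net)$rule)

  # duplicate parallel arcs, negative tokens, nonpositive rate,
  # source transition with an input arc
  net <- petri_net(
    places = data.frame(id = c("A", "B"), initial_tokens = c(-1, 0)),
    transitions = data.frame(id = c("T", "S"), rate_constant = c(0, 1),
                             kind = c("internal", "source")),
    arcs = data.frame(source = c("A", "A", "B"), target = c("T", "T", "S"),
                      weight = 1, arc_type = "standard"))
  rules <- validate_net(net)$rule
  expect_true(all(c("no duplicate arcs", "nonnegative tokens",
                    "positive rate constant", "source arity") %in% rules))

  # dangling endpoint
  net <- petri_net(
    places = data.frame(id = "A"),
    transitions = data.frame(id = "T", rate_constant = 1),
    arcs = data.frame(source = "ghost", target = "T", weight = 1,
                      arc_type = "standard"))
  expect_true("resolving endpoints" %in% validate_net(net)$rule)
})

test_that("every shipped builder output validates cleanly", {
  for (net in shipped_nets()) {
    expect_identical(nrow(validate_net(net)), 0L, info = net$name)
  }
})

test_that("incidence matrix matches its definition and a per-arc oracle", {
  C <- incidence_matrix(chain_net())
  expect_equal(unname(C[, "T"]), c(-1, 1))

  # isolated place: all-zero row
  net <- petri_net(
    places = data.frame(id = c("A", "B", "iso")),
    transitions = data.frame(id = "T", rate_constant = 1),
    arcs = data.frame(source = c("A", "T"), target = c("T", "B"),
                      weight = 1, arc_type = "standard"))
  expect_equal(unname(incidence_matrix(net)["iso", ]), 0)

  # inhibitory arcs contribute nothing
  expect_equal(unname(incidence_matrix(gated_net(i0 = 3))["I", "T"]), 0)

  # random nets against the oracle's independent accumulation
  for (seed in 1:10) {
    net <- random_net(5, 5, seed)
    expect_equal(incidence_matrix(net), oracle_stoichiometry(net),
                 info = paste("seed", seed))
  }

  # invalid nets are refused with a structured error
  bad <- petri_net(
    places = data.frame(id = "A"),
    transitions = data.frame(id = "T", rate_constant = -1),
    arcs = data.frame(source = "A", target = "T", weight = 1,
                      arc_type = "standard"))
  expect_error(incidence_matrix(bad), class = "ogtpn_invalid_net")
})

test_that("p-invariants span conserved token sums", {
  # closed two-place cycle conserves A + B
  inv <- p_invariants(cycle_net())
  expect_identical(nrow(inv), 1L)
  expect_equal(unname(inv[1, c("A", "B")]), c(1, 1))

  # a source transition breaks conservation for the fed place
  net <- petri_net(
    places = data.frame(id = c("S", "B")),
    transitions = data.frame(id = c("src", "T"), rate_constant = 1,
                             kind = c("source", "internal")),
    arcs = data.frame(source = c("src", "S", "T"),
                      target = c("S", "T", "B"),
                      weight = 1, arc_type = "standard"))
  inv <- p_invariants(net)
  if (nrow(inv) > 0) expect_true(all(inv[, "S"] == 0))

  # every returned invariant annihilates C exactly, across random nets
  for (seed in 1:20) {
    net <- random_net(5, 4, seed)
    inv <- p_invariants(net)
    if (nrow(inv) == 0) next
    C <- incidence_matrix(net)
    expect_lt(max(abs(inv %*% C)), 1e-9)
    expect_true(all(inv >= 0))
  }

  # shipped pathway nets conserve each active/inactive protein pair
  net <- build_model("normal_adipocyte")
  inv <- p_invariants(net)
  pairs <- list(c("irs1_active", "irs1_inactive"),
                c("pi3k_active", "pi3k_inactive"),
                c("akt_active", "akt_inactive"),
                c("glut4_internal", "glut4_membrane"))
  for (pair in pairs) {
    hit <- apply(inv, 1, function(x) {
      all(x[pair] == 1) && all(x[setdiff(colnames(inv), pair)] == 0)
    })
    expect_true(any(hit), info = paste(pair, collapse = "+"))
  }
})

test_that("net hash is invariant to element order", {
  net <- cycle_net()
  shuffled <- net
  shuffled$places <- net$places[2:1, ]
  shuffled$arcs <- net$arcs[c(3, 1, 4, 2), ]
  expect_identical(net_hash(net), net_hash(shuffled))
  expect_false(net_hash(net) == net_hash(cycle_net(a0 = 3)))
})
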