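# Tiny fixture nets built in code.

# A --T--> B, unit weights; k is T's rate constant.
chain_net <- function(k = 1, a0 = 1, b0 = 0) {
  petri_net(
    places = data.frame(id = c("A", "B"), initial_tokens = c(a0, b0)),
    transitions = data.frame(id = "T", rate_constant = k, kind = "internal"),
    arcs = data.frame(source = c("A", "T"), target = c("T", "B"),
                      weight = 1, arc_type = "standard"),
    name = "chain")
}

# single linear decay: A --T--> (sink), m_A(t) = a0 * exp(-k t)
decay_net <- function(k = 1, a0 = 1) {
  petri_net(
    places = data.frame(id = "A", initial_tokens = a0),
    transitions = data.frame(id = "T", rate_constant = k, kind = "sink"),
    arcs = data.frame(source = "A", target = "T", weight = 1,
                      arc_type = "standard"),
    name = "decay")
}

# closed two-place cycle A -> T1 -> B -> T2 -> A; conserves A + B
cycle_net <- function(a0 = 2, b0 = 1) {
  petri_net(
    places = data.frame(id = c("A", "B"), initial_tokens = c(a0, b0)),
    transitions = data.frame(id = c("T1", "T2"), rate_constant = c(1, 0.5),
                             kind = "internal"),
    arcs = data.frame(source = c("A", "T1", "B", "T2"),
                      target = c("T1", "B", "T2", "A"),
                      weight = 1, arc_type = "standard"),
    name = "cycle")
}

# inhibitor place I gating a source-fed production of P
gated_net <- function(i0 = 0, w = 1, k = 2) {
  petri_net(
    places = data.frame(id = c("I", "P"), initial_tokens = c(i0, 0)),
    transitions = data.frame(id = "T", rate_constant = k, kind = "internal"),
    arcs = data.frame(source = c("T", "I"), target = c("P", "T"),
                      weight = c(1, w), arc_type = c("standard", "inhibitory")),
    name = "gated")
}

all_variants <- function() {
  c("normal_adipocyte", "insulin_resistant_adipocyte", "cancer_hyperglycemia")
}

# the six case nets (three variants + the shipped perturbed cancer nets)
shipped_nets <- function() {
  cancer <- build_model("cancer_hyperglycemia")
  list(
    build_model("normal_adipocyte"),
    build_model("insulin_resistant_adipocyte"),
    cancer,
    apply_intervention(cancer, intervention("shrna")),
    apply_intervention(cancer, intervention("bzx")),
    apply_intervention(cancer, intervention("metformin")),
    apply_plan(cancer, list(intervention("shrna"), intervention("bzx"))),
    apply_plan(cancer, list(intervention("bzx"), intervention("metformin")))
  )
}

fast_settings <- function(t_end = 100, n_points = 201) {
  sim_settings(t_end = t_end, n_points = n_points)
}
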