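INTERVENTION_KINDS <- c("shrna", "bzx", "metformin")

#' Declare an in-silico intervention
#'
#' Declarative description of one perturbation applied to a built pathway
#' net:
#'
#' * `shrna`: short hairpin RNA against OGT mRNA; stoichiometric
#'   degradation (shRNA and mRNA consumed together), so the dose bounds the
#'   total knockdown.
#' * `bzx`: covalent ("suicide") OGT inhibitor; BZX and free OGT are
#'   consumed irreversibly into an inert complex.
#' * `metformin`: proliferation inhibitor; an inhibitory arc onto the
#'   proliferation transition, with a supply/decay pair holding the drug at
#'   its dose level. It touches nothing else (no reported OGT interaction).
#'
#' @param kind one of `shrna`, `bzx`, `metformin`.
#' @param dose initial tokens of the drug/RNA place (>= 0); `NULL` for the
#'   shipped default.
#' @param extra named list of optional overrides (`binding_rate`,
#'   `turnover`, `inhibition_threshold`).
#' @return An object of class `pn_intervention`.
#' @export
intervention <- function(kind, dose = NULL, extra = list()) {
  kind <- match.arg(kind, INTERVENTION_KINDS)
  defaults <- intervention_defaults()[[kind]]
  if (is.null(dose)) dose <- defaults$dose
  if (!is.numeric(dose) || length(dose) != 1 || !is.finite(dose) || dose < 0) {
    pn_stop("dose must be a single nonnegative number",
            "ogtpn_intervention_error")
  }
  params <- defaults
  params$dose <- dose
  unknown <- setdiff(names(extra), names(defaults))
  if (length(unknown) > 0) {
    pn_stop(sprintf("unknown intervention parameter(s): %s",
                    paste(unknown, collapse = ", ")),
            "ogtpn_intervention_error")
  }
  params[names(extra)] <- extra
  structure(list(kind = kind, dose = dose, params = params),
            class = "pn_intervention")
}

#' @export
print.pn_intervention <- function(x, ...) {
  cat(sprintf("<pn_intervention> %s (dose %g tokens)\n", x$kind, x$dose))
  invisible(x)
}

require_place <- function(net, id, kind) {
  if (!(id %in% net$places$id)) {
    pn_stop(sprintf("intervention '%s' needs place '%s', absent from net '%s'",
                    kind, id, net$name), "ogtpn_missing_target")
  }
}

require_transition <- function(net, id, kind) {
  if (!(id %in% net$transitions$id)) {
    pn_stop(sprintf("intervention '%s' needs transition '%s', absent from net '%s'",
                    kind, id, net$name), "ogtpn_missing_target")
  }
}

add_elements <- function(net, places = NULL, transitions = NULL,
                         arcs = NULL) {
  if (!is.null(places)) net$places <- rbind(net$places,
                                            normalise_places(places))
  if (!is.null(transitions)) {
    net$transitions <- rbind(net$transitions,
                             normalise_transitions(transitions))
  }
  if (!is.null(arcs)) net$arcs <- rbind(net$arcs, normalise_arcs(arcs))
  net
}

#' Apply one intervention to a net
#'
#' Returns a new validating net; the input net is never mutated. Drug/RNA
#' places carry `dose` initial tokens. A zero dose leaves the dynamics at
#' baseline (the added machinery carries no tokens and, for Metformin, an
#' empty drug place leaves the inhibition gate open).
#'
#' @param net a built pathway variant (or any net exposing the targets:
#'   `ogt_mrna` for shRNA, `ogt` for BZX, the `survival_signal` transition
#'   for Metformin).
#' @param iv a [intervention()].
#' @return A new `petri_net` named `<net>+<kind>`.
#' @export
apply_intervention <- function(net, iv) {
  if (!inherits(iv, "pn_intervention")) {
    pn_stop("iv must be a pn_intervention", "ogtpn_intervention_error")
  }
  new_name <- paste0(net$name, "+", iv$kind)
  out <- switch(
    iv$kind,
    shrna = {
      require_place(net, "ogt_mrna", "shrna")
      add_elements(
        net,
        places = data.frame(id = "shrna", initial_tokens = iv$dose,
                            role_tag = "rna"),
        transitions = data.frame(id = "shrna_degradation",
                                 rate_constant = iv$params$binding_rate,
                                 kind = "sink"),
        arcs = data.frame(source = c("shrna", "ogt_mrna"),
                          target = "shrna_degradation",
                          weight = 1, arc_type = "standard"))
    },
    bzx = {
      require_place(net, "ogt", "bzx")
      add_elements(
        net,
        places = data.frame(id = c("bzx", "ogt_bzx_complex"),
                            initial_tokens = c(iv$dose, 0),
                            role_tag = c("drug", "protein")),
        transitions = data.frame(id = "bzx_binding",
                                 rate_constant = iv$params$binding_rate,
                                 kind = "internal"),
        arcs = data.frame(source = c("bzx", "ogt", "bzx_binding"),
                          target = c("bzx_binding", "bzx_binding",
                                     "ogt_bzx_complex"),
                          weight = 1, arc_type = "standard"))
    },
    metformin = {
      require_transition(net, "survival_signal", "metformin")
      turn <- iv$params$turnover
      # supply rate = turnover * dose and decay rate = turnover hold the
      # drug level at its dose; an empty dose needs no supply
      maintain <- iv$dose > 0
      add_elements(
        net,
        places = data.frame(id = "metformin", initial_tokens = iv$dose,
                            role_tag = "drug"),
        transitions = data.frame(
          id = c(if (maintain) "metformin_supply", "metformin_decay"),
          rate_constant = c(if (maintain) turn * iv$dose, turn),
          kind = c(if (maintain) "source", "sink")),
        arcs = data.frame(
          source = c(if (maintain) "metformin_supply", "metformin",
                     "metformin"),
          target = c(if (maintain) "metformin", "metformin_decay",
                     "survival_signal"),
          weight = c(if (maintain) 1, 1, iv$params$inhibition_threshold),
          arc_type = c(if (maintain) "standard", "standard", "inhibitory")))
    })
  out$name <- new_name
  assert_valid(out)
  out
}

#' Apply an intervention plan
#'
#' Builds the base variant and folds 0-2 interventions over it
#' left-to-right. The shipped intervention kinds act on disjoint targets,
#' so the result is order-independent up to element order.
#'
#' @param base_variant variant id passed to [build_model()], or an already
#'   built `petri_net`.
#' @param interventions list of [intervention()] objects (duplicate kinds
#'   forbidden, at most 2).
#' @param overrides forwarded to [build_model()] when `base_variant` is an
#'   id.
#' @return A `petri_net`.
#' @export
apply_plan <- function(base_variant, interventions = list(),
                       overrides = NULL) {
  if (inherits(base_variant, "petri_net")) {
    net <- base_variant
  } else {
    net <- build_model(base_variant, overrides)
  }
  if (length(interventions) > 2) {
    pn_stop("plans combine at most two interventions",
            "ogtpn_intervention_error")
  }
  kinds <- vapply(interventions, `[[`, character(1), "kind")
  if (anyDuplicated(kinds)) {
    pn_stop("duplicate intervention kinds in plan",
            "ogtpn_intervention_error")
  }
  for (iv in interventions) net <- apply_intervention(net, iv)
  net
}

#' Dose sweep over one intervention
#'
#' Re-simulates the plan once per dose with identical settings and reports
#' a scalar readout per dose.
#'
#' @param base_variant variant id or built net.
#' @param interventions list of [intervention()]s; the one whose kind
#'   equals `kind` has its dose replaced by each sweep value.
#' @param kind intervention kind being swept.
#' @param doses nonempty vector of nonnegative doses.
#' @param readout_place place summarised per run.
#' @param settings a [sim_settings()].
#' @param mode readout mode (see [readout()]); `final` mirrors reading the
#'   end of a dose-escalation time course.
#' @return Data frame with columns `dose`, `value`, ordered by dose.
#' @export
dose_sweep <- function(base_variant, interventions, kind, doses,
                       readout_place, settings = sim_settings(),
                       mode = "final") {
  if (length(doses) == 0 || any(doses < 0)) {
    pn_stop("doses must be nonempty and nonnegative",
            "ogtpn_intervention_error")
  }
  kinds <- vapply(interventions, `[[`, character(1), "kind")
  if (!(kind %in% kinds)) {
    pn_stop(sprintf("no '%s' intervention in plan", kind),
            "ogtpn_intervention_error")
  }
  doses <- sort(doses)
  values <- vapply(doses, function(d) {
    ivs <- lapply(interventions, function(iv) {
      if (iv$kind == kind) intervention(kind, dose = d,
                                        extra = iv$params[setdiff(names(iv$params),
                                                                  "dose")])
      else iv
    })
    traj <- simulate_net(apply_plan(base_variant, ivs), settings)
    readout(traj, readout_place, mode = mode)
  }, numeric(1))
  data.frame(dose = doses, value = values)
}
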