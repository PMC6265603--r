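VARIANTS <- c("normal_adipocyte", "insulin_resistant_adipocyte",
              "cancer_hyperglycemia")

default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "ogtpn",
              mustWork = TRUE)
}

resolve_inherit <- function(cfg_variants, variant, field) {
  block <- cfg_variants[[variant]][[field]]
  parent <- block$inherit
  block$inherit <- NULL
  if (!is.null(parent)) {
    base <- resolve_inherit(cfg_variants, parent, field)
    base[names(block)] <- block
    block <- base
  }
  block
}

read_default_config <- function() {
  yaml::read_yaml(default_config_path())
}

#' Shipped default configuration for a pathway variant
#'
#' Returns the calibrated defaults (initial tokens per place, rate constant
#' per transition) for one of the three shipped pathway variants. The values
#' come from a single versioned YAML file installed with the package; they
#' are the package's reconstruction of the model conditions, with calibrated
#' entries commented in the file.
#'
#' @param variant one of `normal_adipocyte`, `insulin_resistant_adipocyte`,
#'   `cancer_hyperglycemia`.
#' @return List with elements `places` (named initial tokens) and `rates`
#'   (named rate constants).
#' @export
default_config <- function(variant) {
  variant <- match.arg(variant, VARIANTS)
  cfg <- read_default_config()
  rates <- unlist(resolve_inherit(cfg$variants, variant, "rates"))
  # inheritance may carry rates of transitions absent from this wiring
  rates <- rates[names(rates) %in% variant_transition_ids(variant)]
  list(places = unlist(resolve_inherit(cfg$variants, variant, "places")),
       rates = rates)
}

variant_transition_ids <- function(variant) {
  wiring <- c(skeleton_wiring(),
              switch(variant,
                     normal_adipocyte = adipocyte_wiring(),
                     insulin_resistant_adipocyte = adipocyte_wiring(),
                     cancer_hyperglycemia = cancer_wiring()))
  vapply(wiring, `[[`, character(1), "id")
}

#' Shipped intervention defaults
#'
#' @return Named list of per-intervention defaults (doses, binding rates,
#'   the Metformin inhibitory-arc threshold) and the BZX dose-sweep presets.
#' @export
intervention_defaults <- function() {
  cfg <- read_default_config()
  c(cfg$interventions, list(bzx_doses = unlist(cfg$sweep$bzx_doses)))
}

# -- wiring -------------------------------------------------------------

# One row per place of the common skeleton; tokens come from config.
skeleton_places <- function() {
  p <- function(id, role) data.frame(id = id, role_tag = role,
                                     stringsAsFactors = FALSE)
  rbind(
    p("insulin", "protein"), p("insulin_receptor", "protein"),
    p("complex1", "protein"),
    p("irs1_inactive", "protein"), p("irs1_active", "protein"),
    p("pi3k_inactive", "protein"), p("pi3k_active", "protein"),
    p("pip3", "metabolite"),
    p("pdk1", "enzyme"), p("mtorc2", "enzyme"),
    p("akt_inactive", "protein"), p("akt_active", "protein"),
    p("glut4_internal", "protein"), p("glut4_membrane", "protein"),
    p("cell_survival", "process-readout"),
    p("glucose", "metabolite"), p("udp_glcnac", "metabolite"),
    p("ogt_mrna", "rna"), p("ogt", "enzyme"), p("oga", "enzyme")
  )
}

# Transition wiring rows: consumed inputs, produced outputs, catalysts
# (consumed and reproduced, so they gate the rate but conserve tokens).
wiring_row <- function(id, kind = "internal", inputs = character(),
                       outputs = character(), catalysts = character()) {
  list(id = id, kind = kind, inputs = inputs, outputs = outputs,
       catalysts = catalysts)
}

skeleton_wiring <- function() {
  w <- wiring_row
  list(
    w("insulin_supply", "source", outputs = "insulin"),
    w("insulin_decay", "sink", inputs = "insulin"),
    w("receptor_supply", "source", outputs = "insulin_receptor"),
    w("receptor_decay", "sink", inputs = "insulin_receptor"),
    w("complex_formation", inputs = "insulin", outputs = "complex1",
      catalysts = "insulin_receptor"),
    w("complex_dissociation", "sink", inputs = "complex1"),
    w("irs1_activation", inputs = "irs1_inactive", outputs = "irs1_active",
      catalysts = "complex1"),
    w("irs1_deactivation", inputs = "irs1_active", outputs = "irs1_inactive"),
    w("pi3k_activation", inputs = "pi3k_inactive", outputs = "pi3k_active",
      catalysts = "irs1_active"),
    w("pi3k_deactivation", inputs = "pi3k_active", outputs = "pi3k_inactive"),
    w("pip3_synthesis", outputs = "pip3", catalysts = "pi3k_active"),
    w("pip3_degradation", "sink", inputs = "pip3"),
    w("pdk1_supply", "source", outputs = "pdk1"),
    w("pdk1_decay", "sink", inputs = "pdk1"),
    w("mtorc2_supply", "source", outputs = "mtorc2"),
    w("mtorc2_decay", "sink", inputs = "mtorc2"),
    w("akt_activation", inputs = "akt_inactive", outputs = "akt_active",
      catalysts = c("pip3", "pdk1", "mtorc2")),
    w("akt_deactivation", inputs = "akt_active", outputs = "akt_inactive"),
    w("glut4_translocation", inputs = "glut4_internal",
      outputs = "glut4_membrane", catalysts = "akt_active"),
    w("glut4_internalisation", inputs = "glut4_membrane",
      outputs = "glut4_internal"),
    w("survival_decay", "sink", inputs = "cell_survival"),
    w("glucose_supply", "source", outputs = "glucose"),
    w("glycolysis", "sink", inputs = "glucose"),
    w("hbp_flux", inputs = "glucose", outputs = "udp_glcnac"),
    w("udp_glcnac_decay", "sink", inputs = "udp_glcnac"),
    w("ogt_transcription", "source", outputs = "ogt_mrna"),
    w("ogt_mrna_decay", "sink", inputs = "ogt_mrna"),
    w("ogt_synthesis", outputs = "ogt",
      catalysts = c("ogt_mrna", "udp_glcnac")),
    w("ogt_decay", "sink", inputs = "ogt"),
    w("oga_supply", "source", outputs = "oga"),
    w("oga_decay", "sink", inputs = "oga")
  )
}

adipocyte_wiring <- function() {
  w <- wiring_row
  list(
    w("survival_signal", outputs = "cell_survival",
      catalysts = "akt_active"),
    w("irs1_oglcnac", inputs = "irs1_active", outputs = "irs1_inactive",
      catalysts = "ogt"),
    w("irs1_deglcnac", inputs = "irs1_inactive", outputs = "irs1_active",
      catalysts = "oga"),
    w("akt_oglcnac", inputs = "akt_active", outputs = "akt_inactive",
      catalysts = "ogt"),
    w("akt_deglcnac", inputs = "akt_inactive", outputs = "akt_active",
      catalysts = "oga")
  )
}

cancer_wiring <- function() {
  w <- wiring_row
  list(
    w("survival_signal", outputs = "cell_survival",
      catalysts = c("akt_active", "ogt")),
    w("akt_oglcnac_activation", inputs = "akt_inactive",
      outputs = "akt_active", catalysts = "ogt"),
    w("akt_deglcnac", inputs = "akt_active", outputs = "akt_inactive",
      catalysts = "oga"),
    w("glut4_ogt_translocation", inputs = "glut4_internal",
      outputs = "glut4_membrane", catalysts = "ogt")
  )
}

wiring_to_net <- function(name, places, wiring, config) {
  tok <- config$places
  rates <- config$rates
  unknown_p <- setdiff(names(tok), places$id)
  if (length(unknown_p) > 0) {
    pn_stop(sprintf("config references unknown place(s): %s",
                    paste(unknown_p, collapse = ", ")),
            "ogtpn_config_error")
  }
  t_ids <- vapply(wiring, `[[`, character(1), "id")
  unknown_t <- setdiff(names(rates), t_ids)
  if (length(unknown_t) > 0) {
    pn_stop(sprintf("config references unknown transition(s): %s",
                    paste(unknown_t, collapse = ", ")),
            "ogtpn_config_error")
  }
  missing_r <- setdiff(t_ids, names(rates))
  rates[missing_r] <- 1   # unspecified rate constants default to 1
  places$initial_tokens <- unname(tok[places$id])
  places$initial_tokens[is.na(places$initial_tokens)] <- 0

  transitions <- data.frame(
    id = t_ids,
    rate_constant = unname(rates[t_ids]),
    kind = vapply(wiring, `[[`, character(1), "kind"),
    stringsAsFactors = FALSE)

  arc_rows <- list()
  add_arc <- function(src, tgt, type = "standard") {
    arc_rows[[length(arc_rows) + 1]] <<- data.frame(
      source = src, target = tgt, weight = 1, arc_type = type,
      stringsAsFactors = FALSE)
  }
  for (tr in wiring) {
    for (pl in tr$inputs) add_arc(pl, tr$id)
    for (pl in tr$outputs) add_arc(tr$id, pl)
    for (pl in tr$catalysts) { add_arc(pl, tr$id); add_arc(tr$id, pl) }
  }
  petri_net(places, transitions, do.call(rbind, arc_rows), name = name)
}

#' Build a shipped pathway variant
#'
#' Constructs the continuous Petri net for one of the three shipped
#' variants of the insulin-stimulated PI3K/Akt pathway coupled to OGT/OGA
#' O-GlcNAc cycling:
#'
#' * `normal_adipocyte`: intact signalling chain insulin -> receptor ->
#'   complex1 -> IRS-1 -> PI3K -> PIP3 -> (PDK1, mTORC2) -> Akt ->
#'   \{GLUT4 translocation, cell survival\}, with O-GlcNAc addition by OGT
#'   balanced by removal by OGA.
#' * `insulin_resistant_adipocyte`: identical topology with elevated OGT
#'   expression and elevated OGT-driven deactivation of IRS-1 and Akt.
#' * `cancer_hyperglycemia`: raised glucose supply feeding the hexosamine
#'   biosynthetic pathway (glucose -> UDP-GlcNAc -> OGT activity); OGT
#'   enhances Akt activation, GLUT4 surface expression and proliferation
#'   (the `cell_survival` readout). OGT does not target IRS-1 here.
#'
#' Every protein is an active/inactive place pair linked by activation and
#' deactivation transitions; catalysts are consumed and reproduced so each
#' pair's total is a conserved P-invariant. All arc weights are 1.
#'
#' @param variant variant id (see [default_config()]).
#' @param overrides optional list with elements `places` and/or `rates`,
#'   named vectors overriding individual defaults. Unknown ids are an
#'   error.
#' @return A validating `petri_net` with ~20 places.
#' @export
build_model <- function(variant, overrides = NULL) {
  variant <- match.arg(variant, VARIANTS)
  config <- default_config(variant)
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), c("places", "rates"))
    if (length(bad) > 0) {
      pn_stop(sprintf("unknown override section(s): %s",
                      paste(bad, collapse = ", ")), "ogtpn_config_error")
    }
    for (sec in intersect(names(overrides), c("places", "rates"))) {
      ov <- unlist(overrides[[sec]])
      unknown <- setdiff(names(ov), names(config[[sec]]))
      if (length(unknown) > 0) {
        pn_stop(sprintf("override references unknown %s id(s): %s (valid: %s)",
                        sub("s$", "", sec), paste(unknown, collapse = ", "),
                        paste(names(config[[sec]]), collapse = ", ")),
                "ogtpn_config_error")
      }
      config[[sec]][names(ov)] <- ov
    }
  }
  wiring <- c(skeleton_wiring(),
              switch(variant,
                     normal_adipocyte = adipocyte_wiring(),
                     insulin_resistant_adipocyte = adipocyte_wiring(),
                     cancer_hyperglycemia = cancer_wiring()))
  net <- wiring_to_net(variant, skeleton_places(), wiring, config)
  assert_valid(net)
  net
}

#' Seed-deterministic random net (engine test fixture)
#'
#' Generates a small connected net with random standard wiring, about 10%
#' of place-to-transition arcs inhibitory, unit weights, and random initial
#' tokens in [0, 5]. The caller's RNG state is left untouched.
#'
#' @param n_places number of places (>= 1).
#' @param n_transitions number of transitions (>= 0).
#' @param seed integer seed; identical seeds give identical nets.
#' @return A validating `petri_net`.
#' @export
random_net <- function(n_places, n_transitions, seed) {
  if (n_places < 1 || n_transitions < 0) {
    pn_stop("need n_places >= 1 and n_transitions >= 0",
            "ogtpn_config_error")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  p_ids <- sprintf("p%d", seq_len(n_places))
  t_ids <- if (n_transitions > 0) sprintf("t%d", seq_len(n_transitions))
           else character()
  places <- data.frame(id = p_ids,
                       initial_tokens = round(stats::runif(n_places, 0, 5), 3),
                       stringsAsFactors = FALSE)
  arcs <- list()
  seen <- character()
  add_arc <- function(src, tgt, type) {
    key <- paste(src, tgt, type)
    if (key %in% seen) return(invisible(FALSE))
    seen <<- c(seen, key)
    arcs[[length(arcs) + 1]] <<- data.frame(
      source = src, target = tgt, weight = 1, arc_type = type,
      stringsAsFactors = FALSE)
    invisible(TRUE)
  }
  if (n_transitions > 0) {
    for (j in seq_len(n_transitions)) {
      n_in <- sample(0:2, 1)
      n_out <- sample(0:2, 1)
      if (n_in == 0 && n_out == 0) n_out <- 1
      for (pl in sample(p_ids, min(n_in, n_places))) {
        type <- if (stats::runif(1) < 0.1) "inhibitory" else "standard"
        add_arc(pl, t_ids[j], type)
      }
      for (pl in sample(p_ids, min(n_out, n_places))) {
        add_arc(t_ids[j], pl, "standard")
      }
    }
    # connectivity: attach every untouched place to a random transition
    arc_df <- do.call(rbind, arcs)
    untouched <- setdiff(p_ids, c(arc_df$source, arc_df$target))
    for (pl in untouched) {
      add_arc(t_ids[sample.int(n_transitions, 1)], pl, "standard")
    }
    arc_df <- do.call(rbind, arcs)
    kinds <- vapply(t_ids, function(tid) {
      has_in <- any(arc_df$target == tid)
      has_out <- any(arc_df$source == tid)
      if (!has_in) "source" else if (!has_out) "sink" else "internal"
    }, character(1))
    transitions <- data.frame(id = t_ids,
                              rate_constant = round(stats::runif(n_transitions,
                                                                 0.2, 1.5), 3),
                              kind = unname(kinds),
                              stringsAsFactors = FALSE)
    net <- petri_net(places, transitions, arc_df,
                     name = sprintf("random_%d", seed))
  } else {
    net <- petri_net(places,
                     data.frame(id = character(), rate_constant = numeric(),
                                kind = character(), stringsAsFactors = FALSE),
                     data.frame(source = character(), target = character(),
                                weight = numeric(), arc_type = character(),
                                stringsAsFactors = FALSE),
                     name = sprintf("random_%d", seed))
  }
  assert_valid(net)
  net
}
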