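CASE_IDS <- c("hyperglycemia", "shrna", "bzx", "metformin",
              "shrna_bzx", "bzx_metformin")

CASE_READOUTS <- c("ogt", "cell_survival", "akt_active", "glut4_membrane",
                   "irs1_active")

#' Fold change between two simulated conditions
#'
#' Fold = perturbed / baseline readout (default `mean_tail`). Direction is
#' called `up` at fold >= 1.2, `down` at fold <= 0.8, else `no_change`
#' (thresholds symmetric on the log scale). The reduction factor
#' baseline / perturbed is also reported, matching the "x-fold decrease"
#' convention used for intervention efficacy.
#'
#' @param baseline_traj,perturbed_traj `pn_trajectory` objects from runs
#'   with the same settings.
#' @param readout_place place id present in both trajectories.
#' @param mode readout mode, see [readout()].
#' @param context optional character(2) labelling the compared conditions.
#' @return A one-row data frame: `readout`, `baseline`, `perturbed`,
#'   `fold`, `reduction_factor`, `direction`, `baseline_condition`,
#'   `perturbed_condition`.
#' @export
fold_change <- function(baseline_traj, perturbed_traj, readout_place,
                        mode = "mean_tail", context = NULL) {
  b <- readout(baseline_traj, readout_place, mode)
  p <- readout(perturbed_traj, readout_place, mode)
  if (b < 1e-9) {
    pn_stop(sprintf("baseline readout of '%s' below epsilon; fold undefined",
                    readout_place), "ogtpn_undefined_fold")
  }
  fold <- p / b
  direction <- if (fold >= 1.2) "up" else if (fold <= 0.8) "down"
               else "no_change"
  if (is.null(context)) {
    context <- c(baseline_traj$net_name, perturbed_traj$net_name)
  }
  data.frame(readout = readout_place, baseline = b, perturbed = p,
             fold = fold, reduction_factor = b / p, direction = direction,
             baseline_condition = context[1], perturbed_condition = context[2],
             stringsAsFactors = FALSE)
}

case_pair <- function(case_id, overrides = NULL) {
  iv_list <- switch(case_id,
    hyperglycemia = NULL,
    shrna = list(intervention("shrna")),
    bzx = list(intervention("bzx")),
    metformin = list(intervention("metformin")),
    shrna_bzx = list(intervention("shrna"), intervention("bzx")),
    bzx_metformin = list(intervention("bzx"), intervention("metformin")))
  if (case_id == "hyperglycemia") {
    list(baseline = build_model("normal_adipocyte", overrides),
         perturbed = build_model("cancer_hyperglycemia", overrides))
  } else {
    base <- build_model("cancer_hyperglycemia", overrides)
    list(baseline = base, perturbed = apply_plan(base, iv_list))
  }
}

#' Run one named comparison case
#'
#' The six shipped cases compare paired deterministic simulations:
#' `hyperglycemia` compares the hyperglycemic cancer variant against the
#' normal adipocyte; each drug case compares the cancer variant with the
#' intervention against the untreated cancer variant (the hyperglycemic
#' control); `shrna_bzx` and `bzx_metformin` are the two combination
#' plans. Folds are reported for OGT, the proliferation/survival readout,
#' active Akt, membrane GLUT4 and active IRS-1.
#'
#' @param case_id one of `r paste(CASE_IDS, collapse = ", ")`.
#' @param settings a [sim_settings()].
#' @param overrides optional config overrides forwarded to the builders.
#' @return A `summary_table` data frame (one row per readout) with a
#'   `provenance` attribute recording the settings and config hash.
#' @export
run_case <- function(case_id, settings = sim_settings(), overrides = NULL) {
  case_id <- match.arg(case_id, CASE_IDS)
  pair <- case_pair(case_id, overrides)
  base_traj <- simulate_net(pair$baseline, settings)
  pert_traj <- simulate_net(pair$perturbed, settings)
  rows <- lapply(CASE_READOUTS, function(pl) {
    fc <- fold_change(base_traj, pert_traj, pl)
    cbind(data.frame(case = case_id, stringsAsFactors = FALSE), fc)
  })
  out <- do.call(rbind, rows)
  attr(out, "provenance") <- list(
    settings = unclass(settings),
    config_hash = rlang::hash(list(default_config("normal_adipocyte"),
                                   default_config("insulin_resistant_adipocyte"),
                                   default_config("cancer_hyperglycemia"),
                                   intervention_defaults(), overrides)))
  class(out) <- c("summary_table", class(out))
  out
}

#' Direction-of-change matrix across disease contexts
#'
#' Computes, from paired simulations, the qualitative effect of OGT
#' hyperactivity on IRS-1, Akt, GLUT-4 and cell survival in the two
#' disease contexts: the diabetes column compares the insulin-resistant
#' adipocyte against the normal adipocyte; the breast-cancer column
#' compares the hyperglycemic cancer variant against the normal variant.
#' The IRS-1 entry in the cancer column is marked `n/a` (OGT is not wired
#' to IRS-1 in the cancer net).
#'
#' @param settings a [sim_settings()].
#' @param overrides optional config overrides.
#' @return A `summary_table` data frame with columns `readout`, `context`,
#'   `fold`, `direction`.
#' @export
table1_directions <- function(settings = sim_settings(), overrides = NULL) {
  normal <- simulate_net(build_model("normal_adipocyte", overrides), settings)
  resistant <- simulate_net(build_model("insulin_resistant_adipocyte",
                                        overrides), settings)
  cancer <- simulate_net(build_model("cancer_hyperglycemia", overrides),
                         settings)
  readouts <- c(irs1 = "irs1_active", akt = "akt_active",
                glut4 = "glut4_membrane", cell_survival = "cell_survival")
  rows <- list()
  for (i in seq_along(readouts)) {
    fc <- fold_change(normal, resistant, readouts[[i]])
    rows[[length(rows) + 1]] <- data.frame(
      readout = names(readouts)[i], context = "diabetes", fold = fc$fold,
      direction = fc$direction, stringsAsFactors = FALSE)
  }
  for (i in seq_along(readouts)) {
    if (names(readouts)[i] == "irs1") {
      rows[[length(rows) + 1]] <- data.frame(
        readout = "irs1", context = "breast_cancer", fold = NA_real_,
        direction = "n/a", stringsAsFactors = FALSE)
      next
    }
    fc <- fold_change(normal, cancer, readouts[[i]])
    rows[[length(rows) + 1]] <- data.frame(
      readout = names(readouts)[i], context = "breast_cancer",
      fold = fc$fold, direction = fc$direction, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("summary_table", class(out))
  out
}

#' Differential effect of one OGT elevation in the two cell types
#'
#' Applies an identical OGT elevation (the transcription rate multiplied
#' by `elevation`) to the insulin-resistant adipocyte wiring and to the
#' cancer wiring (with glucose held at the normal level so the OGT rise is
#' the same in both), and reports the Akt-activity fold of each elevated
#' net relative to the same wiring without the elevation. The same OGT
#' rise dampens Akt in the adipocyte (fold < 1) and enhances it in the
#' cancer cell (fold > 1).
#'
#' @param elevation multiplier on the OGT transcription rate (> 1).
#' @param settings a [sim_settings()].
#' @return Data frame with columns `context`, `fold`.
#' @export
ogt_dichotomy <- function(elevation = 4, settings = sim_settings()) {
  norm_cfg <- default_config("normal_adipocyte")
  base_txn <- norm_cfg$rates[["ogt_transcription"]]
  glucose_norm <- list(
    places = c(glucose = unname(norm_cfg$places[["glucose"]])),
    rates = c(glucose_supply = unname(norm_cfg$rates[["glucose_supply"]])))

  # adipocyte wiring: resistant topology, OGT level the only variable
  adip_base <- build_model("insulin_resistant_adipocyte",
                           list(rates = c(ogt_transcription = base_txn)))
  adip_elev <- build_model("insulin_resistant_adipocyte",
                           list(rates = c(ogt_transcription =
                                            base_txn * elevation)))
  # cancer wiring at normal glucose, same elevation
  canc_base <- build_model("cancer_hyperglycemia",
                           list(places = glucose_norm$places,
                                rates = c(glucose_norm$rates,
                                          ogt_transcription = base_txn)))
  canc_elev <- build_model("cancer_hyperglycemia",
                           list(places = glucose_norm$places,
                                rates = c(glucose_norm$rates,
                                          ogt_transcription =
                                            base_txn * elevation)))
  folds <- vapply(list(adipocyte = list(adip_base, adip_elev),
                       cancer = list(canc_base, canc_elev)),
                  function(pair) {
                    fold_change(simulate_net(pair[[1]], settings),
                                simulate_net(pair[[2]], settings),
                                "akt_active")$fold
                  }, numeric(1))
  data.frame(context = names(folds), fold = unname(folds),
             stringsAsFactors = FALSE)
}

#' Export a summary table as CSV
#'
#' @param table a `summary_table` from [run_case()] or
#'   [table1_directions()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
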