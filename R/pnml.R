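PNML_NS <- "http://www.pnml.org/version-2009/grammar/pnml"
PTNET_TYPE <- "http://www.pnml.org/version-2009/grammar/ptnet"
TOOL_NAME <- "ogtpn"

#' Write a net as PNML
#'
#' Emits a single-page Place/Transition PNML document. Real-valued initial
#' markings, rate constants, transition kinds, place role tags and the
#' inhibitory arc type live in namespaced `toolspecific` blocks so that
#' third-party PNML tools still read the plain structure; the standard
#' `initialMarking`/`inscription` elements carry rounded integers for
#' their benefit.
#'
#' @param net a valid `petri_net`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_pnml <- function(net, path) {
  assert_valid(net)
  doc <- xml2::xml_new_root("pnml", xmlns = PNML_NS)
  net_node <- xml2::xml_add_child(doc, "net", id = net$name,
                                  type = PTNET_TYPE)
  nm <- xml2::xml_add_child(net_node, "name")
  xml2::xml_add_child(nm, "text", net$name)
  page <- xml2::xml_add_child(net_node, "page", id = "page1")

  tool_block <- function(parent, values) {
    ts <- xml2::xml_add_child(parent, "toolspecific", tool = TOOL_NAME,
                              version = "1.0")
    for (key in names(values)) {
      xml2::xml_add_child(ts, key, format(values[[key]], digits = 17))
    }
    ts
  }

  for (i in seq_len(nrow(net$places))) {
    p <- net$places[i, ]
    node <- xml2::xml_add_child(page, "place", id = p$id)
    nm <- xml2::xml_add_child(node, "name")
    xml2::xml_add_child(nm, "text", p$name)
    mk <- xml2::xml_add_child(node, "initialMarking")
    xml2::xml_add_child(mk, "text", as.character(round(p$initial_tokens)))
    vals <- list(realMarking = p$initial_tokens)
    if (!is.na(p$role_tag)) vals$roleTag <- p$role_tag
    tool_block(node, vals)
  }
  for (i in seq_len(nrow(net$transitions))) {
    tr <- net$transitions[i, ]
    node <- xml2::xml_add_child(page, "transition", id = tr$id)
    nm <- xml2::xml_add_child(node, "name")
    xml2::xml_add_child(nm, "text", tr$name)
    tool_block(node, list(rateConstant = tr$rate_constant, kind = tr$kind))
  }
  for (i in seq_len(nrow(net$arcs))) {
    a <- net$arcs[i, ]
    node <- xml2::xml_add_child(page, "arc",
                                id = sprintf("a%d", i),
                                source = a$source, target = a$target)
    ins <- xml2::xml_add_child(node, "inscription")
    xml2::xml_add_child(ins, "text", as.character(max(1, round(a$weight))))
    tool_block(node, list(realWeight = a$weight, arcType = a$arc_type))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

tool_value <- function(node, key) {
  ts <- xml2::xml_find_first(
    node, sprintf("./x:toolspecific[@tool='%s']/x:%s", TOOL_NAME, key))
  if (inherits(ts, "xml_missing")) NA_character_ else xml2::xml_text(ts)
}

#' Read a net from PNML
#'
#' Parses a PNML Place/Transition document, honouring this package's
#' `toolspecific` blocks when present. Foreign-tool documents load with
#' rate constants defaulting to 1, transition kinds inferred from arc
#' arity, and all arcs standard; unknown toolspecific blocks are skipped
#' with a warning.
#'
#' @param path PNML file.
#' @return A validating `petri_net`.
#' @export
read_pnml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    pn_stop(sprintf("malformed XML in '%s': %s", path, conditionMessage(e)),
            "ogtpn_pnml_error")
  })
  ns <- c(x = xml2::xml_ns(doc)[[1]])
  net_node <- xml2::xml_find_first(doc, "./x:net", ns)
  if (inherits(net_node, "xml_missing")) {
    pn_stop("no <net> element found", "ogtpn_pnml_error")
  }
  name_node <- xml2::xml_find_first(net_node, "./x:name/x:text", ns)
  net_name <- if (inherits(name_node, "xml_missing"))
    xml2::xml_attr(net_node, "id") else xml2::xml_text(name_node)

  foreign <- xml2::xml_find_all(
    doc, sprintf(".//x:toolspecific[@tool!='%s']", TOOL_NAME), ns)
  if (length(foreign) > 0) {
    warning(sprintf("ignoring %d toolspecific block(s) from other tools",
                    length(foreign)), call. = FALSE)
  }

  get1 <- function(node, xpath) {
    r <- xml2::xml_find_first(node, xpath, ns)
    if (inherits(r, "xml_missing")) NA_character_ else xml2::xml_text(r)
  }
  tool1 <- function(node, key) {
    r <- xml2::xml_find_first(
      node, sprintf("./x:toolspecific[@tool='%s']/x:%s", TOOL_NAME, key), ns)
    if (inherits(r, "xml_missing")) NA_character_ else xml2::xml_text(r)
  }

  p_nodes <- xml2::xml_find_all(net_node, ".//x:place", ns)
  if (length(p_nodes) == 0) {
    pn_stop("document contains no places", "ogtpn_pnml_error")
  }
  places <- do.call(rbind, lapply(p_nodes, function(n) {
    id <- xml2::xml_attr(n, "id")
    real_mk <- tool1(n, "realMarking")
    std_mk <- get1(n, "./x:initialMarking/x:text")
    tokens <- if (!is.na(real_mk)) as.numeric(real_mk)
              else if (!is.na(std_mk)) as.numeric(std_mk) else 0
    nm <- get1(n, "./x:name/x:text")
    role <- tool1(n, "roleTag")
    data.frame(id = id, name = if (is.na(nm)) id else nm,
               initial_tokens = tokens, role_tag = role,
               stringsAsFactors = FALSE)
  }))

  t_nodes <- xml2::xml_find_all(net_node, ".//x:transition", ns)
  transitions <- if (length(t_nodes) == 0) {
    data.frame(id = character(), name = character(),
               rate_constant = numeric(), kind = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(t_nodes, function(n) {
      id <- xml2::xml_attr(n, "id")
      k <- tool1(n, "rateConstant")
      kind <- tool1(n, "kind")
      nm <- get1(n, "./x:name/x:text")
      data.frame(id = id, name = if (is.na(nm)) id else nm,
                 rate_constant = if (is.na(k)) 1 else as.numeric(k),
                 kind = if (is.na(kind)) NA_character_ else kind,
                 stringsAsFactors = FALSE)
    }))
  }

  a_nodes <- xml2::xml_find_all(net_node, ".//x:arc", ns)
  arcs <- if (length(a_nodes) == 0) {
    data.frame(source = character(), target = character(),
               weight = numeric(), arc_type = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(a_nodes, function(n) {
      rw <- tool1(n, "realWeight")
      sw <- get1(n, "./x:inscription/x:text")
      at <- tool1(n, "arcType")
      data.frame(source = xml2::xml_attr(n, "source"),
                 target = xml2::xml_attr(n, "target"),
                 weight = if (!is.na(rw)) as.numeric(rw)
                          else if (!is.na(sw)) as.numeric(sw) else 1,
                 arc_type = if (is.na(at)) "standard" else at,
                 stringsAsFactors = FALSE)
    }))
  }

  # infer missing transition kinds from arc arity
  if (nrow(transitions) > 0 && anyNA(transitions$kind)) {
    for (i in which(is.na(transitions$kind))) {
      tid <- transitions$id[i]
      has_in <- any(arcs$target == tid)
      has_out <- any(arcs$source == tid)
      transitions$kind[i] <- if (!has_in) "source"
                             else if (!has_out) "sink" else "internal"
    }
  }

  net <- petri_net(places, transitions, arcs, name = net_name)
  v <- validate_net(net)
  if (nrow(v) > 0) {
    pn_stop(sprintf("PNML document describes an invalid net: %s",
                    v$message[1]), "ogtpn_pnml_error", violations = v)
  }
  net
}

#' Load a configuration override file
#'
#' Reads a YAML file with optional sections `places`, `rates` and
#' `interventions` and returns a typed override map suitable for
#' [build_model()] / [intervention()]. When `variant` is given, keys are
#' checked against that variant's defaults and unknown keys raise an error
#' listing the valid ids.
#'
#' @param path YAML file.
#' @param variant optional variant id to validate keys against.
#' @return Named list of overrides (possibly empty).
#' @export
load_config <- function(path, variant = NULL) {
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    pn_stop(sprintf("cannot parse config '%s': %s", path,
                    conditionMessage(e)), "ogtpn_config_error")
  })
  if (is.null(raw)) return(list())
  bad <- setdiff(names(raw), c("places", "rates", "interventions"))
  if (length(bad) > 0) {
    pn_stop(sprintf("unknown config section(s): %s (valid: places, rates, interventions)",
                    paste(bad, collapse = ", ")), "ogtpn_config_error")
  }
  out <- list()
  for (sec in c("places", "rates")) {
    if (is.null(raw[[sec]])) next
    v <- unlist(raw[[sec]])
    if (!is.numeric(v)) {
      pn_stop(sprintf("config section '%s' must contain numeric values", sec),
              "ogtpn_config_error")
    }
    out[[sec]] <- v
  }
  if (!is.null(raw$interventions)) out$interventions <- raw$interventions
  if (!is.null(variant)) {
    defaults <- default_config(variant)
    for (sec in c("places", "rates")) {
      unknown <- setdiff(names(out[[sec]]), names(defaults[[sec]]))
      if (length(unknown) > 0) {
        pn_stop(sprintf("unknown %s key(s): %s (valid: %s)",
                        sub("s$", "", sec), paste(unknown, collapse = ", "),
                        paste(names(defaults[[sec]]), collapse = ", ")),
                "ogtpn_config_error")
      }
    }
  }
  out
}
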