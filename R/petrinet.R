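#' @importFrom stats setNames
#' @importFrom utils head
NULL

PLACE_ROLES <- c("protein", "enzyme", "drug", "rna", "metabolite",
                 "process-readout")
TRANSITION_KINDS <- c("internal", "source", "sink")
ARC_TYPES <- c("standard", "inhibitory")

pn_stop <- function(message, class, ...) {
  stop(rlang::error_cnd(c(class, "ogtpn_error"), message = message, ...))
}

#' Construct a continuous Petri net
#'
#' A Petri net is a bipartite directed graph of *places* (molecular entities,
#' carrying a nonnegative real number of tokens read as relative activity or
#' concentration) and *transitions* (processes: reactions, modifications,
#' transport), connected by weighted arcs. Standard arcs move tokens;
#' inhibitory arcs (place to transition only) suppress a transition's firing
#' without moving tokens.
#'
#' @param places data frame with columns `id`, `name`, `initial_tokens` and
#'   optionally `role_tag` (one of `r paste(PLACE_ROLES, collapse = ", ")`,
#'   or `NA`). A character vector of ids is accepted as shorthand.
#' @param transitions data frame with columns `id`, `name`, `rate_constant`
#'   (positive, per time unit) and `kind` (`internal`, `source` or `sink`).
#' @param arcs data frame with columns `source`, `target`, `weight`
#'   (positive, default 1) and `arc_type` (`standard` or `inhibitory`).
#' @param name label for the net.
#' @return An object of class `petri_net`.
#' @seealso [validate_net()], [simulate_net()], [build_model()]
#' @export
petri_net <- function(places, transitions, arcs, name = "net") {
  if (is.character(places)) {
    places <- data.frame(id = places)
  }
  places <- normalise_places(places)
  transitions <- normalise_transitions(transitions)
  arcs <- normalise_arcs(arcs)
  structure(
    list(name = name, places = places, transitions = transitions,
         arcs = arcs),
    class = "petri_net"
  )
}

normalise_places <- function(places) {
  places <- as.data.frame(places, stringsAsFactors = FALSE)
  if (is.null(places$name)) places$name <- places$id
  if (is.null(places$initial_tokens)) places$initial_tokens <- 0
  if (is.null(places$role_tag)) places$role_tag <- NA_character_
  places$id <- as.character(places$id)
  places$name <- as.character(places$name)
  places$initial_tokens <- as.numeric(places$initial_tokens)
  places$role_tag <- as.character(places$role_tag)
  rownames(places) <- NULL
  places[c("id", "name", "initial_tokens", "role_tag")]
}

normalise_transitions <- function(transitions) {
  transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
  if (nrow(transitions) == 0) {
    return(data.frame(id = character(), name = character(),
                      rate_constant = numeric(), kind = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(transitions$name)) transitions$name <- transitions$id
  if (is.null(transitions$rate_constant)) transitions$rate_constant <- 1
  if (is.null(transitions$kind)) transitions$kind <- "internal"
  transitions$id <- as.character(transitions$id)
  transitions$name <- as.character(transitions$name)
  transitions$rate_constant <- as.numeric(transitions$rate_constant)
  transitions$kind <- as.character(transitions$kind)
  rownames(transitions) <- NULL
  transitions[c("id", "name", "rate_constant", "kind")]
}

normalise_arcs <- function(arcs) {
  arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)
  if (nrow(arcs) == 0) {
    return(data.frame(source = character(), target = character(),
                      weight = numeric(), arc_type = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(arcs$weight)) arcs$weight <- 1
  if (is.null(arcs$arc_type)) arcs$arc_type <- "standard"
  arcs$source <- as.character(arcs$source)
  arcs$target <- as.character(arcs$target)
  arcs$weight <- as.numeric(arcs$weight)
  arcs$arc_type <- as.character(arcs$arc_type)
  rownames(arcs) <- NULL
  arcs[c("source", "target", "weight", "arc_type")]
}

#' @export
print.petri_net <- function(x, ...) {
  n_inh <- sum(x$arcs$arc_type == "inhibitory")
  cat(sprintf("<petri_net> %s: %d places, %d transitions, %d arcs (%d inhibitory)\n",
              x$name, nrow(x$places), nrow(x$transitions), nrow(x$arcs), n_inh))
  invisible(x)
}

#' Initial marking of a net
#'
#' @param net a `petri_net`.
#' @return Named numeric vector of initial tokens, ordered as the net's
#'   places.
#' @export
initial_marking <- function(net) {
  setNames(net$places$initial_tokens, net$places$id)
}

#' Check a marking against a net
#'
#' A marking must cover exactly the net's places and be nonnegative.
#' @param net a `petri_net`.
#' @param marking named numeric vector.
#' @return The marking, reordered to the net's place order.
#' @keywords internal
check_marking <- function(net, marking) {
  ids <- net$places$id
  if (is.null(names(marking)) || !setequal(names(marking), ids) ||
      length(marking) != length(ids)) {
    pn_stop("marking must cover exactly the net's places",
            "ogtpn_marking_error")
  }
  m <- marking[ids]
  if (any(!is.finite(m)) || any(m < 0)) {
    pn_stop("marking entries must be finite and nonnegative",
            "ogtpn_marking_error")
  }
  m
}

violation <- function(element, rule, message) {
  data.frame(element = element, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

#' Validate the structure of a Petri net
#'
#' Checks every structural invariant: unique ids, nonnegative initial
#' tokens, positive rate constants and weights, bipartite arcs, inhibitory
#' arcs running place-to-transition only, resolving endpoints, no duplicate
#' parallel arcs, and source/sink transition arity. Violations are returned
#' as data, not raised.
#'
#' @param net a `petri_net`.
#' @return A data frame with columns `element`, `rule`, `message`; zero rows
#'   iff the net is valid.
#' @export
validate_net <- function(net) {
  v <- list()
  p <- net$places; tr <- net$transitions; a <- net$arcs

  if (nrow(p) < 1) {
    v[[length(v) + 1]] <- violation(net$name, "nonempty",
                                    "net must contain at least one place")
  }
  dup_p <- unique(p$id[duplicated(p$id)])
  for (id in dup_p) {
    v[[length(v) + 1]] <- violation(id, "unique place id",
                                    sprintf("duplicate place id '%s'", id))
  }
  dup_t <- unique(tr$id[duplicated(tr$id)])
  for (id in dup_t) {
    v[[length(v) + 1]] <- violation(id, "unique transition id",
                                    sprintf("duplicate transition id '%s'", id))
  }
  shared <- intersect(p$id, tr$id)
  for (id in shared) {
    v[[length(v) + 1]] <- violation(id, "disjoint id spaces",
                                    sprintf("id '%s' used for both a place and a transition", id))
  }
  bad_tok <- p$id[!is.finite(p$initial_tokens) | p$initial_tokens < 0]
  for (id in bad_tok) {
    v[[length(v) + 1]] <- violation(id, "nonnegative tokens",
                                    sprintf("place '%s' has negative or non-finite initial tokens", id))
  }
  bad_role <- p$id[!is.na(p$role_tag) & !(p$role_tag %in% PLACE_ROLES)]
  for (id in bad_role) {
    v[[length(v) + 1]] <- violation(id, "known role tag",
                                    sprintf("place '%s' has unknown role_tag", id))
  }
  bad_k <- tr$id[!is.finite(tr$rate_constant) | tr$rate_constant <= 0]
  for (id in bad_k) {
    v[[length(v) + 1]] <- violation(id, "positive rate constant",
                                    sprintf("transition '%s' must have rate_constant > 0", id))
  }
  bad_kind <- tr$id[!(tr$kind %in% TRANSITION_KINDS)]
  for (id in bad_kind) {
    v[[length(v) + 1]] <- violation(id, "known transition kind",
                                    sprintf("transition '%s' has unknown kind", id))
  }

  is_place <- function(id) id %in% p$id
  is_trans <- function(id) id %in% tr$id
  if (nrow(a) > 0) {
    for (i in seq_len(nrow(a))) {
      src <- a$source[i]; tgt <- a$target[i]
      lbl <- sprintf("%s->%s", src, tgt)
      if (!(a$arc_type[i] %in% ARC_TYPES)) {
        v[[length(v) + 1]] <- violation(lbl, "known arc type",
                                        sprintf("arc %s has unknown arc_type '%s'", lbl, a$arc_type[i]))
        next
      }
      if (!is.finite(a$weight[i]) || a$weight[i] <= 0) {
        v[[length(v) + 1]] <- violation(lbl, "positive weight",
                                        sprintf("arc %s must have weight > 0", lbl))
      }
      src_p <- is_place(src); src_t <- is_trans(src)
      tgt_p <- is_place(tgt); tgt_t <- is_trans(tgt)
      if (!(src_p || src_t) || !(tgt_p || tgt_t)) {
        v[[length(v) + 1]] <- violation(lbl, "resolving endpoints",
                                        sprintf("arc %s references an unknown vertex", lbl))
        next
      }
      if (!((src_p && tgt_t) || (src_t && tgt_p))) {
        v[[length(v) + 1]] <- violation(lbl, "non-bipartite arc",
                                        sprintf("arc %s must connect one place and one transition", lbl))
        next
      }
      if (a$arc_type[i] == "inhibitory" && !(src_p && tgt_t)) {
        v[[length(v) + 1]] <- violation(lbl, "inhibitory arc direction",
                                        sprintf("inhibitory arc %s must run place->transition", lbl))
      }
    }
    key <- paste(a$source, a$target, a$arc_type, sep = "\r")
    dup <- unique(key[duplicated(key)])
    for (k in dup) {
      parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
      v[[length(v) + 1]] <- violation(
        sprintf("%s->%s", parts[1], parts[2]), "no duplicate arcs",
        sprintf("duplicate %s arc %s->%s; use weight instead",
                parts[3], parts[1], parts[2]))
    }
    # source/sink arity (only meaningful once endpoints resolve)
    for (i in seq_len(nrow(tr))) {
      tid <- tr$id[i]
      n_in <- sum(a$target == tid)
      n_out <- sum(a$source == tid)
      if (tr$kind[i] == "source" && n_in > 0) {
        v[[length(v) + 1]] <- violation(tid, "source arity",
                                        sprintf("source transition '%s' must have no input arcs", tid))
      }
      if (tr$kind[i] == "sink" && n_out > 0) {
        v[[length(v) + 1]] <- violation(tid, "sink arity",
                                        sprintf("sink transition '%s' must have no output arcs", tid))
      }
    }
  }

  if (length(v) == 0) {
    return(data.frame(element = character(), rule = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

assert_valid <- function(net) {
  v <- validate_net(net)
  if (nrow(v) > 0) {
    pn_stop(sprintf("invalid net '%s': %s", net$name, v$message[1]),
            "ogtpn_invalid_net", violations = v)
  }
  invisible(net)
}

#' Incidence matrix of a Petri net
#'
#' Entry (p, t) is the net token flow into place p when transition t fires
#' once: output-arc weights minus input-arc weights over *standard* arcs.
#' Inhibitory arcs move no tokens and contribute zero.
#'
#' @param net a valid `petri_net`.
#' @return A |P| x |T| numeric matrix with place/transition ids as dimnames.
#' @export
incidence_matrix <- function(net) {
  assert_valid(net)
  p_ids <- net$places$id
  t_ids <- net$transitions$id
  C <- matrix(0, nrow = length(p_ids), ncol = length(t_ids),
              dimnames = list(p_ids, t_ids))
  a <- net$arcs[net$arcs$arc_type == "standard", , drop = FALSE]
  for (i in seq_len(nrow(a))) {
    if (a$source[i] %in% p_ids) {          # place -> transition: consumption
      C[a$source[i], a$target[i]] <- C[a$source[i], a$target[i]] - a$weight[i]
    } else {                               # transition -> place: production
      C[a$target[i], a$source[i]] <- C[a$target[i], a$source[i]] + a$weight[i]
    }
  }
  C
}

#' P-invariants (place invariants) of a Petri net
#'
#' A P-invariant is a nonnegative vector x with t(x) %*% C = 0 for the
#' incidence matrix C; the x-weighted token sum is conserved along every
#' trajectory. Computed with the Farkas algorithm; the returned generating
#' set contains only minimal-support vectors, scaled to smallest integers
#' when entries are (near-)integral.
#'
#' @param net a valid `petri_net`.
#' @param tol entries below `tol` are treated as zero.
#' @return A matrix with one row per invariant, columns named by place id.
#'   Zero rows when no nonnegative invariant exists.
#' @export
p_invariants <- function(net, tol = 1e-9) {
  C <- incidence_matrix(net)
  nP <- nrow(C)
  # Farkas: rows [D | B], D starts as identity, eliminate columns of B
  D <- diag(nP)
  B <- C
  for (j in seq_len(ncol(C))) {
    col <- B[, j]
    keep <- which(abs(col) <= tol)
    pos <- which(col > tol)
    neg <- which(col < -tol)
    newD <- list(); newB <- list()
    for (i in keep) {
      newD[[length(newD) + 1]] <- D[i, ]
      newB[[length(newB) + 1]] <- B[i, ]
    }
    for (ip in pos) {
      for (im in neg) {
        a <- -col[im]; b <- col[ip]
        d <- a * D[ip, ] + b * D[im, ]
        g <- max(abs(d))
        if (g > tol) d <- d / g
        newD[[length(newD) + 1]] <- d
        newB[[length(newB) + 1]] <- (a * B[ip, ] + b * B[im, ]) / max(g, tol)
      }
    }
    if (length(newD) == 0) {
      return(matrix(numeric(0), nrow = 0, ncol = nP,
                    dimnames = list(NULL, rownames(C))))
    }
    D <- do.call(rbind, newD)
    B <- do.call(rbind, newB)
    if (nrow(D) > 10000) {
      pn_stop("p-invariant computation exceeded row budget",
              "ogtpn_invariant_error")
    }
  }
  # drop zero rows, duplicates, and non-minimal supports
  nz <- apply(abs(D) > tol, 1, any)
  D <- D[nz, , drop = FALSE]
  if (nrow(D) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = nP,
                  dimnames = list(NULL, rownames(C))))
  }
  supports <- lapply(seq_len(nrow(D)), function(i) which(abs(D[i, ]) > tol))
  minimal <- rep(TRUE, nrow(D))
  for (i in seq_len(nrow(D))) {
    for (j in seq_len(nrow(D))) {
      if (i != j && minimal[i] &&
          length(supports[[j]]) < length(supports[[i]]) &&
          all(supports[[j]] %in% supports[[i]])) {
        minimal[i] <- FALSE
      }
    }
  }
  D <- D[minimal, , drop = FALSE]
  D <- unique(round(t(apply(D, 1, normalise_invariant, tol = tol)), 12))
  if (ncol(D) != nP) D <- matrix(D, ncol = nP)  # guard 1-row apply collapse
  colnames(D) <- rownames(C)
  rownames(D) <- NULL
  D
}

normalise_invariant <- function(x, tol = 1e-9) {
  x[abs(x) < tol] <- 0
  x <- x / min(x[x > 0])
  xi <- round(x)
  if (max(abs(x - xi)) < 1e-6) {
    # integral: divide by gcd
    nzi <- xi[xi > 0]
    g <- Reduce(gcd2, nzi)
    xi / g
  } else {
    x
  }
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Structural hash of a net
#'
#' Hash over the canonical (sorted) representation of places, transitions
#' and arcs; equal for nets that are identical up to element order.
#' @param net a `petri_net`.
#' @return A character scalar.
#' @export
net_hash <- function(net) {
  p <- net$places[order(net$places$id), ]
  tr <- net$transitions[order(net$transitions$id), ]
  a <- net$arcs[order(net$arcs$source, net$arcs$target, net$arcs$arc_type), ]
  rownames(p) <- rownames(tr) <- rownames(a) <- NULL
  rlang::hash(list(p, tr, a))
}
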