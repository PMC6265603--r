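# Independent fixed-step Euler oracle.
#
# Deliberately re-derives everything straight from the arc table: its own
# stoichiometry accumulation, its own rate computation. Shares no code with
# the package's compiled-structure integrator.

oracle_stoichiometry <- function(net) {
  p_ids <- net$places$id
  t_ids <- net$transitions$id
  S <- matrix(0, length(p_ids), length(t_ids),
              dimnames = list(p_ids, t_ids))
  a <- net$arcs
  for (i in seq_len(nrow(a))) {
    if (a$arc_type[i] != "standard") next
    if (a$source[i] %in% p_ids) {
      S[a$source[i], a$target[i]] <- S[a$source[i], a$target[i]] - a$weight[i]
    } else {
      S[a$target[i], a$source[i]] <- S[a$target[i], a$source[i]] + a$weight[i]
    }
  }
  S
}

oracle_rates <- function(net, m, steepness = 4, hard = FALSE) {
  a <- net$arcs
  vapply(seq_len(nrow(net$transitions)), function(j) {
    tid <- net$transitions$id[j]
    r <- net$transitions$rate_constant[j]
    for (i in which(a$target == tid)) {
      mi <- max(m[[a$source[i]]], 0)
      if (a$arc_type[i] == "standard") {
        r <- r * mi^a$weight[i]
      } else {
        w <- a$weight[i]
        r <- r * if (hard) as.numeric(mi < w)
                 else w^steepness / (w^steepness + mi^steepness)
      }
    }
    r
  }, numeric(1))
}

euler_oracle <- function(net, t_end, h, steepness = 4, hard = FALSE) {
  m <- stats::setNames(net$places$initial_tokens, net$places$id)
  S <- oracle_stoichiometry(net)
  a <- net$arcs
  t_ids <- net$transitions$id
  # index arcs per transition once; rate math stays per-arc as above
  in_rows <- lapply(t_ids, function(tid) which(a$target == tid))
  ks <- net$transitions$rate_constant
  n_steps <- round(t_end / h)
  for (s in seq_len(n_steps)) {
    r <- numeric(length(t_ids))
    for (j in seq_along(t_ids)) {
      rj <- ks[j]
      for (i in in_rows[[j]]) {
        mi <- max(m[[a$source[i]]], 0)
        if (a$arc_type[i] == "standard") {
          rj <- rj * mi^a$weight[i]
        } else {
          w <- a$weight[i]
          rj <- rj * if (hard) as.numeric(mi < w)
                     else w^steepness / (w^steepness + mi^steepness)
        }
      }
      r[j] <- rj
    }
    m <- m + h * drop(S %*% r)
  }
  m
}
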