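# Independent reference implementation of the closed-loop derivative,
# written against the model equations directly: node pressures come from a
# dense solve() of the nodal conductance system assembled here, and the
# aortic valve flow of an inertance-free valve is found by uniroot() on the
# Bernoulli balance rather than the closed-form quadratic the package uses.

oracle_derivative <- function(model) {
  net <- model$network
  n <- net$n_nodes
  G <- matrix(0, n, n)
  for (i in seq_len(nrow(net$segments))) {
    a <- net$segments$from_node[i]
    b <- net$segments$to_node[i]
    g <- 1 / max(net$segments$resistance[i], 1e-8)
    G[a, a] <- G[a, a] + g
    G[b, b] <- G[b, b] + g
    G[a, b] <- G[a, b] - g
    G[b, a] <- G[b, a] - g
  }
  ter <- net$terminals
  for (k in seq_len(nrow(ter))) {
    G[ter$node[k], ter$node[k]] <- G[ter$node[k], ter$node[k]] +
      1 / ter$R_proximal[k]
  }
  T_cyc <- 60 / model$hr
  has_qav <- model$av$inertance_coeff > 0
  s_floor <- 1e-6

  function(state, t) {
    tc <- t %% T_cyc
    V_LA <- state[["V_LA"]]; V_LV <- state[["V_LV"]]
    s_MV <- state[["s_MV"]]; s_AV <- state[["s_AV"]]
    P_term <- unname(state[paste0("P_term_", ter$name)])

    P_LA <- chamber_pressure(V_LA, tc, model$la, T_cyc)
    P_LV <- chamber_pressure(V_LV, tc, model$lv, T_cyc)

    rhs0 <- numeric(n)
    for (k in seq_len(nrow(ter))) {
      rhs0[ter$node[k]] <- rhs0[ter$node[k]] + P_term[k] / ter$R_proximal[k]
    }
    node_p <- function(q_av) {
      rhs <- rhs0
      rhs[net$root_node] <- rhs[net$root_node] + q_av
      solve(G, rhs)
    }

    if (has_qav) {
      Q_AV <- state[["Q_AV_state"]]
      pn <- node_p(Q_AV)
      D <- P_LV - node_p(0)[net$root_node]
      R_eq <- node_p(1)[net$root_node] - node_p(0)[net$root_node]
      dQ_AV <- if (s_AV <= s_floor) {
        -Q_AV / 1e-3
      } else {
        sf <- max(s_AV, sqrt(model$av$bernoulli_coeff / 1e-2))
        (D - R_eq * Q_AV -
           model$av$bernoulli_coeff / sf^2 * Q_AV * abs(Q_AV)) /
          model$av$inertance_coeff
      }
    } else {
      dQ_AV <- NULL
      if (s_AV <= s_floor) {
        Q_AV <- 0
      } else {
        bal <- function(q) {
          P_LV - node_p(q)[net$root_node] -
            model$av$bernoulli_coeff / s_AV^2 * q * abs(q)
        }
        Q_AV <- if (bal(0) == 0) 0 else
          stats::uniroot(bal, c(-2000, 2000), tol = 1e-12)$root
      }
      pn <- node_p(Q_AV)
    }
    P_ao <- pn[net$root_node]

    dpm <- P_LA - P_LV
    Q_MV <- if (s_MV <= s_floor) 0 else
      sign(dpm) * s_MV * sqrt(abs(dpm) / model$mv$bernoulli_coeff)

    den <- 1 / model$R_ven + sum(1 / ter$R_distal)
    P_ven <- (P_LA / model$R_ven + sum(P_term / ter$R_distal)) / den

    dpa <- P_LV - P_ao
    ds_MV <- if (dpm > 0) (1 - s_MV) * model$mv$K_open * dpm else
      s_MV * model$mv$K_close * dpm
    ds_AV <- if (dpa > 0) (1 - s_AV) * model$av$K_open * dpa else
      s_AV * model$av$K_close * dpa

    dP_term <- numeric(nrow(ter))
    for (k in seq_len(nrow(ter))) {
      q_in <- (pn[ter$node[k]] - P_term[k]) / ter$R_proximal[k]
      q_out <- (P_term[k] - P_ven) / ter$R_distal[k]
      dP_term[k] <- (q_in - q_out) / ter$C[k]
    }

    dstate <- c((P_ven - P_LA) / model$R_ven - Q_MV,
                Q_MV - Q_AV, ds_MV, ds_AV, dP_term)
    if (has_qav) dstate <- c(dstate, dQ_AV)
    list(dstate = dstate, P_ao = P_ao, Q_AV = Q_AV, Q_MV = Q_MV,
         P_ven = P_ven, P_LA = P_LA, P_LV = P_LV)
  }
}

# small RK4 stepper used to cross-check the compiled integrator
oracle_rk4 <- function(model, state, dt, n_steps) {
  f <- oracle_derivative(model)
  y <- unname(state)
  nm <- names(state)
  for (i in seq_len(n_steps)) {
    t <- (i - 1) * dt
    k1 <- f(stats::setNames(y, nm), t)$dstate
    k2 <- f(stats::setNames(y + dt / 2 * k1, nm), t + dt / 2)$dstate
    k3 <- f(stats::setNames(y + dt / 2 * k2, nm), t + dt / 2)$dstate
    k4 <- f(stats::setNames(y + dt * k3, nm), t + dt)$dstate
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  stats::setNames(y, nm)
}
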