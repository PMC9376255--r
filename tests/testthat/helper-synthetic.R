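# Hand-built trajectories for metric tests: a tibble with the columns and
# attributes summarize_cycle() and detect_periodicity() rely on.

synthetic_trajectory <- function(df, hr = 60, n_cycles = 1,
                                 terminals = c("coronaries", "descending_aorta"),
                                 capacitances = rep(0.1, length(terminals))) {
  need <- c("V_LA", "V_LV", "s_MV", "s_AV", "P_LA", "P_LV", "P_ao",
            "Q_MV", "Q_AV", "P_ven", "p_sr", "Q_dev", "V_dev")
  for (col in need) if (is.null(df[[col]])) df[[col]] <- 0
  for (nm in terminals) {
    if (is.null(df[[paste0("P_term_", nm)]])) df[[paste0("P_term_", nm)]] <- 80
    if (is.null(df[[paste0("Q_br_", nm)]])) df[[paste0("Q_br_", nm)]] <- 1
    if (is.null(df[[paste0("P_br_", nm)]])) df[[paste0("P_br_", nm)]] <- 80
  }
  traj <- tibble::as_tibble(df)
  attr(traj, "hr") <- hr
  attr(traj, "n_cycles") <- n_cycles
  attr(traj, "record_dt") <- diff(df$time[1:2])
  attr(traj, "terminals") <- terminals
  attr(traj, "capacitances") <- capacitances
  attr(traj, "has_qav") <- FALSE
  class(traj) <- c("cv_trajectory", class(traj))
  traj
}
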