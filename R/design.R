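# Operating-point selection: run the flow and oxygen stages over a sweep of
# perfusion rates and check the probe metrics against physiological windows
# for dermal interstitial flow (velocity), endothelial wall shear stress and
# oxygen tension. Stokes linearity lets the sweep reuse a single chamber and
# unit-cell solve, rescaled per flow rate; the (nonlinear) oxygen stage is
# re-solved for every rate.

#' Physiological target windows
#'
#' Defaults: restrictive interstitial-velocity window 0.1-5 um/s (broad
#' alternative 0.1-10 um/s), wall-shear-stress window 0.1-10 mPa, hypoxia
#' threshold 1 % and dermal normoxia reference 13 % atmospheric O2.
#'
#' @param velocity_window,velocity_window_broad c(lower, upper) in m/s.
#' @param wss_window c(lower, upper) in Pa.
#' @param hypoxia_percent,normoxia_percent oxygen thresholds (% atm).
#' @return object of class `physiological_ranges`.
#' @export
physiological_ranges <- function(velocity_window = c(0.1e-6, 5e-6),
                                 velocity_window_broad = c(0.1e-6, 10e-6),
                                 wss_window = c(0.1e-3, 10e-3),
                                 hypoxia_percent = 1,
                                 normoxia_percent = 13) {
  chk <- function(w) {
    if (length(w) != 2 || w[1] <= 0 || w[2] <= w[1])
      stop("window must be c(lower, upper) with 0 < lower < upper")
    w
  }
  structure(list(velocity_window = chk(velocity_window),
                 velocity_window_broad = chk(velocity_window_broad),
                 wss_window = chk(wss_window),
                 hypoxia_percent = hypoxia_percent,
                 normoxia_percent = normoxia_percent),
            class = "physiological_ranges")
}

# shared solves reused across the sweep (all linear in Q)
build_sweep_base <- function(cfg, Q_ref = "5 uL/min") {
  chamber <- config_chamber(cfg)
  array <- config_array(cfg)
  grid <- build_chamber_grid(chamber, array, config_grid_control(cfg))
  fluid <- config_fluid(cfg)
  metrics <- compute_lattice_metrics(array$microstructure)
  # Brinkman permeability measured on the resolved lattice cell; the
  # analytic fibre-array correlation is kept as an independent cross-check
  kappa <- measure_lattice_permeability(array$microstructure, fluid,
                                        spacing = cfg$unit_cell$spacing)
  flow_ref <- solve_stokes_brinkman(grid, fluid, flow_bc(Q_ref), kappa)
  cell <- build_unit_cell_geometry(array$microstructure,
                                   spacing = cfg$unit_cell$spacing,
                                   clearance = cfg$unit_cell$clearance)
  cell_sol <- suppressWarnings(
    solve_unit_cell_stokes(cell, fluid = fluid, driving = "shear",
                           lid_velocity = 1))
  probes <- build_probe_set(grid)
  list(cfg = cfg, grid = grid, fluid = fluid, metrics = metrics,
       kappa = kappa, flow_ref = flow_ref, cell_sol = cell_sol,
       probes = probes)
}

# rescale a chamber solution to another flow rate (Stokes linearity)
scale_flow <- function(flow, Q) {
  s <- Q / flow$Q
  out <- flow
  out$u <- flow$u * s; out$v <- flow$v * s; out$w <- flow$w * s
  out$p <- flow$p * s
  out$Q <- Q; out$Q_sim <- flow$Q_sim * s
  ch <- flow$grid$chamber
  out$Re <- reynolds_number(Q, ch$width_y, ch$height_z, flow$fluid)
  out
}

#' Evaluate one candidate operating point
#'
#' Runs (or rescales) the chamber flow solve with the nested pore-scale unit
#' cell, extracts the probe velocity and beam-averaged wall-shear-stress
#' tables, solves the oxygen stage, and checks every metric against the
#' physiological windows.
#'
#' @param Q flow rate (m^3/s or unit string such as `"5 uL/min"`).
#' @param cfg a configuration (see [default_config()]).
#' @param base optional precomputed [build_sweep_base()] result (reused
#'   across a sweep).
#' @param ranges a [physiological_ranges()]; default from the config.
#' @return object of class `operating_point` with metrics, tables and
#'   feasibility flags.
#' @export
evaluate_operating_point <- function(Q, cfg = default_config(), base = NULL,
                                     ranges = NULL) {
  Q <- parse_quantity(Q, "Q")
  if (is.null(base)) base <- build_sweep_base(cfg, Q_ref = Q)
  ranges <- ranges %||% config_ranges(cfg)
  flow <- scale_flow(base$flow_ref, Q)
  probes <- base$probes

  vel_unit <- probe_velocity(flow, probes, sampling = "unit_cell",
                             cell_sol = base$cell_sol)
  vel_chamber <- probe_velocity(flow, probes, sampling = "chamber")
  wss_tab <- beam_averaged_wss(flow, probes, base$cell_sol)
  # interstitial (in-scaffold depth-averaged) velocity at each probe
  # column: the quantity the physiological interstitial-flow window refers
  # to, and the near-surface top-layer sampling used for feasibility
  pts <- probes$points
  ms_h <- base$grid$array$microstructure$height
  inter <- superficial_velocity(flow, pts$x, pts$y, depth = ms_h)
  vel_unit$interstitial <- inter
  max_top_velocity <- max(inter)
  min_probe_velocity <- min(vel_unit$speed)
  # representative (median) beam-averaged WSS, the per-rate feasibility
  # statistic; the extreme table values are reported alongside
  wss_stat <- stats::median(wss_tab$tau_zx)
  max_avg_wss <- max(wss_tab$tau_zx)
  min_avg_wss <- min(wss_tab$tau_zx)
  ch <- base$grid$chamber
  flat_tau_analytic <- analytic_plane_poiseuille(Q, ch$width_y, ch$height_z,
                                                 base$fluid)$tau_floor
  flat_tau_solver <- flat_region_floor_shear(flow)

  params <- config_oxygen(cfg)
  loading <- config_loading(cfg)
  conv <- config_conversion(cfg)
  ox <- solve_oxygen(base$grid, flow, params, loading)
  prof_array <- line_profile_at_height(ox, z = 10e-6, path = "through-array",
                                       conv = conv)
  prof_flat <- line_profile_at_height(ox, z = 10e-6, path = "flat-side",
                                      conv = conv)
  drops <- list(
    array_points = percent_drop(prof_array, conv),
    array_relative = percent_drop(prof_array, conv, mode = "relative"),
    flat_points = percent_drop(prof_flat, conv),
    flat_relative = percent_drop(prof_flat, conv, mode = "relative"))
  hyp <- hypoxia_check(ox, conv, flow = flow)

  flags <- list(
    velocity_ok = max_top_velocity >= ranges$velocity_window[1] &&
      max_top_velocity <= ranges$velocity_window[2],
    wss_ok = wss_stat >= ranges$wss_window[1] &&
      wss_stat <= ranges$wss_window[2],
    oxygen_ok = !hyp$hypoxic)

  out <- list(Q = Q, Q_uL_min = Q / UL_PER_MIN,
              velocity_probes = vel_unit,
              velocity_probes_chamber = vel_chamber,
              wss_table = wss_tab,
              max_top_velocity = max_top_velocity,
              min_probe_velocity = min_probe_velocity,
              wss_stat = wss_stat,
              max_avg_wss = max_avg_wss, min_avg_wss = min_avg_wss,
              flat_tau_analytic = flat_tau_analytic,
              flat_tau_solver = flat_tau_solver,
              oxygen = ox, profile_array = prof_array,
              profile_flat = prof_flat, drops = drops, hypoxia = hyp,
              flags = flags, feasible = all(unlist(flags)),
              ranges = ranges)
  class(out) <- "operating_point"
  out
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("operating_point Q = %.3g uL/min\n", x$Q_uL_min))
  cat(sprintf("  max interstitial velocity: %.3g um/s  (window %.2g-%.2g)\n",
              x$max_top_velocity * 1e6, x$ranges$velocity_window[1] * 1e6,
              x$ranges$velocity_window[2] * 1e6))
  cat(sprintf("  beam-averaged WSS: median %.3g mPa, range %.3g-%.3g  (window %.2g-%.2g)\n",
              x$wss_stat * 1e3, x$min_avg_wss * 1e3, x$max_avg_wss * 1e3,
              x$ranges$wss_window[1] * 1e3, x$ranges$wss_window[2] * 1e3))
  cat(sprintf("  oxygen: drop %.3g %%-pts (array), %.3g %%-pts (flat); min %.3g %%\n",
              x$drops$array_points, x$drops$flat_points,
              x$hypoxia$min_percent))
  cat("  flags:", paste(names(x$flags), unlist(x$flags), sep = "=",
                        collapse = ", "), "\n")
  invisible(x)
}

#' Sweep candidate flow rates
#'
#' Evaluates every flow rate of the sweep with shared chamber/unit-cell
#' solves and returns the per-rate metrics plus the recommended operating
#' point.
#'
#' @param Q_list flow rates (m^3/s, or unit strings, or numeric uL/min via
#'   `rates_uL_min` in the config).
#' @param cfg configuration list.
#' @param ranges optional [physiological_ranges()].
#' @return object of class `sweep_result`.
#' @export
sweep_flow_rates <- function(Q_list = NULL, cfg = default_config(),
                             ranges = NULL) {
  if (is.null(Q_list)) Q_list <- cfg$sweep$rates_uL_min * UL_PER_MIN
  Q_list <- vapply(Q_list, parse_quantity, numeric(1))
  if (length(Q_list) == 0) stop("empty flow-rate sweep")
  base <- build_sweep_base(cfg, Q_ref = max(Q_list))
  ranges <- ranges %||% config_ranges(cfg)
  pts <- lapply(Q_list, evaluate_operating_point, cfg = cfg, base = base,
                ranges = ranges)
  tab <- do.call(rbind, lapply(pts, function(p) data.frame(
    Q_uL_min = p$Q_uL_min,
    max_top_velocity_um_s = p$max_top_velocity * 1e6,
    wss_stat_mPa = p$wss_stat * 1e3,
    max_avg_wss_mPa = p$max_avg_wss * 1e3,
    flat_tau_mPa = p$flat_tau_analytic * 1e3,
    drop_array_pts = p$drops$array_points,
    drop_flat_pts = p$drops$flat_points,
    min_percent = p$hypoxia$min_percent,
    velocity_ok = p$flags$velocity_ok,
    wss_ok = p$flags$wss_ok,
    oxygen_ok = p$flags$oxygen_ok,
    feasible = p$feasible)))
  out <- list(points = pts, table = tab, base = base, cfg = cfg,
              ranges = ranges)
  class(out) <- "sweep_result"
  out$recommendation <- recommend_flow_rate(out, rule = cfg$sweep$rule %||%
                                              "largest")
  out
}

#' Recommend a flow rate from a sweep
#'
#' Default rule: the largest feasible rate (strongest physiological stimulus
#' within all windows). If no rate is feasible the result says so rather
#' than raising an error.
#'
#' @param sweep a `sweep_result`.
#' @param rule `"largest"`, `"smallest"` or `"midpoint"`.
#' @return list with `feasible`, `Q` (m^3/s, `NA` if infeasible),
#'   `Q_uL_min` and the rule used.
#' @export
recommend_flow_rate <- function(sweep, rule = c("largest", "smallest",
                                                "midpoint")) {
  rule <- match.arg(rule)
  ok <- sweep$table$Q_uL_min[sweep$table$feasible]
  if (length(ok) == 0)
    return(list(feasible = FALSE, Q = NA_real_, Q_uL_min = NA_real_,
                rule = rule, message = "no feasible operating point"))
  q <- switch(rule, largest = max(ok), smallest = min(ok),
              midpoint = ok[which.min(abs(ok - mean(range(ok))))])
  list(feasible = TRUE, Q = q * UL_PER_MIN, Q_uL_min = q, rule = rule)
}

#' @export
print.sweep_result <- function(x, ...) {
  print(x$table, row.names = FALSE)
  r <- x$recommendation
  if (r$feasible) cat("recommended Q:", r$Q_uL_min, "uL/min (rule:",
                      r$rule, ")\n")
  else cat("no feasible operating point\n")
  invisible(x)
}

#' Report tables for a completed sweep
#'
#' Stable, unit-labelled tables: per-rate maximum velocity and WSS, the
#' per-probe velocity and beam-averaged WSS tables at the recommended rate,
#' and the oxygen summary.
#'
#' @param sweep a `sweep_result`.
#' @return named list of data frames; each carries the configuration hash
#'   as attribute `config_hash`.
#' @export
generate_report_tables <- function(sweep) {
  rec <- sweep$recommendation
  q_show <- if (rec$feasible) rec$Q_uL_min else sweep$table$Q_uL_min[1]
  p <- sweep$points[[which(sweep$table$Q_uL_min == q_show)[1]]]
  vel <- p$velocity_probes
  names(vel) <- c("microstructure", "pore", "height_um", "u_x_m_s",
                  "speed_m_s", "interstitial_m_s")
  vel$speed_um_s <- vel$speed_m_s * 1e6
  vel$interstitial_um_s <- vel$interstitial_m_s * 1e6
  wss <- p$wss_table
  names(wss) <- c("microstructure", "pore", "height_um", "tau_zx_Pa")
  wss$tau_zx_mPa <- wss$tau_zx_Pa * 1e3
  ox <- data.frame(Q_uL_min = sweep$table$Q_uL_min,
                   drop_array_pts = sweep$table$drop_array_pts,
                   drop_flat_pts = sweep$table$drop_flat_pts,
                   min_percent = sweep$table$min_percent)
  tabs <- list(velocity_sweep = sweep$table[, c("Q_uL_min",
                                                "max_top_velocity_um_s",
                                                "velocity_ok")],
               wss_sweep = sweep$table[, c("Q_uL_min", "wss_stat_mPa",
                                           "max_avg_wss_mPa", "wss_ok")],
               probe_velocity = vel, beam_wss = wss, oxygen_summary = ox)
  h <- config_hash(sweep$cfg)
  lapply(tabs, function(t) { attr(t, "config_hash") <- h; t })
}

# small deterministic polynomial hash of a configuration (31-bit, exact in
# double arithmetic)
config_hash <- function(cfg) {
  s <- paste(names(unlist(cfg)), format(unlist(cfg), digits = 15),
             collapse = ";")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
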