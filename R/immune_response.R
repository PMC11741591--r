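#' Simulate the full infection scenario for one neuron profile
#'
#' Starts at the closed-form baseline steady state, integrates through the
#' infection window and the recovery phase, and summarizes the response.
#' Summary levels "during infection" are read at the left limit of the
#' clearance time (end of the 120 h infection phase); the asymptotic
#' closed-form steady state at the elevated production rate is reported
#' alongside, since by that point the fast variables have essentially
#' equilibrated while the slow complex pool has not.
#'
#' @param profile A `neuron_profile` from [get_profile()] (possibly
#'   transformed).
#' @param protocol An [infection_protocol()]; by default built from the
#'   profile's own `alpha_baseline`/`alpha_infection` with the standard
#'   50/170/400 h timing.
#' @param times Optional output grid passed to [simulate_trajectory()].
#'
#' @return List with `trajectory` and `summary`. The summary holds the
#'   baseline steady state, the state at end of infection, the final state,
#'   extremes over the trajectory (min free reelin, max free Abeta42 —
#'   molecules and nM — and min phospho-GSK3beta fraction), the complex pool
#'   at end of infection, and the closed-form steady state at the infection
#'   production rate.
#' @examples
#' res <- run_immune_response(get_profile("LR"))
#' res$summary$max_a_beta_nM
#' @export
run_immune_response <- function(profile, protocol = NULL, times = NULL) {
  stopifnot(inherits(profile, "neuron_profile"))
  params <- profile$params
  if (is.null(protocol)) {
    protocol <- infection_protocol(params$alpha_baseline, params$alpha_infection)
  }
  baseline <- steady_state(params, protocol$alpha_low)
  traj <- simulate_trajectory(params, protocol,
                              initial = as_system_state(baseline),
                              times = times)
  end_inf <- state_at_end_of_infection(traj)
  final <- unlist(traj[nrow(traj), state_names()])
  frac <- traj$gsk3b_p / params$g_tot
  geom <- profile$geometry
  nM <- function(m) molecules_to_molar(m, geom) * 1e9
  summary <- list(
    profile = profile$name,
    protocol = protocol,
    baseline = baseline,
    end_of_infection_state = end_inf,
    final_state = final,
    min_reelin_molecules = min(traj$reelin),
    min_reelin_nM = nM(min(traj$reelin)),
    max_a_beta_molecules = max(traj$a_beta),
    max_a_beta_nM = nM(max(traj$a_beta)),
    min_gsk3b_p_fraction = min(frac),
    complex_at_end_of_infection = end_inf[["a_beta_reelin"]],
    infection_steady_state = steady_state(params, protocol$alpha_high)
  )
  list(trajectory = traj, summary = summary)
}

#' Compare two infection-response summaries
#'
#' Ratios (first over second) of the quantities behind the cross-neuron
#' claims: the complex pool at end of infection, the peak free Abeta42, and
#' the production rates used during infection. Both summaries must come from
#' protocols with identical timing so levels are compared at matching times.
#'
#' @param summary_a,summary_b `summary` components of [run_immune_response()]
#'   results.
#' @return Named list of ratios `a / b`.
#' @examples
#' re <- run_immune_response(get_profile("RePlus"))
#' lr <- run_immune_response(get_profile("LR"))
#' compare_profiles(re$summary, lr$summary)$complex_pool_ratio  # > 5
#' @export
compare_profiles <- function(summary_a, summary_b) {
  pa <- summary_a$protocol; pb <- summary_b$protocol
  if (pa$t_start != pb$t_start || pa$t_end != pb$t_end ||
      pa$horizon != pb$horizon) {
    stop("summaries use different protocol timing; levels are not comparable",
         call. = FALSE)
  }
  list(
    complex_pool_ratio =
      summary_a$complex_at_end_of_infection / summary_b$complex_at_end_of_infection,
    max_a_beta_ratio =
      summary_a$max_a_beta_molecules / summary_b$max_a_beta_molecules,
    alpha_infection_ratio = pa$alpha_high / pb$alpha_high
  )
}

#' Production rate needed to reach a target free-Abeta42 concentration
#'
#' Solves for the constant production rate alpha whose closed-form
#' steady-state free Abeta42 equals the target concentration. Free Abeta42
#' is non-decreasing in alpha, so a monotone 1-D root find on the closed form
#' suffices.
#'
#' @param profile A `neuron_profile`.
#' @param target_conc Target free-Abeta42 concentration, mol/L; must exceed
#'   the baseline steady-state concentration.
#' @param alpha_max Upper bracket for the search (default 1e9 molecules/h).
#' @return Calibrated alpha, molecules/h.
#' @examples
#' calibrate_alpha_infection(get_profile("LR"), 100e-9)   # ~43700
#' @export
calibrate_alpha_infection <- function(profile, target_conc, alpha_max = 1e9) {
  stopifnot(inherits(profile, "neuron_profile"))
  params <- profile$params
  target <- molar_to_molecules(target_conc, profile$geometry)
  a0 <- params$alpha_baseline
  if (steady_state(params, a0)$a_beta >= target) {
    stop("target concentration is not above the baseline free-Abeta42 level",
         call. = FALSE)
  }
  f <- function(a) steady_state(params, a)$a_beta - target
  if (f(alpha_max) < 0) {
    stop("no production rate in the bracket reaches the target concentration",
         call. = FALSE)
  }
  stats::uniroot(f, c(a0, alpha_max), tol = 1e-6 * a0)$root
}
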