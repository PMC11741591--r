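#' Time derivatives of the four state variables
#'
#' Mass-action right-hand side of the kinetic model. Free Abeta42 is produced
#' at rate `alpha_current`, removed first-order (beta) and consumed by
#' second-order binding to free reelin (gamma). Free reelin is produced
#' constitutively (tau), removed first-order (rho) and consumed by the same
#' binding term. The complex accumulates from binding and decays first-order
#' (delta). Phosphorylated GSK3beta is driven by reelin with saturation in the
#' remaining unphosphorylated pool, and relaxes first-order (kappa).
#'
#' @param state A [system_state()] (or named numeric vector with the same
#'   four components).
#' @param params A [model_parameters()] object.
#' @param alpha_current Abeta42 production rate in force, molecules/h, >= 0.
#'
#' @return Named numeric vector of the four derivatives, molecules/h.
#' @examples
#' p <- get_profile("LR")$params
#' model_rhs(system_state(0, 0, 0, 0), p, alpha_current = p$alpha_baseline)
#' @export
model_rhs <- function(state, params, alpha_current) {
  validate_model_parameters(params)
  s <- as_state_vector(state)
  if (!is.finite(alpha_current) || alpha_current < 0) {
    stop("alpha_current must be finite and non-negative", call. = FALSE)
  }
  A <- s[["a_beta"]]; R <- s[["reelin"]]
  B <- s[["a_beta_reelin"]]; P <- s[["gsk3b_p"]]
  bind <- params$gamma * A * R
  c(
    a_beta        = alpha_current - params$beta * A - bind,
    reelin        = params$tau - params$rho * R - bind,
    a_beta_reelin = bind - params$delta * B,
    gsk3b_p       = params$eta * R * (1 - P / params$g_tot) - params$kappa * P
  )
}

# Closed-form steady state of the Abeta/reelin/complex subsystem, vectorized
# over alpha and tau (used both by steady_state() and by the grid search).
# Returns the admissible (+Q) root.
ss_abr_closed_form <- function(alpha, tau, beta, gamma, rho, delta) {
  q <- sqrt(alpha^2 * gamma^2 + 2 * alpha * beta * gamma * rho -
              2 * alpha * gamma^2 * tau + beta^2 * rho^2 +
              2 * beta * gamma * rho * tau + gamma^2 * tau^2)
  if (any(!is.finite(q))) {
    stop("internal error: steady-state discriminant is not finite", call. = FALSE)
  }
  list(
    a_beta        = (alpha * gamma - beta * rho - gamma * tau + q) / (2 * beta * gamma),
    reelin        = (-alpha * gamma - beta * rho + gamma * tau + q) / (2 * gamma * rho),
    a_beta_reelin = (alpha * gamma + beta * rho + gamma * tau - q) / (2 * delta * gamma),
    q             = q
  )
}

# Fixed point of the phospho-GSK3beta equation given steady-state free reelin.
gsk3bp_fixed_point <- function(reelin, eta, kappa, g_tot) {
  eta * reelin * g_tot / (kappa * g_tot + eta * reelin)
}

# The reported long closed form for the phospho-GSK3beta steady state,
# kept verbatim as an independent cross-check of gsk3bp_fixed_point().
gsk3bp_long_form <- function(alpha, tau, beta, gamma, rho, delta, eta, kappa, g_tot) {
  q <- ss_abr_closed_form(alpha, tau, beta, gamma, rho, delta)$q
  num <- g_tot^2 * eta * kappa * q -
    g_tot * eta * (g_tot * alpha * gamma * kappa + g_tot * beta * kappa * rho -
                     g_tot * gamma * kappa * tau + 2 * beta * eta * tau)
  den <- 2 * g_tot^2 * gamma * kappa^2 * rho - 2 * g_tot * alpha * eta * gamma * kappa -
    2 * g_tot * beta * eta * kappa * rho + 2 * g_tot * eta * gamma * kappa * tau -
    2 * beta * eta^2 * tau
  num / den
}

#' Closed-form steady state of the model
#'
#' Evaluates the admissible algebraic root of the steady-state equations for
#' a constant Abeta42 production rate. The other root carries negative
#' components under any valid parameterization and is not returned. When
#' `gamma = 0` the Abeta and reelin equations decouple and the exact limit
#' `(alpha/beta, tau/rho, 0, .)` is used. The phospho-GSK3beta component is
#' computed from its fixed point `eta R* G_tot / (kappa G_tot + eta R*)`,
#' which is algebraically identical to the reported long-form expression.
#'
#' @param params A [model_parameters()] object.
#' @param alpha Constant Abeta42 production rate, molecules/h
#'   (default: `params$alpha_baseline`).
#'
#' @return An object of class `steady_state`: named list with the four state
#'   components, the discriminant root `q`, and the `alpha` it was computed at.
#' @examples
#' steady_state(get_profile("LR")$params)          # baseline
#' steady_state(get_profile("LR")$params, 44000)   # infection level
#' @export
steady_state <- function(params, alpha = params$alpha_baseline) {
  validate_model_parameters(params)
  if (!is.finite(alpha) || alpha < 0) {
    stop("alpha must be finite and non-negative", call. = FALSE)
  }
  if (params$gamma == 0) {
    A <- alpha / params$beta
    R <- params$tau / params$rho
    B <- 0
    q <- params$beta * params$rho  # degenerate-limit discriminant
  } else {
    sol <- ss_abr_closed_form(alpha, params$tau, params$beta, params$gamma,
                              params$rho, params$delta)
    A <- sol$a_beta; R <- sol$reelin; B <- sol$a_beta_reelin; q <- sol$q
  }
  # guard against tiny negative round-off on the admissible root
  comps <- c(a_beta = A, reelin = R, a_beta_reelin = B)
  if (any(comps < -1e-9 * max(1, abs(comps)))) {
    stop("internal error: admissible steady-state root has negative components",
         call. = FALSE)
  }
  comps[comps < 0] <- 0
  P <- gsk3bp_fixed_point(comps[["reelin"]], params$eta, params$kappa, params$g_tot)
  structure(
    list(a_beta = comps[["a_beta"]], reelin = comps[["reelin"]],
         a_beta_reelin = comps[["a_beta_reelin"]], gsk3b_p = P,
         q = q, alpha = alpha),
    class = "steady_state"
  )
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("steady state at alpha = %g molecules/h\n", x$alpha))
  cat(sprintf("  free Abeta42   %12.4g molecules\n", x$a_beta))
  cat(sprintf("  free reelin    %12.4g molecules\n", x$reelin))
  cat(sprintf("  Abeta-reelin   %12.4g molecules\n", x$a_beta_reelin))
  cat(sprintf("  GSK3beta_p     %12.4g molecules\n", x$gsk3b_p))
  invisible(x)
}

#' Coerce a steady state to a system state vector
#'
#' @param ss A [steady_state()] object.
#' @return A [system_state()] with the same four components.
#' @export
as_system_state <- function(ss) {
  system_state(ss$a_beta, ss$reelin, ss$a_beta_reelin, ss$gsk3b_p)
}

#' Steady-state total copy numbers of reelin and Abeta42
#'
#' Totals as measured by densitometry: total reelin is free reelin plus
#' complex; total Abeta42 is free Abeta42 plus complex, both at the same
#' steady state.
#'
#' @inheritParams steady_state
#' @return Named numeric vector `c(total_reelin, total_a_beta)`, molecules.
#' @examples
#' steady_state_totals(get_profile("RePlus")$params)
#' @export
steady_state_totals <- function(params, alpha = params$alpha_baseline) {
  ss <- steady_state(params, alpha)
  c(total_reelin = ss$reelin + ss$a_beta_reelin,
    total_a_beta = ss$a_beta + ss$a_beta_reelin)
}

#' Jacobian of the model at a given state
#'
#' Analytic 4x4 Jacobian of [model_rhs()] with respect to the state. Its
#' diagonal is negative for any positive state and parameters (four negative
#' autoregulatory loops); the (1,2) x (2,1) product is `gamma^2 x1 x2 >= 0`,
#' the single positive feedback loop between free Abeta42 and free reelin.
#'
#' @param params A [model_parameters()] object.
#' @param state A [system_state()] (or named numeric vector).
#' @return 4x4 numeric matrix with dimnames after the state components.
#' @examples
#' p <- get_profile("LR")$params
#' model_jacobian(p, as_system_state(steady_state(p)))
#' @export
model_jacobian <- function(params, state) {
  validate_model_parameters(params)
  s <- as_state_vector(state)
  x1 <- s[["a_beta"]]; x2 <- s[["reelin"]]; x4 <- s[["gsk3b_p"]]
  g <- params$gamma
  J <- matrix(0, 4, 4, dimnames = list(state_names(), state_names()))
  J[1, 1] <- -params$beta - g * x2
  J[1, 2] <- -g * x1
  J[2, 1] <- -g * x2
  J[2, 2] <- -g * x1 - params$rho
  J[3, 1] <- g * x2
  J[3, 2] <- g * x1
  J[3, 3] <- -params$delta
  J[4, 2] <- params$eta * (1 - x4 / params$g_tot)
  J[4, 4] <- -params$kappa - params$eta * x2 / params$g_tot
  J
}

#' Linear stability of a steady state
#'
#' Verifies that the supplied point is a steady state (residual check on
#' [model_rhs()]), then classifies it from the eigenvalues of the Jacobian:
#' all eigenvalues real and negative gives a stable node, complex pairs with
#' negative real parts a stable spiral, any non-negative real part unstable.
#' Both canonical neuron profiles have all four eigenvalues real and negative
#' at their baseline (and infection-level) steady states, so those states are
#' locally asymptotically stable.
#'
#' @param params A [model_parameters()] object.
#' @param ss A [steady_state()] object (carries the alpha it was computed at).
#' @param tol Relative residual tolerance for the steady-state check.
#' @return List with `eigenvalues` (complex), `classification` (character),
#'   and `stable` (logical).
#' @examples
#' p <- get_profile("LR")$params
#' assess_stability(p, steady_state(p))
#' @export
assess_stability <- function(params, ss, tol = 1e-8) {
  stopifnot(inherits(ss, "steady_state"))
  state <- as_system_state(ss)
  res <- model_rhs(state, params, ss$alpha)
  scale <- pmax(abs(unclass(state)), 1)
  if (any(abs(res) > tol * pmax(scale, ss$alpha + params$tau))) {
    stop("supplied point is not a steady state of these parameters", call. = FALSE)
  }
  ev <- eigen(model_jacobian(params, state), only.values = TRUE)$values
  re <- Re(ev); im <- Im(ev)
  classification <- if (all(re < 0)) {
    if (all(abs(im) < 1e-12 * pmax(abs(re), 1))) "stable node" else "stable spiral"
  } else {
    "unstable"
  }
  list(eigenvalues = ev, classification = classification,
       stable = all(re < 0))
}
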