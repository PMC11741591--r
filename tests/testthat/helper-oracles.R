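# Independent oracles used to check the closed-form implementations.

# Damped fixed-point iteration for the Abeta/reelin/complex steady state:
#   A <- alpha / (beta + gamma R);  R <- tau / (rho + gamma A);  B <- gamma A R / delta
# Independent of the quadratic closed form.
oracle_steady_state <- function(params, alpha, damp = 0.5, tol = 1e-12,
                                max_iter = 200000) {
  A <- alpha / params$beta
  R <- params$tau / params$rho
  for (i in seq_len(max_iter)) {
    A_new <- alpha / (params$beta + params$gamma * R)
    R_new <- params$tau / (params$rho + params$gamma * A_new)
    A_next <- (1 - damp) * A + damp * A_new
    R_next <- (1 - damp) * R + damp * R_new
    if (abs(A_next - A) <= tol * max(A, 1) &&
        abs(R_next - R) <= tol * max(R, 1)) {
      A <- A_next; R <- R_next
      break
    }
    A <- A_next; R <- R_next
  }
  B <- params$gamma * A * R / params$delta
  P <- params$eta * R * params$g_tot / (params$kappa * params$g_tot + params$eta * R)
  c(a_beta = A, reelin = R, a_beta_reelin = B, gsk3b_p = P)
}

# Central-difference numerical Jacobian of model_rhs at a state.
oracle_jacobian <- function(params, state, alpha, h_rel = 1e-6) {
  s <- unclass(state)
  n <- length(s)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- h_rel * max(abs(s[j]), 1)
    up <- s; up[j] <- up[j] + h
    dn <- s; dn[j] <- dn[j] - h
    J[, j] <- (model_rhs(up, params, alpha) - model_rhs(dn, params, alpha)) / (2 * h)
  }
  dimnames(J) <- list(names(s), names(s))
  J
}

# Random valid parameter set on the scales of the study (seeded by caller).
random_params <- function() {
  model_parameters(
    alpha_baseline = stats::runif(1, 100, 50000),
    alpha_infection = stats::runif(1, 10000, 200000),
    beta = stats::runif(1, 0.01, 1),
    gamma = stats::runif(1, 1e-5, 0.05),
    tau = stats::runif(1, 1000, 200000),
    rho = stats::runif(1, 0.01, 1),
    delta = stats::runif(1, 0.005, 0.5),
    eta = stats::runif(1, 1, 50),
    kappa = stats::runif(1, 0.05, 5),
    g_tot = stats::runif(1, 1e4, 1e6)
  )
}

lr_params <- function() get_profile("LR")$params
replus_params <- function() get_profile("RePlus")$params

rel_diff <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.eps)
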