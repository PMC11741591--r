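#' Rate and pool constants of the Abeta42--reelin--GSK3beta model
#'
#' Bundles the ten constants of the four-variable kinetic model: production,
#' removal and binding rates for free Abeta42 and free reelin, removal of the
#' Abeta--reelin complex, and the phosphorylation/dephosphorylation cycle of
#' the GSK3beta pool.
#'
#' @param alpha_baseline Abeta42 production rate at baseline, molecules/h.
#' @param alpha_infection Abeta42 production rate during infection, molecules/h.
#' @param beta First-order removal rate of free Abeta42, 1/h.
#' @param gamma Second-order Abeta42--reelin binding rate, 1/(molecules h).
#' @param tau Constitutive reelin production (or import) rate, molecules/h.
#' @param rho First-order removal rate of free reelin, 1/h.
#' @param delta First-order removal rate of the Abeta--reelin complex, 1/h.
#' @param eta GSK3beta phosphorylation rate coefficient, 1/h.
#' @param kappa GSK3beta dephosphorylation rate, 1/h.
#' @param g_tot Total GSK3beta pool, molecules.
#'
#' @return An object of class `model_parameters` (a validated named list).
#' @examples
#' p <- model_parameters(
#'   alpha_baseline = 1560, alpha_infection = 44000, beta = 0.1,
#'   gamma = 0.005, tau = 14500, rho = 0.05, delta = 0.02,
#'   eta = 12, kappa = 0.65, g_tot = 50000
#' )
#' @export
model_parameters <- function(alpha_baseline, alpha_infection, beta, gamma,
                             tau, rho, delta, eta, kappa, g_tot) {
  p <- list(
    alpha_baseline = alpha_baseline, alpha_infection = alpha_infection,
    beta = beta, gamma = gamma, tau = tau, rho = rho, delta = delta,
    eta = eta, kappa = kappa, g_tot = g_tot
  )
  validate_model_parameters(p)
  structure(p, class = "model_parameters")
}

validate_model_parameters <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("non-finite or non-scalar model parameter(s): ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  if (any(unlist(p) < 0)) {
    stop("model parameters must be non-negative", call. = FALSE)
  }
  strictly_pos <- c("beta", "rho", "delta", "kappa", "g_tot")
  bad <- strictly_pos[vapply(strictly_pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad)) {
    stop("parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(p)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Abeta42-reelin-GSK3beta model parameters\n")
  v <- unlist(x)
  units <- c(alpha_baseline = "molecules/h", alpha_infection = "molecules/h",
             beta = "1/h", gamma = "1/(molecules h)", tau = "molecules/h",
             rho = "1/h", delta = "1/h", eta = "1/h", kappa = "1/h",
             g_tot = "molecules")
  for (nm in names(v)) {
    cat(sprintf("  %-16s %12g  %s\n", nm, v[[nm]], units[[nm]]))
  }
  invisible(x)
}

#' State vector of the kinetic model
#'
#' The four state variables, as continuous molecule counts: free Abeta42,
#' free reelin, the Abeta--reelin complex, and phosphorylated (inhibited)
#' GSK3beta.
#'
#' @param a_beta Free Abeta42, molecules.
#' @param reelin Free reelin, molecules.
#' @param a_beta_reelin Bound Abeta--reelin complex, molecules.
#' @param gsk3b_p Phosphorylated GSK3beta, molecules.
#'
#' @return A named numeric vector of class `system_state`.
#' @examples
#' system_state(0, 14500 / 0.05, 0, 0)
#' @export
system_state <- function(a_beta, reelin, a_beta_reelin, gsk3b_p) {
  s <- c(a_beta = a_beta, reelin = reelin,
         a_beta_reelin = a_beta_reelin, gsk3b_p = gsk3b_p)
  if (!is.numeric(s) || length(s) != 4L || !all(is.finite(s))) {
    stop("state components must be finite numeric scalars", call. = FALSE)
  }
  if (any(s < 0)) {
    stop("state components must be non-negative", call. = FALSE)
  }
  structure(s, class = c("system_state", "numeric"))
}

state_names <- function() c("a_beta", "reelin", "a_beta_reelin", "gsk3b_p")

as_state_vector <- function(state) {
  s <- unclass(state)[state_names()]
  if (anyNA(s) || !all(is.finite(s))) {
    stop("state must contain finite components named ",
         paste(state_names(), collapse = ", "), call. = FALSE)
  }
  s
}
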