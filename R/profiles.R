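.CANONICAL_PROFILES <- list(
  LR = list(alpha_baseline = 1560, alpha_infection = 44000, beta = 0.1,
            gamma = 0.005, tau = 14500, rho = 0.05, delta = 0.02,
            eta = 12, kappa = 0.65, g_tot = 50000),
  RePlus = list(alpha_baseline = 7020, alpha_infection = 109000, beta = 0.1,
                gamma = 0.005, tau = 79000, rho = 0.05, delta = 0.02,
                eta = 12, kappa = 0.65, g_tot = 250000)
)

new_neuron_profile <- function(name, params, geometry, provenance) {
  structure(list(name = name, params = params, geometry = geometry,
                 provenance = provenance),
            class = "neuron_profile")
}

#' Canonical neuron parameter profiles
#'
#' Two built-in configurations: `"LR"`, a cortical neuron with low
#' constitutive reelin, and `"RePlus"`, a reelin-rich layer II neuron of the
#' anteriolateral entorhinal cortex (4.5x the baseline Abeta42 production,
#' ~5.4x the reelin production, 5x the GSK3beta pool). Both use a 4850 um^3
#' soma.
#'
#' @param name `"LR"` or `"RePlus"`.
#' @return A `neuron_profile`: list with `name`, `params`
#'   ([model_parameters()]), `geometry` ([soma_geometry()]) and a
#'   `provenance` character vector describing how the profile was derived.
#' @examples
#' get_profile("LR")$params$alpha_baseline       # 1560
#' get_profile("RePlus")$params$g_tot            # 250000
#' @export
get_profile <- function(name = c("LR", "RePlus")) {
  name <- match.arg(name)
  p <- .CANONICAL_PROFILES[[name]]
  new_neuron_profile(
    name = name,
    params = do.call(model_parameters, p),
    geometry = soma_geometry(4850),
    provenance = sprintf("canonical %s parameter set", name)
  )
}

#' @export
print.neuron_profile <- function(x, ...) {
  cat(sprintf("neuron profile \"%s\" (soma %g um^3)\n", x$name,
              x$geometry$volume_um3))
  print(x$params)
  cat("provenance:\n")
  for (note in x$provenance) cat("  - ", note, "\n", sep = "")
  invisible(x)
}

modify_profile <- function(profile, changes, note) {
  stopifnot(inherits(profile, "neuron_profile"))
  p <- unclass(profile$params)
  p[names(changes)] <- changes
  new_neuron_profile(
    name = profile$name,
    params = do.call(model_parameters, p),
    geometry = profile$geometry,
    provenance = c(profile$provenance, note)
  )
}

#' Apply a genotype perturbation to a profile
#'
#' `"ApoE33"` is the reference genotype (identity transform). `"COLBOS"`,
#' a protective RELN variant, is modelled as a near-total loss of
#' Abeta42--reelin binding affinity (`gamma = 1e-7`). `"ApoE44"`, the
#' high-risk ApoE e4/e4 genotype, is modelled as accelerated removal of free
#' reelin from circulation via endosomal vesicle stalling (`rho = 0.2`).
#' All other parameters are untouched.
#'
#' @param profile A `neuron_profile`.
#' @param genotype `"ApoE33"`, `"COLBOS"` or `"ApoE44"`.
#' @return A new `neuron_profile` with an appended provenance note.
#' @examples
#' apply_genotype(get_profile("RePlus"), "COLBOS")$params$gamma  # 1e-7
#' @export
apply_genotype <- function(profile, genotype = c("ApoE33", "COLBOS", "ApoE44")) {
  genotype <- match.arg(genotype)
  switch(genotype,
    ApoE33 = modify_profile(profile, list(),
                            "ApoE33 reference genotype (no change)"),
    COLBOS = modify_profile(profile, list(gamma = 1e-7),
                            "COLBOS RELN variant: gamma = 1e-7"),
    ApoE44 = modify_profile(profile, list(rho = 0.2),
                            "ApoE e4/e4: rho = 0.2 (vesicle stalling)")
  )
}

#' Apply a transgenic fold change to baseline Abeta42 production
#'
#' Models an APP-overexpressing transgenic background purely as a fold change
#' of `alpha_baseline`; `alpha_infection` is untouched (it plays no role in
#' the steady-state fit). Folds outside the plausible transgenic range
#' `[2, 10]` are accepted with a warning.
#'
#' @param profile A `neuron_profile`.
#' @param fold Multiplier for `alpha_baseline`, > 0.
#' @return A new `neuron_profile`.
#' @examples
#' apply_transgene(get_profile("RePlus"), 2.57)$params$alpha_baseline  # 18041.4
#' @export
apply_transgene <- function(profile, fold) {
  if (!is.numeric(fold) || length(fold) != 1L || !is.finite(fold) || fold <= 0) {
    stop("fold must be a single positive number", call. = FALSE)
  }
  if (fold < 2 || fold > 10) {
    warning("transgene fold ", fold,
            " is outside the plausible range [2, 10]", call. = FALSE)
  }
  modify_profile(profile,
                 list(alpha_baseline = profile$params$alpha_baseline * fold),
                 sprintf("transgene: alpha_baseline x %g", fold))
}

#' Apply a reelin-knockdown fraction to the reelin production rate
#'
#' Models a miRNA knockdown of reelin as a fractional reduction of the
#' production (or import) rate `tau`.
#'
#' @param profile A `neuron_profile`.
#' @param tau_fraction Remaining fraction of `tau`, in (0, 1].
#' @return A new `neuron_profile`.
#' @examples
#' apply_knockdown(get_profile("RePlus"), 0.14)$params$tau  # 11060
#' @export
apply_knockdown <- function(profile, tau_fraction) {
  if (!is.numeric(tau_fraction) || length(tau_fraction) != 1L ||
      !is.finite(tau_fraction) || tau_fraction <= 0 || tau_fraction > 1) {
    stop("tau_fraction must lie in (0, 1]", call. = FALSE)
  }
  modify_profile(profile, list(tau = profile$params$tau * tau_fraction),
                 sprintf("knockdown: tau x %g", tau_fraction))
}
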