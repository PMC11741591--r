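#' Write a trajectory to CSV
#'
#' Columns: `time_h, a_beta, reelin, a_beta_reelin, gsk3b_p, alpha, phase`;
#' header row, '.' decimal separator.
#'
#' @param traj A trajectory from [simulate_trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  utils::write.csv(as.data.frame(traj)[, c("time_h", state_names(),
                                           "alpha", "phase")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

steady_state_record <- function(ss, geometry) {
  nM <- function(m) molecules_to_molar(m, geometry) * 1e9
  list(
    alpha_molecules_per_h = ss$alpha,
    a_beta_molecules = ss$a_beta, a_beta_nM = nM(ss$a_beta),
    reelin_molecules = ss$reelin, reelin_nM = nM(ss$reelin),
    a_beta_reelin_molecules = ss$a_beta_reelin,
    a_beta_reelin_nM = nM(ss$a_beta_reelin),
    gsk3b_p_molecules = ss$gsk3b_p
  )
}

#' Read/write model parameters as JSON or YAML
#'
#' Parameter sets are serialized flat, with the exact field names of
#' [model_parameters()]. The format is chosen from the file extension
#' (`.json`, `.yaml`/`.yml`).
#'
#' @param params A [model_parameters()] object.
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `write_parameters()` returns `path` invisibly;
#'   `read_parameters()` returns a [model_parameters()] object.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_parameters(get_profile("LR")$params, f)
#' read_parameters(f)
#' @export
write_parameters <- function(params, path) {
  validate_model_parameters(params)
  fields <- unclass(params)
  switch(file_format(path),
         json = jsonlite::write_json(fields, path, auto_unbox = TRUE,
                                     digits = NA),
         yaml = yaml::write_yaml(fields, path))
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  fields <- switch(file_format(path),
                   json = jsonlite::read_json(path, simplifyVector = TRUE),
                   yaml = yaml::read_yaml(path))
  expected <- names(formals(model_parameters))
  missing <- setdiff(expected, names(fields))
  if (length(missing)) {
    stop("parameter file ", path, " is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  do.call(model_parameters, lapply(fields[expected], as.numeric))
}

file_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = "json", yaml = "yaml", yml = "yaml",
         stop("unsupported file format '.", ext,
              "' (use .json, .yaml or .yml)", call. = FALSE))
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

provenance_block <- function(config) {
  list(
    package = "reelinsink",
    version = as.character(utils::packageVersion("reelinsink")),
    config = config,
    config_hash = config_hash(config),
    seed = config$seed
  )
}

resolve_profile <- function(config) {
  name <- config$profile %||% "LR"
  profile <- if (name %in% c("LR", "RePlus")) {
    get_profile(name)
  } else {
    new_neuron_profile(name = basename(name),
                       params = read_parameters(name),
                       geometry = soma_geometry(config$volume_um3 %||% 4850),
                       provenance = paste("read from", name))
  }
  if (!is.null(config$genotype)) {
    profile <- apply_genotype(profile, config$genotype)
  }
  profile
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_result_json <- function(result, config, path) {
  out <- c(result, list(provenance = provenance_block(config)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Run one pipeline stage from a configuration list
#'
#' Config-driven front end over the package: dispatches on
#' `config$subcommand` and writes provenance-stamped artifacts (CSV for
#' trajectories and synthetic cells, JSON for summaries and fits; every JSON
#' artifact embeds the package version, the full config, its hash, and the
#' seed). Numeric JSON keys carry unit suffixes (`_molecules`, `_nM`, `_h`)
#' to avoid ambiguity.
#'
#' Subcommands and their main config fields:
#' \describe{
#'   \item{`steady-state`}{`profile`, optional `genotype`, optional `alpha`;
#'     writes the four steady-state values with nM equivalents to `out`.}
#'   \item{`stability`}{as above; writes eigenvalues and classification.}
#'   \item{`simulate`}{`profile`, `genotype`, `t_start`, `t_end`, `horizon`;
#'     writes the trajectory CSV to `out` and a response summary to
#'     `summary` (if given).}
#'   \item{`fit`}{grid fields (`fold_min`, ..., `frac_step`), `obs_reelin`,
#'     `obs_abeta`, optional `tau_scale` and `dump_grid`; writes the fit
#'     JSON to `out`.}
#'   \item{`synth`}{`fold`, `fraction`, `seed` and [population_spec()]
#'     fields; writes the per-cell CSV to `out`.}
#'   \item{`recover`}{as `synth` plus grid fields; writes the recovery
#'     report to `out`.}
#' }
#'
#' @param config Named list (typically parsed from a YAML/JSON config file).
#' @return The computed result object, invisibly; artifacts are written as a
#'   side effect.
#' @export
run_pipeline <- function(config) {
  sub <- config$subcommand
  if (is.null(sub)) stop("config$subcommand is required", call. = FALSE)
  out <- config$out %||% stop("config$out is required", call. = FALSE)

  grid_from_config <- function() {
    grid_spec(fold_min = config$fold_min %||% 2,
              fold_max = config$fold_max %||% 10,
              fold_step = config$fold_step %||% 0.005,
              frac_min = config$frac_min %||% 0.05,
              frac_max = config$frac_max %||% 1.0,
              frac_step = config$frac_step %||% 0.005)
  }
  spec_from_config <- function() {
    population_spec(n_control = config$n_control %||% 585,
                    n_experimental = config$n_experimental %||% 820,
                    gain = config$gain %||% 1e-5,
                    sigma = config$sigma %||% 0.6,
                    background_mean = config$background_mean %||% 1,
                    background_sd = config$background_sd %||% 0.52,
                    seed = config$seed %||% 1L)
  }

  result <- switch(
    sub,
    "steady-state" = {
      profile <- resolve_profile(config)
      ss <- steady_state(profile$params,
                         config$alpha %||% profile$params$alpha_baseline)
      rec <- list(profile = profile$name,
                  steady_state = steady_state_record(ss, profile$geometry))
      write_result_json(rec, config, out)
      rec
    },
    "stability" = {
      profile <- resolve_profile(config)
      ss <- steady_state(profile$params,
                         config$alpha %||% profile$params$alpha_baseline)
      st <- assess_stability(profile$params, ss)
      rec <- list(profile = profile$name,
                  eigenvalues_re = Re(st$eigenvalues),
                  eigenvalues_im = Im(st$eigenvalues),
                  classification = st$classification, stable = st$stable)
      write_result_json(rec, config, out)
      rec
    },
    "simulate" = {
      profile <- resolve_profile(config)
      protocol <- infection_protocol(
        alpha_low = config$alpha_low %||% profile$params$alpha_baseline,
        alpha_high = config$alpha_high %||% profile$params$alpha_infection,
        t_start = config$t_start %||% 50,
        t_end = config$t_end %||% 170,
        horizon = config$horizon %||% 400)
      res <- run_immune_response(profile, protocol)
      write_trajectory_csv(res$trajectory, out)
      if (!is.null(config$summary)) {
        s <- res$summary
        rec <- list(
          profile = s$profile,
          protocol_h = list(t_start = protocol$t_start,
                            t_end = protocol$t_end,
                            horizon = protocol$horizon),
          baseline = steady_state_record(s$baseline, profile$geometry),
          min_reelin_molecules = s$min_reelin_molecules,
          min_reelin_nM = s$min_reelin_nM,
          max_a_beta_molecules = s$max_a_beta_molecules,
          max_a_beta_nM = s$max_a_beta_nM,
          min_gsk3b_p_fraction = s$min_gsk3b_p_fraction,
          complex_at_end_of_infection_molecules = s$complex_at_end_of_infection)
        write_result_json(rec, config, config$summary)
      }
      res
    },
    "fit" = {
      profile <- resolve_profile(list(profile = config$profile %||% "RePlus"))
      obs <- ratio_observation(
        reelin_ratio = config$obs_reelin %||% 0.26,
        abeta_ratio = config$obs_abeta %||% 0.69)
      fit <- if (!is.null(config$tau_scale) && config$tau_scale != 1) {
        sensitivity_rerun(profile, config$tau_scale, grid = grid_from_config(),
                          obs = obs, dump_grid = config$dump_grid)
      } else {
        grid_search(profile, grid = grid_from_config(), obs = obs,
                    dump_grid = config$dump_grid)
      }
      rec <- list(best_fold = fit$best_fold, best_fraction = fit$best_fraction,
                  achieved_reelin_ratio = fit$achieved_reelin_ratio,
                  achieved_abeta_ratio = fit$achieved_abeta_ratio,
                  objective = fit$objective, n_records = fit$n_records)
      write_result_json(rec, config, out)
      fit
    },
    "synth" = {
      profile <- resolve_profile(list(profile = config$profile %||% "RePlus"))
      ctrl <- suppressWarnings(apply_transgene(profile, config$fold %||% 2.57))
      expt <- apply_knockdown(ctrl, config$fraction %||% 0.14)
      cells <- generate_population(spec_from_config(),
                                   steady_state_totals(ctrl$params),
                                   steady_state_totals(expt$params))
      utils::write.csv(cells, out, row.names = FALSE, quote = FALSE)
      cells
    },
    "recover" = {
      profile <- resolve_profile(list(profile = config$profile %||% "RePlus"))
      rec <- recover_parameters(spec_from_config(),
                                true_fold = config$fold %||% 2.57,
                                true_fraction = config$fraction %||% 0.14,
                                grid = grid_from_config(), base = profile)
      write_result_json(
        list(true_fold = rec$true[["fold"]],
             true_fraction = rec$true[["fraction"]],
             observed_reelin_ratio = rec$observed[["reelin_ratio"]],
             observed_abeta_ratio = rec$observed[["abeta_ratio"]],
             best_fold = rec$fit$best_fold,
             best_fraction = rec$fit$best_fraction,
             error_fold = rec$error[["fold"]],
             error_fraction = rec$error[["fraction"]]),
        config, out)
      rec
    },
    stop("unknown subcommand: ", sub, call. = FALSE)
  )
  invisible(result)
}
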