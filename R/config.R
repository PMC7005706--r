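# Run configuration: a single YAML file whose defaults carry the
# study's physical constants; every run echoes the fully merged
# configuration so results are self-describing.

#' Default run configuration
#'
#' All physics constants live here with the study's values as defaults:
#' 12 A nonbonded cutoff, 10 kcal/mol/A^2 equilibration spring,
#' 300 K production and 500 K perturbation temperatures, 0.5 fs
#' production and 2 fs perturbation timesteps, 6 slab layers at the Au
#' lattice constant 4.08 A.
#'
#' @return Nested list of settings.
#' @export
default_run_config <- function() {
  list(
    sequence = "Ac-SSFPQPN-NH2",
    slab = list(element = "Au", a = 4.08, miller = c(1, 1, 1),
                n_layers = 6, repeats = c(13, 13)),
    forcefield = list(cutoff = 12, switch_on = 10),
    search = list(n_starts = 1000, iterations = 200,
                  perturb = list(temperature = 500, n_steps = 300,
                                 timestep_fs = 2),
                  beta = 5, height_range = c(3, 8)),
    md = list(timestep_fs = 0.5, temperature = 300,
              thermostat = "nose_hoover", spring_k = 10,
              restrained_fs = 1000, production_fs = 5000, stride = 20),
    water = list(count = 2350),
    analysis = analysis_thresholds(),
    seed = 1,
    output_dir = "pepsurf-out"
  )
}

#' Read a YAML run configuration
#'
#' Values from the file override the defaults of
#' [default_run_config()]; the merged configuration (every default
#' echoed) is returned and should be written alongside any output.
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @return Merged configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

#' @keywords internal
.write_config_echo <- function(cfg, dir) {
  yaml::write_yaml(cfg, file.path(dir, "config-echo.yaml"))
}
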