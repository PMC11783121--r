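#' Default workflow configuration
#'
#' Single structured configuration with four sections:
#' \describe{
#'   \item{model}{arguments of [pk_model()];}
#'   \item{alleles}{the allele-activity table (see
#'     [default_allele_table()]);}
#'   \item{thresholds}{`target_nM` (16), optional `upper_nM` (disabled),
#'     `margin` (0), `mw_endoxifen` (373.5 g/mol),
#'     `informative_cutoff_days` (22) and `steady_state_day` (84, the first
#'     day an observation counts as steady state);}
#'   \item{simulation}{defaults for [cohort_config()].}
#' }
#'
#' @return nested list of configuration values.
#' @export
default_config <- function() {
  list(
    model = list(
      tvc20 = 31.3, theta_as = 2.15,
      theta_age = -0.2, theta_bmi = -0.3, theta_height = 0,
      ref_age = 57, ref_bmi = 26.2, ref_height = 168, ref_as = 0.68,
      omega = 0.50, sigma = 0.20, t_half_acc = 14
    ),
    alleles = as.list(default_allele_table()),
    thresholds = list(
      target_nM = 16,
      upper_nM = NULL,
      margin = 0,
      mw_endoxifen = 373.5,
      informative_cutoff_days = 22,
      steady_state_day = 84
    ),
    simulation = list(
      preset = "control",
      nonadherent_fraction = 0,
      nonadherence_multiplier = 0.5,
      sample_days = c(35, 90),
      seed = 1
    )
  )
}

# recursive modifyList that treats NULL values in `new` as explicit
merge_config <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

#' Load a workflow configuration from a YAML file
#'
#' Values present in the file override the corresponding [default_config()]
#' entries; everything else keeps its default. An annotated copy of the
#' default configuration ships with the package
#' (`system.file("extdata", "default_config.yaml", package = "tamipd")`).
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return nested configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop_domain("config file not found: ", path)
  merge_config(cfg, yaml::read_yaml(path))
}

#' Build the PK model described by a configuration
#'
#' @param config configuration list from [load_config()].
#' @return a [pk_model()].
#' @export
model_from_config <- function(config = default_config()) {
  do.call(pk_model, config$model)
}

#' Allele table described by a configuration
#'
#' @param config configuration list from [load_config()].
#' @return named numeric allele-activity vector.
#' @export
alleles_from_config <- function(config = default_config()) {
  unlist(config$alleles)
}
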