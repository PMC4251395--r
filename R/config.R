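#' Read a simulation run configuration from YAML
#'
#' A run config bundles everything needed to reproduce a simulation: the
#' population specification (descriptor distributions, size, seed), the
#' logistic disease model, and one or more therapy blocks (PK-PD
#' parameters, dosing interval, follow-up, harm). See
#' `system.file("extdata", "default_config.yaml", package = "effectmodel")`
#' for a complete annotated example.
#'
#' @param path Path to a YAML file.
#' @return A list of class `"run_config"` with components `population`
#'   (a `population_spec`), `disease` (`disease_params`), `therapies`
#'   (list of `therapy_config`) and `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_user("config file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_user("cannot parse YAML: ",
                                                conditionMessage(e)))
  as_run_config(raw)
}

#' @rdname read_run_config
#' @param raw A list with the same structure as the YAML document.
#' @export
as_run_config <- function(raw) {
  if (is.null(raw$population)) stop_user("config is missing: population")
  if (is.null(raw$disease)) stop_user("config is missing: disease")
  if (is.null(raw$therapies) || length(raw$therapies) == 0L) {
    stop_user("config is missing: therapies")
  }
  seed <- raw$seed %||% raw$population$seed %||% 1L
  descs <- lapply(raw$population$descriptors, function(d) {
    descriptor_spec(name = d$name,
                    distribution = d$distribution %||% "normal",
                    location = d$location %||% 0,
                    scale = d$scale %||% 1,
                    bounds = if (!is.null(d$bounds)) unlist(d$bounds))
  })
  pop <- population_spec(descs,
                         size = raw$population$size %||% 200,
                         seed = raw$population$seed %||% seed)
  dis <- do.call(disease_params, raw$disease)
  therapies <- lapply(raw$therapies, function(th) {
    therapy_config(label = th$label %||% "drug",
                   pkpd = do.call(pkpd_params, th$pkpd %||% list()),
                   dosing_interval = th$dosing_interval %||% 24,
                   followup = th$followup %||% 1,
                   harm = th$harm %||% 0)
  })
  labels <- vapply(therapies, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop_user("therapy labels must be unique")
  structure(list(population = pop, disease = dis, therapies = therapies,
                 seed = seed),
            class = "run_config")
}
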