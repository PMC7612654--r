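# Scenario files: a YAML or JSON document describing the design parameters,
# the endpoint, and optional composite / simulation settings. Unknown keys
# are rejected so typos cannot silently change a design.

scenario_schema <- list(
  top = c("design", "endpoint", "composite", "simulation"),
  design = c("alpha", "target_power", "adjustment"),
  endpoint = c("outcomes", "corr", "rho", "alloc_ratio"),
  outcome = c("name", "kind", "effect", "sd", "prob_T", "prob_C",
              "n_levels", "thresholds", "response_level", "responder_cut"),
  composite = c("eta", "at_least", "fit", "delta_star", "sigma2"),
  simulation = c("n_per_group", "reps", "seed", "endpoint", "surface")
)

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    lp_abort(paste0("unknown key(s) in ", where, ": ",
                    paste(extra, collapse = ", ")),
             class = "lp_error_config")
  }
  invisible(x)
}

#' Read and write scenario files
#'
#' A scenario file (YAML or JSON, chosen by file extension) bundles
#' `design` ([design_params()] fields), `endpoint` (outcome list plus a
#' full `corr` matrix or `rho` equicorrelation shorthand and
#' `alloc_ratio`), and optional `composite` (`eta`, `at_least`,
#' `delta_star`, `sigma2`) and `simulation` (`n_per_group`, `reps`, `seed`,
#' `endpoint`, `surface`) blocks. Unknown keys raise an error. Writing a
#' loaded scenario and reading it back reproduces the identical objects.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param scenario A list with elements `design`, `endpoint` and optionally
#'   `composite`, `simulation` (as returned by `read_scenario()`).
#' @return `read_scenario()`: a list with `design` (a [design_params()]),
#'   `endpoint` (a [mixed_endpoint()]), `composite`, `simulation`.
#' @export
read_scenario <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  check_keys(raw, scenario_schema$top, "scenario")
  if (is.null(raw$endpoint)) {
    lp_abort("scenario needs an `endpoint` block", class = "lp_error_config")
  }
  check_keys(raw$design %||% list(), scenario_schema$design, "design")
  design <- do.call(design_params, raw$design %||% list())

  ep <- raw$endpoint
  check_keys(ep, scenario_schema$endpoint, "endpoint")
  if (is.null(ep$outcomes) || !length(ep$outcomes)) {
    lp_abort("endpoint needs a non-empty `outcomes` list",
             class = "lp_error_config")
  }
  rows <- purrr::map_dfr(ep$outcomes, parse_outcome_entry)
  corr <- NULL
  if (!is.null(ep$corr)) {
    corr <- ep$corr
    if (is.list(corr) && !is.null(corr$rho)) {
      corr <- NULL
      ep$rho <- ep$corr$rho
    } else if (is.list(corr)) {
      corr <- do.call(rbind, lapply(corr, as.numeric))
    }
  }
  endpoint <- mixed_endpoint(rows, corr = corr, rho = ep$rho,
                             alloc_ratio = ep$alloc_ratio %||% 1)

  composite <- raw$composite
  if (!is.null(composite)) {
    check_keys(composite, scenario_schema$composite, "composite")
    if (!is.null(composite$eta)) composite$eta <- as.numeric(composite$eta)
  }
  simulation <- raw$simulation
  if (!is.null(simulation)) {
    check_keys(simulation, scenario_schema$simulation, "simulation")
  }
  list(design = design, endpoint = endpoint, composite = composite,
       simulation = simulation)
}

parse_outcome_entry <- function(o) {
  check_keys(o, scenario_schema$outcome, paste0("outcome '", o$name %||% "?", "'"))
  kind <- o$kind %||% lp_abort("each outcome needs a `kind`",
                               class = "lp_error_config")
  switch(
    kind,
    continuous = outcome_continuous(o$name, effect = o$effect, sd = o$sd,
                                    responder_cut = o$responder_cut %||% NA_real_),
    ordinal = outcome_ordinal(o$name, n_levels = o$n_levels,
                              prob_T = o$prob_T, prob_C = o$prob_C,
                              effect = o$effect,
                              thresholds = if (!is.null(o$thresholds)) {
                                as.numeric(o$thresholds)
                              },
                              response_level = o$response_level,
                              responder_cut = o$responder_cut %||% NA_real_),
    binary = outcome_binary(o$name, prob_T = o$prob_T, prob_C = o$prob_C,
                            effect = o$effect,
                            responder_cut = o$responder_cut %||% NA_real_),
    lp_abort(paste0("unknown outcome kind '", kind, "'"),
             class = "lp_error_config")
  )
}

#' @rdname read_scenario
#' @export
write_scenario <- function(scenario, path) {
  ep <- scenario$endpoint
  validate_mixed_endpoint(ep)
  outcomes <- lapply(seq_len(ep$K), function(i) {
    row <- ep$outcomes[i, ]
    o <- list(name = row$name, kind = row$kind)
    if (row$kind == "continuous") {
      o$effect <- row$effect_obs
      o$sd <- row$sd
    } else {
      if (!is.na(row$prob_T)) o$prob_T <- row$prob_T
      if (!is.na(row$prob_C)) o$prob_C <- row$prob_C
      if (!is.na(row$effect_latent)) o$effect <- row$effect_latent
      if (row$kind == "ordinal") {
        o$n_levels <- row$n_levels
        o$thresholds <- row$thresholds[[1]]
        o$response_level <- row$response_level
      }
    }
    if (!is.na(row$responder_cut)) o$responder_cut <- row$responder_cut
    o
  })
  doc <- list(
    design = unclass(scenario$design),
    endpoint = list(
      outcomes = outcomes,
      corr = lapply(seq_len(nrow(ep$corr)), function(i) ep$corr[i, ]),
      alloc_ratio = ep$alloc_ratio
    )
  )
  if (!is.null(scenario$composite)) doc$composite <- scenario$composite
  if (!is.null(scenario$simulation)) doc$simulation <- scenario$simulation
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path, handlers = yaml_num_handlers)
  }
  invisible(path)
}

# shortest decimal representation that round-trips the double exactly, so
# that load -> dump -> load is the identity
fmt_double <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(as.character(v))
    s <- as.character(v)
    for (d in 1:17) {
      s <- trimws(formatC(v, digits = d, format = "g"))
      if (as.numeric(s) == v) break
    }
    s
  }, character(1))
}

yaml_num_handlers <- list(
  numeric = function(x) structure(fmt_double(x), class = "verbatim")
)
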