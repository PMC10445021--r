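#' Read and write model configurations as JSON
#'
#' A model configuration bundles a [gating_scheme()] and a
#' [thermo_params()] into a single JSON document (energies in J/mol, rates
#' in 1/s, voltages in mV, temperatures in K).  The document is validated
#' on load: unknown dwell-law families, missing states or invalid
#' parameter values raise errors naming the offending key.
#'
#' @param scheme a [gating_scheme()].
#' @param thermo a [thermo_params()].
#' @param path file path for the JSON document.
#' @return `write_model_config` returns `path` invisibly;
#'   `read_model_config` returns `list(scheme =, thermo =)`.
#' @export
write_model_config <- function(scheme, thermo, path) {
  stopifnot(inherits(scheme, "gating_scheme"),
            inherits(thermo, "thermo_params"))
  doc <- list(
    scheme = list(
      topology = scheme$topology,
      dwell_laws = lapply(scheme$dwell_laws, function(l)
        c(list(family = l$family), l$params)),
      p_c2_open = scheme$p_c2_open
    ),
    thermo = unclass(thermo)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (key in c("scheme", "thermo"))
    if (is.null(doc[[key]]))
      stop("model config: missing required key '", key, "'", call. = FALSE)
  sc <- doc$scheme
  if (is.null(sc$topology))
    stop("model config: missing required key 'scheme.topology'",
         call. = FALSE)
  laws <- lapply(sc$dwell_laws, function(spec) {
    spec <- as.list(spec)
    fam <- spec$family
    if (is.null(fam))
      stop("model config: dwell law without 'family'", call. = FALSE)
    do.call(dwell_law, c(list(family = fam),
                         spec[setdiff(names(spec), "family")]))
  })
  scheme <- if (identical(sc$topology, "three_state_linear")) {
    gating_scheme("three_state_linear", laws,
                  p_c2_open = if (is.null(sc$p_c2_open)) 0.5
                              else sc$p_c2_open)
  } else {
    gating_scheme(sc$topology, laws)
  }
  th_fields <- names(formals(thermo_params))
  extra <- setdiff(names(doc$thermo), th_fields)
  if (length(extra))
    stop("model config: unknown thermo key(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  thermo <- do.call(thermo_params, doc$thermo[names(doc$thermo) %in%
                                                th_fields])
  list(scheme = scheme, thermo = thermo)
}
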