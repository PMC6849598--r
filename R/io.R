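# Model exchange format.
#
# A model file is JSON or YAML with three top-level keys:
#   species: [ {id, name, intrinsic_rate, self_limitation, role}, ... ]
#   links:   [ {resource_id, consumer_id, fr_form, attack_rate,
#               handling_time, interference, conversion_efficiency}, ... ]
#   tims:    [ {tim_id, modifier_id, target: {resource_id, consumer_id},
#               affected_parameter, form, strength, form_params,
#               mode, forced_density}, ... ]
# Round-trips (read -> write -> read) are lossless: numbers are written at
# full double precision.

model_to_list <- function(model) {
  list(
    species = lapply(model$species, function(sp)
      list(id = sp$id, name = sp$name, intrinsic_rate = sp$intrinsic_rate,
           self_limitation = sp$self_limitation, role = sp$role)),
    links = lapply(model$links, function(ln)
      list(resource_id = ln$resource, consumer_id = ln$consumer,
           fr_form = ln$fr_form, attack_rate = ln$attack_rate,
           handling_time = ln$handling_time, interference = ln$interference,
           conversion_efficiency = ln$conversion_efficiency)),
    tims = lapply(model$tims, function(tm)
      list(tim_id = tm$tim_id, modifier_id = tm$modifier,
           target = list(resource_id = tm$resource,
                         consumer_id = tm$consumer),
           affected_parameter = tm$affected_parameter, form = tm$form,
           strength = tm$strength, form_params = tm$form_params,
           mode = tm$mode, forced_density = tm$forced_density)))
}

model_from_list <- function(x) {
  need <- function(rec, f, where) {
    if (is.null(rec[[f]])) stop("model file: missing field '", f, "' in ",
                                where)
    rec[[f]]
  }
  species <- lapply(x$species, function(sp)
    species_spec(need(sp, "id", "species"),
                 need(sp, "intrinsic_rate", "species"),
                 if (is.null(sp$self_limitation)) 0 else sp$self_limitation,
                 need(sp, "role", "species"),
                 if (is.null(sp$name)) sp$id else sp$name))
  links <- lapply(x$links, function(ln)
    trophic_link(need(ln, "resource_id", "links"),
                 need(ln, "consumer_id", "links"),
                 need(ln, "fr_form", "links"),
                 need(ln, "attack_rate", "links"),
                 if (is.null(ln$handling_time)) 0 else ln$handling_time,
                 if (is.null(ln$interference)) 0 else ln$interference,
                 need(ln, "conversion_efficiency", "links")))
  tims <- lapply(x$tims, function(tm) {
    fp <- tm$form_params
    if (is.null(fp) || length(fp) == 0L) fp <- list()
    fp <- lapply(fp, as.numeric)
    tim_spec(need(tm, "tim_id", "tims"),
             if (is.null(tm$modifier_id)) NA_character_ else tm$modifier_id,
             need(tm$target, "resource_id", "tims$target"),
             need(tm$target, "consumer_id", "tims$target"),
             if (is.null(tm$affected_parameter)) "attack_rate"
             else tm$affected_parameter,
             need(tm, "form", "tims"),
             need(tm, "strength", "tims"),
             fp,
             if (is.null(tm$mode)) "dynamic" else tm$mode,
             tm$forced_density)
  })
  community_model(species, links, if (is.null(tims)) list() else tims)
}

model_to_json <- function(model) {
  # digits = I(17): significant digits for exact double round-trips
  as.character(jsonlite::toJSON(model_to_list(model), auto_unbox = TRUE,
                                digits = I(17), null = "null"))
}

#' Write a community model to a JSON or YAML file
#'
#' @param model A \code{community_model}.
#' @param path Output path; format chosen from the extension
#'   (\code{.yaml}/\code{.yml} for YAML, anything else JSON).
#' @export
write_model <- function(model, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    writeLines(yaml::as.yaml(model_to_list(model), precision = 17), path)
  } else {
    writeLines(model_to_json(model), path)
  }
  invisible(path)
}

#' Read and validate a community model from file
#'
#' Parses the documented JSON/YAML schema and validates the result; all
#' invariant violations are reported together.
#'
#' @param path Path to a model file.
#' @return A \code{community_model}.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = FALSE)
  model_from_list(x)
}
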