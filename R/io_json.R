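#' @title Native JSON model dialect
#' @description Canonical-ordered JSON serialization of a `gem` with an
#'   explicit schema version. Load -> save -> load is idempotent (identical
#'   JSON text), which makes model provenance exactly diffable.
#' @name io-json
NULL

OLEAGEM_SCHEMA <- "oleagem-model-1"

#' Write a model to native JSON
#'
#' @param model A `gem`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  validate_gem(model)
  doc <- list(
    schema = OLEAGEM_SCHEMA,
    id = model$id,
    objective = model$objective,
    compartments = as.list(model$compartments),
    genes = as.list(model$genes),
    metabolites = model$mets[order(model$mets$id), , drop = FALSE],
    reactions = model$rxns[order(model$rxns$id), , drop = FALSE],
    stoichiometry = model$stoich[order(model$stoich$rxn, model$stoich$met), ,
                                 drop = FALSE])
  jsonlite::write_json(doc, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a model from native JSON
#'
#' @param path File written by [write_model_json()].
#' @return A `gem`.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, OLEAGEM_SCHEMA)) {
    stop("not a ", OLEAGEM_SCHEMA, " file: ", path, call. = FALSE)
  }
  mets <- as.data.frame(doc$metabolites, stringsAsFactors = FALSE)
  if (!"formula" %in% names(mets)) mets$formula <- NA_character_
  mets$formula <- as.character(mets$formula)
  rxns <- as.data.frame(doc$reactions, stringsAsFactors = FALSE)
  rxns$gpr <- if ("gpr" %in% names(rxns)) as.character(rxns$gpr) else NA_character_
  rxns$subsystem <- if ("subsystem" %in% names(rxns))
    as.character(rxns$subsystem) else NA_character_
  new_gem(id = doc$id,
          compartments = unlist(doc$compartments),
          mets = mets, rxns = rxns,
          stoich = as.data.frame(doc$stoichiometry, stringsAsFactors = FALSE),
          genes = as.character(unlist(doc$genes)),
          objective = doc$objective)
}
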