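#' Label schemas for body-composition compartments
#'
#' A label schema names the integer compartment ids of one body region and the
#' merge rules that define derived compartments. The abdominal schema has seven
#' foreground labels (vertebral bone VB, psoas muscle PM, core muscle CM,
#' superficial and deep subcutaneous adipose tissue sSAT/dSAT, intraperitoneal
#' and retroperitoneal adipose tissue IPAT/RPAT) with derived SAT = sSAT + dSAT
#' and VAT = IPAT + RPAT. The thigh schema has four labels (femur, vessel, SAT,
#' muscle). Label 0 is always background.
#'
#' Schemas are shipped as versioned JSON in `inst/extdata/label_schemas.json`.
#'
#' @param region `"abdomen"` or `"thigh"`.
#' @return An object of class `label_schema`: a list with `region`,
#'   `label_ids` (named integer vector, name -> id), `merge_rules`
#'   (named list, derived name -> character vector of member label names),
#'   and `version`.
#' @examples
#' sch <- label_schema("abdomen")
#' sch$label_ids[["CM"]]
#' sch$merge_rules$SAT
#' @export
label_schema <- function(region = c("abdomen", "thigh")) {
  region <- match.arg(region)
  path <- system.file("extdata", "label_schemas.json", package = "bodycomp")
  all <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- all$schemas[[region]]
  ids <- unlist(raw$label_ids)
  storage.mode(ids) <- "integer"
  merge <- raw$merge_rules
  if (is.null(merge)) merge <- list()
  stopifnot(all(ids > 0L), !anyDuplicated(ids))
  for (m in merge) stopifnot(all(m %in% names(ids)))
  structure(
    list(region = region, label_ids = ids, merge_rules = merge,
         version = all$version),
    class = "label_schema"
  )
}

#' @export
print.label_schema <- function(x, ...) {
  cat("Label schema:", x$region, "(v", x$version, ")\n", sep = "")
  cat("  labels: ", paste0(names(x$label_ids), "=", x$label_ids,
                           collapse = ", "), "\n")
  for (m in names(x$merge_rules))
    cat("  derived ", m, " = ", paste(x$merge_rules[[m]], collapse = " + "),
        "\n", sep = "")
  invisible(x)
}

#' Resolve a compartment name to its set of label ids
#'
#' Raw label names map to a single id; derived names (e.g. `"SAT"` in the
#' abdomen) map to the union of their members' ids per the schema merge rules.
#'
#' @param schema a [label_schema()].
#' @param compartment a compartment name, or directly an integer id vector
#'   (passed through).
#' @return Integer vector of label ids.
#' @export
compartment_ids <- function(schema, compartment) {
  if (is.numeric(compartment)) return(as.integer(compartment))
  stopifnot(inherits(schema, "label_schema"), is.character(compartment),
            length(compartment) == 1L)
  if (compartment %in% names(schema$label_ids))
    return(unname(schema$label_ids[compartment]))
  if (compartment %in% names(schema$merge_rules))
    return(unname(schema$label_ids[schema$merge_rules[[compartment]]]))
  stop("unknown compartment '", compartment, "' for region ", schema$region)
}

# all reportable compartments: raw labels then derived merges
all_compartments <- function(schema) {
  c(names(schema$label_ids), names(schema$merge_rules))
}
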