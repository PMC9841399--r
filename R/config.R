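# Field configuration: which INFO fields to extract and how to store them.

#' Construct a field configuration
#'
#' @param field INFO key in the source VCF.
#' @param alias Output INFO key (defaults to `field`).
#' @param multiplier Positive integer used to quantize float fields
#'   (`stored = round(value * multiplier)`); meaningful only for floats.
#' @param missing_value Integer stored when the source INFO is absent.
#' @param missing_string String returned for absent string fields.
#' @param ftype One of `"integer"`, `"float"`, `"string"`, or `NA` when it
#'   is still to be inferred from the source VCF header.
#' @return A `field_config` list.
#' @export
field_config <- function(field, alias = field, multiplier = 1,
                         missing_value = -1, missing_string = ".",
                         ftype = NA_character_) {
  if (!is.character(field) || length(field) != 1 || !nzchar(field)) {
    stop("config error: 'field' must be a non-empty string", call. = FALSE)
  }
  if (grepl("[;=[:space:]]", alias)) {
    stop(sprintf("config error: alias '%s' is not a valid INFO key", alias), call. = FALSE)
  }
  if (length(multiplier) != 1 || is.na(multiplier) || multiplier != round(multiplier) ||
      multiplier < 1) {
    stop(sprintf("config error: multiplier for '%s' must be a positive integer", field),
         call. = FALSE)
  }
  if (length(missing_value) != 1 || is.na(missing_value) ||
      missing_value != round(missing_value)) {
    stop(sprintf("config error: missing_value for '%s' must be an integer", field),
         call. = FALSE)
  }
  structure(list(field = field, alias = alias, multiplier = as.double(multiplier),
                 missing_value = as.double(missing_value),
                 missing_string = missing_string, ftype = ftype),
            class = "field_config")
}

#' Parse a JSON field configuration
#'
#' The configuration is a JSON array of objects, each with at least
#' `"field"`; `"alias"` defaults to the field name, `"multiplier"` to 1,
#' `"missing_value"` to -1 and `"missing_string"` to ".".
#'
#' @param json_text JSON text, or a path to a JSON file.
#' @return List of `field_config`.
#' @export
#' @examples
#' parse_config('[{"field": "AF", "alias": "gnomad_af", "multiplier": 1000000}]')
parse_config <- function(json_text) {
  if (length(json_text) == 1 && !grepl("[[{]", json_text) && file.exists(json_text)) {
    json_text <- paste(readLines(json_text, warn = FALSE), collapse = "\n")
  }
  parsed <- tryCatch(jsonlite::fromJSON(json_text, simplifyVector = FALSE),
                     error = function(e) stop(sprintf("config error: invalid JSON (%s)",
                                                      conditionMessage(e)), call. = FALSE))
  if (!is.list(parsed)) {
    stop("config error: expected a JSON array of field objects", call. = FALSE)
  }
  configs <- lapply(parsed, function(o) {
    if (is.null(o$field)) stop("config error: every entry needs a \"field\" key", call. = FALSE)
    do.call(field_config, o[intersect(names(o),
      c("field", "alias", "multiplier", "missing_value", "missing_string", "ftype"))])
  })
  aliases <- vapply(configs, `[[`, "", "alias")
  if (anyDuplicated(aliases)) {
    stop(sprintf("config error: duplicate alias '%s'", aliases[duplicated(aliases)][1]),
         call. = FALSE)
  }
  configs
}

#' @noRd
config_to_json <- function(configs) {
  jsonlite::toJSON(lapply(configs, function(cf) {
    list(field = cf$field, alias = cf$alias, multiplier = cf$multiplier,
         missing_value = cf$missing_value, missing_string = cf$missing_string,
         ftype = cf$ftype)
  }), auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Normalize a chromosome name by stripping any leading "chr"
#' @param chrom Character vector.
#' @return Character vector without the (case-insensitive) "chr" prefix.
#' @export
norm_chrom <- function(chrom) {
  sub("^chr", "", chrom, ignore.case = TRUE)
}
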