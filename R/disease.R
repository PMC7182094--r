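#' Declarative disease ascertainment rules
#'
#' A `disease_definition` states how a disease is ascertained from register
#' events: inclusion code prefixes per code system, exclusion code prefixes
#' (codes indicating a non-autoimmune etiology), an optional drug requirement
#' (a minimum number of dispensations of an ATC class for persons alive after
#' a given date), and the minimum number of inclusion events.
#'
#' Matching is by string prefix within a code system, mirroring ICD
#' hierarchies: `"E063"` matches `E063`, `E063A`, ... Inclusion and exclusion
#' prefixes must be disjoint within a system.
#'
#' @param name Disease name.
#' @param inclusion Named list mapping system (`ICD7`...`ICD10`, `ATC`) to a
#'   character vector of code prefixes.
#' @param exclusion Like `inclusion`; events matching these argue against an
#'   autoimmune etiology.
#' @param required_atc Optional list with `atc_prefix`, `min_dispensations`
#'   and `applies_if_alive_after` (ISO date): persons alive after that date
#'   additionally need at least `min_dispensations` drug-register events with
#'   the prefix; persons who died earlier are exempt.
#' @param min_inclusion_count Minimum number of inclusion events (default 1).
#' @param use_diabetes_register If `TRUE`, events tagged
#'   `diabetes_register` count as inclusion events regardless of code
#'   (emulating a cross-match against a dedicated diabetes register).
#' @return Object of class `disease_definition`.
#' @export
disease_definition <- function(name, inclusion, exclusion = list(),
                               required_atc = NULL, min_inclusion_count = 1L,
                               use_diabetes_register = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, min_inclusion_count >= 1L)
  inclusion <- lapply(inclusion, as.character)
  exclusion <- lapply(exclusion, as.character)
  for (sys in intersect(names(inclusion), names(exclusion))) {
    overlap <- intersect(inclusion[[sys]], exclusion[[sys]])
    if (length(overlap))
      stop(sprintf("disease '%s': inclusion and exclusion codes overlap in %s: %s",
                   name, sys, paste(overlap, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(required_atc)) {
    stopifnot(!is.null(required_atc$atc_prefix))
    required_atc$min_dispensations <- as.integer(required_atc$min_dispensations %||% 2L)
    required_atc$applies_if_alive_after <-
      as.Date(required_atc$applies_if_alive_after %||% "2005-12-31")
  }
  structure(list(name = name, inclusion = inclusion, exclusion = exclusion,
                 required_atc = required_atc,
                 min_inclusion_count = as.integer(min_inclusion_count),
                 use_diabetes_register = isTRUE(use_diabetes_register)),
            class = "disease_definition")
}

#' @export
print.disease_definition <- function(x, ...) {
  cat("Disease definition:", x$name, "\n")
  for (sys in names(x$inclusion))
    cat("  include", sys, ":", paste(x$inclusion[[sys]], collapse = ", "), "\n")
  for (sys in names(x$exclusion))
    cat("  exclude", sys, ":", paste(x$exclusion[[sys]], collapse = ", "), "\n")
  if (!is.null(x$required_atc))
    cat(sprintf("  requires >=%d dispensations of ATC %s if alive after %s\n",
                x$required_atc$min_dispensations, x$required_atc$atc_prefix,
                format(x$required_atc$applies_if_alive_after)))
  if (x$use_diabetes_register) cat("  diabetes-register events count as inclusions\n")
  invisible(x)
}

#' Read disease definitions from a YAML or JSON configuration file
#'
#' The file holds a list of definitions keyed by disease name; each entry may
#' have `inclusion`, `exclusion`, `required_atc`, `min_inclusion_count` and
#' `use_diabetes_register` fields as in [disease_definition()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of `disease_definition` objects.
#' @export
read_disease_definitions <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path, simplifyVector = FALSE)
         else yaml::read_yaml(path)
  defs <- lapply(names(raw), function(nm) {
    d <- raw[[nm]]
    disease_definition(
      name = nm,
      inclusion = d$inclusion %||% list(),
      exclusion = d$exclusion %||% list(),
      required_atc = d$required_atc,
      min_inclusion_count = d$min_inclusion_count %||% 1L,
      use_diabetes_register = d$use_diabetes_register %||% FALSE)
  })
  names(defs) <- names(raw)
  defs
}

#' Illustrative default definitions for seven organ-specific autoimmune diseases
#'
#' Ships an editable rule set for Hashimoto's thyroiditis, atrophic
#' gastritis/pernicious anemia, celiac disease, Graves' disease, type 1
#' diabetes, vitiligo and Addison's disease. The code lists are illustrative
#' defaults covering the common ICD-10 (and a few older-revision) codes; real
#' analyses should review and extend them.
#'
#' @return Named list of `disease_definition` objects.
#' @export
default_disease_definitions <- function() {
  read_disease_definitions(
    system.file("extdata", "disease_definitions.yaml", package = "twinherit",
                mustWork = TRUE))
}
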