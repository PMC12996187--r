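#' Parameter registry for the growth and yield model family
#'
#' The registry is a named, versioned container holding every fitted constant
#' of the model family: Richards mean-height/site-index parameters, the
#' self-thinning line, stand density index (SDI) dynamics, the four basal-area
#' model variants, the form-factor volume equation, the additive biomass
#' component equations, carbon fractions, wood densities, the q-value policy
#' and the diameter-class grid. It round-trips to a single JSON document.
#'
#' The packaged default, `"published-2026"`, carries the published parameter
#' estimates for natural Dahurian larch (*Larix gmelinii*) secondary forests
#' in northeast China. Two conventions in it differ deliberately from a naive
#' transcription of the published equation text:
#' * climate exponents are stored *by role* (`sci_exp` on SCI, `mai_exp` on
#'   1/MAI), with the role assignment selected by consistency with the
#'   published age-80 simulation table (see the methods vignette);
#' * stage dummy coding defaults to the non-cumulative scheme (Stage 1 =
#'   (0,0), Stage 2 = (1,0), Stage 3 = (0,1)), again the table-consistent
#'   reading; the cumulative scheme remains selectable via the `coding` field.
#'
#' @param source Either the name of a packaged registry (currently
#'   `"published-2026"`) or a path to a registry JSON file.
#' @return An object of class `fgym_registry`: a named list with components
#'   `name`, `version`, `provenance`, `sci`, `self_thinning`, `sdi_dynamics`,
#'   `bas_base`, `bas_stand`, `bas_climate`, `bas_stage`, `volume`,
#'   `biomass`, `carbon_fractions`, `wood_density`, `q_policy`,
#'   `diameter_grid`.
#' @examples
#' reg <- load_registry()
#' reg$sci$a0
#' @seealso [write_registry()], [validate_registry()]
#' @export
load_registry <- function(source = "published-2026") {
  if (identical(source, "published-2026")) {
    if (is.null(.fgym_cache$default_registry)) {
      path <- system.file("extdata", "registry_published_2026.json",
                          package = "fgym", mustWork = TRUE)
      .fgym_cache$default_registry <- read_registry_file(path)
    }
    return(.fgym_cache$default_registry)
  }
  if (!is.character(source) || length(source) != 1L)
    stop("`source` must be a registry name or a file path", call. = FALSE)
  if (!file.exists(source))
    stop("registry file not found: ", source, call. = FALSE)
  read_registry_file(source)
}

#' @rdname load_registry
#' @export
default_registry <- function() load_registry("published-2026")

read_registry_file <- function(path) {
  reg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_registry(reg)
}

#' Serialize a registry to JSON
#'
#' Writes the registry as a human-diffable JSON document that [load_registry()]
#' reads back identically (deserialize -> serialize is the identity).
#'
#' @param registry An `fgym_registry` (or a list passing
#'   [validate_registry()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  registry <- validate_registry(registry)
  jsonlite::write_json(unclass(registry), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# section -> required field names; anything else in a section is rejected
.registry_schema <- list(
  sci            = c("a0", "a1", "a2", "reference_age"),
  self_thinning  = c("b0", "b1", "d0_cm"),
  sdi_dynamics   = c("b2", "b3", "b4"),
  bas_base       = c("c", "k"),
  bas_stand      = c("c0", "c1", "k0", "k1"),
  bas_climate    = c("c0", "sci_exp", "mai_exp", "k0", "k1"),
  bas_stage      = c("c0", "c01", "c02", "sci_exp", "mai_exp",
                     "k0", "k01", "k02", "k1", "coding"),
  volume         = c("d0", "d1", "d2"),
  carbon_fractions = c("root", "stem", "branch", "leaf"),
  wood_density   = c("commercial", "fuel", "bark"),
  q_policy       = c("mode", "fixed_q", "stage_q", "range"),
  diameter_grid  = c("min_midpoint_cm", "max_midpoint_cm", "width_cm",
                     "min_share")
)

#' Validate a parameter registry
#'
#' Checks the document structure (every section present, no unknown sections
#' or fields, the four biomass component triples complete) and the scientific
#' invariants: positive asymptotes and rates, negative self-thinning slope,
#' carbon fractions in (0, 1), positive effective asymptote and rate for every
#' developmental stage under the declared dummy coding.
#'
#' @param registry A list as produced by [load_registry()].
#' @return The registry, classed `fgym_registry`, invisibly usable.
#' @export
validate_registry <- function(registry) {
  if (!is.list(registry)) stop("registry must be a list", call. = FALSE)
  top_required <- c("name", "version", "provenance", names(.registry_schema),
                    "biomass")
  unknown <- setdiff(names(registry), top_required)
  if (length(unknown))
    stop("unknown registry section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing_top <- setdiff(top_required, names(registry))
  if (length(missing_top))
    stop("registry is missing section(s): ",
         paste(missing_top, collapse = ", "), call. = FALSE)

  for (sec in names(.registry_schema)) {
    fields <- .registry_schema[[sec]]
    have <- names(registry[[sec]])
    miss <- setdiff(fields, have)
    if (length(miss))
      stop("registry section '", sec, "' is missing field(s): ",
           paste(paste0(sec, "$", miss), collapse = ", "), call. = FALSE)
    extra <- setdiff(have, fields)
    if (length(extra))
      stop("registry section '", sec, "' has unknown field(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
  }
  comps <- c("root", "stem", "branch", "leaf")
  miss_b <- setdiff(comps, names(registry$biomass))
  if (length(miss_b))
    stop("registry section 'biomass' is missing component(s): ",
         paste(miss_b, collapse = ", "), call. = FALSE)
  for (cm in comps) {
    miss_e <- setdiff(c("e0", "e1", "e2"), names(registry$biomass[[cm]]))
    if (length(miss_e))
      stop("biomass$", cm, " is missing field(s): ",
           paste(miss_e, collapse = ", "), call. = FALSE)
  }

  with(registry, {
    stopifnot(
      "sci: a0, a1, a2 and reference_age must be positive" =
        sci$a0 > 0 && sci$a1 > 0 && sci$a2 > 0 && sci$reference_age > 0,
      "self_thinning: slope b1 must be negative, d0_cm positive" =
        self_thinning$b1 < 0 && self_thinning$d0_cm > 0,
      "sdi_dynamics: rate b4 must be positive" = sdi_dynamics$b4 > 0,
      "bas_base: c and k must be positive" =
        bas_base$c > 0 && bas_base$k > 0,
      "bas_stand: all parameters must be positive" =
        all(unlist(bas_stand) > 0),
      "bas_climate: all parameters must be positive" =
        all(unlist(bas_climate) > 0),
      "bas_stage: c0 and k0 must be positive" =
        bas_stage$c0 > 0 && bas_stage$k0 > 0,
      "volume: d0, d1, d2 must be positive" = all(unlist(volume) > 0),
      "carbon_fractions must lie in (0, 1)" =
        all(unlist(carbon_fractions) > 0 & unlist(carbon_fractions) < 1),
      "wood densities must be positive" = all(unlist(wood_density) > 0),
      "q_policy$range must be an increasing pair" =
        length(q_policy$range) == 2L && diff(q_policy$range) > 0,
      "diameter_grid must describe a positive-width increasing grid" =
        diameter_grid$width_cm > 0 &&
        diameter_grid$max_midpoint_cm > diameter_grid$min_midpoint_cm
    )
  })
  if (!registry$bas_stage$coding %in% c("non_cumulative", "cumulative"))
    stop("bas_stage$coding must be 'non_cumulative' or 'cumulative'",
         call. = FALSE)
  # effective asymptote scale and rate must stay positive for every stage
  for (st in 1:3) {
    eff <- stage_effective_params(registry$bas_stage, st)
    if (eff$c0 <= 0 || eff$k0 <= 0)
      stop("bas_stage: effective asymptote/rate non-positive for stage ", st,
           call. = FALSE)
  }
  structure(registry, class = "fgym_registry")
}

#' @export
print.fgym_registry <- function(x, ...) {
  cat("<fgym_registry> ", x$name, " (version ", x$version, ")\n", sep = "")
  cat("  SCI:   a0 =", x$sci$a0, " a1 =", x$sci$a1, " a2 =", x$sci$a2,
      " tI =", x$sci$reference_age, "yr\n")
  cat("  MSDL:  b0 =", x$self_thinning$b0, " b1 =", x$self_thinning$b1,
      " D0 =", x$self_thinning$d0_cm, "cm\n")
  cat("  BAS variants: base, stand, climate, stage (coding: ",
      x$bas_stage$coding, ")\n", sep = "")
  cat("  Carbon fractions:",
      paste(names(x$carbon_fractions), unlist(x$carbon_fractions),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

# Resolve a parameter argument that may be a full registry or a bare section.
# `probe` is a field name that identifies the section.
get_params <- function(p, section, probe) {
  if (is.null(p)) p <- default_registry()
  if (!is.null(p[[probe]])) return(p)
  if (!is.null(p[[section]])) return(p[[section]])
  stop("cannot interpret parameter argument as '", section,
       "' parameters (no '", probe, "' field)", call. = FALSE)
}
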