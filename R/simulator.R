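#' Developmental stage from quadratic mean diameter
#'
#' Dg-threshold discrimination of developmental stages:
#' Stage 1 (early) for Dg < 12 cm, Stage 2 (middle) for 12 <= Dg < 18 cm,
#' Stage 3 (late) for Dg >= 18 cm. Both boundaries are inclusive on the
#' upper stage.
#'
#' @param dg Quadratic mean diameter (cm), `> 0`. Vectorized.
#' @return Integer stage labels in `1:3`.
#' @export
assign_stage <- function(dg) {
  if (any(!is.finite(dg)) || any(dg <= 0)) stop("`dg` must be > 0", call. = FALSE)
  1L + (dg >= 12) + (dg >= 18)
}

# One fully resolved stand state at a single age: the nine-step chain.
# Returns a one-row data.frame of the structural and carbon columns.
stand_state_at <- function(t, sci, variant, registry, mai = NULL,
                           stage = NULL, dynamic_stage = FALSE) {
  th  <- height_from_sci(sci, t, registry)
  sdi <- predict_sdi(sci, t, registry)
  if (variant == "stage" && dynamic_stage) {
    # classify from the stage-independent (climate) prediction, then refine
    bas0 <- predict_bas(t, "climate", registry, sci = sci, sdi = sdi,
                        mai = mai)
    stage <- assign_stage(dg_from_bas_sdi(bas0, sdi, registry))
  }
  bas <- predict_bas(t, variant, registry, sci = sci, sdi = sdi, mai = mai,
                     stage = stage)
  dg  <- dg_from_bas_sdi(bas, sdi, registry)
  n   <- n_from_bas_dg(bas, dg)
  vol <- predict_volume(bas, th, registry)
  bio <- predict_biomass_components(bas, th, registry)
  car <- carbon_from_biomass(bio, registry)
  data.frame(age = t, sci_m = sci,
             mai = if (is.null(mai)) NA_real_ else mai,
             stage = if (is.null(stage)) 0L else as.integer(stage),
             th_m = th, sdi = sdi, bas_m2ha = bas, dg_cm = dg, n_ha = n,
             vol_m3ha = vol,
             c_root = car$root, c_stem = car$stem, c_branch = car$branch,
             c_leaf = car$leaf, c_crown = car$crown,
             c_aboveground = car$aboveground, c_total = car$total)
}

#' Simulate a stand trajectory
#'
#' Runs the nine-step stand simulation for one scenario over an age grid.
#' Per age: mean height from the site-index inversion; SDI from its dynamic
#' equation; basal area from the selected model variant; quadratic mean
#' diameter and stem count from the closed-form basal-area/SDI links; volume
#' from the form-factor equation; component biomass and carbon from the
#' additive allometries; the stem count allocated to 2-cm diameter classes
#' under the q-value policy; and class volumes split into timber assortments
#' with commercial/non-commercial carbon closure against stem carbon. The
#' site class index is held constant for the whole trajectory.
#'
#' All quantities are closed-form functions of (age, SCI, MAI, stage), so the
#' simulator is memoryless: each age is evaluated independently.
#'
#' @param sci Site class index (m).
#' @param ages Strictly increasing vector of positive ages (yr).
#' @param variant Basal-area model variant: `"stand"` (default; site and
#'   density effects), `"base"`, `"climate"` or `"stage"`.
#' @param mai De Martonne aridity index (mm/degree C); required for the
#'   climate and stage variants.
#' @param stage Developmental stage (1, 2 or 3) for the stage variant, fixed
#'   for the whole trajectory unless `dynamic_stage = TRUE`.
#' @param dynamic_stage If `TRUE` (stage variant only), the stage is
#'   re-derived at every age from the predicted Dg instead of being held
#'   fixed.
#' @param registry Parameter registry (default: published values).
#' @param assortment_table Assortment proportion table (default: the packaged
#'   synthetic approximation).
#' @param grid Diameter-class midpoints; default from the registry.
#' @return An object of class `fgym_trajectory`: a list with `states` (one
#'   data.frame row per age), `distributions` (list of `fgym_ddist`) and
#'   `assortments` (list of `fgym_assortment`).
#' @examples
#' tr <- simulate_stand(16, ages = c(40, 80, 120))
#' tr$states[, c("age", "dg_cm", "bas_m2ha", "vol_m3ha", "c_total")]
#' @export
simulate_stand <- function(sci, ages, variant = c("stand", "base", "climate",
                                                  "stage"),
                           mai = NULL, stage = NULL, dynamic_stage = FALSE,
                           registry = NULL, assortment_table = NULL,
                           grid = NULL) {
  variant <- match.arg(variant)
  if (is.null(registry)) registry <- default_registry()
  if (is.null(assortment_table)) assortment_table <- default_assortment_table()
  if (length(ages) < 1L || any(!is.finite(ages)) || any(ages <= 0))
    stop("`ages` must be positive", call. = FALSE)
  if (is.unsorted(ages, strictly = TRUE))
    stop("`ages` must be strictly increasing", call. = FALSE)
  if (variant == "stage" && is.null(stage) && !dynamic_stage)
    stop("stage variant needs `stage` (or dynamic_stage = TRUE)",
         call. = FALSE)
  if (variant %in% c("climate", "stage") && is.null(mai))
    stop("variant '", variant, "' needs `mai`", call. = FALSE)

  states <- vector("list", length(ages))
  dists <- vector("list", length(ages))
  assorts <- vector("list", length(ages))
  for (i in seq_along(ages)) {
    st <- tryCatch(
      stand_state_at(ages[i], sci, variant, registry, mai = mai,
                     stage = stage, dynamic_stage = dynamic_stage),
      error = function(e) stop("age ", ages[i], " (step ", i, "): ",
                               conditionMessage(e), call. = FALSE))
    q <- q_from_policy(stage = if (st$stage > 0) st$stage else NULL,
                       dg = st$dg_cm, policy = registry)
    dd <- build_diameter_distribution(st$n_ha, q = q, grid = grid,
                                      registry = registry)
    cv <- allocate_class_volumes(dd, st$vol_m3ha)
    ay <- assortment_volumes(cv, assortment_table)
    ay <- assortment_carbon(ay, registry, stem_carbon = st$c_stem,
                            stem_fraction = registry$carbon_fractions$stem)
    st$c_comm <- ay$c_comm
    st$c_non <- ay$c_non
    states[[i]] <- st; dists[[i]] <- dd; assorts[[i]] <- ay
  }
  structure(list(states = do.call(rbind, states),
                 distributions = dists,
                 assortments = assorts,
                 variant = variant),
            class = "fgym_trajectory")
}

#' @export
print.fgym_trajectory <- function(x, ...) {
  s <- x$states
  cat("<fgym_trajectory> variant '", x$variant, "', SCI ", s$sci_m[1],
      " m, ", nrow(s), " age(s) ", s$age[1], "-", s$age[nrow(s)], " yr\n",
      sep = "")
  print(round(s[c("age", "th_m", "dg_cm", "bas_m2ha", "n_ha", "vol_m3ha",
                  "c_total")], 2), row.names = FALSE)
  invisible(x)
}

#' Scenario grid of stand simulations at a fixed age
#'
#' Simulates every combination of aridity scenario, site class index and
#' developmental stage at one age and returns a yield table (one row per
#' combination). The variant mapping follows the published presentation:
#' an `NA` aridity value denotes the base scenario (stand variant, stage 0);
#' with a finite MAI, stage 0 rows use the climate variant and stage 1-3
#' rows the stage variant.
#'
#' @param sci Vector of site class indices (m).
#' @param mai Vector of De Martonne aridity indices; `NA` entries denote the
#'   base (climate-free) scenario.
#' @param stages Vector of stages from `0:3` (0 = stage-independent).
#' @param age Simulation age (yr), default 80.
#' @inheritParams simulate_stand
#' @return A data.frame, one row per scenario combination, with scenario
#'   label, drivers, stand structure (`dg_cm`, `bas_m2ha`, `num_ha`), total
#'   and per-assortment volumes, and total, component and end-use carbon.
#'   Rows are ordered deterministically (scenario, then stage, then SCI).
#' @examples
#' g <- scenario_grid(sci = c(12, 16, 20), mai = NA, stages = 0)
#' g[, c("scenario", "sci_m", "dg_cm", "bas_m2ha", "vol_total")]
#' @export
scenario_grid <- function(sci, mai = NA, stages = 0, age = 80,
                          registry = NULL, assortment_table = NULL,
                          grid = NULL) {
  if (is.null(registry)) registry <- default_registry()
  if (is.null(assortment_table)) assortment_table <- default_assortment_table()
  if (!length(sci) || !length(mai) || !length(stages))
    stop("scenario axes must be non-empty", call. = FALSE)
  if (!all(stages %in% 0:3)) stop("`stages` must be in 0:3", call. = FALSE)

  rows <- list()
  for (m in mai) for (st in stages) for (s in sci) {
    if (is.na(m) && st != 0) next  # base scenario is stage-independent
    variant <- if (is.na(m)) "stand" else if (st == 0) "climate" else "stage"
    tr <- simulate_stand(s, ages = age, variant = variant,
                         mai = if (is.na(m)) NULL else m,
                         stage = if (st == 0) NULL else st,
                         registry = registry,
                         assortment_table = assortment_table, grid = grid)
    ss <- tr$states
    ay <- tr$assortments[[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = if (is.na(m)) "Base" else paste0("MAI", format(m)),
      stage = st, sci_m = s, age = age,
      dg_cm = ss$dg_cm, bas_m2ha = ss$bas_m2ha, num_ha = ss$n_ha,
      vol_total = ss$vol_m3ha,
      vol_bark = ay$volumes[["bark"]], vol_large = ay$volumes[["large"]],
      vol_middle = ay$volumes[["middle"]], vol_small = ay$volumes[["small"]],
      vol_short = ay$volumes[["short"]], vol_fuel = ay$volumes[["fuel"]],
      c_total = ss$c_total, c_root = ss$c_root, c_stem = ss$c_stem,
      c_branch = ss$c_branch, c_leaf = ss$c_leaf,
      c_non = ss$c_non, c_comm = ss$c_comm)
  }
  do.call(rbind, rows)
}
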