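#' Resolve a q-value from the configured policy
#'
#' The q-value is the ratio of stem counts in adjacent 2-cm diameter classes
#' of a negative-exponential ("reverse-J") diameter distribution. In these
#' stands it declines from about 1.7 (steep, small-tree-dominated) early in
#' development to about 1.2 (flat, large-tree-rich) late. Policies:
#' \describe{
#'   \item{`fixed`}{always `fixed_q`.}
#'   \item{`stage_linear`}{linear in the stage index between the declared
#'     endpoints: Stage 1 -> 1.7, Stage 2 -> 1.45, Stage 3 -> 1.2 by default.
#'     If only `dg` is supplied the stage is derived from the Dg thresholds
#'     (see [assign_stage()]).}
#'   \item{`match_dg`}{the q is not set here; it is solved inside
#'     [build_diameter_distribution()] so the distribution's quadratic mean
#'     diameter matches a target.}
#' }
#'
#' @param stage Developmental stage 1, 2 or 3 (preferred input).
#' @param dg Quadratic mean diameter (cm); used to derive the stage when
#'   `stage` is missing.
#' @param policy Policy list (`mode`, `fixed_q`, `stage_q`, `range`) or a
#'   full registry. Defaults to the published registry's policy.
#' @return The q-value (dimensionless), within the admissible range for the
#'   `fixed` and `stage_linear` modes.
#' @export
q_from_policy <- function(stage = NULL, dg = NULL, policy = NULL) {
  p <- get_params(policy, "q_policy", "mode")
  q <- switch(p$mode,
    fixed = p$fixed_q,
    stage_linear = {
      if (is.null(stage)) {
        if (is.null(dg)) stop("stage_linear policy needs `stage` or `dg`",
                              call. = FALSE)
        stage <- assign_stage(dg)
      }
      if (!all(stage %in% 1:3)) stop("`stage` must be 1, 2 or 3", call. = FALSE)
      p$stage_q[stage]
    },
    match_dg = stop(
      "mode 'match_dg' is resolved inside build_diameter_distribution()",
      call. = FALSE),
    stop("unknown q-policy mode: ", p$mode, call. = FALSE))
  if (any(q < p$range[1] - 1e-9) || any(q > p$range[2] + 1e-9))
    warning("q-value ", paste(round(q, 3), collapse = ", "),
            " outside the admissible range [", p$range[1], ", ",
            p$range[2], "]")
  q
}

#' Build a diameter-class distribution
#'
#' Allocates a total stand density over an arithmetic grid of diameter-class
#' midpoints (width `h` = 2 cm by default) with negative-exponential weights
#' \eqn{\exp(-f_1 x_i)}, where \eqn{f_1 = \ln(q)/h}, rescaled so the counts
#' sum exactly to `n`. Classes receiving less than `min_share` of the total
#' are dropped and the remainder renormalized (the adjacent-class ratio among
#' retained classes is unchanged).
#'
#' With `dg` supplied (match-Dg mode), `f1` is instead solved by 1-D root
#' finding so the distribution's quadratic mean diameter
#' \eqn{\sqrt{\sum N_i x_i^2 / \sum N_i}} equals `dg` (to 1e-8 cm); the
#' implied q may then fall outside the admissible range, in which case a
#' warning is raised.
#'
#' @param n Total stems per hectare, `> 0`.
#' @param q Adjacent-class ratio, `> 1` (steeper than uniform) or exactly the
#'   degenerate `q = 1` (uniform). Ignored when `dg` is given.
#' @param grid Vector of class midpoints (cm); defaults to the registry grid
#'   (6 to 40 cm in steps of 2).
#' @param dg Optional target quadratic mean diameter (cm) for match-Dg mode.
#' @param registry Registry supplying the default grid and q range.
#' @param min_share Minimum class share retained (default from the registry:
#'   1e-4, i.e. 0.01 percent).
#' @return An object of class `fgym_ddist`: a data.frame with columns
#'   `midpoint_cm` and `count_ha`, and attributes `q` and `f1`.
#' @examples
#' d <- build_diameter_distribution(1000, q = 1.5, grid = seq(6, 16, 2))
#' sum(d$count_ha)
#' @export
build_diameter_distribution <- function(n, q = NULL, grid = NULL, dg = NULL,
                                        registry = NULL, min_share = NULL) {
  if (is.null(registry)) registry <- default_registry()
  gcfg <- registry$diameter_grid
  if (is.null(grid))
    grid <- seq(gcfg$min_midpoint_cm, gcfg$max_midpoint_cm, by = gcfg$width_cm)
  if (length(grid) < 1L) stop("empty diameter grid", call. = FALSE)
  if (length(grid) > 1L) {
    h <- diff(grid)
    if (any(abs(h - h[1]) > 1e-9) || h[1] <= 0)
      stop("grid midpoints must form an increasing arithmetic sequence",
           call. = FALSE)
    h <- h[1]
  } else h <- gcfg$width_cm
  if (!is.finite(n) || n <= 0) stop("`n` must be > 0", call. = FALSE)
  if (is.null(min_share)) min_share <- gcfg$min_share

  if (!is.null(dg)) {
    # solve f1 so the implied quadratic mean diameter equals dg
    dg_of <- function(f1) {
      w <- exp(-f1 * (grid - grid[1]))  # shift for numerical stability
      sqrt(sum(w * grid^2) / sum(w))
    }
    lo <- -5; hi <- 5
    if (dg >= dg_of(lo) || dg <= dg_of(hi))
      stop("target Dg = ", dg, " cm is outside the achievable range (",
           round(dg_of(hi), 3), ", ", round(dg_of(lo), 3),
           ") for this grid", call. = FALSE)
    f1 <- uniroot(function(f) dg_of(f) - dg, c(lo, hi), tol = 1e-12)$root
    # tighten until the Dg residual itself is below 1e-8
    if (abs(dg_of(f1) - dg) > 1e-8)
      stop("root finding did not reach the requested Dg tolerance",
           call. = FALSE)
    q <- exp(f1 * h)
    min_share <- 0  # dropping classes would perturb the matched Dg
    rng <- registry$q_policy$range
    if (q < rng[1] || q > rng[2])
      warning("match_dg resolved q = ", round(q, 3),
              ", outside the admissible range [", rng[1], ", ", rng[2], "]")
  } else {
    if (is.null(q))
      stop("supply either `q` or a target `dg`", call. = FALSE)
    if (!is.finite(q) || q < 1) stop("`q` must be >= 1", call. = FALSE)
    f1 <- log(q) / h
  }

  w <- exp(-f1 * (grid - grid[1]))
  share <- w / sum(w)
  keep <- share >= min_share
  grid <- grid[keep]; share <- share[keep] / sum(share[keep])
  counts <- n * share
  structure(data.frame(midpoint_cm = grid, count_ha = counts),
            q = q, f1 = f1, class = c("fgym_ddist", "data.frame"))
}

#' Share stand volume across diameter classes
#'
#' The stand-level volume equation gives no per-class volumes, so the total
#' is shared in proportion to each class's contribution to basal area,
#' \eqn{N_i x_i^2} (consistent with the form-factor volume model, which is
#' nearly linear in basal area). A pure count-proportional rule is available
#' as an alternative.
#'
#' @param dist An `fgym_ddist` (or data.frame with `midpoint_cm`,
#'   `count_ha`).
#' @param total_vol Total stand volume (m^3/ha), `> 0`.
#' @param method `"basal_area"` (default) or `"count"`.
#' @return A data.frame with columns `midpoint_cm`, `count_ha`,
#'   `volume_m3ha`; the volumes sum exactly to `total_vol`.
#' @export
allocate_class_volumes <- function(dist, total_vol,
                                   method = c("basal_area", "count")) {
  method <- match.arg(method)
  if (!all(c("midpoint_cm", "count_ha") %in% names(dist)))
    stop("`dist` must have midpoint_cm and count_ha columns", call. = FALSE)
  if (nrow(dist) == 0L) stop("empty distribution", call. = FALSE)
  if (!is.finite(total_vol) || total_vol <= 0)
    stop("`total_vol` must be > 0", call. = FALSE)
  wt <- switch(method,
               basal_area = dist$count_ha * dist$midpoint_cm^2,
               count = dist$count_ha)
  if (sum(wt) <= 0) stop("all-zero class weights", call. = FALSE)
  out <- dist[c("midpoint_cm", "count_ha")]
  out$volume_m3ha <- total_vol * wt / sum(wt)
  out
}

#' Read a timber-assortment proportion table
#'
#' The table splits stem volume in each DBH class into six assortments:
#' large-, middle-, small- and short-diameter timber (commercial), fuelwood
#' and bark (non-commercial). Expected CSV columns: `dbh_midpoint_cm`,
#' `p_large`, `p_middle`, `p_small`, `p_short`, `p_fuel`, `p_bark`. Each
#' row's six proportions must sum to 1 (tolerance 1e-6) and the DBH keys must
#' be strictly increasing; malformed tables are rejected at load.
#'
#' The packaged default (`default_assortment_table()`) is a synthetic
#' approximation constructed to honour the qualitative behaviour of the
#' provincial yield-rate standard (large timber appearing near 30 cm DBH,
#' middle timber peaking near 40 cm, small timber peaking near 18 cm, bark
#' share declining with DBH); it is shipped for tests and demonstrations, and
#' assortment-level outputs computed from it are illustrative, not the
#' published standard.
#'
#' @param path CSV file path.
#' @return A data.frame of class `fgym_assortment_table`.
#' @export
read_assortment_table <- function(path) {
  tab <- read.csv(path)
  cols <- c("dbh_midpoint_cm", "p_large", "p_middle", "p_small", "p_short",
            "p_fuel", "p_bark")
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    stop("assortment table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  tab <- tab[cols]
  if (any(diff(tab$dbh_midpoint_cm) <= 0))
    stop("dbh_midpoint_cm must be strictly increasing", call. = FALSE)
  props <- as.matrix(tab[-1])
  if (any(props < 0 | props > 1))
    stop("assortment proportions must lie in [0, 1]", call. = FALSE)
  bad <- which(abs(rowSums(props) - 1) > 1e-6)
  if (length(bad))
    stop("assortment proportions must sum to 1 in every row; offending ",
         "row(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(tab, class = c("fgym_assortment_table", "data.frame"))
}

#' @rdname read_assortment_table
#' @export
default_assortment_table <- function() {
  if (is.null(.fgym_cache$assortment_table)) {
    path <- system.file("extdata", "assortment_proportions_synthetic.csv",
                        package = "fgym", mustWork = TRUE)
    .fgym_cache$assortment_table <- read_assortment_table(path)
  }
  .fgym_cache$assortment_table
}

# Linearly interpolate the six proportion columns at arbitrary DBH values,
# clamped at the table ends. Rows of the interpolated matrix still sum to 1
# because interpolation is linear and the input rows sum to 1.
interp_assortment <- function(table, dbh) {
  cols <- c("p_large", "p_middle", "p_small", "p_short", "p_fuel", "p_bark")
  out <- vapply(cols, function(cc)
    approx(table$dbh_midpoint_cm, table[[cc]], xout = dbh, rule = 2)$y,
    numeric(length(dbh)))
  matrix(out, nrow = length(dbh), dimnames = list(NULL, cols))
}

#' Assortment volumes from per-class volumes
#'
#' For each diameter class, splits the class volume by the interpolated
#' assortment proportions and sums over classes. Because every interpolated
#' row of proportions sums to 1, the six assortment volumes conserve the
#' total volume exactly.
#'
#' @param class_volumes A data.frame as returned by
#'   [allocate_class_volumes()].
#' @param table An `fgym_assortment_table`; defaults to the packaged
#'   synthetic approximation.
#' @return An object of class `fgym_assortment`: a list with `volumes` (named
#'   vector: large, middle, small, short, fuel, bark, in m^3/ha),
#'   `commercial` (large + middle + small + short) and `total`.
#' @export
assortment_volumes <- function(class_volumes, table = NULL) {
  if (is.null(table)) table <- default_assortment_table()
  if (!all(c("midpoint_cm", "volume_m3ha") %in% names(class_volumes)))
    stop("`class_volumes` must have midpoint_cm and volume_m3ha columns",
         call. = FALSE)
  props <- interp_assortment(table, class_volumes$midpoint_cm)
  vols <- colSums(props * class_volumes$volume_m3ha)
  names(vols) <- sub("^p_", "", names(vols))
  structure(list(
    volumes = vols,
    commercial = sum(vols[c("large", "middle", "small", "short")]),
    total = sum(vols)), class = "fgym_assortment")
}

#' Commercial and non-commercial carbon from assortment volumes
#'
#' Converts assortment volumes to carbon with wood density times the stem
#' carbon fraction, then rescales so the two end-use categories exactly
#' exhaust the stem-component carbon stock: the scale factor is
#' \eqn{\lambda = C_{stem} / \sum_a V_a \rho_a f_{stem}}, after which
#' `c_comm + c_non = stem carbon` by construction. This closure rule is
#' inferred from the published end-use columns (the published account does
#' not state one); see the methods vignette.
#'
#' @param yield An `fgym_assortment` from [assortment_volumes()].
#' @param densities Wood densities (named list: commercial, fuel, bark, in
#'   t/m^3) or a full registry.
#' @param stem_carbon Stem-component carbon stock (t/ha), `> 0`.
#' @param stem_fraction Stem carbon fraction (default 0.47).
#' @return The input yield with added fields `carbon` (named per-assortment
#'   vector, t/ha), `c_comm`, `c_non` and `lambda`.
#' @export
assortment_carbon <- function(yield, densities = NULL, stem_carbon,
                              stem_fraction = 0.47) {
  d <- get_params(densities, "wood_density", "bark")
  if (!inherits(yield, "fgym_assortment"))
    stop("`yield` must come from assortment_volumes()", call. = FALSE)
  if (!is.finite(stem_carbon) || stem_carbon <= 0)
    stop("`stem_carbon` must be > 0", call. = FALSE)
  dens <- c(large = d$commercial, middle = d$commercial,
            small = d$commercial, short = d$commercial,
            fuel = d$fuel, bark = d$bark)
  unscaled <- yield$volumes * dens[names(yield$volumes)] * stem_fraction
  tot <- sum(unscaled)
  if (tot <= 0) stop("total unscaled assortment carbon is zero", call. = FALSE)
  lambda <- stem_carbon / tot
  carbon <- lambda * unscaled
  yield$carbon <- carbon
  yield$c_comm <- sum(carbon[c("large", "middle", "small", "short")])
  yield$c_non  <- sum(carbon[c("fuel", "bark")])
  yield$lambda <- lambda
  yield
}

#' @export
print.fgym_assortment <- function(x, ...) {
  cat("<fgym_assortment> total volume", round(x$total, 2), "m3/ha",
      "(commercial", round(x$commercial, 2), ")\n")
  print(round(x$volumes, 2))
  if (!is.null(x$c_comm))
    cat("carbon: commercial", round(x$c_comm, 2), "t/ha, non-commercial",
        round(x$c_non, 2), "t/ha (lambda =", round(x$lambda, 4), ")\n")
  invisible(x)
}
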