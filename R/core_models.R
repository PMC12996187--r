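#' Richards mean-height curve
#'
#' Predicts stand mean height from age with the Richards function
#' \deqn{TH = a_0 (1 - e^{-a_1 t})^{a_2}.}
#' Height is zero at age zero, strictly increasing in age, and approaches the
#' asymptote `a0` as the stand ages.
#'
#' @param t Stand age in years (vectorized, `t >= 0`).
#' @param params Site-index parameters: a list with `a0` (asymptotic height,
#'   m), `a1` (rate, 1/yr), `a2` (shape) and `reference_age` (yr), or a full
#'   registry (its `sci` section is used). Defaults to the published registry.
#' @return Stand mean height TH in metres.
#' @examples
#' predict_mean_height(80)
#' @export
predict_mean_height <- function(t, params = NULL) {
  p <- get_params(params, "sci", "a0")
  if (any(!is.finite(t)) || any(t < 0))
    stop("stand age `t` must be finite and >= 0", call. = FALSE)
  p$a0 * (1 - exp(-p$a1 * t))^p$a2
}

#' Site class index from mean height and age
#'
#' Standardizes observed mean height to the reference age `tI` (80 years in
#' the published registry):
#' \deqn{SCI = TH \cdot (1 - e^{-a_1 t_I})^{a_2} / (1 - e^{-a_1 t})^{a_2}.}
#' At the reference age the index equals the observed height.
#'
#' @param th Stand mean height (m), `> 0`.
#' @param t Stand age (yr), `> 0` (the ratio is undefined at `t = 0`).
#' @inheritParams predict_mean_height
#' @return Site class index SCI in metres.
#' @seealso [height_from_sci()] for the inverse.
#' @export
site_class_index <- function(th, t, params = NULL) {
  p <- get_params(params, "sci", "a0")
  if (any(!is.finite(t)) || any(t <= 0))
    stop("stand age `t` must be > 0 (index undefined at age 0)",
         call. = FALSE)
  if (any(!is.finite(th)) || any(th <= 0))
    stop("mean height `th` must be > 0", call. = FALSE)
  th * (1 - exp(-p$a1 * p$reference_age))^p$a2 / (1 - exp(-p$a1 * t))^p$a2
}

#' Mean height trajectory implied by a site class index
#'
#' Algebraic inversion of [site_class_index()]: the height at age `t` of a
#' stand whose height at the reference age equals `sci`. Round-tripping
#' through [site_class_index()] is the identity.
#'
#' @param sci Site class index (m), `> 0`.
#' @param t Stand age (yr), `> 0`.
#' @inheritParams predict_mean_height
#' @return Stand mean height TH in metres.
#' @export
height_from_sci <- function(sci, t, params = NULL) {
  p <- get_params(params, "sci", "a0")
  if (any(!is.finite(t)) || any(t <= 0))
    stop("stand age `t` must be > 0", call. = FALSE)
  if (any(!is.finite(sci)) || any(sci <= 0))
    stop("`sci` must be > 0", call. = FALSE)
  sci * (1 - exp(-p$a1 * t))^p$a2 / (1 - exp(-p$a1 * p$reference_age))^p$a2
}

#' Maximum stand density line (self-thinning frontier)
#'
#' Reineke-type maximum stems per hectare at a given quadratic mean diameter,
#' \deqn{N_{max} = e^{b_0 + b_1 \ln Dg},}
#' decreasing in Dg since the slope `b1` is negative.
#'
#' @param dg Quadratic mean diameter (cm), `> 0`.
#' @param params Self-thinning parameters (`b0`, `b1`, `d0_cm`) or a full
#'   registry. Defaults to the published registry (`b0 = 10.7253`,
#'   `b1 = -1.2338`, reference diameter 20 cm).
#' @return Maximum density in trees per hectare.
#' @export
max_density <- function(dg, params = NULL) {
  p <- get_params(params, "self_thinning", "b0")
  if (any(!is.finite(dg)) || any(dg <= 0))
    stop("`dg` must be > 0", call. = FALSE)
  exp(p$b0 + p$b1 * log(dg))
}

#' Stand density index
#'
#' Stem count standardized along the self-thinning slope to the reference
#' quadratic mean diameter `D0` (20 cm here):
#' \deqn{SDI = N (D_0 / Dg)^{b_1}.}
#'
#' @param n Stems per hectare, `> 0`.
#' @param dg Quadratic mean diameter (cm), `> 0`.
#' @inheritParams max_density
#' @return SDI in trees per hectare (at the reference diameter).
#' @export
stand_density_index <- function(n, dg, params = NULL) {
  p <- get_params(params, "self_thinning", "b0")
  if (any(!is.finite(n)) || any(n <= 0)) stop("`n` must be > 0", call. = FALSE)
  if (any(!is.finite(dg)) || any(dg <= 0)) stop("`dg` must be > 0", call. = FALSE)
  n * (p$d0_cm / dg)^p$b1
}

#' SDI dynamics over stand age
#'
#' In these naturally regenerated stands SDI rises towards a site-dependent
#' asymptote,
#' \deqn{SDI = (b_2 + b_3 \, SCI)(1 - e^{-b_4 t}),}
#' so that better sites (larger SCI) support higher equilibrium density.
#'
#' @param sci Site class index (m).
#' @param t Stand age (yr), `>= 0` (returns 0 at age 0).
#' @param params SDI-dynamics parameters (`b2`, `b3`, `b4`) or a full
#'   registry.
#' @return SDI in trees per hectare.
#' @export
predict_sdi <- function(sci, t, params = NULL) {
  p <- get_params(params, "sdi_dynamics", "b2")
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  asym <- p$b2 + p$b3 * sci
  if (any(!is.finite(asym)) || any(asym <= 0))
    stop("SDI asymptote b2 + b3*SCI must be positive over the supplied SCI",
         call. = FALSE)
  asym * (1 - exp(-p$b4 * t))
}

# Dummy pair (x1, x2) for a developmental stage under a coding scheme.
# non_cumulative: Stage 1 (0,0), Stage 2 (1,0), Stage 3 (0,1)
# cumulative:     Stage 1 (0,0), Stage 2 (1,0), Stage 3 (1,1)
stage_dummies <- function(stage, coding = "non_cumulative") {
  if (!all(stage %in% 1:3)) stop("`stage` must be 1, 2 or 3", call. = FALSE)
  x1 <- switch(coding,
    non_cumulative = as.numeric(stage == 2),
    cumulative     = as.numeric(stage >= 2),
    stop("unknown stage coding: ", coding, call. = FALSE))
  x2 <- as.numeric(stage == 3)
  list(x1 = x1, x2 = x2)
}

# Effective (asymptote scale, rate scale) for one stage.
stage_effective_params <- function(p, stage, coding = p$coding) {
  d <- stage_dummies(stage, coding)
  list(c0 = p$c0 + p$c01 * d$x1 + p$c02 * d$x2,
       k0 = p$k0 + p$k01 * d$x1 + p$k02 * d$x2)
}

#' Stand basal area, four model variants
#'
#' Mitscherlich-type basal-area growth with increasingly rich driver sets:
#' \describe{
#'   \item{`"base"`}{\eqn{BAS = c (1 - e^{-kt})} — age only.}
#'   \item{`"stand"`}{\eqn{BAS = c_0 SCI^{c_1} (1 - e^{-k_0 (SDI/1000)^{k_1} t})}
#'     — site quality scales the asymptote, density scales the rate.}
#'   \item{`"climate"`}{adds the De Martonne aridity index:
#'     \eqn{BAS = c_0 SCI^{sci\_exp} MAI^{-mai\_exp} (1 - e^{-k_0 (SDI/1000)^{k_1} t})}.
#'     More humid climates (larger MAI) reduce basal area.}
#'   \item{`"stage"`}{the climate form with developmental-stage dummy offsets
#'     on both the asymptote scale and the rate scale (see
#'     [load_registry()] for the coding convention).}
#' }
#'
#' @param t Stand age (yr), `>= 0`.
#' @param variant One of `"base"`, `"stand"`, `"climate"`, `"stage"`.
#' @param registry An `fgym_registry` (default: published values).
#' @param sci Site class index (m); required for all but `"base"`.
#' @param sdi Stand density index (trees/ha); required for all but `"base"`.
#' @param mai De Martonne aridity index (mm/degree C); required for
#'   `"climate"` and `"stage"`.
#' @param stage Developmental stage 1, 2 or 3; required for `"stage"`.
#' @param coding Stage dummy coding; defaults to the registry's declared
#'   scheme.
#' @return Basal area in m^2/ha.
#' @examples
#' reg <- load_registry()
#' sdi <- predict_sdi(16, 80, reg)
#' predict_bas(80, "stand", reg, sci = 16, sdi = sdi)
#' @export
predict_bas <- function(t, variant = c("stand", "base", "climate", "stage"),
                        registry = NULL, sci = NULL, sdi = NULL, mai = NULL,
                        stage = NULL, coding = NULL) {
  variant <- match.arg(variant)
  if (is.null(registry)) registry <- default_registry()
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be >= 0", call. = FALSE)

  if (variant == "base") {
    p <- registry$bas_base
    return(p$c * (1 - exp(-p$k * t)))
  }
  if (is.null(sci) || is.null(sdi) || any(sci <= 0) || any(sdi <= 0))
    stop("variant '", variant, "' needs positive `sci` and `sdi`",
         call. = FALSE)

  if (variant == "stand") {
    p <- registry$bas_stand
    return(p$c0 * sci^p$c1 * (1 - exp(-p$k0 * (sdi / 1000)^p$k1 * t)))
  }
  if (is.null(mai) || any(mai <= 0))
    stop("variant '", variant, "' needs positive `mai`", call. = FALSE)

  if (variant == "climate") {
    p <- registry$bas_climate
    return(p$c0 * sci^p$sci_exp * mai^(-p$mai_exp) *
             (1 - exp(-p$k0 * (sdi / 1000)^p$k1 * t)))
  }
  # stage variant
  p <- registry$bas_stage
  if (is.null(stage)) stop("variant 'stage' needs `stage` in 1:3", call. = FALSE)
  if (is.null(coding)) coding <- p$coding
  eff <- stage_effective_params(p, stage, coding)
  eff$c0 * sci^p$sci_exp * mai^(-p$mai_exp) *
    (1 - exp(-eff$k0 * (sdi / 1000)^p$k1 * t))
}

#' Stand volume from basal area and mean height
#'
#' Form-factor volume equation \deqn{VOL = d_0 BAS^{d_1} TH^{d_2}.}
#'
#' @param bas Basal area (m^2/ha), `> 0`.
#' @param th Mean height (m), `> 0`.
#' @param params Volume parameters (`d0`, `d1`, `d2`) or a full registry.
#' @return Stand volume in m^3/ha.
#' @export
predict_volume <- function(bas, th, params = NULL) {
  p <- get_params(params, "volume", "d0")
  if (any(!is.finite(bas)) || any(bas <= 0)) stop("`bas` must be > 0", call. = FALSE)
  if (any(!is.finite(th)) || any(th <= 0)) stop("`th` must be > 0", call. = FALSE)
  p$d0 * bas^p$d1 * th^p$d2
}

#' Additive biomass components from stand basal area and height
#'
#' Evaluates the component allometries
#' \deqn{W_i = e^{e_{i0}} BAS^{e_{i1}} TH^{e_{i2}}}
#' for root, stem, branch and leaf, and returns crown, aboveground and total
#' as exact sums (crown = branch + leaf; aboveground = stem + crown; total =
#' root + aboveground), so additivity holds by construction. The
#' back-transformation applies no log-bias correction: the parameters were
#' estimated as an additive system and direct exponentiation reproduces the
#' published simulation values (see the methods vignette).
#'
#' @param bas Basal area (m^2/ha), `> 0`.
#' @param th Mean height (m), `> 0`.
#' @param params Biomass parameter block (named list with `root`, `stem`,
#'   `branch`, `leaf`, each holding `e0`, `e1`, `e2`) or a full registry.
#' @return A data.frame with one row per input and columns `root`, `stem`,
#'   `branch`, `leaf`, `crown`, `aboveground`, `total` (t/ha).
#' @export
predict_biomass_components <- function(bas, th, params = NULL) {
  p <- if (is.null(params)) default_registry()$biomass
       else if (!is.null(params$biomass)) params$biomass
       else params
  if (!all(c("root", "stem", "branch", "leaf") %in% names(p)))
    stop("biomass parameters must name root, stem, branch and leaf",
         call. = FALSE)
  if (any(!is.finite(bas)) || any(bas <= 0)) stop("`bas` must be > 0", call. = FALSE)
  if (any(!is.finite(th)) || any(th <= 0)) stop("`th` must be > 0", call. = FALSE)
  comp <- lapply(p[c("root", "stem", "branch", "leaf")],
                 function(e) exp(e$e0) * bas^e$e1 * th^e$e2)
  out <- as.data.frame(comp)
  out$crown <- out$branch + out$leaf
  out$aboveground <- out$stem + out$crown
  out$total <- out$root + out$aboveground
  out
}

#' Carbon stocks from biomass components
#'
#' Multiplies each biomass component by its carbon fraction (published
#' values: root 0.52, stem 0.47, branch 0.51, leaf 0.52 t C per t biomass)
#' and re-sums the aggregates from the carbon components.
#'
#' @param biomass A data.frame as returned by
#'   [predict_biomass_components()], or any data.frame with non-negative
#'   `root`, `stem`, `branch`, `leaf` columns.
#' @param fractions Carbon fractions (named list) or a full registry.
#' @return A data.frame with the same seven columns, in t C/ha.
#' @export
carbon_from_biomass <- function(biomass, fractions = NULL) {
  f <- get_params(fractions, "carbon_fractions", "stem")
  comps <- c("root", "stem", "branch", "leaf")
  if (!all(comps %in% names(biomass)))
    stop("`biomass` must have root, stem, branch and leaf columns",
         call. = FALSE)
  if (any(unlist(biomass[comps]) < 0))
    stop("biomass must be >= 0", call. = FALSE)
  out <- as.data.frame(Map(function(w, fr) w * fr, biomass[comps], f[comps]))
  out$crown <- out$branch + out$leaf
  out$aboveground <- out$stem + out$crown
  out$total <- out$root + out$aboveground
  out
}

#' Quadratic mean diameter from basal area and SDI
#'
#' Closed-form link used by the simulator: combining the definition of basal
#' area with the SDI standardization gives
#' \deqn{Dg = \left(\frac{40000\, D_0^{b_1}\, BAS}{\pi\, SDI}\right)^{1/(2+b_1)}.}
#'
#' @param bas Basal area (m^2/ha), `> 0`.
#' @param sdi Stand density index (trees/ha), `> 0`.
#' @inheritParams max_density
#' @return Quadratic mean diameter in cm.
#' @export
dg_from_bas_sdi <- function(bas, sdi, params = NULL) {
  p <- get_params(params, "self_thinning", "b0")
  if (any(!is.finite(bas)) || any(bas <= 0)) stop("`bas` must be > 0", call. = FALSE)
  if (any(!is.finite(sdi)) || any(sdi <= 0)) stop("`sdi` must be > 0", call. = FALSE)
  if (abs(2 + p$b1) < 1e-6)
    stop("self-thinning slope b1 too close to -2: exponent 1/(2+b1) blows up",
         call. = FALSE)
  (40000 * p$d0_cm^p$b1 * bas / (pi * sdi))^(1 / (2 + p$b1))
}

#' Stems per hectare from basal area and quadratic mean diameter
#'
#' From the definition of stand basal area,
#' \deqn{N = 40000\, BAS / (\pi\, Dg^2).}
#'
#' @param bas Basal area (m^2/ha), `> 0`.
#' @param dg Quadratic mean diameter (cm), `> 0`.
#' @return Stems per hectare.
#' @export
n_from_bas_dg <- function(bas, dg) {
  if (any(!is.finite(bas)) || any(bas <= 0)) stop("`bas` must be > 0", call. = FALSE)
  if (any(!is.finite(dg)) || any(dg <= 0)) stop("`dg` must be > 0", call. = FALSE)
  40000 * bas / (pi * dg^2)
}

#' Goodness-of-fit statistics
#'
#' The three criteria used throughout the model family:
#' \itemize{
#'   \item `adj_r2`: \eqn{1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2}. Note this
#'     is the plain coefficient-of-determination ratio, without a
#'     degrees-of-freedom adjustment; the name follows the convention of the
#'     published parameter tables, and the statistic is implemented exactly
#'     as published.
#'   \item `mae_pct`: \eqn{\sum|y-\hat y| / \sum|y| \times 100}.
#'   \item `rmse_pct`: \eqn{\sqrt{\sum(y-\hat y)^2 / (n-k-1)} / \bar y \times 100},
#'     with the residual degrees of freedom `n - k - 1` in the divisor.
#' }
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @param k Number of fitted parameters; `n > k + 1` is required.
#' @return A list of class `fgym_gof` with `adj_r2`, `mae_pct`, `rmse_pct`,
#'   `n`, `k`.
#' @export
goodness_of_fit <- function(observed, predicted, k) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  n <- length(observed)
  if (n <= k + 1)
    stop("need n > k + 1 observations (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("observed values are all equal: R-squared denominator degenerate",
         call. = FALSE)
  if (sum(abs(observed)) == 0 || mean(observed) == 0)
    stop("degenerate denominator for percentage errors", call. = FALSE)
  res <- observed - predicted
  structure(list(
    adj_r2   = 1 - sum(res^2) / ss_tot,
    mae_pct  = sum(abs(res)) / sum(abs(observed)) * 100,
    rmse_pct = sqrt(sum(res^2) / (n - k - 1)) / mean(observed) * 100,
    n = n, k = k), class = "fgym_gof")
}

#' @export
print.fgym_gof <- function(x, ...) {
  cat(sprintf("adjR2 = %.4f  MAE%% = %.2f  RMSE%% = %.2f  (n = %d, k = %d)\n",
              x$adj_r2, x$mae_pct, x$rmse_pct, x$n, x$k))
  invisible(x)
}
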