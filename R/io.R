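#' Read and validate a plot table
#'
#' Reads an inventory-plot CSV (columns `plot_id`, `age_yr`, `th_m`,
#' `dg_cm`, `n_ha`, `bas_m2ha`, `vol_m3ha`, `mai`; extra columns such as
#' `sci_m` or `stage` are kept) and checks the record invariants: all
#' quantities positive, Dg at or above the 5-cm inventory calliper limit,
#' and basal area consistent with stem count and Dg
#' (\eqn{BAS = N \pi Dg^2/40000}) within 5 percent.
#'
#' @param path CSV file path.
#' @param check_consistency Verify the basal-area identity (default `TRUE`).
#' @return The validated data.frame.
#' @export
read_plots <- function(path, check_consistency = TRUE) {
  validate_plots(read.csv(path), check_consistency = check_consistency)
}

#' @rdname read_plots
#' @param plots A plot data.frame to validate in place.
#' @export
validate_plots <- function(plots, check_consistency = TRUE) {
  required <- c("plot_id", "age_yr", "th_m", "dg_cm", "n_ha", "bas_m2ha",
                "vol_m3ha", "mai")
  miss <- setdiff(required, names(plots))
  if (length(miss))
    stop("plot table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  num <- setdiff(required, "plot_id")
  vals <- as.matrix(plots[num])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all plot variables must be positive and finite", call. = FALSE)
  if (any(plots$dg_cm < 5 - 1e-9))
    stop("dg_cm below the 5 cm inventory calliper limit in row(s): ",
         paste(utils::head(which(plots$dg_cm < 5 - 1e-9), 5), collapse = ", "),
         call. = FALSE)
  if (check_consistency) {
    implied <- plots$n_ha * pi / 40000 * plots$dg_cm^2
    rel <- abs(implied - plots$bas_m2ha) / plots$bas_m2ha
    if (any(rel > 0.05))
      stop("basal area inconsistent with (n_ha, dg_cm) by more than 5% in ",
           "row(s): ", paste(utils::head(which(rel > 0.05), 5),
                             collapse = ", "), call. = FALSE)
  }
  plots
}

#' Write a plot table to CSV
#'
#' @param plots A plot data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plots <- function(plots, path) {
  write.csv(plots, path, row.names = FALSE)
  invisible(path)
}

# canonical yield-table column order
.yield_columns <- c("scenario", "stage", "sci_m", "dg_cm", "bas_m2ha",
                    "num_ha", "vol_total", "vol_bark", "vol_large",
                    "vol_middle", "vol_small", "vol_short", "vol_fuel",
                    "c_total", "c_root", "c_stem", "c_branch", "c_leaf",
                    "c_non", "c_comm")

#' Write a scenario yield table to CSV
#'
#' Writes the output of [scenario_grid()] with a deterministic column order.
#' Values are written at full precision by default; `digits = 1` rounds to
#' one decimal (the precision used by published yield tables) at write time
#' only.
#'
#' @param rows Data.frame from [scenario_grid()]; must be non-empty.
#' @param path Output path.
#' @param digits Optional rounding applied at write time.
#' @return `path`, invisibly.
#' @export
write_yield_table <- function(rows, path, digits = NULL) {
  if (is.null(rows) || nrow(rows) == 0L)
    stop("refusing to write an empty yield table", call. = FALSE)
  miss <- setdiff(.yield_columns, names(rows))
  if (length(miss))
    stop("yield table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- rows[.yield_columns]
  if (!is.null(digits)) {
    numcols <- vapply(out, is.numeric, logical(1))
    numcols[names(out) %in% c("stage", "sci_m")] <- FALSE
    out[numcols] <- lapply(out[numcols], round, digits = digits)
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Compare a simulated scenario grid with a published reference table
#'
#' Re-simulates every row of a reference yield table (the packaged default
#' is the published age-80 simulation table for Dg, basal area, stem count,
#' total volume and total/component carbon) and reports per-cell deviations.
#' The comparison tolerance is quantization-aware: a predicted cell agrees
#' with a printed cell when the absolute difference is at most
#' `rel_tol` times the printed value plus half of the printed resolution
#' (0.05 for one-decimal columns, 0.5 for stem counts) — the printed
#' parameters are themselves rounded, and the printed cells are quantized.
#'
#' @param reference Data.frame of published values, or `NULL` for the
#'   packaged reference table.
#' @param age Simulation age (yr), default 80.
#' @param registry Parameter registry.
#' @param rel_tol Relative tolerance component, default 0.025.
#' @return A data.frame with one row per (scenario row, column) pair:
#'   predicted, published, deviation, tolerance and a pass flag. Attribute
#'   `all_pass` summarizes the table.
#' @export
verify_published_simulations <- function(reference = NULL, age = 80,
                                         registry = NULL, rel_tol = 0.025) {
  if (is.null(registry)) registry <- default_registry()
  if (is.null(reference)) {
    path <- system.file("extdata", "published_simulations_age80.csv",
                        package = "fgym", mustWork = TRUE)
    reference <- read.csv(path)
  }
  cols <- c(dg_cm = "dg_cm", bas_m2ha = "bas_m2ha", num_ha = "num_ha",
            vol_total = "vol_m3ha", c_total = "c_total", c_root = "c_root",
            c_stem = "c_stem", c_branch = "c_branch", c_leaf = "c_leaf")
  half_unit <- c(dg_cm = 0.05, bas_m2ha = 0.05, num_ha = 0.5,
                 vol_m3ha = 0.05, c_total = 0.05, c_root = 0.05,
                 c_stem = 0.05, c_branch = 0.05, c_leaf = 0.05)
  out <- list()
  for (i in seq_len(nrow(reference))) {
    r <- reference[i, ]
    m <- if (r$scenario == "Base") NA_real_
         else as.numeric(sub("MAI", "", r$scenario))
    g <- scenario_grid(sci = r$sci_m, mai = m, stages = r$stage, age = age,
                       registry = registry)
    for (j in seq_along(cols)) {
      pred_col <- names(cols)[j]; ref_col <- cols[[j]]
      pred <- g[[pred_col]]; pub <- r[[ref_col]]
      tol <- rel_tol * abs(pub) + half_unit[[ref_col]]
      out[[length(out) + 1L]] <- data.frame(
        scenario = r$scenario, stage = r$stage, sci_m = r$sci_m,
        quantity = ref_col, predicted = pred, published = pub,
        deviation = pred - pub, tolerance = tol,
        pass = abs(pred - pub) <= tol)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "all_pass") <- all(res$pass)
  res
}
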