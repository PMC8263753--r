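# Per-pressure statistics of the gQOIs: group mean +/- s.e.m, ordinary
# least-squares regression against transvalvular pressure with a slope
# t-test, the degenerate constant model, and summary-table assembly with
# left/right leaflets pooled.

#' Mean and standard error of the mean
#'
#' @param values numeric vector, length >= 2.
#' @return List with `mean`, `sem` (sample sd with n-1 denominator over
#'   sqrt(n)), and `n`.
#' @export
group_mean_sem <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) {
    stop("insufficient data: need at least 2 values for a mean +/- s.e.m")
  }
  list(mean = mean(values), sem = sd(values) / sqrt(length(values)),
       n = length(values))
}

#' Ordinary least-squares regression of a gQOI against pressure
#'
#' Fits `value = intercept + slope * TVP` over all individual points, with
#' standard errors from the usual OLS variance estimator and a two-sided
#' p-value for the hypothesis that the slope is zero (t-distribution with
#' n - 2 degrees of freedom).
#'
#' @param points data frame with columns `tvp_mmHg` and `value`.
#' @param weights optional nonnegative case weights (e.g. group sizes when
#'   fitting to per-pressure means).
#' @return An object of class `regression_result` with `model = "linear"`,
#'   `intercept`, `intercept_sem`, `slope`, `slope_sem`, `p_value`,
#'   `n_points`.
#' @export
fit_linear_vs_tvp <- function(points, weights = NULL) {
  tvp <- points$tvp_mmHg
  y <- points$value
  if (length(y) < 3) stop("insufficient data: need at least 3 points")
  if (length(unique(tvp)) < 2) {
    stop("design-degeneracy error: all points share one transvalvular pressure")
  }
  fit <- if (is.null(weights)) {
    lm(y ~ tvp)
  } else {
    lm(y ~ tvp, weights = weights)
  }
  sm <- suppressWarnings(summary(fit))$coefficients  # noiseless fits warn
  structure(list(model = "linear",
                 intercept = sm[1, 1], intercept_sem = sm[1, 2],
                 slope = sm[2, 1], slope_sem = sm[2, 2],
                 p_value = sm[2, 4], n_points = length(y)),
            class = "regression_result")
}

#' Degenerate constant regression (zero slope)
#'
#' Used for quantities whose pressure trend cannot be resolved (leaflet
#' thickness, tilt angle): the fit is the grand mean over all individual
#' points, with no slope test.
#'
#' @param points data frame with a `value` column.
#' @return A `regression_result` with `model = "constant"`, `slope = 0`, and
#'   `p_value = NA`.
#' @export
fit_constant <- function(points) {
  y <- points$value
  if (length(y) < 2) stop("insufficient data: need at least 2 points")
  structure(list(model = "constant",
                 intercept = mean(y), intercept_sem = sd(y) / sqrt(length(y)),
                 slope = 0, slope_sem = NA_real_, p_value = NA_real_,
                 n_points = length(y)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  if (x$model == "constant") {
    cat(sprintf("<regression_result> constant: %.4g +/- %.3g (n = %d)\n",
                x$intercept, x$intercept_sem, x$n_points))
  } else {
    cat(sprintf(paste0("<regression_result> linear: intercept %.4g +/- %.3g, ",
                       "slope %.4g +/- %.3g per mmHg, p = %.3g (n = %d)\n"),
                x$intercept, x$intercept_sem, x$slope, x$slope_sem,
                x$p_value, x$n_points))
  }
  invisible(x)
}

# default model assignment per gQOI
default_model_map <- function() {
  c(L_FE_bar = "linear", L_BA_bar = "linear", H_bar = "linear",
    L_gamma_um = "linear", w_bar_x100 = "constant", beta_deg = "constant")
}

#' Build the per-pressure gQOI summary table
#'
#' Pools the left and right leaflets into one group (each valve contributes
#' two values to pooled rows), reports mean +/- s.e.m per transvalvular
#' pressure, and fits the regression model per row: linear for normalized
#' free-edge/basal lengths, normalized height and perimeter; constant for
#' normalized thickness and tilt. Normalized thickness is tabulated as
#' `w_bar * 100`.
#'
#' @param records list of `gqoi_record` (or a tidy tibble from
#'   [gqoi_to_tibble()]).
#' @param model_map named character vector gQOI -> `"linear"`/`"constant"`.
#' @return An object of class `gqoi_table` with tibbles `stats`
#'   (`gqoi, group, tvp_mmHg, mean, sem, n`) and `regression`.
#' @export
build_table1 <- function(records, model_map = default_model_map()) {
  df <- if (inherits(records, "data.frame")) records else gqoi_to_tibble(records)
  if (length(unique(df$tvp_mmHg)) < 2) {
    stop("completeness error: records must cover at least 2 pressures")
  }
  df <- df[order(df$sample_id, df$leaflet), ]

  per_valve <- unique(df[, c("sample_id", "tvp_mmHg", "H_bar", "w_bar",
                             "beta_deg", "L_gamma_um")])
  rows <- list(
    list(gqoi = "L_FE_bar", group = "anterior",
         data = data.frame(tvp_mmHg = df$tvp_mmHg[df$leaflet == "anterior"],
                           value = df$L_FE_bar[df$leaflet == "anterior"])),
    list(gqoi = "L_FE_bar", group = "left_right",
         data = data.frame(tvp_mmHg = df$tvp_mmHg[df$leaflet != "anterior"],
                           value = df$L_FE_bar[df$leaflet != "anterior"])),
    list(gqoi = "L_BA_bar", group = "anterior",
         data = data.frame(tvp_mmHg = df$tvp_mmHg[df$leaflet == "anterior"],
                           value = df$L_BA_bar[df$leaflet == "anterior"])),
    list(gqoi = "L_BA_bar", group = "left_right",
         data = data.frame(tvp_mmHg = df$tvp_mmHg[df$leaflet != "anterior"],
                           value = df$L_BA_bar[df$leaflet != "anterior"])),
    list(gqoi = "H_bar", group = "valve",
         data = data.frame(tvp_mmHg = per_valve$tvp_mmHg,
                           value = per_valve$H_bar)),
    list(gqoi = "w_bar_x100", group = "valve",
         data = data.frame(tvp_mmHg = per_valve$tvp_mmHg,
                           value = per_valve$w_bar * 100)),
    list(gqoi = "beta_deg", group = "valve",
         data = data.frame(tvp_mmHg = per_valve$tvp_mmHg,
                           value = per_valve$beta_deg)),
    list(gqoi = "L_gamma_um", group = "valve",
         data = data.frame(tvp_mmHg = per_valve$tvp_mmHg,
                           value = per_valve$L_gamma_um)))

  stats_rows <- list(); reg_rows <- list()
  for (rw in rows) {
    dat <- rw$data[is.finite(rw$data$value), , drop = FALSE]
    if (nrow(dat) == 0) {
      stop("completeness error: no data for ", rw$gqoi, " / ", rw$group)
    }
    for (tv in sort(unique(dat$tvp_mmHg))) {
      gs <- group_mean_sem(dat$value[dat$tvp_mmHg == tv])
      stats_rows[[length(stats_rows) + 1]] <-
        tibble(gqoi = rw$gqoi, group = rw$group, tvp_mmHg = tv,
               mean = gs$mean, sem = gs$sem, n = gs$n)
    }
    model <- model_map[[rw$gqoi]]
    fitres <- if (identical(model, "constant")) {
      fit_constant(dat)
    } else {
      fit_linear_vs_tvp(dat)
    }
    scale <- if (rw$gqoi == "L_gamma_um") 1 else 100
    reg_rows[[length(reg_rows) + 1]] <-
      tibble(gqoi = rw$gqoi, group = rw$group, model = fitres$model,
             intercept = fitres$intercept, intercept_sem = fitres$intercept_sem,
             slope = fitres$slope, slope_sem = fitres$slope_sem,
             slope_display = fitres$slope * scale,
             slope_sem_display = fitres$slope_sem * scale,
             slope_scale = scale, p_value = fitres$p_value,
             n_points = fitres$n_points)
  }
  structure(list(stats = do.call(rbind, stats_rows),
                 regression = do.call(rbind, reg_rows)),
            class = "gqoi_table")
}

#' @export
print.gqoi_table <- function(x, ...) {
  cat("<gqoi_table>\n")
  print(format_gqoi_table(x))
  invisible(x)
}

#' Format a gQOI table at printed precision
#'
#' Two decimals for normalized quantities and p-values, integers for
#' micrometres and degrees; slopes are shown multiplied by 100 except for
#' the perimeter row. Machine-readable full precision stays in the
#' `gqoi_table` object itself.
#'
#' @param table a `gqoi_table`.
#' @return A tibble with one row per gQOI and group.
#' @export
format_gqoi_table <- function(table) {
  fmt <- function(gq, v) {
    ifelse(rep_len(gq %in% c("beta_deg", "L_gamma_um"), length(v)),
           sprintf("%.0f", v), sprintf("%.2f", v))
  }
  st <- table$stats
  wide <- unique(st[, c("gqoi", "group")])
  for (tv in sort(unique(st$tvp_mmHg))) {
    col <- paste0(tv, "_mmHg")
    wide[[col]] <- vapply(seq_len(nrow(wide)), function(i) {
      row <- st[st$gqoi == wide$gqoi[i] & st$group == wide$group[i] &
                  st$tvp_mmHg == tv, ]
      if (nrow(row) == 0) return(NA_character_)
      paste0(fmt(wide$gqoi[i], row$mean), " ± ", fmt(wide$gqoi[i], row$sem))
    }, character(1))
  }
  rg <- table$regression
  key <- paste(rg$gqoi, rg$group)
  ord <- match(paste(wide$gqoi, wide$group), key)
  wide$intercept <- paste0(fmt(wide$gqoi, rg$intercept[ord]), " ± ",
                           fmt(wide$gqoi, rg$intercept_sem[ord]))
  wide$slope_display <- ifelse(rg$model[ord] == "constant", "NA",
                               sprintf("%.2f ± %.2f",
                                       rg$slope_display[ord],
                                       rg$slope_sem_display[ord]))
  wide$p_value <- ifelse(is.na(rg$p_value[ord]), "NA",
                         sprintf("%.2f", rg$p_value[ord]))
  as_tibble(wide)
}

#' Anterior to left/right size ratio at one pressure
#'
#' Ratio of the anterior per-pressure mean to the pooled left & right mean
#' for the normalized free-edge or basal-attachment length.
#'
#' @param table a `gqoi_table` (computed or [published_gqoi_table()]).
#' @param quantity `"free_edge"` or `"basal"`.
#' @param tvp pressure (mmHg).
#' @return The ratio (full precision; report output rounds to 2 decimals).
#' @export
anterior_ratio <- function(table, quantity = c("free_edge", "basal"), tvp) {
  quantity <- match.arg(quantity)
  gq <- if (quantity == "free_edge") "L_FE_bar" else "L_BA_bar"
  st <- table$stats
  num <- st$mean[st$gqoi == gq & st$group == "anterior" & st$tvp_mmHg == tvp]
  den <- st$mean[st$gqoi == gq & st$group == "left_right" & st$tvp_mmHg == tvp]
  if (length(num) != 1 || length(den) != 1) {
    stop("missing table rows for ", gq, " at ", tvp, " mmHg")
  }
  if (den == 0) stop("arithmetic error: zero denominator")
  num / den
}

#' Relative change of the valve perimeter between two pressures
#'
#' @param table a `gqoi_table`.
#' @param tvp_from,tvp_to pressures (mmHg).
#' @return Percent change `100 * (mean_to - mean_from) / mean_from`.
#' @export
perimeter_change <- function(table, tvp_from, tvp_to) {
  st <- table$stats
  m0 <- st$mean[st$gqoi == "L_gamma_um" & st$tvp_mmHg == tvp_from]
  m1 <- st$mean[st$gqoi == "L_gamma_um" & st$tvp_mmHg == tvp_to]
  if (length(m0) != 1 || length(m1) != 1) stop("missing perimeter rows")
  if (m0 == 0) stop("arithmetic error: zero baseline perimeter")
  100 * (m1 - m0) / m0
}

#' Published per-pressure reference values for the murine pulmonary valve
#'
#' Printed per-pressure means +/- s.e.m (n = 3, 5, 3 valves at 10, 20,
#' 30 mmHg; left and right leaflets pooled) and the printed regression
#' parameters for each gQOI, as shipped in `extdata`. These are the
#' reference values against which recomputed derived quantities (size
#' ratios, perimeter change, slopes) are checked.
#'
#' @return A `gqoi_table` with `stats` and `regression` tibbles.
#' @export
published_gqoi_table <- function() {
  st <- read.csv(system.file("extdata", "murine_pv_gqoi_means.csv",
                             package = "valvemorph"))
  rg <- read.csv(system.file("extdata", "murine_pv_gqoi_regression.csv",
                             package = "valvemorph"))
  rg$slope <- rg$slope_display / rg$slope_scale
  rg$slope_sem <- rg$slope_sem_display / rg$slope_scale
  structure(list(stats = as_tibble(st), regression = as_tibble(rg)),
            class = "gqoi_table")
}
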