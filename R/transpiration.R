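# Whole-canopy transpiration regression modelling.
#
# The canopy transpiration model regresses measured whole-canopy water loss
# y (mmol H2O s^-1) on x1 = total direct light (umol m^-2 s^-1),
# x2 = air VPD (hPa) and x3 = TCLI (%). The selected form is the
# intercept-free pure quadratic
#   y = a x1^2 + b x2^2 + c x3^2 + d x1 x2 + e x1 x3 + f x2 x3
# so the prediction at the origin is exactly zero (no light, no VPD, no
# interception -> no transpiration). Linear candidates carry an intercept.

MOLAR_MASS_WATER <- 18.015 # g mol^-1

tc_term_names <- function(form, variables) {
  v <- sort(variables)
  if (form == "quadratic") {
    sq <- paste0(v, "_sq")
    cross <- if (length(v) > 1) {
      cmb <- utils::combn(v, 2)
      paste0(cmb[1, ], "_", cmb[2, ])
    } else {
      character(0)
    }
    c(sq, cross)
  } else {
    v
  }
}

tc_design <- function(data, form, variables) {
  v <- sort(variables)
  cols <- lapply(v, function(nm) data[[nm]])
  names(cols) <- v
  if (form == "quadratic") {
    terms <- lapply(v, function(nm) cols[[nm]]^2)
    names(terms) <- paste0(v, "_sq")
    if (length(v) > 1) {
      cmb <- utils::combn(v, 2)
      for (j in seq_len(ncol(cmb))) {
        terms[[paste0(cmb[1, j], "_", cmb[2, j])]] <-
          cols[[cmb[1, j]]] * cols[[cmb[2, j]]]
      }
    }
  } else {
    terms <- cols
  }
  do.call(cbind, terms)
}

#' Construct a canopy transpiration model
#'
#' Usually produced by [fit_tc_model()] or [tc_printed_models()]; this
#' constructor also accepts externally estimated coefficients.
#'
#' @param form `"quadratic"` (pure quadratic, intercept-free) or `"linear"`
#'   (intercept plus linear terms).
#' @param variables Character subset of `c("x1", "x2", "x3")`:
#'   x1 = total direct light (umol m^-2 s^-1), x2 = air VPD (hPa),
#'   x3 = TCLI (%).
#' @param coefficients Named numeric vector over the model's terms (for the
#'   three-variable quadratic: `x1_sq, x2_sq, x3_sq, x1_x2, x1_x3, x2_x3`;
#'   linear models include `intercept`).
#' @param r_squared Coefficient of determination against the fitting data,
#'   if known.
#' @return Object of class `tc_model`.
#' @export
tc_model <- function(form = c("quadratic", "linear"),
                     variables = c("x1", "x2", "x3"),
                     coefficients, r_squared = NA_real_) {
  form <- match.arg(form)
  variables <- sort(match.arg(variables, c("x1", "x2", "x3"),
    several.ok = TRUE
  ))
  expected <- tc_term_names(form, variables)
  if (form == "linear") expected <- c("intercept", expected)
  if (!setequal(names(coefficients), expected)) {
    stop(
      "coefficients must be named exactly: ",
      paste(expected, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      form = form, variables = variables,
      coefficients = coefficients[expected], r_squared = r_squared
    ),
    class = "tc_model"
  )
}

#' @export
print.tc_model <- function(x, ...) {
  cat(sprintf(
    "canopy transpiration model: %s in (%s), R^2 = %s\n",
    x$form, paste(x$variables, collapse = ", "),
    ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared))
  ))
  print(signif(x$coefficients, 6))
  invisible(x)
}

#' Fit a canopy transpiration regression
#'
#' Least-squares fit of the chosen form on observations of whole-canopy
#' transpiration. The quadratic form has no intercept and no linear terms;
#' the linear form includes an intercept.
#'
#' @param observations `data.frame` with columns `y` (mmol H2O s^-1) and the
#'   requested predictor columns among `x1`, `x2`, `x3`.
#' @inheritParams tc_model
#' @return A fitted `tc_model` with `r_squared` computed against
#'   `observations` (centred R^2 for linear fits, uncentred for the
#'   intercept-free quadratic).
#' @export
fit_tc_model <- function(observations, form = c("quadratic", "linear"),
                         variables = c("x1", "x2", "x3")) {
  form <- match.arg(form)
  variables <- sort(match.arg(variables, c("x1", "x2", "x3"),
    several.ok = TRUE
  ))
  missing_cols <- setdiff(c("y", variables), names(observations))
  if (length(missing_cols)) {
    stop("observations lack columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  x <- tc_design(observations, form, variables)
  n_par <- ncol(x) + (form == "linear")
  if (nrow(x) < n_par) {
    stop(sprintf(
      "underdetermined fit: %d observations for %d terms",
      nrow(x), n_par
    ), call. = FALSE)
  }
  y <- observations$y
  fit <- if (form == "quadratic") {
    stats::lm(y ~ x - 1)
  } else {
    stats::lm(y ~ x)
  }
  if (any(is.na(stats::coef(fit)))) {
    stop("underdetermined fit: rank-deficient design", call. = FALSE)
  }
  cf <- stats::coef(fit)
  names(cf) <- if (form == "linear") {
    c("intercept", colnames(x))
  } else {
    colnames(x)
  }
  pred <- stats::fitted(fit)
  ss_res <- sum((y - pred)^2)
  ss_tot <- if (form == "quadratic") sum(y^2) else sum((y - mean(y))^2)
  tc_model(form, variables, cf, r_squared = 1 - ss_res / ss_tot)
}

#' Predict canopy transpiration
#'
#' Evaluates the stored polynomial. Raw negative predictions (possible when
#' extrapolating off the calibration domain) are clamped to zero; the return
#' value carries a `clamped` attribute flagging the affected entries.
#'
#' @param model A `tc_model`.
#' @param x1 Total direct light, umol m^-2 s^-1.
#' @param x2 Air VPD. In hPa by default; set `vpd_unit = "kPa"` to convert
#'   at the boundary.
#' @param x3 TCLI, %.
#' @param vpd_unit Unit of the `x2` argument.
#' @return Predicted transpiration in mmol H2O s^-1 (>= 0), with attribute
#'   `clamped` (logical vector).
#' @export
#' @examples
#' m <- tc_printed_models()[["jun20"]]
#' predict_tc(m, 0, 1, 0) # the bare x2^2 coefficient
predict_tc <- function(model, x1 = 0, x2 = 0, x3 = 0,
                       vpd_unit = c("hPa", "kPa")) {
  vpd_unit <- match.arg(vpd_unit)
  if (vpd_unit == "kPa") x2 <- x2 * 10
  n <- max(length(x1), length(x2), length(x3))
  data <- data.frame(
    x1 = rep_len(x1, n), x2 = rep_len(x2, n), x3 = rep_len(x3, n)
  )
  extra <- setdiff(model$variables, c("x1", "x2", "x3"))
  if (length(extra)) stop("unknown model variables", call. = FALSE)
  x <- tc_design(data, model$form, model$variables)
  cf <- model$coefficients
  y <- if (model$form == "linear") {
    cf[["intercept"]] + drop(x %*% cf[colnames(x)])
  } else {
    drop(x %*% cf[colnames(x)])
  }
  clamped <- y < 0
  if (any(clamped)) {
    warning(sprintf(
      "%d negative prediction(s) clamped to 0 (off calibration domain)",
      sum(clamped)
    ), call. = FALSE)
    y[clamped] <- 0
  }
  attr(y, "clamped") <- clamped
  y
}

#' Published day-specific transpiration coefficient sets
#'
#' Three calibration-day coefficient sets for the three-variable quadratic
#' model (x1 = direct light, x2 = VPD in hPa, x3 = TCLI). The third set as
#' published ends with two x1*x2 cross terms, an apparent transcription slip;
#' `correct_typo = TRUE` reassigns the final coefficient to the x2*x3 term,
#' completing the canonical six-term form. As published, the duplicated
#' x1*x2 coefficients are summed into the single x1*x2 term and x2*x3 is 0.
#'
#' @param correct_typo Return the corrected 1 August variant.
#' @return Named list of `tc_model` objects: `jun20`, `jul02`, `aug01`.
#' @export
tc_printed_models <- function(correct_typo = FALSE) {
  mk <- function(a, b, c, d, e, f, r2) {
    tc_model(
      "quadratic", c("x1", "x2", "x3"),
      c(
        x1_sq = a, x2_sq = b, x3_sq = c,
        x1_x2 = d, x1_x3 = e, x2_x3 = f
      ),
      r_squared = r2
    )
  }
  aug01 <- if (correct_typo) {
    mk(-5.0084e-09, 0.00716466, 4.62933e-06,
      -2.40068e-06, 1.60601e-07, -0.000160624,
      r2 = 0.98
    )
  } else {
    # as published: the -0.000160624 coefficient sits on a second x1*x2 term
    mk(-5.0084e-09, 0.00716466, 4.62933e-06,
      -2.40068e-06 + -0.000160624, 1.60601e-07, 0,
      r2 = 0.98
    )
  }
  list(
    jun20 = mk(7.62563e-09, 0.0104358, 1.49096e-06,
      -7.72001e-06, 1.07106e-07, -0.000129436,
      r2 = 0.96
    ),
    jul02 = mk(-2.88612e-08, -0.0038447, -3.08502e-06,
      4.12417e-05, -7.19364e-07, 0.00044962,
      r2 = 0.93
    ),
    aug01 = aug01
  )
}

#' Convert a transpiration rate from mmol/s to g/h
#'
#' @param y Transpiration in mmol H2O s^-1 (>= 0).
#' @return Rate in g H2O h^-1 (`y * 18.015 * 3600 / 1000`); 1 g of liquid
#'   water is 1 mL, so g/h and mL/h are interchangeable.
#' @export
convert_rate <- function(y) {
  if (any(y < 0)) stop("rate must be >= 0", call. = FALSE)
  y * MOLAR_MASS_WATER * 3600 / 1000
}

#' Daily water use on per-vine, per-area and per-leaf-area bases
#'
#' Scales a mean dawn-to-dusk transpiration rate to the daily totals used in
#' irrigation reasoning.
#'
#' @param mean_rate_g_per_h Mean diurnal canopy water use, g h^-1.
#' @param day_length_h Day length in hours.
#' @param density_per_ha Planting density, vines ha^-1.
#' @param leaf_area_m2 Leaf area per vine, m^2.
#' @return Object of class `daily_water_use`: list with `litres_per_vine`
#'   (L vine^-1 day^-1), `mm_per_day` (area basis) and `litres_per_m2_leaf`.
#' @export
#' @examples
#' daily_totals(229, 15 + 38 / 60, 4000, 3.37)
daily_totals <- function(mean_rate_g_per_h, day_length_h,
                         density_per_ha = 4000, leaf_area_m2 = 3.37) {
  stopifnot(
    mean_rate_g_per_h > 0, day_length_h > 0,
    density_per_ha > 0, leaf_area_m2 > 0
  )
  l_vine <- mean_rate_g_per_h * day_length_h / 1000
  structure(
    list(
      litres_per_vine = l_vine,
      mm_per_day = l_vine * density_per_ha / 10000,
      litres_per_m2_leaf = l_vine / leaf_area_m2
    ),
    class = "daily_water_use"
  )
}

#' @export
print.daily_water_use <- function(x, ...) {
  cat(sprintf(
    "daily water use: %.2f L/vine, %.2f mm/day, %.2f L/m2 leaf\n",
    x$litres_per_vine, x$mm_per_day, x$litres_per_m2_leaf
  ))
  invisible(x)
}

#' Compare candidate transpiration models
#'
#' Fits every linear and quadratic candidate over variable subsets of size
#' `min_vars`..3 and ranks them by R^2, the selection workflow that singled
#' out the quadratic three-variable model.
#'
#' @param observations As for [fit_tc_model()].
#' @param min_vars Smallest subset size to consider.
#' @return `data.frame` with columns `form`, `variables`, `n_terms`,
#'   `r_squared`, `best` (logical; the max-R^2 row), sorted by decreasing
#'   R^2. Candidates whose fit fails are kept with `NA` R^2.
#' @export
compare_tc_models <- function(observations, min_vars = 1) {
  vars <- c("x1", "x2", "x3")
  out <- list()
  for (k in seq(min_vars, 3)) {
    for (subset_idx in seq_len(ncol(utils::combn(3, k)))) {
      v <- vars[utils::combn(3, k)[, subset_idx]]
      for (form in c("linear", "quadratic")) {
        r2 <- tryCatch(
          fit_tc_model(observations, form, v)$r_squared,
          error = function(e) NA_real_
        )
        out[[length(out) + 1]] <- data.frame(
          form = form,
          variables = paste(v, collapse = "+"),
          n_terms = length(tc_term_names(form, v)) + (form == "linear"),
          r_squared = r2
        )
      }
    }
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(-tab$r_squared), ]
  tab$best <- !is.na(tab$r_squared) &
    tab$r_squared == max(tab$r_squared, na.rm = TRUE)
  rownames(tab) <- NULL
  tab
}

#' Transpiration time series and daily integral
#'
#' Evaluates a `tc_model` over an aligned sub-daily grid of light, VPD and
#' TCLI, and integrates the rate over daylight by the trapezoidal rule.
#'
#' @param model A `tc_model`.
#' @param tcli_profile A [tcli_profile()] data frame.
#' @param weather_subdaily `data.frame` with columns `time` (solar hours,
#'   must match the profile grid), `direct_light` (umol m^-2 s^-1) and
#'   `vpd_hpa`.
#' @param density_per_ha Planting density for the mm conversion.
#' @return List with `series` (data.frame: time, x1, x2, x3, tc_mmol_s,
#'   tc_g_h) and `daily` (list: `litres_per_vine`, `mm_per_day`,
#'   `mean_rate_g_h`, `day_length_h`).
#' @export
tc_series <- function(model, tcli_profile, weather_subdaily,
                      density_per_ha = 4000) {
  if (nrow(tcli_profile) != nrow(weather_subdaily) ||
    max(abs(tcli_profile$time - weather_subdaily$time)) > 1e-6) {
    stop("alignment error: TCLI and weather grids differ", call. = FALSE)
  }
  y <- predict_tc(
    model,
    x1 = weather_subdaily$direct_light,
    x2 = weather_subdaily$vpd_hpa,
    x3 = tcli_profile$tcli_percent
  )
  g_h <- convert_rate(as.numeric(y))
  tt <- tcli_profile$time
  # trapezoidal integral of g/h over hours -> g/day -> L/vine
  litres <- sum(diff(tt) * (head(g_h, -1) + tail(g_h, -1)) / 2) / 1000
  dl <- max(tt) - min(tt)
  list(
    series = data.frame(
      time = tt,
      x1 = weather_subdaily$direct_light,
      x2 = weather_subdaily$vpd_hpa,
      x3 = tcli_profile$tcli_percent,
      tc_mmol_s = as.numeric(y),
      tc_g_h = g_h
    ),
    daily = list(
      litres_per_vine = litres,
      mm_per_day = litres * density_per_ha / 10000,
      mean_rate_g_h = if (dl > 0) litres * 1000 / dl else 0,
      day_length_h = dl
    )
  )
}

#' Serialize / restore a transpiration model as JSON
#'
#' @param model A `tc_model`.
#' @param path File path; for `tc_model_to_json`, omit to return the JSON
#'   string.
#' @return `tc_model_to_json`: the path (or JSON string) invisibly;
#'   `tc_model_from_json`: a `tc_model`.
#' @export
tc_model_to_json <- function(model, path = NULL) {
  doc <- list(
    form = model$form,
    variables = model$variables,
    coefficients = as.list(model$coefficients),
    r_squared = model$r_squared
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) {
    return(invisible(as.character(js)))
  }
  writeLines(js, path)
  invisible(path)
}

#' @rdname tc_model_to_json
#' @export
tc_model_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  tc_model(
    form = doc$form,
    variables = doc$variables,
    coefficients = unlist(doc$coefficients),
    r_squared = if (is.null(doc$r_squared)) NA_real_ else doc$r_squared
  )
}
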