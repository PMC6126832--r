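#' Inefficiency determinants of the hospital stroke-care model
#'
#' The canonical set of covariates entering the inefficiency predictor
#' \eqn{\eta^{(u)}}: specialization, certification, centralization,
#' outpatient-care and control variables, each with a flag saying whether
#' the variable enters on the log scale.
#'
#' @return A tibble with columns `name` (covariate column name in the
#'   panel), `log` (logical, `TRUE` if the design uses `log(x)`), and
#'   `binary` (logical, `TRUE` for 0/1 indicators).
#' @export
#' @examples
#' inefficiency_covariates()
inefficiency_covariates <- function() {
  tibble::tribble(
    ~name,            ~log,  ~binary,
    "Spec",           FALSE, FALSE,
    "MSStrDis",       FALSE, FALSE,
    "NumStrHospDis",  FALSE, FALSE,
    "PatShaStroke",   TRUE,  FALSE,
    "MedDepCon",      FALSE, FALSE,
    "SUCert",         FALSE, TRUE,
    "SUnonCert",      FALSE, TRUE,
    "GPsPerDis",      TRUE,  FALSE,
    "HosBed",         TRUE,  FALSE,
    "PrivHos",        FALSE, TRUE,
    "NonProfHos",     FALSE, TRUE,
    "Teach",          FALSE, TRUE,
    "UniHos",         FALSE, TRUE,
    "ShaI61",         FALSE, FALSE,
    "ShaI64",         FALSE, FALSE,
    "DiagCon",        FALSE, FALSE,
    "ShaTRHOMB",      FALSE, FALSE
  )
}

panel_required_cols <- function() {
  c("hospital_id", "year", "district_id", "exp_mortality",
    "obs_mortality", "obs_readmissions", "physicians", "nurses")
}

restore_panel_attrs <- function(new, old) {
  for (a in c("reference_wave", "offsets", "wave_rates", "excluded")) {
    attr(new, a) <- attr(old, a, exact = TRUE)
  }
  class(new) <- unique(c("hospital_panel", class(new)))
  new
}

#' Construct a validated hospital-year panel
#'
#' Checks the invariants of the observation model: non-negative quality
#' counts, strictly positive staffing, unique (hospital, year) keys,
#' 0/1-coded indicator covariates and shares inside the unit interval.
#' Quality inputs are accepted as non-negative reals (aggregated claims
#' rates may be fractional); integrality is not enforced.
#'
#' @param data A data frame with columns `hospital_id`, `year`,
#'   `district_id`, `exp_mortality`, `obs_mortality`, `obs_readmissions`,
#'   `physicians`, `nurses`, plus any inefficiency covariates (see
#'   [inefficiency_covariates()]).
#' @param reference_wave Reference year for wave effects; defaults to the
#'   earliest year present.
#' @param graph Optional [region_graph()]; if given, every `district_id`
#'   must be a region of the graph.
#' @return A `hospital_panel` tibble.
#' @export
hospital_panel <- function(data, reference_wave = NULL, graph = NULL) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(panel_required_cols(), names(data))
  if (length(missing_cols)) {
    abort(paste0("Panel is missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  dup <- duplicated(data[c("hospital_id", "year")])
  if (any(dup)) {
    keys <- unique(paste0(data$hospital_id[dup], "/", data$year[dup]))
    abort(paste0("Duplicated (hospital_id, year) keys: ",
                 paste(head(keys, 5), collapse = ", ")))
  }
  for (col in c("exp_mortality", "obs_mortality", "obs_readmissions")) {
    if (any(data[[col]] < 0, na.rm = TRUE)) {
      abort(sprintf("`%s` must be non-negative.", col))
    }
  }
  for (col in c("physicians", "nurses")) {
    if (any(data[[col]] <= 0, na.rm = TRUE)) {
      abort(sprintf("`%s` must be strictly positive.", col))
    }
  }
  covs <- inefficiency_covariates()
  for (i in seq_len(nrow(covs))) {
    nm <- covs$name[i]
    if (!nm %in% names(data)) next
    if (covs$binary[i] && !is_binary01(data[[nm]])) {
      abort(sprintf("Covariate `%s` must be coded 0/1.", nm))
    }
    if (nm %in% c("ShaI61", "ShaI64", "DiagCon", "MedDepCon", "MSStrDis",
                  "PatShaStroke", "ShaTRHOMB")) {
      bad <- data[[nm]] < 0 | data[[nm]] > 1
      if (any(bad, na.rm = TRUE)) {
        abort(sprintf("Share `%s` must lie in [0, 1].", nm))
      }
    }
  }
  if (!is.null(graph)) {
    unknown <- setdiff(unique(data$district_id), graph$regions)
    if (length(unknown)) {
      abort(paste0("Districts absent from the region graph: ",
                   paste(head(unknown, 5), collapse = ", ")))
    }
  }
  # rows with missing required fields are dropped, not imputed
  need <- stats::complete.cases(data[panel_required_cols()])
  if (any(!need)) {
    inform(sprintf("Dropped %d rows with missing required fields.", sum(!need)))
    data <- data[need, , drop = FALSE]
  }
  attr(data, "reference_wave") <- as.integer(reference_wave %||% min(data$year))
  attr(data, "offsets") <- numeric(0)
  attr(data, "wave_rates") <- NULL
  attr(data, "excluded") <- NULL
  class(data) <- unique(c("hospital_panel", class(data)))
  data
}

#' Risk-adjusted patient volume as frontier output
#'
#' Builds the log output `y` by scaling each hospital's expected 30-day
#' deaths with the inverse of the wave-level average observed mortality
#' rate: `y = log(exp_mortality / rate_t)`.  The wave rate is the simple
#' (unweighted) average across hospitals of `obs_mortality / volume`; a
#' volume-weighted version (total deaths over total volume) is available
#' behind `weighted = TRUE`, and an externally supplied per-wave rate is
#' accepted instead of raw volumes.
#'
#' Records with `exp_mortality = 0` cannot enter the frontier (the log is
#' undefined); they are retained with `y = NA` and flagged in the
#' `frontier_excluded` column, with a warning giving the count.
#'
#' @param panel A `hospital_panel`.
#' @param wave_rates Named numeric vector of observed mortality rates per
#'   wave (names are years), or `NULL` to compute them from `volume`.
#' @param volume Column name holding the stroke patient volume used to
#'   form per-hospital observed mortality rates.
#' @param weighted Use the volume-weighted wave rate instead of the
#'   unweighted hospital average.
#' @return The panel with columns `y` and `frontier_excluded` added and
#'   the wave rates recorded in `attr(panel, "wave_rates")`.
#' @export
build_risk_adjusted_output <- function(panel, wave_rates = NULL,
                                       volume = NULL, weighted = FALSE) {
  waves <- sort(unique(panel$year))
  if (is.null(wave_rates) && is.null(volume) &&
      "wave_mortality_rate" %in% names(panel)) {
    wr <- dplyr::distinct(panel[, c("year", "wave_mortality_rate")])
    if (anyDuplicated(wr$year)) {
      abort("`wave_mortality_rate` is not constant within waves.")
    }
    wave_rates <- setNames(wr$wave_mortality_rate, wr$year)
  }
  if (is.null(wave_rates)) {
    if (is.null(volume)) {
      abort("Supply either `wave_rates` or a `volume` column name.")
    }
    if (!volume %in% names(panel)) {
      abort(sprintf("Volume column `%s` not found.", volume))
    }
    vol <- panel[[volume]]
    if (any(vol <= 0, na.rm = TRUE)) abort("Patient volumes must be positive.")
    rate <- panel$obs_mortality / vol
    wave_rates <- vapply(waves, function(w) {
      i <- panel$year == w
      if (weighted) sum(panel$obs_mortality[i]) / sum(vol[i]) else mean(rate[i])
    }, numeric(1))
    names(wave_rates) <- waves
  } else {
    if (is.null(names(wave_rates))) {
      abort("`wave_rates` must be named by year.")
    }
    miss <- setdiff(as.character(waves), names(wave_rates))
    if (length(miss)) {
      abort(paste0("No wave mortality rate supplied for: ",
                   paste(miss, collapse = ", ")))
    }
  }
  if (any(!is.finite(wave_rates)) || any(wave_rates <= 0)) {
    bad <- names(wave_rates)[!is.finite(wave_rates) | wave_rates <= 0]
    abort(paste0("Non-positive wave mortality rate for: ",
                 paste(bad, collapse = ", ")))
  }
  r_t <- unname(wave_rates[as.character(panel$year)])
  excl <- panel$exp_mortality <= 0
  if (any(excl)) {
    warn(sprintf(
      "%d records have exp_mortality = 0; flagged and excluded from frontier fitting.",
      sum(excl)))
  }
  out <- panel
  out$y <- ifelse(excl, NA_real_, log(panel$exp_mortality / r_t))
  out$frontier_excluded <- excl
  out <- restore_panel_attrs(out, panel)
  attr(out, "wave_rates") <- wave_rates
  attr(out, "excluded") <- sum(excl)
  out
}

#' Encode exact-zero quality inputs
#'
#' Zero observed deaths or readmissions represent optimal realized
#' quality but break the log transformation.  `mode = "dummy"` applies
#' the indicator-plus-floor device: `D = 1` and `x* = 1` when the count
#' is zero (so `log x* = 0`), else `D = 0`, `x* = x`.  `mode =
#' "rescale_half"` adds 0.5 to every observation before logging and
#' drops the dummies from the design.
#'
#' @param panel A `hospital_panel`.
#' @param mode `"dummy"` (default) or `"rescale_half"`.
#' @return Panel with columns `d_mort`, `d_readm`, `obs_mortality_star`,
#'   `obs_readmissions_star`, `log_mort_star`, `log_readm_star`,
#'   `log_phys`, `log_nurse`.
#' @export
encode_zero_inputs <- function(panel, mode = c("dummy", "rescale_half")) {
  mode <- match.arg(mode)
  for (col in c("obs_mortality", "obs_readmissions")) {
    if (any(panel[[col]] < 0, na.rm = TRUE)) {
      abort(sprintf("`%s` contains negative counts.", col))
    }
  }
  out <- panel
  if (mode == "dummy") {
    out$d_mort <- as.numeric(panel$obs_mortality == 0)
    out$d_readm <- as.numeric(panel$obs_readmissions == 0)
    out$obs_mortality_star <- pmax(panel$obs_mortality, out$d_mort)
    out$obs_readmissions_star <- pmax(panel$obs_readmissions, out$d_readm)
  } else {
    out$d_mort <- 0
    out$d_readm <- 0
    out$obs_mortality_star <- panel$obs_mortality + 0.5
    out$obs_readmissions_star <- panel$obs_readmissions + 0.5
  }
  out$log_mort_star <- log(out$obs_mortality_star)
  out$log_readm_star <- log(out$obs_readmissions_star)
  out$log_phys <- log(panel$physicians)
  out$log_nurse <- log(panel$nurses)
  out <- restore_panel_attrs(out, panel)
  attr(out, "zero_mode") <- mode
  out
}

#' Center panel variables at their grand sample means
#'
#' Replaces each named variable by its deviation from the sample mean
#' and records the offsets so raw values can be recovered exactly with
#' [uncenter_variables()].  With centered output and inputs the frontier
#' intercept is the frontier value at sample means.
#'
#' @param panel A `hospital_panel`.
#' @param vars Character vector of column names to center.
#' @return Panel with the named columns centered; offsets accumulate in
#'   `attr(panel, "offsets")`.
#' @export
center_variables <- function(panel, vars) {
  unknown <- setdiff(vars, names(panel))
  if (length(unknown)) {
    abort(paste0("Unknown variables: ", paste(unknown, collapse = ", ")))
  }
  offsets <- attr(panel, "offsets", exact = TRUE) %||% numeric(0)
  out <- panel
  for (v in vars) {
    x <- out[[v]]
    if (!is.numeric(x)) abort(sprintf("`%s` is not numeric.", v))
    if (is_binary01(x)) {
      warn(sprintf("Centering binary dummy `%s`; its coefficient now refers to deviations from the sample share.", v))
    }
    m <- mean(x, na.rm = TRUE)
    out[[v]] <- x - m
    offsets[v] <- m
  }
  out <- restore_panel_attrs(out, panel)
  attr(out, "offsets") <- offsets
  out
}

#' @rdname center_variables
#' @export
uncenter_variables <- function(panel) {
  offsets <- attr(panel, "offsets", exact = TRUE)
  if (is.null(offsets) || !length(offsets)) return(panel)
  out <- panel
  for (v in names(offsets)) out[[v]] <- out[[v]] + offsets[v]
  out <- restore_panel_attrs(out, panel)
  attr(out, "offsets") <- numeric(0)
  out
}

#' One-call panel preparation for frontier fitting
#'
#' Chains [build_risk_adjusted_output()], [encode_zero_inputs()] and
#' [center_variables()] on the log output and the four continuous log
#' inputs, the order used throughout the package (variables are logged
#' before centering).
#'
#' @inheritParams build_risk_adjusted_output
#' @inheritParams encode_zero_inputs
#' @param center Center output and log inputs (default `TRUE`).
#' @return A prepared `hospital_panel`.
#' @export
prepare_panel <- function(panel, wave_rates = NULL, volume = NULL,
                          mode = "dummy", center = TRUE) {
  out <- build_risk_adjusted_output(panel, wave_rates = wave_rates,
                                    volume = volume)
  out <- encode_zero_inputs(out, mode = mode)
  if (center) {
    out <- center_variables(
      out, c("y", "log_mort_star", "log_readm_star", "log_phys", "log_nurse"))
  }
  out
}

#' Read and write hospital panels as delimited text
#'
#' `read_panel()` accepts comma- or tab-separated files with a header
#' row using the canonical column names; a JSON config can map arbitrary
#' source headers onto them (`{"rename": {"source_name": "canonical"}}`).
#' `write_panel()` writes a file that `read_panel()` reproduces exactly.
#'
#' @param path File path; `.tsv`/`.txt` are read tab-separated,
#'   anything else comma-separated.
#' @param config Optional path to a JSON schema config, or an equivalent
#'   list.
#' @param na Missing-value token.
#' @param graph Optional [region_graph()] used to validate districts.
#' @return `read_panel()` returns a `hospital_panel`.
#' @export
read_panel <- function(path, config = NULL, na = "NA", graph = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, na.strings = na,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(config)) {
    cfg <- if (is.character(config)) jsonlite::read_json(config) else config
    ren <- cfg$rename
    for (src in names(ren)) {
      if (src %in% names(df)) names(df)[names(df) == src] <- ren[[src]]
    }
  }
  num_cols <- intersect(
    c("exp_mortality", "obs_mortality", "obs_readmissions",
      "physicians", "nurses", inefficiency_covariates()$name),
    names(df))
  for (col in num_cols) {
    if (!is.numeric(df[[col]])) {
      suppressWarnings(x <- as.numeric(df[[col]]))
      bad <- which(is.na(x) & !is.na(df[[col]]) & df[[col]] != na)
      if (length(bad)) {
        abort(sprintf("Non-numeric values in `%s` at rows: %s", col,
                      paste(head(bad, 5), collapse = ", ")))
      }
      df[[col]] <- x
    }
  }
  hospital_panel(df, graph = graph)
}

#' @rdname read_panel
#' @param panel A `hospital_panel` to write.
#' @export
write_panel <- function(panel, path, na = "NA") {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  utils::write.table(as.data.frame(panel), path, sep = sep, na = na,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
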