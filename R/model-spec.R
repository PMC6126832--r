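#' MCMC sampler settings
#'
#' Defaults follow the study protocol: 120,000 iterations, 20,000
#' burn-in, thinning 100 (1,000 stored draws).  `adapt` is the number of
#' initial iterations during which Metropolis proposal scales are tuned
#' by Robbins-Monro recursion towards an acceptance rate of about 0.25;
#' adaptation always ends before the end of burn-in.
#'
#' @param iterations,burnin,thin MCMC protocol.
#' @param seed Integer seed; identical seeds give bitwise-identical draws.
#' @param adapt Adaptation window (iterations).
#' @param block_size Maximum covariates per Metropolis block for the
#'   inefficiency coefficients.
#' @param fixed Named list of parameters to hold fixed (not updated),
#'   e.g. `list(sigma_v2 = 0.25, delta = c(...))`; used for conjugacy
#'   checks and restricted fits.
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(iterations = 120000L, burnin = 20000L, thin = 100L,
                         seed = 20060101L, adapt = NULL, block_size = 8L,
                         fixed = list()) {
  iterations <- as.integer(iterations)
  burnin <- as.integer(burnin)
  thin <- as.integer(thin)
  if (burnin >= iterations) abort("burnin must be smaller than iterations.")
  if ((iterations - burnin) %% thin != 0L) {
    warn("(iterations - burnin) is not a multiple of thin; the last partial cycle is dropped.")
  }
  structure(list(iterations = iterations, burnin = burnin, thin = thin,
                 seed = as.integer(seed),
                 adapt = as.integer(adapt %||% min(burnin, 5000L)),
                 block_size = as.integer(block_size), fixed = fixed),
            class = "mcmc_control")
}

#' Number of stored posterior draws implied by an MCMC protocol
#'
#' @param iterations,burnin,thin MCMC protocol values.
#' @return Integer count: `(iterations - burnin) %/% thin`.
#' @export
n_stored_draws <- function(iterations, burnin, thin) {
  (as.integer(iterations) - as.integer(burnin)) %/% as.integer(thin)
}

#' Hyperprior settings
#'
#' Inverse-gamma `IG(a, b)` hyperpriors on all variance parameters and
#' optionally proper Gaussian priors on the linear coefficients.
#' Proper coefficient priors with moments are needed e.g. for
#' simulation-based sampler validation.
#'
#' @param a,b Inverse-gamma shape and scale for every variance
#'   (`sigma_v2`, `sigma_ustar2`, `tau2_struct`, `tau2_unstruct`,
#'   `tau2_hospital`), overridable per parameter via the named lists.
#'   The default is the conventional diffuse `IG(0.001, 0.001)` for all
#'   variances except the inefficiency innovation variance, which gets a
#'   weakly informative `IG(2, 1)`: the diffuse choice concentrates
#'   enormous density at zero and, along the softly identified ridge
#'   between the innovation scale and the covariate-driven spread of the
#'   inefficiency predictor, it drags the innovation variance to zero
#'   while inflating every scaling coefficient.  The spatial and
#'   hospital random-effect variances likewise default to a weakly
#'   informative `IG(2, 0.2)`: under `IG(0.001, 0.001)` the implied
#'   marginal prior on the effects has essentially no tail control, and
#'   because the likelihood flattens once the inefficiency scale
#'   underflows, the field and its variance can run away jointly.
#' @param beta_var,delta_var Gaussian prior variances for frontier and
#'   inefficiency coefficients (scalar; `Inf` = flat).  The frontier
#'   coefficients are flat by default; the inefficiency-scaling
#'   coefficients get a proper but very diffuse `N(0, 100)` prior,
#'   because a fully flat prior on scaling coefficients leaves the
#'   posterior improper along a ridge where the innovation variance and
#'   extreme coefficients on skewed covariates grow jointly.
#' @param shapes,scales Named lists overriding `a`/`b` per variance.
#' @return A list of class `sfa_priors`.
#' @export
sfa_priors <- function(a = 0.001, b = 0.001, beta_var = Inf, delta_var = 100,
                       shapes = list(sigma_ustar2 = 2, tau2_struct = 2,
                                     tau2_unstruct = 2, tau2_hospital = 2),
                       scales = list(sigma_ustar2 = 1, tau2_struct = 0.2,
                                     tau2_unstruct = 0.2,
                                     tau2_hospital = 0.2)) {
  vs <- c("sigma_v2", "sigma_ustar2", "tau2_struct", "tau2_unstruct",
          "tau2_hospital")
  sh <- setNames(rep(a, length(vs)), vs)
  sc <- setNames(rep(b, length(vs)), vs)
  for (nm in names(shapes)) sh[nm] <- shapes[[nm]]
  for (nm in names(scales)) sc[nm] <- scales[[nm]]
  structure(list(shape = as.list(sh), scale = as.list(sc),
                 beta_var = beta_var, delta_var = delta_var),
            class = "sfa_priors")
}

#' Specify a geoadditive stochastic frontier model
#'
#' Encodes which inputs enter the production frontier, the functional
#' form, which covariates and spatial terms drive the inefficiency
#' scale, and prior plus MCMC settings.  The inefficiency predictor
#' never contains an intercept: its level is identified through the
#' scale of the base inefficiency innovation.
#'
#' @param frontier_inputs Any of `"quality"` (zero dummies plus log
#'   deaths and readmissions) and `"resource"` (log physician and nurse
#'   FTEs); both by default.
#' @param functional_form `"cobb_douglas"` or `"translog"` (adds squares
#'   and pairwise products of the centered log inputs).
#' @param inefficiency_terms Character vector of covariate names for the
#'   inefficiency predictor; defaults to the full determinant list of
#'   [inefficiency_covariates()].  Names carrying a `log` flag there are
#'   entered on the log scale.
#' @param wave_effects_frontier,wave_effects_inefficiency Include year
#'   effects (reference = the panel's reference wave).
#' @param spatial One of `"both"`, `"struct"`, `"unstruct"`, `"none"`.
#' @param struct_level,unstruct_level `"district"` or `"coarse"`; mixed
#'   combinations give the mixed-level robustness variants.  Coarse
#'   levels require a `coarse_map` on the graph.
#' @param hospital_effect Include an iid hospital-level random effect in
#'   the inefficiency predictor.
#' @param mu_star_free Allow a free truncation mean for the base
#'   inefficiency innovation (default `FALSE`: half-normal).  Provided
#'   as a switch only; the supported analyses set it to zero.
#' @param priors An [sfa_priors()] object.
#' @param mcmc An [mcmc_control()] object.
#' @param label Optional human-readable label.
#' @return An object of class `sfa_model_spec`.
#' @export
sfa_model_spec <- function(frontier_inputs = c("quality", "resource"),
                           functional_form = c("cobb_douglas", "translog"),
                           inefficiency_terms = inefficiency_covariates()$name,
                           wave_effects_frontier = TRUE,
                           wave_effects_inefficiency = TRUE,
                           spatial = c("both", "struct", "unstruct", "none"),
                           struct_level = "district",
                           unstruct_level = "district",
                           hospital_effect = FALSE,
                           mu_star_free = FALSE,
                           priors = sfa_priors(),
                           mcmc = mcmc_control(),
                           label = NULL) {
  functional_form <- match.arg(functional_form)
  spatial <- match.arg(spatial)
  if (length(frontier_inputs)) {
    frontier_inputs <- match.arg(frontier_inputs,
                                 c("quality", "resource"), several.ok = TRUE)
  } else {
    frontier_inputs <- character(0)
  }
  if (functional_form == "translog" && !length(frontier_inputs)) {
    abort("A translog frontier requires frontier inputs.")
  }
  stopifnot(struct_level %in% c("district", "coarse"),
            unstruct_level %in% c("district", "coarse"))
  structure(
    list(frontier_inputs = frontier_inputs,
         functional_form = functional_form,
         inefficiency_terms = inefficiency_terms,
         wave_effects_frontier = isTRUE(wave_effects_frontier),
         wave_effects_inefficiency = isTRUE(wave_effects_inefficiency),
         spatial = spatial,
         struct_level = struct_level,
         unstruct_level = unstruct_level,
         hospital_effect = isTRUE(hospital_effect),
         mu_star_free = isTRUE(mu_star_free),
         priors = priors, mcmc = mcmc,
         label = label %||% "custom"),
    class = "sfa_model_spec")
}

#' @export
print.sfa_model_spec <- function(x, ...) {
  cat(sprintf("<sfa_model_spec> %s\n", x$label))
  cat(sprintf("  frontier: %s (%s)\n",
              if (length(x$frontier_inputs)) paste(x$frontier_inputs, collapse = " + ")
              else "intercept/waves only",
              x$functional_form))
  cat(sprintf("  inefficiency: %d covariates, spatial = %s (struct %s / unstruct %s)%s\n",
              length(x$inefficiency_terms), x$spatial, x$struct_level,
              x$unstruct_level,
              if (x$hospital_effect) ", hospital effect" else ""))
  invisible(x)
}

#' Named model presets
#'
#' Loads one of the specification presets shipped with the package
#' (`model1` ... `model9` for the selection and input-variant suite,
#' `model10_translog`, `model11_rescale`, `model16`, `model17` and
#' friends for the robustness battery).  Presets are JSON files under
#' `inst/extdata/presets` and differ from the default specification only
#' by configuration.
#'
#' @param name Preset name, e.g. `"model2"`.
#' @param mcmc Optional [mcmc_control()] overriding the stored protocol.
#' @return An `sfa_model_spec`.
#' @export
sfa_preset <- function(name, mcmc = NULL) {
  path <- system.file("extdata", "presets", paste0(name, ".json"),
                      package = "geosfa")
  if (path == "") {
    have <- list.files(system.file("extdata", "presets", package = "geosfa"))
    abort(paste0("Unknown preset `", name, "`. Available: ",
                 paste(sub("\\.json$", "", have), collapse = ", ")))
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- sfa_model_spec(
    frontier_inputs = cfg$frontier_inputs %||% c("quality", "resource"),
    functional_form = cfg$functional_form %||% "cobb_douglas",
    inefficiency_terms = cfg$inefficiency_terms %||% inefficiency_covariates()$name,
    spatial = cfg$spatial %||% "both",
    struct_level = cfg$struct_level %||% "district",
    unstruct_level = cfg$unstruct_level %||% "district",
    hospital_effect = isTRUE(cfg$hospital_effect),
    label = cfg$label %||% name)
  if (!is.null(mcmc)) spec$mcmc <- mcmc
  attr(spec, "zero_mode") <- cfg$zero_mode %||% "dummy"
  attr(spec, "preset") <- name
  spec
}

# ---- design matrices ------------------------------------------------------

wave_dummies <- function(panel) {
  ref <- attr(panel, "reference_wave", exact = TRUE) %||% min(panel$year)
  waves <- setdiff(sort(unique(panel$year)), ref)
  if (!length(waves)) {
    return(matrix(numeric(0), nrow = nrow(panel), ncol = 0))
  }
  m <- vapply(waves, function(w) as.numeric(panel$year == w),
              numeric(nrow(panel)))
  m <- matrix(m, nrow = nrow(panel))
  colnames(m) <- paste0("wave", waves)
  m
}

#' Frontier design matrix
#'
#' Builds the production-function design: intercept, zero-input dummies
#' and log quality inputs (if `"quality"` is selected), log staffing
#' inputs (if `"resource"`), wave dummies, and for the translog form all
#' squares and pairwise products of the continuous log inputs.  The
#' panel must have been prepared with [encode_zero_inputs()]; when the
#' panel was encoded with `rescale_half`, the (identically zero) dummies
#' are excluded from the design.
#'
#' @param panel Prepared `hospital_panel`.
#' @param spec An `sfa_model_spec`.
#' @return Numeric matrix with named columns, first column `const`.
#' @export
frontier_design <- function(panel, spec) {
  cols <- list(const = rep(1, nrow(panel)))
  cont <- character(0)
  zero_mode <- attr(panel, "zero_mode", exact = TRUE) %||% "dummy"
  if ("quality" %in% spec$frontier_inputs) {
    for (v in c("d_mort", "d_readm", "log_mort_star", "log_readm_star")) {
      if (!v %in% names(panel)) {
        abort(sprintf("Column `%s` missing; run encode_zero_inputs() first.", v))
      }
    }
    if (zero_mode == "dummy") {
      cols$d_mort <- panel$d_mort
      cols$d_readm <- panel$d_readm
    }
    cols$log_mort_star <- panel$log_mort_star
    cols$log_readm_star <- panel$log_readm_star
    cont <- c(cont, "log_mort_star", "log_readm_star")
  }
  if ("resource" %in% spec$frontier_inputs) {
    for (v in c("log_phys", "log_nurse")) {
      if (!v %in% names(panel)) {
        abort(sprintf("Column `%s` missing; run encode_zero_inputs() first.", v))
      }
    }
    cols$log_phys <- panel$log_phys
    cols$log_nurse <- panel$log_nurse
    cont <- c(cont, "log_phys", "log_nurse")
  }
  if (spec$functional_form == "translog" && length(cont)) {
    for (i in seq_along(cont)) {
      for (j in i:length(cont)) {
        nm <- if (i == j) paste0("tl_", cont[i], "_sq")
              else paste0("tl_", cont[i], "_x_", cont[j])
        cols[[nm]] <- panel[[cont[i]]] * panel[[cont[j]]]
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (spec$wave_effects_frontier) X <- cbind(X, wave_dummies(panel))
  X
}

#' Inefficiency design matrix
#'
#' Covariate design of the inefficiency predictor: the selected
#' determinants (log-transformed where flagged) plus wave dummies.  No
#' intercept is included, for identification.
#'
#' @inheritParams frontier_design
#' @return Numeric matrix with named columns (possibly zero columns).
#' @export
inefficiency_design <- function(panel, spec) {
  info <- inefficiency_covariates()
  cols <- list()
  for (nm in spec$inefficiency_terms) {
    # an explicit log_<col> term logs any panel column
    explicit_log <- startsWith(nm, "log_") && !nm %in% names(panel) &&
      sub("^log_", "", nm) %in% names(panel)
    if (explicit_log) nm <- sub("^log_", "", nm)
    if (!nm %in% names(panel)) {
      abort(sprintf("Inefficiency covariate `%s` missing from panel.", nm))
    }
    x <- panel[[nm]]
    take_log <- explicit_log || nm %in% info$name[info$log]
    if (take_log) {
      if (any(x <= 0, na.rm = TRUE)) {
        abort(sprintf("`%s` must be positive for its log transform.", nm))
      }
      cols[[paste0("log_", nm)]] <- log(x)
    } else {
      cols[[nm]] <- x
    }
  }
  Z <- if (length(cols)) {
    out <- do.call(cbind, cols)
    colnames(out) <- names(cols)
    out
  } else {
    matrix(numeric(0), nrow = nrow(panel), ncol = 0)
  }
  if (spec$wave_effects_inefficiency) Z <- cbind(Z, wave_dummies(panel))
  Z
}
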