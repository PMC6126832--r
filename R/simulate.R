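#' Rook-adjacency lattice district graph
#'
#' `g x g` districts on a regular grid, neighbours sharing a grid edge
#' (`2 g (g - 1)` edges in total, always one connected component).
#' Optionally attaches a coarse (NUTS2-style) map by aggregating
#' `coarse_block x coarse_block` blocks of districts.
#'
#' @param g Grid side length (`g >= 2`).
#' @param coarse_block Optional block size for the coarse map.
#' @return A `region_graph` with regions `d001`, `d002`, ...
#' @export
make_lattice_graph <- function(g, coarse_block = NULL) {
  g <- as.integer(g)
  if (g < 2) abort("`g` must be at least 2.")
  n <- g * g
  ids <- sprintf("d%03d", seq_len(n))
  idx <- function(r, c) (r - 1L) * g + c
  from <- integer(0); to <- integer(0)
  for (r in seq_len(g)) {
    for (c in seq_len(g)) {
      if (c < g) { from <- c(from, idx(r, c)); to <- c(to, idx(r, c + 1L)) }
      if (r < g) { from <- c(from, idx(r, c)); to <- c(to, idx(r + 1L, c)) }
    }
  }
  coarse_map <- NULL
  if (!is.null(coarse_block)) {
    cb <- as.integer(coarse_block)
    r_of <- ((seq_len(n) - 1L) %/% g) + 1L
    c_of <- ((seq_len(n) - 1L) %% g) + 1L
    blk <- sprintf("c%02d_%02d", (r_of - 1L) %/% cb + 1L, (c_of - 1L) %/% cb + 1L)
    coarse_map <- setNames(blk, ids)
  }
  region_graph(ids, data.frame(from = ids[from], to = ids[to]),
               coarse_map = coarse_map)
}

#' Default generating coefficients of the synthetic panel
#'
#' Effect sizes used by [simulate_panel()]: point estimates reported in
#' a published German stroke-care application of this model class, so
#' that synthetic fixtures live in a realistic regime.  They are
#' simulation defaults, not ground truth about any real hospital.
#'
#' @return Named list with `beta` (frontier) and `delta` (inefficiency)
#'   coefficient vectors.
#' @export
default_true_effects <- function() {
  list(
    beta = c(const = 0.470, d_mort = -0.329, d_readm = -0.186,
             log_mort_star = 0.397, log_readm_star = 0.282,
             log_phys = 0.056, log_nurse = 0.015,
             wave2008 = -0.025, wave2010 = -0.085, wave2012 = -0.107,
             wave2013 = -0.056),
    delta = c(Spec = -0.022, MSStrDis = -0.829, NumStrHospDis = 0.009,
              log_PatShaStroke = -0.252, MedDepCon = -0.228,
              SUCert = -1.167, SUnonCert = -0.592, log_GPsPerDis = -0.004,
              log_HosBed = -0.555, PrivHos = 0.310, NonProfHos = 0.158,
              Teach = -0.069, UniHos = 0.175, ShaI61 = 0.619,
              ShaI64 = -0.299, DiagCon = 0.394, ShaTRHOMB = 0.052,
              wave2008 = 0.064, wave2010 = 0.235, wave2012 = 0.253,
              wave2013 = 0.362))
}

#' Configuration of the synthetic hospital-panel generator
#'
#' Defaults emulate the study conditions of the German stroke-care
#' panel: a 21 x 21 rook lattice (441 districts, of which a few host no
#' hospital), about three hospitals per district (~1,300 hospitals),
#' five waves with ~15% per-wave dropout, wave-specific fractions of
#' exact-zero deaths/readmissions of 8-17%, staffing inputs with
#' log-correlation above 0.94, and an inefficiency scale calibrated so
#' the mean technical efficiency sits near 0.73.
#'
#' @param g Lattice side length.
#' @param coarse_block Coarse-region block size (for NUTS2-style maps).
#' @param mean_hospitals Mean hospitals per district (Poisson).
#' @param waves Wave (year) labels.
#' @param dropout Per-wave probability that a hospital is unobserved.
#' @param beta,delta True coefficients (see [default_true_effects()]).
#' @param sigma_v2 Idiosyncratic noise variance.
#' @param te_target Mean technical efficiency the inefficiency scale is
#'   solved for (`NULL` to use `sigma_u_at_means` directly).
#' @param sigma_u_at_means Inefficiency standard deviation at
#'   sample-mean covariates, used when `te_target` is `NULL`; `0` turns
#'   inefficiency off entirely.
#' @param zero_frac_mort,zero_frac_readm Per-wave target fractions of
#'   exact zeros (recycled across waves).
#' @param staffing_corr Target correlation of log physician and log
#'   nurse FTEs.
#' @param wave_mortality_rates Observed mortality rate per wave used to
#'   construct expected deaths from the frontier output.
#' @param tau2_struct,tau2_unstruct Variances of the structured and
#'   unstructured district effects.
#' @param prevalence Named list of binary covariate prevalences.
#' @param poisson_counts Draw quality inputs as Poisson counts instead
#'   of continuous positives with an atom at zero.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(g = 21, coarse_block = 3, mean_hospitals = 3,
                       waves = default_waves(), dropout = 0.15,
                       beta = default_true_effects()$beta,
                       delta = default_true_effects()$delta,
                       sigma_v2 = 0.142,
                       te_target = 0.73,
                       sigma_u_at_means = 1.517,
                       zero_frac_mort = c(0.08, 0.11, 0.15, 0.15, 0.16),
                       zero_frac_readm = c(0.09, 0.11, 0.16, 0.18, 0.17),
                       staffing_corr = 0.95,
                       wave_mortality_rates = c(0.160, 0.155, 0.152,
                                                0.150, 0.148),
                       tau2_struct = 0.15, tau2_unstruct = 0.03,
                       prevalence = list(SUCert = 0.10, SUnonCert = 0.21,
                                         PrivHos = 0.19, NonProfHos = 0.44,
                                         Teach = 0.46, UniHos = 0.03),
                       poisson_counts = FALSE,
                       seed = 1L) {
  if (g < 2) abort("`g` must be at least 2.")
  if (dropout < 0 || dropout >= 1) abort("`dropout` must be in [0, 1).")
  if (any(zero_frac_mort < 0 | zero_frac_mort > 0.95) ||
      any(zero_frac_readm < 0 | zero_frac_readm > 0.95)) {
    abort("Zero fractions must lie in [0, 0.95]: higher targets leave too few positive counts to define the frontier.")
  }
  if (abs(staffing_corr) >= 1) {
    abort("`staffing_corr` must be strictly inside (-1, 1).")
  }
  if (sigma_v2 <= 0) abort("`sigma_v2` must be positive.")
  structure(
    list(g = g, coarse_block = coarse_block, mean_hospitals = mean_hospitals,
         waves = as.integer(waves), dropout = dropout,
         beta = beta, delta = delta, sigma_v2 = sigma_v2,
         te_target = te_target, sigma_u_at_means = sigma_u_at_means,
         zero_frac_mort = rep_len(zero_frac_mort, length(waves)),
         zero_frac_readm = rep_len(zero_frac_readm, length(waves)),
         staffing_corr = staffing_corr,
         wave_mortality_rates = setNames(rep_len(wave_mortality_rates,
                                                 length(waves)),
                                         as.character(waves)),
         tau2_struct = tau2_struct, tau2_unstruct = tau2_unstruct,
         prevalence = prevalence, poisson_counts = poisson_counts,
         seed = as.integer(seed)),
    class = "sim_config")
}

# draw from the intrinsic GMRF on a connected graph via the spectral
# decomposition of K, constrained to sum to zero
ricar <- function(graph, tau2) {
  K <- as.matrix(graph$K)
  eg <- eigen(K, symmetric = TRUE)
  pos <- eg$values > 1e-8
  z <- rnorm(sum(pos))
  f <- as.numeric(eg$vectors[, pos, drop = FALSE] %*%
                    (z * sqrt(tau2 / eg$values[pos])))
  center_by_component(f, graph)
}

rbeta_mean <- function(n, mean, conc) rbeta(n, mean * conc, (1 - mean) * conc)

#' Simulate a hospital panel with known ground truth
#'
#' Draws the full forward model: lattice contiguity graph; structured
#' (intrinsic GMRF) and unstructured district effects; binary and
#' continuous inefficiency determinants with realistic marginals;
#' strongly correlated log staffing inputs; count-like quality inputs
#' with wave-specific atoms at zero (lowest latent values thresholded to
#' zero); half-normal inefficiency innovations scaled by
#' `exp(eta_u)`; Gaussian noise; and expected deaths constructed so that
#' [build_risk_adjusted_output()] inverts exactly to the simulated log
#' output.  Fully reproducible: identical configs give identical panels.
#'
#' @param config A [sim_config()].
#' @return A list with elements `panel` (a `hospital_panel` carrying a
#'   `wave_mortality_rate` column), `graph` (a `region_graph`), and
#'   `truth` (all generating parameters plus per-observation `u`, `te`
#'   and per-district fields).
#' @export
simulate_panel <- function(config = sim_config()) {
  cf <- config
  set.seed(cf$seed)
  graph <- make_lattice_graph(cf$g, cf$coarse_block)
  nd <- length(graph$regions)
  n_h <- rpois(nd, cf$mean_hospitals)
  H <- sum(n_h)
  if (H < 10) abort("Too few hospitals; increase `mean_hospitals` or `g`.")
  hosp_district <- rep(graph$regions, n_h)
  hosp_id <- sprintf("h%04d", seq_len(H))

  # hospital-level static structure
  su_type <- sample(c("cert", "noncert", "none"), H, replace = TRUE,
                    prob = c(cf$prevalence$SUCert, cf$prevalence$SUnonCert,
                             1 - cf$prevalence$SUCert - cf$prevalence$SUnonCert))
  cert_start <- ifelse(su_type == "cert",
                       cf$waves[sample.int(length(cf$waves), H, replace = TRUE)],
                       Inf)
  own <- sample(c("priv", "nonprof", "public"), H, replace = TRUE,
                prob = c(cf$prevalence$PrivHos, cf$prevalence$NonProfHos,
                         1 - cf$prevalence$PrivHos - cf$prevalence$NonProfHos))
  teach <- rbinom(H, 1, cf$prevalence$Teach)
  uni <- rbinom(H, 1, cf$prevalence$UniHos)
  hosbed <- exp(rnorm(H, 5.51, 0.8))
  z_size <- rnorm(H)
  lp_base <- -0.62 + 1.55 * z_size
  ln_base <- 0.55 + 1.70 * (cf$staffing_corr * z_size +
                              sqrt(1 - cf$staffing_corr^2) * rnorm(H))
  gps <- setNames(exp(rnorm(nd, 3.88, 0.16)), graph$regions)

  # wave presence (each hospital observed in at least one wave)
  present <- matrix(runif(H * length(cf$waves)) > cf$dropout, H)
  none <- rowSums(present) == 0
  present[cbind(which(none), sample.int(length(cf$waves), sum(none),
                                        replace = TRUE))] <- TRUE

  rows <- which(present, arr.ind = TRUE)
  hi <- rows[, 1]; wi <- rows[, 2]
  ord <- order(hi, wi)
  hi <- hi[ord]; wi <- wi[ord]
  n <- length(hi)
  year <- cf$waves[wi]
  district <- hosp_district[hi]

  # market structure consistent with the realized panel
  key <- paste(district, year)
  n_in_district <- ave(rep(1, n), key, FUN = sum)
  gshare <- rgamma(n, 1)
  ms <- gshare / ave(gshare, key, FUN = sum)

  panel <- tibble::tibble(
    hospital_id = hosp_id[hi], year = year, district_id = district,
    Spec = pmax(rnorm(n, 1.4, 0.8), 0.05),
    MSStrDis = ms,
    NumStrHospDis = n_in_district,
    PatShaStroke = pmin(exp(rnorm(n, -4.5, 1.4)), 1),
    MedDepCon = rbeta_mean(n, 0.85, 6),
    SUCert = as.numeric(year >= cert_start[hi]),
    SUnonCert = as.numeric(su_type[hi] == "noncert"),
    GPsPerDis = unname(gps[district]),
    HosBed = hosbed[hi],
    PrivHos = as.numeric(own[hi] == "priv"),
    NonProfHos = as.numeric(own[hi] == "nonprof"),
    Teach = teach[hi],
    UniHos = uni[hi],
    ShaI61 = rbeta_mean(n, 0.10, 8),
    ShaI64 = rbeta_mean(n, 0.11, 5),
    DiagCon = rbeta_mean(n, 0.72, 10),
    ShaTRHOMB = rbeta_mean(n, 0.05, 3))

  # staffing: strongly correlated hospital-level logs plus small
  # within-hospital wave noise
  log_phys <- lp_base[hi] + rnorm(n, 0, 0.10)
  log_nurse <- ln_base[hi] + rnorm(n, 0, 0.10)
  panel$physicians <- exp(log_phys)
  panel$nurses <- exp(log_nurse)

  # quality inputs: size-linked latent levels, wave-thresholded to
  # produce the target atoms at zero
  latent_mort <- exp(rnorm(n, 1.65 + 0.65 * z_size[hi], 0.75))
  latent_readm <- exp(rnorm(n, 1.45 + 0.65 * z_size[hi], 0.75))
  if (cf$poisson_counts) {
    latent_mort <- rpois(n, latent_mort)
    latent_readm <- rpois(n, latent_readm)
  }
  obs_mort <- latent_mort
  obs_readm <- latent_readm
  for (k in seq_along(cf$waves)) {
    iw <- which(year == cf$waves[k])
    thr_m <- quantile(latent_mort[iw], cf$zero_frac_mort[k])
    thr_r <- quantile(latent_readm[iw], cf$zero_frac_readm[k])
    obs_mort[iw][latent_mort[iw] <= thr_m] <- 0
    obs_readm[iw][latent_readm[iw] <= thr_r] <- 0
  }
  panel$obs_mortality <- obs_mort
  panel$obs_readmissions <- obs_readm

  # frontier predictor with the zero-input dummy device
  d_mort <- as.numeric(obs_mort == 0)
  d_readm <- as.numeric(obs_readm == 0)
  wave_f <- function(nm) {
    w <- sub("^wave", "", nm)
    as.numeric(year == as.integer(w))
  }
  eta_y <- cf$beta[["const"]] +
    cf$beta[["d_mort"]] * d_mort + cf$beta[["d_readm"]] * d_readm +
    cf$beta[["log_mort_star"]] * log(pmax(obs_mort, d_mort)) +
    cf$beta[["log_readm_star"]] * log(pmax(obs_readm, d_readm)) +
    cf$beta[["log_phys"]] * log_phys + cf$beta[["log_nurse"]] * log_nurse
  for (nm in names(cf$beta)[grepl("^wave", names(cf$beta))]) {
    eta_y <- eta_y + cf$beta[[nm]] * wave_f(nm)
  }

  # inefficiency predictor
  info <- inefficiency_covariates()
  eta_u <- rep(0, n)
  for (j in seq_len(nrow(info))) {
    nm <- info$name[j]
    dn <- if (info$log[j]) paste0("log_", nm) else nm
    if (!dn %in% names(cf$delta)) next
    x <- if (info$log[j]) log(panel[[nm]]) else panel[[nm]]
    eta_u <- eta_u + cf$delta[[dn]] * x
  }
  for (nm in names(cf$delta)[grepl("^wave", names(cf$delta))]) {
    eta_u <- eta_u + cf$delta[[nm]] * wave_f(nm)
  }
  f_struct <- setNames(ricar(graph, cf$tau2_struct), graph$regions)
  f_unstruct <- setNames(rnorm(nd, 0, sqrt(cf$tau2_unstruct)), graph$regions)
  eta_u <- eta_u + unname(f_struct[district]) + unname(f_unstruct[district])

  # inefficiency scale: relative to sample-mean covariates, optionally
  # solved so the marginal mean technical efficiency hits the target
  alpha_rel <- exp(eta_u - mean(eta_u))
  sigma_ustar <- if (!is.null(cf$te_target)) {
    if (cf$te_target >= 1 || cf$te_target <= 0) {
      abort("`te_target` must lie strictly between 0 and 1.")
    }
    f <- function(ls) mean(te_closed_form(exp(ls) * alpha_rel)) - cf$te_target
    exp(stats::uniroot(f, c(-10, 5), tol = 1e-10)$root)
  } else {
    cf$sigma_u_at_means / exp(mean(eta_u))
  }
  u_star <- if (sigma_ustar > 0) rtnorm_lower0(n, 0, sigma_ustar) else rep(0, n)
  u <- u_star * alpha_rel
  v <- rnorm(n, 0, sqrt(cf$sigma_v2))
  y <- eta_y + v - u

  rate <- unname(cf$wave_mortality_rates[as.character(year)])
  panel$exp_mortality <- rate * exp(y)
  panel$wave_mortality_rate <- rate

  out_panel <- hospital_panel(panel, reference_wave = cf$waves[1],
                              graph = graph)
  truth <- list(config = cf, sigma_ustar = sigma_ustar,
                beta = cf$beta, delta = cf$delta,
                f_struct = f_struct, f_unstruct = f_unstruct,
                eta_y = eta_y, eta_u_centered = eta_u - mean(eta_u),
                u = u, te = exp(-u), y = y,
                mean_te = mean(exp(-u)))
  list(panel = out_panel, graph = graph, truth = truth)
}

#' Write a simulated study to plain-text files
#'
#' Emits the panel (CSV), the district edge list (CSV) and the ground
#' truth (JSON) so a simulation can be consumed by the file-based
#' interfaces.
#'
#' @param sim Result of [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "panel.csv")
  p2 <- file.path(dir, "district_edges.csv")
  p3 <- file.path(dir, "truth.json")
  write_panel(sim$panel, p1)
  utils::write.table(sim$graph$edges, p2, sep = ",", row.names = FALSE,
                     quote = FALSE)
  tr <- sim$truth
  jsonlite::write_json(
    list(seed = tr$config$seed, sigma_ustar = tr$sigma_ustar,
         sigma_v2 = tr$config$sigma_v2, beta = as.list(tr$beta),
         delta = as.list(tr$delta), mean_te = tr$mean_te,
         f_struct = as.list(tr$f_struct)),
    p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}
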