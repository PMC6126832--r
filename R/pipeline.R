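#' Fit and compare a suite of model presets
#'
#' Fits each preset on the same prepared panel and reports DIC, pD,
#' WAIC and p_waic in one table, flagging the minimum-DIC model.  All
#' fits are guarded by a common data fingerprint; a preset failure is
#' recorded and the suite continues.
#'
#' @param panel Prepared `hospital_panel`.
#' @param graph A `region_graph`.
#' @param presets Character vector of preset names (see [sfa_preset()])
#'   or a named list of `sfa_model_spec` objects.
#' @param mcmc Optional [mcmc_control()] applied to every preset.
#' @param keep_fits Return the fitted objects alongside the table.
#' @return A tibble (one row per preset, sorted as given) with model
#'   comparison criteria and a logical `best` column; fitted objects in
#'   `attr(, "fits")` when `keep_fits = TRUE`.
#' @export
run_model_suite <- function(panel, graph, presets = paste0("model", 1:7),
                            mcmc = NULL, keep_fits = FALSE) {
  specs <- if (is.character(presets)) {
    setNames(lapply(presets, sfa_preset, mcmc = mcmc), presets)
  } else {
    if (!is.null(mcmc)) presets <- lapply(presets, function(s) { s$mcmc <- mcmc; s })
    presets
  }
  fits <- list()
  rows <- purrr::map_dfr(names(specs), function(nm) {
    res <- tryCatch({
      fit <- fit_sfa(panel, graph, specs[[nm]])
      dic <- compute_dic(fit)
      waic <- compute_waic(fit)
      if (keep_fits) fits[[nm]] <<- fit
      tibble::tibble(preset = nm, label = specs[[nm]]$label,
                     DIC = dic$DIC, p_D = dic$p_D,
                     WAIC = waic$WAIC, p_waic = waic$p_waic,
                     fingerprint = fit$fingerprint, error = NA_character_)
    }, error = function(err) {
      tibble::tibble(preset = nm, label = specs[[nm]]$label,
                     DIC = NA_real_, p_D = NA_real_, WAIC = NA_real_,
                     p_waic = NA_real_, fingerprint = NA_character_,
                     error = conditionMessage(err))
    })
    res
  })
  fps <- unique(rows$fingerprint[!is.na(rows$fingerprint)])
  if (length(fps) > 1) {
    abort("Model-comparison criteria computed on differing observations; fits do not share a data fingerprint.")
  }
  rows$best <- !is.na(rows$DIC) & rows$DIC == min(rows$DIC, na.rm = TRUE)
  if (keep_fits) attr(rows, "fits") <- fits
  rows
}

first_wave_rows <- function(panel) {
  ord <- order(panel$hospital_id, panel$year)
  first <- !duplicated(panel$hospital_id[ord])
  sort(ord[first])
}

#' Matching plus difference-in-differences certification analysis
#'
#' Guards the certification effect against self-selection.  Step 1:
#' propensity scores for becoming certified during the panel, from a
#' logistic model on baseline (first-wave) characteristics; each
#' switcher is matched 1:1, without replacement, to a never-certified
#' hospital (nearest propensity neighbour, optional caliper; switcher
#' order is a seeded shuffle with hospital-id tie-breaking).  Step 2:
#' the frontier is refit on all observations, with the certification
#' term replaced by a matched-pair indicator `D_m`, the DID interaction
#' `D_m x SUCert`, and `(1 - D_m) x SUCert` for non-matched certified
#' observations.
#'
#' @param panel Prepared `hospital_panel` containing `SUCert`.
#' @param graph A `region_graph`.
#' @param spec Base `sfa_model_spec` (certification must be among its
#'   inefficiency terms).
#' @param propensity_covariates Baseline covariates for the propensity
#'   model; defaults to the spec's determinants minus the certification
#'   indicators.
#' @param caliper Optional maximum propensity-score distance.
#' @param seed Seed for the matching shuffle.
#' @return A list of class `did_result`: the refit (`fit`), the matched
#'   pairs (`matches`), the propensity model, and the posterior summary
#'   of the interaction coefficients (`did_summary`).
#' @export
run_matching_did <- function(panel, graph, spec = sfa_preset("model2"),
                             propensity_covariates = NULL, caliper = NULL,
                             seed = 1L) {
  if (!"SUCert" %in% names(panel)) abort("Panel has no `SUCert` column.")
  base_rows <- first_wave_rows(panel)
  base <- panel[base_rows, , drop = FALSE]
  ever <- tapply(panel$SUCert, panel$hospital_id, max)
  status <- tibble::tibble(
    hospital_id = base$hospital_id,
    baseline_cert = base$SUCert,
    ever_cert = unname(ever[as.character(base$hospital_id)]))
  status$switcher <- status$baseline_cert == 0 & status$ever_cert == 1
  status$never <- status$ever_cert == 0
  if (!any(status$switcher)) {
    abort("No hospitals switch into certification during the panel; the DID design is undefined.")
  }
  covs <- propensity_covariates %||%
    setdiff(intersect(spec$inefficiency_terms, names(panel)),
            c("SUCert", "SUnonCert"))
  use <- status$switcher | status$never
  df <- cbind(data.frame(switcher = as.numeric(status$switcher[use])),
              as.data.frame(base[use, covs, drop = FALSE]))
  ps_model <- suppressWarnings(glm(switcher ~ ., data = df,
                                   family = binomial()))
  ps <- stats::predict(ps_model, type = "response")
  ids <- as.character(status$hospital_id[use])
  sw_idx <- which(df$switcher == 1)
  ct_idx <- which(df$switcher == 0)
  ct_idx <- ct_idx[order(ids[ct_idx])]  # distance ties break by id order
  set.seed(seed)
  ord <- sample(sw_idx)                 # seeded processing shuffle
  taken <- rep(FALSE, length(ct_idx))
  pairs <- list()
  unmatched <- character(0)
  for (s in ord) {
    d <- abs(ps[ct_idx] - ps[s])
    d[taken] <- Inf
    if (!is.null(caliper)) d[d > caliper] <- Inf
    j <- which.min(d)
    if (!is.finite(d[j])) {
      unmatched <- c(unmatched, as.character(ids[s]))
      next
    }
    taken[j] <- TRUE
    pairs[[length(pairs) + 1]] <- tibble::tibble(
      switcher = as.character(ids[s]), control = as.character(ids[ct_idx[j]]),
      ps_switcher = ps[s], ps_control = ps[ct_idx[j]])
  }
  if (length(unmatched)) {
    abort(paste0("No admissible control (propensity overlap) for: ",
                 paste(head(unmatched, 10), collapse = ", ")))
  }
  matches <- dplyr::bind_rows(pairs)
  matched_ids <- c(matches$switcher, matches$control)
  out <- panel
  out$D_m <- as.numeric(as.character(out$hospital_id) %in% matched_ids)
  out$D_m_x_SUCert <- out$D_m * out$SUCert
  out$nonmatched_SUCert <- (1 - out$D_m) * out$SUCert
  out <- restore_panel_attrs(out, panel)
  spec2 <- spec
  spec2$inefficiency_terms <- c(
    setdiff(spec$inefficiency_terms, "SUCert"),
    "D_m", "D_m_x_SUCert", "nonmatched_SUCert")
  spec2$label <- paste0(spec$label, " + matching/DID")
  fit <- fit_sfa(out, graph, spec2)
  td <- tidy(fit, "delta")
  did <- td[td$term %in% c("D_m", "D_m_x_SUCert", "nonmatched_SUCert"), ]
  structure(list(fit = fit, matches = matches, propensity_model = ps_model,
                 did_summary = did),
            class = "did_result")
}

#' @export
print.did_result <- function(x, ...) {
  cat(sprintf("<did_result> %d matched pairs\n", nrow(x$matches)))
  print(x$did_summary)
  invisible(x)
}

lattice_polygon <- function(id, g) {
  k <- as.integer(sub("^d", "", id))
  r <- (k - 1L) %/% g
  c <- (k - 1L) %% g
  list(list(list(c(c, r), c(c + 1, r), c(c + 1, r + 1), c(c, r + 1),
                 c(c, r))))
}

#' Export tables, maps and figures for a fitted model
#'
#' Writes (deterministically, so reruns overwrite byte-identically):
#' a coefficient table with credibility stars (1/5/10% intervals
#' excluding zero), a model-fit and effects JSON, per-region posterior
#' spatial means as CSV and — when the graph is a lattice built by
#' [make_lattice_graph()] — as a GeoJSON choropleth, and slack posterior
#' density plots.
#'
#' @param fit An `sfa_fit`.
#' @param effects Optional `effects_report` (computed if missing).
#' @param outdir Output directory.
#' @return Invisibly, the vector of files written.
#' @export
render_reports <- function(fit, effects = NULL, outdir = "sfa-report") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  effects <- effects %||% compute_effects(fit)

  coefs <- dplyr::bind_rows(tidy(fit, "beta"), tidy(fit, "delta"),
                            tidy(fit, "variances"))
  f <- file.path(outdir, "coefficients.csv")
  utils::write.table(coefs, f, sep = ",", row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  g <- glance(fit)
  f <- file.path(outdir, "results.json")
  jsonlite::write_json(
    list(model = fit$spec$label, seed = fit$seed,
         fingerprint = fit$fingerprint,
         fit = as.list(g),
         marginal_effects = effects$marginal,
         te_overall = effects$te_overall, gamma = effects$gamma),
    f, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  files <- c(files, f)

  # spatial effects
  d <- fit$draws
  if (!is.null(d$f_struct) || !is.null(d$f_unstruct)) {
    fs <- if (!is.null(d$f_struct)) colMeans(d$f_struct) else NULL
    fu <- if (!is.null(d$f_unstruct)) colMeans(d$f_unstruct) else NULL
    regions <- names(fs) %||% names(fu)
    sp <- tibble::tibble(
      region = regions,
      f_struct = if (!is.null(fs)) unname(fs[regions]) else 0,
      f_unstruct = if (!is.null(fu)) unname(fu[regions] %na% 0) else 0)
    sp$f_unstruct[is.na(sp$f_unstruct)] <- 0
    sp$composite <- sp$f_struct + sp$f_unstruct
    f <- file.path(outdir, "spatial_effects.csv")
    utils::write.table(sp, f, sep = ",", row.names = FALSE, quote = FALSE)
    files <- c(files, f)
    if (all(grepl("^d[0-9]+$", sp$region))) {
      gsize <- ceiling(sqrt(max(as.integer(sub("^d", "", sp$region)))))
      feats <- purrr::pmap(sp, function(region, f_struct, f_unstruct,
                                        composite) {
        list(type = "Feature",
             properties = list(id = region, f_struct = f_struct,
                               f_unstruct = f_unstruct,
                               composite = composite),
             geometry = list(type = "Polygon",
                             coordinates = lattice_polygon(region, gsize)[[1]]))
      })
      f <- file.path(outdir, "spatial_effects.geojson")
      jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                           f, auto_unbox = TRUE, digits = NA)
      files <- c(files, f)
    } else {
      inform("Graph is not a lattice; skipping GeoJSON choropleth export.")
    }
  }

  slk <- purrr::compact(effects$slack_distributions)
  if (length(slk)) {
    p <- plot_slack_density(fit, names(slk))
    f <- file.path(outdir, "slack_density.png")
    suppressMessages(ggplot2::ggsave(f, p, width = 7, height = 5, dpi = 120))
    files <- c(files, f)
  }

  f <- file.path(outdir, "run_log.txt")
  writeLines(c(sprintf("model: %s", fit$spec$label),
               sprintf("seed: %d", fit$seed),
               sprintf("observations: %d", fit$n_obs),
               sprintf("stored draws: %d", nrow(fit$draws$beta)),
               sprintf("fingerprint: %s", fit$fingerprint)), f)
  files <- c(files, f)
  invisible(files)
}
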