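#' Column schemas of the pipeline's CSV interfaces
#'
#' Named list of schemas; each schema maps a column name to its type
#' (`"numeric"`, `"integer"` or `"character"`), with an attribute
#' `"optional"` naming columns that may be absent. Used by [read_table()]
#' for validation.
#'
#' @format Named list: `rlc_steps`, `pigments`, `spectra`, `incubations`,
#'   `fit_results`, `experiment_table`.
#' @export
photo_schemas <- list(
  rlc_steps = structure(
    c(shoot_id = "character", container_id = "character",
      treatment_par = "numeric", day = "numeric", step_index = "integer",
      actinic_par = "numeric", f = "numeric", fm_prime = "numeric",
      fo_prime = "numeric", fm_dark = "numeric", fo_dark = "numeric"),
    optional = c("fo_prime", "fm_dark", "fo_dark")
  ),
  pigments = structure(
    c(shoot_id = "character", container_id = "character",
      treatment_par = "numeric", a470 = "numeric", a645 = "numeric",
      a662 = "numeric", extract_volume_ml = "numeric",
      fresh_weight_g = "numeric"),
    optional = c("container_id", "treatment_par")
  ),
  spectra = structure(
    c(shoot_id = "character", wavelength_nm = "numeric",
      absorbance = "numeric"),
    optional = character(0)
  ),
  incubations = structure(
    c(shoot_id = "character", container_id = "character",
      treatment_par = "numeric", phase = "character", time_h = "numeric",
      o2_umol_l = "numeric", volume_l = "numeric",
      ps_surface_cm2 = "numeric", total_surface_cm2 = "numeric"),
    optional = c("container_id", "treatment_par")
  ),
  fit_results = structure(
    c(shoot_id = "character", container_id = "character",
      treatment_par = "numeric", day = "numeric", af_kind = "character",
      ps = "numeric", alpha = "numeric", beta = "numeric",
      etr_max = "numeric", ek = "numeric", sse = "numeric",
      converged = "character", rejected = "character",
      reject_reason = "character"),
    optional = c("reject_reason")
  ),
  experiment_table = structure(
    c(shoot_id = "character", container_id = "character",
      treatment_par = "numeric", day = "numeric", response = "character",
      value = "numeric", group = "character"),
    optional = c("group", "day")
  )
)

#' Read and validate a pipeline CSV
#'
#' Reads a CSV (dot decimal, UTF-8, mandatory header), checks the header
#' against a schema (order-insensitive; unknown extra columns are kept),
#' coerces column types and collects row-level validation problems with line
#' numbers. Rows that fail to parse are dropped from the result and reported
#' in the `"problems"` attribute rather than aborting the read.
#'
#' @param path file path.
#' @param schema schema name in [photo_schemas] or a schema vector.
#' @return Validated data frame with a `"problems"` attribute (data frame
#'   with `line` and `message`, zero rows when clean).
#' @export
read_table <- function(path, schema) {
  if (is.character(schema) && length(schema) == 1) {
    if (!schema %in% names(photo_schemas)) {
      stop_photo("unknown schema: ", schema,
                 class = "photoacclim_schema_error")
    }
    schema <- photo_schemas[[schema]]
  }
  if (!file.exists(path)) {
    stop_photo("file not found: ", path, class = "photoacclim_io_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  required <- setdiff(names(schema), attr(schema, "optional"))
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop_photo("missing required column(s): ",
               paste(missing, collapse = ", "),
               class = "photoacclim_schema_error")
  }
  problems <- list()
  bad_rows <- logical(nrow(raw))
  for (col in intersect(names(schema), names(raw))) {
    type <- schema[[col]]
    if (type == "character") next
    vals <- raw[[col]]
    empty <- is.na(vals) | vals == ""
    conv <- suppressWarnings(as.numeric(vals))
    bad <- !empty & is.na(conv)
    if (any(bad)) {
      for (i in which(bad)) {
        problems[[length(problems) + 1]] <- data.frame(
          line = i + 1L,   # header is line 1
          message = sprintf("column '%s': cannot parse '%s'", col, vals[i])
        )
      }
      bad_rows <- bad_rows | bad
    }
    raw[[col]] <- if (type == "integer") as.integer(round(conv)) else conv
  }
  out <- raw[!bad_rows, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "problems") <- if (length(problems)) do.call(rbind, problems) else
    data.frame(line = integer(0), message = character(0))
  out
}

#' Write a pipeline CSV
#'
#' Canonical writer matched to [read_table()]: dot decimal, UTF-8, header
#' row, no row names, no quoting beyond what commas require.
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# fit all RLC traces in a step table; returns (results df, fits list)
fit_all_rlcs <- function(rlc_steps, af = photo_constants$af_default,
                         af_kind = "default_044") {
  keys <- unique(rlc_steps[c("shoot_id", "day")])
  fits <- vector("list", nrow(keys))
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    d <- rlc_steps[rlc_steps$shoot_id == keys$shoot_id[i] &
                     rlc_steps$day == keys$day[i], ]
    d <- d[order(d$actinic_par), ]
    tr <- rlc_trace(d$actinic_par, d$f, d$fm_prime,
                    shoot_id = d$shoot_id[1], container_id = d$container_id[1],
                    treatment_par = d$treatment_par[1], day = d$day[1])
    fit <- tryCatch({
      curve <- build_etr_curve(tr, af = af, af_kind = af_kind)
      fit_platt(curve)
    }, photoacclim_insufficient_data = function(e) NULL)
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      shoot_id = keys$shoot_id[i], container_id = d$container_id[1],
      treatment_par = d$treatment_par[1], day = keys$day[i],
      af_kind = af_kind,
      ps = if (is.null(fit)) NA_real_ else fit$coefficients[["ps"]],
      alpha = if (is.null(fit)) NA_real_ else fit$coefficients[["alpha"]],
      beta = if (is.null(fit)) NA_real_ else fit$coefficients[["beta"]],
      etr_max = if (is.null(fit)) NA_real_ else fit$etr_max,
      ek = if (is.null(fit)) NA_real_ else fit$ek,
      sse = if (is.null(fit)) NA_real_ else fit$sse,
      converged = if (is.null(fit)) FALSE else fit$converged,
      rejected = if (is.null(fit)) TRUE else fit$rejected,
      reject_reason = if (is.null(fit)) "insufficient_data" else
        ifelse(is.na(fit$reject_reason), "", fit$reject_reason)
    )
  }
  list(results = do.call(rbind, rows), fits = fits)
}

#' Run the full photoacclimation analysis pipeline
#'
#' Sequences every stage over one experiment's data: RLC fitting with the
#' default absorption factor, pigment quantification, spectral absorption
#' factors, per-shoot re-correction of the day-25 ETR fits with the measured
#' AF_photo, metabolic rates and mean respiration, hierarchical
#' irradiance-response models for alpha / ETRmax / Ek (date-specific
#' smooths) and NPP, the minimum quantum requirement, and its daily-dose
#' conversion. Deterministic given the data.
#'
#' @param experiment a `photo_experiment` from [simulate_experiment()], or a
#'   named list of data frames `rlc_steps`, `pigments`, `spectra`,
#'   `incubations` following [photo_schemas] (e.g. assembled with
#'   [read_table()]).
#' @param af absorption factor for the primary ETR fits (default 0.44).
#' @param hgam_method smoothing criterion passed to [fit_hgam()].
#' @return List of class `photo_pipeline` with components `fits`
#'   (data frame), `fits_corrected`, `pigments`, `absorption_factors`,
#'   `rates`, `mean_respiration`, `models` (list of `hgam_fit`), `mqr`,
#'   `mqr_daily_dose` and a reproducibility `manifest`.
#' @export
run_pipeline <- function(experiment, af = photo_constants$af_default,
                         hgam_method = "GCV.Cp") {
  for (nm in c("rlc_steps", "pigments", "incubations")) {
    if (is.null(experiment[[nm]])) {
      stop_photo("pipeline stage input missing: ", nm,
                 class = "photoacclim_io_error")
    }
  }

  # 1. fluorescence -> ETR curves -> Platt fits (default AF)
  rl <- fit_all_rlcs(experiment$rlc_steps, af = af)
  fits <- rl$results

  # 2. pigments
  pg <- experiment$pigments
  pig <- cbind(pg["shoot_id"],
               pigment_concentrations(pg$a470, pg$a645, pg$a662,
                                      pg$extract_volume_ml,
                                      pg$fresh_weight_g))

  # 3. spectral absorption factors
  af_tab <- NULL
  if (!is.null(experiment$spectra) && nrow(experiment$spectra) > 0) {
    af_rows <- lapply(split(experiment$spectra,
                            experiment$spectra$shoot_id), function(d) {
      la <- leaf_absorptance(d$wavelength_nm, d$absorbance)
      data.frame(shoot_id = d$shoot_id[1], af_total = la$af_total,
                 af_photo = la$af_photo, n_clipped = la$n_clipped)
    })
    af_tab <- do.call(rbind, af_rows)
    rownames(af_tab) <- NULL
  }

  # 4. re-correct day-25 fits with per-shoot AF_photo
  fits_corrected <- NULL
  if (!is.null(af_tab)) {
    keys <- which(fits$day == max(fits$day) & !is.na(fits$etr_max))
    rows <- lapply(keys, function(i) {
      j <- match(fits$shoot_id[i], af_tab$shoot_id)
      if (is.na(j)) return(NULL)
      fit <- rl$fits[[i]]
      cor <- correct_etr_fit(fit, af_new = af_tab$af_photo[j],
                             af_kind = "af_photo")
      data.frame(shoot_id = fits$shoot_id[i],
                 container_id = fits$container_id[i],
                 treatment_par = fits$treatment_par[i], day = fits$day[i],
                 af_kind = "af_photo",
                 ps = cor$coefficients[["ps"]],
                 alpha = cor$coefficients[["alpha"]],
                 beta = cor$coefficients[["beta"]],
                 etr_max = cor$etr_max, ek = cor$ek, sse = cor$sse,
                 converged = cor$converged, rejected = cor$rejected,
                 reject_reason = ifelse(is.na(cor$reject_reason), "",
                                        cor$reject_reason))
    })
    fits_corrected <- do.call(rbind, rows)
  }

  # 5. metabolism
  inc <- experiment$incubations
  rate_rows <- lapply(split(inc, inc$shoot_id), function(d) {
    light <- d[d$phase == "light", ]
    dark <- d[d$phase == "dark", ]
    rr <- rates(light = list(time_h = light$time_h,
                             o2_umol_l = light$o2_umol_l),
                dark = list(time_h = dark$time_h,
                            o2_umol_l = dark$o2_umol_l),
                volume_l = d$volume_l[1],
                ps_surface_cm2 = d$ps_surface_cm2[1],
                total_surface_cm2 = d$total_surface_cm2[1])
    data.frame(shoot_id = d$shoot_id[1], container_id = d$container_id[1],
               treatment_par = d$treatment_par[1],
               npp = rr$npp, gpp = rr$gpp, r = rr$r,
               slope_light = rr$slope_light, slope_dark = rr$slope_dark,
               se_light = rr$se_light, se_dark = rr$se_dark)
  })
  rates_tab <- do.call(rbind, rate_rows)
  rownames(rates_tab) <- NULL
  mr <- mean_respiration(rates_tab$r)

  # 6. irradiance-response models on accepted fits
  ok <- !fits$rejected & fits$converged & is.na(fits$etr_max) == FALSE
  fit_dat <- fits[ok, ]
  fit_dat$day <- factor(fit_dat$day)
  models <- list()
  for (resp in c("alpha", "etr_max", "ek")) {
    models[[resp]] <- fit_hgam(fit_dat, response = resp, group = "day",
                               method = hgam_method)
  }
  models$npp <- npp_irradiance_model(
    rates_tab[c("treatment_par", "npp", "container_id")], mr$magnitude,
    random = "container_id", method = hgam_method
  )
  mqr <- estimate_mqr(models$npp)

  structure(list(
    fits = fits, fits_corrected = fits_corrected,
    pigments = pig, absorption_factors = af_tab,
    rates = rates_tab, mean_respiration = mr,
    models = models, mqr = mqr,
    mqr_daily_dose = if (is.na(mqr$mqr)) NA_real_ else
      convert_par_to_daily(mqr$mqr),
    manifest = list(
      package_version = as.character(utils::packageVersion("photoacclim")),
      af = af, hgam_method = hgam_method,
      n_traces = nrow(fits), n_rejected = sum(fits$rejected),
      config = if (!is.null(experiment$truth)) experiment$truth$config else
        NULL
    )
  ), class = "photo_pipeline")
}

#' @export
print.photo_pipeline <- function(x, ...) {
  cat("Photoacclimation pipeline results\n")
  cat(sprintf("  RLC fits: %d (%d rejected by QC)\n",
              nrow(x$fits), sum(x$fits$rejected)))
  cat(sprintf("  mean respiration: %.3f umol O2 cm-2 h-1 (n = %d)\n",
              x$mean_respiration$mean, x$mean_respiration$n))
  if (!x$mqr$no_root) {
    cat(sprintf("  MQR: %.2f umol photons m-2 s-1 (%.2f mol m-2 d-1)\n",
                x$mqr$mqr, x$mqr_daily_dose))
  }
  invisible(x)
}
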