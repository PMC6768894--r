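#' Model parameter sets
#'
#' A model parameter set bundles every constant of the compartment system:
#' the Rn-222 decay constant, the blood pool (cardiac output, arterial and
#' venous volumes, blood-air partition coefficient), the skin sub-model
#' (baseline permeability, partitions, volumes, skin blood-flow fractions,
#' dermal-subcutaneous transfer coefficient, immersed fraction), the
#' modulation schedule of permeability and skin blood flow during immersion,
#' instrument settings (dead space, sampling spacing), reference respiratory
#' values, and the tissue table (flow fraction of cardiac output, tissue-blood
#' partition coefficient and volume per compartment).
#'
#' Internal unit system: time in hours, volumes in litres, activities in Bq,
#' source concentrations in Bq m^-3. The permeability coefficient is stored in
#' m s^-1 and converted once when the rate matrix is assembled.
#'
#' @param config optional path to a YAML or JSON configuration; entries
#'   override the shipped adult-female defaults (see
#'   `system.file("extdata", "reference_female_synthetic.yaml", package = "radonskin")`).
#' @return an object of class `rn_params`: a named list with components
#'   `physical`, `blood`, `skin`, `modulation`, `instrument`, `respiration`,
#'   `tissues` (data frame) and `provenance` (named character vector mapping
#'   dotted keys to `"paper"`, `"reference-config"`, `"assumption"` or
#'   `"user"`).
#' @examples
#' p <- rn_parameters()
#' p$skin$p_ssb
#' @export
rn_parameters <- function(config = NULL) {
  default_path <- system.file("extdata", "reference_female_synthetic.yaml",
                              package = "radonskin")
  params <- .params_from_list(yaml::yaml.load_file(default_path))
  if (!is.null(config)) params <- .merge_config(params, config)
  issues <- validate_parameters(params)
  if (length(issues) > 0L)
    stop("invalid parameter configuration:\n  ", paste(issues, collapse = "\n  "))
  params
}

#' Load a model parameter configuration from file
#'
#' Reads a YAML or JSON configuration, fills any missing entry from the
#' shipped adult-female defaults, validates the result and tracks provenance:
#' entries taken from the shipped defaults keep their original provenance
#' string, entries supplied by the file are marked `"user"`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a validated [rn_parameters()] object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  rn_parameters(config = path)
}

#' Write a model parameter set to file
#'
#' Numbers are serialized at full double precision so that a write/load
#' round trip reproduces every numeric field bit-exactly. The format follows
#' the file extension: `.yaml`/`.yml` or `.json`.
#'
#' @param params an `rn_params` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "rn_params"))
  x <- unclass(params)
  x$tissues <- lapply(seq_len(nrow(params$tissues)), function(i)
    as.list(params$tissues[i, , drop = FALSE]))
  x$provenance <- as.list(params$provenance)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    writeLines(yaml::as.yaml(x, precision = 17L), path)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  } else {
    stop("unsupported extension: ", ext, " (use .yaml or .json)")
  }
  invisible(path)
}

#' Validate a model parameter set
#'
#' Checks every structural invariant of the parameter system and reports the
#' violations without raising. The input is never modified.
#'
#' Checked invariants: positive decay constant; strictly positive blood-pool
#' entries; positive skin volumes, partitions, permeability and transfer
#' coefficient; immersed fraction in `[0, 1]`; non-negative dead space;
#' modulation bounds (`ramp_factor >= 1`, `swell_factor >= 1`,
#' `0 <= kds_coupling <= 1`, ordered breakpoints); non-negative tissue flow
#' fractions with positive partitions and volumes; and the closure condition
#' that all flow fractions (tissues plus both skin chains) sum to 1 within
#' 1e-9.
#'
#' @param params an `rn_params` object.
#' @return character vector of violated invariants; empty when valid.
#' @export
validate_parameters <- function(params) {
  v <- character(0)
  say <- function(cond, msg) if (isTRUE(cond)) v <<- c(v, msg)
  ph <- params$physical; bl <- params$blood; sk <- params$skin
  mo <- params$modulation; ins <- params$instrument; ti <- params$tissues

  say(!is.numeric(ph$lambda_r_per_h) || ph$lambda_r_per_h <= 0,
      "physical.lambda_r_per_h must be > 0")
  for (f in c("cardiac_output_l_per_h", "v_arterial_l", "v_venous_l", "p_blood_air"))
    say(!is.numeric(bl[[f]]) || bl[[f]] <= 0, paste0("blood.", f, " must be > 0"))
  for (f in c("k0_m_per_s", "p_sw", "p_sa", "p_dsb", "p_ssb", "v_ds_l", "v_ss_l",
              "area_m2", "k_ds_per_h", "kappa_dry"))
    say(!is.numeric(sk[[f]]) || sk[[f]] <= 0, paste0("skin.", f, " must be > 0"))
  for (f in c("flow_fraction_ds", "flow_fraction_ss"))
    say(!is.numeric(sk[[f]]) || sk[[f]] < 0, paste0("skin.", f, " must be >= 0"))
  say(!is.numeric(sk$exposed_fraction) ||
        sk$exposed_fraction < 0 || sk$exposed_fraction > 1,
      "skin.exposed_fraction must lie in [0, 1]")
  say(mo$ramp_factor < 1, "modulation.ramp_factor must be >= 1")
  say(mo$swell_factor < 1, "modulation.swell_factor must be >= 1")
  say(mo$kds_coupling < 0 || mo$kds_coupling > 1,
      "modulation.kds_coupling must lie in [0, 1]")
  say(!(mo$ramp_end_min <= mo$swell_start_min &&
          mo$swell_start_min <= mo$swell_end_min),
      "modulation breakpoints must satisfy ramp_end <= swell_start <= swell_end")
  say(ins$v_dead_l < 0, "instrument.v_dead_l must be >= 0")

  if (!is.data.frame(ti) || nrow(ti) == 0L) {
    v <- c(v, "tissue table is empty")
  } else {
    bad <- ti$flow_fraction < 0
    say(any(bad), paste0("tissue flow_fraction < 0: ",
                         paste(ti$name[bad], collapse = ", ")))
    bad <- ti$partition <= 0
    say(any(bad), paste0("tissue partition <= 0: ",
                         paste(ti$name[bad], collapse = ", ")))
    bad <- ti$volume_l <= 0
    say(any(bad), paste0("tissue volume <= 0: ",
                         paste(ti$name[bad], collapse = ", ")))
    total <- sum(ti$flow_fraction) + sk$flow_fraction_ds + sk$flow_fraction_ss
    say(abs(total - 1) > 1e-9,
        sprintf("flow fractions (tissues + skin) sum to %.12f, expected 1", total))
  }
  v
}

#' @export
print.rn_params <- function(x, ...) {
  cat("Radon biokinetic model parameters\n")
  cat(sprintf("  decay constant    : %.6f h^-1\n", x$physical$lambda_r_per_h))
  cat(sprintf("  cardiac output    : %.1f l h^-1 (V_BA %.2f l, V_BV %.2f l, P_BA %.2f)\n",
              x$blood$cardiac_output_l_per_h, x$blood$v_arterial_l,
              x$blood$v_venous_l, x$blood$p_blood_air))
  cat(sprintf("  skin permeability : %.3g m s^-1 (dry-skin multiplier %.1f)\n",
              x$skin$k0_m_per_s, x$skin$kappa_dry))
  cat(sprintf("  skin compartments : V_DS %.2f l, V_SS %.2f l, k_DS %.2f h^-1, area %.2f m^2 (%.0f%% immersed)\n",
              x$skin$v_ds_l, x$skin$v_ss_l, x$skin$k_ds_per_h, x$skin$area_m2,
              100 * x$skin$exposed_fraction))
  cat(sprintf("  modulation        : ramp x%.1f over %.0f min; swelling %s (/%.1f, %.1f-%.0f min)\n",
              x$modulation$ramp_factor, x$modulation$ramp_end_min,
              if (isTRUE(x$modulation$apply_swelling)) "on" else "off",
              x$modulation$swell_factor, x$modulation$swell_start_min,
              x$modulation$swell_end_min))
  cat(sprintf("  tissues           : %d compartments, flow fractions sum %.4f (with skin)\n",
              nrow(x$tissues),
              sum(x$tissues$flow_fraction) + x$skin$flow_fraction_ds +
                x$skin$flow_fraction_ss))
  invisible(x)
}

# ---- subjects -------------------------------------------------------------

#' Construct a subject profile
#'
#' Per-person anthropometry and respiratory parameters that scale skin uptake
#' (body surface area) and exhalation (respiratory tract volume, tidal volume,
#' breathing frequency, respiratory minute volume).
#'
#' @param id subject identifier.
#' @param gender `"F"` or `"M"`; selects the reference respiratory minute
#'   volume used to scale the RT-air/environment exchange coefficient.
#' @param height_cm,mass_kg height and body mass; used for the Mosteller body
#'   surface area when `bsa_m2` is not given.
#' @param bsa_m2 body surface area (m^2); defaults to [mosteller_bsa()].
#' @param v_rt_l respiratory tract volume (functional residual capacity plus
#'   extrathoracic volume, litres).
#' @param v_t_l tidal volume (litres); must be smaller than `v_rt_l`.
#' @param rf_per_min breathing frequency (min^-1).
#' @param rmv_l_per_h respiratory minute volume (l h^-1); defaults to
#'   `v_t_l * rf_per_min * 60` and must agree with it within 10%.
#' @param age_y,body_fat_kg optional descriptive fields.
#' @return an object of class `rn_subject`.
#' @examples
#' s <- rn_subject(1, "F", height_cm = 168, mass_kg = 58,
#'                 v_rt_l = 3.25, v_t_l = 0.56, rf_per_min = 15.3)
#' s$rmv_l_per_h
#' @export
rn_subject <- function(id, gender = c("F", "M"), height_cm, mass_kg,
                       bsa_m2 = NULL, v_rt_l, v_t_l, rf_per_min,
                       rmv_l_per_h = NULL, age_y = NA_real_,
                       body_fat_kg = NA_real_) {
  gender <- match.arg(gender)
  if (is.null(bsa_m2)) bsa_m2 <- mosteller_bsa(height_cm, mass_kg)
  if (is.null(rmv_l_per_h)) rmv_l_per_h <- v_t_l * rf_per_min * 60
  if (bsa_m2 <= 0) stop("bsa_m2 must be > 0")
  if (!(v_t_l < v_rt_l)) stop("tidal volume must be smaller than respiratory tract volume")
  imputed <- v_t_l * rf_per_min * 60
  if (abs(rmv_l_per_h - imputed) / imputed > 0.10)
    stop(sprintf("rmv_l_per_h (%.0f) inconsistent with v_t * rf * 60 (%.0f) beyond 10%%",
                 rmv_l_per_h, imputed))
  structure(list(id = id, gender = gender, age_y = age_y,
                 height_cm = height_cm, mass_kg = mass_kg, bsa_m2 = bsa_m2,
                 body_fat_kg = body_fat_kg, v_rt_l = v_rt_l, v_t_l = v_t_l,
                 rf_per_min = rf_per_min, rmv_l_per_h = rmv_l_per_h),
            class = "rn_subject")
}

#' Reference adult subject
#'
#' The reference profile used for population-level simulations: reference
#' respiratory tract volume and minute volume for the chosen gender and the
#' reference female body surface area of the default parameter set.
#'
#' @param gender `"F"` (default) or `"M"`.
#' @param params parameter set supplying the reference values.
#' @return an `rn_subject`.
#' @export
reference_subject <- function(gender = c("F", "M"), params = rn_parameters()) {
  gender <- match.arg(gender)
  resp <- params$respiration
  if (gender == "F") {
    rn_subject("reference-F", "F", height_cm = 163, mass_kg = 60,
               bsa_m2 = params$skin$area_m2, v_rt_l = resp$v_rt_female_l,
               v_t_l = 0.52, rf_per_min = resp$rmv_icrp_female_l_per_h / (0.52 * 60),
               rmv_l_per_h = resp$rmv_icrp_female_l_per_h)
  } else {
    rn_subject("reference-M", "M", height_cm = 176, mass_kg = 73,
               bsa_m2 = 1.90, v_rt_l = resp$v_rt_male_l,
               v_t_l = 0.70, rf_per_min = resp$rmv_icrp_male_l_per_h / (0.70 * 60),
               rmv_l_per_h = resp$rmv_icrp_male_l_per_h)
  }
}

#' @export
print.rn_subject <- function(x, ...) {
  cat(sprintf("Subject %s (%s): BSA %.2f m^2, V_RT %.2f l, V_T %.2f l, RF %.1f min^-1, RMV %.0f l h^-1\n",
              as.character(x$id), x$gender, x$bsa_m2, x$v_rt_l, x$v_t_l,
              x$rf_per_min, x$rmv_l_per_h))
  invisible(x)
}

# ---- internal helpers -----------------------------------------------------

.params_from_list <- function(x) {
  tissues <- do.call(rbind, lapply(x$tissues, function(t)
    data.frame(name = t$name, flow_fraction = t$flow_fraction,
               partition = t$partition, volume_l = t$volume_l)))
  prov <- unlist(x$provenance %||% list())
  if ("tissues" %in% names(prov)) {
    tprov <- stats::setNames(rep(prov[["tissues"]], nrow(tissues)),
                             paste0("tissues.", tissues$name))
    prov <- c(prov[names(prov) != "tissues"], tprov)
  }
  structure(list(physical = x$physical, blood = x$blood, skin = x$skin,
                 modulation = x$modulation, instrument = x$instrument,
                 respiration = x$respiration, tissues = tissues,
                 provenance = prov),
            class = "rn_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::yaml.load_file(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    stop("unsupported configuration format: ", ext, " (use YAML or JSON)")
  }
}

.merge_config <- function(params, path) {
  user <- .read_config_file(path)
  prov <- params$provenance
  for (section in c("physical", "blood", "skin", "modulation", "instrument",
                    "respiration")) {
    if (is.null(user[[section]])) next
    for (field in names(user[[section]])) {
      if (!field %in% names(params[[section]]))
        stop("unknown parameter field: ", section, ".", field)
      new <- user[[section]][[field]]
      if (!identical(new, params[[section]][[field]]))
        prov[[paste0(section, ".", field)]] <- "user"
      params[[section]][[field]] <- new
    }
  }
  if (!is.null(user$tissues)) {
    params$tissues <- do.call(rbind, lapply(user$tissues, function(t)
      data.frame(name = t$name, flow_fraction = t$flow_fraction,
                 partition = t$partition, volume_l = t$volume_l)))
    prov <- prov[!startsWith(names(prov), "tissues.")]
    prov <- c(prov, stats::setNames(rep("user", nrow(params$tissues)),
                                    paste0("tissues.", params$tissues$name)))
  }
  if (!is.null(user$provenance))
    for (k in names(user$provenance)) prov[[k]] <- user$provenance[[k]]
  params$provenance <- prov
  params
}
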