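#' Simulation configuration
#'
#' Bundles every knob of the synthetic data generator. The defaults
#' describe the study conditions the package is tested under: a code
#' universe of 18 body systems with 12 codes each (20% CC, 10% MCC, 5%
#' POA-exempt), comorbidity attachment probabilities whose encounter-level
#' prevalences land near the commonly reported top categories
#' (hypertension ~26%, fluid/electrolyte ~24%, deficiency anemia ~18%,
#' chronic pulmonary ~17%), a mean of 10 diagnoses per encounter with
#' roughly 90% of codes present on admission (so that, as in working
#' documentation-improvement programs, most non-POA severity capture
#' flows through chart review rather than routine coding), and a
#' body-system-variant truth model whose intercept puts the marginal
#' high-severity rate near 44%.
#'
#' @param seed root seed; map generation, encounter generation and the
#'   CDI process use `seed`, `seed + 1`, `seed + 2` respectively.
#' @param n_encounters number of encounters to draw.
#' @param codes_per_system synthetic codes per body system.
#' @param cc_fraction,mcc_fraction per-code probabilities of CC / MCC
#'   status.
#' @param exempt_fraction per-code probability of POA-reporting exemption.
#' @param elix_attach named 30-vector of per-code probabilities that a
#'   code carries each comorbidity category.
#' @param mean_dx mean number of coded diagnoses per encounter (1
#'   principal + Poisson secondaries).
#' @param poa_flag_probs named probabilities over the POA flag values
#'   assigned to non-exempt codes (exempt codes get flag `"1"`).
#' @param nonpoa_ccmcc_keep fraction of the base not-POA rate retained for
#'   CC/MCC codes: severe conditions are predominantly present on
#'   admission, so most of their drawn `N` flags flip to `Y`.
#' @param variant truth-model variant.
#' @param intercept,coefficients truth-model parameters on the
#'   orthogonal-contrast basis (length must match the variant width).
#' @param cdi_threshold latent admission-score threshold above which a
#'   case is selected for CDI review.
#' @param cdi_intensity mean number of non-POA CC/MCC codes injected into
#'   a reviewed case.
#' @param cdi_query_fraction fraction of reviewed cases also queried.
#' @param n_facilities facility labels to spread encounters across.
#' @param months discharge months (YYYY-MM) to sample from.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_encounters = 10000L,
                       codes_per_system = 12L,
                       cc_fraction = 0.20,
                       mcc_fraction = 0.10,
                       exempt_fraction = 0.05,
                       elix_attach = default_elix_attach(),
                       mean_dx = 10,
                       poa_flag_probs = c(Y = 0.94, W = 0.02, N = 0.02,
                                          U = 0.01, `1` = 0.01),
                       nonpoa_ccmcc_keep = 0.25,
                       variant = "body_system",
                       intercept = 7.0,
                       coefficients = default_truth_coefficients(),
                       cdi_threshold = 0.35,
                       cdi_intensity = 3,
                       cdi_query_fraction = 0.5,
                       n_facilities = 21L,
                       months = format(seq(as.Date("2018-07-01"),
                                           by = "month", length.out = 12),
                                       "%Y-%m")) {
  cfg <- list(seed = as.integer(seed), n_encounters = as.integer(n_encounters),
              codes_per_system = as.integer(codes_per_system),
              cc_fraction = cc_fraction, mcc_fraction = mcc_fraction,
              exempt_fraction = exempt_fraction, elix_attach = elix_attach,
              mean_dx = mean_dx, poa_flag_probs = poa_flag_probs,
              nonpoa_ccmcc_keep = nonpoa_ccmcc_keep,
              variant = variant, intercept = intercept,
              coefficients = coefficients, cdi_threshold = cdi_threshold,
              cdi_intensity = cdi_intensity,
              cdi_query_fraction = cdi_query_fraction,
              n_facilities = as.integer(n_facilities), months = months)
  probs <- c(cfg$cc_fraction, cfg$mcc_fraction, cfg$exempt_fraction,
             cfg$elix_attach, cfg$poa_flag_probs, cfg$cdi_query_fraction,
             cfg$nonpoa_ccmcc_keep)
  if (any(probs < 0 | probs > 1)) {
    stop_fatal("all probabilities must lie in [0, 1]")
  }
  if (cfg$cc_fraction + cfg$mcc_fraction > 1) {
    stop_fatal("cc_fraction + mcc_fraction must not exceed 1")
  }
  if (length(cfg$elix_attach) != length(elix_registry())) {
    stop_fatal("elix_attach must have one probability per registry category")
  }
  width <- design_info(cfg$variant)$n_columns
  if (length(cfg$coefficients) != width) {
    stop_fatal("truth coefficient vector must have length ", width,
               " for variant '", cfg$variant, "'")
  }
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_elix_attach <- function() {
  p <- stats::setNames(rep(0.008, length(elix_registry())), elix_registry())
  p[c("HTN", "LYTES", "ANEMDEF", "CHRNLUNG")] <- c(0.032, 0.030, 0.022,
                                                   0.020)
  p
}

#' @rdname sim_config
#' @export
default_truth_coefficients <- function() {
  lin <- rep(c(2.2, 1.4, 1.0), length.out = N_BODY_SYSTEMS)
  quad <- rep(c(0.20, -0.15), length.out = N_BODY_SYSTEMS)
  stats::setNames(as.vector(rbind(lin, quad)),
                  design_info("body_system")$columns)
}

#' Generate a synthetic reference-map set
#'
#' Builds a deterministic synthetic ICD-10-CM-shaped code universe: each
#' body system gets `codes_per_system` codes, each code draws a CC/MCC
#' status, zero or more comorbidity categories and POA-exempt membership
#' at the configured rates. Identical configs produce identical maps.
#'
#' @param config a [sim_config()].
#' @return A [reference_maps] object (version label records the seed).
#' @export
generate_reference_maps <- function(config) {
  with_seed(config$seed, {
    cps <- config$codes_per_system
    sys <- rep(seq_len(N_BODY_SYSTEMS), each = cps)
    codes <- sprintf("%s%02d%03d", LETTERS[sys], sys,
                     rep(seq_len(cps), N_BODY_SYSTEMS))
    u <- stats::runif(length(codes))
    status <- ifelse(u < config$mcc_fraction, "MCC",
                     ifelse(u < config$mcc_fraction + config$cc_fraction,
                            "CC", "NONE"))
    # every body system contains severe diagnoses in real code maps;
    # without one, level 2 would be structurally unreachable and the
    # ordinal design rank deficient
    if (config$cc_fraction + config$mcc_fraction > 0) {
      for (s in seq_len(N_BODY_SYSTEMS)) {
        in_s <- which(sys == s)
        if (all(status[in_s] == "NONE")) {
          status[sample(in_s, 1)] <- "CC"
        }
      }
    }
    registry <- elix_registry()
    rows <- lapply(seq_along(registry), function(j) {
      hit <- stats::runif(length(codes)) < config$elix_attach[[j]]
      # real comorbidity maps never have an empty category; guarantee
      # at least one code so no flag is structurally constant
      if (!any(hit)) hit[sample.int(length(codes), 1)] <- TRUE
      data.frame(code = codes[hit], category = registry[j],
                 stringsAsFactors = FALSE)
    })
    elix <- do.call(rbind, rows)
    exempt <- codes[stats::runif(length(codes)) < config$exempt_fraction]
    reference_maps(
      body_system = stats::setNames(sys, codes),
      ccmcc = stats::setNames(status[status != "NONE"],
                              codes[status != "NONE"]),
      elixhauser = elix,
      poa_exempt = exempt,
      version_label = sprintf("synthetic-v%d", config$seed),
      registry = registry)
  })
}

#' Generate synthetic encounters with known ground truth
#'
#' Per encounter: draws a diagnosis list (1 principal + Poisson
#' secondaries) from the code universe, assigns POA flags, builds the true
#' discharge and admission features, computes the true high-severity
#' probability `p = plogis(intercept + x' beta)` for each phase, draws the
#' binary label, and maps it to a cosmetic 4-level SOI (high -> 3 or 4,
#' low -> 1 or 2, uniformly). Demographics (age ~49y mean, ~53% female, a
#' typical race mix, 21 facilities, 12 discharge months) are drawn for the
#' descriptive reports. The latent truth (true probabilities and labels
#' for both phases) is attached for recovery testing.
#'
#' @param config a [sim_config()].
#' @param maps the matching [generate_reference_maps()] result.
#' @return An [encounter_set()] with a `truth` data.frame
#'   (`encounter_id`, `p_true`, `label`, `p_true_poa`, `label_poa`).
#' @export
generate_encounters <- function(config, maps) {
  with_seed(config$seed + 1L, {
    n <- config$n_encounters
    ids <- sprintf("E%07d", seq_len(n))
    n_dx <- 1L + stats::rpois(n, max(config$mean_dx - 1, 0))
    universe <- names(maps$body_system)
    total <- sum(n_dx)
    code <- sample(universe, total, replace = TRUE)
    poa <- sample(names(config$poa_flag_probs), total, replace = TRUE,
                  prob = config$poa_flag_probs)
    # severe (CC/MCC) conditions are predominantly present on admission;
    # most not-POA coding concerns minor diagnoses added during the stay
    severe_n <- ccmcc_of(maps, code) != "NONE" & poa == "N"
    flip <- severe_n &
      stats::runif(total) >= config$nonpoa_ccmcc_keep
    poa[flip] <- "Y"
    poa[is_poa_exempt(maps, code)] <- "1"
    position <- rep("secondary", total)
    position[cumsum(c(1L, utils::head(n_dx, -1)))] <- "principal"
    dx <- data.frame(encounter_id = rep(ids, n_dx), code = code,
                     poa = poa, position = position,
                     stringsAsFactors = FALSE)
    truth_p <- function(d) {
      ftr <- list(body = body_system_levels(d, maps, encounter_ids = ids),
                  elix = elixhauser_flags(d, maps, encounter_ids = ids),
                  registry = maps$registry)
      class(ftr) <- "severity_features"
      X <- encode_design(ftr, config$variant)
      stats::plogis(config$intercept + drop(X %*% config$coefficients))
    }
    p_dis <- truth_p(dx)
    label <- stats::rbinom(n, 1, p_dis)
    adm <- select_codes(dx, "admission", maps)
    p_adm <- truth_p(adm)
    label_adm <- stats::rbinom(n, 1, p_adm)
    soi_from <- function(lab) {
      ifelse(lab == 1, 3L, 1L) + stats::rbinom(n, 1, 0.5)
    }
    race_levels <- c("White", "Black", "Asian", "Other", "Unavailable",
                     "Declined", "Unknown")
    race_probs <- c(0.627, 0.146, 0.053, 0.106, 0.048, 0.017, 0.003)
    enc <- data.frame(
      encounter_id = ids,
      age = pmax(18, round(stats::rnorm(n, 49, 18))),
      sex = sample(c("Female", "Male"), n, replace = TRUE,
                   prob = c(0.534, 0.466)),
      race = sample(race_levels, n, replace = TRUE, prob = race_probs),
      facility = sprintf("F%02d", sample.int(config$n_facilities, n,
                                             replace = TRUE)),
      discharge_month = sample(config$months, n, replace = TRUE),
      admit_soi = soi_from(label_adm),
      discharge_soi = soi_from(label),
      cds_reviewed = NA,
      cds_queried = NA,
      stringsAsFactors = FALSE)
    truth <- data.frame(encounter_id = ids, p_true = p_dis, label = label,
                        p_true_poa = p_adm, label_poa = label_adm,
                        stringsAsFactors = FALSE)
    encounter_set(enc, dx, truth = truth)
  })
}

#' Emulate a clinical-documentation-improvement process
#'
#' Marks for review the encounters whose latent admission severity
#' exceeds `cdi_threshold` (specialists target severe-looking cases at
#' admission), flags a configured fraction of reviewed cases as queried,
#' and injects extra non-POA CC/MCC secondary codes into reviewed cases
#' at the configured mean intensity. Captured codes target body systems
#' not yet at level 2 (a query documents severity that was missed), and
#' because severity assignment works from the final coded record, the
#' discharge truth probabilities, labels and SOI of augmented encounters
#' are redrawn from the post-capture features; admission truth is
#' untouched (injected codes are not present on admission). With
#' intensity 0 the process is a pure selection with no augmentation.
#'
#' @param encset a [generate_encounters()] result (latent truth required).
#' @param maps the matching reference maps.
#' @param config the same [sim_config()].
#' @return A new `encounter_set` with `cds_reviewed`/`cds_queried` filled
#'   and augmented diagnoses.
#' @export
generate_cdi_process <- function(encset, maps, config) {
  if (is.null(encset$truth)) {
    stop_fatal("encounter set carries no latent truth; generate it with ",
               "generate_encounters()")
  }
  with_seed(config$seed + 2L, {
    enc <- encset$encounters
    truth <- encset$truth
    reviewed <- truth$p_true_poa >= config$cdi_threshold
    queried <- reviewed &
      stats::runif(nrow(enc)) < config$cdi_query_fraction
    enc$cds_reviewed <- reviewed
    enc$cds_queried <- queried
    dx <- encset$diagnoses
    pool <- names(maps$ccmcc)
    idx <- which(reviewed)
    if (length(idx) && config$cdi_intensity > 0 && length(pool)) {
      # a query captures severity that was missed: injected CC/MCC codes
      # go to body systems not already at level 2 for that encounter
      lv <- body_system_levels(dx, maps,
                               encounter_ids = enc$encounter_id)
      pool_sys <- body_system_of(maps, pool)
      k <- stats::rpois(length(idx), config$cdi_intensity)
      extra <- vector("list", length(idx))
      for (j in seq_along(idx)) {
        if (k[j] == 0) next
        open_sys <- which(lv[idx[j], ] < 2L)
        cand <- pool[pool_sys %in% open_sys]
        if (!length(cand)) next
        extra[[j]] <- data.frame(
          encounter_id = enc$encounter_id[idx[j]],
          code = sample(cand, min(k[j], length(cand))),
          poa = "N",
          position = "secondary",
          stringsAsFactors = FALSE)
      }
      extra <- do.call(rbind, extra)
      if (!is.null(extra)) {
        dx <- rbind(dx, extra)
        # discharge severity is assigned from the FINAL coded record, so
        # captured codes feed back into the discharge truth and SOI
        ftr <- list(body = body_system_levels(dx, maps,
                                              encounter_ids = enc$encounter_id),
                    elix = elixhauser_flags(dx, maps,
                                            encounter_ids = enc$encounter_id),
                    registry = maps$registry)
        class(ftr) <- "severity_features"
        X <- encode_design(ftr, config$variant)
        truth$p_true <- stats::plogis(config$intercept +
                                        drop(X %*% config$coefficients))
        redraw <- truth$encounter_id %in% extra$encounter_id
        new_label <- stats::rbinom(nrow(truth), 1, truth$p_true)
        truth$label[redraw] <- new_label[redraw]
        new_soi <- ifelse(truth$label == 1, 3L, 1L) +
          stats::rbinom(nrow(truth), 1, 0.5)
        enc$discharge_soi[redraw] <- new_soi[redraw]
      }
    }
    encounter_set(enc, dx, truth = truth)
  })
}
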