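# Synthetic hormone time courses, estrous-stage sequences and cohorts.

#' Simulate LH time courses with known surge labels
#'
#' Each animal gets one AM sample (proestrus morning, 0 h of the paradigm)
#' and `n_pm_samples` PM samples spanning the afternoon/evening sampling
#' window. Surge-labelled animals (Bernoulli with probability
#' `surge_probability`) receive a log-normal surge peak in a random PM slot,
#' with the adjacent slots at 50% and 25% of the peak to give the profile a
#' surge-like shape; all other draws come from the truncated-normal AM
#' baseline law. Values are censored to the ultrasensitive LH assay
#' reportable range (`censor_min`-`censor_max`; 0.16-40 ng/ml at the study's
#' 1:10 dilution) with a flag.
#'
#' @param n_animals Number of animals (>= 1).
#' @param surge_probability Probability an animal expresses a surge.
#' @param am_baseline_mean,am_baseline_sd Baseline LH law (ng/ml); draws are
#'   truncated at zero.
#' @param surge_peak_meanlog,surge_peak_sdlog Log-normal surge-peak law
#'   (log ng/ml scale).
#' @param n_pm_samples PM samples per animal (>= 1).
#' @param censor_min,censor_max Assay reportable range (ng/ml).
#' @param seed Integer seed.
#' @return A data frame with columns `animal_id`, `time_h`, `period`
#'   (`"AM"`/`"PM"`), `conc_ng_ml`, `censored`, `true_surge`.
#' @export
#' @examples
#' lh <- generate_lh_profiles(4, surge_probability = 0.5, seed = 3)
#' head(lh)
generate_lh_profiles <- function(n_animals, surge_probability = 0.8,
                                 am_baseline_mean = 0.8,
                                 am_baseline_sd = 0.4,
                                 surge_peak_meanlog = log(15),
                                 surge_peak_sdlog = 0.5,
                                 n_pm_samples = 6,
                                 censor_min = 0.16, censor_max = 40,
                                 seed = 1L) {
  check_scalar(n_animals, "n_animals", positive = TRUE, integerish = TRUE)
  check_probability(surge_probability, "surge_probability")
  check_scalar(am_baseline_sd, "am_baseline_sd", nonnegative = TRUE)
  if (am_baseline_mean < 0) {
    stop("`am_baseline_mean` must be non-negative", call. = FALSE)
  }
  check_scalar(n_pm_samples, "n_pm_samples", positive = TRUE,
               integerish = TRUE)
  rng <- assay_range("LH", censor_min, censor_max)
  with_seed(seed, {
    baseline_draw <- function(n) {
      pmax(stats::rnorm(n, am_baseline_mean, am_baseline_sd), 0)
    }
    rows <- lapply(seq_len(n_animals), function(a) {
      surge <- stats::runif(1) < surge_probability
      am <- baseline_draw(1L)
      pm <- baseline_draw(n_pm_samples)
      if (surge) {
        peak <- stats::rlnorm(1, surge_peak_meanlog, surge_peak_sdlog)
        slot <- sample.int(n_pm_samples, 1L)
        pm[slot] <- peak
        if (slot > 1L) pm[slot - 1L] <- pmax(pm[slot - 1L], 0.5 * peak)
        if (slot < n_pm_samples) pm[slot + 1L] <- pmax(pm[slot + 1L],
                                                       0.25 * peak)
      }
      data.frame(
        animal_id = a,
        time_h = c(0, 7 + seq_len(n_pm_samples)),
        period = c("AM", rep("PM", n_pm_samples)),
        conc_ng_ml = c(am, pm),
        true_surge = surge
      )
    })
    out <- do.call(rbind, rows)
    cen <- censor_to_range(out$conc_ng_ml, rng)
    out$conc_ng_ml <- cen$values
    out$censored <- cen$censored
    out[c("animal_id", "time_h", "period", "conc_ng_ml", "censored",
          "true_surge")]
  })
}

#' Simulate daily estrous-stage sequences
#'
#' Generates one stage sequence per animal over the stages diestrus (`"D"`),
#' proestrus (`"P"`) and estrus (`"E"`), matching daily vaginal-lavage
#' monitoring over a 21 d window. `transition_law` is either a 3x3 row-
#' stochastic matrix with dimnames over `c("D","P","E")` (a first-order
#' Markov chain) or a character vector of stages that is repeated verbatim
#' (a deterministic cycle, which a memoryless chain cannot express). The
#' default chain leaves diestrus with probability 0.4/day and steps P -> E
#' -> D deterministically, giving ~4-5 day cycles (mean cycle length
#' 2 + 1/0.4 = 4.5 d).
#'
#' @param n_animals Number of animals.
#' @param n_days Days monitored per animal (default 21).
#' @param transition_law 3x3 stochastic matrix or character stage pattern.
#' @param init Initial stage (matrix form only).
#' @param seed Integer seed.
#' @return A data frame with columns `animal_id`, `day`, `stage`.
#' @export
#' @examples
#' cyc <- generate_cycle_sequences(2, seed = 5)
#' table(cyc$stage)
generate_cycle_sequences <- function(n_animals, n_days = 21,
                                     transition_law = NULL, init = "D",
                                     seed = 1L) {
  check_scalar(n_animals, "n_animals", positive = TRUE, integerish = TRUE)
  check_scalar(n_days, "n_days", positive = TRUE, integerish = TRUE)
  stages <- c("D", "P", "E")
  if (is.null(transition_law)) {
    transition_law <- matrix(
      c(0.6, 0.4, 0,
        0,   0,   1,
        1,   0,   0),
      nrow = 3, byrow = TRUE, dimnames = list(stages, stages)
    )
  }
  if (is.character(transition_law)) {
    if (!all(transition_law %in% stages)) {
      stop("stage pattern may only contain D, P, E", call. = FALSE)
    }
    seqs <- lapply(seq_len(n_animals), function(a) {
      rep_len(transition_law, n_days)
    })
  } else {
    if (!is.matrix(transition_law) || !all(dim(transition_law) == c(3, 3))) {
      stop("`transition_law` must be a 3x3 matrix or a stage pattern",
           call. = FALSE)
    }
    if (is.null(dimnames(transition_law))) {
      dimnames(transition_law) <- list(stages, stages)
    }
    if (!all(rownames(transition_law) %in% stages) ||
        !all(colnames(transition_law) %in% stages)) {
      stop("transition matrix dimnames must be D, P, E", call. = FALSE)
    }
    transition_law <- transition_law[stages, stages]
    if (any(transition_law < 0) ||
        any(abs(rowSums(transition_law) - 1) > 1e-8)) {
      stop("transition matrix rows must be probabilities summing to 1",
           call. = FALSE)
    }
    if (!init %in% stages) stop("`init` must be one of D, P, E",
                                call. = FALSE)
    seqs <- with_seed(seed, {
      lapply(seq_len(n_animals), function(a) {
        s <- character(n_days)
        s[1] <- init
        for (d in seq_len(n_days - 1L)) {
          s[d + 1L] <- sample(stages, 1L, prob = transition_law[s[d], ])
        }
        s
      })
    })
  }
  data.frame(
    animal_id = rep(seq_len(n_animals), each = n_days),
    day = rep(seq_len(n_days), times = n_animals),
    stage = unlist(seqs, use.names = FALSE)
  )
}

#' Specification for a synthetic study cohort
#'
#' Describes the nested design of the study: dams assigned to standard
#' (STD) or limited bedding and nesting (LBN) rearing, litters normalized
#' to 5-8 pups, and adult offspring split between control (CON) and acute
#' layered psychosocial stress (ALPS), giving the four groups STD-CON,
#' STD-ALPS, LBN-CON and LBN-ALPS. Effect parameters are per-group
#' multipliers/shifts consumed by the generators; random-effect SDs act on
#' the log10 scale for corticosterone.
#'
#' @param n_dams_per_group Dams per rearing-by-adult-treatment group.
#' @param pups_per_litter Integer range (length 2, within 5-8) from which
#'   litter sizes are drawn uniformly.
#' @param event_rate_hz Named per-group PSC event rates (Hz).
#' @param surge_probability Named per-group LH surge probabilities.
#' @param cort_fold Named per-group post/pre corticosterone fold changes.
#' @param cort_baseline_ng_ml Geometric-mean pre-stress corticosterone.
#' @param dam_sd_log10,mouse_sd_log10,resid_sd_log10 Random-effect and
#'   residual SDs on the log10 corticosterone scale.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_dams_per_group = 5,
                        pups_per_litter = c(5, 8),
                        event_rate_hz = c("STD-CON" = 0.5, "STD-ALPS" = 0.5,
                                          "LBN-CON" = 0.5, "LBN-ALPS" = 0.5),
                        surge_probability = c("STD-CON" = 0.9,
                                              "STD-ALPS" = 0.3,
                                              "LBN-CON" = 0.9,
                                              "LBN-ALPS" = 0.3),
                        cort_fold = c("STD-CON" = 2.9, "STD-ALPS" = 9,
                                      "LBN-CON" = 2.9, "LBN-ALPS" = 9),
                        cort_baseline_ng_ml = 30,
                        dam_sd_log10 = 0.10, mouse_sd_log10 = 0.10,
                        resid_sd_log10 = 0.15, seed = 1L) {
  check_scalar(n_dams_per_group, "n_dams_per_group", positive = TRUE,
               integerish = TRUE)
  if (length(pups_per_litter) != 2L || any(pups_per_litter < 5) ||
      any(pups_per_litter > 8) || pups_per_litter[1] > pups_per_litter[2]) {
    stop("`pups_per_litter` must be an increasing range within 5-8",
         call. = FALSE)
  }
  groups <- psc_groups()
  for (nm in c("event_rate_hz", "surge_probability", "cort_fold")) {
    v <- get(nm)
    if (!all(groups %in% names(v))) {
      stop(sprintf("`%s` must be named with all four group labels", nm),
           call. = FALSE)
    }
  }
  for (p in surge_probability) check_probability(p, "surge_probability")
  structure(
    list(
      n_dams_per_group = as.integer(n_dams_per_group),
      pups_per_litter = as.integer(pups_per_litter),
      groups = groups,
      event_rate_hz = event_rate_hz[groups],
      surge_probability = surge_probability[groups],
      cort_fold = cort_fold[groups],
      cort_baseline_ng_ml = cort_baseline_ng_ml,
      dam_sd_log10 = dam_sd_log10,
      mouse_sd_log10 = mouse_sd_log10,
      resid_sd_log10 = resid_sd_log10,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Draw the animals of a synthetic cohort
#'
#' Realizes the dam -> litter -> mouse nesting of a [cohort_spec()]: each
#' group gets `n_dams_per_group` dams, each dam one litter of 5-8 female
#' pups.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with columns `dam_id`, `group`, `mouse_id`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    rows <- list()
    dam <- 0L
    mouse <- 0L
    for (g in spec$groups) {
      for (d in seq_len(spec$n_dams_per_group)) {
        dam <- dam + 1L
        n_pups <- sample(seq(spec$pups_per_litter[1],
                             spec$pups_per_litter[2]), 1L)
        ids <- mouse + seq_len(n_pups)
        mouse <- mouse + n_pups
        rows[[dam]] <- data.frame(
          dam_id = sprintf("dam%03d", dam),
          group = g,
          mouse_id = sprintf("mouse%04d", ids)
        )
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate pre/post corticosterone for a cohort
#'
#' Serum corticosterone is log-normal: on the log10 scale each mouse's pre
#' (0 h) and post (5 h, end of the adult paradigm) concentrations are the
#' group baseline plus the group's post/pre fold change (post samples
#' only), dam and mouse random intercepts, and residual noise. Values are
#' censored to the corticosterone EIA reportable range (3.9-1,000 ng/ml)
#' with a flag.
#'
#' @param spec A [cohort_spec()].
#' @param cohort Optional cohort table from [generate_cohort()]; generated
#'   from `spec` when omitted.
#' @return A data frame with columns `mouse_id`, `dam_id`, `group`, `time`
#'   (`"pre"`/`"post"`), `conc_ng_ml`, `censored`.
#' @export
#' @examples
#' cort <- generate_cort_profiles(cohort_spec(n_dams_per_group = 2))
#' head(cort)
generate_cort_profiles <- function(spec, cohort = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(cohort)) cohort <- generate_cohort(spec)
  rng <- assay_range("corticosterone")
  with_seed(derive_seed(spec$seed, 101L), {
    dams <- unique(cohort$dam_id)
    dam_re <- stats::setNames(
      stats::rnorm(length(dams), 0, spec$dam_sd_log10), dams
    )
    mouse_re <- stats::rnorm(nrow(cohort), 0, spec$mouse_sd_log10)
    base <- log10(spec$cort_baseline_ng_ml)
    out <- do.call(rbind, lapply(c("pre", "post"), function(tt) {
      shift <- if (tt == "post") log10(spec$cort_fold[cohort$group]) else 0
      mu <- base + shift + dam_re[cohort$dam_id] + mouse_re
      val <- 10^(mu + stats::rnorm(nrow(cohort), 0, spec$resid_sd_log10))
      data.frame(
        mouse_id = cohort$mouse_id, dam_id = cohort$dam_id,
        group = cohort$group, time = tt, conc_ng_ml = val
      )
    }))
    cen <- censor_to_range(out$conc_ng_ml, rng)
    out$conc_ng_ml <- cen$values
    out$censored <- cen$censored
    rownames(out) <- NULL
    out
  })
}
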