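#' Published cohort marginals for the tongue-feature study
#'
#' Per-category participant counts of the 2,675-participant clinical cohort
#' the generator emulates (1,658 diabetic, 1,017 non-diabetic). Fur colour
#' as published covers only 2,400 participants; the remaining 275 are
#' carried as the explicit `none` category, aligned with the `no_fur`
#' thickness category (the 58-record excess is treated as sparse coating on
#' thin-fur tongues, see the methods vignette).
#'
#' @return Named list: per single-valued feature a named integer count
#'   vector summing to 2675; `surface` holds the prevalence counts of the
#'   four multi-label surface marks; `teeth_markings` the yes-count;
#'   `phases` the four acquisition-phase sizes as a DM/non-DM matrix.
#' @export
table1_marginals <- function() {
  list(
    tongue_body   = c(medium = 1332L, enlarged = 915L, small = 428L),
    tongue_color  = c(mild_red = 1400L, red = 677L, pale = 375L, bluish = 223L),
    fur_color     = c(white = 1203L, black = 201L, yellow = 996L, none = 275L),
    fur_thickness = c(thin = 852L, thick = 1606L, no_fur = 217L),
    saliva        = c(normal = 1884L, dry = 518L, wet = 273L),
    surface       = c(red_spots = 1489L, black_spots = 1044L,
                      fissures = 1038L, petechiae = 205L),
    teeth_markings = 1662L,
    phases = matrix(c(272L, 258L, 483L, 267L, 723L, 339L, 180L, 153L),
                    nrow = 4, byrow = TRUE,
                    dimnames = list(paste0("phase", 1:4), c("DM", "non_DM")))
  )
}

#' Class-conditional effect models for the cohort generator
#'
#' Labels in a simulated cohort follow a logistic model: each record's
#' log-odds of diabetes is a calibrated intercept plus per-category offsets.
#' `effect_model_null()` gives no association between features and label.
#' `effect_model_default()` places a positive offset on the four signs the
#' TCM literature ties most strongly to diabetes — thick fur, yellow fur,
#' bluish tongue body colour and teeth markings. `effect_model_strong()`
#' is the fully informative template: every feature carries a signed offset
#' of the given magnitude, positive for the clinically abnormal categories
#' and negative for the unremarkable ones, which makes the classification
#' task strongly learnable.
#'
#' An effect model is a named list keyed by feature. Single-valued features
#' map to a named offset vector over categories (unnamed categories count
#' as 0); the boolean features (`teeth_markings` and the four surface
#' marks) map to either a single offset applied when the flag is present,
#' or a named pair `c(present = , absent = )`.
#'
#' @param magnitude Log-odds offset magnitude.
#' @return An effect-model list consumed by [simulate_cohort()] and
#'   [record_logits()].
#' @rdname effect_models
#' @export
effect_model_default <- function(magnitude = 1) {
  list(
    fur_thickness = c(thick = magnitude),
    fur_color     = c(yellow = magnitude),
    tongue_color  = c(bluish = magnitude),
    teeth_markings = magnitude
  )
}

#' @rdname effect_models
#' @export
effect_model_null <- function() list()

#' @rdname effect_models
#' @export
effect_model_strong <- function(magnitude = 2) {
  m <- magnitude
  list(
    tongue_body   = c(medium = -m, enlarged = m, small = m),
    tongue_color  = c(mild_red = -m, red = m, pale = m, bluish = m),
    fur_color     = c(white = -m, black = m, yellow = m, none = m),
    fur_thickness = c(thin = -m, thick = m, no_fur = m),
    saliva        = c(normal = -m, dry = m, wet = m),
    teeth_markings = c(present = m, absent = -m),
    red_spots     = c(present = m, absent = -m),
    black_spots   = c(present = m, absent = -m),
    fissures      = c(present = m, absent = -m),
    petechiae     = c(present = m, absent = -m)
  )
}

#' Per-record log-odds offsets under an effect model
#'
#' Sums a record's per-category effect offsets (without the intercept).
#'
#' @param records Validated record data.frame.
#' @param effects Effect model (see [effect_model_default()]).
#' @return Numeric vector of log-odds offsets, one per record.
#' @export
record_logits <- function(records, effects) {
  s <- numeric(nrow(records))
  schema <- tongue_schema()
  bool_feats <- c(schema$surface_flags, "teeth_markings")
  for (feat in names(effects)) {
    eff <- effects[[feat]]
    if (feat %in% names(schema$levels)) {
      unknown <- setdiff(names(eff), schema$levels[[feat]])
      if (length(unknown)) {
        tn_stop("config_error", "effect model: unknown %s category '%s'",
                feat, unknown[1])
      }
      full <- stats::setNames(numeric(length(schema$levels[[feat]])),
                              schema$levels[[feat]])
      full[names(eff)] <- eff
      s <- s + unname(full[as.character(records[[feat]])])
    } else if (feat %in% bool_feats) {
      present <- if (is.null(names(eff))) eff[1] else eff[["present"]]
      absent <- if (!is.null(names(eff)) && "absent" %in% names(eff)) eff[["absent"]] else 0
      s <- s + ifelse(records[[feat]], present, absent)
    } else {
      tn_stop("config_error", "effect model: unknown feature '%s'", feat)
    }
  }
  s
}

#' Calibrate the logistic intercept of the label model
#'
#' Finds, by bisection, the intercept `b0` such that the mean of
#' `plogis(b0 + offsets)` equals `target_rate` — i.e. the expected number
#' of DM labels matches the requested class size. With all offsets zero
#' this reduces to `qlogis(target_rate)` exactly.
#'
#' @param offsets Per-record log-odds offsets (from [record_logits()]).
#' @param target_rate Desired expected DM fraction in (0, 1).
#' @param tol Convergence tolerance on the rate (default 1e-10).
#' @return The intercept, a single numeric.
#' @export
calibrate_intercept <- function(offsets, target_rate, tol = 1e-10) {
  if (target_rate <= 0 || target_rate >= 1) {
    tn_stop("config_error", "target rate must be in (0,1), got %g", target_rate)
  }
  rate <- function(b0) mean(stats::plogis(b0 + offsets))
  lo <- -60; hi <- 60
  if (rate(lo) > target_rate || rate(hi) < target_rate) {
    tn_stop("calibration_error",
            "effects too extreme: target rate %g unreachable", target_rate)
  }
  mid <- 0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (abs(rate(mid) - target_rate) < tol) return(mid)
    if (rate(mid) < target_rate) lo <- mid else hi <- mid
  }
  mid
}

#' Specify a synthetic tongue-feature cohort
#'
#' Bundles and validates the generator's parameters. Defaults reproduce the
#' published cohort: 2,675 participants, 1,658 of them diabetic, with the
#' per-category counts of [table1_marginals()] and the
#' [effect_model_default()] class-conditional structure.
#'
#' @param n_total Number of participants.
#' @param n_dm Number (quota mode) or expected number (multinomial mode) of
#'   DM labels.
#' @param marginals Per-feature category counts (quota mode, integers
#'   summing to `n_total`) or probabilities (multinomial mode). Same shape
#'   as [table1_marginals()].
#' @param effects Effect model; see [effect_model_default()].
#' @param sampling `"quota"` — every single-valued feature's category
#'   counts (and the DM label count) are reproduced exactly; or
#'   `"multinomial"` — categories and labels are sampled independently so
#'   counts match in expectation only.
#' @param include_phase Add an acquisition-phase column with the four
#'   published phase sizes (no effect on features or labels).
#' @param seed Integer RNG seed; identical `(spec, seed)` gives an
#'   identical cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_total = 2675, n_dm = 1658,
                        marginals = table1_marginals(),
                        effects = effect_model_default(),
                        sampling = c("quota", "multinomial"),
                        include_phase = FALSE,
                        seed = 1L) {
  sampling <- match.arg(sampling)
  if (!is_count(n_total) || n_total < 1) tn_stop("config_error", "n_total must be a positive count")
  if (!is_count(n_dm) || n_dm > n_total) tn_stop("config_error", "n_dm must be a count <= n_total")
  feats <- names(tongue_schema()$levels)
  scaled <- marginals
  for (feat in feats) {
    m <- marginals[[feat]]
    if (is.null(m)) tn_stop("config_error", "marginals missing feature '%s'", feat)
    if (sampling == "quota") {
      # counts with a different total (e.g. the published marginals at a
      # reduced n_total) are apportioned proportionally at simulation time
      if (any(m != floor(m))) {
        tn_stop("config_error", "quota mode requires integer counts for '%s'", feat)
      }
      if (abs(sum(m) - 1) <= 1e-9) {
        tn_stop("config_error", "quota mode requires counts, not probabilities, for '%s'", feat)
      }
    } else if (abs(sum(m) - 1) > 1e-9) {
      scaled[[feat]] <- m / sum(m)
    }
  }
  structure(list(n_total = as.integer(n_total), n_dm = as.integer(n_dm),
                 marginals = scaled, effects = effects, sampling = sampling,
                 include_phase = include_phase, seed = as.integer(seed)),
            class = "cohort_spec")
}

# exact integer apportionment of n slots to category probabilities
# (largest remainder), used when scaling count marginals to a new n_total
apportion <- function(probs, n) {
  raw <- probs / sum(probs) * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(probs))
}

#' Simulate a synthetic tongue-feature cohort
#'
#' Draws `n_total` records whose single-valued feature categories follow
#' the spec's marginals — exactly in quota mode, in expectation in
#' multinomial mode — with the four surface marks as independent Bernoulli
#' flags at their published prevalences. Fur colour and fur thickness are
#' coupled: every `no_fur` record has fur colour `none`. Labels follow the
#' logistic effect model with the intercept calibrated by
#' [calibrate_intercept()] so the expected DM count equals `n_dm`; in quota
#' mode exactly `n_dm` DM labels are assigned (weighted, without
#' replacement, by each record's odds).
#'
#' @param spec A [cohort_spec()].
#' @return A record data.frame of `n_total` rows with attributes
#'   `dm_prob` (per-record diabetes probability under the generating
#'   model) and `intercept` (the calibrated baseline log-odds).
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) tn_stop("config_error", "spec must be a cohort_spec")
  withr::with_seed(spec$seed, simulate_cohort_impl(spec))
}

simulate_cohort_impl <- function(spec) {
  n <- spec$n_total
  marg <- spec$marginals
  quota <- spec$sampling == "quota"

  counts_for <- function(feat) {
    m <- marg[[feat]]
    if (quota && abs(sum(m) - n) < 0.5) return(stats::setNames(as.integer(m), names(m)))
    apportion(m, n)
  }

  draw_feature <- function(feat) {
    m <- marg[[feat]]
    if (quota) {
      cnt <- counts_for(feat)
      sample(rep(names(cnt), times = cnt))
    } else {
      sample(names(m), n, replace = TRUE, prob = m / sum(m))
    }
  }

  records <- data.frame(
    tongue_body = draw_feature("tongue_body"),
    tongue_color = draw_feature("tongue_color"),
    stringsAsFactors = FALSE
  )

  # fur: thickness first, colour coupled (no_fur <-> none)
  thickness <- draw_feature("fur_thickness")
  col_m <- marg$fur_color
  if (quota) {
    col_cnt <- counts_for("fur_color")
    n_none <- col_cnt[["none"]]
    n_nofur <- sum(thickness == "no_fur")
    if (n_none < n_nofur) {
      tn_stop("config_error",
              "fur_color 'none' count (%d) below fur_thickness 'no_fur' count (%d)",
              n_none, n_nofur)
    }
    extra_none <- n_none - n_nofur
    thin_idx <- which(thickness == "thin")
    if (extra_none > length(thin_idx)) {
      tn_stop("config_error", "not enough thin-fur records to absorb 'none' excess")
    }
    fur_color <- rep(NA_character_, n)
    fur_color[thickness == "no_fur"] <- "none"
    if (extra_none > 0) {
      fur_color[sample(thin_idx, extra_none)] <- "none"
    }
    open <- which(is.na(fur_color))
    rest <- col_cnt[setdiff(names(col_cnt), "none")]
    fur_color[open] <- sample(rep(names(rest), times = rest))
  } else {
    p <- col_m / sum(col_m)
    p_nofur <- sum(marg$fur_thickness / sum(marg$fur_thickness) *
                     (names(marg$fur_thickness) == "no_fur"))
    extra_none <- max(p[["none"]] - p_nofur, 0)
    fur_color <- rep(NA_character_, n)
    fur_color[thickness == "no_fur"] <- "none"
    thin_idx <- which(thickness == "thin")
    p_thin <- mean(thickness == "thin")
    if (length(thin_idx) && extra_none > 0) {
      is_none <- stats::runif(length(thin_idx)) < extra_none / max(p_thin, 1e-12)
      fur_color[thin_idx[is_none]] <- "none"
    }
    open <- which(is.na(fur_color))
    rest <- p[setdiff(names(p), "none")]
    fur_color[open] <- sample(names(rest), length(open), replace = TRUE,
                              prob = rest / sum(rest))
  }
  records$fur_thickness <- thickness
  records$fur_color <- fur_color
  records$saliva <- draw_feature("saliva")

  # prevalence counts are understood relative to the marginals' own cohort
  # size (their tongue_body total); probabilities (<= 1) pass through
  basis <- sum(marg$tongue_body)
  if (basis <= 1) basis <- 1
  surf <- marg$surface %||% table1_marginals()$surface
  surf_p <- ifelse(surf <= 1, surf, surf / basis)
  names(surf_p) <- names(surf)
  for (flag in names(surf_p)) {
    records[[flag]] <- stats::runif(n) < surf_p[[flag]]
  }
  teeth <- marg$teeth_markings %||% table1_marginals()$teeth_markings
  teeth_p <- if (teeth <= 1) teeth else teeth / basis
  records$teeth_markings <- stats::runif(n) < teeth_p

  # labels: calibrated logistic model
  s <- record_logits(records, spec$effects)
  b0 <- calibrate_intercept(s, spec$n_dm / n)
  p_dm <- stats::plogis(b0 + s)
  lab <- rep("non_DM", n)
  if (quota) {
    dm_idx <- sample.int(n, spec$n_dm, prob = p_dm)
    lab[dm_idx] <- "DM"
  } else {
    lab[stats::runif(n) < p_dm] <- "DM"
  }
  records$label <- lab

  if (isTRUE(spec$include_phase)) {
    ph <- rowSums(table1_marginals()$phases)
    cnt <- apportion(ph, n)
    records$phase <- sample(rep(names(cnt), times = cnt))
  }

  cols <- c(schema_columns(), if (isTRUE(spec$include_phase)) "phase")
  records <- records[cols] # canonical order
  rownames(records) <- NULL
  attr(records, "dm_prob") <- p_dm
  attr(records, "intercept") <- b0
  records
}

#' Stratified train/test split of a cohort
#'
#' Splits records by label: per class, the train size is
#' `round-half-up(train_fraction x class size)`; assignment within a class
#' is a seeded shuffle. The two parts are disjoint and exhaustive. At the
#' published class sizes (1,658 DM / 1,017 non-DM) and the study's 0.7
#' fraction this reproduces the 1161/712 train and 497/305 test per-class
#' counts.
#'
#' @param records Labeled record data.frame.
#' @param train_fraction Fraction in (0, 1); default 0.7.
#' @param seed Integer RNG seed.
#' @return List with elements `train` and `test` (record data.frames).
#' @export
split_cohort <- function(records, train_fraction = 0.7, seed = 1L) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    tn_stop("config_error", "train_fraction must be in (0,1), got %g", train_fraction)
  }
  records <- validate_records(records, require_label = TRUE)
  lab <- as.character(records$label)
  classes <- unique(lab)
  small <- classes[vapply(classes, function(cl) sum(lab == cl), 0L) < 2]
  if (length(small)) {
    tn_stop("data_error", "class '%s' has fewer than 2 records", small[1])
  }
  withr::with_seed(seed, {
    train_idx <- integer(0)
    for (cl in sort(classes)) {
      idx <- which(lab == cl)
      n_tr <- round_half_up(train_fraction * length(idx))
      train_idx <- c(train_idx, sample(idx)[seq_len(n_tr)])
    }
    train_idx <- sort(train_idx)
  })
  list(train = records[train_idx, , drop = FALSE],
       test = records[-train_idx, , drop = FALSE])
}
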