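# Seeded generator of synthetic clinical-note corpora with gold
# annotations. The corpus emulates the note population the extraction
# rules were designed for: planted FEV1 values across the surface-variant
# template bank, fever distractors (the classic false-positive mode of a
# naive keyword search), FEV1 mentions with no numeric value in reach, and
# FEV1/FVC ratio contexts. The template bank is fixed and versioned here
# so gold answers are stable; filler comes from a small neutral sentence
# pool with no PHI-like content.

# Liters templates; {v} is filled with a 2-decimal value.
TEMPLATES_LITERS <- c(
  "FEV1 %s L.",
  "FEV1: %s L.",
  "FEV-1 was %s liters.",
  "fev_1 %s on spirometry."
)

# Percent-predicted templates; {p} is filled with an integer.
TEMPLATES_PERCENT <- c(
  "FEV1 %s%% predicted.",
  "FEV-1: %s%% of predicted.",
  "FEV 1 of %s%%.",
  "fev_1 = %s%%.",
  "FEV1 was %s percent of predicted."
)

# Ratio contexts: the numeric after the mention is the FEV1/FVC ratio, not
# an FEV1 value; the ratio guard must reject it.
TEMPLATES_RATIO <- c(
  "FEV1/FVC ratio %s.",
  "FEV1/FVC %s, consistent with obstruction."
)
RATIO_VALUES <- c(0.45, 0.55, 0.62, 0.70)

# Valueless mentions: an FEV1 mention with no numeric token within reach.
# Each template keeps at least 20 digit-free characters after the mention
# so the forward window can never leak into the following sentence.
TEMPLATES_VALUELESS <- c(
  "FEV1 improved compared with prior testing.",
  "FEV1 not obtainable today; patient unable to perform maneuver.",
  "FEV-1 stable per previous pulmonary documentation."
)

# Fever distractors: contain "fever" but no FEV1 mention.
TEMPLATES_FEVER <- c(
  "Febrile overnight with fever of 101.3.",
  "Low-grade fever noted yesterday evening.",
  "Denies fever, chills, or night sweats."
)

FILLER_OPEN <- c(
  "Seen in pulmonary clinic for routine follow-up.",
  "Patient returns for evaluation of chronic dyspnea.",
  "Veteran with known obstructive lung disease presents today."
)
FILLER_CLOSE <- c(
  "Plan reviewed with patient.",
  "Will continue current inhaler regimen.",
  "Return to clinic as scheduled."
)

#' Simulation configuration for the synthetic note generator
#'
#' Planted value distributions are truncated normals emulating a COPD-clinic
#' population (liters mean 2.0 sd 0.8 on \[0.5, 5\]; percent-predicted mean
#' 65 sd 20 on \[15, 140\]). Truncation bounds sit strictly inside the
#' default extraction plausibility ranges, so on clean positives any
#' generator-vs-extractor disagreement indicates a code defect, not a
#' configuration mismatch.
#'
#' @param n_notes number of notes to generate.
#' @param seed integer RNG seed; corpora are byte-identical for a fixed
#'   seed.
#' @param p_positive proportion of notes carrying at least one true FEV1
#'   value (default 0.4).
#' @param p_fever_distractor proportion with a fever mention (default 0.2).
#' @param p_valueless_fev proportion with an FEV1 mention but no numeric in
#'   the window (default 0.05).
#' @param p_ratio_context proportion with an FEV1/FVC phrase (default 0.1).
#' @param p_multi_mention among positives, proportion with a second FEV1
#'   value mention (default 0.15).
#' @param liters_mean,liters_sd,liters_bounds truncated-normal parameters
#'   for liters-style values.
#' @param percent_mean,percent_sd,percent_bounds truncated-normal
#'   parameters for percent-predicted-style values.
#' @param p_percent_format probability a planted value is
#'   percent-predicted style (default 0.5).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_notes,
                       seed = 1L,
                       p_positive = 0.4,
                       p_fever_distractor = 0.2,
                       p_valueless_fev = 0.05,
                       p_ratio_context = 0.1,
                       p_multi_mention = 0.15,
                       liters_mean = 2.0, liters_sd = 0.8,
                       liters_bounds = c(0.5, 5.0),
                       percent_mean = 65, percent_sd = 20,
                       percent_bounds = c(15, 140),
                       p_percent_format = 0.5) {
  n_notes <- as.integer(n_notes)
  if (is.na(n_notes) || n_notes < 0L) stop_validation("n_notes must be >= 0")
  probs <- c(
    p_positive, p_fever_distractor, p_valueless_fev,
    p_ratio_context, p_multi_mention, p_percent_format
  )
  if (any(is.na(probs) | probs < 0 | probs > 1)) {
    stop_validation("all probabilities must lie in [0, 1]")
  }
  ranges <- extraction_config()
  if (liters_bounds[1] < ranges$liters_range[1] ||
    liters_bounds[2] > ranges$liters_range[2]) {
    stop_validation("liters_bounds must lie inside the extraction liters range")
  }
  if (percent_bounds[1] < ranges$percent_range[1] ||
    percent_bounds[2] > ranges$percent_range[2]) {
    stop_validation("percent_bounds must lie inside the extraction percent range")
  }
  structure(
    list(
      n_notes = n_notes, seed = as.integer(seed),
      p_positive = p_positive,
      p_fever_distractor = p_fever_distractor,
      p_valueless_fev = p_valueless_fev,
      p_ratio_context = p_ratio_context,
      p_multi_mention = p_multi_mention,
      liters_mean = liters_mean, liters_sd = liters_sd,
      liters_bounds = as.numeric(liters_bounds),
      percent_mean = percent_mean, percent_sd = percent_sd,
      percent_bounds = as.numeric(percent_bounds),
      p_percent_format = p_percent_format
    ),
    class = "sim_config"
  )
}

# Truncated-normal draws by rejection; exact truncation, deterministic
# under the scoped seed.
rtrunc_norm <- function(k, mean, sd, lo, hi) {
  out <- numeric(k)
  need <- seq_len(k)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

draw_value <- function(config, is_percent) {
  if (is_percent) {
    round(rtrunc_norm(1, config$percent_mean, config$percent_sd,
      config$percent_bounds[1], config$percent_bounds[2]))
  } else {
    round(rtrunc_norm(1, config$liters_mean, config$liters_sd,
      config$liters_bounds[1], config$liters_bounds[2]), 2)
  }
}

positive_segment <- function(config, is_percent, value) {
  if (is_percent) {
    sprintf(sample(TEMPLATES_PERCENT, 1), format(value))
  } else {
    sprintf(sample(TEMPLATES_LITERS, 1), sprintf("%.2f", value))
  }
}

random_datetime <- function(n) {
  # Uniform over the 1996-2015 study window, seconds resolution.
  origin <- as.POSIXct("1996-01-01 00:00:00", tz = "UTC")
  span <- as.numeric(as.POSIXct("2015-12-31 23:59:59", tz = "UTC")) -
    as.numeric(origin)
  t <- origin + floor(stats::runif(n, 0, span))
  format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

#' Generate a synthetic note corpus with gold annotations
#'
#' Deterministic for a fixed seed. Positive notes embed one (or, for
#' multi-mention notes, two) values drawn from the configured truncated
#' distributions into templates covering every default surface variant;
#' fever, valueless-FEV1 and ratio distractors are injected independently
#' per their class probabilities. Patient ids are drawn from a pool of
#' about half the corpus size, so some patients have multiple notes.
#'
#' The gold table records ground truth exactly: `reference_value` is the
#' first extractable value in document order (so the gold table doubles as
#' a reference-annotation table for [evaluate()]), `planted_unit` its
#' style, `n_mentions` the number of FEV1 mentions of any kind, and
#' `distractor_classes` a `;`-separated subset of `fever`, `valueless`,
#' `ratio`.
#'
#' @param config a [sim_config()].
#' @return list with `notes` and `gold` data.frames.
#' @export
#' @examples
#' corpus <- generate_corpus(sim_config(n_notes = 10, seed = 42))
#' corpus$notes$text[corpus$gold$has_value][1]
generate_corpus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_notes
  gold_cols <- list(
    note_id = character(), has_value = logical(),
    reference_value = numeric(), planted_unit = character(),
    n_mentions = integer(), distractor_classes = character()
  )
  if (n == 0L) {
    return(list(
      notes = as.data.frame(stats::setNames(rep(list(character()), 4), NOTE_FIELDS)),
      gold = as.data.frame(gold_cols)
    ))
  }
  with_seed(config$seed, {
    id_w <- max(5L, nchar(as.character(n)))
    note_id <- sprintf(paste0("N%0", id_w, "d"), seq_len(n))
    pool <- sprintf("P%05d", seq_len(max(1L, ceiling(n / 2))))
    patient_id <- sample(pool, n, replace = TRUE)
    note_datetime <- random_datetime(n)

    is_pos <- stats::runif(n) < config$p_positive
    has_fever <- stats::runif(n) < config$p_fever_distractor
    has_valueless <- stats::runif(n) < config$p_valueless_fev
    has_ratio <- stats::runif(n) < config$p_ratio_context
    is_multi <- is_pos & stats::runif(n) < config$p_multi_mention

    text <- character(n)
    ref_value <- rep(NA_real_, n)
    unit <- rep(NA_character_, n)
    n_mentions <- integer(n)
    classes <- character(n)

    for (i in seq_len(n)) {
      segs <- sample(FILLER_OPEN, 1)
      m <- 0L
      if (has_ratio[i]) {
        segs <- c(segs, sprintf(
          sample(TEMPLATES_RATIO, 1),
          sprintf("%.2f", sample(RATIO_VALUES, 1))
        ))
        m <- m + 1L
      }
      if (is_pos[i]) {
        is_percent <- stats::runif(1) < config$p_percent_format
        v <- draw_value(config, is_percent)
        segs <- c(segs, positive_segment(config, is_percent, v))
        ref_value[i] <- v
        unit[i] <- if (is_percent) "percent_predicted" else "liters"
        m <- m + 1L
        if (is_multi[i]) {
          is_percent2 <- stats::runif(1) < config$p_percent_format
          segs <- c(segs, positive_segment(
            config, is_percent2, draw_value(config, is_percent2)
          ))
          m <- m + 1L
        }
      }
      if (has_valueless[i]) {
        segs <- c(segs, sample(TEMPLATES_VALUELESS, 1))
        m <- m + 1L
      }
      if (has_fever[i]) {
        segs <- c(segs, sample(TEMPLATES_FEVER, 1))
      }
      segs <- c(segs, sample(FILLER_CLOSE, 1))
      text[i] <- paste(segs, collapse = " ")
      n_mentions[i] <- m
      cls <- c(
        if (has_fever[i]) "fever",
        if (has_valueless[i]) "valueless",
        if (has_ratio[i]) "ratio"
      )
      classes[i] <- paste(cls, collapse = ";")
    }

    notes <- data.frame(
      note_id = note_id, patient_id = patient_id,
      note_datetime = note_datetime, text = text,
      stringsAsFactors = FALSE
    )
    gold <- data.frame(
      note_id = note_id, has_value = is_pos,
      reference_value = ref_value, planted_unit = unit,
      n_mentions = n_mentions, distractor_classes = classes,
      stringsAsFactors = FALSE
    )
    list(notes = notes, gold = gold)
  })
}

#' Generate a structured measurement table overlapping a synthetic corpus
#'
#' Selects each patient of the corpus into an emulated warehouse table with
#' probability `p_in_structured`, attaching one quantifiable measurement
#' drawn from the liters distribution. With `p_in_structured = 1` the
#' structured table covers every patient (so the text tool adds nobody);
#' with 0 it is empty (the tool adds every extracted patient) — giving
#' known expected counts for exercising [merge_yield()].
#'
#' @param notes notes data.frame from [generate_corpus()].
#' @param config the [sim_config()] used to generate the corpus (supplies
#'   the value distribution).
#' @param p_in_structured inclusion probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return data.frame with `patient_id`, `measure_datetime`, `fev1_value`.
#' @export
generate_structured_overlap <- function(notes, config, p_in_structured, seed = 1L) {
  if (is.na(p_in_structured) || p_in_structured < 0 || p_in_structured > 1) {
    stop_validation("p_in_structured must lie in [0, 1]")
  }
  patients <- sort(unique(notes$patient_id))
  with_seed(seed, {
    sel <- patients[stats::runif(length(patients)) < p_in_structured]
    data.frame(
      patient_id = sel,
      measure_datetime = random_datetime(length(sel)),
      fev1_value = if (length(sel)) {
        round(rtrunc_norm(
          length(sel), config$liters_mean, config$liters_sd,
          config$liters_bounds[1], config$liters_bounds[2]
        ), 2)
      } else {
        numeric()
      },
      stringsAsFactors = FALSE
    )
  })
}
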