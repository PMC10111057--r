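#' @importFrom stats rnorm runif rbinom approx
NULL

THERAPY_GROUPS <- c("placebo", "BBT", "TRT", "TEAE", "ADT", "control")
THI_LEVELS  <- c("light", "mild", "moderate", "severe", "catastrophic")
HADS_LEVELS <- c("normal", "borderline", "abnormal")
AUDIOGRAM_FREQS <- c(125, 250, 500, 1000, 2000, 4000, 8000)

#' Construct an audiogram
#'
#' Per-ear hearing thresholds (dB HL) over the standard octave test
#' frequencies 125--8000 Hz.
#'
#' @param left,right Numeric vectors of thresholds in dB HL, one per frequency.
#' @param freqs Test frequencies in Hz, strictly increasing.
#' @return An object of class `audiogram`: list with `freqs`, `left`, `right`.
#' @export
new_audiogram <- function(left, right, freqs = AUDIOGRAM_FREQS) {
  stopifnot(length(left) == length(freqs), length(right) == length(freqs))
  if (any(diff(freqs) <= 0)) stop("audiogram frequencies must be strictly increasing")
  if (any(c(left, right) < -10 | c(left, right) > 120))
    stop("hearing thresholds must lie in [-10, 120] dB HL")
  structure(list(freqs = freqs, left = left, right = right), class = "audiogram")
}

#' Interpolate hearing loss at arbitrary frequencies
#'
#' Linear interpolation of an audiogram on a log-frequency axis, constant
#' extrapolation beyond the tested range.
#'
#' @param ag An `audiogram`.
#' @param freq Frequencies (Hz) at which to evaluate.
#' @param ear `"left"`, `"right"` or `"both"` (mean of ears).
#' @return Hearing loss in dB HL at `freq`.
#' @export
hearing_loss_at <- function(ag, freq, ear = c("both", "left", "right")) {
  ear <- match.arg(ear)
  thr <- switch(ear, left = ag$left, right = ag$right,
                both = (ag$left + ag$right) / 2)
  approx(log2(ag$freqs), thr, xout = log2(freq), rule = 2)$y
}

#' Hearing-level band of an audiogram
#'
#' Classifies the mean threshold into the five standard hearing-level bands:
#' normal (0--25 dB), slight (26--40), moderate (41--60), severe (61--80),
#' profound (> 80).
#'
#' @param ag An `audiogram`.
#' @return One of `"normal"`, `"slight"`, `"moderate"`, `"severe"`, `"profound"`.
#' @export
hearing_level_band <- function(ag) {
  m <- mean(c(ag$left, ag$right))
  if (m <= 25) "normal" else if (m <= 40) "slight" else if (m <= 60) "moderate"
  else if (m <= 80) "severe" else "profound"
}

#' Construct a tinnitus profile
#'
#' @param pitch Tinnitus pitch in Hz (> 0).
#' @param intensity Perceived loudness, 0 (very soft) to 100 dB (very loud).
#' @param laterality `"L"`, `"R"` or `"B"` (both ears).
#' @param well_identified Whether the pitch match was unambiguous; drives
#'   assignment to the pitch-personalized therapies.
#' @return An object of class `tinnitus_profile`.
#' @export
new_tinnitus_profile <- function(pitch, intensity, laterality,
                                 well_identified = TRUE) {
  stopifnot(pitch > 0, intensity >= 0, intensity <= 100)
  laterality <- match.arg(laterality, c("L", "R", "B"))
  structure(list(pitch = pitch, intensity = intensity,
                 laterality = laterality, well_identified = well_identified),
            class = "tinnitus_profile")
}

#' Recruitment bookkeeping of the study design
#'
#' Per-group recruit and completion counts of the cohort the simulator
#' emulates: 103 recruits, 71 completers, 32 non-completers.
#'
#' @return Data frame with columns `group`, `recruited`, `completed`.
#' @export
recruitment_table <- function() {
  data.frame(
    group = THERAPY_GROUPS,
    recruited = c(16L, 18L, 18L, 18L, 19L, 14L),
    completed = c(11L, 14L, 15L, 15L, 8L, 8L),
    stringsAsFactors = FALSE
  )
}

# draw one participant consistent with the generating rules of its group
simulate_participant <- function(id, group) {
  healthy <- group == "control"
  age <- round(min(max(rnorm(1, 48, 14), 18), 80))
  sex <- sample(c("F", "M"), 1, prob = c(0.53, 0.47))
  heart_rate <- round(min(max(rnorm(1, 72, 8), 45), 120))

  # age-dependent sloping loss, worse at high frequencies; per-ear wobble
  base <- pmax(rnorm(1, 8, 6), -5) + pmax(age - 40, 0) * 0.25
  slope <- runif(1, 2, 9)                       # dB per octave above 1 kHz
  oct_above <- pmax(log2(AUDIOGRAM_FREQS / 1000), 0)
  shape <- base + slope * oct_above
  clamp_hl <- function(x) pmin(pmax(x, -10), 120)
  left  <- clamp_hl(round(shape + rnorm(length(shape), 0, 4)))
  right <- clamp_hl(round(shape + rnorm(1, 0, 6) + rnorm(length(shape), 0, 4)))
  ag <- new_audiogram(left, right, AUDIOGRAM_FREQS)

  tin <- NULL
  if (!healthy) {
    pitch <- switch(group,
      BBT = runif(1, 125, 990),
      2 ^ runif(1, log2(1000), log2(8000)))  # pitch-matched 1-8 kHz otherwise
    well <- group %in% c("BBT", "TRT", "ADT")
    # intensity tracks right-ear loss (built-in dependence for the
    # correlation screen), plus reporting noise, clipped to the 0-100 scale
    hl_r <- mean(ag$right)
    intensity <- min(max(round(0.9 * hl_r + 12 + rnorm(1, 0, 14)), 0), 100)
    laterality <- sample(c("L", "R", "B"), 1, prob = c(0.50, 0.32, 0.18))
    tin <- new_tinnitus_profile(pitch, intensity, laterality, well)
  }

  # questionnaires: baseline severity, mostly-unchanged follow-up
  if (healthy) {
    thi0 <- sample(0:14, 1)
  } else {
    thi0 <- min(max(round(rnorm(1, 46, 20)), 0), 100)
  }
  thif <- min(max(thi0 + round(rnorm(1, 0, 9)), 0), 100)
  ha0 <- min(max(round(rnorm(1, if (healthy) 4 else 8, 3.5)), 0), 21)
  haf <- min(max(ha0 + round(rnorm(1, 0, 2)), 0), 21)
  hs0 <- min(max(round(rnorm(1, if (healthy) 4 else 8, 3.5)), 0), 21)
  hsf <- min(max(hs0 + round(rnorm(1, 0, 2)), 0), 21)

  structure(list(
    id = id,
    condition = if (healthy) "healthy" else "tinnitus",
    age = age, sex = sex, heart_rate = heart_rate,
    audiogram = ag, tinnitus = tin, group = group,
    thi_score = c(S0 = thi0, Sf = thif),
    hads_anxiety = c(S0 = ha0, Sf = haf),
    hads_stress = c(S0 = hs0, Sf = hsf)
  ), class = "participant")
}

#' Simulate a study cohort
#'
#' Draws a seeded synthetic cohort with the structure of the study sample:
#' per-group sizes default to the completed-procedure counts (11 placebo,
#' 14 BBT, 15 TRT, 15 TEAE, 8 ADT, 8 healthy controls; 71 in total).
#' Each participant carries demographics, an audiogram, a tinnitus profile
#' (pitch up to 8 kHz, intensity 0--100 dB, laterality L/R/B) consistent with
#' its therapy-assignment rule, and THI/HADS scores for the initial (S0) and
#' final (Sf) sessions.
#'
#' @param n_per_group Named integer vector of group sizes over
#'   `r paste(THERAPY_GROUPS, collapse = ", ")`; all entries >= 1.
#' @param seed Integer seed; the cohort is a deterministic function of it.
#' @return A list of `participant` objects, class `cohort`, with attributes
#'   `recruited` (per-group recruit counts when the default sizes are used)
#'   and `seed`.
#' @export
simulate_cohort <- function(n_per_group = NULL, seed = 1) {
  rt <- recruitment_table()
  default_sizes <- is.null(n_per_group)
  if (default_sizes) {
    n_per_group <- stats::setNames(rt$completed, rt$group)
  }
  if (is.null(names(n_per_group)) && length(n_per_group) == length(THERAPY_GROUPS))
    names(n_per_group) <- THERAPY_GROUPS
  if (!setequal(names(n_per_group), THERAPY_GROUPS))
    stop("n_per_group must be named with: ", paste(THERAPY_GROUPS, collapse = ", "))
  n_per_group <- n_per_group[THERAPY_GROUPS]
  if (any(n_per_group < 1)) stop("every group size must be >= 1")

  set.seed(seed)
  cohort <- list()
  k <- 0
  for (g in THERAPY_GROUPS) {
    for (j in seq_len(n_per_group[[g]])) {
      k <- k + 1
      cohort[[k]] <- simulate_participant(sprintf("P%03d", k), g)
    }
  }
  structure(cohort, class = "cohort",
            recruited = if (default_sizes) stats::setNames(rt$recruited, rt$group) else NULL,
            seed = seed)
}

#' Assign a participant to a therapy group
#'
#' Applies the assignment rules in priority order: healthy volunteers form
#' the control group; tinnitus pitch below 1 kHz goes to binaural-beats
#' therapy (BBT); otherwise a well-identified pitch goes randomly to TRT or
#' ADT; remaining patients (no severe hearing loss assumed at recruitment)
#' go randomly to placebo or TEAE.
#'
#' @param p A `participant`.
#' @param seed Optional integer seed for the random arms.
#' @return Group label, one of `r paste(THERAPY_GROUPS, collapse = ", ")`.
#' @export
assign_group <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (p$condition == "healthy") return("control")
  if (is.null(p$tinnitus)) stop("tinnitus participant without a tinnitus profile")
  if (p$tinnitus$pitch < 1000) return("BBT")
  if (isTRUE(p$tinnitus$well_identified)) return(sample(c("TRT", "ADT"), 1))
  sample(c("placebo", "TEAE"), 1)
}

#' Categorize a THI score
#'
#' Maps a Tinnitus Handicap Inventory total (0--100) onto the five standard
#' grades: light (0--16), mild (18--36), moderate (38--56), severe (58--76),
#' catastrophic (78--100), extended linearly to odd scores.
#'
#' @param score Numeric in \[0, 100\].
#' @return Factor level among `light, mild, moderate, severe, catastrophic`.
#' @export
categorize_thi <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 100))
    stop("THI score must lie in [0, 100]")
  idx <- findInterval(score, c(0, 17.5, 37.5, 57.5, 77.5))
  factor(THI_LEVELS[idx], levels = THI_LEVELS, ordered = TRUE)
}

#' Categorize a HADS subscale score
#'
#' Maps a Hospital Anxiety and Depression Scale subscale total (0--21) onto
#' the standard bands: normal (0--7), borderline abnormal (8--10),
#' abnormal (11--21).
#'
#' @param score Numeric in \[0, 21\].
#' @return Factor level among `normal, borderline, abnormal`.
#' @export
categorize_hads <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 21))
    stop("HADS score must lie in [0, 21]")
  idx <- findInterval(score, c(0, 7.5, 10.5))
  factor(HADS_LEVELS[idx], levels = HADS_LEVELS, ordered = TRUE)
}

#' Categorize a before/after questionnaire effect
#'
#' Compares the category at the final session (Sf) with the initial one (S0):
#' a lower category is a positive effect (reduction of tinnitus perception,
#' anxiety or stress), equal categories no effect, a higher category a
#' negative effect.
#'
#' @param cat_s0,cat_sf Ordered factors from [categorize_thi()] or
#'   [categorize_hads()]; both from the same instrument.
#' @return One of `"positive"`, `"none"`, `"negative"`.
#' @export
categorize_effect <- function(cat_s0, cat_sf) {
  l0 <- levels(cat_s0); lf <- levels(cat_sf)
  if (!identical(l0, lf))
    stop("categories come from different instruments")
  d <- as.integer(cat_sf) - as.integer(cat_s0)
  if (d < 0) "positive" else if (d == 0) "none" else "negative"
}

#' Flatten a cohort to one row per participant
#'
#' @param cohort A `cohort`.
#' @return Data frame with demographics, tinnitus profile, mean hearing loss
#'   per ear, and S0/Sf questionnaire scores.
#' @export
cohort_table <- function(cohort) {
  rows <- lapply(cohort, function(p) {
    data.frame(
      id = p$id, group = p$group, condition = p$condition,
      age = p$age, sex = p$sex, heart_rate = p$heart_rate,
      hl_left = mean(p$audiogram$left), hl_right = mean(p$audiogram$right),
      hearing_band = hearing_level_band(p$audiogram),
      pitch = if (is.null(p$tinnitus)) NA_real_ else p$tinnitus$pitch,
      intensity = if (is.null(p$tinnitus)) NA_real_ else p$tinnitus$intensity,
      laterality = if (is.null(p$tinnitus)) NA_character_ else p$tinnitus$laterality,
      thi_s0 = p$thi_score[["S0"]], thi_sf = p$thi_score[["Sf"]],
      hads_a_s0 = p$hads_anxiety[["S0"]], hads_a_sf = p$hads_anxiety[["Sf"]],
      hads_s_s0 = p$hads_stress[["S0"]], hads_s_sf = p$hads_stress[["Sf"]],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
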