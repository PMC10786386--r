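#' Simulation configuration for synthetic event logs
#'
#' Describes the statistical structure of a synthetic emergency-department
#' observation study: cohort sizes, the per-trajectory interaction-count
#' distribution (discrete on 2..12 with median 5), presentation-mode
#' probabilities, the team rosters of a default catalog, the probability
#' that a cross-team interaction is mediated by the hub agent (the
#' Psychiatric Liaison Nurse), the referral trigger signatures (an
#' interaction between a Registrar and the Patient File, or between a
#' Consultant and the Patient), and an exponential model for the gaps
#' between interactions (mean 25 minutes, tuned so that the median
#' trajectory time is about 1.5 h at the default interaction counts).
#'
#' @param seed RNG seed used by [generate_event_log()].
#' @param n_ed_patients,n_mhoa_only_patients Cohort sizes.
#' @param n_referred Number of ED patients referred to Emergency Psychiatry.
#' @param interaction_count_probs Named probability vector over interaction
#'   counts per ED trajectory.
#' @param interaction_counts,mhoa_interaction_counts,referral_steps Optional
#'   explicit per-patient values overriding the random draws (used by the
#'   study-scale fixture to pin bookkeeping exactly).
#' @param presentation_probs Named probability vector of presentation modes
#'   (a combined mode such as `"Ambulance+Police"` is one categorical level).
#' @param catalog An [agent_catalog()]; must contain the rosters below.
#' @param hub Name of the hub agent mediating cross-team interactions.
#' @param hub_mediation_prob Probability that a cross-team interaction is
#'   routed through the hub instead of occurring directly between doctors.
#' @param cross_team_prob Probability that a pre-referral interaction is
#'   cross-team.
#' @param trigger_probs Named probabilities over referral trigger
#'   signatures, names of the form `"Agent|Agent or system"`.
#' @param referral_action Action string emitted at the referral interaction.
#' @param mean_gap_mins Mean of the exponential inter-interaction gap.
#' @param prob_associate Probability that an associate accompanies the
#'   patient at triage (in addition to `"Associate"` presentations).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_ed_patients = 36,
                       n_mhoa_only_patients = 7,
                       n_referred = 20,
                       interaction_count_probs = c(
                         `2` = 0.10, `3` = 0.14, `4` = 0.15, `5` = 0.15,
                         `6` = 0.12, `7` = 0.10, `8` = 0.08, `9` = 0.06,
                         `10` = 0.05, `11` = 0.03, `12` = 0.02),
                       interaction_counts = NULL,
                       mhoa_interaction_counts = NULL,
                       referral_steps = NULL,
                       presentation_probs = c(
                         Ambulance = 0.30, Police = 0.15,
                         `Ambulance+Police` = 0.12, Self = 0.25,
                         Associate = 0.18),
                       catalog = default_catalog(),
                       hub = "Psychiatric Liaison Nurse",
                       hub_mediation_prob = 0.9,
                       cross_team_prob = 0.15,
                       trigger_probs = c(`Registrar|Patient File` = 0.5,
                                         `Consultant|Patient` = 0.5),
                       referral_action = "Referral to Emergency Psychiatry",
                       mean_gap_mins = 20,
                       prob_associate = 0.2) {
  cfg <- list(seed = seed, n_ed_patients = n_ed_patients,
              n_mhoa_only_patients = n_mhoa_only_patients,
              n_referred = n_referred,
              interaction_count_probs = interaction_count_probs,
              interaction_counts = interaction_counts,
              mhoa_interaction_counts = mhoa_interaction_counts,
              referral_steps = referral_steps,
              presentation_probs = presentation_probs,
              catalog = catalog, hub = hub,
              hub_mediation_prob = hub_mediation_prob,
              cross_team_prob = cross_team_prob,
              trigger_probs = trigger_probs,
              referral_action = referral_action,
              mean_gap_mins = mean_gap_mins,
              prob_associate = prob_associate)
  probs <- c(hub_mediation_prob, cross_team_prob, prob_associate)
  stopifnot(all(probs >= 0 & probs <= 1),
            abs(sum(interaction_count_probs) - 1) < 1e-8,
            abs(sum(presentation_probs) - 1) < 1e-8,
            abs(sum(trigger_probs) - 1) < 1e-8)
  if (hub_mediation_prob > 0 && !hub %in% catalog$name) {
    stop("hub agent ", hub, " is not in the catalog")
  }
  class(cfg) <- "sim_config"
  cfg
}

# roster helpers
roster <- function(catalog, team, role = NULL) {
  keep <- catalog$category == "clinical_staff" & catalog$team == team
  if (!is.null(role)) keep <- keep & catalog$role == role
  catalog$name[keep]
}

#' Generate a synthetic clinical event log
#'
#' Simulates trajectories with the structure the downstream analyses
#' measure rather than clinical content: every patient starts with a triage
#' interaction; pre-referral interactions are drawn from Emergency Medical
#' patterns (nursing observations, junior-doctor assessments, staff
#' discussions with information-system access); cross-team information flow
#' is routed through the hub agent with probability `hub_mediation_prob`
#' (and otherwise occurs directly between doctors of the two teams);
#' referred patients emit the referral action at the first occurrence of a
#' trigger signature, which the generator withholds from all earlier
#' interactions so the referral point is identifiable; post-referral
#' interactions involve the Emergency Psychiatry team and its restricted
#' systems. Information systems are only ever listed alongside at least one
#' staff member permitted to access them, so no record reduces to a
#' forbidden pairing. Timestamp gaps are exponential at minute precision.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `log` (an `event_log`) and `truth` (ground
#'   truth: hub identity, team rosters, per-patient referral steps and the
#'   trigger signature used).
#' @export
generate_event_log <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  catalog <- cfg$catalog
  em_doctors <- roster(catalog, "emergency_medical", "doctor")
  em_nurses <- setdiff(roster(catalog, "emergency_medical", "nurse"), "Triage Nurse")
  ep_staff <- roster(catalog, "emergency_psychiatry")
  ep_doctors <- roster(catalog, "emergency_psychiatry", "doctor")
  mhoa_staff <- roster(catalog, "mhoa")
  junior <- intersect(em_doctors, c("RMO", "Intern"))
  if (length(junior) == 0) junior <- em_doctors

  n_ed <- cfg$n_ed_patients
  counts <- cfg$interaction_counts
  if (is.null(counts)) {
    counts <- as.integer(sample(names(cfg$interaction_count_probs), n_ed,
                                replace = TRUE,
                                prob = cfg$interaction_count_probs))
  }
  stopifnot(length(counts) == n_ed, all(counts >= 1))
  n_ref <- min(cfg$n_referred, n_ed)
  # referral requires at least 2 interactions (triage, then the trigger);
  # larger trajectories host larger referral steps
  eligible <- order(-counts)[seq_len(n_ref)]
  steps <- cfg$referral_steps
  if (is.null(steps)) {
    steps <- vapply(counts[eligible], function(m) {
      sample(2:min(m, 7), 1)
    }, integer(1))
  }
  stopifnot(length(steps) == n_ref, all(steps >= 2),
            all(steps <= counts[eligible]))

  presentations <- sample(names(cfg$presentation_probs), n_ed + cfg$n_mhoa_only_patients,
                          replace = TRUE, prob = cfg$presentation_probs)

  rows <- list()
  truth_steps <- integer(0)
  truth_trigger <- character(0)
  referred_ids <- character(0)

  add_row <- function(patient, setting, presentation, ts, agents, systems, action) {
    rows[[length(rows) + 1]] <<- data.frame(
      patient = patient, setting = setting, presentation = presentation,
      date = format(ts, "%d/%m/%Y"), time = format(ts, "%H:%M"),
      agents = paste(agents, collapse = "; "),
      information_systems = paste(systems, collapse = "; "),
      action = action, stringsAsFactors = FALSE)
  }

  base <- as.POSIXct("01/07/2018 00:00", format = "%d/%m/%Y %H:%M", tz = "UTC")

  draw_medical <- function(referred_patient, escort, primary) {
    # one pre-referral Emergency Medical interaction; for patients that will
    # be referred, the trigger signatures (Registrar with the Patient File,
    # Consultant with the Patient) are withheld until the referral step
    pattern <- sample(c("nurse_obs", "doctor_assess", "doctor_review",
                        "tn_handover", "escort_handover", "team_round",
                        "hub_read"),
                      1, prob = c(0.24, 0.2, 0.13, 0.11, 0.12, 0.12, 0.08))
    if (pattern == "escort_handover" && length(escort) == 0) {
      pattern <- "nurse_obs"
    }
    if (pattern == "nurse_obs") {
      agents <- c("Nurse", "Patient")
      systems <- if (runif(1) < 0.3) "EDIS" else character(0)
    } else if (pattern == "doctor_assess") {
      # the primary treating doctor does most of the assessing
      pool <- if (referred_patient) junior else em_doctors
      d <- if (runif(1) < 0.7) primary else sample(pool, 1)
      agents <- c(d, "Patient")
      if (runif(1) < 0.25) agents <- c(agents, "Associate")
      if (runif(1) < 0.3) agents <- c(agents, "Nurse")
      with_pf <- runif(1) < 0.5 && !(referred_patient && d == "Registrar")
      systems <- if (with_pf) "Patient File" else "EDIS"
      if (referred_patient && d == "Consultant") agents <- setdiff(agents, "Patient")
    } else if (pattern == "doctor_review") {
      d <- if (runif(1) < 0.6) primary else sample(em_doctors, 1)
      partner <- if (runif(1) < 0.6) "Nurse" else sample(setdiff(em_doctors, d), 1)
      agents <- unique(c(d, partner))
      if (referred_patient && "Registrar" %in% agents) {
        systems <- "EDIS"
      } else {
        systems <- sample(c("Patient File", "EDIS"), 1)
      }
    } else if (pattern == "tn_handover") {
      # triage nurse hands the presentation over to the treating team
      agents <- c("Triage Nurse", sample(c("Nurse", sample(em_doctors, 1)), 1))
      systems <- if (runif(1) < 0.4) "EDIS" else character(0)
    } else if (pattern == "team_round") {
      # bedside round: the treating doctor, a colleague, the nurse, patient
      pool <- if (referred_patient) setdiff(em_doctors, "Consultant") else em_doctors
      agents <- c(if (primary %in% pool) primary else sample(pool, 1),
                  "Nurse", "Patient")
      if (runif(1) < 0.4) agents <- unique(c(agents, sample(pool, 1)))
      systems <- if (runif(1) < 0.4) "EDIS" else character(0)
    } else if (pattern == "escort_handover") {
      # ambulance or police escort briefs the treating staff (cf. a
      # paramedic talking to the nurse at the bedside)
      agents <- c(sample(escort, 1),
                  sample(c("Nurse", "Triage Nurse", sample(em_doctors, 1)), 1))
      systems <- if (runif(1) < 0.3) "EDIS" else character(0)
    } else { # hub_read: the PLN gathers information from medical systems
      agents <- cfg$hub
      systems <- sample(c("EDIS", "Patient File"), 1)
    }
    list(agents = unique(agents), systems = systems)
  }

  draw_cross_team <- function() {
    if (runif(1) < cfg$hub_mediation_prob) {
      other <- sample(c(em_doctors, em_nurses, "Nurse"), 1)
      agents <- c(cfg$hub, other)
      systems <- if (runif(1) < 0.35) sample(c("PSOLIS", "EDYHO"), 1) else character(0)
    } else {
      agents <- c(sample(em_doctors, 1), sample(ep_doctors, 1))
      systems <- character(0)
    }
    list(agents = unique(agents), systems = systems)
  }

  draw_psych <- function() {
    pattern <- sample(c("pln_patient", "psych_assess", "psych_handover",
                        "pln_system", "pln_community"),
                      1, prob = c(0.28, 0.25, 0.2, 0.17, 0.1))
    if (pattern == "pln_patient") {
      list(agents = c(cfg$hub, "Patient"), systems = character(0))
    } else if (pattern == "psych_assess") {
      # the PLN usually sits in on the psychiatric assessment
      agents <- c(sample(ep_doctors, 1), "Patient")
      if (runif(1) < 0.6) agents <- c(agents, cfg$hub)
      list(agents = agents,
           systems = if (runif(1) < 0.4) "PSOLIS" else character(0))
    } else if (pattern == "psych_handover") {
      list(agents = c(cfg$hub, sample(ep_doctors, 1)),
           systems = if (runif(1) < 0.5) "EDYHO" else character(0))
    } else if (pattern == "pln_system") {
      list(agents = cfg$hub, systems = sample(c("PSOLIS", "EDYHO"), 1))
    } else {
      # liaison with community mental health services
      list(agents = c(cfg$hub, "Community Mental Health"),
           systems = character(0))
    }
  }

  for (p in seq_len(n_ed)) {
    id <- sprintf("ED%02d", p)
    m <- counts[p]
    is_ref <- p %in% eligible
    r <- if (is_ref) steps[match(p, eligible)] else NA_integer_
    pres <- presentations[p]
    primary <- if (is_ref) sample(junior, 1) else sample(em_doctors, 1)
    ts <- base + (p - 1) * 86400 + round(runif(1, 8 * 60, 20 * 60)) * 60
    triage_agents <- c("Triage Nurse", "Patient")
    escort <- character(0)
    if (grepl("Ambulance", pres)) escort <- c(escort, "Paramedic")
    if (grepl("Police", pres)) escort <- c(escort, "Police")
    triage_agents <- c(triage_agents, escort)
    if (pres == "Associate" || runif(1) < cfg$prob_associate) {
      triage_agents <- c(triage_agents, "Associate")
    }
    add_row(id, "ED", pres, ts, triage_agents, "EDIS",
            "Referral to Emergency Medical")
    for (t in 2:max(m, 2)) {
      if (t > m) break
      ts <- ts + max(1, round(rexp(1, 1 / cfg$mean_gap_mins))) * 60
      if (is_ref && t == r) {
        trig <- sample(names(cfg$trigger_probs), 1, prob = cfg$trigger_probs)
        parts <- strsplit(trig, "|", fixed = TRUE)[[1]]
        sys_part <- parts %in% catalog$name[catalog$category == "information_system"]
        add_row(id, "ED", pres, ts, parts[!sys_part], parts[sys_part],
                cfg$referral_action)
        truth_steps <- c(truth_steps, r)
        truth_trigger <- c(truth_trigger, trig)
        referred_ids <- c(referred_ids, id)
      } else if (is_ref && t > r) {
        draw <- draw_psych()
        action <- if (t == m && runif(1) < 0.4) {
          sample(c("Transfer to MHOA", "Discharge home",
                   "Discharge to Community Mental Health"), 1,
                 prob = c(0.5, 0.3, 0.2))
        } else ""
        add_row(id, "ED", pres, ts, draw$agents, draw$systems, action)
      } else {
        draw <- if (runif(1) < cfg$cross_team_prob) draw_cross_team()
                else draw_medical(is_ref, escort, primary)
        action <- if (!is_ref && t == m && runif(1) < 0.7) {
          sample(c("Discharge home", "Transfer to Observation Ward",
                   "Discharge against medical advice"), 1,
                 prob = c(0.7, 0.2, 0.1))
        } else ""
        add_row(id, "ED", pres, ts, draw$agents, draw$systems, action)
      }
    }
  }

  n_mhoa <- cfg$n_mhoa_only_patients
  mhoa_counts <- cfg$mhoa_interaction_counts
  if (is.null(mhoa_counts) && n_mhoa > 0) {
    mhoa_counts <- sample(5:12, n_mhoa, replace = TRUE)
  }
  for (p in seq_len(n_mhoa)) {
    id <- sprintf("MH%02d", p)
    pres <- presentations[n_ed + p]
    ts <- base + (n_ed + p - 1) * 86400 + round(runif(1, 8 * 60, 20 * 60)) * 60
    add_row(id, "MHOA", pres, ts, c("MHOA Nurse", "Patient"), character(0),
            "Referral to MHOA")
    for (t in seq_len(mhoa_counts[p] - 1)) {
      ts <- ts + max(1, round(rexp(1, 1 / (cfg$mean_gap_mins * 2)))) * 60
      who <- sample(c("nurse", "doctor", "round"), 1, prob = c(0.5, 0.3, 0.2))
      agents <- switch(who,
        nurse = c("MHOA Nurse", "Patient"),
        doctor = c("MHOA Doctor", "Patient"),
        round = mhoa_staff)
      systems <- if (runif(1) < 0.3) "Patient File" else character(0)
      action <- if (t == mhoa_counts[p] - 1 && runif(1) < 0.6) "Discharge home" else ""
      add_row(id, "MHOA", pres, ts, agents, systems, action)
    }
  }

  df <- do.call(rbind, rows)
  log <- as_event_log(df, catalog)
  truth <- list(
    hub = cfg$hub,
    teams = list(emergency_medical = roster(catalog, "emergency_medical"),
                 emergency_psychiatry = ep_staff),
    referred = referred_ids,
    referral_steps = setNames(truth_steps, referred_ids),
    triggers = setNames(truth_trigger, referred_ids)
  )
  list(log = log, truth = truth)
}

#' Study-scale synthetic fixture
#'
#' A deterministic packaged event log pinned to the bookkeeping of the
#' emulated study: 43 patients (36 observed in the ED, 7 only in the MHOA)
#' and 272 interaction records (213 ED, 59 MHOA); 20 ED patients carry a
#' referral to Emergency Psychiatry, with 87 interaction states up to and
#' including the referral point in total. Interaction counts per trajectory
#' lie in 2..12 with median 5. The log is synthetic throughout: it
#' reproduces reported sample sizes and planted structure, not any observed
#' data.
#'
#' @return A list with elements `log` and `truth`, as
#'   [generate_event_log()].
#' @export
study_scale_fixture <- function() {
  counts <- c(rep(2, 4), rep(3, 5), rep(4, 5), rep(5, 6), rep(6, 4),
              rep(7, 2), rep(8, 3), 9, 10, 11, rep(12, 4))   # sum 213
  mhoa_counts <- c(6, 7, 8, 8, 9, 10, 11)                    # sum 59
  # 20 referred patients: steps sum to 87 (mean 4.35), paired to the
  # largest trajectories so every step fits within its trajectory
  steps_desc <- c(7, 7, 7, 6, 6, 5, 5, 5, 5, 4, 4, 4, 4, 3, 3, 3, 3, 2, 2, 2)
  eligible <- order(-counts)[seq_len(20)]
  cfg <- sim_config(
    seed = 20180701,
    interaction_counts = counts,
    mhoa_interaction_counts = mhoa_counts,
    referral_steps = steps_desc
  )
  # generate_event_log assigns steps to patients ordered by decreasing count
  stopifnot(all(steps_desc <= counts[eligible]))
  generate_event_log(cfg)
}
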