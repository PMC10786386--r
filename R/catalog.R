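#' Agent catalogs
#'
#' An agent catalog registers every agent and information system that may
#' appear in an event log, together with the attributes that drive the
#' forbidden-edge policy of the clinical interaction network: a category
#' (patient, associate, clinical_staff, support_service, external_service or
#' information_system), a clinical team for staff (emergency_medical,
#' emergency_psychiatry, mhoa or none), a role (doctor, nurse, allied, other
#' or none) and a flag marking psychiatry-restricted information systems
#' (systems such as PSOLIS and EDYHO that only Emergency Psychiatry staff may
#' access).
#'
#' @param name,category,team,role,psychiatry_restricted Parallel vectors
#'   describing one agent per element.
#' @return A data frame of class `agent_catalog` with columns `name`,
#'   `category`, `team`, `role` and `psychiatry_restricted`.
#' @examples
#' cat <- agent_catalog(
#'   name = c("Patient", "Nurse", "EDIS"),
#'   category = c("patient", "clinical_staff", "information_system"),
#'   team = c("none", "emergency_medical", "none"),
#'   role = c("none", "nurse", "none"),
#'   psychiatry_restricted = c(FALSE, FALSE, FALSE)
#' )
#' @export
agent_catalog <- function(name, category, team = "none", role = "none",
                          psychiatry_restricted = FALSE) {
  df <- data.frame(
    name = as.character(name),
    category = as.character(category),
    team = rep_len(as.character(team), length(name)),
    role = rep_len(as.character(role), length(name)),
    psychiatry_restricted = rep_len(as.logical(psychiatry_restricted), length(name)),
    stringsAsFactors = FALSE
  )
  validate_catalog(df)
}

.categories <- c("patient", "associate", "clinical_staff", "support_service",
                 "external_service", "information_system")
.teams <- c("emergency_medical", "emergency_psychiatry", "mhoa", "none")
.roles <- c("doctor", "nurse", "allied", "other", "none")

validate_catalog <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("name", "category", "team", "role", "psychiatry_restricted")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("catalog is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$name)) {
    stop("duplicate agent names in catalog: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  }
  bad <- setdiff(df$category, .categories)
  if (length(bad) > 0) stop("unknown categories: ", paste(bad, collapse = ", "))
  bad <- setdiff(df$team, .teams)
  if (length(bad) > 0) stop("unknown teams: ", paste(bad, collapse = ", "))
  bad <- setdiff(df$role, .roles)
  if (length(bad) > 0) stop("unknown roles: ", paste(bad, collapse = ", "))
  off <- df$psychiatry_restricted & df$category != "information_system"
  if (any(off)) {
    stop("psychiatry_restricted applies only to information systems: ",
         paste(df$name[off], collapse = ", "))
  }
  off <- df$team != "none" & df$category != "clinical_staff"
  if (any(off)) {
    stop("only clinical staff belong to a team: ",
         paste(df$name[off], collapse = ", "))
  }
  class(df) <- c("agent_catalog", "data.frame")
  rownames(df) <- NULL
  df
}

#' Read or write an agent catalog CSV
#'
#' The on-disk format is a plain CSV with columns
#' `name,category,team,role,psychiatry_restricted`.
#'
#' @param path Path to a CSV file.
#' @return [read_agent_catalog()] returns an `agent_catalog`;
#'   [write_agent_catalog()] returns `path` invisibly.
#' @export
read_agent_catalog <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  df$psychiatry_restricted <- toupper(trimws(df$psychiatry_restricted)) %in%
    c("TRUE", "T", "1", "YES")
  validate_catalog(df)
}

#' @rdname read_agent_catalog
#' @param catalog An `agent_catalog`.
#' @export
write_agent_catalog <- function(catalog, path) {
  write.csv(as.data.frame(catalog), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Default agent catalog
#'
#' A reconstructed catalog approximating the agents and information systems of
#' a tertiary-hospital emergency department with an adjacent short-stay
#' psychiatric unit (MHOA): the patient and their associates, an Emergency
#' Medical team (triage nurse, nurses, consultant, registrar, resident medical
#' officer, intern), an Emergency Psychiatry team (psychiatric liaison nurse,
#' psychiatry registrar and consultant), MHOA staff, support and external
#' services, and four information systems of which PSOLIS and EDYHO are
#' psychiatry-restricted. The roster is synthetic: it reproduces the structure
#' the analyses need, not any particular hospital's staffing.
#'
#' @return An `agent_catalog`.
#' @export
default_catalog <- function() {
  agent_catalog(
    name = c(
      "Patient", "Associate",
      "Triage Nurse", "Nurse", "Consultant", "Registrar", "RMO", "Intern",
      "Psychiatric Liaison Nurse", "Psychiatry Registrar", "Psychiatry Consultant",
      "MHOA Nurse", "MHOA Doctor",
      "Orderly", "Security Officer",
      "Paramedic", "Police", "Community Mental Health",
      "EDIS", "Patient File", "PSOLIS", "EDYHO"
    ),
    category = c(
      "patient", "associate",
      rep("clinical_staff", 11),
      rep("support_service", 2),
      rep("external_service", 3),
      rep("information_system", 4)
    ),
    team = c(
      "none", "none",
      rep("emergency_medical", 6),
      rep("emergency_psychiatry", 3),
      rep("mhoa", 2),
      rep("none", 9)
    ),
    role = c(
      "none", "none",
      "nurse", "nurse", "doctor", "doctor", "doctor", "doctor",
      "nurse", "doctor", "doctor",
      "nurse", "doctor",
      "other", "other",
      "other", "other", "other",
      rep("none", 4)
    ),
    psychiatry_restricted = c(rep(FALSE, 18), FALSE, FALSE, TRUE, TRUE)
  )
}

catalog_lookup <- function(catalog, names) {
  idx <- match(names, catalog$name)
  if (anyNA(idx)) {
    stop("unknown agent name(s): ", paste(names[is.na(idx)], collapse = ", "))
  }
  catalog[idx, , drop = FALSE]
}

#' @export
print.agent_catalog <- function(x, ...) {
  cat("Agent catalog with", nrow(x), "entries\n")
  print(table(category = x$category))
  invisible(x)
}
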