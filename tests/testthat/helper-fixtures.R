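# In-code fixtures: the worked example event log (two partial trajectories,
# seven interactions) and small graphs used across tests.

table1_df <- function() {
  data.frame(
    patient = c("1", "1", "1", "2", "2", "2", "2"),
    setting = "ED",
    presentation = c("Associate", "Associate", "Associate",
                     "Ambulance", "Ambulance", "Ambulance", "Ambulance"),
    date = c("01/08/2018", "01/08/2018", "01/08/2018",
             "02/08/2018", "02/08/2018", "02/08/2018", "02/08/2018"),
    time = c("12:52", "13:36", "13:37", "12:15", "12:16", "12:20", "12:26"),
    agents = c("Triage Nurse; Patient; Associate",
               "Consultant; Patient; Associate",
               "Consultant; Psychiatric Liaison Nurse",
               "Triage Nurse; Paramedic",
               "Triage Nurse; Patient",
               "Triage Nurse; Paramedic",
               "Nurse; Paramedic"),
    information_systems = c("EDIS", "Patient File", "", "", "EDIS", "EDIS",
                            "Patient File"),
    action = c("Referral to Emergency Medical",
               "Referral to Emergency Psychiatry", "", "",
               "Referral to Emergency Medical", "", ""),
    stringsAsFactors = FALSE
  )
}

table1_log <- function() as_event_log(table1_df(), default_catalog())

# path graph with named vertices
path_graph <- function(nodes) {
  igraph::make_graph(rbind(nodes[-length(nodes)], nodes[-1]), directed = FALSE)
}

star_graph <- function(center = "c", leaves = c("l1", "l2", "l3", "l4")) {
  igraph::make_graph(rbind(center, leaves), directed = FALSE)
}

random_connected_graph <- function(n, p = 0.45) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) >= 1) {
      igraph::V(g)$name <- letters[seq_len(n)]
      return(g)
    }
  }
}

# a tiny event log builder for referral tests
mini_log <- function(rows) {
  as_event_log(do.call(rbind, rows), default_catalog())
}

mini_row <- function(patient, time, agents, systems = "", action = "",
                     presentation = "Self", date = "01/08/2018",
                     setting = "ED") {
  data.frame(patient = patient, setting = setting,
             presentation = presentation, date = date, time = time,
             agents = agents, information_systems = systems, action = action,
             stringsAsFactors = FALSE)
}
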