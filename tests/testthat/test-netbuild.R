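test_that("forbidden-edge rules (a)-(c) and symmetry hold", {
  cat <- default_catalog()
  # (a) system-system
  expect_true(is_forbidden("Patient File", "EDIS", cat))
  # (b) system with a non-staff agent
  expect_true(is_forbidden("Patient", "Patient File", cat))
  expect_true(is_forbidden("EDIS", "Paramedic", cat))
  expect_false(is_forbidden("EDIS", "Nurse", cat))
  # (c) psychiatry-restricted systems
  expect_true(is_forbidden("PSOLIS", "Consultant", cat))
  expect_true(is_forbidden("EDYHO", "MHOA Nurse", cat))
  expect_false(is_forbidden("PSOLIS", "Psychiatry Registrar", cat))
  expect_false(is_forbidden("EDYHO", "Psychiatric Liaison Nurse", cat))
  # staff-staff and agent-agent pairs are never forbidden
  expect_false(is_forbidden("Patient", "Consultant", cat))
  # symmetry
  for (pair in list(c("Patient", "EDIS"), c("PSOLIS", "Nurse"),
                    c("Patient File", "PSOLIS"))) {
    expect_equal(is_forbidden(pair[1], pair[2], cat),
                 is_forbidden(pair[2], pair[1], cat))
  }
  expect_error(is_forbidden("Unicorn", "Nurse", cat), "unknown")
})

test_that("a record expands to its agent clique plus admissible system links", {
  cat <- default_catalog()
  e <- edges_from_interaction(c("Triage Nurse", "Patient", "Associate"),
                              "EDIS", cat)
  lab <- apply(e, 1, paste, collapse = "|")
  expect_setequal(lab, c("Patient|Triage Nurse", "Associate|Triage Nurse",
                         "Associate|Patient", "EDIS|Triage Nurse"))

  expect_equal(nrow(edges_from_interaction("Nurse", character(0), cat)), 0)

  e <- edges_from_interaction(c("Psychiatry Registrar", "Psychiatric Liaison Nurse"),
                              "EDYHO", cat)
  expect_equal(nrow(e), 3)  # one staff pair + two staff-system links
})

test_that("the worked-example interaction network has 9 nodes and 11 edges", {
  net <- build_interaction_network(table1_log())
  expect_equal(igraph::vcount(net), 9)
  expect_equal(igraph::ecount(net), 11)
  deg <- degree_centrality(net)
  expect_equal(unname(deg["Triage Nurse"]), 4)
  expect_setequal(
    names(igraph::neighbors(net, "Triage Nurse")),
    c("Patient", "Associate", "Paramedic", "EDIS"))
  # frequency metadata counts records mentioning the node
  expect_equal(igraph::V(net)$frequency[igraph::V(net)$name == "Triage Nurse"], 4L)
})

test_that("network construction is a set operation over records", {
  df <- table1_df()
  base <- build_interaction_network(as_event_log(df, default_catalog()))
  # duplicated records change nothing
  dup <- build_interaction_network(as_event_log(rbind(df, df[c(1, 4), ]),
                                                default_catalog()))
  expect_true(igraph::identical_graphs(
    igraph::permute(dup, match(igraph::V(dup)$name, igraph::V(base)$name)),
    base, attrs = FALSE))
  # record order changes nothing
  set.seed(5)
  shuf <- build_interaction_network(as_event_log(df[sample(nrow(df)), ],
                                                 default_catalog()))
  expect_true(igraph::identical_graphs(
    igraph::permute(shuf, match(igraph::V(shuf)$name, igraph::V(base)$name)),
    base, attrs = FALSE))
})

test_that("adding records never removes nodes or edges", {
  df <- table1_df()
  small <- build_interaction_network(as_event_log(df[1:3, ], default_catalog()))
  full <- build_interaction_network(as_event_log(df, default_catalog()))
  small_edges <- apply(igraph::as_edgelist(small), 1,
                       function(p) paste(sort(p), collapse = "|"))
  full_edges <- apply(igraph::as_edgelist(full), 1,
                      function(p) paste(sort(p), collapse = "|"))
  expect_true(all(igraph::V(small)$name %in% igraph::V(full)$name))
  expect_true(all(small_edges %in% full_edges))
})

test_that("no forbidden edge ever appears in a built network", {
  for (s in 1:3) {
    sim <- generate_event_log(sim_config(seed = s, n_ed_patients = 12,
                                         n_mhoa_only_patients = 2,
                                         n_referred = 6))
    net <- build_interaction_network(exclude_mhoa_only_patients(sim$log))
    el <- igraph::as_edgelist(net)
    expect_false(any(is_forbidden(el[, 1], el[, 2], sim$log$catalog)))
  }
})

test_that("empty logs build an empty network with a warning", {
  log <- mini_log(list(mini_row("A", "10:00", "Nurse; Patient")))
  log$records <- log$records[0, ]
  expect_warning(net <- build_interaction_network(log), "empty")
  expect_equal(igraph::vcount(net), 0)
})

test_that("the trajectory network follows presentation, referral and discharge", {
  net <- build_trajectory_network(table1_log())
  el <- apply(igraph::as_edgelist(net), 1, paste, collapse = " -> ")
  expect_setequal(el, c("Associate -> Emergency Medical",
                        "Emergency Medical -> Emergency Psychiatry",
                        "Ambulance -> Emergency Medical"))
  expect_true(igraph::is_directed(net))

  # presentation nodes have in-degree 0; discharge nodes out-degree 0
  fx <- study_scale_fixture()
  tn <- suppressWarnings(build_trajectory_network(fx$log))
  type <- igraph::V(tn)$type
  expect_true(all(igraph::degree(tn, mode = "in")[type == "presentation"] == 0))
  expect_true(all(igraph::degree(tn, mode = "out")[type == "discharge"] == 0))
})

test_that("trajectories without actions fall back to the first treating team", {
  log <- mini_log(list(mini_row("A", "10:00", "Nurse; Patient",
                                presentation = "Police")))
  net <- build_trajectory_network(log)
  el <- apply(igraph::as_edgelist(net), 1, paste, collapse = " -> ")
  expect_equal(el, "Police -> Emergency Medical")
})

test_that("a referral to the treating team is ignored with a warning", {
  rows <- list(
    mini_row("A", "10:00", "Triage Nurse; Patient",
             action = "Referral to Emergency Medical"),
    mini_row("A", "10:30", "Consultant; Patient",
             action = "Referral to Emergency Medical")
  )
  expect_warning(net <- build_trajectory_network(mini_log(rows)),
                 "already treating")
  expect_equal(igraph::ecount(net), 1)
})
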