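#' Forbidden-edge policy
#'
#' The operational policy of the hospital forbids edges that cannot
#' correspond to a real interaction channel:
#' (a) between two information systems;
#' (b) between an information system and any agent that is not clinical
#'     staff (a hard-copy patient file is never accessed directly by the
#'     patient);
#' (c) between a psychiatry-restricted information system (PSOLIS, EDYHO)
#'     and any agent that is not clinical staff on the Emergency Psychiatry
#'     team.
#' The predicate is symmetric in its two arguments.
#'
#' @param i,j Agent or information-system names resolving in `catalog`.
#' @param catalog An [agent_catalog()].
#' @return Logical: `TRUE` when the edge (i, j) is forbidden.
#' @examples
#' cat <- default_catalog()
#' is_forbidden("Patient File", "EDIS", cat)   # rule (a): TRUE
#' is_forbidden("Patient", "Patient File", cat) # rule (b): TRUE
#' is_forbidden("PSOLIS", "Consultant", cat)   # rule (c): TRUE
#' is_forbidden("PSOLIS", "Psychiatry Registrar", cat) # FALSE
#' @export
is_forbidden <- function(i, j, catalog) {
  a <- catalog_lookup(catalog, i)
  b <- catalog_lookup(catalog, j)
  sys_a <- a$category == "information_system"
  sys_b <- b$category == "information_system"
  psych_staff_a <- a$category == "clinical_staff" & a$team == "emergency_psychiatry"
  psych_staff_b <- b$category == "clinical_staff" & b$team == "emergency_psychiatry"
  (sys_a & sys_b) |
    (sys_a & !sys_b & b$category != "clinical_staff") |
    (sys_b & !sys_a & a$category != "clinical_staff") |
    (a$psychiatry_restricted & !psych_staff_b) |
    (b$psychiatry_restricted & !psych_staff_a)
}

# Symmetric logical matrix of the policy over a fixed node set.
forbidden_matrix <- function(nodes, catalog) {
  n <- length(nodes)
  mat <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (n < 2) return(mat)
  idx <- which(upper.tri(mat), arr.ind = TRUE)
  f <- is_forbidden(nodes[idx[, 1]], nodes[idx[, 2]], catalog)
  mat[idx] <- f
  mat[idx[, c(2, 1), drop = FALSE]] <- f
  mat
}

#' Expand one interaction record into network edges
#'
#' Each record lists the agents present and the information systems accessed
#' during one interaction. An interaction among the listed parties implies
#' pairwise interaction, so the record expands to a clique over its agents
#' plus every agent-system pair; pairs violating the forbidden-edge policy
#' are dropped, and system-system pairs are never formed.
#'
#' @param agents Character vector of agent names (non-systems).
#' @param info_systems Character vector of information-system names.
#' @param catalog An [agent_catalog()].
#' @return A two-column character matrix of unordered edges, each row sorted
#'   alphabetically; zero rows when the record yields no admissible pair.
#' @export
edges_from_interaction <- function(agents, info_systems = character(0), catalog) {
  agents <- unique(agents)
  info_systems <- unique(info_systems)
  pairs <- NULL
  if (length(agents) >= 2) {
    pairs <- t(combn(agents, 2))
  }
  if (length(info_systems) > 0 && length(agents) > 0) {
    cross <- cbind(rep(agents, times = length(info_systems)),
                   rep(info_systems, each = length(agents)))
    pairs <- rbind(pairs, cross)
  }
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to"))))
  }
  keep <- !is_forbidden(pairs[, 1], pairs[, 2], catalog)
  pairs <- pairs[keep, , drop = FALSE]
  # canonical order within each edge, for set semantics downstream
  flip <- pairs[, 1] > pairs[, 2]
  tmp <- pairs[flip, 1]
  pairs[flip, 1] <- pairs[flip, 2]
  pairs[flip, 2] <- tmp
  dimnames(pairs) <- list(NULL, c("from", "to"))
  pairs
}

#' Build the clinical interaction network
#'
#' Constructs the undirected, unweighted, simple graph whose nodes are the
#' agents and information systems appearing in at least one record and whose
#' edges record at least one observed interaction between a pair, expanded
#' per [edges_from_interaction()] under the forbidden-edge policy. Node
#' attributes carry the catalog fields and the per-node interaction
#' frequency (number of records listing the node); frequencies are metadata
#' only and enter no computation. MHOA-only patients should be excluded by
#' the caller first when modelling the ED.
#'
#' @param log An `event_log`.
#' @return An [igraph::igraph] with vertex attributes `category`, `team`,
#'   `role`, `psychiatry_restricted` and `frequency`.
#' @export
build_interaction_network <- function(log) {
  stopifnot(inherits(log, "event_log"))
  rec <- log$records
  if (nrow(rec) == 0) {
    warning("empty event log: returning an empty network")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  edge_list <- lapply(seq_len(nrow(rec)), function(i) {
    edges_from_interaction(rec$agents[[i]], rec$info_systems[[i]], log$catalog)
  })
  edges <- unique(do.call(rbind, edge_list))
  mentions <- unlist(lapply(seq_len(nrow(rec)), function(i) {
    unique(c(rec$agents[[i]], rec$info_systems[[i]]))
  }))
  freq <- table(mentions)
  nodes <- sort(names(freq))
  info <- catalog_lookup(log$catalog, nodes)
  vertices <- data.frame(
    name = nodes,
    category = info$category,
    team = info$team,
    role = info$role,
    psychiatry_restricted = info$psychiatry_restricted,
    frequency = as.integer(freq[nodes]),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE,
                                vertices = vertices)
}

#' Default action vocabulary for the trajectory network
#'
#' Maps the action strings of an event log to trajectory-network nodes. Each
#' entry names a target node and whether it is a clinical `team` or a
#' `discharge` mode. The vocabulary is configurable because action phrasing
#' varies between services.
#'
#' @return A data frame with columns `action`, `node`, `type`.
#' @export
default_action_map <- function() {
  data.frame(
    action = c("Referral to Emergency Medical",
               "Referral to Emergency Psychiatry",
               "Referral to MHOA",
               "Transfer to MHOA",
               "Transfer to Observation Ward",
               "Discharge",
               "Discharge home",
               "Discharge against medical advice",
               "Discharge to Community Mental Health"),
    node = c("Emergency Medical", "Emergency Psychiatry", "MHOA", "MHOA",
             "Observation Ward", "Discharge home", "Discharge home",
             "Discharge against medical advice", "Community Mental Health"),
    type = c("team", "team", "team", "team", "team",
             "discharge", "discharge", "discharge", "discharge"),
    stringsAsFactors = FALSE
  )
}

#' Build the patient trajectory network
#'
#' A directed, unweighted graph over presentation modes, clinical teams and
#' discharge modes. Per patient, an edge is drawn from the presentation mode
#' to the first treating team, from team to team at each referral or
#' transfer action, and from the current team to the discharge mode at a
#' discharge action; an edge is present iff the transition was observed at
#' least once. A referral to the team already treating is ignored with a
#' warning. When a trajectory carries no team action at all, the first
#' treating team is inferred from the team of the first clinical staff
#' observed (falling back to the care setting).
#'
#' @param log An `event_log` (combined ED and MHOA data).
#' @param action_map Action vocabulary, see [default_action_map()].
#' @return A directed [igraph::igraph] with a vertex attribute `type`
#'   (`presentation`, `team` or `discharge`).
#' @export
build_trajectory_network <- function(log, action_map = default_action_map()) {
  stopifnot(inherits(log, "event_log"))
  rec <- log$records
  from <- character(0); to <- character(0)
  node_type <- list()
  note <- function(node, type) {
    if (is.null(node_type[[node]])) node_type[[node]] <<- type
    node_type
  }
  unknown_actions <- character(0)
  for (p in unique(rec$patient)) {
    r <- rec[rec$patient == p, , drop = FALSE]
    pres <- r$presentation[r$presentation != ""][1]
    if (is.na(pres)) pres <- "Unknown"
    node_type <- note(pres, "presentation")
    current <- NULL
    for (i in seq_len(nrow(r))) {
      act <- r$action[i]
      if (act == "") next
      k <- match(act, action_map$action)
      if (is.na(k)) {
        unknown_actions <- c(unknown_actions, act)
        next
      }
      target <- action_map$node[k]
      if (action_map$type[k] == "team") {
        node_type <- note(target, "team")
        if (is.null(current)) {
          from <- c(from, pres); to <- c(to, target)
        } else if (target == current) {
          warning("patient ", p, ": referral to the team already treating (",
                  target, ") ignored")
          next
        } else {
          from <- c(from, current); to <- c(to, target)
        }
        current <- target
      } else {
        node_type <- note(target, "discharge")
        if (is.null(current)) {
          from <- c(from, pres); to <- c(to, target)
        } else {
          from <- c(from, current); to <- c(to, target)
        }
      }
    }
    if (is.null(current)) {
      # no team action observed: infer the first treating team
      first_team <- infer_first_team(r, log$catalog)
      node_type <- note(first_team, "team")
      from <- c(from, pres); to <- c(to, first_team)
    }
  }
  if (length(unknown_actions) > 0) {
    warning("unmapped action(s) ignored: ",
            paste(unique(unknown_actions), collapse = ", "))
  }
  edges <- unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
  nodes <- unique(c(edges$from, edges$to, names(node_type)))
  vertices <- data.frame(
    name = nodes,
    type = vapply(nodes, function(nm) node_type[[nm]] %||% "team", ""),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
}

infer_first_team <- function(records, catalog) {
  staff <- catalog[catalog$category == "clinical_staff", , drop = FALSE]
  for (i in seq_len(nrow(records))) {
    teams <- staff$team[match(records$agents[[i]], staff$name)]
    teams <- teams[!is.na(teams) & teams != "none"]
    if (length(teams) > 0) {
      return(switch(teams[1],
                    emergency_medical = "Emergency Medical",
                    emergency_psychiatry = "Emergency Psychiatry",
                    mhoa = "MHOA"))
    }
  }
  if (records$setting[1] == "MHOA") "MHOA" else "Emergency Medical"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a network to GraphML or edge-list format
#'
#' @param net An igraph network built by [build_interaction_network()] or
#'   [build_trajectory_network()].
#' @param path Output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  igraph::write_graph(net, path, format = format)
  invisible(path)
}
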