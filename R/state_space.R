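# State space: clinical health states, permitted transitions, and the
# expanded (state x lifetime-event-count) computational space.

#' Default health states of the cardiovascular model
#'
#' Eleven mutually exclusive states: a single CVD-free state; five acute
#' event states (acute myocardial infarction, stable angina, unstable
#' angina, transient ischaemic attack, stroke); three post-event states
#' (post-AMI, post-TIA, post-stroke); and two absorbing death states
#' (CVD death and non-CVD death). The angina states have no separate
#' post-event counterpart: they are chronic, i.e. each angina state is its
#' own post-event destination and persists from one annual cycle to the
#' next.
#'
#' @return A tibble with one row per state and columns `name`, `category`
#'   (one of `"event_free"`, `"acute"`, `"post"`, `"dead"`), `linked_acute`
#'   (for post-event states, the acute event they follow) and `fatal`
#'   (`TRUE` for death states).
#' @seealso [default_registry()], [cvd_transitions()]
#' @export
#' @examples
#' cvd_states()
cvd_states <- function() {
  tibble::tribble(
    ~name,             ~category,    ~linked_acute, ~fatal,
    "event_free",      "event_free", NA_character_, FALSE,
    "ami",             "acute",      NA_character_, FALSE,
    "stable_angina",   "acute",      NA_character_, FALSE,
    "unstable_angina", "acute",      NA_character_, FALSE,
    "tia",             "acute",      NA_character_, FALSE,
    "stroke",          "acute",      NA_character_, FALSE,
    "post_ami",        "post",       "ami",         FALSE,
    "post_tia",        "post",       "tia",         FALSE,
    "post_stroke",     "post",       "stroke",      FALSE,
    "cvd_death",       "dead",       NA_character_, TRUE,
    "noncvd_death",    "dead",       NA_character_, TRUE
  )
}

# For each acute state, the state occupied after the acute year:
# its linked post-event state if one exists, otherwise itself (chronic).
post_state_map <- function(states) {
  acute <- states$name[states$category == "acute"]
  post <- states[states$category == "post", , drop = FALSE]
  out <- setNames(acute, acute)
  for (i in seq_len(nrow(post))) {
    out[post$linked_acute[i]] <- post$name[i]
  }
  out
}

#' Default permitted transitions between health states
#'
#' The CVD-free state can move to any acute event or either death state
#' (fatal first events flow directly to CVD death). Acute states move to
#' their post-event destination, to any acute event (a repeat event), or to
#' either death. Post-event (and chronic angina) states persist, move to
#' any acute event, or die. Death states are absorbing.
#'
#' @param states A state table as returned by [cvd_states()].
#' @return A tibble edge list with columns `from` and `to`.
#' @export
cvd_transitions <- function(states = cvd_states()) {
  acute <- states$name[states$category == "acute"]
  post <- states$name[states$category == "post"]
  dead <- states$name[states$category == "dead"]
  ef <- states$name[states$category == "event_free"]
  post_of <- post_state_map(states)
  dplyr::bind_rows(
    tidyr::expand_grid(from = ef, to = c(acute, dead)),
    tidyr::expand_grid(from = acute, to = c(acute, dead)),
    tibble::tibble(from = acute, to = unname(post_of[acute])),
    tibble::tibble(from = post, to = post),
    tidyr::expand_grid(from = post, to = c(acute, dead))
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$from, .data$to)
}

#' Create a state registry
#'
#' A registry bundles the state table, the permitted transition edge list
#' and the lifetime cap on CVD events. Alternative model topologies are
#' data, not code: supply your own `states`/`transitions`.
#'
#' @param states State table (see [cvd_states()] for the schema).
#' @param transitions Edge list with columns `from`, `to`.
#' @param max_events Maximum number of CVD events per simulated lifetime.
#' @param cvd_death,noncvd_death Names of the two death states.
#' @return An object of class `state_registry`.
#' @export
state_registry <- function(states = cvd_states(),
                           transitions = cvd_transitions(states),
                           max_events = 3L,
                           cvd_death = "cvd_death",
                           noncvd_death = "noncvd_death") {
  structure(
    list(
      states = tibble::as_tibble(states),
      transitions = tibble::as_tibble(transitions),
      max_events = as.integer(max_events),
      cvd_death = cvd_death,
      noncvd_death = noncvd_death
    ),
    class = "state_registry"
  )
}

#' Default state registry
#'
#' @return The [state_registry()] built from [cvd_states()] and
#'   [cvd_transitions()] with a lifetime cap of three CVD events.
#' @export
default_registry <- function() state_registry()

#' @export
print.state_registry <- function(x, ...) {
  cat(
    "<state_registry> ", nrow(x$states), " states, ",
    nrow(x$transitions), " permitted transitions, max ",
    x$max_events, " CVD events\n",
    sep = ""
  )
  invisible(x)
}

#' Validate a state registry
#'
#' Checks the structural invariants of the state space: exactly one
#' CVD-free state; at least two death states including the named CVD and
#' non-CVD deaths; death states absorbing; post-event states linked to a
#' registered acute state; transitions referencing registered states only;
#' and every living state able to reach both death states.
#'
#' @param reg A [state_registry()].
#' @return A tibble of violations (columns `rule`, `detail`); zero rows if
#'   the registry is valid. Violations are data, not errors.
#' @export
validate_registry <- function(reg) {
  st <- reg$states
  tr <- reg$transitions
  v <- list()
  bad <- function(rule, detail) tibble::tibble(rule = rule, detail = detail)

  n_ef <- sum(st$category == "event_free")
  if (n_ef != 1L) {
    v <- c(v, list(bad(
      "unique_event_free",
      paste0("expected exactly 1 event-free state, found ", n_ef)
    )))
  }
  dead <- st$name[st$category == "dead"]
  if (length(dead) < 2L) {
    v <- c(v, list(bad("two_death_states", paste0(
      "expected at least 2 death states, found ", length(dead)
    ))))
  }
  for (d in c(reg$cvd_death, reg$noncvd_death)) {
    if (!d %in% dead) {
      v <- c(v, list(bad(
        "named_death_state",
        paste0("death state '", d, "' is not registered as category 'dead'")
      )))
    }
  }
  out_of_dead <- tr[tr$from %in% dead, , drop = FALSE]
  if (nrow(out_of_dead) > 0L) {
    v <- c(v, list(bad(
      "absorbing_death",
      paste0(
        "transition out of death state: ",
        paste(out_of_dead$from, "->", out_of_dead$to, collapse = "; ")
      )
    )))
  }
  acute <- st$name[st$category == "acute"]
  post <- st[st$category == "post", , drop = FALSE]
  bad_link <- post$name[is.na(post$linked_acute) | !post$linked_acute %in% acute]
  if (length(bad_link) > 0L) {
    v <- c(v, list(bad(
      "post_links_acute",
      paste0(
        "post-event state(s) without a registered acute link: ",
        paste(bad_link, collapse = ", ")
      )
    )))
  }
  unknown <- setdiff(unique(c(tr$from, tr$to)), st$name)
  if (length(unknown) > 0L) {
    v <- c(v, list(bad(
      "edges_registered",
      paste0("transition references unregistered state(s): ", paste(unknown, collapse = ", "))
    )))
  }
  living <- st$name[st$category != "dead"]
  for (d in c(reg$cvd_death, reg$noncvd_death)) {
    if (!d %in% dead) next
    missing <- living[!vapply(
      living, function(s) any(tr$from == s & tr$to == d), logical(1)
    )]
    if (length(missing) > 0L) {
      v <- c(v, list(bad(
        "death_reachable",
        paste0(
          "state(s) with no permitted transition to '", d, "': ",
          paste(missing, collapse = ", ")
        )
      )))
    }
  }
  if (!is.finite(reg$max_events) || reg$max_events < 1L) {
    v <- c(v, list(bad("max_events_positive", "max_events must be a positive integer")))
  }
  if (length(v) == 0L) {
    tibble::tibble(rule = character(), detail = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Expanded computational state space
#'
#' Expands the clinical states over a lifetime event count 0..`max_events`
#' and enumerates the combinations reachable from (event-free, 0) under the
#' registry's permitted transitions. Entering any acute state increments
#' the count; moving from an acute state to its own post-event destination
#' (or persisting in a chronic state) does not. Once the cap is reached
#' only persistence and death remain.
#'
#' @param reg A [state_registry()].
#' @return A list with `nodes` (tibble: `label`, `state`, `count`,
#'   `category`, `chronic`) and `edges` (tibble: `from`, `to` expanded
#'   labels), plus the registry itself as `registry`.
#' @export
expanded_state_space <- function(reg) {
  st <- reg$states
  max_e <- reg$max_events
  cat_of <- setNames(st$category, st$name)
  post_of <- post_state_map(st)
  adj <- split(reg$transitions$to, reg$transitions$from)

  lab <- function(s, c) {
    if (cat_of[[s]] %in% c("event_free", "dead")) s else paste0(s, ".", c)
  }

  # BFS from (event_free, 0) over (state, count) nodes; deaths drop count.
  ef <- st$name[st$category == "event_free"][1]
  seen <- new.env(parent = emptyenv())
  queue <- list(list(state = ef, count = 0L))
  assign(lab(ef, 0L), list(state = ef, count = 0L), envir = seen)
  edges_from <- character()
  edges_to <- character()

  successors <- function(s, c) {
    outs <- adj[[s]] %||% character()
    res <- list()
    if (cat_of[[s]] == "event_free") {
      # Persistence in the CVD-free state is implicit.
      res <- c(res, list(list(state = s, count = c)))
    }
    for (to in outs) {
      tc <- cat_of[[to]]
      if (tc == "dead") {
        res <- c(res, list(list(state = to, count = 0L)))
      } else if (cat_of[[s]] == "event_free") {
        if (tc == "acute") res <- c(res, list(list(state = to, count = 1L)))
      } else if (cat_of[[s]] %in% c("acute", "post")) {
        # Moving to the post-event destination (the state itself for
        # chronic/post states) keeps the count; any acute destination is
        # also a repeat event with an incremented count, including a
        # recurrence of a chronic state.
        if (identical(to, unname(post_of[s])) || identical(to, s)) {
          res <- c(res, list(list(state = to, count = c)))
        }
        if (tc == "acute" && c < max_e) {
          res <- c(res, list(list(state = to, count = c + 1L)))
        }
      }
    }
    res
  }

  while (length(queue) > 0L) {
    node <- queue[[1]]
    queue <- queue[-1]
    from_lab <- lab(node$state, node$count)
    if (cat_of[[node$state]] == "dead") {
      next
    }
    for (nx in successors(node$state, node$count)) {
      to_lab <- lab(nx$state, nx$count)
      edges_from <- c(edges_from, from_lab)
      edges_to <- c(edges_to, to_lab)
      if (!exists(to_lab, envir = seen, inherits = FALSE)) {
        assign(to_lab, nx, envir = seen)
        queue <- c(queue, list(nx))
      }
    }
  }

  reach <- mget(ls(seen), envir = seen)
  nodes <- tibble::tibble(
    state = vapply(reach, `[[`, character(1), "state"),
    count = vapply(reach, `[[`, integer(1), "count")
  )
  # Canonical ordering: registry state order, count ascending, deaths last.
  nodes <- nodes |>
    dplyr::mutate(
      category = unname(cat_of[.data$state]),
      chronic = .data$category == "acute" & unname(post_of[.data$state] == .data$state),
      label = ifelse(.data$category %in% c("event_free", "dead"),
        .data$state, paste0(.data$state, ".", .data$count)
      ),
      .ord = match(.data$state, st$name)
    ) |>
    dplyr::arrange(.data$category == "dead", .data$.ord, .data$count) |>
    dplyr::select("label", "state", "count", "category", "chronic")

  edges <- tibble::tibble(from = edges_from, to = edges_to) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$from, .data$to)

  list(nodes = nodes, edges = edges, registry = reg)
}

#' Write / read a state registry as plain-text CSV
#'
#' Serialized as `states.csv` (name, category, linked_acute, fatal) and
#' `transitions.csv` (from, to) plus `registry.yaml` holding `max_events`
#' and the death-state names.
#'
#' @param reg A [state_registry()].
#' @param dir Directory to write to / read from (created if needed).
#' @return `write_registry()` returns `dir` invisibly; `read_registry()`
#'   returns a [state_registry()].
#' @export
write_registry <- function(reg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(reg$states, file.path(dir, "states.csv"))
  readr::write_csv(reg$transitions, file.path(dir, "transitions.csv"))
  yaml::write_yaml(
    list(
      max_events = reg$max_events,
      cvd_death = reg$cvd_death,
      noncvd_death = reg$noncvd_death
    ),
    file.path(dir, "registry.yaml")
  )
  invisible(dir)
}

#' @rdname write_registry
#' @export
read_registry <- function(dir) {
  states <- readr::read_csv(
    file.path(dir, "states.csv"),
    col_types = readr::cols(
      name = "c", category = "c", linked_acute = "c", fatal = "l"
    )
  )
  transitions <- readr::read_csv(
    file.path(dir, "transitions.csv"),
    col_types = readr::cols(from = "c", to = "c")
  )
  meta <- yaml::read_yaml(file.path(dir, "registry.yaml"))
  reg <- state_registry(
    states, transitions,
    max_events = meta$max_events,
    cvd_death = meta$cvd_death, noncvd_death = meta$noncvd_death
  )
  viol <- validate_registry(reg)
  if (nrow(viol) > 0L) {
    abort(paste0(
      "registry read from '", dir, "' is invalid:\n",
      paste0("- ", viol$rule, ": ", viol$detail, collapse = "\n")
    ))
  }
  reg
}
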