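# fixture builders shared across test files; everything is generated in
# code, no stored data

mk_participants <- function(ids, sex = "male", birth_year = 1961,
                            education = "low", residence = "rural",
                            smoking = "no", drinking = "no", weight = 1,
                            entry_age = 50, exit_age = 57) {
  data.frame(person_id = ids, sex = sex, birth_year = birth_year,
             education = education, residence = residence,
             smoking = smoking, drinking = drinking, weight = weight,
             entry_age = entry_age, exit_age = exit_age,
             stringsAsFactors = FALSE)
}

mk_events <- function(person_id, disease, onset_age, report_wave = 2011,
                      confirmed = TRUE) {
  data.frame(person_id = person_id, disease = disease,
             onset_age = onset_age, report_wave = report_wave,
             confirmed = confirmed, stringsAsFactors = FALSE)
}

mk_cohort <- function(participants, events = NULL, diseases = NULL, ...) {
  new_cohort(participants, events, diseases = diseases, ...)
}

# matched sets from a compact spec: a list of logical vectors, first
# element the case's exposure, the rest the controls'
mk_sets <- function(patterns) {
  rows <- lapply(seq_along(patterns), function(s) {
    x <- patterns[[s]]
    data.frame(set_id = s,
               person_id = sprintf("s%d_%d", s, seq_along(x)),
               role = c("case", rep("control", length(x) - 1L)),
               index_age = 60, exposure = as.logical(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# independent grid-search maximizer of the conditional log-likelihood,
# written directly from the likelihood formula (oracle for clogit_fit)
grid_clogit <- function(sets, lo = -5, hi = 5) {
  by_set <- split(sets, sets$set_id)
  ll <- function(b) sum(vapply(by_set, function(g) {
    xc <- g$exposure[g$role == "case"]
    b * xc - log(sum(exp(b * g$exposure)))
  }, numeric(1)))
  coarse <- seq(lo, hi, by = 0.01)
  b0 <- coarse[which.max(vapply(coarse, ll, numeric(1)))]
  fine <- seq(b0 - 0.01, b0 + 0.01, by = 1e-5)
  fine[which.max(vapply(fine, ll, numeric(1)))]
}

# brute-force enumeration of all simple directed paths (2..max_len nodes)
# from an adjacency matrix (oracle for chain_trajectories)
brute_paths <- function(adj, max_len) {
  nodes <- rownames(adj)
  out <- list()
  grow <- function(path) {
    if (length(path) >= 2L) out[[length(out) + 1L]] <<- path
    if (length(path) == max_len) return()
    for (v in nodes[adj[path[length(path)], ] == 1])
      if (!v %in% path) grow(c(path, v))
  }
  for (v in nodes) grow(v)
  keys <- vapply(out, paste, character(1), collapse = " -> ")
  out[order(lengths(out), keys)]
}

# small two-disease simulation used by several tests
quick_sim <- function(n = 4000, hr = 3, seed = 1, h1 = 0.02, h2 = 0.01,
                      start_age = "entry", entry = c(45, 70)) {
  dep <- if (is.null(hr)) NULL else
    data.frame(d1 = "arthritis", d2 = "hypertension", hr = hr)
  sim_config(n_participants = n, seed = seed,
             diseases = c("arthritis", "hypertension"),
             baseline_hazards = c(arthritis = h1, hypertension = h2),
             dependency_hr = dep, start_age = start_age,
             entry_age_range = entry)
}
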