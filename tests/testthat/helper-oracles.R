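# Independent brute-force oracles and tiny fixture builders used across the
# suite. Oracles deliberately avoid the package's own code paths.

# O(N^2) dyad census by direct pair enumeration over an adjacency matrix.
oracle_dyad_census <- function(edges, nodes) {
  nodes <- sort(unique(nodes))
  A <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) A[edges$from[k], edges$to[k]] <- 1L
  m <- a <- nl <- 0L
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i >= j) next
      s <- A[i, j] + A[j, i]
      if (s == 2) m <- m + 1L else if (s == 1) a <- a + 1L else nl <- nl + 1L
    }
  }
  list(mutual = m, asymmetric = a, null = nl, n_edges = sum(A))
}

oracle_rho <- function(edges, nodes) {
  cc <- oracle_dyad_census(edges, nodes)
  n <- length(unique(nodes))
  r <- 2 * cc$mutual / (2 * cc$mutual + cc$asymmetric)
  a_bar <- cc$n_edges / (n * (n - 1))
  (r - a_bar) / (1 - a_bar)
}

# Jackknife over ALL N(N-1)/2 pairs, no null-dyad shortcut.
oracle_jackknife <- function(edges, nodes) {
  nodes <- sort(unique(nodes))
  full <- oracle_rho(edges, nodes)
  sq <- 0
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i >= j) next
      keep <- !((edges$from == nodes[i] & edges$to == nodes[j]) |
                  (edges$from == nodes[j] & edges$to == nodes[i]))
      sub <- edges[keep, , drop = FALSE]
      if (nrow(sub) == 0) next
      sq <- sq + (oracle_rho(sub, nodes) - full)^2
    }
  }
  sqrt(sq)
}

# A dyad_census object from known counts (for closed-form examples).
census_stub <- function(mutual, asymmetric, n_nodes) {
  structure(list(mutual = mutual, asymmetric = asymmetric,
                 null = n_nodes * (n_nodes - 1) / 2 - mutual - asymmetric,
                 n_edges = 2 * mutual + asymmetric, n_nodes = n_nodes),
            class = "dyad_census")
}

random_directed_edges <- function(n_nodes, n_edges, seed) {
  withr::with_seed(seed, {
    nodes <- sprintf("N%03d", seq_len(n_nodes))
    pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    idx <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
    list(edges = tibble::tibble(from = pairs$from[idx], to = pairs$to[idx]),
         nodes = nodes)
  })
}

# Direct single-pass application of the date-reassignment rule, written as a
# plain loop over edges against a frozen copy of the original network.
oracle_reassign <- function(edges, dates, prefer = "earlier") {
  orig <- paste(edges$date, edges$from, edges$to)
  has <- function(d, f, t) paste(d, f, t) %in% orig
  out <- edges
  for (k in seq_len(nrow(edges))) {
    d <- edges$date[k]; f <- edges$from[k]; t <- edges$to[k]
    if (has(d, t, f)) next                      # already mutual
    ok <- function(dd) dd %in% dates && !has(dd, f, t) && has(dd, t, f)
    cands <- c(d - 1, d + 1)[c(ok(d - 1), ok(d + 1))]
    if (length(cands) == 0) next
    out$date[k] <- if (prefer == "earlier") min(cands) else max(cands)
  }
  out
}

# Readings for one directed stream at 15-s cadence, constant RSSI.
constant_readings <- function(observer, observed, start, n, rssi) {
  tibble::tibble(
    observer_id = observer, observed_id = observed,
    timestamp = as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * 15,
    rssi_dbm = as.integer(rssi)
  )
}

tiny_config <- function(...) {
  generator_config(
    n_participants = 20, n_days = 3, n_interviewed = 6,
    household_size_distribution = c(1, 0, 0, 0, 0, 0),
    contact_rate = 1, household_contact_rate = 0,
    wear_prob_by_day = rep(1, 3), p_household_card_left_home = 0,
    rssi_noise_sd = 0, p_report = 1, p_date_shift = 0, seed = 42, ...
  )
}
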