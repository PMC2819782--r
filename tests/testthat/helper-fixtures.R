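# small fixtures built in code

# hand-built dataset: 4 small areas in 2 higher areas on a path graph
tiny_data <- function(P = 2, Q = 1, L = 1) {
  set.seed(42)
  areas <- tibble::tibble(
    area_id = c("w1", "w2", "w3", "w4"),
    higher_id = c("A", "A", "B", "B"))
  for (p in seq_len(P)) areas[[paste0("y_", p)]] <- c(3L, 1L, 4L, 2L) + p
  for (p in seq_len(P)) areas[[paste0("O_", p)]] <- c(2, 1.5, 3, 2.5) + p / 2
  for (q in seq_len(Q)) areas[[paste0("E_", q)]] <- c(5, 4, 6, 5) + q
  for (l in seq_len(L)) areas[[paste0("x_", l)]] <- as.numeric(scale(rnorm(4)))
  higher <- tibble::tibble(higher_id = c("A", "B"))
  for (q in seq_len(Q)) higher[[paste0("Z_", q)]] <- c(9L, 12L) + q
  edges <- tibble::tibble(from = c("w1", "w2", "w3"), to = c("w2", "w3", "w4"))
  prev_data(areas, higher, edges)
}

# path graph on n nodes as a prev_graph
path_graph <- function(n) {
  ids <- paste0("v", seq_len(n))
  if (n == 1) return(as_prev_graph(tibble::tibble(from = character(),
                                                  to = character()), ids))
  as_prev_graph(tibble::tibble(from = ids[-n], to = ids[-1]), ids)
}

# random undirected graph on n nodes (each edge present w.p. p_edge)
random_graph <- function(n, p_edge = 0.5) {
  ids <- paste0("v", seq_len(n))
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  as_prev_graph(tibble::tibble(from = ids[pairs[1, keep]],
                               to = ids[pairs[2, keep]]), ids)
}

# conditional moments of component j derived from a joint precision matrix
conditional_from_precision <- function(j, f, eta, Qprec) {
  Qprec <- as.matrix(Qprec)
  v <- 1 / Qprec[j, j]
  m <- eta[j] - v * sum(Qprec[j, -j] * (f[-j] - eta[-j]))
  list(mean = m, var = v)
}

# minimal hand-made prev_fit-like object for postprocessing tests:
# delta draws supplied directly (draws x N_L), single outcome
fake_fit <- function(data, delta_draws, chains = 1) {
  d <- data$dims
  ch <- list(delta = delta_draws,
             dev_y = rep(0, nrow(delta_draws)),
             dev_z = rep(0, nrow(delta_draws)))
  structure(
    list(chains = rep(list(ch), chains), data = data,
         graph = as_prev_graph(data), mode = "constrained", dims = d,
         membership = match(data$areas$higher_id, data$higher$higher_id),
         config = list(chains = chains, iter = nrow(delta_draws),
                       burnin = 0, thin = 1, seed = 1, likelihood = TRUE),
         n_retained = nrow(delta_draws)),
    class = "prev_fit")
}
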