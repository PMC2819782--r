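#' Assemble a two-scale prevalence dataset
#'
#' Bundles the three tables the model consumes: a small-area table (one row
#' per small area with its higher-area membership, observed indicator counts,
#' expected counts, expected prevalence and standardised risk factors), a
#' higher-area table of observed prevalence totals, and an undirected
#' adjacency edge list over small areas. All downstream functions take this
#' object.
#'
#' @param areas Data frame with columns `area_id`, `higher_id`, indicator
#'   counts `y_1..y_P`, expected indicator counts `O_1..O_P`, expected
#'   prevalence `E_1..E_Q` and standardised risk factors `x_1..x_L`
#'   (the covariate block may be absent, giving `L = 0`).
#' @param higher Data frame with columns `higher_id` and prevalence totals
#'   `Z_1..Z_Q` observed only at the higher scale.
#' @param edges Data frame with columns `from`, `to` holding one undirected
#'   adjacency pair per row; duplicates and reversed duplicates are collapsed
#'   silently. May have zero rows.
#' @param standardize_x Standardise covariate columns (mean 0, sd 1) if they
#'   are not already standardised; a notice is emitted when rescaling happens.
#'
#' @return An object of class `prev_data`: a list with tibbles `areas`,
#'   `higher`, `edges` and a `dims` list (`N_L`, `N_H`, `P`, `Q`, `L`).
#' @examples
#' sim <- simulate_prev_data(n_row = 4, n_col = 4, n_higher = 4, seed = 1)
#' sim$data
#' @export
prev_data <- function(areas, higher, edges, standardize_x = TRUE) {
  areas <- tibble::as_tibble(areas)
  higher <- tibble::as_tibble(higher)
  edges <- tibble::as_tibble(edges)

  req <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0)
      abort(sprintf("%s is missing column(s): %s", what,
                    paste(miss, collapse = ", ")))
  }
  req(areas, c("area_id", "higher_id"), "small-area table")
  req(higher, "higher_id", "higher-area table")
  if (nrow(edges) > 0) req(edges, c("from", "to"), "adjacency table")
  if (nrow(edges) == 0) edges <- tibble(from = character(), to = character())

  areas$area_id <- as.character(areas$area_id)
  areas$higher_id <- as.character(areas$higher_id)
  higher$higher_id <- as.character(higher$higher_id)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)

  P <- n_block(areas, "y")
  Q <- n_block(higher, "Z")
  L <- n_block(areas, "x")
  if (P == 0) abort("small-area table has no indicator columns y_1..y_P")
  if (Q == 0) abort("higher-area table has no total columns Z_1..Z_Q")
  if (n_block(areas, "O") != P)
    abort("expected-count columns O_1..O_P do not match the y block")
  if (n_block(areas, "E") != Q)
    abort("expected-prevalence columns E_1..E_Q do not match the Z block")

  # collapse duplicated and reversed edges, reject self-loops
  if (nrow(edges) > 0) {
    self <- edges$from == edges$to
    if (any(self))
      abort(sprintf("adjacency contains self-loop(s), e.g. row %d (%s)",
                    which(self)[1], edges$from[which(self)[1]]))
    key <- ifelse(edges$from < edges$to,
                  paste(edges$from, edges$to, sep = "\r"),
                  paste(edges$to, edges$from, sep = "\r"))
    keep <- !duplicated(key)
    edges <- tibble(
      from = pmin(edges$from, edges$to)[keep],
      to   = pmax(edges$from, edges$to)[keep]
    )
  }

  x <- structure(
    list(areas = areas, higher = higher, edges = edges,
         dims = list(N_L = nrow(areas), N_H = nrow(higher),
                     P = P, Q = Q, L = L)),
    class = "prev_data")
  validate_prev_data(x, standardize_x = standardize_x)
}

# number of columns named <prefix>_1..<prefix>_k (contiguous from 1)
n_block <- function(df, prefix) {
  k <- 0L
  while (paste0(prefix, "_", k + 1L) %in% names(df)) k <- k + 1L
  k
}

block_matrix <- function(df, prefix, k) {
  if (k == 0L) return(matrix(0, nrow(df), 0))
  m <- as.matrix(df[paste0(prefix, "_", seq_len(k))])
  storage.mode(m) <- "double"
  rownames(m) <- NULL
  m
}

#' @rdname prev_data
#' @param x A `prev_data` object.
#' @export
validate_prev_data <- function(x, standardize_x = TRUE) {
  a <- x$areas; h <- x$higher; d <- x$dims

  if (anyDuplicated(a$area_id))
    abort(sprintf("duplicated area_id: %s",
                  a$area_id[anyDuplicated(a$area_id)]))
  if (anyDuplicated(h$higher_id))
    abort(sprintf("duplicated higher_id: %s",
                  h$higher_id[anyDuplicated(h$higher_id)]))
  if (any(is.na(a$higher_id)))
    abort(sprintf("missing higher-area membership for area row %d (%s)",
                  which(is.na(a$higher_id))[1],
                  a$area_id[which(is.na(a$higher_id))[1]]))
  bad <- !a$higher_id %in% h$higher_id
  if (any(bad))
    abort(sprintf("area row %d (%s) maps to unknown higher area '%s'",
                  which(bad)[1], a$area_id[which(bad)[1]],
                  a$higher_id[which(bad)[1]]))
  empty <- setdiff(h$higher_id, a$higher_id)
  if (length(empty) > 0)
    abort(sprintf("higher area(s) with no member small areas: %s",
                  paste(empty, collapse = ", ")))
  if (d$N_L < d$N_H)
    abort("more higher areas than small areas")

  y <- block_matrix(a, "y", d$P)
  Z <- block_matrix(h, "Z", d$Q)
  for (nm in c("y", "Z")) {
    m <- if (nm == "y") y else Z
    if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
      ij <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)[1, ]
      abort(sprintf("%s_%d has a non-integer or negative count in row %d",
                    nm, ij[2], ij[1]))
    }
  }
  O <- block_matrix(a, "O", d$P)
  E <- block_matrix(a, "E", d$Q)
  if (any(!is.finite(O)) || any(O <= 0)) {
    ij <- which(!is.finite(O) | O <= 0, arr.ind = TRUE)[1, ]
    abort(sprintf("O_%d must be strictly positive; offending row %d (%s)",
                  ij[2], ij[1], a$area_id[ij[1]]))
  }
  if (any(!is.finite(E)) || any(E <= 0)) {
    ij <- which(!is.finite(E) | E <= 0, arr.ind = TRUE)[1, ]
    abort(sprintf("E_%d must be strictly positive; offending row %d (%s)",
                  ij[2], ij[1], a$area_id[ij[1]]))
  }

  e <- x$edges
  if (nrow(e) > 0) {
    bad <- !(e$from %in% a$area_id) | !(e$to %in% a$area_id)
    if (any(bad))
      abort(sprintf("adjacency row %d references unknown area id '%s'",
                    which(bad)[1],
                    setdiff(c(e$from[which(bad)[1]], e$to[which(bad)[1]]),
                            a$area_id)[1]))
  }
  g <- as_prev_graph(x)
  if (n_components(g) > 1L)
    warn(sprintf("adjacency graph is disconnected (%d components); the Leroux prior remains proper for kappa < 1",
                 n_components(g)))

  if (d$L > 0 && d$N_L > 1) {
    X <- block_matrix(a, "x", d$L)
    mu <- colMeans(X)
    s <- apply(X, 2, sd)
    if (any(abs(mu) > 1e-6 | abs(s - 1) > 1e-6)) {
      if (!standardize_x)
        abort("covariate columns x_* are not standardised (mean 0, sd 1)")
      inform("standardising covariate columns x_* to mean 0, sd 1")
      if (any(s == 0)) abort("constant covariate column cannot be standardised")
      X <- scale(X)
      x$areas[paste0("x_", seq_len(d$L))] <- as.data.frame(X)
    }
  }
  x
}

#' Read a two-scale prevalence dataset from delimited files
#'
#' Files follow the schema written by [write_prev_data()]: the small-area
#' table (`area_id, higher_id, y_*, O_*, E_*, x_*`), an edge list
#' (`from, to`) and the higher-area totals (`higher_id, Z_*`), all as CSV.
#'
#' @param area_file,adjacency_file,higher_file Paths to the three tables.
#' @inheritParams prev_data
#' @return A validated [prev_data] object.
#' @export
read_prev_data <- function(area_file, adjacency_file, higher_file,
                           standardize_x = TRUE) {
  areas <- readr::read_csv(area_file, show_col_types = FALSE)
  edges <- readr::read_csv(adjacency_file, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  higher <- readr::read_csv(higher_file, show_col_types = FALSE)
  prev_data(areas, higher, edges, standardize_x = standardize_x)
}

#' Write a two-scale prevalence dataset to delimited files
#'
#' @param x A [prev_data] object.
#' @param dir Output directory (created if needed). Writes `areas.csv`,
#'   `adjacency.csv` and `higher.csv`.
#' @return `dir`, invisibly.
#' @export
write_prev_data <- function(x, dir) {
  stopifnot(inherits(x, "prev_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(x$areas, file.path(dir, "areas.csv"))
  readr::write_csv(x$edges, file.path(dir, "adjacency.csv"))
  readr::write_csv(x$higher, file.path(dir, "higher.csv"))
  invisible(dir)
}

#' @export
print.prev_data <- function(x, ...) {
  d <- x$dims
  cat(sprintf(
    "<prev_data> %d small areas in %d higher areas; P = %d indicator(s), Q = %d prevalence outcome(s), L = %d covariate(s); %d adjacency edge(s)\n",
    d$N_L, d$N_H, d$P, d$Q, d$L, nrow(x$edges)))
  invisible(x)
}

#' Internal-standard scaling of expected counts
#'
#' Rescales each expected-count column so region-wide observed and expected
#' totals agree: `O_p` columns are scaled so that `sum(O_p) = sum(y_p)`
#' (region-wide average relative risk of 1 for each indicator), and `E_q`
#' columns so that `sum(E_q) = sum(Z_q)` (region-wide standard prevalence
#' ratio of 1). Relative proportions within a column are unchanged, and the
#' operation is idempotent.
#'
#' @param x A [prev_data] object.
#' @return The rescaled `prev_data` object.
#' @export
scale_expected <- function(x) {
  stopifnot(inherits(x, "prev_data"))
  d <- x$dims
  y <- block_matrix(x$areas, "y", d$P)
  O <- block_matrix(x$areas, "O", d$P)
  for (p in seq_len(d$P)) {
    tot <- sum(O[, p])
    if (tot <= 0) abort(sprintf("column O_%d has non-positive total", p))
    x$areas[[paste0("O_", p)]] <- O[, p] * sum(y[, p]) / tot
  }
  E <- block_matrix(x$areas, "E", d$Q)
  Z <- block_matrix(x$higher, "Z", d$Q)
  for (q in seq_len(d$Q)) {
    tot <- sum(E[, q])
    if (tot <= 0) abort(sprintf("column E_%d has non-positive total", q))
    x$areas[[paste0("E_", q)]] <- E[, q] * sum(Z[, q]) / tot
  }
  x
}

#' Expected counts from a demographic rate schedule
#'
#' Applies a reference (age-sex) rate schedule to stratified area population
#' counts, giving the expected count for each area and outcome:
#' `E[area, outcome] = sum over strata of population * rate`.
#'
#' @param populations Data frame with columns `area_id`, stratum columns
#'   (e.g. `sex`, `ageband`; any set of names shared with `rates`), and
#'   `population`.
#' @param rates Data frame with columns `outcome`, the same stratum columns,
#'   and `rate` (non-negative).
#' @return A tibble `area_id, outcome, expected`, one row per combination,
#'   in area-then-outcome order.
#' @examples
#' pop <- tibble::tibble(area_id = "a", sex = c("m", "f"),
#'                       ageband = "all", population = c(100, 200))
#' rates <- tibble::tibble(outcome = "chd", sex = c("m", "f"),
#'                         ageband = "all", rate = c(0.1, 0.05))
#' compute_expected_counts(pop, rates)  # 100*0.1 + 200*0.05 = 20
#' @export
compute_expected_counts <- function(populations, rates) {
  populations <- tibble::as_tibble(populations)
  rates <- tibble::as_tibble(rates)
  strata <- setdiff(intersect(names(populations), names(rates)),
                    c("area_id", "outcome", "population", "rate"))
  if (length(strata) == 0)
    abort("populations and rates share no stratum columns")
  if (any(rates$rate < 0)) abort("rates must be non-negative")

  pop_key <- do.call(paste, c(populations[strata], sep = "\r"))
  rate_key <- do.call(paste, c(rates[strata], sep = "\r"))
  missing <- setdiff(unique(pop_key), unique(rate_key))
  if (length(missing) > 0)
    abort(sprintf("population stratum '%s' has no matching rate",
                  gsub("\r", "/", missing[1])))

  joined <- dplyr::inner_join(populations, rates, by = strata,
                              relationship = "many-to-many")
  out <- joined %>%
    group_by(.data$area_id, .data$outcome) %>%
    summarise(expected = sum(.data$population * .data$rate),
              .groups = "drop") %>%
    arrange(.data$area_id, .data$outcome)
  out
}

# ---- adjacency graph -------------------------------------------------------

#' Adjacency graph of the small areas
#'
#' Builds the symmetric 0/1 adjacency structure used by the Leroux prior:
#' neighbour lists, degrees `m_j`, and the edge index matrix. Areas are
#' indexed 1..N in the row order of the small-area table; ids are kept for
#' reporting only.
#'
#' @param x A [prev_data] object, or a data frame of edges (`from`, `to`)
#'   together with `ids`.
#' @param ids Character vector of area ids fixing the index order (only when
#'   `x` is an edge table).
#' @return An object of class `prev_graph`: list with `n`, `ids`, `nbr`
#'   (neighbour index lists), `m` (degrees) and `edges` (two-column index
#'   matrix, each undirected edge once).
#' @export
as_prev_graph <- function(x, ids = NULL) {
  if (inherits(x, "prev_graph")) return(x)
  if (inherits(x, "prev_data")) {
    ids <- x$areas$area_id
    e <- x$edges
  } else {
    e <- tibble::as_tibble(x)
    if (is.null(ids)) abort("ids must be supplied with an edge table")
    ids <- as.character(ids)
  }
  n <- length(ids)
  if (nrow(e) > 0) {
    i <- match(e$from, ids); j <- match(e$to, ids)
    if (anyNA(i) || anyNA(j)) abort("edge references unknown area id")
    if (any(i == j)) abort("self-loops are not allowed")
    em <- cbind(pmin(i, j), pmax(i, j))
    em <- em[!duplicated(em), , drop = FALSE]
  } else {
    em <- matrix(integer(), 0, 2)
  }
  nbr <- rep(list(integer()), n)
  for (k in seq_len(nrow(em))) {
    nbr[[em[k, 1]]] <- c(nbr[[em[k, 1]]], em[k, 2])
    nbr[[em[k, 2]]] <- c(nbr[[em[k, 2]]], em[k, 1])
  }
  structure(list(n = n, ids = ids, nbr = nbr,
                 m = lengths(nbr), edges = em),
            class = "prev_graph")
}

# connected components by BFS (for the disconnected-geography warning)
n_components <- function(g) {
  n <- g$n
  if (n == 0) return(0L)
  seen <- logical(n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      fresh <- g$nbr[[v]][!seen[g$nbr[[v]]]]
      seen[fresh] <- TRUE
      queue <- c(queue, fresh)
    }
  }
  comp
}

# 0-based higher-area membership vector (internal)
membership_index <- function(x) {
  match(x$areas$higher_id, x$higher$higher_id)
}
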