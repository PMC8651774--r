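#' Deformation index
#'
#' `Dr = sqrt(S_d / S_ud)` with `S_ud` the pixel area before and `S_d` the
#' pixel area after compression. Values below 1 (contraction) are allowed.
#' The pixel scale cancels, so pixel areas and physical areas give the same
#' Dr.
#'
#' @param s_ud pre-compression area (> 0). Vectorized.
#' @param s_d post-compression area (>= 0).
#' @return dimensionless Dr.
#' @examples deformation_index(100, 144)  # 1.2
#' @export
deformation_index <- function(s_ud, s_d) {
  if (any(!is.finite(s_ud)) || any(s_ud <= 0))
    abort("s_ud must be positive")
  if (any(!is.finite(s_d)) || any(s_d < 0)) abort("s_d must be non-negative")
  sqrt(s_d / s_ud)
}

# Jonker-Volgenant shortest-augmenting-path solver for the rectangular
# linear assignment problem (rows <= cols), minimizing total cost.
# Returns, for each row, the assigned column. O(n * m^2).
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  INF <- Inf
  u <- numeric(n); v <- numeric(m + 1L)
  p <- integer(m + 1L)              # p[j]: row currently assigned to col j
  for (i in seq_len(n)) {
    p[m + 1L] <- i
    j0 <- m + 1L
    minv <- rep(INF, m + 1L)
    used <- rep(FALSE, m + 1L)
    way <- integer(m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      ui0 <- if (i0 > 0L) u[i0] else 0
      for (j in seq_len(m)) {
        if (!used[j]) {
          cur <- cost[i0, j] - ui0 - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(m + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) assign[p[j]] <- j
  assign
}

#' Match cells between the pre- and post-compression frames
#'
#' Cells are immobilized in the gel, so matching uses centroids only
#' (areas change under compression and are deliberately not a matching
#' feature). Candidate pairs are gated at `max_disp`; within each connected
#' group of candidates the one-to-one assignment maximizing the number of
#' matches and minimizing the summed centroid distance is found with the
#' Hungarian (Jonker-Volgenant) algorithm. No region is used twice.
#'
#' @param pre,post per-cell tibbles from [measure_cells()] of the two
#'   frames (same geometry and pixel scale).
#' @param max_disp matching gate, um (default 3: gel-immobilized cells
#'   barely move).
#' @return object of class `rbc_match`: list with `pairs` (tibble:
#'   `pair_id`, `pre_id`, `post_id`, `s_ud`, `s_d`, `dr`, `displacement`),
#'   `unmatched_pre`, `unmatched_post`.
#' @export
match_cells <- function(pre, post, max_disp = 3) {
  n1 <- nrow(pre); n2 <- nrow(post)
  empty_pairs <- tibble(pair_id = integer(), pre_id = integer(),
                        post_id = integer(), s_ud = numeric(),
                        s_d = numeric(), dr = numeric(),
                        displacement = numeric())
  if (n1 == 0L || n2 == 0L) {
    return(structure(list(pairs = empty_pairs, unmatched_pre = pre,
                          unmatched_post = post), class = "rbc_match"))
  }
  dx <- outer(pre$centroid_x, post$centroid_x, `-`)
  dy <- outer(pre$centroid_y, post$centroid_y, `-`)
  D <- sqrt(dx^2 + dy^2)
  feas <- D <= max_disp
  big <- (max_disp + 1) * (max(n1, n2) + 1) * 10

  # connected groups of mutually reachable candidates
  g <- igraph::make_empty_graph(n = n1 + n2, directed = FALSE)
  ed <- which(feas, arr.ind = TRUE)
  if (nrow(ed) > 0L)
    g <- igraph::add_edges(g, t(cbind(ed[, 1], n1 + ed[, 2])))
  comp <- igraph::components(g)$membership
  comp_pre <- comp[seq_len(n1)]
  comp_post <- comp[n1 + seq_len(n2)]

  out <- list()
  for (cmp in intersect(unique(comp_pre), unique(comp_post))) {
    ip <- which(comp_pre == cmp); jp <- which(comp_post == cmp)
    cost <- D[ip, jp, drop = FALSE]
    cost[cost > max_disp] <- big
    flip <- nrow(cost) > ncol(cost)
    if (flip) cost <- t(cost)
    a <- solve_assignment(cost)
    rows <- seq_len(nrow(cost))
    keep <- cost[cbind(rows, a)] <= max_disp
    pre_i <- if (flip) ip[a[keep]] else ip[rows[keep]]
    post_j <- if (flip) jp[rows[keep]] else jp[a[keep]]
    if (length(pre_i))
      out[[length(out) + 1L]] <- tibble(pre_idx = pre_i, post_idx = post_j)
  }
  matched <- if (length(out)) dplyr::bind_rows(out) else
    tibble(pre_idx = integer(), post_idx = integer())
  matched <- matched[order(matched$pre_idx), ]
  pairs <- if (nrow(matched)) tibble(
    pair_id = seq_len(nrow(matched)),
    pre_id = pre$cell_id[matched$pre_idx],
    post_id = post$cell_id[matched$post_idx],
    s_ud = pre$area_px[matched$pre_idx],
    s_d = post$area_px[matched$post_idx],
    dr = deformation_index(pre$area_px[matched$pre_idx],
                           post$area_px[matched$post_idx]),
    displacement = D[cbind(matched$pre_idx, matched$post_idx)]
  ) else empty_pairs
  structure(list(
    pairs = pairs,
    unmatched_pre = pre[setdiff(seq_len(n1), matched$pre_idx), ],
    unmatched_post = post[setdiff(seq_len(n2), matched$post_idx), ]
  ), class = "rbc_match")
}

#' @export
print.rbc_match <- function(x, ...) {
  cat(sprintf("<rbc_match> %d pairs (%d / %d unmatched pre / post)\n",
              nrow(x$pairs), nrow(x$unmatched_pre), nrow(x$unmatched_post)))
  invisible(x)
}

#' Population deformability statistics
#'
#' Mean, sample SD, distribution width (CV%) and median of the per-cell
#' deformation index over matched pairs. The full per-cell table is kept in
#' the result for scatter plotting.
#'
#' @param pairs an `rbc_match` from [match_cells()], or any tibble with a
#'   `dr` column.
#' @return one-row tibble: `n`, `dr_mean`, `dr_sd`, `dr_dw` (CV%),
#'   `dr_median`, with the per-cell table in attribute `scatter`.
#' @export
deformability_summary <- function(pairs) {
  tab <- if (inherits(pairs, "rbc_match")) pairs$pairs else pairs
  if (nrow(tab) == 0L) abort("no matched pairs to summarize")
  dr <- tab$dr
  out <- tibble(
    n = length(dr),
    dr_mean = mean(dr),
    dr_sd = if (length(dr) > 1L) sd(dr) else 0,
    dr_dw = if (mean(dr) != 0) 100 * (if (length(dr) > 1L) sd(dr) else 0) / mean(dr) else NA_real_,
    dr_median = median(dr)
  )
  attr(out, "scatter") <- tab
  out
}
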