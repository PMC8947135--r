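#' Munkres (Hungarian) optimal assignment
#'
#' Solves the rectangular linear assignment problem: given a cost matrix,
#' find the one-to-one row-to-column assignment minimizing total cost.  Used
#' by the tracker to associate detections with track predictions, where it
#' keeps distractor detections from stealing a track.  Implementation is the
#' O(n^3) shortest-augmenting-path form with dual potentials.
#'
#' @param cost Numeric matrix of finite costs; may be rectangular.  With more
#'   rows than columns only \code{ncol} rows are assigned (a partial
#'   assignment), and vice versa.
#' @return List with \code{assignment}, an integer vector of length
#'   \code{nrow(cost)} giving the assigned column per row (\code{NA} for
#'   unassigned rows), and \code{cost}, the total assigned cost.
#' @examples
#' munkres_assign(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3))$assignment
#' @export
munkres_assign <- function(cost) {
  if (length(cost) == 0)
    return(list(assignment = integer(0), cost = 0))
  cost <- as.matrix(cost)
  if (any(!is.finite(cost))) stop("costs must be finite")
  transposed <- FALSE
  if (nrow(cost) > ncol(cost)) {
    cost <- t(cost)
    transposed <- TRUE
  }
  n <- nrow(cost); m <- ncol(cost)
  # dual potentials u (rows), v (cols); p[j+1] = row assigned to column j,
  # column 0 is a virtual column used to start each augmenting path
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, m)
    used <- logical(m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0
      free_j <- which(!used[2:(m + 1)])
      cur <- cost[i0, free_j] - u[i0 + 1] - v[free_j + 1]
      better <- cur < minv[free_j]
      if (any(better)) {
        idx <- free_j[better]
        minv[idx] <- cur[better]
        way[idx + 1] <- j0
      }
      j1 <- free_j[which.min(minv[free_j])]
      delta <- minv[j1]
      usedj <- which(used)  # 1-based indices into 0..m
      rows_used <- p[usedj]
      u[rows_used + 1] <- u[rows_used + 1] + delta
      v[usedj] <- v[usedj] - delta
      minv[free_j] <- minv[free_j] - delta
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  row_of_col <- p[-1]
  assignment <- rep(NA_integer_, n)
  assignment[row_of_col[row_of_col > 0]] <- which(row_of_col > 0)
  total <- sum(cost[cbind(seq_len(n), assignment)], na.rm = TRUE)
  if (transposed) {
    a2 <- rep(NA_integer_, m)
    ok <- which(!is.na(assignment))
    a2[assignment[ok]] <- ok
    assignment <- a2
  }
  list(assignment = assignment, cost = total)
}
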