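#' Link localizations into single-molecule trajectories
#'
#' Frame-to-frame association: for every pair of successive camera frames, an
#' exact one-to-one assignment between open trajectory ends and new spots is
#' computed that minimizes the total squared displacement over all candidate
#' pairs closer than `search_radius_nm` (equivalently, maximizes the total
#' gain `radius^2 - d^2`, the Crocker-Grier convention, so links are made
#' whenever possible and the cheapest set wins). Unassigned spots start new
#' trajectories; unextended trajectories terminate. No gaps are allowed and
#' trajectories shorter than `min_len` frames are discarded.
#'
#' The assignment is solved exactly by decomposing the candidate graph into
#' connected components and enumerating assignments within each component
#' with branch-and-bound; at the spot densities this pipeline targets the
#' components contain only a handful of spots. Cost ties are broken by lowest
#' localization index, so output is deterministic.
#'
#' @param locs Localization data.frame (x_nm, y_nm, frame, other columns
#'   carried through).
#' @param search_radius_nm Maximum displacement between successive frames, nm.
#' @param min_len Minimum trajectory length, frames.
#' @return data.frame with a leading traj_id column followed by the input
#'   columns, ordered by traj_id then frame.
#' @export
link_trajectories <- function(locs, search_radius_nm = 500, min_len = 5) {
  if (is.null(locs) || nrow(locs) == 0) {
    out <- cbind(data.frame(traj_id = integer(0)),
                 locs[integer(0), , drop = FALSE])
    return(out)
  }
  stopifnot(all(c("x_nm", "y_nm", "frame") %in% names(locs)),
            search_radius_nm > 0, min_len >= 1)
  o <- order(locs$frame)
  locs <- locs[o, , drop = FALSE]
  rownames(locs) <- NULL
  frames <- sort(unique(locs$frame))
  by_frame <- split(seq_len(nrow(locs)), factor(locs$frame, levels = frames))
  r2 <- search_radius_nm^2

  traj_of <- integer(nrow(locs))          # trajectory id per localization row
  next_id <- 0L
  # open trajectory ends after the current frame: row indices of last spots
  open_rows <- integer(0)

  for (fi in seq_along(frames)) {
    rows <- by_frame[[fi]]
    if (fi == 1L || frames[fi] != frames[fi - 1L] + 1L) {
      open_rows <- integer(0)             # frame gap: everything terminates
    }
    if (length(open_rows) == 0) {
      traj_of[rows] <- next_id + seq_along(rows)
      next_id <- next_id + length(rows)
      open_rows <- rows
      next
    }
    A <- open_rows; B <- rows
    d2 <- outer(locs$x_nm[A], locs$x_nm[B], "-")^2 +
          outer(locs$y_nm[A], locs$y_nm[B], "-")^2
    cand <- d2 <= r2
    match_b <- .solve_assignment(d2, cand, r2)   # per A: B column index or NA
    linked_b <- logical(length(B))
    for (ai in seq_along(A)) {
      bi <- match_b[ai]
      if (!is.na(bi)) {
        traj_of[B[bi]] <- traj_of[A[ai]]
        linked_b[bi] <- TRUE
      }
    }
    new_b <- B[!linked_b]
    traj_of[new_b] <- next_id + seq_along(new_b)
    next_id <- next_id + length(new_b)
    open_rows <- B
  }

  len <- table(traj_of)
  keep_ids <- as.integer(names(len)[len >= min_len])
  keep <- traj_of %in% keep_ids
  out <- cbind(data.frame(traj_id = match(traj_of[keep], sort(keep_ids))),
               locs[keep, , drop = FALSE])
  out <- out[order(out$traj_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exact max-gain bipartite matching restricted to candidate pairs.
# d2: |A| x |B| squared distances; cand: logical candidacy; gain = r2 - d2.
# Returns, for each row of d2, the matched column or NA. Ties resolved in
# favor of the first assignment found when choices are explored in
# (A ascending, B ascending, then "unmatched") order.
.solve_assignment <- function(d2, cand, r2) {
  nA <- nrow(d2); nB <- ncol(d2)
  match_b <- rep(NA_integer_, nA)
  if (!any(cand)) return(match_b)

  # connected components over the bipartite candidate graph
  comp_a <- integer(nA); comp_b <- integer(nB); nc <- 0L
  for (a0 in seq_len(nA)) {
    if (comp_a[a0] != 0L || !any(cand[a0, ])) next
    nc <- nc + 1L
    qa <- a0
    while (length(qa)) {
      a <- qa[1]; qa <- qa[-1]
      if (comp_a[a] != 0L) next
      comp_a[a] <- nc
      bs <- which(cand[a, ] & comp_b == 0L)
      comp_b[bs] <- nc
      for (b in bs) qa <- c(qa, which(cand[, b] & comp_a == 0L))
    }
  }

  for (cc in seq_len(nc)) {
    as <- which(comp_a == cc); bs <- which(comp_b == cc)
    gain <- matrix(0, length(as), length(bs))
    ok <- cand[as, bs, drop = FALSE]
    gain[ok] <- (r2 - d2[as, bs, drop = FALSE])[ok]
    best <- .enumerate_matching(gain, ok)
    for (k in seq_along(as))
      if (!is.na(best[k])) match_b[as[k]] <- bs[best[k]]
  }
  match_b
}

# Depth-first enumeration with an upper-bound prune; strict improvement only,
# so the first optimum in exploration order wins ties.
.enumerate_matching <- function(gain, ok) {
  nA <- nrow(gain); nB <- ncol(gain)
  best_val <- -Inf; best_asg <- rep(NA_integer_, nA)
  row_max <- apply(gain, 1, function(g) max(c(g, 0)))
  suffix_bound <- rev(cumsum(rev(row_max)))
  asg <- rep(NA_integer_, nA)
  used <- logical(nB)
  rec <- function(k, val) {
    if (k > nA) {
      if (val > best_val) { best_val <<- val; best_asg <<- asg }
      return(invisible())
    }
    if (val + suffix_bound[k] <= best_val) return(invisible())
    for (b in which(ok[k, ] & !used)) {
      used[b] <<- TRUE; asg[k] <<- b
      rec(k + 1L, val + gain[k, b])
      used[b] <<- FALSE; asg[k] <<- NA_integer_
    }
    rec(k + 1L, val)                       # leave A-node k unmatched
  }
  rec(1L, 0)
  best_asg
}
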