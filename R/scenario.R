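# Parsimony inference over the karyotype event calculus.

# all single-event neighbors of k under the segment-conserving move set
# {fission, telomeric fusion (4 end joins), inversion}; returns a list of
# list(event, karyotype, key)
neighbor_states <- function(k) {
  out <- list()
  nch <- n_chromosomes(k)
  lens <- lengths(k$chromosomes)
  # fissions
  for (i in seq_len(nch)) {
    if (lens[i] < 2) next
    for (p in seq_len(lens[i] - 1L)) {
      ev <- ev_fission(i, p)
      k2 <- apply_event(k, ev)
      out[[length(out) + 1L]] <- list(event = ev, k = k2)
    }
  }
  # telomeric fusions, all four end joins
  if (nch >= 2) {
    for (i in seq_len(nch - 1L)) for (j in (i + 1L):nch) {
      for (f1 in c(FALSE, TRUE)) for (f2 in c(FALSE, TRUE)) {
        ev <- ev_fusion(i, j, f1, f2)
        k2 <- apply_event(k, ev)
        out[[length(out) + 1L]] <- list(event = ev, k = k2)
      }
    }
  }
  # inversions (a full-chromosome inversion is only a reading change)
  for (i in seq_len(nch)) {
    L <- lens[i]
    for (a in seq_len(L)) for (b in a:L) {
      if (a == 1L && b == L) next
      ev <- ev_inversion(i, a, b)
      k2 <- apply_event(k, ev)
      out[[length(out) + 1L]] <- list(event = ev, k = k2)
    }
  }
  for (i in seq_along(out)) out[[i]]$key <- canonical_key(out[[i]]$k)
  out
}

# forward BFS from `k` up to `depth`, returning an environment mapping
# key -> list(karyotype, events-from-root); stops early if `stop_key` found
bfs_forward <- function(k, depth, stop_key = NULL) {
  seen <- new.env(parent = emptyenv())
  root_key <- canonical_key(k)
  assign(root_key, list(k = k, events = list(), depth = 0L), envir = seen)
  frontier <- list(list(k = k, key = root_key, events = list()))
  d <- 0L
  while (d < depth && length(frontier) > 0) {
    d <- d + 1L
    nxt <- list()
    for (node in frontier) {
      for (nb in neighbor_states(node$k)) {
        if (!is.null(get0(nb$key, envir = seen))) next
        rec <- list(k = nb$k, events = c(node$events, list(nb$event)),
                    depth = d)
        assign(nb$key, rec, envir = seen)
        nxt[[length(nxt) + 1L]] <- list(k = nb$k, key = nb$key,
                                        events = rec$events)
        if (!is.null(stop_key) && nb$key == stop_key) return(seen)
      }
    }
    frontier <- nxt
  }
  seen
}

#' Infer a minimal rearrangement scenario between two karyotypes
#'
#' Exact mode runs a (bidirectional) breadth-first search over canonical
#' karyotype states using the segment-conserving moves — fission, telomeric
#' fusion (all four end joins) and inversion — and returns a provably
#' minimal scenario when the target is reachable within `budget` events.
#' Heuristic mode decomposes the start karyotype into single-segment
#' chromosomes by fissions and rebuilds the target by fusions; the result
#' is always a valid scenario and an upper bound on the minimum.
#'
#' @param start,target `karyotype` objects over the same segment alphabet.
#' @param budget maximum number of events for the exact search.
#' @param mode `"exact"` or `"heuristic"`.
#' @return list with `status` (`"found"` or `"not_found"`), `mode`,
#'   `n_events`, and `scenario` (a `pk_scenario`, replaying `start` to a
#'   karyotype canonically equal to `target`). In exact mode an
#'   unreachable target within budget gives `status = "not_found"`.
#' @export
infer_min_events <- function(start, target, budget = 6,
                             mode = c("exact", "heuristic")) {
  mode <- match.arg(mode)
  pk_assert(setequal(seg_labels(start), seg_labels(target)),
            "start and target must share the same segment alphabet")
  if (mode == "heuristic") return(heuristic_scenario(start, target))
  key_s <- canonical_key(start)
  key_t <- canonical_key(target)
  if (key_s == key_t)
    return(list(status = "found", mode = "exact", n_events = 0L,
                scenario = replay(start, list())))
  d1 <- ceiling(budget / 2)
  d2 <- budget - d1
  fwd <- bfs_forward(start, d1, stop_key = key_t)
  hit <- get0(key_t, envir = fwd)
  best <- NULL
  if (!is.null(hit)) {
    best <- list(d = hit$depth, events = hit$events)
  } else if (d2 > 0) {
    bwd <- bfs_forward(target, d2)
    # meet in the middle at the smallest combined depth
    for (key in ls(fwd)) {
      b <- get0(key, envir = bwd)
      if (is.null(b)) next
      f <- get(key, envir = fwd)
      if (is.null(best) || f$depth + b$depth < best$d)
        best <- list(d = f$depth + b$depth, meet = key, f = f, b = b)
    }
    if (!is.null(best) && is.null(best$events)) {
      # certificate for the second half: a short forward search from the
      # meeting state (a concrete karyotype on the start side)
      tail_bfs <- bfs_forward(best$f$k, best$b$depth, stop_key = key_t)
      tail_rec <- get0(key_t, envir = tail_bfs)
      pk_assert(!is.null(tail_rec), "internal: meet-in-middle tail not found")
      best$events <- c(best$f$events, tail_rec$events)
    }
  }
  if (is.null(best))
    return(list(status = "not_found", mode = "exact", n_events = NA_integer_,
                scenario = NULL, budget = budget))
  list(status = "found", mode = "exact", n_events = length(best$events),
       scenario = replay(start, best$events))
}

# decompose-and-rebuild upper bound: fission start to singletons, then
# rebuild each target chromosome left to right by telomeric fusions
heuristic_scenario <- function(start, target) {
  events <- list()
  k <- start
  repeat {
    lens <- lengths(k$chromosomes)
    i <- which(lens > 1)[1]
    if (is.na(i)) break
    ev <- ev_fission(i, 1L)
    events[[length(events) + 1L]] <- ev
    k <- apply_event(k, ev)
  }
  lbl_k <- seg_labels(k)
  lbl_t <- seg_labels(target)
  find_singleton <- function(k, label, used) {
    for (i in seq_along(k$chromosomes)) {
      x <- k$chromosomes[[i]]
      if (length(x) == 1 && !(i %in% used) && lbl_k[abs(x)] == label)
        return(i)
    }
    NA_integer_
  }
  # grow each target chromosome; `cur` is the index being extended
  for (tc in target$chromosomes) {
    labels <- lbl_t[abs(tc)]
    signs <- sign(tc)
    i0 <- find_singleton(k, labels[1], integer(0))
    pk_assert(!is.na(i0), "segment '%s' missing from start", labels[1])
    cur <- i0
    cur_sign <- sign(k$chromosomes[[cur]][1])
    if (cur_sign != signs[1]) {
      # orientation of the seed singleton is fixed by flipping at first join
      flip_first <- TRUE
    } else flip_first <- FALSE
    if (length(tc) >= 2) for (j in 2:length(tc)) {
      nxt <- find_singleton(k, labels[j], cur)
      pk_assert(!is.na(nxt), "segment '%s' missing from start", labels[j])
      seg_sign <- sign(k$chromosomes[[nxt]][1])
      ev <- ev_fusion(cur, nxt, flip1 = if (j == 2) flip_first else FALSE,
                      flip2 = seg_sign != signs[j])
      events[[length(events) + 1L]] <- ev
      k <- apply_event(k, ev)
      if (nxt < cur) cur <- cur - 1L
    }
  }
  sc <- replay(start, events)
  pk_assert(karyotypes_equal(sc$end, target),
            "internal: heuristic rebuild failed")
  list(status = "found", mode = "heuristic", n_events = length(events),
       scenario = sc)
}
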