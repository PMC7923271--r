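# Circular signed gene-order comparison: breakpoint distance, conserved
# blocks, single-event classification and bounded scenario search over
# reversals, transpositions, reverse transpositions and tandem
# duplication-random loss (TDRL).
#
# Internally an order is a signed integer vector: token i of the reference
# order gets id i, the sign encodes the coding strand. The circle is
# quotiented by rotation and mirror (reading the other strand) through
# canonicalization: id 1 first, positive. Every event therefore acts on a
# block that does not contain position 1; this loses no generality because
# reversing/moving a block containing the anchor equals acting on its
# complement up to rotation and mirror.

order_ints <- function(ord, ref_tokens) {
  ord$sign * match(ord$token, ref_tokens)
}

canonical_ints <- function(v) {
  i <- which(abs(v) == 1)
  if (v[i] < 0) {
    v <- rev(-v)
    i <- which(abs(v) == 1)
  }
  if (i > 1) v <- c(v[i:length(v)], v[seq_len(i - 1)])
  v
}

ints_to_order <- function(v, ref_tokens) {
  new_gene_order(ref_tokens[abs(v)], sign(v))
}

order_key <- function(v) paste(v, collapse = ",")

check_same_tokens <- function(a, b) {
  if (!setequal(a$token, b$token) || nrow(a) != nrow(b)) {
    abort("gene orders are over different token sets", class = "mito_data_error")
  }
}

#' Breakpoint distance between circular signed gene orders
#'
#' Counts the signed adjacencies (ordered neighbour pairs around the circle,
#' with \eqn{(x, y) \equiv (-y, -x)} since the circle may be read from
#' either strand) present in `a` but absent from `b`. The count is symmetric
#' and zero exactly for equivalent orders.
#'
#' @param a,b `gene_order` objects over the same token set.
#' @return Non-negative integer.
#' @export
breakpoint_distance <- function(a, b) {
  check_same_tokens(a, b)
  ref <- a$token
  va <- canonical_ints(order_ints(a, ref))
  vb <- canonical_ints(order_ints(b, ref))
  adj_keys <- function(v) {
    nxt <- c(v[-1], v[1])
    vapply(seq_along(v), function(i) {
      k1 <- paste(v[i], nxt[i], sep = "|")
      k2 <- paste(-nxt[i], -v[i], sep = "|")
      min(k1, k2)
    }, "")
  }
  sum(!adj_keys(va) %in% adj_keys(vb))
}

#' Maximal conserved blocks of two circular signed gene orders
#'
#' A conserved block is a run of tokens contiguous in both circles with a
#' consistent relative orientation (same signed sequence, or the reversed
#' sequence with flipped signs). All maximal blocks are returned, in `a`'s
#' reading frame.
#'
#' @inheritParams breakpoint_distance
#' @return Tibble with `length` and a list-column `tokens` of signed token
#'   vectors (a leading `-` marks the minus strand).
#' @export
conserved_blocks <- function(a, b) {
  check_same_tokens(a, b)
  ref <- a$token
  va <- canonical_ints(order_ints(a, ref))
  vb <- canonical_ints(order_ints(b, ref))
  n <- length(va)
  pos_b <- integer(n); sgn_b <- integer(n)
  pos_b[abs(vb)] <- seq_len(n)
  sgn_b[abs(vb)] <- sign(vb)
  arc_ok <- function(s, l) {
    idx <- ((s - 1 + 0:(l - 1)) %% n) + 1
    x <- va[idx]
    p <- pos_b[abs(x)]
    if (l == 1) return(TRUE)
    fwd <- all((p[-1] - p[-l]) %% n == 1) &&
      all(sgn_b[abs(x)] == sign(x))
    bwd <- all((p[-l] - p[-1]) %% n == 1) &&
      all(sgn_b[abs(x)] == -sign(x))
    fwd || bwd
  }
  if (arc_ok(1, n)) {
    tok <- ifelse(va < 0, paste0("-", ref[abs(va)]), ref[abs(va)])
    return(tibble::tibble(length = n, tokens = list(tok)))
  }
  blocks <- list()
  for (s in seq_len(n)) {
    for (l in seq_len(n - 1)) {
      if (!arc_ok(s, l)) break
      # maximal iff no conserved extension on either side
      if (l < n - 1 && (arc_ok(s, l + 1) || arc_ok((s - 2) %% n + 1, l + 1))) next
      idx <- ((s - 1 + 0:(l - 1)) %% n) + 1
      x <- va[idx]
      blocks[[length(blocks) + 1]] <-
        ifelse(x < 0, paste0("-", ref[abs(x)]), ref[abs(x)])
    }
  }
  # a shorter block starting inside a longer one was already skipped by the
  # extension test; drop any residual duplicates/contained runs
  pad <- function(x) paste0(" ", paste(x, collapse = " "), " ")
  keys <- vapply(blocks, pad, "")
  blocks <- blocks[!duplicated(keys)]
  lens <- vapply(blocks, length, 0L)
  contained <- vapply(seq_along(blocks), function(i) {
    any(vapply(seq_along(blocks), function(j) {
      i != j && lens[j] > lens[i] &&
        grepl(pad(blocks[[i]]), pad(c(blocks[[j]], blocks[[j]])), fixed = TRUE)
    }, TRUE))
  }, TRUE)
  blocks <- blocks[!contained]
  lens <- lens[!contained]
  ord <- order(-lens)
  tibble::tibble(length = lens[ord], tokens = blocks[ord])
}

# ----------------------------------------------------------------- events

#' Construct a rearrangement event
#'
#' Events are expressed in the canonical linearization of the order they
#' apply to (position 1 is the anchor gene and never moves). `start`/`end`
#' delimit the block; `dest` is the position (after block removal) after
#' which a transposed block is re-inserted; `partition` is a logical vector
#' over positions, `TRUE` marking tokens retained from the first copy in a
#' tandem duplication-random loss.
#'
#' @param kind One of `reversal`, `transposition`, `reverse_transposition`,
#'   `tdrl`.
#' @param start,end,dest,partition See above.
#' @return A `rearrangement_event`.
#' @export
rearrangement_event <- function(kind, start = NULL, end = NULL, dest = NULL,
                                partition = NULL) {
  kind <- match.arg(kind, c("reversal", "transposition",
                            "reverse_transposition", "tdrl"))
  structure(list(kind = kind, start = start, end = end, dest = dest,
                 partition = partition),
            class = "rearrangement_event")
}

#' @export
print.rearrangement_event <- function(x, ...) {
  cat(sprintf("<event> %s%s\n", x$kind,
              if (x$kind == "tdrl") {
                sprintf(" (first copy keeps %d tokens)", sum(x$partition))
              } else {
                sprintf(" block %d..%d%s", x$start, x$end,
                        if (!is.null(x$dest)) paste0(" -> after ", x$dest) else "")
              }))
  invisible(x)
}

apply_event_ints <- function(v, e) {
  n <- length(v)
  switch(e$kind,
    reversal = {
      v[e$start:e$end] <- -rev(v[e$start:e$end])
      v
    },
    transposition = ,
    reverse_transposition = {
      block <- v[e$start:e$end]
      if (e$kind == "reverse_transposition") block <- -rev(block)
      rest <- v[-(e$start:e$end)]
      append(rest, block, after = e$dest)
    },
    tdrl = c(v[e$partition], v[!e$partition])
  )
}

#' Apply a rearrangement event to a gene order
#'
#' Reversal flips the block order and all signs; a (reverse) transposition
#' moves (and possibly reverses) the block; TDRL duplicates the linearized
#' circle and deletes one copy of every gene according to the partition.
#' The result is re-canonicalized.
#'
#' @param order A `gene_order`.
#' @param e A [rearrangement_event()].
#' @return The rearranged `gene_order`.
#' @export
apply_event <- function(order, e) {
  v <- canonical_ints(order_ints(order, order$token))
  n <- length(v)
  if (e$kind == "tdrl") {
    if (length(e$partition) != n) abort("invalid tdrl partition")
  } else {
    if (is.null(e$start) || e$start < 2 || e$end < e$start || e$end > n) {
      abort("invalid event block")
    }
    if (e$kind != "reversal") {
      if (is.null(e$dest) || e$dest < 0 || e$dest > n - (e$end - e$start + 1)) {
        abort("invalid transposition destination")
      }
    }
  }
  ints_to_order(canonical_ints(apply_event_ints(v, e)), order$token)
}

# Test whether vb is one TDRL step from va. After a tandem duplication of
# the linearized circle and loss of one copy of every gene, the copy-1
# survivors form a contiguous arc followed by the copy-2 survivors; since
# the anchor has the minimal source position, the canonical linearization of
# the result is an increasing prefix followed by an increasing suffix of
# va-positions, with signs unchanged. Returns the copy-1 partition (logical
# over va's positions) or NULL.
tdrl_partition <- function(va, vb) {
  n <- length(va)
  sgn_a <- integer(n); sgn_a[abs(va)] <- sign(va)
  if (!all(sgn_a[abs(vb)] == sign(vb))) return(NULL)
  pos_a <- integer(n); pos_a[abs(va)] <- seq_len(n)
  p <- pos_a[abs(vb)]
  desc <- which(diff(p) < 0)
  if (!length(desc)) return(NULL)  # identical order, not an event
  k <- desc[1]
  if (any(diff(p[(k + 1):n]) < 0)) return(NULL)  # suffix must be increasing
  seq_len(n) %in% p[seq_len(k)]
}

# enumerate single events from canonical vector v in the fixed priority
# order (reversal > transposition > reverse_transposition); tdrl handled
# separately by the partition test. Callback fn(e, w) returning TRUE stops.
visit_neighbors <- function(v, fn, kinds = c("reversal", "transposition",
                                             "reverse_transposition")) {
  n <- length(v)
  for (kind in kinds) {
    if (kind == "reversal") {
      for (s in 2:n) for (e in s:n) {
        ev <- rearrangement_event("reversal", s, e)
        if (fn(ev, canonical_ints(apply_event_ints(v, ev)))) return(invisible(TRUE))
      }
    } else {
      for (s in 2:n) for (e in s:n) {
        l <- e - s + 1
        if (l == n - 1) next  # moving everything but the anchor is a rotation
        # dest = 0 (front) is circularly the same placement as dest = n - l
        for (d in seq_len(n - l)) {
          if (d == s - 1) next  # identity placement
          ev <- rearrangement_event(kind, s, e, dest = d)
          if (fn(ev, canonical_ints(apply_event_ints(v, ev)))) return(invisible(TRUE))
        }
      }
    }
  }
  invisible(FALSE)
}

#' Classify the single rearrangement event separating two gene orders
#'
#' Tests, in the fixed priority order reversal > transposition >
#' reverse transposition > TDRL, whether `b` is reachable from `a` by
#' exactly one event; ties (a transposition is always also a TDRL) resolve
#' by that priority.
#'
#' @inheritParams breakpoint_distance
#' @return A [rearrangement_event()], or `NULL` when no single event
#'   suffices (including identical orders).
#' @export
classify_single_event <- function(a, b) {
  check_same_tokens(a, b)
  ref <- a$token
  va <- canonical_ints(order_ints(a, ref))
  vb <- canonical_ints(order_ints(b, ref))
  if (identical(va, vb)) return(NULL)
  target <- order_key(vb)
  found <- NULL
  visit_neighbors(va, function(ev, w) {
    if (order_key(w) == target) {
      found <<- ev
      TRUE
    } else FALSE
  })
  if (!is.null(found)) return(found)
  part <- tdrl_partition(va, vb)
  if (!is.null(part)) return(rearrangement_event("tdrl", partition = part))
  NULL
}

#' Shortest rearrangement scenario between two gene orders
#'
#' Breadth-first search over the event space (with rotation/mirror
#' deduplication) for a shortest sequence of at most `max_events` events
#' transforming `a` into `b`. The search is bidirectional; TDRL events are
#' tested as scenario-closing steps (their neighbourhoods are exponentially
#' large). With more than 2 events the search is restricted to small orders
#' (at most 14 tokens). Ties follow the event priority and leftmost block.
#'
#' @inheritParams breakpoint_distance
#' @param max_events Search bound, at most 4.
#' @return A `rearrangement_scenario`: list with `events` (possibly empty;
#'   `NULL` when the bound is exceeded), `found`, and the
#'   `breakpoint_distance`.
#' @export
infer_scenario <- function(a, b, max_events = 2) {
  check_same_tokens(a, b)
  stopifnot(max_events >= 0, max_events <= 4)
  ref <- a$token
  va <- canonical_ints(order_ints(a, ref))
  vb <- canonical_ints(order_ints(b, ref))
  n <- length(va)
  bd <- breakpoint_distance(a, b)
  done <- function(events, found = TRUE) {
    structure(list(events = events, found = found, source = a, target = b,
                   breakpoint_distance = bd),
              class = "rearrangement_scenario")
  }
  if (identical(va, vb)) return(done(list()))
  if (max_events >= 1) {
    e1 <- classify_single_event(a, b)
    if (!is.null(e1)) return(done(list(e1)))
  }
  if (max_events >= 2) {
    if (max_events > 2 && n > 14) {
      abort("scenario search beyond 2 events needs a reduced token set (<= 14)")
    }
    res <- scenario_bfs(va, vb, ref, max_events)
    if (!is.null(res)) return(done(res))
  }
  done(NULL, found = FALSE)
}

# meet-in-the-middle search, depth >= 2; returns event list or NULL
scenario_bfs <- function(va, vb, ref, max_events) {
  # backward 1-neighbourhood of the target (reversal/transpositions are
  # closed under inversion, so these keys are exactly the orders one
  # non-TDRL event away from vb)
  back1 <- new.env(parent = emptyenv())
  visit_neighbors(vb, function(ev, w) {
    assign(order_key(w), TRUE, envir = back1)
    FALSE
  })
  key_b <- order_key(vb)
  events_from_path <- function(vecs) {
    purrr::map2(vecs[-length(vecs)], vecs[-1], function(x, y) {
      classify_single_event(ints_to_order(x, ref), ints_to_order(y, ref))
    })
  }
  # depth 2 (any n)
  hit <- NULL
  visit_neighbors(va, function(ev, w) {
    k <- order_key(w)
    if (exists(k, envir = back1, inherits = FALSE) ||
        !is.null(tdrl_partition(w, vb))) {
      hit <<- w
      TRUE
    } else FALSE
  })
  if (!is.null(hit)) return(events_from_path(list(va, hit, vb)))
  if (max_events < 3) return(NULL)
  # deeper levels, small n only: plain forward BFS storing paths
  frontier <- list(list(va))
  seen <- new.env(parent = emptyenv())
  assign(order_key(va), TRUE, envir = seen)
  for (depth in 2:(max_events - 1)) {
    nxt <- list()
    for (path in frontier) {
      v <- path[[length(path)]]
      visit_neighbors(v, function(ev, w) {
        k <- order_key(w)
        if (!exists(k, envir = seen, inherits = FALSE)) {
          assign(k, TRUE, envir = seen)
          nxt[[length(nxt) + 1]] <<- c(path, list(w))
        }
        FALSE
      })
    }
    frontier <- nxt
    for (path in frontier) {
      v <- path[[length(path)]]
      if (exists(order_key(v), envir = back1, inherits = FALSE) ||
          !is.null(tdrl_partition(v, vb))) {
        return(events_from_path(c(path, list(vb))))
      }
    }
  }
  NULL
}

#' @export
print.rearrangement_scenario <- function(x, ...) {
  if (!x$found) {
    cat(sprintf("<scenario> not found within bound (breakpoint distance %d)\n",
                x$breakpoint_distance))
  } else if (!length(x$events)) {
    cat("<scenario> orders are equivalent (0 events)\n")
  } else {
    cat(sprintf("<scenario> %d event(s), breakpoint distance %d:\n",
                length(x$events), x$breakpoint_distance))
    for (e in x$events) print(e)
  }
  invisible(x)
}

#' @export
#' @method tidy rearrangement_scenario
tidy.rearrangement_scenario <- function(x, ...) {
  if (!x$found || !length(x$events)) {
    return(tibble::tibble(step = integer(), kind = character(),
                          start = integer(), end = integer(), dest = integer()))
  }
  dplyr::bind_rows(purrr::imap(x$events, function(e, i) {
    tibble::tibble(step = i, kind = e$kind,
                   start = e$start %||% NA_integer_,
                   end = e$end %||% NA_integer_,
                   dest = e$dest %||% NA_integer_)
  }))
}
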